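#' Domain maps for P450 proteins
#'
#' A domain map is a tibble describing the conserved cytochrome P450 regions
#' on a reference protein: the six substrate recognition sites (SRS1-6), the
#' I-helix (a subcomponent of SRS4), the K-helix, the ERR-triad/PERF motif,
#' the heme-binding motif and the N-terminal transmembrane anchor. Columns:
#'
#' \describe{
#'   \item{domain}{Name, unique.}
#'   \item{start_aa, end_aa}{1-based inclusive residue interval.}
#'   \item{consensus}{Residue text on the reference.}
#'   \item{essential}{Logical; whether loss of the region is treated as
#'     abolishing enzyme activity. The transmembrane anchor is never
#'     essential.}
#' }
#'
#' @param map A domain map tibble.
#' @param protein_length Reference protein length used for validation.
#' @return \code{validate_domain_map} returns the map invisibly or errors.
#' @name domain_map
NULL

DOMAIN_ORDER <- c("transmembrane", "SRS1", "SRS2", "SRS3", "SRS4", "I-helix",
                  "K-helix", "SRS5", "ERR-triad", "heme-binding", "SRS6")

#' @rdname domain_map
#' @export
validate_domain_map <- function(map, protein_length = NULL) {
  need <- c("domain", "start_aa", "end_aa", "consensus", "essential")
  if (!all(need %in% names(map)))
    stop("domain map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(map$domain))
    stop("domain names must be unique", call. = FALSE)
  if (any(map$end_aa < map$start_aa))
    stop("domain intervals must satisfy start_aa <= end_aa", call. = FALSE)
  if (!is.null(protein_length) && any(map$end_aa > protein_length))
    stop("domain intervals exceed protein length", call. = FALSE)
  srs <- paste0("SRS", 1:6)
  present <- srs[srs %in% map$domain]
  starts <- map$start_aa[match(present, map$domain)]
  if (is.unsorted(starts))
    stop("SRS domains must occur in order SRS1 < ... < SRS6", call. = FALSE)
  invisible(map)
}

#' Read or write a domain map as TSV
#'
#' Tab-separated with columns name, start, end, essential (0/1), consensus.
#'
#' @param path File path.
#' @return \code{read_domain_map} returns a domain map tibble.
#' @export
read_domain_map <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  map <- tibble(
    domain = as.character(raw$name),
    start_aa = as.integer(raw$start),
    end_aa = as.integer(raw$end),
    consensus = as.character(raw$consensus),
    essential = as.integer(raw$essential) == 1L
  )
  validate_domain_map(map)
  map
}

#' @rdname read_domain_map
#' @param map Domain map tibble to serialize.
#' @export
write_domain_map <- function(map, path) {
  validate_domain_map(map)
  out <- data.frame(name = map$domain, start = map$start_aa,
                    end = map$end_aa, essential = as.integer(map$essential),
                    consensus = map$consensus)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default essential-domain set
#'
#' The regions whose loss is treated as abolishing P450 activity: SRS1-SRS6,
#' the I-helix, K-helix, ERR-triad and the heme-binding motif — the union of
#' the features repeatedly implicated in null alleles of flavonoid
#' hydroxylase genes. The transmembrane anchor is excluded.
#'
#' @return Character vector of domain names.
#' @export
essential_domains <- function() {
  setdiff(DOMAIN_ORDER, "transmembrane")
}
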