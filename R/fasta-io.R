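#' Read sequences from a FASTA file
#'
#' Multi-record FASTA (wrapped or unwrapped lines); sequences are upper-cased
#' on read.
#'
#' @param path File path.
#' @param type \code{"dna"} or \code{"protein"}.
#' @return Tibble with columns \code{id} (first word of the header) and
#'   \code{sequence}.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  tibble(
    id = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    sequence = unname(toupper(as.character(set)))
  )
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble (or data frame) with columns \code{id} and \code{sequence}.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[i]), con)
    s <- x$sequence[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
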