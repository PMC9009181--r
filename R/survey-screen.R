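#' Rule-based hydroxylase proteome screen
#'
#' Applies, in order: the fuzzy heme-binding motif search
#' ([find_heme_motif()]), domain projection against the annotated reference
#' with a completeness check over the essential set, and SRS6 hydroxylase
#' classification ([classify_srs6()]). Every intermediate outcome is
#' recorded; nothing is silently dropped.
#'
#' @param proteins Tibble with columns \code{id} and \code{sequence} (or a
#'   named character vector of residue strings).
#' @param reference Reference object (protein + domain map) or a residue
#'   string (then \code{ref_map} is required).
#' @param ref_map Optional domain map override.
#' @param max_mismatch Heme-motif mismatch tolerance (default 2).
#' @param rule_index SRS6 rule position (default 8).
#' @param essential Character vector of domain names that must be present
#'   for \code{domains_complete}.
#' @return Tibble with one row per protein: \code{id},
#'   \code{heme_motif_found}, \code{heme_motif_position},
#'   \code{domains_complete}, \code{failing_domains} (list-column),
#'   \code{srs6_residue}, \code{hydroxylase_class}, \code{passed_filter}.
#' @examples
#' ref <- make_reference()
#' screen_proteome(c(query = ref$protein), ref)$passed_filter
#' @export
screen_proteome <- function(proteins, reference, ref_map = NULL,
                            max_mismatch = 2L, rule_index = 8L,
                            essential = essential_domains()) {
  proteins <- as_protein_panel(proteins)
  if (is.null(ref_map)) ref_map <- reference$domain_map
  ref_prot <- if (inherits(reference, "flavhap_reference"))
    reference$protein else reference
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- proteins$sequence[i]
    hm <- find_heme_motif(p, max_mismatch = max_mismatch)
    status <- project_domains(p, ref_prot, ref_map)
    ess <- status[status$domain %in% essential, ]
    failing <- ess$domain[ess$status != "present"]
    complete <- length(failing) == 0L
    srs6 <- classify_srs6(status, rule_index = rule_index)
    tibble(id = proteins$id[i],
           heme_motif_found = !is.na(hm),
           heme_motif_position = hm,
           domains_complete = complete,
           failing_domains = list(failing),
           srs6_residue = srs6$residue,
           hydroxylase_class = srs6$class,
           passed_filter = !is.na(hm) && complete && srs6$class != "unknown")
  })
  bind_rows(rows)
}

as_protein_panel <- function(proteins) {
  if (is.data.frame(proteins)) {
    stopifnot(all(c("id", "sequence") %in% names(proteins)))
    return(as_tibble(proteins))
  }
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
    return(tibble(id = ids, sequence = unname(proteins)))
  }
  stop("proteins must be a data frame or character vector", call. = FALSE)
}

#' Count unique domain sequences among screened proteins
#'
#' Exact-match deduplication of the projected domain texts for records that
#' passed the screen filter. Used to quantify per-domain variability (e.g.
#' which SRS is most variable across a survey).
#'
#' @param proteins Protein panel (as in [screen_proteome()]).
#' @param reference Reference object.
#' @param domain Domain name.
#' @param records Optionally a precomputed screen table to define the
#'   passing set.
#' @inheritParams screen_proteome
#' @return Integer count of distinct projected residue texts.
#' @export
unique_domain_sequences <- function(proteins, reference, domain,
                                    ref_map = NULL, records = NULL, ...) {
  proteins <- as_protein_panel(proteins)
  if (is.null(ref_map)) ref_map <- reference$domain_map
  if (!domain %in% ref_map$domain)
    stop("unknown domain: ", domain, call. = FALSE)
  if (is.null(records)) records <- screen_proteome(proteins, reference,
                                                   ref_map = ref_map, ...)
  passing <- proteins[proteins$id %in% records$id[records$passed_filter], ]
  if (nrow(passing) == 0L)
    stop("no records pass the screen filter", call. = FALSE)
  ref_prot <- if (inherits(reference, "flavhap_reference"))
    reference$protein else reference
  texts <- vapply(passing$sequence, function(p) {
    st <- project_domains(p, ref_prot, ref_map)
    st$query_text[st$domain == domain]
  }, character(1))
  texts <- texts[!is.na(texts)]
  if (length(texts) == 0L)
    stop("domain ", domain, " absent from all passing records", call. = FALSE)
  length(unique(texts))
}

#' Per-column information content of aligned domain texts
#'
#' Shannon information in bits per alignment column over the 20 amino
#' acids: \eqn{I = \log_2 20 - H} with
#' \eqn{H = -\sum p \log_2 p} over the observed residues. Gap characters
#' keep their column fraction but carry no frequency mass. The optional
#' small-sample correction subtracts
#' \eqn{e_n = \frac{1}{\ln 2}\,\frac{19}{2n}}.
#'
#' @param texts Character vector of equal-length residue strings.
#' @param small_sample_correction Apply the correction (default FALSE).
#' @return A list of class \code{"flavhap_logo"}: \code{frequencies}
#'   (tibble: \code{column}, \code{residue}, \code{frequency}),
#'   \code{information} (tibble: \code{column}, \code{bits},
#'   \code{gap_fraction}), and \code{n}.
#' @examples
#' logo <- logo_information(c("AC", "AD", "AE", "AF"))
#' logo$information$bits[1]  # log2(20), invariant column
#' @export
logo_information <- function(texts, small_sample_correction = FALSE) {
  if (length(texts) == 0L) stop("no sequences supplied", call. = FALSE)
  lens <- unique(nchar(texts))
  if (length(lens) != 1L)
    stop("texts must be equal length (aligned)", call. = FALSE)
  n <- length(texts)
  chars <- do.call(rbind, strsplit(texts, "", fixed = TRUE))
  freq_rows <- list(); info_rows <- list()
  for (j in seq_len(lens)) {
    col <- chars[, j]
    gap_fraction <- mean(!col %in% AA_ALPHABET)
    res <- col[col %in% AA_ALPHABET]
    if (length(res) == 0L) {
      info_rows[[j]] <- tibble(column = j, bits = NA_real_,
                               gap_fraction = gap_fraction)
      next
    }
    tab <- table(res) / length(res)
    H <- -sum(tab * log2(tab))
    bits <- log2(20) - H
    if (small_sample_correction)
      bits <- max(bits - (1 / log(2)) * (19 / (2 * length(res))), 0)
    freq_rows[[j]] <- tibble(column = j, residue = names(tab),
                             frequency = as.numeric(tab))
    info_rows[[j]] <- tibble(column = j, bits = bits,
                             gap_fraction = gap_fraction)
  }
  structure(list(frequencies = bind_rows(freq_rows),
                 information = bind_rows(info_rows), n = n),
            class = "flavhap_logo")
}

#' @export
print.flavhap_logo <- function(x, ...) {
  cat("Sequence logo over ", x$n, " sequences, ",
      nrow(x$information), " columns; mean information ",
      sprintf("%.2f", mean(x$information$bits, na.rm = TRUE)),
      " bits\n", sep = "")
  invisible(x)
}

#' @method tidy flavhap_logo
#' @export
tidy.flavhap_logo <- function(x, ...) {
  left_join(x$frequencies, x$information, by = "column")
}
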