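#' Locate the P450 heme-binding motif by fuzzy ungapped matching
#'
#' Scans a protein for the best ungapped match to the conserved heme-binding
#' consensus (default \code{PFGAGRRICAG}) allowing up to
#' \code{max_mismatch} substitutions. Matching is substitution-only: a
#' gapped motif would fail the downstream completeness filter anyway.
#'
#' @param protein Residue string (or a one-row tibble from
#'   [translate_cds()]).
#' @param max_mismatch Maximum substitutions tolerated (default 2).
#' @param motif Motif consensus text.
#' @return 1-based start of the best (leftmost on ties) qualifying window,
#'   or \code{NA_integer_} when no window qualifies (including proteins
#'   shorter than the motif).
#' @examples
#' ref <- make_reference()
#' find_heme_motif(ref$protein, max_mismatch = 0)  # 460
#' @export
find_heme_motif <- function(protein, max_mismatch = 2L,
                            motif = "PFGAGRRICAG") {
  if (is.data.frame(protein)) protein <- protein$residues
  if (max_mismatch < 0) stop("max_mismatch must be >= 0", call. = FALSE)
  m <- seq_chars(motif)
  k <- length(m)
  n <- nchar(protein)
  if (n < k) return(NA_integer_)
  p <- seq_chars(protein)
  mism <- vapply(seq_len(n - k + 1L),
                 function(i) sum(p[i:(i + k - 1L)] != m), integer(1))
  best <- min(mism)
  if (best > max_mismatch) return(NA_integer_)
  which(mism == best)[1L]
}

#' Project reference domains onto a query protein
#'
#' Globally aligns the query to the annotated reference (BLOSUM62, affine
#' gaps) and maps every domain interval through the alignment columns. Each
#' domain is classified:
#'
#' \describe{
#'   \item{present}{all reference columns of the interval are aligned to
#'     query residues;}
#'   \item{truncated}{the interval loses residues to a gap run that extends
#'     to the end of the query (a premature stop upstream of or inside the
#'     domain);}
#'   \item{absent}{no query residue aligns anywhere in the interval;}
#'   \item{internal-deletion}{one or more gap columns fall strictly inside
#'     the aligned interval.}
#' }
#'
#' When alignment identity over the N-terminal 200 columns is below 30% the
#' query is reported \code{unalignable} for every domain (a non-homolog).
#'
#' @param query,reference Residue strings (query may also be a
#'   [translate_cds()] row).
#' @param ref_map Domain map tibble for the reference.
#' @return Tibble with one row per domain: \code{domain}, \code{status},
#'   \code{query_start}, \code{query_end}, \code{query_text},
#'   \code{essential}.
#' @export
project_domains <- function(query, reference, ref_map) {
  if (is.data.frame(query)) query <- query$residues
  if (is.data.frame(reference)) reference <- reference$residues
  validate_domain_map(ref_map, protein_length = nchar(reference))
  al <- align_global(reference, query, type = "protein")
  ra <- seq_chars(al$a_aln)
  qa <- seq_chars(al$b_aln)
  head_cols <- seq_len(min(200L, length(ra)))
  if (mean(ra[head_cols] == qa[head_cols]) < 0.30) {
    return(tibble(domain = ref_map$domain, status = "unalignable",
                  query_start = NA_integer_, query_end = NA_integer_,
                  query_text = NA_character_, essential = ref_map$essential))
  }
  ref_pos <- cumsum(ra != GAP)          # reference coordinate per column
  qry_pos <- cumsum(qa != GAP)          # query coordinate per column
  rows <- lapply(seq_len(nrow(ref_map)), function(i) {
    cols <- which(ref_pos >= ref_map$start_aa[i] &
                    ref_pos <= ref_map$end_aa[i] & ra != GAP)
    qchars <- qa[cols]
    aligned <- qchars != GAP
    # query_text is per reference column: positions within it correspond to
    # positions within the reference domain, with "-" marking deleted columns
    if (!any(aligned)) {
      status <- "absent"; qs <- NA_integer_; qe <- NA_integer_; qt <- NA_character_
    } else {
      qs <- qry_pos[cols[aligned][1L]]
      qe <- qry_pos[cols[aligned][length(cols[aligned])]]
      qt <- paste(qchars, collapse = "")
      if (all(aligned)) {
        status <- "present"
      } else {
        # does the gap run continue to the end of the query?
        last_gap_col <- cols[!aligned][sum(!aligned)]
        tail_is_gap <- all(qa[last_gap_col:length(qa)] == GAP)
        status <- if (tail_is_gap) "truncated" else "internal-deletion"
      }
    }
    tibble(domain = ref_map$domain[i], status = status,
           query_start = qs, query_end = qe, query_text = qt,
           essential = ref_map$essential[i])
  })
  bind_rows(rows)
}

#' Classify hydroxylase type from the SRS6 rule residue
#'
#' Flavonoid 3'5'-hydroxylases carry Ala or Ser at the SRS6 rule position
#' (the 8th residue of SRS6 by default), while flavonoid 3'-hydroxylases
#' carry Thr there. Anything else — including a gap or a missing SRS6 —
#' is \code{unknown}.
#'
#' @param status Domain-status tibble from [project_domains()].
#' @param rule_index Position within SRS6 of the discriminating residue.
#'   Defaults to 8; published descriptions of the rule differ between 8 and
#'   9, so the index is configurable.
#' @return A list with \code{class} (one of \code{"F35H"}, \code{"F3H"},
#'   \code{"unknown"}), \code{residue} and \code{reason}.
#' @export
classify_srs6 <- function(status, rule_index = 8L) {
  row <- status[status$domain == "SRS6", ]
  if (nrow(row) != 1L) stop("status lacks an SRS6 row", call. = FALSE)
  if (row$status %in% c("absent", "unalignable") || is.na(row$query_text))
    return(list(class = "unknown", residue = NA_character_,
                reason = "domain missing"))
  txt <- seq_chars(row$query_text)
  if (rule_index > length(txt))
    return(list(class = "unknown", residue = NA_character_,
                reason = "rule position beyond projected SRS6"))
  res <- txt[rule_index]
  if (res == GAP)
    return(list(class = "unknown", residue = res,
                reason = "gap at rule position"))
  cls <- if (res %in% c("A", "S")) "F35H" else if (res == "T") "F3H" else "unknown"
  list(class = cls, residue = res,
       reason = if (cls == "unknown") "non-diagnostic residue" else NA_character_)
}
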