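#' Call nucleotide variants between haplotypes and a reference CDS
#'
#' Derives SNP and indel calls from the left-normalized global alignment of
#' each haplotype against the reference. Adjacent gap columns merge into a
#' single indel event. Coordinates are 1-based reference CDS positions; for
#' indels \code{position} is the reference base immediately left of the
#' left-normalized event.
#'
#' @param panel Tibble with columns \code{haplotype} and \code{sequence}, a
#'   named character vector, or a single sequence string.
#' @param reference A [make_reference()] object or a reference CDS string.
#' @param min_identity Refuse to call when alignment identity falls below
#'   this fraction (default 0.5) — the sequences are not comparable.
#' @return Tibble with columns \code{haplotype}, \code{kind} (SNP,
#'   insertion, deletion), \code{position}, \code{ref}, \code{alt},
#'   \code{length}, sorted by haplotype then position.
#' @examples
#' ref <- make_reference()
#' pp <- make_natural_panel(ref)
#' call_variants(pp$panel, ref) |> dplyr::count(haplotype)
#' @export
call_variants <- function(panel, reference, min_identity = 0.5) {
  panel <- as_panel(panel)
  ref_cds <- ref_sequence(reference)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    v <- variants_one(panel$sequence[i], ref_cds, min_identity)
    if (nrow(v)) v$haplotype <- panel$haplotype[i]
    v
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0)
    return(tibble(haplotype = character(), kind = character(),
                  position = integer(), ref = character(),
                  alt = character(), length = integer()))
  out <- out[, c("haplotype", "kind", "position", "ref", "alt", "length")]
  out[order(out$haplotype, out$position), ]
}

as_panel <- function(panel) {
  if (is.data.frame(panel)) {
    stopifnot(all(c("haplotype", "sequence") %in% names(panel)))
    return(as_tibble(panel))
  }
  if (is.character(panel)) {
    ids <- names(panel)
    if (is.null(ids)) ids <- paste0("hap", seq_along(panel))
    return(tibble(haplotype = ids, sequence = unname(panel)))
  }
  stop("panel must be a data frame or character vector", call. = FALSE)
}

ref_sequence <- function(reference) {
  if (inherits(reference, "flavhap_reference")) reference$cds else reference
}

variants_one <- function(hap, ref_cds, min_identity) {
  empty <- tibble(haplotype = character(), kind = character(),
                  position = integer(), ref = character(),
                  alt = character(), length = integer())
  if (identical(hap, ref_cds)) return(empty)
  al <- align_global(ref_cds, hap, type = "dna")
  if (al$identity < min_identity)
    stop("not comparable: alignment identity ",
         sprintf("%.1f%%", 100 * al$identity), " below ",
         sprintf("%.0f%%", 100 * min_identity), call. = FALSE)
  ra <- seq_chars(al$a_aln)
  qa <- seq_chars(al$b_aln)
  ref_pos <- cumsum(ra != GAP)
  n <- length(ra)
  calls <- list()
  i <- 1L
  while (i <= n) {
    if (ra[i] != GAP && qa[i] != GAP) {
      if (ra[i] != qa[i])
        calls[[length(calls) + 1L]] <-
          tibble(kind = "SNP", position = ref_pos[i],
                 ref = ra[i], alt = qa[i], length = 1L)
      i <- i + 1L
    } else if (qa[i] == GAP) {          # deletion relative to reference
      j <- i
      while (j < n && qa[j + 1L] == GAP && ra[j + 1L] != GAP) j <- j + 1L
      calls[[length(calls) + 1L]] <-
        tibble(kind = "deletion", position = ref_pos[i] - 1L,
               ref = paste(ra[i:j], collapse = ""), alt = "",
               length = j - i + 1L)
      i <- j + 1L
    } else {                            # insertion relative to reference
      j <- i
      while (j < n && ra[j + 1L] == GAP && qa[j + 1L] != GAP) j <- j + 1L
      calls[[length(calls) + 1L]] <-
        tibble(kind = "insertion", position = ref_pos[i], ref = "",
               alt = paste(qa[i:j], collapse = ""), length = j - i + 1L)
      i <- j + 1L
    }
  }
  if (!length(calls)) return(empty)
  out <- bind_rows(calls)
  out$haplotype <- NA_character_
  out
}

#' Critical-residue catalogue
#'
#' Reference residues whose substitution is treated as impairing catalysis
#' even without any domain loss: the invariant SRS1 glycine, the SRS2 valine
#' under purifying selection, the positively selected SRS3 histidine and
#' SRS4 asparagine, the arginine adjacent to the PERF motif, and the SRS6
#' class-discriminating position (where Ala and Ser are interchangeable).
#'
#' @return Tibble with columns \code{position}, \code{allowed} (string of
#'   tolerated residues) and \code{annotation}.
#' @export
default_critical_residues <- function() {
  tibble(
    position = c(114L, 210L, 245L, 302L, 428L, 494L),
    allowed = c("G", "V", "H", "N", "R", "AS"),
    annotation = c("SRS1 invariant glycine (residue 5 of SRS1)",
                   "SRS2 residue 3 valine",
                   "SRS3 positively selected histidine",
                   "SRS4 positively selected asparagine",
                   "arginine adjacent to the PERF motif",
                   "SRS6 rule position (Ala/Ser in F3'5'H)")
  )
}

#' Predict protein-level consequences of haplotype variation
#'
#' Translates haplotype and reference, aligns the proteins, and derives the
#' consequence report: where the mutant diverges, where a premature stop
#' falls, how much protein is truncated, and which essential domains are
#' lost or altered. Multiple frameshifts that restore frame are handled by
#' literal translation of the edited sequence, never by per-variant
#' annotation arithmetic.
#'
#' @inheritParams call_variants
#' @param ref_map Optional domain map (defaults to the reference object's).
#' @param critical Critical-residue tibble for [classify_function()].
#' @return Tibble with one row per haplotype: variant counts, consequence
#'   class, \code{divergence_start_aa}, \code{altered_run_length_aa},
#'   \code{premature_stop_codon}, \code{mutant_protein_length_aa},
#'   \code{truncation_length_aa}, list-columns \code{domains_lost},
#'   \code{domains_altered} and \code{aa_substitutions}, and
#'   \code{functional_class}.
#' @examples
#' ref <- make_reference()
#' pp <- make_natural_panel(ref)
#' predict_consequences(pp$panel, ref)[, c("haplotype", "functional_class")]
#' @export
predict_consequences <- function(panel, reference, ref_map = NULL,
                                 critical = default_critical_residues()) {
  panel <- as_panel(panel)
  stopifnot(inherits(reference, "flavhap_reference") || !is.null(ref_map))
  if (is.null(ref_map)) ref_map <- reference$domain_map
  bind_rows(lapply(seq_len(nrow(panel)), function(i)
    predict_consequence(panel$sequence[i], reference, ref_map = ref_map,
                        critical = critical,
                        haplotype = panel$haplotype[i])))
}

#' @rdname predict_consequences
#' @param haplotype_cds A single haplotype CDS string.
#' @param haplotype Label for the report row.
#' @export
predict_consequence <- function(haplotype_cds, reference, ref_map = NULL,
                                critical = default_critical_residues(),
                                haplotype = "haplotype") {
  if (is.null(ref_map)) ref_map <- reference$domain_map
  ref_cds <- ref_sequence(reference)
  variants <- variants_one(haplotype_cds, ref_cds, min_identity = 0.5)
  ref_tr <- translate_cds(ref_cds)
  mut_tr <- translate_cds(haplotype_cds)
  ref_len <- ref_tr$length
  mut_len <- mut_tr$length

  indel_net <- variants$length * ifelse(variants$kind == "insertion", 1L, -1L)
  frameshift <- nrow(variants) > 0 &&
    any(variants$kind != "SNP" & variants$length %% 3L != 0L)
  classes <- variant_classes(variants, ref_tr$residues, mut_tr$residues)

  premature_stop <- if (mut_tr$terminated_early) mut_len + 1L else NA_integer_
  divergence <- first_difference(ref_tr$residues, mut_tr$residues)
  if (!is.na(divergence) && divergence > min(ref_len, mut_len))
    divergence <- if (mut_len < ref_len) mut_len + 1L else NA_integer_
  if (frameshift) {
    # the divergent run is the frameshifted reading: start it at the first
    # residue differing at or after the first frame-disrupting indel, so an
    # upstream missense SNP is reported separately, not as run entry
    fs <- variants[variants$kind != "SNP" & variants$length %% 3L != 0L, ]
    fs_codon <- nt_to_codon(min(fs$position) + 1L)
    d2 <- first_difference_from(ref_tr$residues, mut_tr$residues, fs_codon)
    if (!is.na(d2)) divergence <- d2
  }
  altered_run <- if (!is.na(premature_stop) && !is.na(divergence))
    premature_stop - divergence else 0L
  truncation <- if (!is.na(premature_stop)) ref_len - mut_len else 0L

  # domain status follows from the stop position and the indel codon spans;
  # protein-alignment projection is reserved for external query proteins
  # where the edit structure is unknown
  inframe_del <- variants[variants$kind == "deletion" &
                            variants$length %% 3L == 0L, ]
  internally_deleted <- rep(FALSE, nrow(ref_map))
  if (nrow(inframe_del) > 0) {
    for (k in seq_len(nrow(inframe_del))) {
      aa_lo <- nt_to_codon(inframe_del$position[k] + 1L)
      aa_hi <- nt_to_codon(inframe_del$position[k] + inframe_del$length[k])
      internally_deleted <- internally_deleted |
        (ref_map$start_aa <= aa_hi & ref_map$end_aa >= aa_lo)
    }
  }
  downstream_of_stop <- if (!is.na(premature_stop))
    ref_map$start_aa > mut_len else rep(FALSE, nrow(ref_map))
  straddles_stop <- if (!is.na(premature_stop))
    ref_map$start_aa <= mut_len & ref_map$end_aa > mut_len
  else rep(FALSE, nrow(ref_map))
  lost <- ref_map$domain[ref_map$essential &
                           (downstream_of_stop | internally_deleted)]
  run_lo <- if (!is.na(premature_stop)) divergence else NA_integer_
  run_hi <- if (!is.na(premature_stop)) premature_stop - 1L else NA_integer_
  overlaps_run <- !is.na(run_lo) &
    ref_map$start_aa <= run_hi & ref_map$end_aa >= run_lo
  altered <- setdiff(ref_map$domain[straddles_stop | overlaps_run], lost)

  subs <- aa_substitution_table(ref_tr$residues, mut_tr$residues,
                                run_lo, run_hi, variants)
  report <- tibble(
    haplotype = haplotype,
    n_snps = sum(variants$kind == "SNP"),
    n_insertions = sum(variants$kind == "insertion"),
    n_deletions = sum(variants$kind == "deletion"),
    consequence_class = consequence_class(variants, frameshift, subs),
    divergence_start_aa = divergence,
    altered_run_length_aa = altered_run,
    premature_stop_codon = premature_stop,
    mutant_protein_length_aa = mut_len,
    truncation_length_aa = truncation,
    domains_lost = list(lost),
    domains_altered = list(altered),
    aa_substitutions = list(subs)
  )
  report$functional_class <- classify_function(report, critical)
  report
}

# per-variant protein classes folded to the haplotype's headline class
consequence_class <- function(variants, frameshift, subs) {
  if (nrow(variants) == 0) return("reference")
  if (frameshift) return("frameshift")
  if (any(variants$kind != "SNP")) return("in-frame-indel")
  if (nrow(subs) > 0) return("missense")
  "synonymous"
}

variant_classes <- function(variants, ref_prot, mut_prot) {
  if (nrow(variants) == 0) return(character())
  ifelse(variants$kind == "SNP", "substitution",
         ifelse(variants$length %% 3L == 0L, "in-frame-indel", "frameshift"))
}

# substitutions at 1:1 aligned positions, excluding the frameshift-altered
# run (reported through the run fields) and anything at or beyond the first
# indel-affected codon, where positional correspondence breaks down
aa_substitution_table <- function(ref_prot, mut_prot, run_lo, run_hi,
                                  variants) {
  n <- min(nchar(ref_prot), nchar(mut_prot))
  if (n == 0)
    return(tibble(position = integer(), ref = character(), alt = character()))
  ra <- seq_chars(substr(ref_prot, 1, n))
  ma <- seq_chars(substr(mut_prot, 1, n))
  pos <- which(ra != ma)
  if (!is.na(run_lo)) pos <- pos[pos < run_lo | pos > run_hi]
  indels <- variants[variants$kind != "SNP", ]
  if (nrow(indels) > 0) {
    first_indel_codon <- nt_to_codon(min(indels$position) + 1L)
    pos <- pos[pos < first_indel_codon]
  }
  tibble(position = pos, ref = ra[pos], alt = ma[pos])
}

first_difference_from <- function(a, b, from) {
  n <- min(nchar(a), nchar(b))
  if (from > n) return(if (nchar(a) != nchar(b)) n + 1L else NA_integer_)
  ca <- seq_chars(substr(a, from, n)); cb <- seq_chars(substr(b, from, n))
  d <- which(ca != cb)
  if (length(d)) from + d[1L] - 1L
  else if (nchar(a) != nchar(b)) n + 1L else NA_integer_
}

#' Classify predicted enzyme functionality
#'
#' \code{null_truncation} when any essential domain is lost or internally
#' deleted; otherwise \code{impaired_substitution} when a missense change
#' hits a critical residue; otherwise \code{functional}. Compound
#' haplotypes take the most severe class. This predicts enzyme
#' functionality, not flower color.
#'
#' @param report One-row consequence tibble from [predict_consequence()].
#' @param critical Critical-residue tibble.
#' @return One of \code{"null_truncation"}, \code{"impaired_substitution"},
#'   \code{"functional"}.
#' @export
classify_function <- function(report, critical = default_critical_residues()) {
  stopifnot(nrow(report) == 1L)
  if (length(report$domains_lost[[1L]]) > 0) return("null_truncation")
  subs <- report$aa_substitutions[[1L]]
  if (nrow(subs) > 0) {
    hit <- vapply(seq_len(nrow(subs)), function(i) {
      j <- match(subs$position[i], critical$position)
      !is.na(j) && !grepl(subs$alt[i], critical$allowed[j], fixed = TRUE)
    }, logical(1))
    if (any(hit)) return("impaired_substitution")
  }
  "functional"
}

#' Export variant calls as VCF-style records
#'
#' Minimal VCF-like tibble (CHROM = reference id, 1-based POS, REF/ALT with
#' anchor base for indels) from a [call_variants()] table.
#'
#' @param variants Variant tibble.
#' @param reference Reference object (supplies id and anchor bases).
#' @return Tibble with columns \code{CHROM}, \code{POS}, \code{ID},
#'   \code{REF}, \code{ALT}.
#' @export
variants_as_vcf <- function(variants, reference) {
  ref_cds <- ref_sequence(reference)
  chrom <- if (inherits(reference, "flavhap_reference")) reference$id else "ref"
  chars <- seq_chars(ref_cds)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (v$kind == "SNP") {
      tibble(CHROM = chrom, POS = v$position, ID = v$haplotype,
             REF = v$ref, ALT = v$alt)
    } else {
      # indel position is already the anchor base left of the event
      anchor_pos <- max(v$position, 1L)
      anchor <- chars[anchor_pos]
      if (v$kind == "insertion") {
        tibble(CHROM = chrom, POS = anchor_pos, ID = v$haplotype,
               REF = anchor, ALT = paste0(anchor, v$alt))
      } else {
        tibble(CHROM = chrom, POS = anchor_pos, ID = v$haplotype,
               REF = paste0(anchor, v$ref), ALT = anchor)
      }
    }
  })
  bind_rows(rows)
}
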