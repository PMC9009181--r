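#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join n row_number across all_of distinct rename count pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap list_rbind
#' @importFrom stringr str_sub str_length str_split str_detect str_c
#' @importFrom methods as
NULL

GAP <- "-"
STOP_CODONS <- c("TAA", "TAG", "TGA")
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a single non-empty string", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  invisible(x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Translate a coding sequence
#'
#' Translates a CDS under the standard genetic code, stopping at (and
#' excluding) the first stop codon. A trailing partial codon is ignored.
#' Ambiguity codes are rejected rather than guessed.
#'
#' @param cds Single string over \code{A,C,G,T}.
#' @param id Optional sequence label carried into the result.
#' @return A one-row tibble with columns \code{id}, \code{residues},
#'   \code{length} (residue count) and \code{terminated_early} (\code{TRUE}
#'   when a stop codon occurred before the final complete codon).
#' @examples
#' translate_cds("ATGGCT")$residues   # "MA"
#' translate_cds("ATGTAAGCT")         # stops after M, terminated_early
#' @export
translate_cds <- function(cds, id = "cds") {
  assert_dna(cds, "cds")
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L)
    return(tibble(id = id, residues = "", length = 0L, terminated_early = FALSE))
  starts <- 3L * seq_len(n_codon) - 2L
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) {
    first <- stop_at[1L]
    residues <- paste(aa[seq_len(first - 1L)], collapse = "")
    # a stop in the final codon position is a normal terminator
    early <- first < n_codon
    return(tibble(id = id, residues = residues,
                  length = first - 1L, terminated_early = early))
  }
  tibble(id = id, residues = paste(aa, collapse = ""),
         length = n_codon, terminated_early = FALSE)
}

# standard code, keyed by codon; sourced from Biostrings at build of the
# lookup (stops encoded as "*")
GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Map a CDS coordinate to its codon index
#'
#' Codon \eqn{i} spans nucleotides \eqn{3i-2 \ldots 3i} (1-based, closed).
#'
#' @param position 1-based nucleotide position(s) on the CDS.
#' @return Integer codon index vector, \code{ceiling(position / 3)}.
#' @examples
#' nt_to_codon(1323)  # 441
#' @export
nt_to_codon <- function(position) {
  if (any(!is.finite(position)) || any(position < 1))
    stop("position must be >= 1", call. = FALSE)
  as.integer(ceiling(position / 3))
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via \pkg{Biostrings}, followed by a
#' left-normalization pass that shifts every indel to its leftmost
#' score-equivalent placement so that variant coordinates are reproducible.
#'
#' Default nucleotide scoring is match +2, mismatch -3, gap open -8, gap
#' extend -1 (a gap of length \eqn{k} costs \eqn{8 + k}), chosen so that a
#' contiguous multi-nucleotide deletion is preferred over scattered gaps.
#' Protein alignments use BLOSUM62 with gap open -11, extend -1.
#'
#' @param a,b Sequences to align (single strings; \code{a} is treated as the
#'   reference when variants are derived downstream).
#' @param type \code{"dna"} or \code{"protein"}.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters (DNA only;
#'   protein scoring is BLOSUM62).
#' @return A list of class \code{"flavhap_alignment"} with elements
#'   \code{a_aln}, \code{b_aln} (gapped strings), \code{score}, and
#'   \code{identity} (fraction of matching columns).
#' @examples
#' al <- align_global("ACGT", "AGT")
#' al$a_aln; al$b_aln
#' @export
align_global <- function(a, b, type = c("dna", "protein"),
                         match = 2, mismatch = -3,
                         gap_open = 8, gap_extend = 1) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences", call. = FALSE)
  if (type == "dna") {
    assert_dna(a, "a"); assert_dna(b, "b")
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(b), Biostrings::DNAString(a),
      type = "global", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(b), Biostrings::AAString(a),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
  }
  a_aln <- as.character(Biostrings::alignedSubject(pa))
  b_aln <- as.character(Biostrings::alignedPattern(pa))
  norm <- normalize_alignment(a_aln, b_aln)
  cols_a <- seq_chars(norm$a_aln)
  cols_b <- seq_chars(norm$b_aln)
  structure(list(a_aln = norm$a_aln, b_aln = norm$b_aln,
                 score = Biostrings::score(pa),
                 identity = mean(cols_a == cols_b)),
            class = "flavhap_alignment")
}

#' @export
print.flavhap_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score,
      ", identity ", sprintf("%.1f%%", 100 * x$identity), ")\n", sep = "")
  cat("  a: ", x$a_aln, "\n  b: ", x$b_aln, "\n", sep = "")
  invisible(x)
}

# Shift every gap run to its leftmost equivalent placement: a gap run may
# slide one column left whenever the non-gap character just before it equals
# the non-gap character at its right end (standard indel left-alignment).
normalize_alignment <- function(a_aln, b_aln) {
  a <- seq_chars(a_aln)
  b <- seq_chars(b_aln)
  a <- shift_gaps_left(a, b)
  b <- shift_gaps_left(b, a)
  list(a_aln = paste(a, collapse = ""),
       b_aln = paste(b, collapse = ""))
}

# slide gap runs in `g` leftwards over `o` (the other row); returns g modified
shift_gaps_left <- function(g, o) {
  repeat {
    moved <- FALSE
    i <- 1L
    n <- length(g)
    while (i <= n) {
      if (g[i] == GAP) {
        j <- i
        while (j < n && g[j + 1L] == GAP) j <- j + 1L
        # gap run i..j in g; deleted/inserted chars are o[i..j]
        if (i > 1L && g[i - 1L] != GAP && o[i - 1L] != GAP &&
            o[i - 1L] == o[j]) {
          # rotate: move the run one column left
          g[j] <- g[i - 1L]
          g[i - 1L] <- GAP
          moved <- TRUE
          i <- max(i - 2L, 1L)
          next
        }
        i <- j + 1L
      } else i <- i + 1L
    }
    if (!moved) break
  }
  g
}
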