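#' Synthetic flavonoid 3'5'-hydroxylase reference and haplotype panels
#'
#' `make_reference()` builds a stylized 510-residue F3'5'H reference protein
#' (CDS of 1,533 nt including the terminal stop) together with its full
#' domain map. The sequence content is constructed, not biological, but its
#' coordinate anatomy mirrors a real CYP75A enzyme: SRS1 110-125 (invariant
#' Gly at 114), SRS2 208-214 (Val at 210), SRS3 244-250 (His at 245),
#' SRS4 295-315 containing the I-helix (Asn at 302), K-helix 392-402 with
#' the ExxR signature at 399-402, SRS5 404-414, the ERR-triad/PERF motif
#' 424-433 (Arg at 428), the heme-binding motif PFGAGRRICAG at 460-470, and
#' SRS6 487-496 whose 8th residue (494, Ala) is the
#' hydroxylase-class-discriminating position.
#'
#' Codon choices downstream of residue 350 are engineered so that the
#' frameshifted reading frames produced by the panel's indels terminate at
#' the positions the nine-haplotype panel requires (see
#' [make_natural_panel()]); this is asserted at generation time.
#'
#' @return A list of class \code{"flavhap_reference"} with elements
#'   \code{id}, \code{cds}, \code{protein} and \code{domain_map}.
#' @examples
#' ref <- make_reference()
#' nchar(ref$protein)  # 510
#' @export
make_reference <- function() {
  prot <- reference_protein_chars()
  codons <- reference_codons(prot)
  cds <- paste0(paste(codons, collapse = ""), "TGA")
  map <- reference_domain_map(prot)

  tr <- translate_cds(cds, id = "V5-593")
  stopifnot(
    tr$length == 510L, !tr$terminated_early,
    tr$residues == paste(prot, collapse = ""),
    substr(tr$residues, 460, 470) == "PFGAGRRICAG",
    substr(tr$residues, 428, 428) == "R",
    substr(tr$residues, 494, 494) == "A"
  )
  validate_domain_map(map, protein_length = 510L)
  structure(list(id = "V5-593", cds = cds,
                 protein = tr$residues, domain_map = map),
            class = "flavhap_reference")
}

#' @export
print.flavhap_reference <- function(x, ...) {
  cat("Synthetic F3'5'H reference ", x$id, ": ",
      nchar(x$cds), " nt CDS, ", nchar(x$protein), " aa; ",
      nrow(x$domain_map), " mapped domains\n", sep = "")
  invisible(x)
}

# deterministic residue layout; see the methods vignette for the rationale
# behind every positional override
reference_protein_chars <- function() {
  cycle <- c("A", "D", "E", "G", "H", "K", "N", "P", "Q", "R", "S", "T", "W", "Y")
  prot <- cycle[((seq_len(510L) - 1L) %% length(cycle)) + 1L]
  set <- function(p, start, text) {
    ch <- seq_chars(text)
    p[start:(start + length(ch) - 1L)] <- ch
    p
  }
  prot[1L] <- "M"
  prot <- set(prot, 5L, "LVLALLPLLAVFLVGLLWRVS")      # transmembrane 5-25
  prot <- set(prot, 110L, "SPDAGKRWEANHQSTE")          # SRS1, G at 114
  # 4-fold-degenerate Ala sites hosting the panel's synonymous SNPs
  prot[c(50L, 90L, 130L, 150L, 167L, 220L, 270L, 330L, 350L)] <- "A"
  prot <- set(prot, 208L, "GAVKDQE")                   # SRS2, V at 210
  prot <- set(prot, 244L, "GHTDPRW")                   # SRS3, H at 245
  prot <- set(prot, 295L, "AGHDTTSNQAGEHTADSWKPE")     # SRS4/I-helix, N at 302
  prot[358L] <- "E"   # +1-frameshift entry point of the G19833 haplotype
  prot[385L] <- "A"; prot[386L] <- "K"   # engineered +1-frame stop boundary
  prot <- set(prot, 392L, "SKRDNAPETGR")               # K-helix, ExxR 399-402
  prot <- set(prot, 404L, "GTPDNAHQWSE")               # SRS5
  prot[416L] <- "G"; prot[420L] <- "Q"; prot[421L] <- "G"
  prot <- set(prot, 424L, "EDPERFGNSA")                # ERR-triad/PERF, R 428
  prot[434L] <- "G"; prot[435L] <- "K"                 # 14-nt-deletion stop
  prot[437L] <- "S"; prot[438L] <- "K"                 # +4-insertion stop
  prot[441L] <- "D"; prot[442L] <- "E"                 # 1-nt-deletion entry
  prot <- set(prot, 443L, "GSTPEKRDNQHWYA")            # 2nd codon base != T
  prot[457L] <- "I"; prot[458L] <- "T"                 # 1-nt-deletion stop
  prot <- set(prot, 460L, "PFGAGRRICAG")               # heme-binding motif
  prot <- set(prot, 487L, "GSDTPNWAQE")                # SRS6, A at 494
  prot
}

# one codon per residue; defaults never end in T so shifted reading frames
# can only terminate where a T-ending codon is planted deliberately
DEFAULT_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAA", F = "TTC", G = "GGA",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCA", Q = "CAA", R = "CGC", S = "TCC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC")

reference_codons <- function(prot) {
  codons <- unname(DEFAULT_CODON[prot])
  override <- c(
    `385` = "GCT",  # Ala; T + AAA(386) terminates the +1 frame at codon 386
    `386` = "AAA",
    `415` = "CAG",  # Gln; keeps the 14-nt deletion left-anchored at nt 1246
    `428` = "AGG",  # Arg; nt 1283 G>T gives the R428M substitution
    `434` = "GGT",  # Gly; T + AAA(435) terminates the deletion frame at 430
    `435` = "AAA",
    `437` = "TCT",  # Ser; T + AAA(438) terminates the +4 frame immediately
    `438` = "AAA",
    `441` = "GAT",  # Asp; nt 1323 = T is the deleted base of UI111
    `442` = "GAA",
    `457` = "ATA",  # Ile; TA + A(458) terminates the -1 frame at codon 457
    `458` = "ACA")
  codons[as.integer(names(override))] <- override
  stopifnot(all(GENETIC_CODE_TABLE[codons] == prot))
  codons
}

reference_domain_map <- function(prot) {
  dm <- tibble(
    domain = c("transmembrane", "SRS1", "SRS2", "SRS3", "SRS4", "I-helix",
               "K-helix", "SRS5", "ERR-triad", "heme-binding", "SRS6"),
    start_aa = c(5L, 110L, 208L, 244L, 295L, 300L, 392L, 404L, 424L, 460L, 487L),
    end_aa   = c(25L, 125L, 214L, 250L, 315L, 310L, 402L, 414L, 433L, 470L, 496L)
  )
  dm$consensus <- vapply(seq_len(nrow(dm)), function(i)
    paste(prot[dm$start_aa[i]:dm$end_aa[i]], collapse = ""), character(1))
  dm$essential <- dm$domain != "transmembrane"
  dm
}

# ---- sequence editing on reference coordinates -----------------------------

# edits: tibble(kind, position, ref, alt, length); position semantics:
#   SNP       position = the substituted base
#   insertion position = reference base immediately LEFT of the inserted text
#   deletion  position = first deleted reference base
apply_edits <- function(cds, edits) {
  chars <- seq_chars(cds)
  out <- as.list(chars)
  if (nrow(edits) > 0) {
    for (i in seq_len(nrow(edits))) {
      kind <- edits$kind[i]; pos <- edits$position[i]
      if (kind == "SNP") {
        stopifnot(chars[pos] == edits$ref[i])
        out[[pos]] <- edits$alt[i]
      } else if (kind == "insertion") {
        out[[pos]] <- paste0(out[[pos]], edits$alt[i])
      } else if (kind == "deletion") {
        idx <- pos:(pos + edits$length[i] - 1L)
        stopifnot(paste(chars[idx], collapse = "") == edits$ref[i])
        for (j in idx) out[[j]] <- ""
      } else stop("unknown edit kind: ", kind)
    }
  }
  paste(unlist(out), collapse = "")
}

edit_row <- function(kind, position, ref, alt) {
  tibble(kind = kind, position = as.integer(position), ref = ref, alt = alt,
         length = ifelse(kind == "SNP", 1L,
                         ifelse(kind == "insertion", nchar(alt), nchar(ref))))
}

natural_panel_edits <- function(cds) {
  base <- seq_chars(cds)
  snp <- function(pos, alt) edit_row("SNP", pos, base[pos], alt)
  del <- function(pos, len)
    edit_row("deletion", pos, paste(base[pos:(pos + len - 1L)], collapse = ""), "")
  ins <- function(pos, alt) edit_row("insertion", pos, "", alt)

  g19_snps <- bind_rows(lapply(c(150L, 270L, 390L, 660L, 810L, 990L, 1050L),
                               function(p) snp(p, "A")))
  v0491 <- bind_rows(snp(501L, "A"), snp(1283L, "T"))
  mdrk <- bind_rows(v0491, ins(1310L, "ACCA"))
  list(
    `V5-593`  = edit_row("SNP", 1L, "", "")[0, ],
    `vG19833` = bind_rows(g19_snps, ins(1072L, "C")),
    `vlae-V0491` = v0491,
    `vlae-MDRK`  = mdrk,
    `vlae-G5686` = bind_rows(mdrk, snp(450L, "A")),
    `vMex235` = del(1246L, 14L),
    `vM0056`  = bind_rows(snp(501L, "A"), del(1246L, 14L)),
    `vUI111`  = del(1323L, 1L),
    `vG2858`  = del(1381L, 15L)
  )
}

#' Generate the nine-haplotype natural-variant panel
#'
#' Deterministically emits the reference haplotype plus eight derived mutant
#' haplotypes of the synthetic F3'5'H gene, engineered so that the
#' protein-level consequence of every haplotype matches its documented
#' phenotype class:
#'
#' * `vG19833` — 7 synonymous SNPs plus a single cytosine insertion inside
#'   codon 358; the shifted frame reads 28 divergent residues and stops,
#'   truncating the protein by 125 residues (null).
#' * `vlae-V0491` — a synonymous SNP and the R428M substitution next to the
#'   PERF motif (impaired).
#' * `vlae-MDRK` — V0491's edits plus a 4-nt insertion at nt 1310 (null).
#' * `vlae-G5686` — MDRK's edits plus one more synonymous SNP (null).
#' * `vMex235` — a 14-nt deletion at nt 1246-1259; 14 altered residues from
#'   416, then a premature stop that removes the heme-binding motif and SRS6
#'   and alters the ERR-triad (null).
#' * `vM0056` — the 5' end of MDRK (through nt 900) joined to the 3' end of
#'   Mex235: one SNP plus the 14-nt deletion; an intragenic recombinant
#'   (null).
#' * `vUI111` — a single T deletion at nt 1,323 (codon 441) with a premature
#'   stop 16 codons downstream, removing heme-binding and SRS6 (null).
#' * `vG2858` — an in-frame 15-nt deletion removing residues 461-465 inside
#'   the heme-binding motif (null).
#'
#' Every emitted haplotype is validated against the translation engine
#' before return; a mismatch is a hard error.
#'
#' @param reference Optionally a prebuilt [make_reference()] object.
#' @return A list with \code{panel} (tibble: \code{haplotype},
#'   \code{sequence}) and \code{truth} (tibble of planted edits and expected
#'   outcomes; list-column \code{edits}).
#' @export
make_natural_panel <- function(reference = make_reference()) {
  edits <- natural_panel_edits(reference$cds)
  panel <- tibble(
    haplotype = names(edits),
    sequence = unname(vapply(edits, function(e) apply_edits(reference$cds, e),
                             character(1)))
  )
  truth <- tibble(
    haplotype = names(edits),
    edits = unname(edits),
    n_snps = vapply(edits, function(e) sum(e$kind == "SNP"), integer(1)),
    n_insertions = vapply(edits, function(e) sum(e$kind == "insertion"), integer(1)),
    n_deletions = vapply(edits, function(e) sum(e$kind == "deletion"), integer(1)),
    expected_class = c("functional", "null_truncation", "impaired_substitution",
                       "null_truncation", "null_truncation", "null_truncation",
                       "null_truncation", "null_truncation", "null_truncation"),
    recombinant_parents = list(NULL, NULL, NULL, NULL, NULL, NULL,
                               c("vlae-MDRK", "vMex235"), NULL, NULL),
    recombination_breakpoint = c(NA, NA, NA, NA, NA, NA, 900L, NA, NA)
  )
  validate_panel_truth(panel, truth, reference)
  list(panel = panel, truth = truth)
}

# generation-time self-test: translation-level expectations that must hold
# before the panel is handed to any consumer
validate_panel_truth <- function(panel, truth, reference) {
  ref_tr <- translate_cds(reference$cds)
  expect <- list(
    `vG19833` = list(div = 358L, stop = 386L, len = 385L),
    `vMex235` = list(div = 416L, stop = 430L, len = 429L),
    `vM0056`  = list(div = 416L, stop = 430L, len = 429L),
    `vUI111`  = list(div = 441L, stop = 457L, len = 456L)
  )
  for (h in names(expect)) {
    s <- panel$sequence[panel$haplotype == h]
    tr <- translate_cds(s, id = h)
    e <- expect[[h]]
    div <- first_difference(ref_tr$residues, tr$residues)
    if (!tr$terminated_early || tr$length != e$len || div != e$div)
      stop("fixture self-test failed for ", h, call. = FALSE)
  }
  v <- panel$sequence[panel$haplotype == "vlae-V0491"]
  tr <- translate_cds(v)
  if (tr$terminated_early || substr(tr$residues, 428, 428) != "M")
    stop("fixture self-test failed for vlae-V0491", call. = FALSE)
  m <- panel$sequence[panel$haplotype == "vM0056"]
  md <- panel$sequence[panel$haplotype == "vlae-MDRK"]
  mx <- panel$sequence[panel$haplotype == "vMex235"]
  if (!identical(substr(m, 1, 900), substr(md, 1, 900)) ||
      !identical(substr(m, 901, nchar(m)), substr(mx, 901, nchar(mx))))
    stop("fixture self-test failed: vM0056 is not the MDRK/Mex235 chimera",
         call. = FALSE)
  invisible(TRUE)
}

first_difference <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  ca <- seq_chars(substr(a, 1, n)); cb <- seq_chars(substr(b, 1, n))
  d <- which(ca != cb)
  if (length(d)) d[1L] else if (nchar(a) != nchar(b)) n + 1L else NA_integer_
}

#' Random mutation panels with planted truth
#'
#' Draws `n` haplotypes from the synthetic reference by planting SNPs and
#' indels at the given per-nucleotide rates. Substituted bases are resampled
#' if they would create an in-frame stop codon within their own codon, so
#' premature termination arises only from planted frameshifts. All edit
#' records are left-normalized against the reference so they are directly
#' comparable with [call_variants()] output.
#'
#' @param n Number of haplotypes (0 allowed).
#' @param snp_rate,indel_rate Per-nucleotide event rates, each in (0, 0.05].
#' @param indel_lengths Integer vector of candidate indel lengths, sampled
#'   uniformly.
#' @param seed Integer seed; panels are reproducible per seed.
#' @param reference Optionally a prebuilt reference object.
#' @return A list with \code{panel} (tibble \code{haplotype},
#'   \code{sequence}) and \code{truth} (tibble with list-column \code{edits}
#'   and the generator's \code{expected_class} label).
#' @export
make_random_panel <- function(n, snp_rate = 0.002, indel_rate = 2e-4,
                              indel_lengths = 1:6, seed,
                              reference = make_reference()) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (snp_rate <= 0 || snp_rate > 0.05 || indel_rate <= 0 || indel_rate > 0.05)
    stop("rates must lie in (0, 0.05]", call. = FALSE)
  if (n == 0)
    return(list(panel = tibble(haplotype = character(), sequence = character()),
                truth = tibble(haplotype = character(), edits = list(),
                               expected_class = character())))
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  ref <- reference
  attr(ref, ".rate_snp") <- snp_rate
  attr(ref, ".rate_indel") <- indel_rate
  attr(ref, ".opt_indel_lengths") <- as.integer(indel_lengths)
  withr_seed({
    rows <- lapply(seq_len(n), function(i)
      random_haplotype(sprintf("hap%03d", i), ref))
  })
  list(panel = bind_rows(lapply(rows, `[[`, "panel")),
       truth = bind_rows(lapply(rows, `[[`, "truth")))
}

random_haplotype <- function(id, ref) {
  chars <- seq_chars(ref$cds)
  L <- length(chars) - 3L  # never edit the terminal stop codon
  edits <- list()
  snp_pos <- which(stats::runif(L) < get_rate(ref, "snp"))
  for (p in snp_pos) {
    alt <- random_alt_base(chars, p)
    if (!is.na(alt)) edits[[length(edits) + 1L]] <-
        edit_row("SNP", p, chars[p], alt)
  }
  n_indel <- stats::rbinom(1L, L, get_rate(ref, "indel"))
  if (n_indel > 0) {
    pos <- sample.int(L - 10L, n_indel)
    for (p in pos) {
      lens <- get_opt(ref, "indel_lengths")
      len <- if (length(lens) == 1L) lens else sample(lens, 1L)
      if (stats::runif(1) < 0.5) {
        edits[[length(edits) + 1L]] <-
          edit_row("deletion", p, paste(chars[p:(p + len - 1L)], collapse = ""), "")
      } else {
        alt <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
        edits[[length(edits) + 1L]] <- edit_row("insertion", p, "", alt)
      }
    }
  }
  edits <- if (length(edits)) bind_rows(edits) else edit_row("SNP", 1L, "", "")[0, ]
  edits <- drop_overlapping_edits(edits)
  seqn <- apply_edits(ref$cds, edits)
  edits <- normalize_planted_edits(edits, ref$cds)
  truth_class <- truth_functional_class(edits, ref)
  list(panel = tibble(haplotype = id, sequence = seqn),
       truth = tibble(haplotype = id, edits = list(edits),
                      expected_class = truth_class))
}

# rate/option plumbing: stored on the reference object by make_random_panel
get_rate <- function(ref, what) attr(ref, paste0(".rate_", what))
get_opt <- function(ref, what) attr(ref, paste0(".opt_", what))

random_alt_base <- function(chars, p) {
  codon_i <- nt_to_codon(p)
  idx <- (3L * codon_i - 2L):(3L * codon_i)
  for (alt in sample(setdiff(c("A", "C", "G", "T"), chars[p]))) {
    cd <- chars[idx]; cd[p - idx[1L] + 1L] <- alt
    if (!(paste(cd, collapse = "") %in% STOP_CODONS)) return(alt)
  }
  NA_character_
}

# keep edit lists unambiguous: sort by position and drop any edit whose
# reference footprint touches a previously kept edit (rare at the specified
# rates)
drop_overlapping_edits <- function(edits) {
  if (nrow(edits) < 2L) return(edits)
  edits <- edits[order(edits$position), , drop = FALSE]
  span_end <- edits$position +
    ifelse(edits$kind == "deletion", edits$length, 1L) - 1L
  keep <- rep(TRUE, nrow(edits))
  last_end <- -10L
  for (i in seq_len(nrow(edits))) {
    if (edits$position[i] <= last_end + 1L) keep[i] <- FALSE
    else last_end <- span_end[i]
  }
  edits[keep, , drop = FALSE]
}

# left-normalize planted indels against the reference so truth records use
# the same canonical coordinates as the variant caller
normalize_planted_edits <- function(edits, ref_cds) {
  if (nrow(edits) == 0) return(edits)
  chars <- seq_chars(ref_cds)
  for (i in seq_len(nrow(edits))) {
    kind <- edits$kind[i]
    if (kind == "deletion") {
      s <- edits$position[i]; e <- s + edits$length[i] - 1L
      while (s > 1L && chars[s - 1L] == chars[e]) { s <- s - 1L; e <- e - 1L }
      edits$position[i] <- s
      edits$ref[i] <- paste(chars[s:e], collapse = "")
    } else if (kind == "insertion") {
      p <- edits$position[i]; ins <- seq_chars(edits$alt[i])
      while (p > 0L && chars[p] == ins[length(ins)]) {
        ins <- c(ins[length(ins)], ins[-length(ins)])
        p <- p - 1L
      }
      edits$position[i] <- p
      edits$alt[i] <- paste(ins, collapse = "")
    }
  }
  edits[order(edits$position), , drop = FALSE]
}

# generator-side label: derived from the planted edits alone (translation of
# the edited sequence plus domain arithmetic), independent of the
# alignment-based consequence engine
truth_functional_class <- function(edits, ref) {
  mutant <- apply_edits(ref$cds, edits)
  tr <- translate_cds(mutant)
  map <- ref$domain_map[ref$domain_map$essential, ]
  if (tr$terminated_early && any(map$start_aa > tr$length))
    return("null_truncation")
  # in-frame deletion inside an essential domain?
  dels <- edits[edits$kind == "deletion" & edits$length %% 3L == 0L, ]
  if (nrow(dels) > 0) {
    for (i in seq_len(nrow(dels))) {
      aa <- nt_to_codon(c(dels$position[i], dels$position[i] + dels$length[i] - 1L))
      if (any(map$start_aa <= aa[2L] & map$end_aa >= aa[1L]))
        return("null_truncation")
    }
  }
  # critical substitutions are only well-defined where reference and mutant
  # coordinates still correspond: before the first indel-affected codon
  indels <- edits[edits$kind != "SNP", ]
  first_indel_codon <- if (nrow(indels) > 0)
    nt_to_codon(min(indels$position) + 1L) else Inf
  crit <- default_critical_residues()
  ref_aa <- seq_chars(ref$protein)
  mut_aa <- seq_chars(tr$residues)
  n <- min(length(ref_aa), length(mut_aa))
  for (i in seq_len(nrow(crit))) {
    p <- crit$position[i]
    if (p <= n && p < first_indel_codon && mut_aa[p] != ref_aa[p] &&
        !grepl(mut_aa[p], crit$allowed[i], fixed = TRUE))
      return("impaired_substitution")
  }
  "functional"
}

#' Express planted edits in variant-caller coordinates
#'
#' Truth records store a deletion at the first deleted reference base;
#' [call_variants()] reports indels at the base immediately left of the
#' left-normalized event. This helper converts an edit tibble to the caller
#' convention so the two are directly comparable.
#'
#' @param edits Edit tibble from a truth record.
#' @return Tibble with columns \code{kind}, \code{position}, \code{ref},
#'   \code{alt}, \code{length} in caller coordinates.
#' @export
edits_as_calls <- function(edits) {
  out <- edits[, c("kind", "position", "ref", "alt", "length")]
  del <- out$kind == "deletion"
  out$position[del] <- out$position[del] - 1L
  out[order(out$position), , drop = FALSE]
}

#' Plant an intragenic recombinant
#'
#' Builds a chimeric haplotype carrying parent A's sequence over reference
#' positions 1..breakpoint and parent B's sequence thereafter. Parents are
#' expressed as edit lists on the reference, so the chimera inherits A's
#' edits at positions <= breakpoint and B's edits beyond it. An edit
#' straddling the breakpoint is an error.
#'
#' @param parentA_edits,parentB_edits Edit tibbles (as in panel truth).
#' @param breakpoint Reference nucleotide position of the crossover.
#' @param reference Optionally a prebuilt reference object.
#' @param id Haplotype id for the chimera.
#' @return A list with \code{sequence}, \code{edits}, \code{degenerate}
#'   (TRUE when the chimera equals one parent) and \code{breakpoint}.
#' @export
plant_recombinant <- function(parentA_edits, parentB_edits, breakpoint,
                              reference = make_reference(), id = "chimera") {
  L <- nchar(reference$cds)
  if (breakpoint < 1 || breakpoint >= L)
    stop("breakpoint outside the shared coordinate range", call. = FALSE)
  straddles <- function(e) any(e$kind == "deletion" &
                                 e$position <= breakpoint &
                                 e$position + e$length - 1L > breakpoint)
  if (straddles(parentA_edits) || straddles(parentB_edits))
    stop("an indel straddles the breakpoint", call. = FALSE)
  keepA <- parentA_edits[parentA_edits$position <= breakpoint, , drop = FALSE]
  keepB <- parentB_edits[parentB_edits$position > breakpoint, , drop = FALSE]
  edits <- bind_rows(keepA, keepB)
  edits <- edits[order(edits$position), , drop = FALSE]
  degenerate <- identical(edits[c("kind", "position", "ref", "alt")],
                          parentA_edits[c("kind", "position", "ref", "alt")]) ||
    identical(edits[c("kind", "position", "ref", "alt")],
              parentB_edits[c("kind", "position", "ref", "alt")])
  list(id = id, sequence = apply_edits(reference$cds, edits),
       edits = edits, degenerate = degenerate, breakpoint = breakpoint)
}
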