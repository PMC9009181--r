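ref <- make_reference()
pp <- make_natural_panel(ref)
variants <- call_variants(pp$panel, ref)
cons <- predict_consequences(pp$panel, ref)

get_row <- function(h) cons[cons$haplotype == h, ]
get_vars <- function(h) variants[variants$haplotype == h, ]

test_that("a haplotype identical to the reference yields no calls and a
           functional all-zero report", {
  expect_equal(nrow(get_vars("V5-593")), 0L)
  r <- get_row("V5-593")
  expect_equal(r$consequence_class, "reference")
  expect_equal(r$truncation_length_aa, 0L)
  expect_equal(r$functional_class, "functional")
})

test_that("the G19833-type haplotype carries 7 SNPs and a single C insertion
           with a 28-residue divergent run truncating 125 residues", {
  v <- get_vars("vG19833")
  expect_equal(sum(v$kind == "SNP"), 7L)
  ins <- v[v$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$alt, "C")
  r <- get_row("vG19833")
  expect_equal(r$consequence_class, "frameshift")
  expect_equal(r$divergence_start_aa, 358L)
  expect_equal(r$altered_run_length_aa, 28L)
  expect_equal(r$mutant_protein_length_aa, 385L)
  expect_equal(r$truncation_length_aa, 125L)
  expect_setequal(r$domains_lost[[1]],
                  c("K-helix", "SRS5", "ERR-triad", "heme-binding", "SRS6"))
})

test_that("the V0491-type haplotype has two SNPs and one amino-acid
           substitution (R428M) classified impaired", {
  v <- get_vars("vlae-V0491")
  expect_equal(nrow(v), 2L)
  expect_true(all(v$kind == "SNP"))
  r <- get_row("vlae-V0491")
  subs <- r$aa_substitutions[[1]]
  expect_equal(nrow(subs), 1L)
  expect_equal(subs$position, 428L)
  expect_equal(subs$ref, "R")
  expect_equal(subs$alt, "M")
  expect_equal(r$functional_class, "impaired_substitution")
})

test_that("the Mex235-type 14-nt deletion is called as one left-anchored event
           and changes 14 residues from 416 before a premature stop", {
  v <- get_vars("vMex235")
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "deletion")
  expect_equal(v$length, 14L)
  expect_equal(v$position, 1245L)
  r <- get_row("vMex235")
  expect_equal(r$divergence_start_aa, 416L)
  expect_equal(r$altered_run_length_aa, 14L)
  expect_setequal(r$domains_lost[[1]], c("heme-binding", "SRS6"))
  expect_true("ERR-triad" %in% r$domains_altered[[1]])
  expect_equal(r$functional_class, "null_truncation")
})

test_that("the M0056-type haplotype is one SNP plus the 14-nt deletion", {
  v <- get_vars("vM0056")
  expect_equal(nrow(v), 2L)
  expect_equal(sum(v$kind == "SNP"), 1L)
  del <- v[v$kind == "deletion", ]
  expect_equal(del$length, 14L)
  expect_equal(del$position, 1245L)
})

test_that("the UI111-type single-T deletion at nt 1,323 shifts frame at codon
           441 with a stop 16 codons downstream losing heme-binding and SRS6", {
  v <- get_vars("vUI111")
  expect_equal(nrow(v), 1L)
  expect_equal(v$ref, "T")
  r <- get_row("vUI111")
  expect_equal(r$divergence_start_aa, 441L)
  expect_equal(r$premature_stop_codon - r$divergence_start_aa, 16L)
  expect_equal(r$mutant_protein_length_aa, 456L)
  expect_setequal(r$domains_lost[[1]], c("heme-binding", "SRS6"))
  expect_equal(r$functional_class, "null_truncation")
})

test_that("the in-frame 15-nt deletion haplotype keeps frame but loses the
           heme-binding motif by internal deletion", {
  r <- get_row("vG2858")
  expect_equal(r$consequence_class, "in-frame-indel")
  expect_true(is.na(r$premature_stop_codon))
  expect_equal(r$mutant_protein_length_aa, 505L)
  expect_equal(r$domains_lost[[1]], "heme-binding")
  expect_equal(r$functional_class, "null_truncation")
})

test_that("panel-wide tallies: nine haplotypes, eight non-functional", {
  expect_equal(nrow(cons), 9L)
  tally <- table(cons$functional_class)
  expect_equal(unname(tally[["functional"]]), 1L)
  expect_equal(unname(tally[["impaired_substitution"]]), 1L)
  expect_equal(unname(tally[["null_truncation"]]), 7L)
})

test_that("variant calling refuses non-comparable sequences", {
  set.seed(8)
  junk <- random_dna(1500)
  expect_error(call_variants(c(x = junk), ref), "not comparable")
})

test_that("a deletion engineered by hand is recovered at the planted
           left-normalized coordinates", {
  mut <- paste0(substr(ref$cds, 1, 1245), substr(ref$cds, 1260, nchar(ref$cds)))
  v <- call_variants(c(edited = mut), ref)
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "deletion")
  expect_equal(v$length, 14L)
  expect_equal(v$position, 1245L)
  expect_equal(v$ref, substr(ref$cds, 1246, 1259))
})

test_that("planted edits round-trip through the caller and classifier on
           random panels (recovery and agreement >= 99%)", {
  ok_edits <- 0L; ok_class <- 0L; total <- 0L
  for (seed in 0:9) {
    rp <- make_random_panel(10, seed = seed, reference = ref)
    v <- call_variants(rp$panel, ref)
    cc <- predict_consequences(rp$panel, ref)
    for (i in seq_len(nrow(rp$panel))) {
      total <- total + 1L
      h <- rp$panel$haplotype[i]
      truth <- edits_as_calls(rp$truth$edits[[i]])
      got <- v[v$haplotype == h, c("kind", "position", "ref", "alt", "length")]
      got <- got[order(got$position), ]
      if (isTRUE(all.equal(as.data.frame(truth), as.data.frame(got),
                           check.attributes = FALSE)))
        ok_edits <- ok_edits + 1L
      if (cc$functional_class[cc$haplotype == h] == rp$truth$expected_class[i])
        ok_class <- ok_class + 1L
    }
  }
  expect_gte(ok_edits / total, 0.99)
  expect_gte(ok_class / total, 0.99)
})

test_that("frameshift class appears exactly when an indel length is not a
           multiple of three", {
  for (seed in 0:4) {
    rp <- make_random_panel(6, snp_rate = 0.001, indel_rate = 6e-4,
                            seed = 100 + seed, reference = ref)
    cc <- predict_consequences(rp$panel, ref)
    for (i in seq_len(nrow(rp$panel))) {
      e <- rp$truth$edits[[i]]
      has_fs <- any(e$kind != "SNP" & e$length %% 3L != 0L)
      is_fs <- cc$consequence_class[cc$haplotype == rp$panel$haplotype[i]] ==
        "frameshift"
      expect_equal(is_fs, has_fs)
    }
  }
})

test_that("mutant length plus truncation equals reference length whenever a
           premature stop exists", {
  rows <- cons[!is.na(cons$premature_stop_codon), ]
  expect_gt(nrow(rows), 0)
  expect_true(all(rows$mutant_protein_length_aa + rows$truncation_length_aa ==
                    510L))
})

test_that("VCF-style export anchors indels on the base to their left", {
  vcf <- variants_as_vcf(get_vars("vM0056"), ref)
  expect_equal(vcf$CHROM, rep("V5-593", 2))
  del <- vcf[nchar(vcf$REF) > 1, ]
  expect_equal(del$POS, 1245L)
  expect_equal(nchar(del$REF), 15L)  # anchor + 14 deleted bases
  expect_equal(del$ALT, substr(del$REF, 1, 1))
})
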