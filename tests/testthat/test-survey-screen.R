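ref <- make_reference()
pp <- make_natural_panel(ref)
panel_proteins <- tibble::tibble(
  id = pp$panel$haplotype,
  sequence = vapply(pp$panel$sequence,
                    function(s) translate_cds(s)$residues, character(1),
                    USE.NAMES = FALSE))

test_that("the reference passes its own screen as F3'5'H", {
  rec <- screen_proteome(c(refprot = ref$protein), ref)
  expect_true(rec$passed_filter)
  expect_true(rec$heme_motif_found)
  expect_equal(rec$heme_motif_position, 460L)
  expect_equal(rec$hydroxylase_class, "F35H")
})

test_that("an A->T edit at the SRS6 rule position reclassifies as F3'H but
           still passes the filter", {
  p <- ref$protein
  substr(p, 494, 494) <- "T"
  rec <- screen_proteome(c(edited = p), ref)
  expect_equal(rec$hydroxylase_class, "F3H")
  expect_true(rec$passed_filter)
})

test_that("a premature-stop haplotype protein fails the completeness filter
           with heme-binding and SRS6 missing", {
  ui <- panel_proteins[panel_proteins$id == "vUI111", ]
  expect_equal(nchar(ui$sequence), 456L)
  rec <- screen_proteome(ui, ref)
  expect_false(rec$domains_complete)
  expect_true(all(c("heme-binding", "SRS6") %in% rec$failing_domains[[1]]))
  expect_false(rec$passed_filter)
})

test_that("screening the translated panel fails every truncated haplotype and
           the in-frame heme deletion, and passes the rest", {
  recs <- screen_proteome(panel_proteins, ref)
  expect_equal(nrow(recs), 9L)  # no silent drops
  failing <- recs$id[!recs$domains_complete]
  frameshifted <- c("vG19833", "vlae-MDRK", "vlae-G5686", "vMex235",
                    "vM0056", "vUI111")
  expect_true(all(frameshifted %in% failing))
  expect_true("vG2858" %in% failing)  # in-frame deletion inside heme motif
  expect_setequal(recs$id[recs$passed_filter], c("V5-593", "vlae-V0491"))
})

test_that("screen records satisfy the filter-cascade invariant", {
  recs <- screen_proteome(panel_proteins, ref)
  expect_equal(recs$passed_filter,
               recs$heme_motif_found & recs$domains_complete &
                 recs$hydroxylase_class != "unknown")
})

test_that("relaxing the screen is monotone: higher mismatch tolerance or a
           smaller essential set never decreases the passing count", {
  mut <- ref$protein
  substr(mut, 461, 461) <- "Y"
  substr(mut, 463, 463) <- "W"
  substr(mut, 466, 466) <- "K"   # 3 mismatches in the heme motif
  prots <- dplyr::bind_rows(panel_proteins,
                            tibble::tibble(id = "heme3mm", sequence = mut))
  counts <- vapply(0:4, function(mm)
    sum(screen_proteome(prots, ref, max_mismatch = mm)$passed_filter),
    numeric(1))
  expect_true(all(diff(counts) >= 0))

  full <- sum(screen_proteome(panel_proteins, ref)$passed_filter)
  reduced <- sum(screen_proteome(panel_proteins, ref,
                                 essential = c("SRS1", "SRS2"))$passed_filter)
  expect_gte(reduced, full)
})

test_that("unique domain sequences deduplicate exactly", {
  five_same <- tibble::tibble(id = paste0("p", 1:5),
                              sequence = rep(ref$protein, 5))
  expect_equal(unique_domain_sequences(five_same, ref, "SRS1"), 1L)

  v1 <- ref$protein; substr(v1, 111, 111) <- "K"
  v2 <- ref$protein; substr(v2, 124, 124) <- "H"
  prots <- tibble::tibble(id = paste0("p", 1:10),
                          sequence = c(rep(ref$protein, 8), v1, v2))
  expect_equal(unique_domain_sequences(prots, ref, "SRS1"), 3L)
  expect_equal(unique_domain_sequences(prots, ref, "SRS2"), 1L)
  expect_error(unique_domain_sequences(five_same, ref, "SRS9"), "unknown domain")
})

test_that("logo information matches closed forms", {
  inv <- logo_information(rep("A", 5))
  expect_equal(inv$information$bits, log2(20), tolerance = 1e-12)

  uniform <- logo_information(AA20)
  expect_equal(uniform$information$bits, 0, tolerance = 1e-12)

  half <- logo_information(c(rep("L", 5), rep("K", 5)))
  expect_equal(half$information$bits, log2(20) - 1, tolerance = 1e-12)

  expect_error(logo_information(character(0)))
  expect_error(logo_information(c("AA", "A")), "equal length")
})

test_that("logo frequencies sum to one and information is bounded", {
  set.seed(2)
  texts <- vapply(1:30, function(i)
    paste(sample(AA20, 12, replace = TRUE), collapse = ""),
    character(1))
  logo <- logo_information(texts)
  sums <- tapply(logo$frequencies$frequency, logo$frequencies$column, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(logo$information$bits >= 0 &
                    logo$information$bits <= log2(20) + 1e-12))
})

test_that("information content is invariant to residue relabelling and
           column order", {
  set.seed(6)
  texts <- vapply(1:20, function(i)
    paste(sample(c("A", "L", "K", "W"), 8, replace = TRUE), collapse = ""),
    character(1))
  base_bits <- logo_information(texts)$information$bits

  relabel <- chartr("ALKW", "MGDE", texts)
  expect_equal(logo_information(relabel)$information$bits, base_bits)

  perm <- sample(8)
  shuffled <- vapply(texts, function(t)
    paste(strsplit(t, "")[[1]][perm], collapse = ""), character(1),
    USE.NAMES = FALSE)
  expect_setequal(round(logo_information(shuffled)$information$bits, 12),
                  round(base_bits, 12))
})

test_that("small-sample correction subtracts the expected amount", {
  n <- 8
  bits <- logo_information(rep("A", n))$information$bits
  corrected <- logo_information(rep("A", n),
                                small_sample_correction = TRUE)$information$bits
  expect_equal(bits - corrected, (1 / log(2)) * (19 / (2 * n)),
               tolerance = 1e-12)
})

test_that("gap columns keep their fraction but carry no frequency mass", {
  logo <- logo_information(c("A-", "A-", "AC", "AD"))
  expect_equal(logo$information$gap_fraction, c(0, 0.5))
  col2 <- logo$frequencies[logo$frequencies$column == 2, ]
  expect_setequal(col2$residue, c("C", "D"))
  expect_equal(sum(col2$frequency), 1)
})
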