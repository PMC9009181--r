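ref <- make_reference()
pp <- make_natural_panel(ref)

test_that("minimal breakpoint counting matches trivial cases and flags
           unexplained child-private characters", {
  pa <- c(1L, 1L, 1L, 1L); pb <- c(0L, 0L, 0L, 0L)
  expect_equal(min_breakpoints(pa, pa, pb)$breakpoints, 0L)
  expect_equal(min_breakpoints(c(1L, 1L, 0L, 0L), pa, pb)$breakpoints, 1L)
  expect_equal(min_breakpoints(c(1L, 0L, 1L, 0L), pa, pb)$breakpoints, 3L)

  # parents identical at all sites -> uninformative
  expect_error(min_breakpoints(c(1L, 0L), c(1L, 1L), c(1L, 1L)),
               "uninformative")

  res <- min_breakpoints(c(1L, 1L, 1L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  expect_equal(res$unexplained, 1L)
  expect_equal(length(res$informative), 2L)
})

test_that("breakpoint counts equal the exhaustive switch-assignment oracle", {
  set.seed(12)
  for (i in 1:40) {
    k <- sample(2:12, 1)
    pa <- rbinom(k, 1, 0.5)
    pb <- 1L - pa
    child <- ifelse(rbinom(k, 1, 0.5) == 1L, pa, pb)
    expect_equal(min_breakpoints(child, pa, pb)$breakpoints,
                 oracle_min_breakpoints(child, pa, pb))
  }
})

test_that("the nine-haplotype panel contains exactly one recombinant:
           the M0056-type child from MDRK (5') and Mex235 (3')", {
  sc <- scan_triplets(pp$panel, ref)
  rec <- sc[sc$recombinant, ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$child, "vM0056")
  expect_equal(rec$parent_5prime, "vlae-MDRK")
  expect_equal(rec$parent_3prime, "vMex235")
  expect_equal(rec$min_breakpoints, 1L)
  expect_equal(rec$unexplained_sites, 0L)
  # the planted crossover (nt 900) lies inside the reported interval
  expect_lte(rec$breakpoint_lo, 900L)
  expect_gte(rec$breakpoint_hi, 900L)
})

test_that("a panel of the reference plus two independent mutants yields no
           recombinant call", {
  s1 <- ref$cds; substr(s1, 33, 33) <- "A"; substr(s1, 99, 99) <- "T"
  s2 <- ref$cds; substr(s2, 600, 600) <- "A"; substr(s2, 1200, 1200) <- "C"
  sc <- scan_triplets(c(ref = ref$cds, mutA = s1, mutB = s2), ref)
  expect_false(any(sc$recombinant))
})

test_that("a planted chimera is recovered with the correct parents and a
           breakpoint interval containing the crossover", {
  rp <- make_random_panel(2, snp_rate = 0.015, indel_rate = 5e-4,
                          seed = 3, reference = ref)
  ch <- plant_recombinant(rp$truth$edits[[1]], rp$truth$edits[[2]], 766L,
                          reference = ref)
  expect_false(ch$degenerate)
  panel <- dplyr::bind_rows(
    tibble::tibble(haplotype = ref$id, sequence = ref$cds),
    rp$panel,
    tibble::tibble(haplotype = "chimera", sequence = ch$sequence))
  sc <- scan_triplets(panel, ref)
  row <- sc[sc$child == "chimera", ]
  expect_true(row$recombinant)
  expect_setequal(c(row$parent_5prime, row$parent_3prime),
                  c("hap001", "hap002"))
  expect_lte(row$breakpoint_lo, 766L)
  expect_gte(row$breakpoint_hi, 766L)
})

test_that("parent-pair recovery holds in at least 95% of simulated chimeras
           with well-populated flanks", {
  eligible <- 0L; recovered <- 0L
  for (s in 0:39) {
    rp <- make_random_panel(2, snp_rate = 0.015, indel_rate = 5e-4,
                            seed = 1000 + s, reference = ref)
    ch <- tryCatch(
      plant_recombinant(rp$truth$edits[[1]], rp$truth$edits[[2]], 766L,
                        reference = ref),
      error = function(e) NULL)
    if (is.null(ch) || ch$degenerate) next
    sides <- vapply(rp$truth$edits, function(e)
      c(sum(e$position <= 766), sum(e$position > 766)), numeric(2))
    if (min(rowSums(sides)) < 8) next
    eligible <- eligible + 1L
    panel <- dplyr::bind_rows(
      tibble::tibble(haplotype = ref$id, sequence = ref$cds),
      rp$panel,
      tibble::tibble(haplotype = "chimera", sequence = ch$sequence))
    sc <- scan_triplets(panel, ref)
    row <- sc[sc$child == "chimera", ]
    if (isTRUE(row$recombinant) &&
        setequal(c(row$parent_5prime, row$parent_3prime),
                 c("hap001", "hap002")))
      recovered <- recovered + 1L
  }
  expect_gte(eligible, 20L)
  expect_gte(recovered / eligible, 0.95)
})

test_that("permutation p-values are reproducible, honest for scattered
           children, and significant for clean mosaics", {
  set.seed(77)
  pa <- rbinom(24, 1, 0.5); pb <- 1L - pa
  mosaic <- c(pa[1:12], pb[13:24])
  p1 <- permutation_pvalue(mosaic, pa, pb, n_permutations = 1000, seed = 11)
  p2 <- permutation_pvalue(mosaic, pa, pb, n_permutations = 1000, seed = 11)
  expect_identical(p1$p_value, p2$p_value)
  expect_lte(p1$p_value, 0.05)

  # maximally shuffled child: alternating labels, worst possible fit
  alternating <- ifelse(seq_len(24) %% 2 == 0, pa, pb)
  p3 <- permutation_pvalue(alternating, pa, pb, n_permutations = 500, seed = 2)
  expect_gte(p3$p_value, 0.9)

  expect_error(permutation_pvalue(mosaic, pa, pb, n_permutations = 10,
                                  seed = 1), ">= 100")
})

test_that("permutation type-I error is controlled under the null", {
  set.seed(5)
  rejections <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    pa <- rbinom(16, 1, 0.5); pb <- 1L - pa
    child <- pa
    flip <- runif(16) < 0.3
    child[flip] <- pb[flip]
    p <- permutation_pvalue(child, pa, pb, n_permutations = 199,
                            seed = 5000 + i)$p_value
    if (p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections / n_sim, 0.07)
})
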