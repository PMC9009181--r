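# Independent oracles, written before the implementation paths they check.
# Each deliberately avoids the package's machinery.

# -- codon-table translation oracle ------------------------------------------
# hand-entered standard genetic code
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_translate <- function(cds) {
  n <- nchar(cds) %/% 3
  res <- character(0)
  early <- FALSE
  for (i in seq_len(n)) {
    aa <- ORACLE_CODON_TABLE[[substr(cds, 3 * i - 2, 3 * i)]]
    if (aa == "*") {
      early <- i < n
      return(list(residues = paste(res, collapse = ""), terminated_early = early))
    }
    res <- c(res, aa)
  }
  list(residues = paste(res, collapse = ""), terminated_early = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# -- alignment score oracles --------------------------------------------------
# exhaustive enumeration over every gapped alignment (pure recursion; use only
# for tiny inputs). Gap of length k costs open + k * extend.
oracle_align_enumerate <- function(a, b, match = 2, mismatch = -3,
                                   open = 8, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      s <- if (av[i] == bv[j]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(av)) {  # gap in b
      cost <- extend + if (last == "GB") 0 else open
      best <- max(best, -cost + rec(i + 1, j, "GB"))
    }
    if (j <= length(bv)) {  # gap in a
      cost <- extend + if (last == "GA") 0 else open
      best <- max(best, -cost + rec(i, j + 1, "GA"))
    }
    best
  }
  rec(1, 1, "M")
}

# memoized three-state recursion; exact optimum, independent implementation
oracle_align_dp <- function(a, b, match = 2, mismatch = -3,
                            open = 8, extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); GA <- M; GB <- M
  M[1, 1] <- 0
  for (j in seq_len(m)) {
    GA[1, j + 1] <- -(open + extend * j)
  }
  for (i in seq_len(n)) {
    GB[i + 1, 1] <- -(open + extend * i)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], GA[i, j], GB[i, j])
      GA[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              GA[i + 1, j] - extend)
      GB[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              GB[i, j + 1] - extend)
    }
  }
  max(M[n + 1, m + 1], GA[n + 1, m + 1], GB[n + 1, m + 1])
}

# -- median closure oracle ----------------------------------------------------
# fixpoint over character-string state sets, triple loops written plainly
oracle_median_closure <- function(vectors) {
  states <- if (is.matrix(vectors)) {
    unique(apply(vectors, 1, paste, collapse = ""))
  } else {
    unique(vapply(vectors, function(v) paste(v, collapse = ""), character(1)))
  }
  repeat {
    new_states <- character(0)
    for (x in states) for (y in states) for (z in states) {
      xv <- as.integer(strsplit(x, "")[[1]])
      yv <- as.integer(strsplit(y, "")[[1]])
      zv <- as.integer(strsplit(z, "")[[1]])
      med <- paste(ifelse(xv + yv + zv >= 2, 1L, 0L), collapse = "")
      if (!(med %in% states) && !(med %in% new_states))
        new_states <- c(new_states, med)
    }
    if (length(new_states) == 0) break
    states <- c(states, new_states)
  }
  sort(states)
}

closure_keys <- function(closure_matrix) {
  unname(sort(apply(closure_matrix, 1, paste, collapse = "")))
}

# -- breakpoint-count oracle --------------------------------------------------
# exhaustive minimum over all 2^k assignments of informative sites to parents
oracle_min_breakpoints <- function(child, parentA, parentB) {
  inf <- which(parentA != parentB)
  k <- length(inf)
  stopifnot(k >= 1)
  best <- Inf
  for (mask in 0:(2^k - 1)) {
    assign_a <- as.logical(bitwAnd(rep(mask, k), 2^(seq_len(k) - 1)))
    active <- ifelse(assign_a, parentA[inf], parentB[inf])
    if (any(active != child[inf])) next
    switches <- sum(assign_a[-1] != assign_a[-k])
    best <- min(best, switches)
  }
  best
}

# small helper: random binary matrix with no constant columns
random_binary_matrix <- function(n_hap, n_char) {
  repeat {
    m <- matrix(rbinom(n_hap * n_char, 1, 0.4), n_hap, n_char)
    if (all(colSums(m) > 0 & colSums(m) < n_hap) &&
        nrow(unique(m)) >= 2) return(m)
  }
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
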