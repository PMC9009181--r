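#' Minimal breakpoints explaining a child as a parental mosaic
#'
#' Given binary state vectors over characters ordered by reference
#' coordinate, the informative sites are those where the two parents
#' differ. For binary characters the child matches exactly one parent at
#' every informative site, so the minimal number of parent switches is the
#' number of label changes along the ordered informative sites.
#' Characters where the parents agree but the child differs are
#' "unexplained" (private to the child relative to this pair); they are
#' excluded from the scan and counted.
#'
#' @param child,parentA,parentB Equal-length 0/1 vectors (characters in
#'   reference-coordinate order).
#' @return List with \code{breakpoints}, \code{labels} (the matched parent,
#'   \code{"A"}/\code{"B"}, per informative site), \code{informative}
#'   (indices), \code{unexplained} (indices of child-private characters).
#' @examples
#' min_breakpoints(c(1,1,0,0), c(1,1,1,1), c(0,0,0,0))$breakpoints  # 1
#' @export
min_breakpoints <- function(child, parentA, parentB) {
  stopifnot(length(child) == length(parentA),
            length(child) == length(parentB))
  informative <- which(parentA != parentB)
  unexplained <- which(parentA == parentB & child != parentA)
  if (length(informative) == 0L)
    stop("uninformative triplet: the parents do not differ", call. = FALSE)
  labels <- ifelse(child[informative] == parentA[informative], "A", "B")
  breakpoints <- if (length(labels) < 2L) 0L
  else sum(labels[-1L] != labels[-length(labels)])
  list(breakpoints = as.integer(breakpoints), labels = labels,
       informative = informative, unexplained = unexplained)
}

#' Scan a haplotype panel for intragenic recombinants
#'
#' For every candidate child haplotype and every unordered pair of other
#' haplotypes, evaluates whether the child is a single- or few-crossover
#' mosaic of the pair. A pair is a valid recombination explanation only
#' when (i) it explains the child at every character — no "unexplained"
#' child-private state where the parents agree — and (ii) the child
#' inherits derived (non-reference) material from both sides of the
#' crossover; otherwise the child is at least as parsimoniously explained
#' by direct descent from one parent plus private mutation. Among valid
#' pairs the scan minimizes breakpoints, breaking ties by larger
#' informative-site count, then lexicographic parent ids. The 5' parent is
#' the parent matched at the first informative site.
#'
#' @param panel Haplotype tibble (should include the reference haplotype).
#' @param reference Reference object or CDS string.
#' @param max_breakpoints Report children only when the best valid pair
#'   needs at most this many crossovers (default 2).
#' @param characters Optionally a precomputed [encode_characters()] object.
#' @return Tibble with one row per child: \code{child},
#'   \code{recombinant}, \code{parent_5prime}, \code{parent_3prime},
#'   \code{min_breakpoints}, \code{informative_sites},
#'   \code{informative_5prime}, \code{informative_3prime},
#'   \code{unexplained_sites}, \code{breakpoint_lo}, \code{breakpoint_hi}
#'   (reference CDS interval bounding the first crossover, exclusive of the
#'   flanking informative sites).
#' @examples
#' ref <- make_reference()
#' pp <- make_natural_panel(ref)
#' scan_triplets(pp$panel, ref) |> dplyr::filter(recombinant)
#' @export
scan_triplets <- function(panel, reference, max_breakpoints = 2L,
                          characters = NULL) {
  panel <- as_panel(panel)
  if (nrow(panel) < 3L)
    stop("need at least 3 distinct haplotypes", call. = FALSE)
  if (is.null(characters)) characters <- encode_characters(panel, reference)
  mat <- characters$matrix
  ids <- rownames(mat)
  pos <- characters$characters$position
  rows <- lapply(ids, function(child_id)
    scan_one_child(child_id, mat, ids, pos, max_breakpoints))
  bind_rows(rows)
}

scan_one_child <- function(child_id, mat, ids, pos, max_breakpoints) {
  child <- mat[child_id, ]
  others <- setdiff(ids, child_id)
  best <- NULL
  if (length(others) >= 2L) {
    pairs <- utils::combn(sort(others), 2L)
    for (k in seq_len(ncol(pairs))) {
      pa <- pairs[1L, k]; pb <- pairs[2L, k]
      res <- min_breakpoints(child, mat[pa, ], mat[pb, ])
      if (length(res$unexplained) > 0L) next
      la <- res$labels
      derived_A <- any(la == "A" & child[res$informative] == 1L)
      derived_B <- any(la == "B" & child[res$informative] == 1L)
      if (!derived_A || !derived_B) next
      cand <- list(parentA = pa, parentB = pb, res = res,
                   n_inf = length(res$informative))
      if (is.null(best) ||
          res$breakpoints < best$res$breakpoints ||
          (res$breakpoints == best$res$breakpoints &&
             cand$n_inf > best$n_inf)) {
        best <- cand
      }
    }
  }
  if (is.null(best) || best$res$breakpoints > max_breakpoints) {
    return(tibble(child = child_id, recombinant = FALSE,
                  parent_5prime = NA_character_, parent_3prime = NA_character_,
                  min_breakpoints = NA_integer_, informative_sites = NA_integer_,
                  informative_5prime = NA_integer_,
                  informative_3prime = NA_integer_,
                  unexplained_sites = NA_integer_,
                  breakpoint_lo = NA_integer_, breakpoint_hi = NA_integer_))
  }
  res <- best$res
  first_is_A <- res$labels[1L] == "A"
  p5 <- if (first_is_A) best$parentA else best$parentB
  p3 <- if (first_is_A) best$parentB else best$parentA
  lab5 <- if (first_is_A) "A" else "B"
  switch_at <- which(res$labels[-1L] != res$labels[-length(res$labels)])[1L]
  bp_lo <- pos[res$informative[switch_at]]
  bp_hi <- pos[res$informative[switch_at + 1L]]
  tibble(child = child_id, recombinant = TRUE,
         parent_5prime = p5, parent_3prime = p3,
         min_breakpoints = res$breakpoints,
         informative_sites = length(res$informative),
         informative_5prime = sum(res$labels == lab5),
         informative_3prime = sum(res$labels != lab5),
         unexplained_sites = length(res$unexplained),
         breakpoint_lo = bp_lo, breakpoint_hi = bp_hi)
}

#' Permutation support for a recombination call
#'
#' Permutes the order of the informative sites and recomputes the minimal
#' breakpoint count; the p-value is
#' \eqn{(1 + \#\{k_{perm} \le k_{obs}\}) / (n + 1)}. A true mosaic packs
#' its parental matches into contiguous blocks, so few permutations do as
#' well; a child scattered across both parents is insensitive to order.
#'
#' @param child,parentA,parentB 0/1 vectors as in [min_breakpoints()].
#' @param n_permutations At least 100 (default 999).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return List with \code{p_value}, \code{observed} breakpoints and
#'   \code{n_permutations}.
#' @export
permutation_pvalue <- function(child, parentA, parentB,
                               n_permutations = 999L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_permutations < 100L)
    stop("n_permutations must be >= 100", call. = FALSE)
  obs <- min_breakpoints(child, parentA, parentB)
  labels <- obs$labels
  if (length(labels) < 2L)
    stop("need at least 2 informative sites", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- sample(labels)
    k <- sum(perm[-1L] != perm[-length(perm)])
    if (k <= obs$breakpoints) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_permutations + 1),
       observed = obs$breakpoints, n_permutations = n_permutations)
}
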