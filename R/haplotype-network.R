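#' Encode haplotypes as a binary character matrix
#'
#' Every segregating substitution column and every distinct indel event
#' (regardless of length) becomes one binary character: 0 = reference
#' state, 1 = derived state. Characters with identical presence/absence
#' patterns are condensed into one column with summed weight. Haplotypes
#' with identical sequences collapse onto one observed state vector whose
#' members are recorded.
#'
#' @param panel Haplotype tibble (or named character vector) including, by
#'   convention, the reference haplotype itself.
#' @param reference Reference object or CDS string.
#' @return A list of class \code{"flavhap_characters"}: \code{matrix}
#'   (0/1, distinct haplotype vectors x condensed characters, ordered by
#'   reference coordinate), \code{characters} (tibble: \code{label},
#'   \code{position}, \code{weight}, \code{members} list-column of
#'   underlying variant labels), and \code{nodes} (tibble: \code{state_id},
#'   \code{members} list of haplotype ids).
#' @export
encode_characters <- function(panel, reference) {
  panel <- as_panel(panel)
  variants <- call_variants(panel, reference)
  dedup <- panel |>
    group_by(.data$sequence) |>
    summarise(members = list(.data$haplotype), .groups = "drop")
  rep_ids <- vapply(dedup$members, `[`, character(1), 1L)
  if (length(rep_ids) < 2L) stop("nothing to network", call. = FALSE)

  key <- variant_label(variants)
  uniq <- !duplicated(key)
  vt <- variants[uniq, ]
  vt$label <- key[uniq]
  if (nrow(vt) == 0L) stop("nothing to network", call. = FALSE)
  # presence matrix: representative haplotype x raw variant
  pres <- matrix(0L, nrow = length(rep_ids), ncol = nrow(vt),
                 dimnames = list(rep_ids, vt$label))
  hk <- variant_label(variants)
  for (i in seq_len(nrow(variants))) {
    hap <- variants$haplotype[i]
    row <- which(vapply(dedup$members, function(m) hap %in% m, logical(1)))
    pres[row, match(hk[i], vt$label)] <- 1L
  }
  keep <- colSums(pres) > 0L & colSums(pres) < nrow(pres)
  pres <- pres[, keep, drop = FALSE]
  vt <- vt[keep, , drop = FALSE]
  if (ncol(pres) == 0L) stop("nothing to network", call. = FALSE)

  pattern <- apply(pres, 2L, paste, collapse = "")
  first <- !duplicated(pattern)
  cond_idx <- match(pattern, pattern[first])
  characters <- tibble(
    label = vt$label[first],
    position = vt$position[first],
    weight = as.integer(table(cond_idx)[as.character(seq_len(sum(first)))]),
    members = lapply(seq_len(sum(first)),
                     function(j) vt$label[cond_idx == j])
  )
  ord <- order(characters$position)
  characters <- characters[ord, ]
  mat <- pres[, first, drop = FALSE][, ord, drop = FALSE]
  colnames(mat) <- characters$label
  structure(list(matrix = mat, characters = characters,
                 nodes = tibble(state_id = rep_ids, members = dedup$members)),
            class = "flavhap_characters")
}

variant_label <- function(variants) {
  ifelse(variants$kind == "SNP",
         paste0("SNP@", variants$position, variants$ref, ">", variants$alt),
         ifelse(variants$kind == "insertion",
                paste0("+", variants$length, "nt", variants$alt, "@",
                       variants$position),
                paste0("del", variants$length, "nt@", variants$position)))
}

#' Median closure of binary haplotype vectors
#'
#' Smallest superset of the observed 0/1 state vectors closed under the
#' coordinatewise majority (median) of every triple, iterated to a fixed
#' point. For binary states the majority of three values is always defined,
#' and the closure is unique, hence order-independent.
#'
#' @param x A \code{flavhap_characters} object or a 0/1 matrix (rows =
#'   haplotype state vectors).
#' @param max_characters Guard against exponential blow-up; matrices wider
#'   than this are refused with instructions to prune.
#' @return Integer 0/1 matrix of all closure vectors; observed rows keep
#'   their names, inferred median vectors are named \code{median1},
#'   \code{median2}, ...
#' @export
median_closure <- function(x, max_characters = 25L) {
  mat <- if (inherits(x, "flavhap_characters")) x$matrix else x
  if (ncol(mat) > max_characters)
    stop("more than ", max_characters, " condensed characters; ",
         "prune rare characters before computing the median closure",
         call. = FALSE)
  if (is.null(rownames(mat)))
    rownames(mat) <- paste0("obs", seq_len(nrow(mat)))
  keys <- apply(mat, 1L, paste, collapse = "")
  vecs <- mat[!duplicated(keys), , drop = FALSE]
  seen <- new.env(parent = emptyenv())
  for (k in unique(keys)) assign(k, TRUE, envir = seen)
  repeat {
    n <- nrow(vecs)
    if (n < 3L) break
    added <- list()
    combs <- utils::combn(n, 3L)
    for (c_i in seq_len(ncol(combs))) {
      trio <- vecs[combs[, c_i], , drop = FALSE]
      med <- as.integer(colSums(trio) >= 2L)
      k <- paste(med, collapse = "")
      if (!exists(k, envir = seen, inherits = FALSE)) {
        assign(k, TRUE, envir = seen)
        added[[length(added) + 1L]] <- med
      }
    }
    if (!length(added)) break
    vecs <- rbind(vecs, do.call(rbind, added))
  }
  blank <- rownames(vecs) == "" | is.na(rownames(vecs))
  rownames(vecs)[blank] <- paste0("median", seq_len(sum(blank)))
  storage.mode(vecs) <- "integer"
  vecs
}

#' Build the median haplotype network
#'
#' Nodes are the median-closure vectors; edges connect vectors at condensed
#' Hamming distance 1 and are labelled by the separating character. The
#' closure guarantees connectivity — a disconnected result is an internal
#' error.
#'
#' @param x \code{flavhap_characters} object (or 0/1 matrix of observed
#'   vectors).
#' @param closure Optionally a precomputed [median_closure()] matrix.
#' @return A list of class \code{"haplotype_network"}: \code{graph}
#'   (igraph), \code{nodes} (tibble: \code{node}, \code{observed},
#'   \code{members}), \code{edges} (tibble: \code{from}, \code{to},
#'   \code{label}, \code{weight}) and \code{characters}.
#' @examples
#' ref <- make_reference()
#' pp <- make_natural_panel(ref)
#' net <- build_network(encode_characters(pp$panel, ref))
#' glance(net)
#' @export
build_network <- function(x, closure = NULL) {
  chars <- if (inherits(x, "flavhap_characters")) x$characters else NULL
  if (is.null(closure)) closure <- median_closure(x)
  n <- nrow(closure)
  labels <- rownames(closure)
  edge_rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff <- which(closure[i, ] != closure[j, ])
      if (length(diff) == 1L) {
        lab <- colnames(closure)[diff]
        w <- if (!is.null(chars)) chars$weight[match(lab, chars$label)] else 1L
        edge_rows[[length(edge_rows) + 1L]] <-
          tibble(from = labels[i], to = labels[j],
                 label = lab %||% paste0("char", diff), weight = w)
      }
    }
  }
  edges <- bind_rows(edge_rows)
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = labels))
  igraph::E(g)$label <- edges$label
  if (igraph::components(g)$no != 1L)
    stop("internal error: median network is disconnected", call. = FALSE)
  observed <- !startsWith(labels, "median")
  members <- if (inherits(x, "flavhap_characters")) {
    x$nodes$members[match(labels, x$nodes$state_id)]
  } else {
    as.list(labels)
  }
  nodes <- tibble(node = labels, observed = observed, members = members,
                  degree = as.integer(igraph::degree(g)[labels]))
  structure(list(graph = g, nodes = nodes, edges = edges,
                 characters = chars, closure = closure),
            class = "haplotype_network")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Median haplotype network: ", sum(x$nodes$observed), " observed + ",
      sum(!x$nodes$observed), " inferred median nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  hub <- x$nodes$node[x$nodes$observed][
    which.max(x$nodes$degree[x$nodes$observed])]
  cat("Hub (max-degree observed node): ", hub, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy haplotype_network
#' @export
tidy.haplotype_network <- function(x, ...) x$edges

#' @method glance haplotype_network
#' @export
glance.haplotype_network <- function(x, ...) {
  tibble(n_observed = sum(x$nodes$observed),
         n_median = sum(!x$nodes$observed),
         n_edges = nrow(x$edges),
         n_characters = if (is.null(x$characters)) ncol(x$closure)
         else nrow(x$characters),
         hub = x$nodes$node[x$nodes$observed][
           which.max(x$nodes$degree[x$nodes$observed])])
}

#' Export a haplotype network
#'
#' Writes GML (via \pkg{igraph}) plus a plain edge-list TSV and a node
#' table with observed/median flags and member haplotype ids.
#'
#' @param network A [build_network()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
export_network <- function(network, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gml <- file.path(dir, paste0(prefix, ".gml"))
  edges <- file.path(dir, paste0(prefix, "_edges.tsv"))
  nodes <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  igraph::write_graph(network$graph, gml, format = "gml")
  # igraph stamps a timestamped Creator line; drop it so reruns on identical
  # inputs are byte-identical
  lines <- readLines(gml)
  writeLines(lines[!startsWith(lines, "Creator")], gml)
  readr::write_tsv(network$edges[, c("from", "to", "label")], edges)
  nt <- network$nodes
  nt$members <- vapply(nt$members, function(m)
    paste(m, collapse = ","), character(1))
  readr::write_tsv(nt, nodes)
  invisible(c(gml = gml, edges = edges, nodes = nodes))
}
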