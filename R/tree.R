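#' Condensed pairwise Euclidean distances between events
#'
#' Computes all n(n-1)/2 unordered-pair Euclidean norms, block-wise through
#' BLAS so that nothing larger than the condensed vector (plus an
#' O(block x n) temporary) is ever materialized.
#'
#' @param events A `dh_events` or a numeric matrix (rows = events).
#' @param block Row-block size for the BLAS pass.
#' @return A `stats::dist`-classed condensed distance vector.
#' @export
pairwise_distances <- function(events, block = 256L) {
  x <- if (inherits(events, "dh_events")) events$events else as.matrix(events)
  if (nrow(x) < 2) stop("need at least 2 events to form pairwise distances")
  d <- .dist_condensed_cpp(x, as.integer(block))
  attr(d, "Size") <- nrow(x)
  attr(d, "Diag") <- FALSE
  attr(d, "Upper") <- FALSE
  attr(d, "method") <- "euclidean"
  class(d) <- "dist"
  d
}

#' Build the Ward dendrogram over events
#'
#' Agglomerates events by Ward's minimum-variance criterion on Euclidean
#' distances (nearest-neighbor-chain algorithm; Lance-Williams update on
#' squared distances, heights reported on the distance scale as in
#' `hclust(method = "ward.D2")`). Deterministic: ties in nearest-neighbor
#' selection resolve to the smallest cluster index.
#'
#' @param x A `dh_events`, a numeric matrix of events, or a `dist`.
#' @param block Passed to [pairwise_distances()] when distances are computed.
#' @return A `dh_dendro` binary merge tree: `n_leaves`, `merge` (hclust
#'   coding: negative entries are leaves), `height` (nondecreasing).
#' @export
build_tree <- function(x, block = 256L) {
  d <- if (inherits(x, "dist")) x else pairwise_distances(x, block)
  n <- attr(d, "Size")
  if (is.null(n)) stop("distance input lacks a Size attribute")
  res <- .ward_nnchain_cpp(as.numeric(d), as.integer(n))
  structure(list(n_leaves = as.integer(n), merge = res$merge,
                 height = res$height),
            class = "dh_dendro")
}

#' @export
print.dh_dendro <- function(x, ...) {
  cat(sprintf("<dh_dendro> Ward tree: %d leaves, %d merges, height range [%.4g, %.4g]\n",
              x$n_leaves, nrow(x$merge), min(x$height), max(x$height)))
  invisible(x)
}

# left-to-right leaf order by iterative traversal of the merge matrix
tree_leaf_order <- function(merge, n) {
  ord <- integer(n); pos <- 0L
  stack <- integer(2L * n); top <- 1L
  stack[1] <- n - 1L  # root merge row
  while (top > 0L) {
    node <- stack[top]; top <- top - 1L
    if (node < 0L) { pos <- pos + 1L; ord[pos] <- -node; next }
    stack[top + 1L] <- merge[node, 2]
    stack[top + 2L] <- merge[node, 1]
    top <- top + 2L
  }
  ord
}

#' Convert to a base-R hclust object
#' @param x A `dh_dendro`.
#' @param labels Optional leaf labels.
#' @param ... Unused.
#' @return An `hclust` object (method `"ward.D2"`).
#' @export
as.hclust.dh_dendro <- function(x, labels = NULL, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = tree_leaf_order(x$merge, x$n_leaves),
                 labels = labels, method = "ward.D2",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Export a dendrogram as a Newick string
#'
#' Merge heights are encoded as branch lengths (ultrametric tree); the
#' string round-trips through standard Newick parsers.
#'
#' @param tree A `dh_dendro`.
#' @param labels Leaf labels; default `L1..Ln`. Length must equal `n_leaves`.
#' @return A single Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree, labels = NULL) {
  stopifnot(inherits(tree, "dh_dendro"))
  if (is.null(labels)) labels <- paste0("L", seq_len(tree$n_leaves))
  if (length(labels) != tree$n_leaves)
    stop("labels length (", length(labels), ") must equal n_leaves (",
         tree$n_leaves, ")")
  phy <- ape::as.phylo(as.hclust(tree, labels = labels))
  ape::write.tree(phy)
}

#' Export the merge table as a data frame
#'
#' @param tree A `dh_dendro`.
#' @return Data frame with columns `left`, `right` (hclust node coding:
#'   negative = leaf id, positive = earlier merge row), `height`, `size`.
#' @export
linkage_table <- function(tree) {
  stopifnot(inherits(tree, "dh_dendro"))
  n <- tree$n_leaves
  size <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    s <- function(c) if (c < 0) 1 else size[c]
    size[k] <- s(tree$merge[k, 1]) + s(tree$merge[k, 2])
  }
  data.frame(left = tree$merge[, 1], right = tree$merge[, 2],
             height = tree$height, size = size)
}
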