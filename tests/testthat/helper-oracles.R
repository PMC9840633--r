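# Independent oracles used to freeze expected values. Each is deliberately
# written against a different algorithmic route than the implementation it
# checks (recursion instead of iteration, pair enumeration instead of rank
# identities), so an agreement is informative.

# random binary merge tree (uniform random agglomeration order), heights 1..n-1
random_tree <- function(n, seed) {
  set.seed(seed)
  merge <- matrix(0L, n - 1L, 2L)
  active <- as.list(-(1:n))  # hclust node codes of active roots
  for (k in seq_len(n - 1L)) {
    pick <- sample(length(active), 2)
    a <- active[[pick[1]]]; b <- active[[pick[2]]]
    merge[k, ] <- sort(c(a, b))
    active <- c(active[-pick], list(k))
  }
  structure(list(n_leaves = as.integer(n), merge = merge,
                 height = as.numeric(seq_len(n - 1L))),
            class = "dh_dendro")
}

# recursive leaf enumeration of an internal node (hclust code)
oracle_leaves <- function(merge, code) {
  if (code < 0) return(-code)
  sort(c(oracle_leaves(merge, merge[code, 1]),
         oracle_leaves(merge, merge[code, 2])))
}

# recursive, path-enumerating reimplementation of the 2-adic coding: for
# every leaf walk root -> leaf collecting digits, smallest-leaf subtree = 0
oracle_codes <- function(tree) {
  merge <- tree$merge
  n <- tree$n_leaves
  walk <- function(code, path) {
    if (code < 0) return(stats::setNames(list(path), -code))
    l1 <- oracle_leaves(merge, merge[code, 1])
    l2 <- oracle_leaves(merge, merge[code, 2])
    zero_first <- min(l1) <= min(l2)
    c(walk(merge[code, if (zero_first) 1 else 2], c(path, 0L)),
      walk(merge[code, if (zero_first) 2 else 1], c(path, 1L)))
  }
  paths <- walk(n - 1L, integer(0))
  paths <- paths[order(as.integer(names(paths)))]
  vi <- vapply(paths, function(d) sum(d * 2^(seq_along(d) - 1)), 0)
  list(digits = unname(paths), value = unname(vi))
}

# node depths of every node; leaves and internal nodes separately
oracle_depths <- function(tree) {
  merge <- tree$merge
  n <- tree$n_leaves
  leaf_depth <- integer(n); int_depth <- integer(n - 1L)
  recurse <- function(code, d) {
    if (code < 0) { leaf_depth[-code] <<- d; return(invisible()) }
    int_depth[code] <<- d
    recurse(merge[code, 1], d + 1L)
    recurse(merge[code, 2], d + 1L)
  }
  recurse(n - 1L, 0L)
  list(leaf = leaf_depth, internal = int_depth)
}

# threshold line at depth e dissects one subtree per node sitting exactly at
# depth e, plus every leaf that ends above the line; this equals the count
# of branches with Vi < 2^e
oracle_dissection_count <- function(tree, e) {
  d <- oracle_depths(tree)
  sum(d$internal == e) + sum(d$leaf == e) + sum(d$leaf < e)
}

# brute-force Mann-Whitney AUC by pair enumeration (ties count half)
oracle_auc_pairs <- function(neg, pos) {
  wins <- 0
  for (x in neg) for (y in pos)
    wins <- wins + (y > x) + 0.5 * (y == x)
  wins / (length(neg) * length(pos))
}

# trapezoidal area under an ROC curve data frame
oracle_auc_trapezoid <- function(curve) {
  o <- order(curve$fpf, curve$tpf)
  x <- curve$fpf[o]; y <- curve$tpf[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# canonical partition signature of a merge tree: sorted leaf sets
partition_signature <- function(merge, n) {
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    g <- function(c) if (c < 0) -c else sets[[c]]
    sets[[k]] <- sort(c(g(merge[k, 1]), g(merge[k, 2])))
  }
  sort(vapply(sets, paste, "", collapse = ","))
}
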