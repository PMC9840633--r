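# 2-adic encoding of a binary dendrogram. Each leaf's root-to-leaf path is a
# binary digit string a_0..a_k (a_0 at the root split) whose value is
# Vi = sum_j a_j 2^j. Frozen conventions (they change individual Vi values,
# so they are part of the signature's definition):
#   * a_0 is the digit chosen at the ROOT split (root = lowest-order digit),
#     which makes |Va - Vb|_2 small exactly when the shared root-branch is
#     long;
#   * at every internal node the child subtree containing the smallest leaf
#     id receives digit 0, the other digit 1.
# Vi can exceed 2^53 for deep trees; all signature comparisons are therefore
# carried out on the 2-adic ball (the highest set-bit index), which is exact
# for any depth. The numeric `value` field is NA whenever it would be
# inexact; `value_bits` always carries the exact binary representation.

# rolling polynomial hash (mod 2^31 - 1) over a string; cheap content
# identity for trees and configs, not cryptographic
content_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

tree_uid <- function(tree) {
  content_hash(paste(c(tree$n_leaves, as.integer(tree$merge),
                       signif(tree$height, 12)), collapse = ","))
}

#' Assign 2-adic branch codes to every leaf of a dendrogram
#'
#' Walks the binary tree from the root; at each internal node the child
#' subtree containing the smallest leaf id receives digit 0, the other
#' digit 1. Digits are ordered a_0 (root split) .. a_k (final split), so a
#' leaf's value is `Vi = sum_j a_j 2^j` and two leaves' common-prefix length
#' equals the depth of their lowest common ancestor.
#'
#' @param tree A `dh_dendro` from [build_tree()].
#' @return A `dh_coded`: the tree plus per-leaf `digits` (list of 0/1
#'   integer vectors), `ball` (`floor(log2 Vi)`; `-Inf` for the all-zeros
#'   leaf), `value` (numeric `Vi`, `NA` when `Vi >= 2^53`), `value_bits`
#'   (exact binary string, most significant bit first), and `max_ball`.
#' @export
assign_codes <- function(tree) {
  stopifnot(inherits(tree, "dh_dendro"))
  n <- tree$n_leaves
  merge <- tree$merge
  if (ncol(merge) != 2) stop("non-binary tree: merge table must have 2 children per node")
  # smallest leaf id within each internal node's subtree
  minleaf <- integer(n - 1)
  for (k in seq_len(n - 1)) {
    ml <- function(c) if (c < 0) -c else minleaf[c]
    minleaf[k] <- min(ml(merge[k, 1]), ml(merge[k, 2]))
  }
  digits <- vector("list", n)
  cur <- integer(n)  # digits along the current root path; cur[d] = a_{d-1}
  # DFS stack of (node code, depth, incoming digit)
  stack_code <- integer(2L * n); stack_depth <- integer(2L * n)
  stack_digit <- integer(2L * n)
  push <- function(top, code, depth, digit) {
    stack_code[top] <<- code; stack_depth[top] <<- depth
    stack_digit[top] <<- digit
  }
  root <- n - 1L
  c1 <- merge[root, 1]; c2 <- merge[root, 2]
  ml <- function(c) if (c < 0) -c else minleaf[c]
  zero_child <- if (ml(c1) <= ml(c2)) c1 else c2
  one_child <- if (identical(zero_child, c1)) c2 else c1
  top <- 2L
  push(1L, one_child, 1L, 1L)
  push(2L, zero_child, 1L, 0L)
  while (top > 0L) {
    code <- stack_code[top]; d <- stack_depth[top]; dg <- stack_digit[top]
    top <- top - 1L
    cur[d] <- dg
    if (code < 0L) { digits[[-code]] <- cur[seq_len(d)]; next }
    c1 <- merge[code, 1]; c2 <- merge[code, 2]
    zc <- if (ml(c1) <= ml(c2)) c1 else c2
    oc <- if (identical(zc, c1)) c2 else c1
    push(top + 1L, oc, d + 1L, 1L)
    push(top + 2L, zc, d + 1L, 0L)
    top <- top + 2L
  }
  ball <- vapply(digits, function(d) {
    ones <- which(d == 1L)
    if (length(ones) == 0) -Inf else max(ones) - 1
  }, 0)
  value <- vapply(digits, function(d) {
    ones <- which(d == 1L)
    if (length(ones) == 0) return(0)
    if (max(ones) - 1 > 52) return(NA_real_)
    sum(2^(ones - 1))
  }, 0)
  value_bits <- vapply(digits, function(d) {
    ones <- which(d == 1L)
    if (length(ones) == 0) return("0")
    paste(rev(d[seq_len(max(ones))]), collapse = "")
  }, "")
  structure(list(tree = tree, digits = digits, ball = ball, value = value,
                 value_bits = value_bits, max_ball = max(ball),
                 n_leaves = n, uid = tree_uid(tree)),
            class = "dh_coded")
}

#' @export
print.dh_coded <- function(x, ...) {
  cat(sprintf("<dh_coded> %d leaves, max 2-adic ball %s\n", x$n_leaves,
              format(x$max_ball)))
  invisible(x)
}

#' Extract one leaf's branch code
#' @param coded A `dh_coded`.
#' @param leaf_id Leaf index (1-based event row).
#' @return A `dh_branch_code` with `leaf_id`, `digits`, `depth`, `value`,
#'   `value_bits`, `ball`, and the owning tree's `tree_uid`.
#' @export
branch_code <- function(coded, leaf_id) {
  stopifnot(inherits(coded, "dh_coded"))
  if (leaf_id < 1 || leaf_id > coded$n_leaves) stop("leaf_id out of range")
  structure(list(leaf_id = as.integer(leaf_id),
                 digits = coded$digits[[leaf_id]],
                 depth = length(coded$digits[[leaf_id]]),
                 value = coded$value[leaf_id],
                 value_bits = coded$value_bits[leaf_id],
                 ball = coded$ball[leaf_id],
                 tree_uid = coded$uid),
            class = "dh_branch_code")
}

#' 2-adic distance between two branch codes
#'
#' `2^(-L)` where `L` is the common-prefix length of the two digit strings;
#' 0 for a code against itself. The longer the common root-branch, the
#' smaller the distance.
#'
#' @param code_a,code_b `dh_branch_code`s from the same coded tree.
#' @return A nonnegative number.
#' @export
two_adic_distance <- function(code_a, code_b) {
  stopifnot(inherits(code_a, "dh_branch_code"),
            inherits(code_b, "dh_branch_code"))
  if (!identical(code_a$tree_uid, code_b$tree_uid))
    stop("branch codes come from different trees")
  if (code_a$leaf_id == code_b$leaf_id) return(0)
  a <- code_a$digits; b <- code_b$digits
  L <- 0L
  m <- min(length(a), length(b))
  while (L < m && a[L + 1L] == b[L + 1L]) L <- L + 1L
  2^(-L)
}

#' 2-adic ball of a branch value
#'
#' `floor(log2(Vi))` for `Vi >= 1`; the all-zeros branch (`Vi = 0`) has no
#' finite ball and returns `-Inf`, placing it below every threshold
#' exponent (it always counts toward PUDHS/E).
#'
#' @param vi Nonnegative integer-valued numeric (vectorized).
#' @return `floor(log2(vi))`, with `-Inf` at `vi = 0`.
#' @export
ball_of <- function(vi) {
  if (any(!is.finite(vi)) || any(vi < 0) || any(abs(vi - round(vi)) > 0))
    stop("Vi must be a nonnegative integer")
  out <- rep(-Inf, length(vi))
  pos <- vi >= 1
  if (any(pos)) {
    e <- floor(log2(vi[pos]))
    # repair any floating-log boundary error exactly
    e <- ifelse(2^e > vi[pos], e - 1, e)
    e <- ifelse(2^(e + 1) <= vi[pos], e + 1, e)
    out[pos] <- e
  }
  out
}

#' Export branch codes as a data frame
#' @param coded A `dh_coded`.
#' @return Data frame: `leaf_id`, `digits` (path string a_0..a_k), `value`,
#'   `value_bits`, `ball`.
#' @export
codes_table <- function(coded) {
  stopifnot(inherits(coded, "dh_coded"))
  data.frame(leaf_id = seq_len(coded$n_leaves),
             digits = vapply(coded$digits, paste, "", collapse = ""),
             value = coded$value, value_bits = coded$value_bits,
             ball = coded$ball)
}
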