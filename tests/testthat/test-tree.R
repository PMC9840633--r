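test_that("pairwise distances match hand values and the pair count", {
  d <- pairwise_distances(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(as.numeric(d), 5.0)

  x <- matrix(rnorm(50), 10, 5)
  expect_equal(length(pairwise_distances(x)), 10 * 9 / 2)
  expect_equal(as.numeric(pairwise_distances(x)), as.numeric(dist(x)),
               tolerance = 1e-12)

  same <- matrix(1, 3, 4)
  expect_true(all(as.numeric(pairwise_distances(same)) == 0))
  expect_error(pairwise_distances(matrix(1, 1, 4)), "at least 2")
})

test_that("Ward tree matches the hand-computed 3-point example", {
  tr <- toy_tree3()
  expect_equal(nrow(tr$merge), 2)
  # first merge joins leaves 1,2 (positions 0 and 1); root attaches leaf 3
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))
  expect_true(-3L %in% tr$merge[2, ])
  expect_equal(tr$height[1], 1)                      # singleton pair: d itself
  expect_equal(tr$height[2], sqrt(2 * (2 / 3) * 9.5^2))  # Ward cost of {0,1}+{10}
})

test_that("n events give n-1 merges and two far clusters split at the root", {
  set.seed(1)
  x <- matrix(rnorm(12 * 3), 12, 3)
  tr <- build_tree(x)
  expect_equal(nrow(tr$merge), 11)

  y <- matrix(c(rep(0, 5), rep(100, 5)), ncol = 1)
  tr2 <- build_tree(y)
  root_sides <- lapply(tr2$merge[9, ], function(c) oracle_leaves(tr2$merge, c))
  expect_setequal(vapply(root_sides, paste, "", collapse = ","),
                  c("1,2,3,4,5", "6,7,8,9,10"))
})

test_that("heights are nondecreasing along the merge sequence", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- build_tree(matrix(rnorm(30 * 4), 30, 4))
    expect_true(all(diff(tr$height) >= -1e-12))
  }
})

test_that("agreement with hclust ward.D2 on random distinct-distance inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:50, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    ours <- build_tree(x)
    ref <- hclust(dist(x), method = "ward.D2")
    expect_identical(partition_signature(ours$merge, n),
                     partition_signature(ref$merge, n))
    expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-8)
  }
})

test_that("permuting input rows yields an isomorphic tree", {
  set.seed(6)
  x <- matrix(rnorm(15 * 4), 15, 4)
  perm <- sample(15)
  t1 <- build_tree(x)
  t2 <- build_tree(x[perm, ])
  sig1 <- partition_signature(t1$merge, 15)
  # map t2 leaf ids back through the permutation
  relabel <- function(sig) {
    vapply(strsplit(sig, ","), function(s)
      paste(sort(perm[as.integer(s)]), collapse = ","), "")
  }
  expect_setequal(relabel(partition_signature(t2$merge, 15)), sig1)
})

test_that("newick export round-trips topology and branch lengths", {
  tr <- toy_tree3()
  nwk <- to_newick(tr, c("A", "B", "C"))
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), c("A", "B", "C"))
  # topology ((A,B),C): A and B are sisters
  mrca <- ape::getMRCA(phy, c("A", "B"))
  expect_equal(length(ape::extract.clade(phy, mrca)$tip.label), 2)

  t2 <- build_tree(matrix(c(0, 2), ncol = 1))
  expect_match(to_newick(t2, c("A", "B")), "^\\(A:1,B:1\\);$")
  expect_error(to_newick(tr, c("A", "B")), "labels length")

  set.seed(7)
  tbig <- build_tree(matrix(rnorm(40), 20, 2))
  rt <- ape::read.tree(text = to_newick(tbig))
  expect_equal(ape::Ntip(rt), 20)
  if (requireNamespace("phangorn", quietly = TRUE)) {
    ref <- ape::as.phylo(as.hclust(tbig, labels = paste0("L", 1:20)))
    expect_equal(phangorn::RF.dist(rt, ref), 0)
  }
})

test_that("non-finite distances are rejected", {
  d <- pairwise_distances(matrix(rnorm(12), 4, 3))
  d[2] <- NaN
  expect_error(build_tree(d), "non-finite")
})

test_that("linkage table reports sizes summing to the root", {
  tr <- build_tree(matrix(rnorm(16), 8, 2))
  lt <- linkage_table(tr)
  expect_equal(nrow(lt), 7)
  expect_equal(lt$size[7], 8)
})
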