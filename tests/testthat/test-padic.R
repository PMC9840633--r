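test_that("the 3-leaf worked example codes as V = {0, 2, 1} with max_ball 1", {
  cd <- assign_codes(toy_tree3())
  tab <- codes_table(cd)
  expect_equal(tab$digits, c("00", "01", "1"))
  expect_equal(tab$value, c(0, 2, 1))
  expect_equal(tab$ball, c(-Inf, 1, 0))
  expect_equal(cd$max_ball, 1)
})

test_that("2-leaf and balanced 4-leaf trees enumerate the expected values", {
  t2 <- build_tree(matrix(c(0, 1), ncol = 1))
  expect_setequal(assign_codes(t2)$value, c(0, 1))

  # two tight pairs far apart -> balanced 4-leaf tree
  t4 <- build_tree(matrix(c(0, 1, 100, 101), ncol = 1))
  expect_setequal(assign_codes(t4)$value, c(0, 1, 2, 3))
})

test_that("2-adic distance follows common-prefix length and identity", {
  cd <- assign_codes(toy_tree3())
  A <- branch_code(cd, 1); B <- branch_code(cd, 2); C <- branch_code(cd, 3)
  expect_equal(two_adic_distance(A, B), 1 / 2)
  expect_equal(two_adic_distance(A, C), 1)
  expect_equal(two_adic_distance(B, C), 1)
  expect_equal(two_adic_distance(A, A), 0)

  other <- assign_codes(build_tree(matrix(c(0, 5, 6), ncol = 1)))
  expect_error(two_adic_distance(A, branch_code(other, 1)), "different trees")
})

test_that("ball_of handles floors, powers of two, and the zero sentinel", {
  expect_equal(ball_of(1), 0)
  expect_equal(ball_of(c(2, 3)), c(1, 1))
  expect_equal(ball_of(1024), 10)
  expect_equal(ball_of(0), -Inf)
  expect_equal(ball_of(2^40 - 1), 39)
  expect_equal(ball_of(2^40), 40)
  expect_error(ball_of(-1), "nonnegative")
  expect_error(ball_of(2.5), "integer")
})

test_that("codes agree with the recursive path-enumeration oracle", {
  for (seed in 1:200) {
    n <- 2 + (seed %% 15)
    tr <- random_tree(n, seed)
    got <- assign_codes(tr)
    want <- oracle_codes(tr)
    expect_identical(got$digits, want$digits)
    expect_equal(got$value, want$value)
  }
})

test_that("tree-induced 2-adic distance is ultrametric", {
  for (seed in 1:20) {
    n <- sample(3:16, 1)
    tr <- random_tree(n, seed + 1000)
    cd <- assign_codes(tr)
    codes <- lapply(seq_len(n), branch_code, coded = cd)
    for (x in 1:n) for (y in 1:n) for (z in 1:n) {
      dxz <- two_adic_distance(codes[[x]], codes[[z]])
      dxy <- two_adic_distance(codes[[x]], codes[[y]])
      dyz <- two_adic_distance(codes[[y]], codes[[z]])
      expect_lte(dxz, max(dxy, dyz))
    }
  }
})

test_that("codes form a prefix code and identify leaves uniquely", {
  for (seed in 1:20) {
    n <- sample(4:16, 1)
    tr <- random_tree(n, seed + 2000)
    cd <- assign_codes(tr)
    strs <- vapply(cd$digits, paste, "", collapse = "")
    expect_equal(anyDuplicated(strs), 0)
    # paths end at leaves, so no code may be a prefix of another
    for (i in seq_len(n)) for (j in seq_len(n))
      if (i != j) expect_false(startsWith(strs[j], strs[i]))
  }
})

test_that("longer common prefix means strictly smaller 2-adic distance", {
  cd <- assign_codes(random_tree(12, 99))
  codes <- lapply(1:12, branch_code, coded = cd)
  prefix_len <- function(a, b) {
    m <- min(length(a$digits), length(b$digits)); L <- 0L
    while (L < m && a$digits[L + 1] == b$digits[L + 1]) L <- L + 1L
    L
  }
  pairs <- utils::combn(12, 2, simplify = FALSE)
  L <- vapply(pairs, function(p) prefix_len(codes[[p[1]]], codes[[p[2]]]), 0L)
  d <- vapply(pairs, function(p)
    two_adic_distance(codes[[p[1]]], codes[[p[2]]]), 0)
  for (l in sort(unique(L))) for (l2 in sort(unique(L))) {
    if (l < l2) expect_gt(min(d[L == l]), max(d[L == l2]))
  }
})

test_that("deep chain trees exceed 53-bit values but keep exact balls", {
  # hand-built caterpillar: leaf 2 sits at depth n-1, so its V is 2^(n-2)
  n <- 70
  merge <- matrix(0L, n - 1, 2)
  merge[1, ] <- c(-1L, -2L)
  for (k in 2:(n - 1)) merge[k, ] <- c(as.integer(k - 1), -as.integer(k + 1))
  tr <- structure(list(n_leaves = n, merge = merge,
                       height = as.numeric(1:(n - 1))), class = "dh_dendro")
  cd <- assign_codes(tr)
  expect_true(any(is.na(cd$value)))          # beyond exact double range
  expect_true(all(cd$ball[is.na(cd$value)] > 52))
  expect_equal(nchar(cd$value_bits[which.max(cd$ball)]), cd$max_ball + 1)
})
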