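test_that("truncated SVD recovers a diagonal spectrum with the sign convention", {
  s <- truncated_svd(diag(c(3, 2, 1)), L = 2)
  expect_equal(s$d, c(3, 2))
  expect_equal(abs(s$u[, 1]), c(1, 0, 0), tolerance = 1e-12)
  # convention: the largest-magnitude entry of each u column is positive
  expect_gt(s$u[1, 1], 0)
  expect_gt(s$u[2, 2], 0)
  expect_equal(s$u[, 1] * s$v[, 1], c(1, 0, 0), tolerance = 1e-12)
  expect_error(truncated_svd(diag(3), L = 4), "exceeds")
})

test_that("dense and sparse paths match a full-decomposition oracle", {
  set.seed(21)
  x <- matrix(rnorm(80 * 40), 80, 40)
  s <- truncated_svd(x, L = 5)
  full <- svd(x)
  expect_equal(s$d, full$d[1:5], tolerance = 1e-9)
  expect_lt(principal_angle(s$u, full$u[, 1:5]), 1e-6)
  expect_lt(principal_angle(s$v, full$v[, 1:5]), 1e-6)
  # orthonormal factors
  expect_lt(max(abs(crossprod(s$u) - diag(5))), 1e-8)
  expect_lt(max(abs(crossprod(s$v) - diag(5))), 1e-8)

  xs <- Matrix::rsparsematrix(2000, 100, 0.03)
  ss <- truncated_svd(xs, L = 10)
  ds <- svd(as.matrix(xs), nu = 0, nv = 0)$d
  expect_equal(ss$d, ds[1:10], tolerance = 1e-8)
})

test_that("rank-L truncation is the best among the oracle's L-subsets", {
  set.seed(22)
  x <- matrix(rnorm(30 * 20), 30, 20)
  L <- 4
  s <- truncated_svd(x, L)
  err_pkg <- norm(x - s$u %*% diag(s$d) %*% t(s$v), "F")
  full <- svd(x)
  for (rep in 1:10) {
    subset <- sort(sample(20, L))
    recon <- full$u[, subset] %*% diag(full$d[subset]) %*% t(full$v[, subset])
    expect_lte(err_pkg, norm(x - recon, "F") + 1e-10)
  }
})

test_that("feature projection equals the brute-force contraction", {
  set.seed(23)
  u1 <- rnorm(50); u1 <- u1 / sqrt(sum(u1^2))
  v1 <- rnorm(12); v1 <- v1 / sqrt(sum(v1^2))
  x <- 3 * tcrossprod(u1, v1)
  s <- truncated_svd(x, L = 1)
  p <- project_features(s, x)
  expect_equal(abs(as.numeric(p)), abs(3 * v1), tolerance = 1e-10)
  # and equals d * v' exactly for exact-low-rank input
  expect_equal(as.numeric(p), s$d[1] * s$v[, 1], tolerance = 1e-10)

  expect_equal(project_features(s, matrix(0, 50, 12)), matrix(0, 1, 12))

  xs <- Matrix::rsparsematrix(300, 40, 0.1)
  ss <- truncated_svd(xs, L = 6)
  ps <- project_features(ss, xs)
  brute <- matrix(0, 6, 40)
  dx <- as.matrix(xs)
  for (l in 1:6) for (j in 1:40)
    brute[l, j] <- sum(ss$u[, l] * dx[, j])
  expect_equal(unname(ps), brute, tolerance = 1e-10)

  expect_error(project_features(ss, xs[-1, ]), "mismatch")
})

test_that("projection-through-SVD is invariant to cell order", {
  set.seed(24)
  x <- matrix(rnorm(60 * 15), 60, 15, dimnames = list(NULL, paste0("c", 1:15)))
  s <- truncated_svd(x, L = 3)
  p <- project_features(s, x)
  perm <- sample(15)
  s2 <- truncated_svd(x[, perm], L = 3)
  p2 <- project_features(s2, x[, perm])
  # same cells must get the same projected coordinates up to column sign
  for (l in 1:3) {
    a <- p[l, ]; b <- p2[l, colnames(x)]
    expect_equal(abs(unname(a)), abs(unname(b)), tolerance = 1e-8)
  }
})

test_that("a site-scale sparse matrix is decomposed without densification", {
  set.seed(25)
  x <- Matrix::rsparsematrix(1e6, 200, 0.03)
  s <- truncated_svd(x, L = 10)
  expect_length(s$d, 10)
  expect_true(all(diff(s$d) <= 1e-8))
  expect_lt(max(abs(crossprod(s$v) - diag(10))), 1e-8)
})

test_that("tensor stacking aligns layers on the shared cells", {
  p1 <- matrix(1:9, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  p2 <- matrix(11:19, 3, dimnames = list(NULL, c("c2", "c3", "c4")))
  t1 <- stack_tensor(list(expression = p1, methylation = p2))
  expect_equal(t1$cell_ids, c("c2", "c3"))
  expect_equal(dim(t1$values), c(3L, 2L, 2L))
  expect_equal(unname(t1$values[, , 1]), unname(p1[, c("c2", "c3")]))
  expect_equal(unname(t1$values[, , 2]), unname(p2[, c("c2", "c3")]))

  # identical cell sets copy verbatim; shuffling one layer changes nothing
  p3 <- matrix(21:29, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  t2 <- stack_tensor(list(a = p1, b = p3))
  expect_equal(unname(t2$values[, , 2]), unname(p3))
  t3 <- stack_tensor(list(a = p1, b = p3[, c(3, 1, 2)]))
  expect_equal(t2$values, t3$values)

  p4 <- matrix(1:6, 3, dimnames = list(NULL, c("x1", "x2")))
  expect_error(stack_tensor(list(a = p1, b = p4)), "shared")
  expect_error(stack_tensor(list(a = p1)), "at least 2")
  expect_error(stack_tensor(list(a = p1, b = rbind(p3, 0))), "same reduced rank")
})
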