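test_that("back-projection is the documented contraction", {
  set.seed(51)
  u <- qr.Q(qr(matrix(rnorm(40 * 5), 40, 5)))
  rownames(u) <- paste0("g", 1:40)
  # identity feature-mode factor returns the layer's own left vectors
  expect_equal(unname(backproject(diag(5), u, 3)), u[, 3], ignore_attr = TRUE)
  expect_equal(names(backproject(diag(5), u, 3)), rownames(u))
  # L = 1 reduces to a scalar multiple
  expect_equal(unname(backproject(matrix(0.7), u[, 1, drop = FALSE], 1)),
               0.7 * unname(u[, 1]))
  # brute-force double loop
  m1 <- matrix(rnorm(25), 5, 5)
  bp <- backproject(m1, u, 2)
  brute <- numeric(40)
  for (i in 1:40) for (l in 1:5) brute[i] <- brute[i] + m1[l, 2] * u[i, l]
  expect_equal(unname(bp), brute, tolerance = 1e-12)
  expect_error(backproject(m1, u[, 1:4], 2), "mismatch")
  expect_error(backproject(m1, u, 9), "out of range")
})

test_that("chi-squared p-values follow the standardized sum of squares", {
  expect_equal(chi2_pvalues(matrix(0, 5, 2), scales = c(1, 1))$p.value,
               rep(1, 5))
  # single component: |u|/sigma = 1.959964 sits at the 5% tail
  p <- chi2_pvalues(matrix(1.959964), scales = 1)$p.value
  expect_equal(p, 0.05, tolerance = 1e-6)

  set.seed(52)
  u <- matrix(rnorm(1e4, sd = 0.3))
  p <- chi2_pvalues(u, scales = 0.3)$p.value
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)

  # scale invariance: scaling a column and its sigma together is a no-op
  u2 <- cbind(rnorm(50), rnorm(50))
  p1 <- chi2_pvalues(u2, scales = c(1, 2))$p.value
  u2b <- u2; u2b[, 1] <- u2[, 1] * 13
  p2 <- chi2_pvalues(u2b, scales = c(13, 2))$p.value
  expect_equal(p1, p2, tolerance = 1e-12)

  # monotone: growing one |loading| never increases its p
  base <- chi2_pvalues(matrix(c(1, 2), 2, 1), scales = 1)$p.value
  expect_lt(base[2], base[1])

  expect_error(chi2_pvalues(matrix(0, 3, 1), scales = "estimate"), "positive")
  expect_error(chi2_pvalues(matrix(rnorm(6), 3, 2), scales = 1), "one scale")
  # zero-mean variant differs from the centered estimate when shifted
  shifted <- matrix(rnorm(200) + 5)
  s_c <- chi2_pvalues(shifted, center = TRUE)$scales
  s_z <- chi2_pvalues(shifted, center = FALSE)$scales
  expect_gt(s_z, s_c)
})

test_that("feature selection recovers a planted tail at BH alpha", {
  p_all1 <- select_features(rep(1, 10))
  expect_equal(sum(p_all1$selected), 0)
  everything <- select_features(runif(10), alpha = 1)
  expect_equal(sum(everything$selected), 10)

  set.seed(53)
  sigma <- 0.5
  loadings <- matrix(rnorm(2000, sd = sigma))
  planted <- sample(2000, 50)
  loadings[planted] <- 6 * sigma * sample(c(-1, 1), 50, replace = TRUE)
  rownames(loadings) <- sprintf("g%04d", 1:2000)
  chi <- chi2_pvalues(loadings, scales = sigma)
  res <- select_features(chi$p.value, alpha = 0.01,
                         feature_ids = rownames(loadings),
                         statistic = chi$statistic, loadings = loadings)
  sel <- res$feature_id[res$selected]
  expect_true(all(sprintf("g%04d", planted) %in% sel))
  expect_lte(length(setdiff(sel, sprintf("g%04d", planted))), 1)
  # ordered by adjusted p then id
  expect_true(!is.unsorted(res$adj.p.value))

  d <- withr::local_tempdir()
  f <- write_gene_list(res, file.path(d, "genes.txt"))
  expect_equal(sort(readLines(f)), sort(sel))
})
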