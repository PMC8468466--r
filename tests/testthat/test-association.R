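test_that("categorical regression matches a hand-rolled ANOVA and handles edges", {
  v <- c(1, 1, 1, 0, 0, 0)
  g <- factor(rep(c("A", "B"), each = 3))
  fit <- categorical_regression_p(v, g)
  expect_lt(fit$p.value, 1e-12)
  expect_equal(sort(fit$coefficients), c(0, 1))

  const <- categorical_regression_p(rep(2, 8), factor(rep(1:2, each = 4)))
  expect_equal(const$p.value, 1)
  expect_equal(const$fstat, 0)

  set.seed(41)
  for (i in 1:100) {
    m <- 60
    v <- rnorm(m)
    g <- factor(sample(3, m, replace = TRUE))
    while (any(table(g) < 2)) g <- factor(sample(3, m, replace = TRUE))
    expect_equal(categorical_regression_p(v, g)$p.value,
                 oracle_anova_p(v, g), tolerance = 1e-10)
  }

  expect_error(categorical_regression_p(rnorm(4), factor(c(1, 1, 1, 2))),
               "at least 2 cells")
  expect_error(categorical_regression_p(rnorm(4), factor(1:4)),
               "at least 2")
})

test_that("the F-test is invariant to relabeling and affine transforms", {
  set.seed(42)
  v <- rnorm(45)
  g <- factor(sample(c("x", "y", "z"), 45, replace = TRUE))
  p0 <- categorical_regression_p(v, g)$p.value
  relab <- factor(c(x = "3", y = "1", z = "2")[as.character(g)])
  expect_equal(categorical_regression_p(v, relab)$p.value, p0,
               tolerance = 1e-12)
  expect_equal(categorical_regression_p(-2.5 * v + 7, g)$p.value, p0,
               tolerance = 1e-10)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    # monotone in the raw p-values
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
    expect_true(all(adj >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("raw p-values are calibrated under the global null", {
  set.seed(44)
  m <- 40
  g <- factor(rep(1:4, each = 10))
  p <- replicate(2000, categorical_regression_p(rnorm(m), g)$p.value)
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("coincident-vector selection flags planted signal and controls the null", {
  set.seed(45)
  m <- 300
  g <- factor(rep(1:3, each = 100))
  noise <- matrix(rnorm(m * 29), m, 29)
  signal <- as.numeric(g) + rnorm(m, sd = 0.05)
  vectors <- cbind(noise[, 1:15], signal, noise[, 16:29])
  res <- select_coincident(vectors, g, alpha = 0.01)
  expect_s3_class(res, "td_association")
  expect_true(res$selected[16])
  expect_true(all(res$adj.p.value >= res$p.value - 1e-15))
  expect_equal(res$selected, res$adj.p.value < 0.01)

  # pure noise: selections at alpha = 0.01 are rare
  hits <- vapply(1:40, function(i) {
    v <- matrix(rnorm(m * 30), m, 30)
    sum(select_coincident(v, g, alpha = 0.01)$selected)
  }, 0L)
  expect_gte(mean(hits == 0), 0.95)

  none <- select_coincident(vectors, g, alpha = 0)
  expect_equal(sum(none$selected), 0)
})

test_that("core-energy ranking follows the summed squared core", {
  core <- array(0, c(4, 6, 3))
  core[2, 3, 1] <- 5
  h <- structure(list(core = core), class = "td_hosvd")
  r <- rank_l1_by_core(h, selected_l2 = c(3, 4))
  expect_equal(r$l1[1], 2L)
  expect_equal(r$core_energy[1], 25)
  expect_equal(r$core_energy[-1], rep(0, 3))

  set.seed(46)
  core <- array(rnorm(4 * 6 * 3), c(4, 6, 3))
  h <- structure(list(core = core), class = "td_hosvd")
  sel <- c(1, 4, 5)
  r <- rank_l1_by_core(h, sel)
  brute <- numeric(4)
  for (l1 in 1:4) for (l2 in sel) for (l3 in 1:3)
    brute[l1] <- brute[l1] + core[l1, l2, l3]^2
  expect_equal(r$core_energy, sort(brute, decreasing = TRUE),
               tolerance = 1e-12)
  expect_equal(r$core_energy[match(1:4, r$l1)], brute, tolerance = 1e-12)

  # with all l2 selected the HOSVD ordering makes scores non-increasing
  set.seed(47)
  tens <- array(rnorm(5 * 10 * 3), c(5, 10, 3))
  hh <- hosvd(tens)
  rr <- rank_l1_by_core(hh, seq_len(dim(hh$core)[2]))
  expect_equal(rr$l1, 1:5)

  expect_error(rank_l1_by_core(h, integer()), "no coincident")
  expect_error(rank_l1_by_core(h, 99), "out of range")
})
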