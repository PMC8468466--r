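test_that("simulation is a deterministic function of its spec", {
  s1 <- simulate_multiomics(small_spec(seed = 5))
  s2 <- simulate_multiomics(small_spec(seed = 5))
  expect_identical(as.matrix(s1$expression$values),
                   as.matrix(s2$expression$values))
  expect_identical(s1$met_sites, s2$met_sites)
  expect_identical(s1$acc_sites, s2$acc_sites)
  expect_identical(s1$planted, s2$planted)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_multiomics(s1, d1); write_multiomics(s2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("generated layers satisfy their value-range and label invariants", {
  sim <- simulate_multiomics(small_spec(seed = 6))
  expect_true(all(sim$methylation$values@x %in% c(-1, 1)))
  expect_true(all(sim$accessibility$values@x >= 0))
  expect_true(all(as.matrix(sim$expression$values) >= 0))
  expect_setequal(sim$labels$cell_id, cell_ids(sim$expression))
  expect_true(all(sim$planted$genes %in% feature_ids(sim$expression)))
  expect_true(all(sim$planted$methylation %in% feature_ids(sim$methylation)))
  expect_true(all(sim$planted$accessibility %in%
                    feature_ids(sim$accessibility)))
  for (s in sim$met_sites)
    expect_true(all(s$value >= 0 & s$value <= 1))
})

test_that("study-scale defaults hit the target sparsity regime", {
  sim <- simulate_multiomics(simulation_spec(seed = 7))
  spec <- sim$spec
  expect_lt(abs(nonzero_fraction(sim$expression) - spec$expr_nonzero),
            0.2 * spec$expr_nonzero)
  expect_lt(abs(nonzero_fraction(sim$methylation) - spec$met_obs_prob),
            0.2 * spec$met_obs_prob)
  expect_lt(abs(nonzero_fraction(sim$accessibility) - spec$acc_obs_prob),
            0.2 * spec$acc_obs_prob)
})

test_that("infeasible specifications are rejected", {
  expect_error(simulation_spec(n_genes = 10, planted_genes = 20),
               "planted")
  expect_error(simulation_spec(n_cells = 4, n_classes = 3), "at least 2")
  expect_error(simulation_spec(met_obs_prob = 0), "probabilities")
  expect_error(simulation_spec(effect = -1), "nonnegative")
})

test_that("the written dialects are exactly what the readers ingest", {
  sim <- simulate_multiomics(small_spec(seed = 8))
  d <- withr::local_tempdir()
  write_multiomics(sim, d)
  expr <- read_expression_matrix(file.path(d, "expression.tsv"))
  expect_equal(as.matrix(expr$values), as.matrix(sim$expression$values))
  lab <- read_labels(file.path(d, "labels.tsv"))
  expect_equal(as.character(lab$label), as.character(sim$labels$label))
  met_files <- list.files(file.path(d, "met"), full.names = TRUE)
  met <- read_site_files(met_files)
  rebuilt <- suppressWarnings(build_ternary_methylation(met))
  expect_equal(as.matrix(rebuilt$values)[feature_ids(sim$methylation),
                                         cell_ids(sim$methylation)],
               as.matrix(sim$methylation$values))
})

test_that("the toy worked example matches its hand-computed manifest", {
  toy <- toy_worked_example()
  met <- build_ternary_methylation(toy$met_sites)
  expect_equal(as.matrix(met$values), toy$expected$methylation)
  acc <- bin_accessibility(toy$acc_sites)
  expect_equal(as.matrix(acc$values), toy$expected$accessibility)

  # the toy analysis tensor is (L = 3, M = 6, K = 3) and HOSVD is exact
  L <- toy$expected$tensor_dim[["L"]]
  layers <- list(expression = normalize_center_scale(toy$expression),
                 methylation = normalize_l1(met)$values,
                 accessibility = normalize_l1(acc)$values)
  projections <- lapply(layers, function(x) {
    s <- suppressWarnings(truncated_svd(x, L = L))  # tiny ranks may tie
    project_features(s, x)
  })
  tens <- stack_tensor(projections)
  expect_equal(unname(dim(tens$values)), unname(toy$expected$tensor_dim))
  h <- hosvd(tens)
  expect_lt(norm_rel(reconstruct(h) - tens$values, tens$values), 1e-10)
})
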