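# Independent brute-force oracles used to check the package's
# implementations. These deliberately avoid the code paths they verify.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Relative Frobenius norm of a deviation against a reference array.
norm_rel <- function(x, ref) sqrt(sum(x^2)) / sqrt(sum(ref^2))

# Benjamini-Hochberg step-up by its definition:
# adjusted p_(i) = min_{j >= i} min(1, p_(j) * n / j), mapped back.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n))
    adj[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# One-way ANOVA F-test p-value from group sums, written from the
# textbook decomposition rather than any model-fitting machinery.
oracle_anova_p <- function(v, g) {
  g <- factor(g)
  n <- length(v)
  k <- nlevels(g)
  grand <- mean(v)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    x <- v[g == lev]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# Mode-n matricization by explicit index loops (small tensors only).
oracle_unfold <- function(arr, n) {
  d <- dim(arr)
  rest <- setdiff(1:3, n)
  out <- matrix(0, d[n], prod(d[rest]))
  for (i1 in seq_len(d[1])) for (i2 in seq_len(d[2])) for (i3 in seq_len(d[3])) {
    idx <- c(i1, i2, i3)
    col <- (idx[rest[2]] - 1) * d[rest[1]] + idx[rest[1]]
    out[idx[n], col] <- arr[i1, i2, i3]
  }
  out
}

# Largest principal angle (in radians) between the column spaces of two
# matrices with orthonormal columns.
principal_angle <- function(a, b) {
  s <- svd(crossprod(a, b), nu = 0, nv = 0)$d
  acos(min(1, max(0, min(s))))
}

# Triple-loop tensor reconstruction from a Tucker factorization.
oracle_reconstruct <- function(core, u1, u2, u3) {
  d <- c(nrow(u1), nrow(u2), nrow(u3))
  out <- array(0, d)
  dc <- dim(core)
  for (a in seq_len(dc[1])) for (b in seq_len(dc[2])) for (cc in seq_len(dc[3]))
    out <- out + core[a, b, cc] *
      outer(outer(u1[, a], u2[, b]), u3[, cc])
  out
}

# Small, fast simulation settings for unit tests (not the study-scale
# defaults used in the acceptance suite).
small_spec <- function(seed = 1L, ...) {
  simulation_spec(n_cells = 90L, n_classes = 3L, n_genes = 400L,
                  n_met_sites = 4000L, n_acc_sites = 4000L,
                  planted_genes = 20L, planted_met = 200L,
                  planted_acc = 200L, seed = seed, ...)
}

# Random per-cell site tables for ingestion tests.
random_sites <- function(n_cells, n_sites, p_obs, values = function(n)
                         stats::runif(n), seed = 1) {
  set.seed(seed)
  pos <- sort(sample.int(n_sites * 20, n_sites)) - 1L
  out <- lapply(seq_len(n_cells), function(j) {
    idx <- which(stats::runif(n_sites) < p_obs)
    data.frame(chrom = "chr1", pos = pos[idx], value = values(length(idx)))
  })
  names(out) <- sprintf("c%03d", seq_len(n_cells))
  out
}
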