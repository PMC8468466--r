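#' Specification for a synthetic single-cell multiomics dataset
#'
#' Describes a trimodal dataset with planted class structure and
#' single-cell-like sparsity: expression with roughly 28% nonzero
#' entries and site-level methylation/accessibility layers observed in
#' only a few percent of (site, cell) pairs, matching the sparsity
#' regime the pipeline is designed for. A subset of features in each
#' layer ("planted" features) carries a class-dependent signal of the
#' given effect size; everything else is class-independent noise.
#' Classes model ordered stages of a developmental trajectory (the
#' typical origin of single-cell multiomics classifications), so each
#' planted feature follows a monotone gradient over the class order,
#' up- or down-regulated with equal probability.
#'
#' @param n_cells total number of cells M.
#' @param n_classes number of classes S; cells are split as evenly as
#'   possible.
#' @param n_genes,n_met_sites,n_acc_sites native feature counts per
#'   layer (accessibility counts are per site, pre-binning).
#' @param planted_genes,planted_met,planted_acc number of planted
#'   class-informative features per layer (5% of each layer by
#'   default).
#' @param effect class separation on the log scale between adjacent
#'   classes, in units of the within-class spread of the corresponding
#'   layer model; 0 disables all planted signal.
#' @param expr_nonzero target fraction of nonzero expression entries.
#' @param met_obs_prob,acc_obs_prob per-(site, cell) observation
#'   probabilities for the site-level layers.
#' @param bin_size accessibility bin width in nucleotides.
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the spec.
#' @return A list of class `sim_spec`.
#' @export
simulation_spec <- function(n_cells = 300L, n_classes = 3L,
                            n_genes = 2000L, n_met_sites = 50000L,
                            n_acc_sites = 50000L,
                            planted_genes = 50L, planted_met = 2500L,
                            planted_acc = 2500L,
                            effect = 2, expr_nonzero = 0.28,
                            met_obs_prob = 0.03, acc_obs_prob = 0.05,
                            bin_size = 200L, seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), n_classes = as.integer(n_classes),
               n_genes = as.integer(n_genes),
               n_met_sites = as.integer(n_met_sites),
               n_acc_sites = as.integer(n_acc_sites),
               planted_genes = as.integer(planted_genes),
               planted_met = as.integer(planted_met),
               planted_acc = as.integer(planted_acc),
               effect = effect, expr_nonzero = expr_nonzero,
               met_obs_prob = met_obs_prob, acc_obs_prob = acc_obs_prob,
               bin_size = as.integer(bin_size), seed = as.integer(seed))
  if (spec$planted_genes > spec$n_genes ||
      spec$planted_met > spec$n_met_sites ||
      spec$planted_acc > spec$n_acc_sites)
    stop("planted feature counts cannot exceed layer feature counts")
  if (spec$n_classes < 2 || spec$n_cells < 2 * spec$n_classes)
    stop("need at least 2 classes with at least 2 cells each")
  probs <- c(spec$expr_nonzero, spec$met_obs_prob, spec$acc_obs_prob)
  if (any(probs <= 0 | probs > 1))
    stop("observation probabilities must lie in (0, 1]")
  if (spec$effect < 0) stop("effect must be nonnegative")
  structure(spec, class = "sim_spec")
}

#' Generate a synthetic single-cell multiomics dataset
#'
#' Draws expression counts from an overdispersed negative-binomial
#' model with multiplicative class effects on planted genes (then thins
#' entries to the target nonzero fraction), per-cell methylation calls
#' at Bernoulli-observed sites with class-shifted methylation
#' probability on planted sites, and per-cell accessibility counts with
#' class-scaled rates on planted sites. The site-level layers are
#' returned both as per-cell site tables (the on-disk dialect) and as
#' the matrices obtained by running those tables through
#' [build_ternary_methylation()] and [bin_accessibility()], so the
#' generator exercises the same ingestion code as real data.
#'
#' @param spec a [simulation_spec()].
#' @return A list of class `td_sim` with elements `expression`,
#'   `methylation`, `accessibility` (each an [omics_matrix()]),
#'   `met_sites`, `acc_sites` (per-cell site tables), `labels`
#'   ([class_labels()]), `planted` (feature ids per layer), and `spec`.
#' @export
simulate_multiomics <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  M <- spec$n_cells; S <- spec$n_classes
  cells <- sprintf("cell%04d", seq_len(M))
  sizes <- rep(M %/% S, S) + c(rep(1, M %% S), rep(0, S - M %% S))
  cls <- rep(sprintf("class%d", seq_len(S)), sizes)
  labels <- class_labels(cells, cls)
  class_idx <- as.integer(labels$label)
  # centered, equally spaced class scores in [-1, 1]
  w <- if (S > 1) (seq_len(S) - (S + 1) / 2) / ((S - 1) / 2) else 0

  expression <- sim_expression(spec, cells, class_idx, w)
  met <- sim_sites(spec, cells, class_idx, w, layer = "methylation")
  acc <- sim_sites(spec, cells, class_idx, w, layer = "accessibility")

  suppressWarnings({
    met_mat <- build_ternary_methylation(met$sites)
    acc_mat <- bin_accessibility(acc$sites, bin_size = spec$bin_size)
  })
  structure(list(expression = expression$matrix,
                 methylation = met_mat,
                 accessibility = acc_mat,
                 met_sites = met$sites, acc_sites = acc$sites,
                 labels = labels,
                 # sites never observed in any cell are absent from the
                 # union feature set and can carry no signal
                 planted = list(genes = expression$planted,
                                methylation = intersect(met$planted,
                                                        feature_ids(met_mat)),
                                accessibility =
                                  intersect(acc$planted,
                                            feature_ids(acc_mat))),
                 spec = spec),
            class = "td_sim")
}

# Expression layer: NB counts, log-scale class shifts on planted genes,
# Bernoulli thinning of entries down to the target nonzero fraction.
sim_expression <- function(spec, cells, class_idx, w) {
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  mu <- stats::rlnorm(spec$n_genes, meanlog = log(2), sdlog = 1)
  planted <- sort(sample.int(spec$n_genes, spec$planted_genes))
  # markers emulate canonical stage markers: highly expressed when on,
  # with comparable magnitudes, not drawn from the low-expression bulk
  mu[planted] <- stats::rlnorm(spec$planted_genes, meanlog = log(60),
                               sdlog = 0.25)
  # classes model ordered stages of a trajectory: each planted gene's
  # mean follows mu * (1 + a * z_s), linear in the centered stage score
  # z, up- or down-regulated with equal probability (a = +/- effect,
  # capped at 2 = fully on/off across the trajectory). The amplitudes
  # are centered so that every class has the same expected total
  # output: regulation redistributes transcriptome share, it does not
  # change how much a cell yields overall.
  z <- w / 2
  a <- numeric(spec$n_genes)
  a[planted] <- sample(c(-1, 1), spec$planted_genes, replace = TRUE) *
    min(spec$effect, 2)
  if (spec$effect > 0 && length(planted))
    a[planted] <- balance_amplitudes(a[planted], mu[planted])
  mult <- pmax(1 + outer(a, z), 0)
  mu_cell <- mu * mult[, class_idx, drop = FALSE]
  counts <- matrix(stats::rnbinom(length(mu_cell), size = 2, mu = mu_cell),
                   nrow = spec$n_genes)
  f <- mean(counts > 0)
  if (f > spec$expr_nonzero) {
    keep <- matrix(stats::runif(length(counts)) < spec$expr_nonzero / f,
                   nrow = nrow(counts))
    counts <- counts * keep
  }
  mat <- omics_matrix(counts, feature_ids = genes, cell_ids = cells,
                      omics_kind = "expression")
  list(matrix = mat, planted = genes[planted])
}

# Adjust signed class amplitudes so that both the expected total signal
# (sum w*a = 0) and its second moment against the baseline profile
# (sum w^2*a = 0) are class-independent: the class then expresses
# itself only as a contrast among planted features, never through the
# cell-wide magnitude or mean-profile directions.
balance_amplitudes <- function(a, weight) {
  b <- cbind(1, weight)
  m <- crossprod(b * weight, b)
  rhs <- -crossprod(b * weight, a)
  beta <- solve(m, rhs)
  as.numeric(a + b %*% beta)
}

# Site-level layer: Bernoulli observation per (site, cell); methylation
# emits binary calls with logit-shifted probability on planted sites,
# accessibility emits positive Poisson counts with rate scaled on
# planted sites. Accessibility sites sit one per bin so planted bins
# are identifiable.
sim_sites <- function(spec, cells, class_idx, w, layer) {
  n <- if (layer == "methylation") spec$n_met_sites else spec$n_acc_sites
  p_obs <- if (layer == "methylation") spec$met_obs_prob else spec$acc_obs_prob
  n_planted <- if (layer == "methylation") spec$planted_met else spec$planted_acc
  if (layer == "methylation") {
    pos <- sort(sample.int(n * 60L, n)) - 1L
    base <- stats::qlogis(pmin(pmax(stats::rbeta(n, 0.4, 0.4), 0.02), 0.98))
  } else {
    pos <- (seq_len(n) - 1L) * spec$bin_size +
      sample.int(spec$bin_size, n, replace = TRUE) - 1L
    base <- stats::rlnorm(n, meanlog = log(0.8), sdlog = 0.5)
  }
  planted <- sort(sample.int(n, n_planted))
  z <- w / 2
  sgn <- sample(c(-1, 1), n_planted, replace = TRUE)
  if (layer == "methylation") {
    # differentially methylated sites sweep from hypo- to
    # hypermethylated (or back) along the trajectory on the logit scale
    shift <- matrix(0, n, spec$n_classes)
    shift[planted, ] <- outer(sgn * spec$effect, w)
    # hold the expected global methylated fraction class-independent
    if (n_planted && spec$effect > 0) {
      for (s in seq_len(spec$n_classes)) {
        target <- sum(stats::plogis(base[planted]))
        f <- function(t) sum(stats::plogis(base[planted] +
                                           shift[planted, s] + t)) - target
        shift[planted, s] <- shift[planted, s] +
          stats::uniroot(f, c(-20, 20))$root
      }
    }
  } else {
    # accessibility rates scale linearly with the centered stage score
    # (amplitude capped at 2 = fully opening/closing bins); amplitudes
    # centered so expected total signal is class-independent
    a <- numeric(n)
    a[planted] <- sgn * min(spec$effect, 2)
    if (n_planted && spec$effect > 0)
      a[planted] <- balance_amplitudes(a[planted], base[planted])
    ratemult <- pmax(1 + outer(a, z), 0)
  }

  sites <- lapply(seq_along(cells), function(j) {
    n_obs <- stats::rbinom(1, n, p_obs)
    idx <- sort(sample.int(n, n_obs))
    if (layer == "methylation") {
      prob <- stats::plogis(base[idx] + shift[idx, class_idx[j]])
      value <- stats::rbinom(n_obs, 1, prob)
    } else {
      rate <- base[idx] * ratemult[idx, class_idx[j]]
      value <- stats::rpois(n_obs, rate) + 1
    }
    data.frame(chrom = "chr1", pos = pos[idx], value = as.numeric(value))
  })
  names(sites) <- cells
  ids <- if (layer == "methylation") paste0("chr1:", pos[planted])
         else paste0("chr1:", (pos[planted] %/% spec$bin_size) * spec$bin_size,
                     "-", (pos[planted] %/% spec$bin_size + 1) * spec$bin_size)
  list(sites = sites, planted = ids)
}

#' Write a simulated dataset to disk in the ingestion dialects
#'
#' Produces `expression.tsv` (genes x cells, header of cell ids, first
#' column of gene ids), `labels.tsv`, per-cell `met/<cell>.tsv` and
#' `acc/<cell>.tsv` site files (1-based positions, as on input), and a
#' `planted.tsv` manifest of the class-informative features. Output is
#' a deterministic function of the simulation, so identical seeds give
#' byte-identical files.
#'
#' @param sim a `td_sim` from [simulate_multiomics()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_multiomics <- function(sim, dir) {
  stopifnot(inherits(sim, "td_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- as.matrix(sim$expression$values)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell_id = sim$labels$cell_id,
                                class = as.character(sim$labels$label)),
                     file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (layer in c("met", "acc")) {
    sub <- file.path(dir, layer)
    dir.create(sub, showWarnings = FALSE)
    sites <- if (layer == "met") sim$met_sites else sim$acc_sites
    for (cell in names(sites)) {
      out <- sites[[cell]]
      out$pos <- out$pos + 1L  # external dialect is 1-based
      utils::write.table(out, file.path(sub, paste0(cell, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  planted <- sim$planted
  utils::write.table(
    data.frame(layer = rep(names(planted), lengths(planted)),
               feature_id = unlist(planted, use.names = FALSE)),
    file.path(dir, "planted.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}

#' Tiny fixed multiomics dataset with hand-checkable intermediates
#'
#' Six cells in two classes, a handful of features per layer, and a
#' manifest of expected intermediate matrices worked out by hand:
#' useful as a worked example and as a fixture for exact tests of the
#' ingestion rules (union of observed sites, the +1/-1/0 ternary
#' encoding with its >= threshold, half-open 200-nt binning with
#' per-bin summation).
#'
#' @return A list with `expression` ([omics_matrix()]), `met_sites`,
#'   `acc_sites` (per-cell site tables, 0-based positions), `labels`,
#'   and `expected`: dense ternary methylation and binned accessibility
#'   matrices, plus the tensor dimensions (`L = 3`, `M = 6`, `K = 3`)
#'   the toy analysis uses.
#' @export
toy_worked_example <- function() {
  cells <- paste0("c", 1:6)
  labels <- class_labels(cells, rep(c("A", "B"), each = 3))
  counts <- matrix(c(9, 8, 7, 1, 0, 1,
                     0, 1, 2, 6, 8, 7,
                     3, 0, 4, 2, 5, 0,
                     1, 2, 0, 0, 1, 3,
                     5, 6, 4, 5, 7, 6,
                     0, 0, 1, 2, 0, 0,
                     2, 3, 1, 0, 4, 2,
                     7, 5, 6, 8, 6, 9),
                   nrow = 8, byrow = TRUE)
  expression <- omics_matrix(counts, feature_ids = paste0("g", 1:8),
                             cell_ids = cells, omics_kind = "expression")
  site <- function(chrom, pos, value) data.frame(chrom = chrom, pos = pos,
                                                 value = value)
  met_sites <- list(
    c1 = site("chr1", c(100L, 300L), c(1.0, 0.2)),
    c2 = site(c("chr1", "chr2"), c(100L, 50L), c(0.9, 0.5)),
    c3 = site("chr1", 300L, 0.0),
    c4 = site(c("chr2", "chr1"), c(50L, 100L), c(0.1, 0.0)),
    c5 = site("chr2", 50L, 0.3),
    c6 = site("chr1", 300L, 1.0))
  acc_sites <- list(
    c1 = site("chr1", c(50L, 150L, 250L), c(2, 3, 1)),
    c2 = site("chr1", 199L, 4),
    c3 = site("chr1", 200L, 2),
    c4 = site("chr2", 10L, 1),
    c5 = site(c("chr1", "chr2"), c(0L, 399L), c(1, 2)),
    c6 = site("chr2", 250L, 3))
  expected_met <- matrix(
    c( 1,  1,  0, -1,  0,  0,
      -1,  0, -1,  0,  0,  1,
       0,  1,  0, -1, -1,  0),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("chr1:100", "chr1:300", "chr2:50"), cells))
  expected_acc <- matrix(
    c(5, 4, 0, 0, 1, 0,
      1, 0, 2, 0, 0, 0,
      0, 0, 0, 1, 0, 0,
      0, 0, 0, 0, 2, 3),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("chr1:0-200", "chr1:200-400",
                      "chr2:0-200", "chr2:200-400"), cells))
  list(expression = expression, met_sites = met_sites, acc_sites = acc_sites,
       labels = labels,
       expected = list(methylation = expected_met,
                       accessibility = expected_acc,
                       tensor_dim = c(L = 3L, M = 6L, K = 3L)))
}
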