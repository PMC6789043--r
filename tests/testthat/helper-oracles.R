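# Independent oracles used to cross-check the package implementations.
# Each one follows a deliberately different computational route than the
# code under test (brute force, enumeration, or closed form).

# Exponential-decay fit by dense grid search over tau: for each candidate
# tau the model A*exp(-t/tau)+C is linear in (A, C) and solved exactly by
# least squares; the tau minimizing the RSS wins, refined by optimize().
oracle_tau_grid <- function(t, v, tau_range = c(0.02, 5), n_grid = 400) {
  rss_at <- function(tau) {
    X <- cbind(exp(-t / tau), 1)
    sum(stats::lm.fit(X, v)$residuals^2)
  }
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_grid))
  rss <- vapply(taus, rss_at, numeric(1))
  i <- which.min(rss)
  lo <- taus[max(1, i - 1)]; hi <- taus[min(n_grid, i + 1)]
  stats::optimize(rss_at, c(lo, hi), tol = 1e-10)$minimum
}

# Covariance-ellipse axes by exhaustive rotation search: the major-axis
# variance is the maximum variance of the projection onto a direction,
# the minor axis is the variance perpendicular to the argmax.
oracle_ellipse_rotation <- function(pairs) {
  proj_var <- function(th)
    stats::var(pairs[, 1] * cos(th) + pairs[, 2] * sin(th))
  grid <- seq(0, pi, length.out = 2001)
  vals <- vapply(grid, proj_var, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  th <- stats::optimize(proj_var, c(lo, hi), maximum = TRUE, tol = 1e-12)
  major_var <- th$objective
  minor_var <- proj_var(th$maximum + pi / 2)
  sqrt(major_var / minor_var)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of every
# possible draw of size |set| from the universe (feasible for <= 12 genes).
oracle_hypergeom_enum <- function(set, pathway, universe) {
  k_obs <- length(intersect(set, pathway))
  draws <- utils::combn(universe, length(set))
  hits <- apply(draws, 2, function(d) length(intersect(d, pathway)) >= k_obs)
  mean(hits)
}

# Pearson chi-square from the textbook formula sum((O-E)^2/E) with expected
# counts from the pooled margins.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Trace extraction oracle: per-frame mean over the generator's true mask
# minus the true background level.
oracle_trace_from_truth <- function(sim) {
  frames <- sim$stack$frames
  idx <- which(sim$mask)
  vapply(seq_len(dim(frames)[1]),
         function(ti) mean(frames[ti, , ][idx]) - sim$truth$background,
         numeric(1))
}

# Row-wise QC recomputation on a dense copy, one cell at a time.
oracle_qc_keep <- function(counts, mito_pattern = "^MT-") {
  d <- as.matrix(counts)
  mito_cols <- grepl(mito_pattern, colnames(d))
  vapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]
    umis <- sum(row); genes <- sum(row > 0)
    mito <- sum(row[mito_cols]) / umis
    !(mito > 0.40 || genes < 200 || umis < 2000)
  }, logical(1))
}
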