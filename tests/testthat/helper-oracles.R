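# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive and separate from the
# package's own code paths.

# Pearson spatial correlation, written out longhand.
oracle_corr <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# GEV by direct evaluation of the defining sum.
oracle_gev <- function(maps, templates, assign, w = NULL) {
  if (is.null(w)) w <- apply(maps, 2, function(m) sqrt(mean((m - mean(m))^2)))
  num <- 0
  for (t in seq_len(ncol(maps))) {
    ct <- oracle_corr(maps[, t], templates[, assign[t]])
    num <- num + (w[t] * ct)^2
  }
  num / sum(w^2)
}

# Exhaustive polarity-invariant 2-means: enumerate every 2-partition,
# fit each cluster's optimal template (leading eigenvector of the
# cluster cross-product), return the best GEV.
oracle_kmeans2 <- function(maps) {
  n <- ncol(maps)
  best <- -Inf
  for (code in 0:(2^(n - 1) - 1)) {            # fix map 1 in cluster 1
    bits <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    if (all(bits == 0L)) next                  # need both clusters non-empty
    assign <- bits + 1L
    templates <- sapply(1:2, function(j) {
      M <- maps[, assign == j, drop = FALSE]
      if (ncol(M) == 1) M[, 1] else eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1]
    })
    g <- oracle_gev(maps, templates, assign)
    if (g > best) best <- g
  }
  best
}

# Holm step-down, spelled out.
oracle_holm <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  running <- 0
  for (i in seq_along(p)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# Restricted log-likelihood of the random-effects model, and a dense
# grid search for tau^2.
oracle_reml_ll <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * g) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (g - mu)^2))
}
oracle_grid_tau2 <- function(g, v, upper = 1, step = 1e-5) {
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, oracle_reml_ll, numeric(1), g = g, v = v)
  grid[which.max(ll)]
}

# Per-sample argmax relabeling, the slow way.
oracle_backfit <- function(data, templates) {
  vapply(seq_len(ncol(data)), function(t) {
    cc <- abs(apply(templates, 2, oracle_corr, a = data[, t]))
    which.max(cc)
  }, integer(1))
}

# One-sample standardized mean difference from summary moments.
mean_sd_d <- function(mean, sd, n) mean / sd

# Column-wise correlation between matching columns of two matrices.
corr_diag <- function(A, B)
  vapply(seq_len(ncol(A)), function(j) oracle_corr(A[, j], B[, j]), numeric(1))

# Population-SD GFP per column, computed longhand.
gfp_of_test <- function(x) apply(x, 2, function(m) sqrt(mean((m - mean(m))^2)))

# A tiny average-referenced recording holding the given sample maps.
rec_from_maps <- function(maps, fs = 128) {
  eeg_recording(apply(maps, 2, function(m) m - mean(m)), fs,
                reference_state = "average")
}

# Balanced split-plot sums of squares from cell/subject means
# (closed form; no model fitting).
oracle_splitplot <- function(d) {
  # d: subject, group, class, y; fully balanced
  k <- length(unique(d$class))
  npg <- length(unique(d$subject[d$group == d$group[1]]))
  gm <- mean(d$y)
  subj_means <- tapply(d$y, d$subject, mean)
  grp_means <- tapply(d$y, d$group, mean)
  cls_means <- tapply(d$y, d$class, mean)
  cell <- tapply(d$y, list(d$group, d$class), mean)
  ss_group <- k * npg * sum((grp_means - gm)^2)
  ss_subj_err <- k * sum((subj_means - gm)^2) - ss_group
  ss_class <- length(grp_means) * npg * sum((cls_means - gm)^2)
  ss_gc <- npg * sum((sweep(sweep(cell, 1, grp_means - gm), 2,
                            cls_means - gm) - gm)^2) # cell - g - c + gm
  ss_total <- sum((d$y - gm)^2)
  ss_werr <- ss_total - ss_group - ss_subj_err - ss_class - ss_gc
  list(group = ss_group, subj_err = ss_subj_err, class = ss_class,
       group_class = ss_gc, within_err = ss_werr,
       df = c(group = length(grp_means) - 1,
              subj_err = length(subj_means) - length(grp_means),
              class = k - 1,
              group_class = (length(grp_means) - 1) * (k - 1)))
}
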