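# Random-effects meta-analysis of standardized mean differences:
# Hedges' small-sample correction, REML estimation of the between-study
# variance, inverse-variance pooling with z-tests, and the per-cell
# (parameter x class) driver with joint Holm correction.

#' Hedges' g and its sampling variance from Cohen's d
#'
#' Applies the small-sample correction `J = 1 - 3 / (4 df - 1)` with
#' `df = n1 + n2 - 2`: `g = J d` and
#' `var_g = J^2 ((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param d Cohen's d.
#' @param n1,n2 Group sizes (>= 2).
#' @return List with `g`, `var_g`, `J`.
#' @examples
#' hedges_g(0.5, 25, 25)
#' @export
hedges_g <- function(d, n1, n2) {
  stop_if_not(all(n1 >= 2) && all(n2 >= 2), "need n >= 2 per group")
  df <- n1 + n2 - 2
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  var_g <- J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(g = g, var_g = var_g, J = J)
}

# Restricted log-likelihood of the random-effects model
# g_i ~ N(mu, v_i + tau2), profiled over mu.
reml_loglik <- function(tau2, g, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * g) / sum(w)
  -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) -
    0.5 * sum(w * (g - mu)^2)
}

#' REML estimate of the between-study variance
#'
#' Maximizes the restricted log-likelihood of the random-effects model
#' `g_i ~ Normal(mu, var_i + tau^2)` by Fisher scoring with analytic
#' derivatives, falling back to bisection on the score function when a
#' step leaves the feasible region; the estimate is floored at 0.
#'
#' @param g Study effects.
#' @param var_g Their sampling variances (> 0).
#' @param tol Convergence tolerance on tau^2 (default 1e-10).
#' @param max_iter Iteration cap (default 200).
#' @return tau^2 (scalar, >= 0); attribute `iterations` holds the count.
#' @export
reml_tau2 <- function(g, var_g, tol = 1e-10, max_iter = 200L) {
  stop_if_not(length(g) >= 2L && length(g) == length(var_g),
              "need >= 2 studies with matching variances")
  stop_if_not(all(var_g > 0), "variances must be positive")
  score <- function(tau2) {
    w <- 1 / (var_g + tau2)
    mu <- sum(w * g) / sum(w)
    0.5 * (sum(w^2 * (g - mu)^2) - sum(w) + sum(w^2) / sum(w))
  }
  if (score(0) <= 0) {
    out <- 0
    attr(out, "iterations") <- 0L
    return(out)
  }
  tau2 <- max(stats::var(g) - mean(var_g), mean(var_g) * 0.1)  # start
  it <- 0L
  repeat {
    it <- it + 1L
    w <- 1 / (var_g + tau2)
    info <- 0.5 * (sum(w^2) - sum(w^3) / sum(w) * 2 +
                     (sum(w^2) / sum(w))^2)       # expected information
    step <- score(tau2) / max(info, .Machine$double.eps)
    new <- tau2 + step
    if (!is.finite(new) || new < 0) break         # fall back to bisection
    if (abs(new - tau2) <= tol) { tau2 <- new; break }
    tau2 <- new
    if (it >= max_iter) {
      warning("REML Fisher scoring hit the iteration cap; refining by bisection")
      break
    }
  }
  # bisection safeguard: bracket the root of the score function
  hi <- max(tau2, 1e-4)
  while (score(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (score(hi) > 0) stop("REML did not converge: score positive at tau2 = 1e8",
                          call. = FALSE)
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (score(mid) > 0) lo <- mid else hi <- mid
  }
  out <- max((lo + hi) / 2, 0)
  attr(out, "iterations") <- it
  out
}

#' Inverse-variance random-effects pooling
#'
#' Weights `w_i = 1 / (var_i + tau^2)`; pooled effect
#' `g* = sum(w g) / sum(w)`, `se = 1 / sqrt(sum(w))`, 95% CI
#' `g* +/- 1.96 se`, z-test `z = g*/se` with a two-sided normal p.
#'
#' @param g Study effects (>= 1).
#' @param var_g Sampling variances.
#' @param tau2 Between-study variance (>= 0).
#' @return Object of class `meta_result`: list with `g_star`, `se`,
#'   `ci95`, `z`, `p`, `tau2`, `k_studies`, `weights`.
#' @export
pool_random_effects <- function(g, var_g, tau2 = 0) {
  stop_if_not(length(g) >= 1L && length(g) == length(var_g),
              "need >= 1 study with matching variances")
  stop_if_not(tau2 >= 0, "tau2 must be nonnegative")
  w <- 1 / (var_g + tau2)
  g_star <- sum(w * g) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- g_star / se
  structure(list(g_star = g_star, se = se,
                 ci95 = g_star + c(-1, 1) * stats::qnorm(0.975) * se,
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 tau2 = tau2, k_studies = length(g), weights = w / sum(w)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects pooled estimate (k = %d studies)\n", x$k_studies))
  cat(sprintf("  g* = %.3f, 95%% CI [%.3f, %.3f], z = %.3f, p = %.3g, tau2 = %.4f\n",
              x$g_star, x$ci95[1], x$ci95[2], x$z, x$p, x$tau2))
  invisible(x)
}

#' Random-effects meta-analysis of per-study effect sizes
#'
#' One-call front end: takes per-study Cohen's d (or precomputed g and
#' var_g) with group sizes, applies the Hedges correction, estimates
#' tau^2 by REML (fixed at 0 for single-study cells), and pools.
#'
#' @param data data.frame with columns `study_id`, `n1`, `n2`, and
#'   either `d` or both `g` and `var_g`.
#' @return A `meta_result` with an added `studies` data.frame (study_id,
#'   g, var_g, ci bounds, weight) suitable for a forest plot.
#' @examples
#' df <- data.frame(study_id = 1:3, n1 = 25, n2 = 25, d = c(0.2, 0.5, 0.8))
#' meta_random_effects(df)
#' @export
meta_random_effects <- function(data) {
  data <- as.data.frame(data)
  if (!("g" %in% names(data) && "var_g" %in% names(data))) {
    stop_if_not(all(c("d", "n1", "n2") %in% names(data)),
                "need columns d, n1, n2 (or g and var_g)")
    hg <- hedges_g(data$d, data$n1, data$n2)
    data$g <- hg$g; data$var_g <- hg$var_g
  }
  tau2 <- if (nrow(data) >= 2L) as.numeric(reml_tau2(data$g, data$var_g)) else 0
  out <- pool_random_effects(data$g, data$var_g, tau2)
  ci <- stats::qnorm(0.975) * sqrt(data$var_g)
  out$studies <- data.frame(study_id = data$study_id, g = data$g,
                            var_g = data$var_g,
                            ci_low = data$g - ci, ci_high = data$g + ci,
                            weight = out$weights)
  out
}

#' @export
summary.meta_result <- function(object, ...) {
  print(object)
  if (!is.null(object$studies)) {
    cat("Per-study effects:\n")
    print(object$studies, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Forest plot of a meta-analytic result
#'
#' @param x A `meta_result` from [meta_random_effects()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.meta_result <- function(x, ...) {
  stop_if_not(!is.null(x$studies), "no per-study table to plot")
  st <- x$studies
  n <- nrow(st)
  ys <- rev(seq_len(n)) + 1
  xlim <- range(c(st$ci_low, st$ci_high, x$ci95, 0))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 1.5), yaxt = "n",
                 xlab = "Hedges' g", ylab = "", ...)
  graphics::segments(st$ci_low, ys, st$ci_high, ys)
  graphics::points(st$g, ys, pch = 15, cex = 0.8 + 2 * st$weight)
  graphics::points(x$g_star, 0.8, pch = 18, cex = 1.6)
  graphics::segments(x$ci95[1], 0.8, x$ci95[2], 0.8, lwd = 2)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = c(ys, 0.8), labels = c(st$study_id, "pooled"),
                 las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Meta-analysis over parameter x class cells with joint Holm correction
#'
#' Runs [meta_random_effects()] independently in each parameter x class
#' cell of a long study table and applies the Bonferroni-Holm correction
#' jointly across all cells (default family size 12 = 3 parameters x 4
#' classes). Cells listed in `expected_cells` but absent from the data
#' are reported in the `missing` component rather than silently skipped.
#'
#' @param data data.frame with columns `study_id`, `parameter`, `class`,
#'   `n1`, `n2`, and `d` (or `g` + `var_g`).
#' @param holm_m Family size for the Holm correction (default: number of
#'   cells present, or 12 if `expected_cells` is given).
#' @param expected_cells Optional data.frame (`parameter`, `class`) of
#'   cells that ought to exist.
#' @return List with `results` (data.frame: parameter, class, k_studies,
#'   g_star, tau2, ci_low, ci_high, z, p, p_holm), `cells` (named list of
#'   `meta_result`s), `forest` (stacked per-study table), `missing`.
#' @export
run_meta <- function(data, holm_m = NULL, expected_cells = NULL) {
  data <- as.data.frame(data)
  key <- interaction(data$parameter, data$class, drop = TRUE, sep = ":")
  cells <- split(data, key)
  res <- lapply(cells, meta_random_effects)
  tab <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    data.frame(parameter = parts[1], class = parts[2],
               k_studies = r$k_studies, g_star = r$g_star, tau2 = r$tau2,
               ci_low = r$ci95[1], ci_high = r$ci95[2], z = r$z, p = r$p)
  }))
  missing <- NULL
  if (!is.null(expected_cells)) {
    want <- paste(expected_cells$parameter, expected_cells$class, sep = ":")
    have <- paste(tab$parameter, tab$class, sep = ":")
    missing <- expected_cells[!(want %in% have), , drop = FALSE]
    if (is.null(holm_m)) holm_m <- nrow(expected_cells)
  }
  if (is.null(holm_m)) holm_m <- nrow(tab)
  tab$p_holm <- holm_adjust(tab$p, m = holm_m)
  forest <- do.call(rbind, lapply(names(res), function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    cbind(parameter = parts[1], class = parts[2], res[[nm]]$studies)
  }))
  list(results = tab, cells = res, forest = forest, missing = missing)
}
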