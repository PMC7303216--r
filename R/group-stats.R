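# Group-level statistics: demographics tests, effect sizes and
# conversions, Bonferroni-Holm correction, split-plot (mixed-design)
# ANOVA with covariates, correlations, and BIC Bayes factors.

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction by default (the
#' convention that reproduces printed demographic test statistics); the
#' Yates correction is available behind a flag.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `df` (= 1), `p`.
#' @examples
#' chi_square_2x2(rbind(c(11, 90), c(39, 36)))$statistic # 35.76...
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stop_if_not(all(dim(table) == 2L), "table must be 2x2")
  stop_if_not(all(table >= 0) && sum(table) > 0, "counts must be nonnegative")
  exp_counts <- outer(rowSums(table), colSums(table)) / sum(table)
  stop_if_not(all(exp_counts > 0), "degenerate margins (zero expected cell)")
  ht <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' Two-sample pooled t-test from summary statistics
#'
#' @param n1,mean1,sd1 First group size, mean, sample SD.
#' @param n2,mean2,sd2 Second group.
#' @return List with `t`, `df` (= n1 + n2 - 2), `p` (two-sided).
#' @export
independent_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stop_if_not(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  stop_if_not(sp2 > 0, "zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Cohen's d with a normal-approximation 95% CI
#'
#' Independent-groups mode: `d = (mean1 - mean2) / pooled SD` with
#' `SE(d) = sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2)))`. One-sample
#' mode (difference scores): `d = mean(delta) / sd(delta)` with
#' `SE(d) = sqrt(1/n + d^2 / (2 n))`. Positive d means the first group
#' (or a positive mean difference) is larger.
#'
#' @param mode `"independent"` or `"one_sample"`.
#' @param n1,mean1,sd1,n2,mean2,sd2 Summaries for independent mode.
#' @param deltas Difference scores for one-sample mode (length >= 2).
#' @return List with `d`, `se`, `ci` (length-2), and the inputs' `n`.
#' @examples
#' cohens_d("one_sample", deltas = c(-1, 0, 1, -2))$d
#' @export
cohens_d <- function(mode = c("independent", "one_sample"),
                     n1 = NULL, mean1 = NULL, sd1 = NULL,
                     n2 = NULL, mean2 = NULL, sd2 = NULL,
                     deltas = NULL) {
  mode <- match.arg(mode)
  if (mode == "independent") {
    stop_if_not(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    stop_if_not(sp2 > 0, "zero pooled SD")
    d <- (mean1 - mean2) / sqrt(sp2)
    se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
    n <- c(n1, n2)
  } else {
    stop_if_not(length(deltas) >= 2, "need at least 2 difference scores")
    s <- stats::sd(deltas)
    stop_if_not(s > 0, "zero SD of difference scores")
    d <- mean(deltas) / s
    n <- length(deltas)
    se <- sqrt(1 / n + d^2 / (2 * n))
  }
  list(d = d, se = se, ci = d + c(-1, 1) * stats::qnorm(0.975) * se, n = n)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Sorts the p-values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity by a running maximum, caps at 1,
#' and returns the adjusted values in the input order. `m` may exceed
#' the number of supplied p-values (comparisons planned but not listed).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p, m = length(p)) {
  stop_if_not(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stop_if_not(m >= length(p), "m must be at least length(p)")
  ord <- order(p)
  mult <- m - seq_along(p) + 1L
  adj <- cummax(p[ord] * mult)
  pmin(adj, 1)[order(ord)]
}

#' Convert classical eta-squared to Cohen's d
#'
#' `d = 2 sqrt(eta2 / (1 - eta2))`; inverse `eta2 = d^2 / (d^2 + 4)`.
#'
#' @param eta2 Value in `[0, 1)`.
#' @return Cohen's d (nonnegative).
#' @export
eta2_to_d <- function(eta2) {
  stop_if_not(all(eta2 >= 0 & eta2 < 1), "eta2 must lie in [0, 1)")
  2 * sqrt(eta2 / (1 - eta2))
}

#' Bayes factor for the null from BIC values
#'
#' BIC approximation to the Bayes factor: `BF_01 = exp((BIC_alt -
#' BIC_null) / 2)`; values above 1 favour the null (smaller) model.
#'
#' @param bic_null,bic_alt BIC of the null and alternative models.
#' @return BF_01.
#' @export
bayes_factor_bic <- function(bic_null, bic_alt) {
  stop_if_not(is.finite(bic_null) && is.finite(bic_alt),
              "BIC values must be finite")
  exp((bic_alt - bic_null) / 2)
}

#' Pearson correlation with t-based p and optional Holm adjustment
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param holm_m If not `NULL`, also return `p * (holm rank multiplier)`
#'   semantics by adjusting this single p within a family of `holm_m`
#'   comparisons where it is the only member supplied (i.e. `min(1, m*p)`
#'   bound); for a joint family use [holm_adjust()] on the collected
#'   p-values.
#' @return List with `r`, `df` (= n - 2), `p` (two-sided), and `p_holm`
#'   when requested.
#' @export
pearson_correlation <- function(x, y, holm_m = NULL) {
  stop_if_not(length(x) == length(y) && length(x) >= 3,
              "need equal lengths >= 3")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0, "zero variance input")
  n <- length(x)
  r <- stats::cor(x, y)
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  out <- list(r = r, df = df, p = p)
  if (!is.null(holm_m)) out$p_holm <- min(1, holm_m * p)
  out
}

# ---- split-plot ANOVA ------------------------------------------------------

# Type III sum of squares for each term of an lm-style design: fit the
# full sum-contrast model, then for each term drop its columns and take
# the RSS increase.
type3_ss <- function(response, mm, assign, term_labels) {
  qr_full <- qr(mm)
  rss_full <- sum(qr.resid(qr_full, response)^2)
  ss <- numeric(length(term_labels))
  for (i in seq_along(term_labels)) {
    keep <- assign != i
    rss_red <- sum(qr.resid(qr(mm[, keep, drop = FALSE]), response)^2)
    ss[i] <- rss_red - rss_full
  }
  list(ss = ss, rss = rss_full, df_resid = nrow(mm) - qr_full$rank)
}

# 90% CI for eta^2 by inverting the noncentral-F distribution at the
# observed F (partial eta^2 parameterization mapped back through the
# effect/error SS ratio).
eta2_ci <- function(F, df1, df2, level = 0.90) {
  if (!is.finite(F) || F <= 0) return(c(0, 0))
  if (F > 1e6) return(c(1, 1))     # numerically saturated effect
  alpha <- (1 - level) / 2
  pf_at <- function(ncp) suppressWarnings(stats::pf(F, df1, df2, ncp = ncp))
  hi_bound <- max(4 * (F * df1 + df1 + df2), 100)
  lo <- if (pf_at(0) < 1 - alpha) 0 else
    stats::uniroot(function(nc) pf_at(nc) - (1 - alpha), c(0, hi_bound))$root
  hi <- if (pf_at(0) < alpha) 0 else
    stats::uniroot(function(nc) pf_at(nc) - alpha, c(0, hi_bound))$root
  ncp_to_eta <- function(nc) nc / (nc + df1 + df2 + 1)
  c(ncp_to_eta(lo), ncp_to_eta(hi))
}

#' Mixed-design (split-plot) ANOVA with covariates
#'
#' General linear model for one within-subject factor crossed with
#' between-subject factors and subject-constant covariates, estimated in
#' two strata with Type III (drop-one-term) sums of squares under
#' sum-to-zero factor coding:
#' \itemize{
#'   \item between stratum - per-subject means modelled as
#'     `crossed between factors + covariates`, tested against the
#'     subject-within-group error;
#'   \item within stratum - the long data with a subject factor
#'     absorbing all between-subject variation; the within factor and
#'     its interactions with between factors/covariates are tested
#'     against the subject x within residual.
#' }
#' No sphericity correction is applied. Classical eta^2 (effect SS over
#' the stratum's total corrected SS), partial eta^2, and a 90% CI for
#' partial eta^2 from the noncentral-F inversion are reported per
#' effect.
#'
#' @param data Long-format data.frame.
#' @param response Name of the response column.
#' @param subject Name of the subject id column.
#' @param within Name of the within-subject factor column (one
#'   observation per subject per level).
#' @param between Character vector of between-subject factor columns
#'   (crossed), possibly empty.
#' @param covariates Character vector of numeric subject-constant
#'   covariate columns (entered additively), possibly empty.
#' @return Object of class `mixed_anova`: data.frame with one row per
#'   effect (`effect`, `stratum`, `ss`, `df1`, `df2`, `F`, `p`, `eta2`,
#'   `eta2_partial`, `eta2_ci_low`, `eta2_ci_high`).
#' @export
mixed_design_anova <- function(data, response, subject, within,
                               between = character(0),
                               covariates = character(0)) {
  data <- as.data.frame(data)
  for (v in c(subject, within, between)) data[[v]] <- factor(data[[v]])
  y <- data[[response]]
  stop_if_not(is.numeric(y) && !anyNA(y), "response must be numeric, no NAs")
  # balance check: one observation per subject per within level
  tab <- table(data[[subject]], data[[within]])
  stop_if_not(all(tab == 1L),
              "each subject needs exactly one observation per within level")
  # covariates constant within subject
  for (v in covariates) {
    rng <- tapply(data[[v]], data[[subject]], function(z) diff(range(z)))
    stop_if_not(all(rng == 0), sprintf("covariate %s varies within subject", v))
  }
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  k <- nlevels(data[[within]])

  # ---- between stratum on subject means
  agg <- stats::aggregate(y, by = lapply(c(subject, between, covariates),
                                         function(v) data[[v]]), FUN = mean)
  names(agg) <- c(subject, between, covariates, ".y")
  rhs_b <- c(if (length(between)) paste(between, collapse = "*"),
             covariates)
  res <- list()
  if (length(rhs_b)) {
    fb <- stats::as.formula(paste("`.y` ~", paste(rhs_b, collapse = " + ")))
    mf <- stats::model.frame(fb, agg)
    mm <- stats::model.matrix(fb, mf)
    if (qr(mm)$rank < ncol(mm))
      stop("rank-deficient between-subject design (aliased terms)",
           call. = FALSE)
    terms_b <- attr(stats::terms(fb), "term.labels")
    t3 <- type3_ss(agg$.y, mm, attr(mm, "assign"), terms_b)
    # scale to the long-data metric: subject means carry 1/k of the
    # per-observation variance, so SS on means * k = split-plot SS
    ss_b <- t3$ss * k
    err_b <- t3$rss * k
    df_err_b <- t3$df_resid
    tot_b <- sum((agg$.y - mean(agg$.y))^2) * k
    for (i in seq_along(terms_b)) {
      df1 <- sum(attr(mm, "assign") == i)
      F <- (ss_b[i] / df1) / (err_b / df_err_b)
      res[[length(res) + 1L]] <- data.frame(
        effect = terms_b[i], stratum = "between", ss = ss_b[i],
        df1 = df1, df2 = df_err_b, F = F,
        p = stats::pf(F, df1, df_err_b, lower.tail = FALSE),
        eta2 = ss_b[i] / tot_b,
        eta2_partial = ss_b[i] / (ss_b[i] + err_b))
    }
    res[[length(res) + 1L]] <- data.frame(
      effect = "subject(between) error", stratum = "between", ss = err_b,
      df1 = df_err_b, df2 = NA, F = NA, p = NA, eta2 = NA, eta2_partial = NA)
  }

  # ---- within stratum: subject factor + within-factor terms.
  # The design is assembled by hand (sum-contrast columns and their
  # products) so interaction terms keep their proper df even though the
  # between-subject main effects live in the subject factor, not here.
  sum_cols <- function(f) {
    m <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))
    m[, -1L, drop = FALSE]
  }
  col_products <- function(blocks) {
    out <- blocks[[1L]]
    for (b in blocks[-1L]) {
      out <- do.call(cbind, lapply(seq_len(ncol(b)), function(j) out * b[, j]))
    }
    out
  }
  Cw <- sum_cols(data[[within]])
  between_cols <- lapply(data[between], sum_cols)
  blocks <- list()
  blocks[[within]] <- Cw
  if (length(between)) {
    for (d in seq_along(between)) {
      combos <- utils::combn(between, d, simplify = FALSE)
      for (cmb in combos) {
        nm <- paste(c(within, cmb), collapse = ":")
        blocks[[nm]] <- col_products(c(list(Cw), between_cols[cmb]))
      }
    }
  }
  for (v in covariates)
    blocks[[paste0(within, ":", v)]] <- Cw * data[[v]]
  Zs <- stats::model.matrix(~f, data = list(f = data[[subject]]),
                            contrasts.arg = list(f = "contr.sum"))
  terms_w <- names(blocks)
  mm <- cbind(Zs, do.call(cbind, blocks))
  assign_w <- c(rep(0L, ncol(Zs)),
                rep(seq_along(blocks), vapply(blocks, ncol, integer(1))))
  t3 <- type3_ss(y, mm, assign_w, terms_w)
  df_err_w <- t3$df_resid
  err_w <- t3$rss
  tot_w <- sum((y - mean(y))^2)
  for (i in seq_along(terms_w)) {
    if (terms_w[i] == subject) next
    df1 <- sum(assign_w == i)
    F <- (t3$ss[i] / df1) / (err_w / df_err_w)
    res[[length(res) + 1L]] <- data.frame(
      effect = terms_w[i], stratum = "within", ss = t3$ss[i],
      df1 = df1, df2 = df_err_w, F = F,
      p = stats::pf(F, df1, df_err_w, lower.tail = FALSE),
      eta2 = t3$ss[i] / tot_w,
      eta2_partial = t3$ss[i] / (t3$ss[i] + err_w))
  }
  res[[length(res) + 1L]] <- data.frame(
    effect = "subject x within error", stratum = "within", ss = err_w,
    df1 = df_err_w, df2 = NA, F = NA, p = NA, eta2 = NA, eta2_partial = NA)

  out <- do.call(rbind, res)
  ci <- t(vapply(seq_len(nrow(out)), function(i) {
    if (is.na(out$F[i])) return(c(NA_real_, NA_real_))
    eta2_ci(out$F[i], out$df1[i], out$df2[i])
  }, numeric(2)))
  out$eta2_ci_low <- ci[, 1]; out$eta2_ci_high <- ci[, 2]
  class(out) <- c("mixed_anova", "data.frame")
  out
}

#' @export
print.mixed_anova <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  for (v in c("ss", "F", "eta2", "eta2_partial", "eta2_ci_low", "eta2_ci_high"))
    y[[v]] <- signif(y[[v]], digits)
  y$p <- format.pval(y$p, digits = 3)
  print(y, row.names = FALSE)
  invisible(x)
}
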