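test_that("chi-square reproduces the published demographics statistics", {
  fx <- demographics_fixtures()
  stat <- function(a, b, w)
    chi_square_2x2(fx$pair2x2(a, b, w))$statistic
  expect_equal(round(stat("patients", "controls", "gender"), 3), 35.762)
  expect_equal(round(stat("siblings", "controls", "gender"), 3), 0.109)
  expect_equal(round(suppressWarnings(stat("patients", "controls", "handedness")), 3), 0.030)
  expect_equal(round(suppressWarnings(stat("siblings", "controls", "handedness")), 3), 0.026)
  expect_equal(round(suppressWarnings(stat("FEP", "patients22", "handedness")), 3), 0.000)
})

test_that("chi-square is invariant to transposition and joint row/column swaps", {
  tab <- rbind(c(11, 90), c(39, 36))
  x <- chi_square_2x2(tab)$statistic
  expect_equal(chi_square_2x2(t(tab))$statistic, x)
  expect_equal(chi_square_2x2(tab[2:1, 2:1])$statistic, x)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("pooled t from summaries matches analytic expectations", {
  # equal means
  eq <- independent_t_from_summary(10, 5, 1, 12, 5, 1.2)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # education summaries from the demographics table: printed t(174) = -3.915
  # came from unrounded raw data; rounded summaries must land within 0.1
  tt <- independent_t_from_summary(101, 13.4, 2.7, 75, 15.1, 2.9)
  expect_equal(tt$df, 174)
  expect_lt(abs(tt$t - (-3.915)), 0.1)
  # doubling both n at fixed summaries scales |t| by sqrt(2); the pooled
  # SD is unchanged for equal group sizes so the ratio is exact there
  a <- independent_t_from_summary(20, 1, 1, 20, 0, 1)
  b <- independent_t_from_summary(40, 1, 1, 40, 0, 1)
  expect_equal(b$t / a$t, sqrt(2), tolerance = 1e-12)
})

test_that("Cohen's d covers both modes with the documented sign convention", {
  expect_equal(cohens_d("independent", 10, 3, 1, 10, 3, 1)$d, 0)
  expect_equal(cohens_d("independent", 12, 1, 1, 12, 0, 1)$d, 1)
  # one-sample d on the patient-sibling difference scores: printed -0.576
  d <- mean_sd_d(-7.21, 12.50, 32)
  expect_lt(abs(d - (-0.576)), 0.005)
  # package one-sample route on synthetic deltas with those moments
  set.seed(1)
  z <- rnorm(32); z <- (z - mean(z)) / sd(z) * 12.50 - 7.21
  got <- cohens_d("one_sample", deltas = z)
  expect_equal(got$d, -7.21 / 12.50, tolerance = 1e-9)
  expect_equal(got$se, sqrt(1 / 32 + got$d^2 / 64), tolerance = 1e-12)
  # positive delta -> positive d
  expect_gt(cohens_d("one_sample", deltas = c(1, 2, 3))$d, 0)
})

test_that("Holm adjustment reproduces the published corrected column", {
  fx <- demographics_fixtures()
  ph <- holm_adjust(fx$table1_p, m = 12)
  names(ph) <- names(fx$table1_p)
  expect_equal(round(unname(ph["duration.B"]), 3), 0.018)
  expect_equal(round(unname(ph["occurrence.A"]), 3), 0.898)  # raised by monotonicity
  expect_equal(round(unname(ph["coverage.A"]), 3), 0.898)
  expect_equal(round(unname(ph["duration.D"]), 6), round(3.311e-5, 6))
  expect_equal(round(unname(ph["coverage.C"]), 7), round(1.742e-6, 7))
})

test_that("Holm agrees with the brute-force oracle and handles edge cases", {
  set.seed(2)
  for (rep in 1:30) {
    n <- sample(1:12, 1)
    p <- runif(n)
    expect_equal(holm_adjust(p), oracle_holm(p), tolerance = 1e-12)
    m <- n + sample(0:3, 1)
    expect_equal(holm_adjust(p, m), oracle_holm(p, m), tolerance = 1e-12)
  }
  expect_equal(holm_adjust(0.2), 0.2)            # single p unchanged
  expect_equal(holm_adjust(c(0.9, 0.95), 12), c(1, 1))
  pv <- runif(6)
  expect_equal(holm_adjust(pv), unname(stats::p.adjust(pv, "holm")))
})

test_that("eta2 to d conversion and its inverse round-trip", {
  expect_equal(eta2_to_d(0), 0)
  expect_equal(eta2_to_d(0.5), 2)
  set.seed(3)
  e <- runif(20, 0, 0.95)
  d <- eta2_to_d(e)
  expect_equal(d^2 / (d^2 + 4), e, tolerance = 1e-12)
  expect_error(eta2_to_d(1))
})

test_that("BIC Bayes factors follow exp(delta BIC / 2) and favour the null under null data", {
  expect_equal(bayes_factor_bic(10, 10), 1)
  expect_equal(bayes_factor_bic(8, 10), exp(1))
  set.seed(4)
  bf <- replicate(200, {
    y <- rnorm(40); g <- rep(0:1, each = 20)
    m0 <- lm(y ~ 1); m1 <- lm(y ~ g)
    bayes_factor_bic(BIC(m0), BIC(m1))
  })
  expect_gt(median(bf), 1)
})

test_that("Pearson correlation reproduces the printed clinical correlation p", {
  pc_vals <- pearson_correlation(1:10, 2 * (1:10) + 1)
  expect_equal(pc_vals$r, 1)
  x <- c(1, -1, 1, -1); y <- c(1, 1, -1, -1)
  expect_equal(pearson_correlation(x, y)$p, 1)
  expect_equal(pearson_correlation(x, y)$r, 0)
  # r = 0.430 at df = 30 -> p ~ 0.014 via the t transform; build data
  # with exactly that correlation
  set.seed(5)
  a <- rnorm(32); b <- rnorm(32)
  b <- residuals(lm(b ~ a)); b <- b / sd(b)
  a_s <- (a - mean(a)) / sd(a)
  y2 <- 0.430 * a_s + sqrt(1 - 0.430^2) * (b - mean(b)) / sd(b)
  res <- pearson_correlation(a_s, y2)
  expect_equal(res$r, 0.430, tolerance = 1e-9)
  expect_equal(res$df, 30)
  expect_equal(round(res$p, 3), 0.014)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("split-plot ANOVA matches the closed-form balanced oracle and aov", {
  set.seed(6)
  ns <- 8
  d <- data.frame(subject = factor(rep(1:(2 * ns), each = 3)),
                  group = rep(c("a", "b"), each = 3 * ns),
                  class = rep(c("w1", "w2", "w3"), 2 * ns),
                  y = rnorm(6 * ns, mean = rep(c(0, 0.4), each = 3 * ns)))
  m <- mixed_design_anova(d, "y", "subject", "class", between = "group")
  o <- oracle_splitplot(d)
  get <- function(eff) m[m$effect == eff, ]
  expect_equal(get("group")$ss, o$group, tolerance = 1e-9)
  expect_equal(get("class")$ss, o$class, tolerance = 1e-9)
  expect_equal(get("class:group")$ss, o$group_class, tolerance = 1e-9)
  expect_equal(get("subject(between) error")$ss, o$subj_err, tolerance = 1e-9)
  expect_equal(get("subject x within error")$ss, o$within_err, tolerance = 1e-9)
  F_group <- (o$group / o$df["group"]) / (o$subj_err / o$df["subj_err"])
  expect_equal(get("group")$F, unname(F_group), tolerance = 1e-9)
  # cross-check every F against stats::aov
  av <- summary(aov(y ~ group * class + Error(subject / class), data = d))
  expect_equal(get("group")$F, av[[1]][[1]]["group", "F value"],
               tolerance = 1e-9)
  expect_equal(get("class")$F, av[[2]][[1]]["class", "F value"],
               tolerance = 1e-9)
  expect_equal(get("class:group")$F, av[[2]][[1]]["group:class", "F value"],
               tolerance = 1e-9)
  # balanced design: effect + error SS decompose the total exactly
  tot <- sum((d$y - mean(d$y))^2)
  expect_equal(sum(m$ss), tot, tolerance = 1e-9 * tot)
  expect_true(all(m$ss >= 0))
})

test_that("split-plot ANOVA reproduces the study's degrees of freedom layout", {
  set.seed(7)
  n1 <- 101; n2 <- 75; n <- n1 + n2
  d <- data.frame(
    subject = factor(rep(1:n, each = 4)),
    group = rep(c(rep("pat", n1), rep("ctl", n2)), each = 4),
    gender = rep(sample(c("F", "M"), n, TRUE), each = 4),
    educ = rep(rnorm(n, 14, 3), each = 4),
    class = rep(c("A", "B", "C", "D"), n),
    y = rnorm(4 * n))
  m <- mixed_design_anova(d, "y", "subject", "class",
                          between = c("group", "gender"),
                          covariates = "educ")
  w <- m[m$stratum == "within" & !is.na(m$F), ]
  expect_true(all(w$df1 == 3))
  expect_true(all(w$df2 == 513))
  b <- m[m$stratum == "between" & !is.na(m$F), ]
  expect_true(all(b$df2 == 171))
  expect_true(all(m$eta2 >= 0 & m$eta2 <= 1, na.rm = TRUE))
  expect_true(all(m$eta2_ci_low <= m$eta2_ci_high, na.rm = TRUE))
})

test_that("mirrored group responses yield a zero group F", {
  # the two groups contain subjects with identical response profiles,
  # so the group contrast carries exactly zero sum of squares
  mu <- c(0, 1, 2, 3, 4)
  prof <- rbind(c(1, 2), c(1, 2))
  y_one <- as.vector(vapply(mu, function(m) m + c(1, 2), numeric(2)))
  d <- data.frame(subject = factor(rep(1:10, each = 2)),
                  group = rep(c("a", "b"), each = 10),
                  class = rep(c("w1", "w2"), 10),
                  y = c(y_one, y_one))
  m <- mixed_design_anova(d, "y", "subject", "class", between = "group")
  expect_equal(m[m$effect == "group", "F"], 0, tolerance = 1e-12)
})

test_that("unbalanced within coverage and varying covariates are rejected", {
  d <- data.frame(subject = factor(c(1, 1, 2)),
                  group = c("a", "a", "b"),
                  class = c("w1", "w2", "w1"),
                  y = rnorm(3))
  expect_error(mixed_design_anova(d, "y", "subject", "class",
                                  between = "group"),
               "one observation per within level")
  d2 <- data.frame(subject = factor(rep(1:4, each = 2)),
                   group = rep(c("a", "b"), each = 4),
                   cov = rnorm(8),
                   class = rep(c("w1", "w2"), 4),
                   y = rnorm(8))
  expect_error(mixed_design_anova(d2, "y", "subject", "class",
                                  between = "group", covariates = "cov"),
               "varies within subject")
})
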