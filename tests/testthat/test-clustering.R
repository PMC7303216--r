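test_that("spatial correlation matches the Pearson formula and its symmetries", {
  expect_equal(spatial_correlation(c(1, 0, -1), c(0, 1, -1)), 0.5)
  m <- rnorm(10); m <- m - mean(m)
  expect_equal(spatial_correlation(m, m), 1)
  expect_equal(spatial_correlation(m, -m), -1)
  b <- rnorm(10)
  expect_equal(spatial_correlation(m, b), spatial_correlation(b, m))
  expect_error(spatial_correlation(m, rep(0, 10)), "zero-variance")
})

test_that("GEV matches hand evaluation and attains its bounds", {
  # two equal-GFP maps, corr 1 and 0.5 to their templates -> 0.625
  t1 <- c(1, 0, -1); t2 <- c(0, 1, -1)
  m2 <- c(1, 0, -1)                  # corr(m2, t2) = 0.5, same GFP as map 1
  maps <- cbind(t1, m2)
  tpl <- template_set(cbind(t1, t2))
  gev <- global_explained_variance(maps, tpl, c(1L, 2L))
  expect_equal(gev, (1 + 0.25) / 2)
  # perfect fit
  expect_equal(global_explained_variance(cbind(2 * t1, -3 * t2), tpl, c(1L, 2L)), 1)
  # orthogonal fit: map orthogonal (in the centered sense) to its template
  orth <- c(1, -2, 1)                             # centered, corr with t1 = 0
  expect_equal(global_explained_variance(cbind(orth), tpl, 1L), 0)
  # agreement with the longhand oracle on random inputs
  set.seed(3)
  maps <- apply(matrix(rnorm(12 * 6), 12), 2, function(v) v - mean(v))
  tplr <- template_set(matrix(rnorm(12 * 3), 12))
  a <- sample(1:3, 6, TRUE)
  expect_equal(global_explained_variance(maps, tplr, a),
               oracle_gev(maps, tplr$maps, a), tolerance = 1e-12)
})

test_that("GEV is invariant to a common positive rescaling of the maps", {
  set.seed(8)
  maps <- matrix(rnorm(10 * 8), 10)
  tpl <- template_set(matrix(rnorm(10 * 2), 10))
  a <- sample(1:2, 8, TRUE)
  expect_equal(global_explained_variance(maps, tpl, a),
               global_explained_variance(2.5 * maps, tpl, a), tolerance = 1e-12)
})

test_that("modified k-means is polarity invariant and recovers planted templates", {
  tpl <- make_templates(32, 4, min_separation = 0.4, seed = 5)
  # noise-free samples from the 4 planted maps with random polarity/gain
  set.seed(6)
  idx <- sample(1:4, 60, TRUE)
  gains <- runif(60, 0.5, 2) * sample(c(-1, 1), 60, TRUE)
  maps <- tpl$maps[, idx] * rep(gains, each = 32)
  fit <- microstate_kmeans(maps, 4, n_restarts = 10, seed = 2)
  al <- align_templates(fit$templates, tpl)
  expect_true(all(al$correlation > 0.99))
  expect_equal(fit$gev, 1, tolerance = 1e-9)
  # negating every input changes nothing
  fit_neg <- microstate_kmeans(-maps, 4, n_restarts = 10, seed = 2)
  expect_equal(abs(corr_diag(fit$templates$maps, fit_neg$templates$maps)),
               rep(1, 4), tolerance = 1e-9)
  expect_identical(fit$assignments, fit_neg$assignments)
})

test_that("k = 1 on a map and its negation yields one template matching both", {
  m <- rnorm(12); m <- m - mean(m)
  fit <- microstate_kmeans(cbind(m, -m), 1, n_restarts = 2, seed = 1)
  expect_equal(abs(spatial_correlation(fit$templates$maps[, 1], m)), 1,
               tolerance = 1e-9)
})

test_that("k-means equals the exhaustive 2-partition oracle on small problems", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(5:8, 1)
    maps <- apply(matrix(rnorm(10 * n), 10), 2, function(v) {
      v <- v - mean(v); v / sqrt(mean(v^2))       # unit GFP inputs
    })
    fit <- microstate_kmeans(maps, 2, n_restarts = 30, seed = rep)
    expect_equal(fit$gev, oracle_kmeans2(maps), tolerance = 1e-6)
  }
})

test_that("k-means is deterministic given a seed and returns its best restart", {
  set.seed(20)
  maps <- matrix(rnorm(16 * 30), 16)
  f1 <- microstate_kmeans(maps, 3, n_restarts = 8, seed = 4)
  f2 <- microstate_kmeans(maps, 3, n_restarts = 8, seed = 4)
  expect_identical(f1$templates$maps, f2$templates$maps)
  expect_identical(f1$gev, f2$gev)
  # a single-restart fit can never beat the multi-restart one
  single <- microstate_kmeans(maps, 3, n_restarts = 1, seed = 4)
  expect_lte(single$gev, f1$gev + 1e-12)
})

test_that("two-level clustering recovers common templates across subjects", {
  tpl <- make_templates(32, 4, min_separation = 0.4, seed = 30)
  set.seed(31)
  subject_maps <- lapply(1:6, function(s) {
    idx <- sample(1:4, 80, TRUE)
    noise <- matrix(rnorm(32 * 80, sd = 0.4), 32)
    m <- tpl$maps[, idx] + noise
    apply(m, 2, function(v) v - mean(v))
  })
  res <- two_level_clustering(subject_maps, k = 4, n_restarts = 8, seed = 7)
  al <- align_templates(res$group$templates, tpl)
  expect_gte(mean(al$correlation), 0.95)
  expect_true(res$group_gev >= 0 && res$group_gev <= 1)
  expect_identical(res$group$templates$level, "group")
  # degenerate pool: identical subjects -> group templates equal
  # individual templates up to sign/permutation
  same <- lapply(1:3, function(s) subject_maps[[1]])
  res2 <- two_level_clustering(same, k = 4, n_restarts = 8, seed = 7)
  ali <- align_templates(res2$group$templates, res2$individual[[1]]$templates)
  expect_true(all(ali$correlation > 1 - 1e-6))
})

test_that("two-level clustering reports which subject failed", {
  good <- matrix(rnorm(16 * 10), 16)
  expect_error(
    two_level_clustering(list(good, matrix(rnorm(16 * 2), 16)), k = 4),
    "subject 2")
})

test_that("template alignment undoes a known permutation and sign flip", {
  tpl <- make_templates(24, 4, seed = 40)
  perm <- c(3, 1, 4, 2)
  signs <- c(-1, 1, -1, 1)
  cand <- template_set(tpl$maps[, perm] * rep(signs, each = 24),
                       normalize = FALSE)
  al <- align_templates(cand, tpl)
  expect_equal(al$aligned$maps, tpl$maps, tolerance = 1e-12)
  expect_equal(al$correlation, rep(1, 4), tolerance = 1e-12)
  expect_identical(al$aligned$labels, tpl$labels)
  # identity case
  al2 <- align_templates(tpl, tpl)
  expect_identical(al2$mapping, 1:4)
  # optimality: never worse than the identity mapping
  set.seed(41)
  other <- template_set(matrix(rnorm(24 * 4), 24))
  al3 <- align_templates(other, tpl)
  ident <- abs(diag(cor(other$maps, tpl$maps)))
  expect_gte(mean(al3$correlation), mean(ident) - 1e-12)
})

test_that("canonical labelling attaches A-D and is stable under relabeling", {
  can <- canonical_templates(64)
  expect_identical(can$labels, c("A", "B", "C", "D"))
  expect_equal(unname(colSums(can$maps)), rep(0, 4), tolerance = 1e-9)
  # shuffled canonical maps are labelled back to themselves
  shuffled <- template_set(can$maps[, c(2, 4, 1, 3)], normalize = FALSE)
  lab <- label_templates(shuffled)
  expect_equal(lab$maps, can$maps, tolerance = 1e-9)
})

test_that("templates round-trip through TSV + sidecar", {
  tpl <- make_templates(16, 4, seed = 50)
  path <- tempfile(fileext = ".tsv")
  write_templates(tpl, path, gev = 0.8, seed = 50)
  back <- read_templates(path)
  expect_equal(back$maps, tpl$maps, tolerance = 1e-12)
  expect_identical(back$labels, tpl$labels)
  unlink(c(path, paste0(path, ".json")))
})
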