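#' Spatial correlation between two topographic maps
#'
#' Pearson correlation across electrodes between two average-referenced
#' scalp maps. Sign-aware: polarity handling (taking absolute values) is
#' the caller's concern.
#'
#' @param a,b Numeric vectors of equal length (per-electrode potentials),
#'   average-referenced.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' spatial_correlation(c(1, 0, -1), c(0, 1, -1))
#' @export
spatial_correlation <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stop_if_not(length(a) == length(b), "maps must have equal electrode counts")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  stop_if_not(na > 0 && nb > 0, "zero-variance map")
  sum(a * b) / (na * nb)
}

# Column-normalize an electrodes x maps matrix: average reference then
# unit GFP (norm = sqrt(n_el)). Columns must be nonzero.
normalize_maps <- function(x) {
  x <- average_reference(x)
  nrm <- sqrt(colSums(x^2))
  stop_if_not(all(nrm > 0), "zero-variance map cannot be normalized")
  sweep(x, 2L, nrm / sqrt(nrow(x)), "/")
}

#' Construct a template set
#'
#' A set of k average-referenced, unit-GFP topographic maps with class
#' labels.
#'
#' @param maps Numeric matrix, electrodes x k.
#' @param labels Character labels, unique, one per map; default
#'   `"1".."k"`.
#' @param level `"individual"` or `"group"` provenance tag.
#' @param normalize Normalize columns to average reference + unit GFP
#'   (default TRUE).
#' @return Object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL,
                         level = c("individual", "group"),
                         normalize = TRUE) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  if (normalize) maps <- normalize_maps(maps)
  k <- ncol(maps)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  stop_if_not(length(labels) == k && !anyDuplicated(labels),
              "labels must be unique, one per map")
  colnames(maps) <- labels
  structure(list(maps = maps, labels = as.character(labels),
                 level = level, k = k),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> k=%d (%s), %d electrodes, labels: %s\n",
              x$k, x$level, nrow(x$maps), paste(x$labels, collapse = ", ")))
  invisible(x)
}

# Correlations of each column map in X (el x n, average-referenced)
# against each template column in Tm (el x k): returns n x k matrix.
corr_matrix <- function(X, Tm) {
  Xc <- average_reference(X); Tc <- average_reference(Tm)
  nx <- sqrt(colSums(Xc^2)); nt <- sqrt(colSums(Tc^2))
  C <- crossprod(Xc, Tc)
  C <- sweep(C, 1L, pmax(nx, .Machine$double.eps), "/")
  sweep(C, 2L, pmax(nt, .Machine$double.eps), "/")
}

#' Global explained variance of a template assignment
#'
#' GEV = sum_t (w_t * corr_t)^2 / sum_t w_t^2, where w_t is the GFP of
#' map t and corr_t the spatial correlation between map t and its
#' assigned template. Polarity-invariant (correlation enters squared).
#'
#' @param maps Electrodes x n matrix of average-referenced maps.
#' @param templates A [template_set] (or electrodes x k matrix).
#' @param assignments Integer vector in `1..k`, one per map.
#' @param weights Per-map GFP weights; defaults to the maps' own GFP.
#' @return Fraction in `[0, 1]`.
#' @export
global_explained_variance <- function(maps, templates, assignments,
                                      weights = NULL) {
  Tm <- if (inherits(templates, "template_set")) templates$maps else as.matrix(templates)
  maps <- as.matrix(maps)
  stop_if_not(length(assignments) == ncol(maps),
              "one assignment per map is required")
  if (is.null(weights)) weights <- gfp_of(maps)
  C <- corr_matrix(maps, Tm)
  ct <- C[cbind(seq_len(ncol(maps)), assignments)]
  sum((weights * ct)^2) / sum(weights^2)
}

# One modified-k-means run from a given template initialization.
# X: el x n normalized maps; w: GFP weights; T0: el x k.
.mkmeans_run <- function(X, w, T0, max_iter, tol) {
  k <- ncol(T0); n <- ncol(X)
  Tm <- T0
  state <- NULL                 # best accepted iterate so far
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- corr_matrix(X, Tm)
    A <- max.col(C^2, ties.method = "first")   # lowest index on ties
    # repair empty clusters from the worst-represented map
    best <- C[cbind(seq_len(n), A)]^2
    for (j in seq_len(k)) {
      if (!any(A == j)) {
        worst <- which.min(best)
        A[worst] <- j
        best[worst] <- 1
      }
    }
    # update: dominant spatial pattern (leading eigenvector of the
    # cluster's cross-product); polarity-invariant by construction
    for (j in seq_len(k)) {
      idx <- which(A == j)
      M <- X[, idx, drop = FALSE]
      if (length(idx) == 1L) {
        Tm[, j] <- M[, 1L]
      } else {
        S <- tcrossprod(M)               # el x el cross-product
        Tm[, j] <- eigen(S, symmetric = TRUE)$vectors[, 1L]
      }
    }
    Tm <- normalize_maps(Tm)
    C <- corr_matrix(X, Tm)
    A <- max.col(C^2, ties.method = "first")
    gev <- sum((w * C[cbind(seq_len(n), A)])^2) / sum(w^2)
    if (!is.null(state)) {
      if (gev + 1e-12 < state$gev) break      # objective must not decrease
      if (abs(gev - state$gev) <= tol * max(state$gev, 1e-12)) {
        state <- list(Tm = Tm, A = A, gev = gev)
        converged <- TRUE
        break
      }
    }
    state <- list(Tm = Tm, A = A, gev = gev)
  }
  C <- corr_matrix(X, state$Tm)
  pol <- ifelse(C[cbind(seq_len(n), state$A)] >= 0, 1L, -1L)
  list(templates = state$Tm, assignments = state$A, polarities = pol,
       gev = state$gev, converged = converged)
}

#' Polarity-invariant modified k-means for topographic maps
#'
#' Clusters scalp topographies ignoring polarity: the assignment step
#' labels each map by the template maximizing the squared spatial
#' correlation, and the update step recomputes each template as the
#' dominant spatial pattern (leading eigenvector of the cluster's
#' cross-product matrix), renormalized to unit GFP. The best of
#' `n_restarts` random initializations by global explained variance (GEV)
#' is returned.
#'
#' @param maps Electrodes x n matrix of topographic maps (e.g. GFP-peak
#'   maps), or an [eeg_recording] whose samples are used as maps.
#' @param k Number of classes.
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Iteration cap per restart (default 100).
#' @param tol Relative GEV change declaring convergence (default 1e-6).
#' @param seed Integer master seed; restart r uses a sub-seed derived
#'   from it, so results are reproducible.
#' @param normalize Normalize input maps to unit GFP before clustering
#'   (default TRUE); GEV weights are always the original map GFPs.
#' @return Object of class `microstate_kmeans`: a [template_set] plus
#'   `assignments`, `polarities`, `gev`, `converged`.
#' @examples
#' tpl <- make_templates(16, 2, seed = 1)
#' maps <- tpl$maps[, c(1, 1, 2, 2)] * rep(c(1, -1), 2)
#' fit <- microstate_kmeans(maps, k = 2, n_restarts = 4, seed = 1)
#' fit$gev
#' @export
microstate_kmeans <- function(maps, k, n_restarts = 20L, max_iter = 100L,
                              tol = 1e-6, seed = NULL, normalize = TRUE) {
  if (inherits(maps, "eeg_recording")) maps <- maps$data
  maps <- as.matrix(maps)
  n <- ncol(maps)
  stop_if_not(n >= k, "need at least k maps")
  w <- gfp_of(maps)
  X <- if (normalize) normalize_maps(maps) else average_reference(maps)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    T0 <- with_seed(derive_seed(seed, r),
                    X[, sample.int(n, k), drop = FALSE])
    fit <- .mkmeans_run(X, w, T0, max_iter, tol)
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  ts <- template_set(best$templates, level = "individual")
  structure(list(templates = ts, assignments = best$assignments,
                 polarities = best$polarities, gev = best$gev,
                 converged = best$converged, k = as.integer(k),
                 n_maps = n),
            class = "microstate_kmeans")
}

#' @export
print.microstate_kmeans <- function(x, ...) {
  cat(sprintf("<microstate_kmeans> k=%d on %d maps, GEV = %.4f%s\n",
              x$k, x$n_maps, x$gev,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.microstate_kmeans <- function(object, ...) {
  counts <- tabulate(object$assignments, nbins = object$k)
  out <- data.frame(class = object$templates$labels, n_maps = counts)
  cat(sprintf("Modified k-means fit: k = %d, GEV = %.4f\n", object$k, object$gev))
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
plot.microstate_kmeans <- function(x, ...) {
  graphics::matplot(x$templates$maps, type = "l", lty = 1,
                    xlab = "electrode", ylab = "normalized potential", ...)
  graphics::legend("topright", legend = x$templates$labels, lty = 1,
                   col = seq_len(x$k), bty = "n")
  invisible(x)
}

#' Two-level (individual then group) microstate clustering
#'
#' Runs modified k-means per subject on that subject's GFP-peak maps,
#' then pools the per-subject templates (k per subject, unit GFP so each
#' participant contributes equally) and clusters the pool again to obtain
#' the group template set. Within each subject the k templates are
#' ordered by their GEV contribution, most dominant first.
#'
#' @param subject_maps List of electrodes x n_i matrices (one per
#'   subject), each with at least k maps.
#' @param k Number of classes (default 4).
#' @param n_restarts,max_iter,tol Passed to [microstate_kmeans()].
#' @param seed Master seed; per-subject and group sub-seeds are derived
#'   from it.
#' @return List with `group` (a group-level `microstate_kmeans` fit),
#'   `individual` (list of per-subject fits), and `group_gev`.
#' @export
two_level_clustering <- function(subject_maps, k = 4L, n_restarts = 20L,
                                 max_iter = 100L, tol = 1e-6, seed = NULL) {
  stop_if_not(length(subject_maps) >= 1L, "at least one subject is required")
  fits <- vector("list", length(subject_maps))
  for (s in seq_along(subject_maps)) {
    m <- as.matrix(subject_maps[[s]])
    if (ncol(m) < k)
      stop(sprintf("subject %d has %d maps; need >= k = %d", s, ncol(m), k),
           call. = FALSE)
    fits[[s]] <- tryCatch(
      microstate_kmeans(m, k, n_restarts, max_iter, tol,
                        seed = derive_seed(seed, s)),
      error = function(e)
        stop(sprintf("subject %d: %s", s, conditionMessage(e)), call. = FALSE))
    # order templates by per-class GEV contribution, dominant first
    w <- gfp_of(m)
    C <- corr_matrix(m, fits[[s]]$templates$maps)
    contrib <- vapply(seq_len(k), function(j) {
      idx <- fits[[s]]$assignments == j
      sum((w[idx] * C[idx, j])^2)
    }, numeric(1)) / sum(w^2)
    ord <- order(contrib, decreasing = TRUE)
    fits[[s]]$templates$maps <- fits[[s]]$templates$maps[, ord, drop = FALSE]
    colnames(fits[[s]]$templates$maps) <- fits[[s]]$templates$labels
    fits[[s]]$class_gev <- contrib[ord]
  }
  pool <- do.call(cbind, lapply(fits, function(f) f$templates$maps))
  group <- microstate_kmeans(pool, k, n_restarts, max_iter, tol,
                             seed = derive_seed(seed, 0L))
  group$templates$level <- "group"
  list(group = group, individual = fits, group_gev = group$gev)
}

#' Align a candidate template set to a reference
#'
#' Finds the one-to-one class mapping maximizing the total absolute
#' spatial correlation over all permutations (exhaustive for k <= 8),
#' reorders and re-signs the candidate maps to correlate positively with
#' the reference, and relabels them with the reference labels.
#'
#' @param candidate,reference [template_set]s with equal k and electrode
#'   count.
#' @return List: `aligned` (relabeled template_set), `mapping` (for each
#'   reference class, the index of the matched candidate map),
#'   `correlation` (per-pair |spatial correlation|).
#' @export
align_templates <- function(candidate, reference) {
  stopifnot(inherits(candidate, "template_set"),
            inherits(reference, "template_set"))
  k <- reference$k
  stop_if_not(candidate$k == k, "template sets must have equal k")
  stop_if_not(nrow(candidate$maps) == nrow(reference$maps),
              "electrode counts must match")
  stop_if_not(k <= 8L, "exhaustive alignment supports k <= 8")
  C <- abs(corr_matrix(candidate$maps, reference$maps))  # cand x ref
  perms <- permutations_of(k)
  scores <- apply(perms, 1L, function(p) sum(C[cbind(p, seq_len(k))]))
  p <- perms[which.max(scores), ]                        # p[j] = cand for ref j
  maps <- candidate$maps[, p, drop = FALSE]
  signs <- vapply(seq_len(k), function(j)
    sign(spatial_correlation(maps[, j], reference$maps[, j])), numeric(1))
  signs[signs == 0] <- 1
  maps <- sweep(maps, 2L, signs, "*")
  aligned <- template_set(maps, labels = reference$labels,
                          level = candidate$level, normalize = FALSE)
  list(aligned = aligned, mapping = p,
       correlation = C[cbind(p, seq_len(k))])
}

# All permutations of 1..k as rows (k! x k).
permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Canonical microstate class templates (synthetic)
#'
#' Built-in synthetic stand-ins for the four canonical resting-state map
#' configurations used to attach A-D labels: classes A and B are
#' left/right diagonal field gradients, class C an anterior-posterior
#' gradient, class D a fronto-central extreme. Electrodes are placed on
#' concentric rings of an idealized circular montage; these maps are a
#' labelling aid, not measured grand averages.
#'
#' @param n_electrodes Electrode count (>= 4).
#' @return A [template_set] with labels A, B, C, D, level `"group"`.
#' @export
canonical_templates <- function(n_electrodes = 64L) {
  stop_if_not(n_electrodes >= 4L, "need at least 4 electrodes")
  pos <- ring_layout(n_electrodes)             # x: left->right, y: post->ant
  A <- pos$y - pos$x                           # right-frontal vs left-posterior
  B <- pos$y + pos$x                           # left-frontal vs right-posterior
  C <- pos$y                                   # anterior-posterior axis
  D <- exp(-((pos$x)^2 + (pos$y - 0.3)^2) / 0.35)  # fronto-central extreme
  template_set(cbind(A, B, C, D), labels = c("A", "B", "C", "D"),
               level = "group")
}

# Idealized circular montage: electrodes on concentric rings.
ring_layout <- function(n) {
  n_rings <- max(2L, ceiling(sqrt(n / 3)))
  radii <- seq(0, 1, length.out = n_rings + 1L)[-1L]
  per_ring <- diff(round(seq(0, n, length.out = n_rings + 1L)))
  x <- y <- numeric(0)
  for (r in seq_len(n_rings)) {
    m <- per_ring[r]
    th <- 2 * pi * (seq_len(m) - 1L) / max(m, 1L) + r  # stagger rings
    x <- c(x, radii[r] * cos(th)); y <- c(y, radii[r] * sin(th))
  }
  list(x = x[seq_len(n)], y = y[seq_len(n)])
}

#' Label group templates by similarity to the canonical classes
#'
#' Convenience wrapper: aligns a fitted template set against
#' [canonical_templates()] and returns it relabeled A-D.
#'
#' @param fit A `microstate_kmeans` fit or [template_set] with k = 4.
#' @return The relabeled [template_set], with the alignment stored in
#'   attribute `"alignment"`.
#' @export
label_templates <- function(fit) {
  ts <- if (inherits(fit, "microstate_kmeans")) fit$templates else fit
  stop_if_not(ts$k == 4L, "canonical labelling requires k = 4")
  al <- align_templates(ts, canonical_templates(nrow(ts$maps)))
  out <- al$aligned
  attr(out, "alignment") <- al
  out
}

#' Serialize / read a template set as TSV plus sidecar
#'
#' @param ts A [template_set]; `gev`, `seed` optional sidecar entries.
#' @param path Output TSV (electrodes x classes, with header labels).
#' @param gev,seed Optional numbers recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_templates <- function(ts, path, gev = NULL, seed = NULL) {
  stopifnot(inherits(ts, "template_set"))
  utils::write.table(ts$maps, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE)
  meta <- list(labels = ts$labels, level = ts$level, k = ts$k)
  if (!is.null(gev)) meta$gev <- gev
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE))
  dimnames(x) <- NULL
  template_set(x, labels = meta$labels, level = meta$level, normalize = FALSE)
}
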