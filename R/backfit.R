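# Competitive backfitting of template maps onto continuous EEG, temporal
# smoothing with a Besag neighbourhood penalty, and the per-class
# temporal parameters (mean duration, coverage, occurrence).

#' Construct a microstate segmentation
#'
#' @param labels Integer vector of per-sample class indices in `1..k`.
#' @param sampling_rate Hz.
#' @param k Number of classes (default `max(labels)`).
#' @return Object of class `microstate_segmentation`.
#' @export
microstate_segmentation <- function(labels, sampling_rate, k = max(labels)) {
  labels <- as.integer(labels)
  stop_if_not(length(labels) >= 1L && !anyNA(labels),
              "labels must be a non-empty integer vector")
  stop_if_not(all(labels >= 1L & labels <= k), "labels must lie in 1..k")
  structure(list(labels = labels, sampling_rate = sampling_rate,
                 k = as.integer(k)),
            class = "microstate_segmentation")
}

#' @export
print.microstate_segmentation <- function(x, ...) {
  r <- rle(x$labels)
  cat(sprintf("<microstate_segmentation> %d samples @ %g Hz, k=%d, %d segments\n",
              length(x$labels), x$sampling_rate, x$k, length(r$lengths)))
  invisible(x)
}

#' Competitive fitting of templates to every EEG sample
#'
#' Labels each time point with the class whose template has the highest
#' absolute spatial correlation with the instantaneous scalp map
#' (polarity ignored). Ties go to the lowest class index. Samples with
#' zero variance across electrodes cannot be correlated; they inherit
#' the preceding sample's label (lowest index for a leading run) and are
#' counted in the `diagnostics` attribute.
#'
#' @param rec An average-referenced [eeg_recording].
#' @param templates A [template_set] with matching electrode count.
#' @return A `microstate_segmentation`; attribute `diagnostics` holds
#'   `n_zero_variance`.
#' @export
competitive_fit <- function(rec, templates) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(templates, "template_set"))
  stop_if_not(rec$reference_state == "average",
              "recording must be average-referenced")
  stop_if_not(nrow(rec$data) == nrow(templates$maps),
              "electrode counts must match")
  X <- rec$data
  nrm <- sqrt(colSums(average_reference(X)^2))
  zero <- nrm <= .Machine$double.eps * nrow(X)
  C2 <- corr_safe(X, templates$maps)^2
  lab <- max.col(C2, ties.method = "first")
  if (any(zero)) {
    idx <- which(zero)
    for (i in idx) lab[i] <- if (i == 1L) 1L else lab[i - 1L]
    # a zero sample at t=1 followed by zero samples propagates class 1
  }
  seg <- microstate_segmentation(lab, rec$sampling_rate, templates$k)
  attr(seg, "diagnostics") <- list(n_zero_variance = sum(zero))
  seg
}

# corr_matrix variant that returns 0 rows for zero-variance samples
# instead of erroring.
corr_safe <- function(X, Tm) {
  Xc <- average_reference(X); Tc <- average_reference(Tm)
  nx <- sqrt(colSums(Xc^2)); nt <- sqrt(colSums(Tc^2))
  nx[nx <= .Machine$double.eps * nrow(X)] <- Inf
  C <- crossprod(Xc, Tc)
  C <- sweep(C, 1L, nx, "/")
  sweep(C, 2L, pmax(nt, .Machine$double.eps), "/")
}

#' Temporal smoothing of a segmentation (Besag penalty)
#'
#' Iteratively relabels each sample to maximize
#' `fit(t, class) + lambda * N_b(t, class)`, where `fit` is the squared
#' spatial correlation between the sample and the class template and
#' `N_b` counts same-class labels among the `2b` neighbours
#' (window half-size `b`, truncated at the edges) under the current
#' labeling. Sweeps are synchronous (all labels updated from the
#' previous iterate) and repeat until a fixed point or `max_iter`.
#' Optionally, single-sample segments are then merged into the temporal
#' neighbour whose template correlates better (in absolute value) at
#' that sample, earlier neighbour on ties, repeatedly until none remain.
#'
#' @param seg A `microstate_segmentation` (e.g. from [competitive_fit()]).
#' @param rec The recording the segmentation belongs to.
#' @param templates The [template_set] used for fitting.
#' @param window_half_size Neighbourhood half-width b in samples
#'   (default 5).
#' @param strength Penalty weight lambda (default 10).
#' @param reject_single_frames Merge 1-sample segments afterwards
#'   (default TRUE).
#' @param max_iter Sweep cap (default 50).
#' @return A smoothed `microstate_segmentation`; attribute `converged`
#'   is FALSE with a warning if the sweep cap was hit.
#' @export
smooth_labels <- function(seg, rec, templates,
                          window_half_size = 5L, strength = 10,
                          reject_single_frames = TRUE, max_iter = 50L) {
  stopifnot(inherits(seg, "microstate_segmentation"))
  b <- as.integer(window_half_size)
  stop_if_not(b >= 0L && strength >= 0, "need b >= 0 and strength >= 0")
  n <- length(seg$labels); k <- seg$k
  stop_if_not(ncol(rec$data) == n, "recording and segmentation lengths differ")
  C2 <- corr_safe(rec$data, templates$maps)^2
  lab <- seg$labels
  converged <- TRUE
  if (strength > 0 && b > 0) {
    converged <- FALSE
    prev <- NULL
    for (it in seq_len(max_iter)) {
      score <- C2
      for (j in seq_len(k)) {
        ind <- as.numeric(lab == j)
        cs <- c(0, cumsum(ind))
        lo <- pmax(seq_len(n) - b, 1L); hi <- pmin(seq_len(n) + b, n)
        nb <- cs[hi + 1L] - cs[lo] - ind      # exclude the sample itself
        score[, j] <- score[, j] + strength * nb
      }
      new <- max.col(score, ties.method = "first")
      if (all(new == lab)) { converged <- TRUE; break }
      if (!is.null(prev) && all(new == prev)) {
        # synchronous sweeps can settle into a 2-cycle; take the current
        # iterate as the (deterministic) fixed point of the cycle
        converged <- TRUE
        break
      }
      prev <- lab
      lab <- new
    }
    if (!converged) warning("label smoothing did not converge; returning last iterate")
  }
  if (reject_single_frames) lab <- reject_singletons(lab, rec, templates)
  out <- microstate_segmentation(lab, seg$sampling_rate, k)
  attr(out, "converged") <- converged
  out
}

# Merge every 1-sample run into the neighbouring run whose template has
# the higher |spatial correlation| at that sample (earlier neighbour on
# ties); repeat until no 1-sample run remains.
reject_singletons <- function(lab, rec, templates) {
  n <- length(lab)
  if (n <= 1L) return(lab)
  Cabs <- abs(corr_safe(rec$data, templates$maps))
  # merge one singleton per pass: each merge strictly lowers the run
  # count, so the loop terminates even on alternating label patterns
  repeat {
    r <- rle(lab)
    if (length(r$lengths) == 1L) break
    s <- which(r$lengths == 1L)[1L]
    if (is.na(s)) break
    t <- (cumsum(r$lengths) - r$lengths + 1L)[s]
    prev <- if (s > 1L) r$values[s - 1L] else NA_integer_
    nxt  <- if (s < length(r$values)) r$values[s + 1L] else NA_integer_
    lab[t] <- if (is.na(prev)) nxt
              else if (is.na(nxt)) prev
              else if (Cabs[t, prev] >= Cabs[t, nxt]) prev else nxt
  }
  lab
}

#' Per-class temporal microstate parameters
#'
#' Segments are maximal runs of a constant label (truncated first/last
#' runs included). For each class: mean duration is the average run
#' length in ms; coverage the percentage of samples spent in the class;
#' occurrence the number of runs per second. Classes absent from the
#' sequence get 0 for all three. The identity
#' `occurrence * mean_duration / 1000 = coverage / 100` holds exactly.
#'
#' @param seg A `microstate_segmentation`.
#' @return Object of class `microstate_params`: a data.frame with columns
#'   `class`, `mean_duration`, `coverage`, `occurrence`, `n_segments`,
#'   plus attributes `total_time` (s) and `gev` if present upstream.
#' @examples
#' seg <- microstate_segmentation(rep(c(1, 2, 1), each = 4), 128, k = 2)
#' microstate_parameters(seg)
#' @export
microstate_parameters <- function(seg) {
  stopifnot(inherits(seg, "microstate_segmentation"))
  n <- length(seg$labels); fs <- seg$sampling_rate
  r <- rle(seg$labels)
  total_s <- n / fs
  out <- data.frame(class = seq_len(seg$k), mean_duration = 0,
                    coverage = 0, occurrence = 0, n_segments = 0L)
  for (j in seq_len(seg$k)) {
    runs <- r$lengths[r$values == j]
    if (length(runs) == 0L) next
    out$n_segments[j] <- length(runs)
    out$mean_duration[j] <- mean(runs) * 1000 / fs
    out$coverage[j] <- sum(runs) / n * 100
    out$occurrence[j] <- length(runs) / total_s
  }
  attr(out, "total_time") <- total_s
  class(out) <- c("microstate_params", "data.frame")
  out
}

#' @export
print.microstate_params <- function(x, ...) {
  cat(sprintf("Microstate temporal parameters (total %.2f s):\n",
              attr(x, "total_time")))
  y <- as.data.frame(x)
  y$mean_duration <- round(y$mean_duration, 2)
  y$coverage <- round(y$coverage, 2)
  y$occurrence <- round(y$occurrence, 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Backfit templates onto a recording (predict method)
#'
#' Full backfitting stage: competitive fit, then temporal smoothing with
#' the given configuration. `predict.microstate_kmeans` is a thin alias
#' so a fitted clustering object can be applied directly to new data.
#'
#' @param object A `microstate_kmeans` fit (or [template_set] for
#'   `backfit()`).
#' @param rec The average-referenced [eeg_recording] to label.
#' @param smooth Apply temporal smoothing (default TRUE).
#' @param ... Passed to [smooth_labels()] (window_half_size, strength,
#'   reject_single_frames).
#' @return A `microstate_segmentation`.
#' @export
backfit <- function(object, rec, smooth = TRUE, ...) {
  ts <- if (inherits(object, "microstate_kmeans")) object$templates else object
  seg <- competitive_fit(rec, ts)
  if (smooth) seg <- smooth_labels(seg, rec, ts, ...)
  seg
}

#' @rdname backfit
#' @param newdata An [eeg_recording] (alias for `rec`).
#' @export
predict.microstate_kmeans <- function(object, newdata, ...) {
  backfit(object, newdata, ...)
}

#' Write a segmentation / parameter table as TSV
#'
#' @param seg A `microstate_segmentation`.
#' @param path Output TSV (columns sample, label).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  utils::write.table(
    data.frame(sample = seq_along(seg$labels), label = seg$labels),
    path, sep = "\t", row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Tidy long-format parameter table for a cohort
#'
#' Stacks per-subject [microstate_parameters()] results into the tidy
#' exchange format consumed by the statistics layer: one row per
#' subject x class x parameter.
#'
#' @param params_list Named list of `microstate_params` (names = subject
#'   ids).
#' @param class_labels Optional class label vector (e.g. A-D).
#' @return data.frame with columns subject, class, parameter, value.
#' @export
params_long <- function(params_list, class_labels = NULL) {
  rows <- lapply(names(params_list), function(id) {
    p <- params_list[[id]]
    lab <- if (is.null(class_labels)) as.character(p$class) else
      class_labels[p$class]
    data.frame(subject = id,
               class = rep(lab, 3L),
               parameter = rep(c("mean_duration", "coverage", "occurrence"),
                               each = nrow(p)),
               value = c(p$mean_duration, p$coverage, p$occurrence))
  })
  do.call(rbind, rows)
}
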