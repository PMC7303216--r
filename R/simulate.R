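# Surrogate EEG with planted microstate dynamics, plus the tabular
# fixtures (demographic counts, uncorrected p-values) used by the
# statistical layer.

#' Generate mutually dissimilar random template maps
#'
#' Draws k average-referenced, unit-GFP topographies by rejection
#' sampling until every pair satisfies |spatial correlation| <=
#' `min_separation`.
#'
#' @param n_electrodes Electrode count (>= k).
#' @param k Number of maps.
#' @param min_separation Upper bound on pairwise |spatial correlation|,
#'   in `[0, 1)`.
#' @param seed Integer seed for reproducibility.
#' @param max_attempts Rejection-sampling budget before failing.
#' @return A [template_set] with k maps.
#' @examples
#' tpl <- make_templates(64, 4, min_separation = 0.5, seed = 7)
#' max(abs(crossprod(tpl$maps))) # off-diagonal bounded by 64 * 0.5
#' @export
make_templates <- function(n_electrodes, k, min_separation = 0.5,
                           seed = NULL, max_attempts = 1000L) {
  stop_if_not(k >= 1L, "k must be >= 1")
  stop_if_not(n_electrodes >= k, "need n_electrodes >= k")
  stop_if_not(min_separation >= 0 && min_separation < 1,
              "min_separation must be in [0, 1)")
  with_seed(seed, {
    maps <- matrix(NA_real_, n_electrodes, k)
    got <- 0L
    for (attempt in seq_len(max_attempts)) {
      cand <- normalize_maps(matrix(stats::rnorm(n_electrodes), ncol = 1L))
      ok <- got == 0L ||
        all(abs(corr_matrix(cand, maps[, seq_len(got), drop = FALSE])) <=
              min_separation)
      if (ok) {
        got <- got + 1L
        maps[, got] <- cand
        if (got == k) break
      }
    }
    if (got < k)
      stop(sprintf(
        "could not draw %d maps with pairwise |corr| <= %g in %d attempts",
        k, min_separation, max_attempts), call. = FALSE)
    template_set(maps, normalize = FALSE)
  })
}

#' Specification of a surrogate microstate EEG simulation
#'
#' Bundles and validates the generative parameters: the class templates,
#' mean segment durations, the class transition matrix of the embedded
#' Markov chain (zero diagonal, rows summing to 1), the signal-to-noise
#' ratio (ratio of the time-averaged GFP of the noiseless signal to that
#' of the noise), and the GFP amplitude profile.
#'
#' @param templates A [template_set].
#' @param sampling_rate Hz (default 128).
#' @param duration Seconds (default 300, i.e. 5 min).
#' @param mean_durations Per-class mean segment duration in ms (recycled
#'   to k); default 78 ms, inside the canonical 60-120 ms range.
#' @param transition_matrix k x k probabilities, zero diagonal, rows sum
#'   to 1; default uniform off-diagonal.
#' @param snr Signal-to-noise ratio (> 0); `Inf` for noise-free.
#' @param amplitude Either `"sinusoidal"` (default; GFP modulated as
#'   1 + depth * sin(2 pi t / period) so GFP peaks exist) or
#'   `"constant"`.
#' @param amplitude_period Modulation period in samples (default
#'   `round(0.1 * sampling_rate)`, i.e. ~100 ms).
#' @param amplitude_depth Modulation depth in `[0, 1)` (default 0.3).
#' @param seed Integer seed.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(templates, sampling_rate = 128,
                            duration = 300,
                            mean_durations = 78,
                            transition_matrix = NULL,
                            snr = 4,
                            amplitude = c("sinusoidal", "constant"),
                            amplitude_period = round(0.1 * sampling_rate),
                            amplitude_depth = 0.3,
                            seed = NULL) {
  stopifnot(inherits(templates, "template_set"))
  amplitude <- match.arg(amplitude)
  k <- templates$k
  mean_durations <- rep_len(as.numeric(mean_durations), k)
  stop_if_not(all(mean_durations > 0), "mean_durations must be positive")
  stop_if_not(all(mean_durations >= 1000 / sampling_rate),
              "mean_durations must be at least one sample period")
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / max(k - 1L, 1L), k, k)
    diag(transition_matrix) <- 0
    if (k == 1L) transition_matrix <- matrix(1, 1L, 1L) * 0
  }
  transition_matrix <- as.matrix(transition_matrix)
  stop_if_not(all(dim(transition_matrix) == k), "transition matrix must be k x k")
  stop_if_not(all(abs(diag(transition_matrix)) == 0),
              "transition matrix diagonal must be 0")
  if (k > 1L)
    stop_if_not(all(abs(rowSums(transition_matrix) - 1) <= 1e-12),
                "transition matrix rows must sum to 1")
  stop_if_not(snr > 0, "snr must be positive")
  stop_if_not(sampling_rate > 0 && duration > 0,
              "sampling_rate and duration must be positive")
  structure(list(templates = templates, n_electrodes = nrow(templates$maps),
                 sampling_rate = sampling_rate, duration = duration,
                 mean_durations = mean_durations,
                 transition_matrix = transition_matrix, snr = snr,
                 amplitude = amplitude, amplitude_period = amplitude_period,
                 amplitude_depth = amplitude_depth, seed = seed, k = k),
            class = "simulation_spec")
}

# Stationary distribution of the embedded Markov chain (left eigenvector
# of the transition matrix at eigenvalue 1).
embedded_stationary <- function(P) {
  k <- nrow(P)
  if (k == 1L) return(1)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Stationary class coverage of the semi-Markov segment process
#'
#' Closed form: coverage_j is proportional to nu_j * m_j, where nu is
#' the stationary distribution of the embedded class chain and m_j the
#' class's mean segment length.
#'
#' @param spec A [simulation_spec].
#' @return Numeric vector of k fractions summing to 1.
#' @export
stationary_coverage <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  nu <- embedded_stationary(spec$transition_matrix)
  m <- spec$mean_durations * spec$sampling_rate / 1000
  p <- nu * m
  p / sum(p)
}

#' Simulate surrogate EEG with planted microstate dynamics
#'
#' The class label sequence is a semi-Markov chain: classes switch
#' according to `transition_matrix`; each visit's length is 1 + a
#' geometric draw whose mean equals the class's mean duration in samples
#' (so the floor is one sample). The signal at sample t is
#' amplitude(t) x the active class's template; independent zero-mean
#' Gaussian sensor noise, projected to the average-reference subspace,
#' is added at the requested GFP-based SNR.
#'
#' @param spec A [simulation_spec].
#' @return List with `recording` (average-referenced [eeg_recording]) and
#'   `ground_truth` (class `ground_truth`: `labels` per sample and
#'   `segments`, a data.frame with columns class/start/length).
#' @examples
#' tpl <- make_templates(16, 3, seed = 2)
#' sim <- simulate_microstate_eeg(simulation_spec(tpl, duration = 5, seed = 3))
#' head(sim$ground_truth$segments)
#' @export
simulate_microstate_eeg <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  fs <- spec$sampling_rate
  n <- round(spec$duration * fs)
  k <- spec$k
  mean_len <- spec$mean_durations * fs / 1000          # samples, >= 1
  with_seed(spec$seed, {
    nu <- embedded_stationary(spec$transition_matrix)
    cls <- integer(0); len <- integer(0)
    total <- 0L
    cur <- sample.int(k, 1L, prob = nu)
    while (total < n) {
      # truncated geometric: 1 + Geom(p), mean 1 + (1-p)/p = mean_len
      p <- if (mean_len[cur] <= 1) 1 else 1 / mean_len[cur]
      L <- 1L + stats::rgeom(1L, p)
      L <- min(L, n - total)
      cls <- c(cls, cur); len <- c(len, L)
      total <- total + L
      cur <- if (k > 1L)
        sample.int(k, 1L, prob = spec$transition_matrix[cur, ]) else cur
    }
    labels <- rep.int(cls, len)
    amp <- switch(spec$amplitude,
      constant = rep(1, n),
      sinusoidal = 1 + spec$amplitude_depth *
        sin(2 * pi * seq_len(n) / spec$amplitude_period))
    signal <- spec$templates$maps[, labels, drop = FALSE] *
      rep(amp, each = spec$n_electrodes)
    if (is.finite(spec$snr)) {
      noise <- matrix(stats::rnorm(spec$n_electrodes * n), spec$n_electrodes)
      noise <- average_reference(noise)
      scale <- mean(gfp_of(signal)) / (spec$snr * mean(gfp_of(noise)))
      x <- signal + scale * noise
    } else {
      x <- signal
    }
    rec <- eeg_recording(average_reference(x), fs,
                         reference_state = "average")
    segs <- data.frame(class = cls,
                       start = c(1L, 1L + cumsum(len)[-length(len)]),
                       length = len)
    gt <- structure(list(labels = labels, segments = segs, k = k,
                         sampling_rate = fs),
                    class = "ground_truth")
    list(recording = rec, ground_truth = gt)
  })
}

#' Write a ground-truth segment table as TSV
#'
#' @param gt A `ground_truth` object.
#' @param path Output TSV path (columns class, start, length).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.table(gt$segments, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Demographic contingency tables and uncorrected p-values (fixtures)
#'
#' Returns the printed group demographics of the schizophrenia
#' endophenotype study exactly as published: 2x2 gender and handedness
#' counts for the patient/sibling/control groups, the first-episode
#' (FEP) versus matched-chronic-patient handedness counts, and the 12
#' uncorrected post hoc p-values (3 parameters x 4 classes) of the
#' patients-versus-controls comparison.
#'
#' @return A list with components `gender` (named counts `c(F, M)` per
#'   group), `handedness` (named counts `c(L, R)` per group),
#'   `table1_p` (named numeric vector of 12 uncorrected p-values), and
#'   `pair2x2(a, b, which)` helper building a 2x2 matrix for two groups.
#' @examples
#' fx <- demographics_fixtures()
#' fx$pair2x2("patients", "controls", "gender")
#' @export
demographics_fixtures <- function() {
  gender <- list(
    patients   = c(F = 11L, M = 90L),
    siblings   = c(F = 21L, M = 22L),
    controls   = c(F = 39L, M = 36L),
    FEP        = c(F = 12L, M = 10L),
    patients22 = c(F = 8L,  M = 14L))
  handedness <- list(
    patients   = c(L = 6L, R = 95L),
    siblings   = c(L = 2L, R = 41L),
    controls   = c(L = 4L, R = 71L),
    FEP        = c(L = 1L, R = 21L),
    patients22 = c(L = 1L, R = 21L))
  table1_p <- c(
    duration.A  = 0.054,    duration.B  = 0.003,
    duration.C  = 1.315e-4, duration.D  = 3.010e-6,
    coverage.A  = 0.449,    coverage.B  = 0.074,
    coverage.C  = 1.452e-7, coverage.D  = 3.445e-6,
    occurrence.A = 0.882,   occurrence.B = 0.112,
    occurrence.C = 1.170e-4, occurrence.D = 1.620e-4)
  pair2x2 <- function(a, b, which = c("gender", "handedness")) {
    which <- match.arg(which)
    src <- if (which == "gender") gender else handedness
    m <- rbind(src[[a]], src[[b]])
    rownames(m) <- c(a, b)
    m
  }
  list(gender = gender, handedness = handedness, table1_p = table1_p,
       pair2x2 = pair2x2)
}
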