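#' Construct a multichannel EEG recording
#'
#' Container for a continuous multichannel EEG segment: an electrodes x
#' samples matrix of potentials (microvolts) with its sampling rate,
#' channel labels, and reference state.
#'
#' @param data Numeric matrix, electrodes in rows, samples in columns.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of channel names; defaults to
#'   `E1..En`.
#' @param reference_state Either `"raw"` or `"average"`. When `"average"`
#'   is declared the constructor checks that each sample sums to ~0 across
#'   electrodes.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(64 * 256), 64), 128)
#' rec
#' @export
eeg_recording <- function(data, sampling_rate,
                          channel_labels = NULL,
                          reference_state = c("raw", "average")) {
  reference_state <- match.arg(reference_state)
  data <- as.matrix(data)
  stop_if_not(is.numeric(data) && !anyNA(data),
              "data must be a numeric matrix without missing values")
  stop_if_not(nrow(data) >= 2L, "at least 2 electrodes are required")
  stop_if_not(is.numeric(sampling_rate) && length(sampling_rate) == 1L &&
                sampling_rate > 0, "sampling_rate must be a positive scalar")
  if (is.null(channel_labels)) channel_labels <- paste0("E", seq_len(nrow(data)))
  stop_if_not(length(channel_labels) == nrow(data),
              "channel_labels length must equal the electrode count")
  if (reference_state == "average") {
    scale <- pmax(colSums(abs(data)), .Machine$double.eps)
    stop_if_not(all(abs(colSums(data)) <= 1e-9 * scale + 1e-12),
                "declared average reference but samples do not sum to 0")
  }
  structure(
    list(data = data, sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels),
         reference_state = reference_state),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, x$reference_state))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# ---- filtering helpers -----------------------------------------------------

# Apply a linear-phase FIR filter by FFT convolution with group-delay
# compensation (zero net phase). h must have odd length (type-I FIR).
fir_apply <- function(x, h) {
  n <- length(x)
  m <- length(h)
  delay <- (m - 1L) %/% 2L
  nf <- stats::nextn(n + m - 1L, 2L)
  X <- stats::fft(c(x, rep(0, nf - n)))
  H <- stats::fft(c(h, rep(0, nf - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nf
  y[(delay + 1L):(delay + n)]
}

# Band-pass an electrodes x samples matrix with a windowed-sinc FIR.
fir_bandpass <- function(data, fs, low, high, order = NULL) {
  if (is.null(order)) {
    # transition width ~ low/2 Hz governs the length; cap for tractability
    order <- min(4096L, max(64L, 2L * ceiling(3.3 * fs / low / 2) * 2L))
  }
  if (order %% 2L == 1L) order <- order + 1L          # even order -> odd taps
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  t(apply(data, 1L, fir_apply, h = as.numeric(h)))
}

#' Condition a raw EEG recording for microstate analysis
#'
#' Band-pass filters (zero-phase FIR), downsamples by an integer factor
#' (anti-alias FIR low-pass then decimation), and re-references to the
#' common average. Re-referencing is idempotent.
#'
#' @param rec An [eeg_recording].
#' @param band Length-2 numeric `(low, high)` pass band in Hz. Must satisfy
#'   `0 < low < high < target_rate / 2`.
#' @param target_rate Output sampling rate in Hz; must divide (or equal)
#'   the input rate.
#' @return An average-referenced [eeg_recording] at `target_rate` with
#'   `floor(n * target_rate / input_rate)` samples.
#' @examples
#' raw <- eeg_recording(matrix(rnorm(4 * 2560), 4), 256)
#' out <- preprocess_recording(raw, band = c(1, 40), target_rate = 128)
#' dim(out)
#' @export
preprocess_recording <- function(rec, band = c(1, 40),
                                 target_rate = rec$sampling_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  stop_if_not(length(band) == 2L && band[1] > 0 && band[1] < band[2],
              "band must be (low, high) with 0 < low < high")
  stop_if_not(band[2] < target_rate / 2,
              "band high edge must be below the Nyquist of target_rate")
  stop_if_not(target_rate <= fs, "target_rate must not exceed the input rate")
  m <- fs / target_rate
  stop_if_not(abs(m - round(m)) < 1e-9,
              "target_rate must divide the input sampling rate")
  m <- as.integer(round(m))

  x <- rec$data - rowMeans(rec$data)          # remove per-channel DC
  x <- fir_bandpass(x, fs, band[1], band[2])
  if (m > 1L) {
    # anti-alias low-pass at 80% of the new Nyquist before decimation
    h <- signal::fir1(64L, 0.8 / m)
    x <- t(apply(x, 1L, fir_apply, h = as.numeric(h)))
    n_out <- floor(ncol(rec$data) / m)
    x <- x[, seq(1L, by = m, length.out = n_out), drop = FALSE]
  }
  x <- average_reference(x)
  eeg_recording(x, target_rate, rec$channel_labels, reference_state = "average")
}

#' Global field power of an average-referenced recording
#'
#' GFP at each time point is the population (1/N) standard deviation of
#' the potential across all electrodes — for average-referenced data the
#' Euclidean norm of the sample divided by the square root of the
#' electrode count.
#'
#' @param rec An average-referenced [eeg_recording].
#' @return An object of class `gfp_series`: list with `values`
#'   (nonnegative, one per sample) and `sampling_rate`.
#' @examples
#' rec <- eeg_recording(rbind(c(1, 2), c(-1, -2)), 128,
#'                      reference_state = "average")
#' global_field_power(rec)$values
#' @export
global_field_power <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  stop_if_not(rec$reference_state == "average",
              "GFP requires an average-referenced recording")
  v <- sqrt(colSums(rec$data^2) / nrow(rec$data))
  structure(list(values = v, sampling_rate = rec$sampling_rate),
            class = "gfp_series")
}

# GFP of arbitrary (possibly non-average-referenced) column maps:
# population SD across electrodes per column.
gfp_of <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
}

#' Locate GFP peaks
#'
#' Returns the indices of strict local maxima of a GFP series: samples
#' whose value exceeds both neighbours. A flat plateau flanked by smaller
#' values contributes its first index. Endpoints are never peaks.
#'
#' @param gfp A `gfp_series` (from [global_field_power()]) or a numeric
#'   vector of length >= 3.
#' @return Integer vector of peak sample indices (possibly empty),
#'   strictly increasing.
#' @examples
#' gfp_peaks(c(0, 1, 0, 2, 0))
#' @export
gfp_peaks <- function(gfp) {
  v <- if (inherits(gfp, "gfp_series")) gfp$values else as.numeric(gfp)
  n <- length(v)
  stop_if_not(n >= 3L, "need at least 3 samples")
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L  # walk the plateau
      if (j < n && v[j + 1L] < v[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  peaks
}

# ---- text I/O --------------------------------------------------------------

#' Write / read a recording as delimited text plus a JSON sidecar
#'
#' The matrix (electrodes x samples) is written as TSV without headers;
#' sampling rate, channel labels, reference state and an optional
#' free-form `extra` list go to `<path>.json`.
#'
#' @param rec An [eeg_recording].
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @param extra Optional named list recorded verbatim in the sidecar
#'   (e.g. simulation seed and spec echo).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, extra = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               channel_labels = rec$channel_labels,
               reference_state = rec$reference_state)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  eeg_recording(x, meta$sampling_rate, meta$channel_labels,
                reference_state = meta$reference_state)
}
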