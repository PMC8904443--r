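#' Reference wall-motion signal by spatial averaging
#'
#' Averages the complex time series over the ROI voxels of one slice,
#' frame by frame. The result is the (unfiltered) reference wall-motion
#' signal; pass it through [highpass()] before spectral analysis so that
#' respiration does not dominate.
#'
#' @param slice_data complex (frame, row, col) array — see
#'   [series_slice()].
#' @param roi an [make_roi()] result (or any object with a binary
#'   \code{$mask}).
#' @param dt frame spacing (s).
#' @return An object of class \code{reference_signal}: complex vector of
#'   length n_frames with attributes \code{dt}, \code{filtered},
#'   \code{cutoff_hz}, \code{n_voxels}.
#' @export
spatial_average <- function(slice_data, roi, dt) {
  mask <- if (is.list(roi)) roi$mask else roi
  d <- dim(slice_data)
  if (length(d) != 3L || !identical(d[2:3], dim(mask)[1:2]))
    stop("slice data and ROI mask shapes disagree", call. = FALSE)
  idx <- which(mask == 1L)
  if (length(idx) == 0L) stop("empty ROI", call. = FALSE)
  flat <- matrix(slice_data, d[1], d[2] * d[3])
  sig <- rowMeans(flat[, idx, drop = FALSE])
  reference_signal(sig, dt = dt, n_voxels = length(idx))
}

#' Construct a reference signal from raw complex samples
#'
#' Mostly produced by [spatial_average()]; exported so externally derived
#' wall-motion signals can enter the pipeline.
#'
#' @param values complex vector of samples.
#' @param dt frame spacing (s).
#' @param filtered has the signal already been high-pass filtered?
#' @param cutoff_hz cutoff used, if filtered (Hz).
#' @param n_voxels ROI voxel count provenance.
#' @return A \code{reference_signal}.
#' @export
reference_signal <- function(values, dt, filtered = FALSE, cutoff_hz = NA_real_,
                             n_voxels = NA_integer_) {
  structure(as.complex(values), dt = dt, filtered = filtered,
            cutoff_hz = cutoff_hz, n_voxels = n_voxels,
            class = "reference_signal")
}

# Signed DFT bin frequencies (Hz) in R's fft() storage order.
fft_freqs <- function(n, dt) {
  k <- 0:(n - 1)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * dt)
}

#' Ideal high-pass filter for complex time series
#'
#' Zero-phase brick-wall filter in the DFT domain: every bin with
#' |frequency| < cutoff — including the zero-frequency (DC) bin — is set
#' to zero; all surviving bins pass unchanged. Exactly linear and
#' idempotent, and composes transparently with the spectral periodicity
#' index. Default cutoff 0.5 Hz separates adult free-breathing respiration
#' (~0.2-0.4 Hz) from resting cardiac frequencies (>= 0.7 Hz).
#'
#' @param signal a \code{reference_signal}, or a complex vector (then
#'   \code{dt} must be given).
#' @param cutoff_hz high-pass cutoff (Hz), 0 <= cutoff < Nyquist.
#' @param dt frame spacing (s), taken from the signal's attribute when
#'   absent.
#' @return Filtered \code{reference_signal} (attributes updated).
#' @export
highpass <- function(signal, cutoff_hz = 0.5, dt = attr(signal, "dt")) {
  if (is.null(dt)) stop("dt is required", call. = FALSE)
  n <- length(signal)
  nyq <- 1 / (2 * dt)
  if (cutoff_hz < 0 || cutoff_hz >= nyq)
    stop("cutoff must satisfy 0 <= cutoff < Nyquist = ", nyq, " Hz",
         call. = FALSE)
  sp <- stats::fft(as.complex(unclass(signal)))
  sp[abs(fft_freqs(n, dt)) < cutoff_hz] <- 0i
  out <- stats::fft(sp, inverse = TRUE) / n
  reference_signal(out, dt = dt, filtered = TRUE, cutoff_hz = cutoff_hz,
                   n_voxels = attr(signal, "n_voxels"))
}

# Same brick-wall mask applied to the columns of a complex matrix
# (frames x voxels); used by the correlation map.
highpass_matrix <- function(x, cutoff_hz, dt) {
  n <- nrow(x)
  keep <- abs(fft_freqs(n, dt)) >= cutoff_hz
  sp <- stats::mvfft(x)
  sp[!keep, ] <- 0i
  stats::mvfft(sp, inverse = TRUE) / n
}

#' @export
print.reference_signal <- function(x, ...) {
  cat("<reference_signal> T = ", length(x), ", dt = ",
      attr(x, "dt") * 1000, " ms",
      if (isTRUE(attr(x, "filtered")))
        paste0(", high-passed at ", attr(x, "cutoff_hz"), " Hz"),
      "\n", sep = "")
  invisible(x)
}

#' Export a reference signal to CSV
#'
#' Writes frame index (0-based), time (s), real and imaginary parts.
#'
#' @param signal a \code{reference_signal}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  dt <- attr(signal, "dt")
  df <- data.frame(frame = seq_along(signal) - 1L,
                   time_s = (seq_along(signal) - 1L) * dt,
                   real = Re(signal), imaginary = Im(signal))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
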