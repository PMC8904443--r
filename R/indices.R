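#' Frequency spectrum of a reference signal
#'
#' Unitary discrete Fourier transform (forward transform divided by
#' sqrt(T)) so that total spectral energy equals time-domain energy
#' (Parseval). Because the underlying image data are complex, the spectrum
#' is generally not conjugate symmetric: positive and negative frequencies
#' carry independent information and both enter the periodicity index.
#'
#' @param signal a \code{reference_signal} (length T >= 16).
#' @return Object of class \code{spectral_profile}: list with complex
#'   \code{values} and signed \code{freq_hz} (both in DFT storage order),
#'   \code{df_hz}, \code{dt}, and the \code{filtered}/\code{cutoff_hz}
#'   provenance of the input.
#' @export
spectrum_profile <- function(signal) {
  n <- length(signal)
  if (n < 16L) stop("signal must have at least 16 frames", call. = FALSE)
  dt <- attr(signal, "dt")
  if (is.null(dt)) stop("signal carries no dt", call. = FALSE)
  vals <- stats::fft(as.complex(unclass(signal))) / sqrt(n)
  structure(list(values = vals, freq_hz = fft_freqs(n, dt),
                 df_hz = 1 / (n * dt), dt = dt,
                 filtered = isTRUE(attr(signal, "filtered")),
                 cutoff_hz = attr(signal, "cutoff_hz")),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat("<spectral_profile> ", length(x$values), " bins, df = ",
      signif(x$df_hz, 4), " Hz",
      if (x$filtered) paste0(" (source high-passed at ", x$cutoff_hz, " Hz)"),
      "\n", sep = "")
  invisible(x)
}

#' Detect the cardiac frequency
#'
#' The dominant spectral peak of the reference wall-motion signal inside a
#' physiological search band. The peak is found on the paired power
#' |S(+f)|^2 + |S(-f)|^2 over positive in-band frequencies; ties break
#' toward the lower frequency. Default band 0.7-3.0 Hz (42-180 bpm) covers
#' resting and exercise heart rates.
#'
#' @param spec a \code{spectral_profile}.
#' @param band numeric length-2, search band in Hz, inside (0, Nyquist).
#' @return Object of class \code{cardiac_frequency}: list with \code{f_c}
#'   (Hz), \code{bin} (positive-frequency DFT index, 1-based), \code{band},
#'   \code{peak_power}.
#' @export
detect_cardiac_frequency <- function(spec, band = c(0.7, 3.0)) {
  stopifnot(inherits(spec, "spectral_profile"))
  nyq <- 1 / (2 * spec$dt)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("band must lie inside (0, Nyquist) with band[1] < band[2]",
         call. = FALSE)
  f <- spec$freq_hz
  pos <- which(f >= band[1] & f <= band[2] & f > 0)
  if (length(pos) == 0L)
    stop("search band contains no frequency bins", call. = FALSE)
  p <- paired_power(spec, f[pos])
  # lowest in-band frequency within floating-point reach of the maximum:
  # exact ties (equal-amplitude tones) must break toward low frequency
  best <- pos[which(p >= max(p) * (1 - 1e-12))[1]]
  structure(list(f_c = f[best], bin = best, band = band,
                 peak_power = max(p)),
            class = "cardiac_frequency")
}

# |S(+f)|^2 + |S(-f)|^2 for each requested positive frequency f.
paired_power <- function(spec, f_pos) {
  vapply(f_pos, function(fp) {
    i <- which(abs(spec$freq_hz - fp) < spec$df_hz / 2)
    j <- which(abs(spec$freq_hz + fp) < spec$df_hz / 2)
    sum(Mod(spec$values[i])^2) + sum(Mod(spec$values[j])^2)
  }, numeric(1))
}

#' @export
print.cardiac_frequency <- function(x, ...) {
  cat("<cardiac_frequency> f_c = ", signif(x$f_c, 5), " Hz (",
      signif(60 * x$f_c, 4), " bpm), band [", x$band[1], ", ", x$band[2],
      "] Hz\n", sep = "")
  invisible(x)
}

#' Temporal periodicity of the reference wall-motion signal
#'
#' Root-sum-square of the spectral components at the cardiac frequency
#' (both signs) over the root-sum-square of all components:
#' \deqn{TP = \sqrt{|S(f_c)|^2 + |S(-f_c)|^2} \Big/
#'   \sqrt{\sum_n |S(f_n)|^2 + |S(-f_n)|^2}}
#' A perfectly periodic signal concentrates all energy at the cardiac
#' bins and scores 1; heartbeat variability and contraction inconsistency
#' leak energy to other frequencies and lower the score. The value lies in
#' [0, 1] by Cauchy-Schwarz and is invariant to global scaling and phase
#' rotation of the signal.
#'
#' The signal must be high-pass filtered first (zeroed stop-band bins
#' contribute nothing to the denominator; in particular the DC bin, which
#' the paired sum would otherwise count twice, is exactly zero).
#'
#' @param spec \code{spectral_profile} of a filtered signal.
#' @param fc a \code{cardiac_frequency} (or frequency in Hz).
#' @param numerator_halfwidth integer k >= 0: widen the numerator to the
#'   f_c +/- k bins (both signs). Default 0 — exactly the single bin pair.
#' @return Periodicity in [0, 1].
#' @export
temporal_periodicity <- function(spec, fc, numerator_halfwidth = 0L) {
  stopifnot(inherits(spec, "spectral_profile"))
  if (!spec$filtered)
    stop("temporal periodicity is defined on a high-pass-filtered signal",
         call. = FALSE)
  f_c <- if (inherits(fc, "cardiac_frequency")) fc$f_c else as.numeric(fc)
  total <- sum(Mod(spec$values)^2)
  if (total == 0) stop("degenerate all-zero signal", call. = FALSE)
  k <- as.integer(numerator_halfwidth)
  f_num <- f_c + spec$df_hz * (-k:k)
  num <- sum(paired_power(spec, f_num[f_num > 0]))
  sqrt(num / total)
}

#' Voxelwise correlation map over the ventricular anatomy
#'
#' For every voxel inside the VA, the voxel's complex time series is
#' high-pass filtered with the same cutoff as the reference, then the
#' Pearson correlation coefficient with the reference signal is computed
#' on the complex samples (mean-subtracted cross-covariance over the
#' product of standard deviations). In \code{"modulus"} mode (default) the
#' map stores |r|, which lies in [0, 1] and is invariant to a per-voxel
#' phase rotation; \code{"signed"} mode stores Re(r) in [-1, 1].
#'
#' Voxels with zero temporal variance get r = 0 (they stay in the map so
#' the anatomy size M is preserved); their count is recorded.
#'
#' @param slice_data complex (frame, row, col) array.
#' @param ref a filtered \code{reference_signal}.
#' @param va a [make_va()] result.
#' @param mode \code{"modulus"} or \code{"signed"}.
#' @return Object of class \code{correlation_map}: list with \code{values}
#'   (numeric matrix, NA outside the VA), \code{va}, \code{mode},
#'   \code{n_zero_variance}.
#' @export
correlation_map <- function(slice_data, ref, va, mode = c("modulus", "signed")) {
  mode <- match.arg(mode)
  if (!isTRUE(attr(ref, "filtered")))
    stop("reference signal must be high-pass filtered", call. = FALSE)
  d <- dim(slice_data)
  if (length(d) != 3L || !identical(d[2:3], dim(va$mask)[1:2]))
    stop("series slice and VA mask shapes disagree", call. = FALSE)
  if (d[1] < 16L) stop("need at least 16 frames", call. = FALSE)
  idx <- which(va$mask == 1L)
  ts <- matrix(slice_data, d[1], d[2] * d[3])[, idx, drop = FALSE]
  ts <- highpass_matrix(ts, attr(ref, "cutoff_hz"), attr(ref, "dt"))

  r <- complex_pearson(ts, as.complex(unclass(ref)))
  zero_var <- attr(r, "zero_variance")
  vals <- if (mode == "modulus") Mod(r) else Re(r)

  map <- matrix(NA_real_, d[2], d[3])
  map[idx] <- vals
  structure(list(values = map, va = va, mode = mode,
                 n_zero_variance = zero_var),
            class = "correlation_map")
}

# Complex Pearson coefficient of each column of x against y:
# sum((x - xbar) * Conj(y - ybar)) / sqrt(sum|x - xbar|^2 * sum|y - ybar|^2).
# Zero-variance columns give 0 (count returned as attribute).
complex_pearson <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x), "-")
  yc <- y - mean(y)
  sy <- sum(Mod(yc)^2)
  sx <- colSums(Mod(xc)^2)
  num <- (t(Conj(xc)) %*% yc)[, 1]
  den <- sqrt(sx * sy)
  bad <- den == 0
  r <- complex(length(num))
  r[!bad] <- Conj(num[!bad]) / den[!bad]
  attr(r, "zero_variance") <- sum(bad)
  r
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map> M = ", x$va$M, " voxel(s), mode = ", x$mode,
      ", mean R = ", signif(mean(x$values[x$va$mask == 1L]), 4),
      if (x$n_zero_variance > 0)
        paste0(" (", x$n_zero_variance, " zero-variance voxel(s))"),
      "\n", sep = "")
  invisible(x)
}

#' Spatial coherence of wall motion
#'
#' Mean of the correlation map over the M voxels of the ventricular
#' anatomy: coherence is higher when more time series inside the anatomy
#' are temporally correlated with the reference wall-motion signal, i.e.
#' when wall motion spreads more widely.
#'
#' @param map a \code{correlation_map}.
#' @param va optional [make_va()] result (defaults to the map's own VA).
#' @return Mean correlation (in [0, 1] for modulus mode).
#' @export
spatial_coherence <- function(map, va = map$va) {
  if (va$M == 0L) stop("empty ventricular anatomy", call. = FALSE)
  mean(map$values[va$mask == 1L])
}

#' Full temporospatial characterization of one subject
#'
#' Runs the whole pipeline per slice and chamber: ROI (ED minus ES) →
#' spatial averaging → high-pass filtering → spectrum → cardiac-frequency
#' detection → temporal periodicity, and VA → correlation map → spatial
#' coherence. Slices whose ROI is empty for a chamber are skipped with a
#' recorded diagnostic; if every slice fails, characterization errors.
#'
#' Per-subject aggregation across slices is an ROI-voxel-weighted mean by
#' default (chambers weighted by their own slice ROI sizes), with
#' unweighted-mean and single-slice alternatives.
#'
#' @param series an \code{rt_series}.
#' @param masks a \code{mask_set} on the same grid.
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param band cardiac-frequency search band (Hz).
#' @param mode correlation mode, \code{"modulus"} or \code{"signed"}.
#' @param numerator_halfwidth see [temporal_periodicity()].
#' @param aggregate \code{"roi_weighted"}, \code{"mean"} or a single slice
#'   index.
#' @return Object of class \code{temporospatial_result}: list with
#'   \code{per_slice} (data.frame: slice, chamber, n_roi, f_c_hz,
#'   periodicity, coherence), \code{aggregated} (data.frame: chamber,
#'   periodicity, coherence), \code{params}, \code{skipped}.
#' @export
characterize_subject <- function(series, masks, cutoff_hz = 0.5,
                                 band = c(0.7, 3.0),
                                 mode = c("modulus", "signed"),
                                 numerator_halfwidth = 0L,
                                 aggregate = "roi_weighted") {
  mode <- match.arg(mode)
  d <- series_dim(series)
  rows <- vector("list", 2L * d[1])
  skipped <- character(0)
  k <- 0L
  for (s in seq_len(d[1])) {
    sl <- series_slice(series, s)
    va <- make_va(masks$lv_ed[s, , ], masks$rv_ed[s, , ])
    for (ch in c("lv", "rv")) {
      ed <- masks[[paste0(ch, "_ed")]][s, , ]
      es <- masks[[paste0(ch, "_es")]][s, , ]
      res <- tryCatch({
        roi <- make_roi(ed, es)
        ref <- highpass(spatial_average(sl, roi, series$dt), cutoff_hz)
        sp <- spectrum_profile(ref)
        fc <- detect_cardiac_frequency(sp, band)
        tp <- temporal_periodicity(sp, fc, numerator_halfwidth)
        cm <- correlation_map(sl, ref, va, mode)
        sc <- spatial_coherence(cm)
        data.frame(slice = s, chamber = toupper(ch), n_roi = roi$n_voxels,
                   f_c_hz = fc$f_c, periodicity = tp, coherence = sc)
      }, error = function(e) {
        skipped <<- c(skipped,
                      sprintf("slice %d %s: %s", s, toupper(ch),
                              conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) { k <- k + 1L; rows[[k]] <- res }
    }
  }
  per_slice <- do.call(rbind, rows[seq_len(k)])
  if (is.null(per_slice) || nrow(per_slice) == 0L)
    stop("all slices failed: ", paste(skipped, collapse = "; "),
         call. = FALSE)

  agg_one <- function(df) {
    w <- if (identical(aggregate, "roi_weighted")) df$n_roi
         else if (identical(aggregate, "mean")) rep(1, nrow(df))
         else { df <- df[df$slice == aggregate, , drop = FALSE]
                rep(1, nrow(df)) }
    data.frame(chamber = df$chamber[1],
               periodicity = sum(w * df$periodicity) / sum(w),
               coherence = sum(w * df$coherence) / sum(w),
               f_c_hz = sum(w * df$f_c_hz) / sum(w))
  }
  aggregated <- do.call(rbind, lapply(split(per_slice, per_slice$chamber),
                                      agg_one))
  rownames(aggregated) <- NULL
  structure(list(per_slice = per_slice, aggregated = aggregated,
                 params = list(cutoff_hz = cutoff_hz, band = band,
                               mode = mode,
                               numerator_halfwidth = numerator_halfwidth,
                               aggregate = aggregate),
                 skipped = skipped),
            class = "temporospatial_result")
}

#' @export
print.temporospatial_result <- function(x, ...) {
  cat("<temporospatial_result>\n")
  print(x$aggregated, row.names = FALSE)
  if (length(x$skipped))
    cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
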