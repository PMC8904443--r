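#' Phantom configuration for the synthetic beating heart
#'
#' Builds and validates the configuration of the synthetic real-time
#' short-axis cardiac MRI series. Defaults emulate the acquisition the
#' analysis is designed for: a ~7.7 s free-breathing window (384 frames at
#' 20 ms), several sequential heartbeats at a resting rate with mild RR
#' variability, respiratory amplitude modulation, and complex Gaussian
#' noise. Geometry is a left-ventricular disk and a smaller
#' right-ventricular disk per slice, each wrapped in a myocardial annulus.
#'
#' @param rows,cols image grid size in pixels.
#' @param n_slices number of short-axis slices.
#' @param pixel_mm in-plane pixel spacing (mm).
#' @param thickness_mm slice thickness (mm).
#' @param gap_mm inter-slice gap (mm).
#' @param dt frame spacing (s).
#' @param n_frames number of time frames (>= 16).
#' @param mean_hr mean heart rate (bpm), in (30, 220).
#' @param sigma_rr RR-interval jitter as a fraction of the mean interval.
#' @param systolic_fraction fraction of each cycle occupied by the
#'   contraction-relaxation pulse, in (0, 1].
#' @param lv_r_ed,lv_r_es LV end-diastolic / end-systolic endocardial
#'   radius (pixels); recycled across slices or given per slice.
#' @param rv_r_ed,rv_r_es RV radii (pixels), same convention.
#' @param wall_px epicardial wall thickness (pixels).
#' @param blood,myocardium,background compartment magnitudes (a.u.).
#' @param noise_sd standard deviation of the complex Gaussian noise added
#'   independently to the real and imaginary channel of every voxel.
#' @param a_resp respiratory amplitude-modulation fraction.
#' @param f_resp respiratory frequency (Hz).
#' @param desync_fraction fraction of myocardial angles (about each
#'   chamber centre) whose wall follows a delayed contraction waveform.
#' @param desync_lag_s delay (s) of the desynchronized wedge.
#' @param contraction_scale 0-1 scaling of the ED-to-ES excursion
#'   (1 = full excursion).
#' @param seed integer random seed; identical seed and config give
#'   bit-identical output.
#' @return An object of class \code{phantom_config} (a validated list).
#' @seealso [generate_series()], [phantom_preset()]
#' @export
phantom_config <- function(rows = 64L, cols = 64L, n_slices = 3L,
                           pixel_mm = 1.5, thickness_mm = 8, gap_mm = 2,
                           dt = 0.02, n_frames = 384L,
                           mean_hr = 72, sigma_rr = 0.03,
                           systolic_fraction = 0.35,
                           lv_r_ed = 12, lv_r_es = 7,
                           rv_r_ed = 9, rv_r_es = 6,
                           wall_px = 3,
                           blood = 100, myocardium = 40, background = 2,
                           noise_sd = 5,
                           a_resp = 0.1, f_resp = 0.25,
                           desync_fraction = 0, desync_lag_s = 0.3,
                           contraction_scale = 1,
                           seed = 1L) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              n_slices = as.integer(n_slices),
              pixel_mm = pixel_mm, thickness_mm = thickness_mm,
              gap_mm = gap_mm, dt = dt, n_frames = as.integer(n_frames),
              mean_hr = mean_hr, sigma_rr = sigma_rr,
              systolic_fraction = systolic_fraction,
              lv_r_ed = rep_len(lv_r_ed, n_slices),
              lv_r_es = rep_len(lv_r_es, n_slices),
              rv_r_ed = rep_len(rv_r_ed, n_slices),
              rv_r_es = rep_len(rv_r_es, n_slices),
              wall_px = wall_px,
              blood = blood, myocardium = myocardium,
              background = background, noise_sd = noise_sd,
              a_resp = a_resp, f_resp = f_resp,
              desync_fraction = desync_fraction,
              desync_lag_s = desync_lag_s,
              contraction_scale = contraction_scale,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$dt <= 0) stop("frame spacing dt must be positive", call. = FALSE)
  if (cfg$n_frames < 16L) stop("n_frames must be >= 16", call. = FALSE)
  if (cfg$mean_hr <= 30 || cfg$mean_hr >= 220)
    stop("mean_hr must lie in (30, 220) bpm", call. = FALSE)
  if (cfg$sigma_rr < 0) stop("sigma_rr must be >= 0", call. = FALSE)
  if (cfg$systolic_fraction <= 0 || cfg$systolic_fraction > 1)
    stop("systolic_fraction must lie in (0, 1]", call. = FALSE)
  if (any(cfg$lv_r_es >= cfg$lv_r_ed) || any(cfg$rv_r_es >= cfg$rv_r_ed))
    stop("ES radius must be strictly smaller than ED radius", call. = FALSE)
  if (cfg$desync_fraction < 0 || cfg$desync_fraction > 1)
    stop("desync_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$contraction_scale < 0 || cfg$contraction_scale > 1)
    stop("contraction_scale must lie in [0, 1]", call. = FALSE)
  # both chambers plus wall must fit inside the grid
  centres <- phantom_centres(cfg)
  half <- min(cfg$rows, cfg$cols) / 2
  reach_lv <- max(cfg$lv_r_ed) + cfg$wall_px
  reach_rv <- max(cfg$rv_r_ed) + cfg$wall_px
  if (reach_lv > centres$lv[1] || reach_lv > cfg$rows - centres$lv[1] ||
      reach_lv > centres$lv[2] || reach_lv > cfg$cols - centres$lv[2] ||
      reach_rv > centres$rv[2] || reach_rv > cfg$cols - centres$rv[2] ||
      reach_rv > centres$rv[1] || reach_rv > cfg$rows - centres$rv[1] ||
      reach_lv > half)
    stop("chamber geometry overflows the image grid", call. = FALSE)
  invisible(cfg)
}

# LV sits right of centre, RV left of centre (standard short-axis layout),
# 0-based voxel-centre coordinates.
phantom_centres <- function(cfg) {
  list(lv = c(cfg$rows / 2, cfg$cols * 0.62),
       rv = c(cfg$rows / 2, cfg$cols * 0.28))
}

#' Preset phantom configurations
#'
#' Two stated worlds used throughout the tests and demos: a healthy-like
#' heart (low RR jitter, full contraction, no regional desynchronization)
#' and a failing-heart-like one (high jitter, reduced excursion, a
#' desynchronized wedge). They produce the qualitative healthy-vs-HF
#' ordering of both indices without claiming any cohort's exact numbers.
#'
#' @param which `"healthy"` or `"hf"`.
#' @param ... overrides passed on to [phantom_config()] (e.g. `seed`,
#'   `rows`, `n_frames` for scaled-down simulation studies).
#' @return A \code{phantom_config}.
#' @export
phantom_preset <- function(which = c("healthy", "hf"), ...) {
  which <- match.arg(which)
  over <- list(...)
  base <- if (which == "healthy") {
    list(sigma_rr = 0.03, contraction_scale = 1, desync_fraction = 0)
  } else {
    list(sigma_rr = 0.12, contraction_scale = 0.6, desync_fraction = 0.3)
  }
  do.call(phantom_config, utils::modifyList(base, over))
}

#' Generate a pseudo-periodic RR-interval schedule
#'
#' Each interval is `(60/mean_hr) * (1 + sigma_rr * e)` with `e` standard
#' normal, truncated below at 0.3 of the mean interval so no beat becomes
#' non-physically short. Intervals are appended until they cover at least
#' `duration` seconds.
#'
#' @param mean_hr mean heart rate (bpm), in (30, 220).
#' @param sigma_rr jitter fraction (>= 0).
#' @param duration time to cover (s).
#' @param seed optional integer seed (set before drawing).
#' @return Numeric vector of RR intervals (s) whose sum is >= `duration`.
#' @export
generate_rr_schedule <- function(mean_hr, sigma_rr, duration, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive", call. = FALSE)
  if (!is.numeric(mean_hr) || mean_hr <= 30 || mean_hr >= 220)
    stop("mean_hr must lie in (30, 220) bpm", call. = FALSE)
  if (sigma_rr < 0) stop("sigma_rr must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mean_rr <- 60 / mean_hr
  floor_rr <- 0.3 * mean_rr
  rr <- numeric(0)
  total <- 0
  while (total <= duration) {
    iv <- mean_rr * (1 + sigma_rr * stats::rnorm(1))
    iv <- max(iv, floor_rr)
    rr <- c(rr, iv)
    total <- total + iv
  }
  rr
}

# Raised-cosine contraction pulse on intra-beat phase phi in [0, 1):
# 0 outside the systolic fraction, rising to 1 (end-systole) at the pulse
# midpoint and back to 0, C1-smooth.
contraction_pulse <- function(phi, systolic_fraction) {
  out <- numeric(length(phi))
  inside <- phi >= 0 & phi < systolic_fraction
  out[inside] <- 0.5 * (1 - cos(2 * pi * phi[inside] / systolic_fraction))
  out
}

# Map absolute times (s) to intra-beat phase given an RR schedule.
# Times beyond the schedule wrap into the last interval's rate.
beat_phase <- function(times, rr) {
  edges <- c(0, cumsum(rr))
  idx <- findInterval(times, edges, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > length(rr)] <- length(rr)
  (times - edges[idx]) / rr[idx]
}

#' Generate a synthetic real-time cardiac MRI series
#'
#' Renders the full complex 4-D series (slice, frame, row, col), the
#' end-diastolic and end-systolic endocardial masks per chamber and slice,
#' and the ground truth (realized RR schedule, per-frame radii, desync
#' voxel labels, noiseless series).
#'
#' Per frame, each chamber's endocardial radius follows
#' `r(t) = r_ED - (r_ED - r_ES) * s * c(phi(t))` with `c` the raised-cosine
#' systolic pulse, `phi` the intra-beat phase from the RR schedule and `s`
#' the contraction scale. Voxels in the desynchronized wedge follow the
#' same waveform delayed by `desync_lag_s`. Whole-frame amplitude is scaled
#' by `1 + a_resp * sin(2 pi f_resp t)`; complex Gaussian noise is added
#' last. The complex phase is constant per tissue compartment with a small
#' smooth in-plane ramp, so spectra are genuinely non-conjugate-symmetric.
#'
#' @param cfg A [phantom_config()].
#' @return A list with components \code{series} (class \code{rt_series}),
#'   \code{masks} (class \code{mask_set}) and \code{truth} (class
#'   \code{phantom_truth}).
#' @export
generate_series <- function(cfg) {
  validate_phantom_config(cfg)
  set.seed(cfg$seed)

  n_t <- cfg$n_frames
  times <- (seq_len(n_t) - 1L) * cfg$dt
  duration <- n_t * cfg$dt
  rr <- generate_rr_schedule(cfg$mean_hr, cfg$sigma_rr, duration)
  phi <- beat_phase(times, rr)
  pulse <- contraction_pulse(phi, cfg$systolic_fraction)
  phi_lag <- beat_phase(pmax(times - cfg$desync_lag_s, 0), rr)
  pulse_lag <- contraction_pulse(phi_lag, cfg$systolic_fraction)
  resp <- 1 + cfg$a_resp * sin(2 * pi * cfg$f_resp * times)

  centres <- phantom_centres(cfg)
  # 0-based voxel-centre coordinates
  rowc <- matrix(rep(0:(cfg$rows - 1L), cfg$cols), cfg$rows, cfg$cols)
  colc <- matrix(rep(0:(cfg$cols - 1L), each = cfg$rows), cfg$rows, cfg$cols)
  d_lv <- sqrt((rowc - centres$lv[1])^2 + (colc - centres$lv[2])^2)
  d_rv <- sqrt((rowc - centres$rv[1])^2 + (colc - centres$rv[2])^2)
  ang_lv <- atan2(colc - centres$lv[2], rowc - centres$lv[1]) + pi  # [0, 2pi)
  ang_rv <- atan2(colc - centres$rv[2], rowc - centres$rv[1]) + pi

  # smooth in-plane phase ramp (radians) plus per-compartment offsets
  ramp <- 0.3 * (rowc / cfg$rows + colc / cfg$cols)
  ph_blood <- 0.4; ph_myo <- 1.1; ph_bg <- 0

  dims <- c(cfg$n_slices, n_t, cfg$rows, cfg$cols)
  clean <- array(complex(real = 0), dims)
  lv_ed <- rv_ed <- lv_es <- rv_es <-
    array(0L, c(cfg$n_slices, cfg$rows, cfg$cols))
  radii <- array(NA_real_, c(cfg$n_slices, n_t, 2),
                 dimnames = list(NULL, NULL, c("lv", "rv")))
  desync_labels <- vector("list", cfg$n_slices)

  wedge_lv <- ang_lv < 2 * pi * cfg$desync_fraction
  wedge_rv <- ang_rv < 2 * pi * cfg$desync_fraction

  for (s in seq_len(cfg$n_slices)) {
    r_lv_t <- cfg$lv_r_ed[s] - (cfg$lv_r_ed[s] - cfg$lv_r_es[s]) *
      cfg$contraction_scale * pulse
    r_rv_t <- cfg$rv_r_ed[s] - (cfg$rv_r_ed[s] - cfg$rv_r_es[s]) *
      cfg$contraction_scale * pulse
    r_lv_lag <- cfg$lv_r_ed[s] - (cfg$lv_r_ed[s] - cfg$lv_r_es[s]) *
      cfg$contraction_scale * pulse_lag
    r_rv_lag <- cfg$rv_r_ed[s] - (cfg$rv_r_ed[s] - cfg$rv_r_es[s]) *
      cfg$contraction_scale * pulse_lag
    radii[s, , "lv"] <- r_lv_t
    radii[s, , "rv"] <- r_rv_t

    lv_ed[s, , ] <- (d_lv <= cfg$lv_r_ed[s]) * 1L
    rv_ed[s, , ] <- (d_rv <= cfg$rv_r_ed[s]) * 1L
    r_lv_min <- cfg$lv_r_ed[s] - (cfg$lv_r_ed[s] - cfg$lv_r_es[s]) *
      cfg$contraction_scale
    r_rv_min <- cfg$rv_r_ed[s] - (cfg$rv_r_ed[s] - cfg$rv_r_es[s]) *
      cfg$contraction_scale
    lv_es[s, , ] <- (d_lv <= r_lv_min) * 1L
    rv_es[s, , ] <- (d_rv <= r_rv_min) * 1L

    myo_ed <- (d_lv <= cfg$lv_r_ed[s] + cfg$wall_px & d_lv > r_lv_min) |
      (d_rv <= cfg$rv_r_ed[s] + cfg$wall_px & d_rv > r_rv_min)
    lab <- which(myo_ed & (wedge_lv | wedge_rv))
    desync_labels[[s]] <- lab

    # vectorized rendering: voxels x frames matrices, column-major voxel
    # order matching which()/matrix indexing above
    n_px <- cfg$rows * cfg$cols
    rl <- matrix(r_lv_t, n_px, n_t, byrow = TRUE)
    rr_m <- matrix(r_rv_t, n_px, n_t, byrow = TRUE)
    if (length(lab)) {
      rl[lab, ] <- matrix(r_lv_lag, length(lab), n_t, byrow = TRUE)
      rr_m[lab, ] <- matrix(r_rv_lag, length(lab), n_t, byrow = TRUE)
    }
    dlv <- as.vector(d_lv); drv <- as.vector(d_rv)
    blood_m <- dlv <= rl | drv <= rr_m
    myo_m <- !blood_m & (dlv <= rl + cfg$wall_px | drv <= rr_m + cfg$wall_px)
    mag <- cfg$background + myo_m * (cfg$myocardium - cfg$background) +
      blood_m * (cfg$blood - cfg$background)
    ph <- ph_bg + myo_m * (ph_myo - ph_bg) + blood_m * (ph_blood - ph_bg) +
      as.vector(ramp)
    cx <- mag * exp(1i * ph) * rep(resp, each = n_px)
    clean[s, , , ] <- array(t(cx), c(n_t, cfg$rows, cfg$cols))
  }

  noisy <- clean
  if (cfg$noise_sd > 0) {
    n <- prod(dims)
    noisy <- clean + array(complex(real = stats::rnorm(n, 0, cfg$noise_sd),
                                   imaginary = stats::rnorm(n, 0, cfg$noise_sd)),
                           dims)
  }

  series <- rt_series(noisy, dt = cfg$dt, pixel_mm = cfg$pixel_mm,
                      thickness_mm = cfg$thickness_mm, gap_mm = cfg$gap_mm)
  masks <- mask_set(lv_ed = lv_ed, lv_es = lv_es,
                    rv_ed = rv_ed, rv_es = rv_es,
                    pixel_mm = cfg$pixel_mm, thickness_mm = cfg$thickness_mm,
                    gap_mm = cfg$gap_mm)

  # ED frames: intra-beat phase ~0 (pulse minimum); ES frames: pulse maximum
  beat_idx <- findInterval(times, c(0, cumsum(rr)))
  ed_frames <- vapply(split(seq_len(n_t), beat_idx),
                      function(ix) ix[which.min(pulse[ix])], integer(1))
  es_frames <- vapply(split(seq_len(n_t), beat_idx),
                      function(ix) ix[which.max(pulse[ix])], integer(1))

  truth <- structure(list(rr = rr, cardiac_freq_hz = cfg$mean_hr / 60,
                          radii = radii,
                          ed_frames = unname(ed_frames),
                          es_frames = unname(es_frames),
                          desync_labels = desync_labels,
                          clean = clean, config = cfg),
                     class = "phantom_truth")
  list(series = series, masks = masks, truth = truth)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config> ", x$rows, "x", x$cols, " px, ", x$n_slices,
      " slice(s), ", x$n_frames, " frames @ ", x$dt * 1000, " ms\n",
      "  HR ", x$mean_hr, " bpm (sigma_RR ", x$sigma_rr, "), contraction ",
      x$contraction_scale, ", desync ", x$desync_fraction, "\n", sep = "")
  invisible(x)
}
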