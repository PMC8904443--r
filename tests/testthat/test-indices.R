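filtered_sig <- function(values, dt, cutoff = 0.5)
  highpass(reference_signal(values, dt), cutoff)

test_that("spectrum: DC concentration, one-sided tones, Parseval", {
  dt <- 0.05; t_n <- 64L
  cst <- reference_signal(rep(2 - 1i, t_n), dt)
  sp <- spectrum_profile(cst)
  expect_equal(sum(Mod(sp$values[sp$freq_hz != 0])^2), 0)
  expect_gt(Mod(sp$values[sp$freq_hz == 0]), 0)
  # complex exponential puts all energy in bin +k, none in -k
  k <- 5
  tone <- reference_signal(exp(2i * pi * k * (0:(t_n - 1)) / t_n), dt)
  spt <- spectrum_profile(tone)
  fk <- k / (t_n * dt)
  expect_equal(sum(Mod(spt$values[abs(spt$freq_hz - fk) < 1e-9])^2),
               sum(Mod(unclass(tone))^2))  # all time-domain energy at +k
  expect_equal(sum(Mod(spt$values[abs(spt$freq_hz + fk) < 1e-9])^2), 0)
  # Parseval under the unitary convention, against a direct sum
  set.seed(4)
  x <- complex(real = rnorm(t_n), imaginary = rnorm(t_n))
  spx <- spectrum_profile(reference_signal(x, dt))
  expect_equal(sum(Mod(spx$values)^2), sum(Mod(x)^2), tolerance = 1e-10)
  expect_equal(spx$values, dft_direct(x), tolerance = 1e-10)
  expect_error(spectrum_profile(reference_signal(x[1:8], dt)), "16")
})

test_that("cardiac frequency detection: on-bin tones, dominance, ties, errors", {
  dt <- 0.025; t_n <- 320L  # 8 s window, df = 0.125 Hz
  tt <- (0:(t_n - 1)) * dt
  tone <- filtered_sig(exp(2i * pi * 1.25 * tt), dt)
  fc <- detect_cardiac_frequency(spectrum_profile(tone))
  expect_equal(fc$f_c, 1.25)
  # dominant of two tones wins
  two <- filtered_sig(2 * exp(2i * pi * 1 * tt) + exp(2i * pi * 2 * tt), dt)
  expect_equal(detect_cardiac_frequency(spectrum_profile(two))$f_c, 1)
  # exact tie breaks toward the lower frequency
  tie <- filtered_sig(exp(2i * pi * 1 * tt) + exp(2i * pi * 2 * tt), dt)
  expect_equal(detect_cardiac_frequency(spectrum_profile(tie))$f_c, 1)
  sp <- spectrum_profile(tone)
  expect_error(detect_cardiac_frequency(sp, band = c(30, 40)), "band")
  expect_error(detect_cardiac_frequency(sp, band = c(1.01, 1.02)),
               "no frequency bins")
})

test_that("cardiac frequency on a jittered phantom is within one bin of truth", {
  cfg <- small_config(mean_hr = 72, sigma_rr = 0.05, seed = 21)
  ph <- generate_series(cfg)
  roi <- make_roi(ph$masks$lv_ed[1, , ], ph$masks$lv_es[1, , ])
  ref <- highpass(spatial_average(series_slice(ph$series, 1), roi, cfg$dt), 0.5)
  sp <- spectrum_profile(ref)
  fc <- detect_cardiac_frequency(sp)
  expect_lt(abs(fc$f_c - 1.2), sp$df_hz + 1e-12)
})

test_that("temporal periodicity: pure tone 1, two equal tones 1/sqrt(2)", {
  dt <- 0.025; t_n <- 320L; tt <- (0:(t_n - 1)) * dt
  tone <- filtered_sig(exp(2i * pi * 1.25 * tt), dt)
  sp <- spectrum_profile(tone)
  fc <- detect_cardiac_frequency(sp)
  expect_equal(temporal_periodicity(sp, fc), 1, tolerance = 1e-10)
  two <- filtered_sig(exp(2i * pi * 1 * tt) + exp(2i * pi * 2.25 * tt), dt)
  sp2 <- spectrum_profile(two)
  fc2 <- detect_cardiac_frequency(sp2)
  expect_equal(temporal_periodicity(sp2, fc2), 1 / sqrt(2), tolerance = 1e-10)
  # unfiltered spectra are rejected; all-zero signals are degenerate
  raw <- spectrum_profile(reference_signal(exp(2i * pi * tt), dt))
  expect_error(temporal_periodicity(raw, 1), "filtered")
  zero <- filtered_sig(rep(0 + 0i, t_n), dt)
  expect_error(temporal_periodicity(spectrum_profile(zero), 1), "degenerate")
})

test_that("periodicity equals the direct-DFT evaluation on a preset phantom", {
  cfg <- small_preset("healthy", seed = 1)
  ph <- generate_series(cfg)
  roi <- make_roi(ph$masks$lv_ed[1, , ], ph$masks$lv_es[1, , ])
  ref <- highpass(spatial_average(series_slice(ph$series, 1), roi, cfg$dt), 0.5)
  sp <- spectrum_profile(ref)
  tp <- temporal_periodicity(sp, detect_cardiac_frequency(sp))
  expect_equal(tp, periodicity_direct(unclass(ref), cfg$dt),
               tolerance = 1e-10)
})

test_that("periodicity is bounded and invariant to global scale and phase", {
  set.seed(12)
  dt <- 0.02
  for (i in 1:10) {
    x <- complex(real = rnorm(128), imaginary = rnorm(128))
    f <- filtered_sig(x, dt)
    sp <- spectrum_profile(f)
    fc <- detect_cardiac_frequency(sp)
    tp <- temporal_periodicity(sp, fc)
    expect_gte(tp, 0); expect_lte(tp, 1)
    g <- reference_signal(3.7 * exp(1i * 1.1) * unclass(f), dt,
                          filtered = TRUE, cutoff_hz = 0.5)
    tp2 <- temporal_periodicity(spectrum_profile(g), fc)
    expect_equal(tp, tp2, tolerance = 1e-12)
  }
})

test_that("numerator widening includes neighbouring bin pairs", {
  dt <- 0.025; t_n <- 320L; tt <- (0:(t_n - 1)) * dt
  df <- 1 / (t_n * dt)
  x <- filtered_sig(exp(2i * pi * 1.25 * tt) + 0.5 * exp(2i * pi * (1.25 + df) * tt), dt)
  sp <- spectrum_profile(x)
  fc <- detect_cardiac_frequency(sp)
  expect_lt(temporal_periodicity(sp, fc), 1)
  expect_equal(temporal_periodicity(sp, fc, numerator_halfwidth = 1L), 1,
               tolerance = 1e-10)
})

test_that("correlation map: perfect linear relation and phase invariance", {
  dt <- 0.02; t_n <- 64L
  set.seed(3)
  ref <- filtered_sig(complex(real = rnorm(t_n), imaginary = rnorm(t_n)), dt)
  va <- make_va(matrix(1L, 4, 4), matrix(0L, 4, 4))
  # every voxel = 2 x reference
  sl <- array(0i, c(t_n, 4, 4))
  for (r in 1:4) for (c in 1:4) sl[, r, c] <- 2 * unclass(ref)
  cm <- correlation_map(sl, ref, va)
  expect_equal(unname(cm$values[va$mask == 1L]), rep(1, 16),
               tolerance = 1e-10)
  expect_equal(spatial_coherence(cm), 1, tolerance = 1e-10)
  # global phase rotation leaves modulus-mode R at 1
  for (r in 1:4) for (c in 1:4) sl[, r, c] <- exp(1i * 0.8) * unclass(ref)
  cm2 <- correlation_map(sl, ref, va)
  expect_equal(unname(cm2$values[va$mask == 1L]), rep(1, 16),
               tolerance = 1e-10)
  # signed mode sees the rotation
  cm3 <- correlation_map(sl, ref, va, mode = "signed")
  expect_equal(unname(cm3$values[1, 1]), cos(0.8), tolerance = 1e-10)
  # zero-variance voxels: R = 0, flagged
  sl[, 1, 1] <- 5 + 5i
  cm4 <- correlation_map(sl, ref, va)
  expect_equal(unname(cm4$values[1, 1]), 0)
  expect_equal(cm4$n_zero_variance, 1L)
})

test_that("correlation map equals the per-voxel loop oracle on a phantom", {
  cfg <- tiny_config(seed = 6, desync_fraction = 0.3)
  ph <- generate_series(cfg)
  sl <- series_slice(ph$series, 1)
  roi <- make_roi(ph$masks$lv_ed[1, , ], ph$masks$lv_es[1, , ])
  ref <- highpass(spatial_average(sl, roi, cfg$dt), 0.5)
  va <- make_va(ph$masks$lv_ed[1, , ], ph$masks$rv_ed[1, , ])
  for (mode in c("modulus", "signed")) {
    cm <- correlation_map(sl, ref, va, mode = mode)
    oracle <- pearson_loop_map(sl, unclass(ref), va$mask, 0.5, cfg$dt, mode)
    expect_equal(cm$values, oracle, tolerance = 1e-10)
  }
})

test_that("null correlation level matches a Monte-Carlo oracle", {
  dt <- 0.02; t_n <- 384L; cutoff <- 0.5
  set.seed(99)
  ref <- filtered_sig(complex(real = rnorm(t_n), imaginary = rnorm(t_n)),
                      dt, cutoff)
  n_vox <- 400L
  sl <- array(complex(real = rnorm(t_n * n_vox),
                      imaginary = rnorm(t_n * n_vox)),
              c(t_n, 20, 20))
  va <- make_va(matrix(1L, 20, 20), matrix(0L, 20, 20))
  cm <- correlation_map(sl, ref, va)
  observed <- mean(cm$values)

  # oracle: 10,000 independent draws through an independently coded
  # filter + direct-sum correlation against freshly drawn references
  n_mc <- 10000L
  y <- highpass_direct(complex(real = rnorm(t_n), imaginary = rnorm(t_n)),
                       cutoff, dt)
  yc <- y - mean(y)
  draws <- vapply(seq_len(n_mc), function(i) {
    x <- highpass_direct(complex(real = rnorm(t_n), imaginary = rnorm(t_n)),
                         cutoff, dt)
    xc <- x - mean(x)
    Mod(sum(xc * Conj(yc)) /
          sqrt(sum(Mod(xc)^2) * sum(Mod(yc)^2)))
  }, numeric(1))
  se <- sd(draws) / sqrt(n_vox)  # observed mean uses n_vox voxels
  expect_lt(abs(observed - mean(draws)), 3 * se + 3 * sd(draws) / sqrt(n_mc))
})

test_that("spatial coherence is the arithmetic mean over the anatomy", {
  va <- make_va(matrix(1L, 2, 5), matrix(0L, 2, 5))
  vals <- matrix(c(rep(1, 5), rep(0, 5)), 2, 5, byrow = TRUE)
  cm <- structure(list(values = vals, va = va, mode = "modulus",
                       n_zero_variance = 0L), class = "correlation_map")
  expect_equal(spatial_coherence(cm), 0.5)
  cm$values[] <- 1
  expect_equal(spatial_coherence(cm), 1)
  # loop-oracle equality on an HF-preset phantom slice
  cfg <- small_preset("hf", seed = 1)
  ph <- generate_series(cfg)
  sl <- series_slice(ph$series, 1)
  roi <- make_roi(ph$masks$lv_ed[1, , ], ph$masks$lv_es[1, , ])
  ref <- highpass(spatial_average(sl, roi, cfg$dt), 0.5)
  va2 <- make_va(ph$masks$lv_ed[1, , ], ph$masks$rv_ed[1, , ])
  cm2 <- correlation_map(sl, ref, va2)
  acc <- 0
  for (r in 1:48) for (c in 1:48)
    if (va2$mask[r, c] == 1L) acc <- acc + cm2$values[r, c]
  expect_equal(spatial_coherence(cm2), acc / va2$M, tolerance = 1e-12)
})

test_that("characterize_subject: aggregation identity and rules", {
  cfg <- tiny_config(seed = 14)
  ph <- generate_series(cfg)
  res <- characterize_subject(ph$series, ph$masks)
  expect_equal(nrow(res$per_slice), 2L)  # one slice, two chambers
  expect_equal(res$aggregated$periodicity,
               res$per_slice$periodicity[order(res$per_slice$chamber)])
  # multi-slice: aggregate lies between per-slice min and max
  cfg3 <- tiny_config(n_slices = 3L, seed = 14,
                      lv_r_ed = c(5, 4.5, 4), lv_r_es = c(3, 2.7, 2.4),
                      rv_r_ed = c(4, 3.6, 3.2), rv_r_es = c(2.5, 2.2, 2))
  ph3 <- generate_series(cfg3)
  res3 <- characterize_subject(ph3$series, ph3$masks)
  for (ch in c("LV", "RV")) {
    per <- res3$per_slice[res3$per_slice$chamber == ch, ]
    agg <- res3$aggregated[res3$aggregated$chamber == ch, ]
    expect_gte(agg$periodicity, min(per$periodicity) - 1e-12)
    expect_lte(agg$periodicity, max(per$periodicity) + 1e-12)
    # roi-weighted mean is what it says
    expect_equal(agg$coherence,
                 sum(per$n_roi * per$coherence) / sum(per$n_roi))
  }
  # unweighted and single-slice rules
  resm <- characterize_subject(ph3$series, ph3$masks, aggregate = "mean")
  per <- resm$per_slice[resm$per_slice$chamber == "LV", ]
  expect_equal(resm$aggregated$periodicity[resm$aggregated$chamber == "LV"],
               mean(per$periodicity))
  res1 <- characterize_subject(ph3$series, ph3$masks, aggregate = 2)
  expect_equal(res1$aggregated$periodicity[res1$aggregated$chamber == "LV"],
               res3$per_slice$periodicity[res3$per_slice$slice == 2 &
                                            res3$per_slice$chamber == "LV"])
})

test_that("near-ideal phantom: high periodicity, oracle-checked coherence", {
  # sinusoidal wall motion (systolic fraction 1), near-total sweep,
  # noiseless, jitter-free, respiration-free, integer cycles (8 in 8 s)
  cfg <- small_config(n_frames = 400L, dt = 0.02, mean_hr = 60, sigma_rr = 0,
                      noise_sd = 0, a_resp = 0, systolic_fraction = 1,
                      lv_r_es = 2, rv_r_es = 1.5)
  ph <- generate_series(cfg)
  res <- characterize_subject(ph$series, ph$masks)
  expect_true(all(res$aggregated$periodicity >= 0.95))
  expect_equal(res$aggregated$f_c_hz, c(1, 1))
  # coherence equals the loop oracle; its level is bounded by the static
  # blood-pool core, not by 1 (see methods vignette)
  sl <- series_slice(ph$series, 1)
  roi <- make_roi(ph$masks$lv_ed[1, , ], ph$masks$lv_es[1, , ])
  ref <- highpass(spatial_average(sl, roi, cfg$dt), 0.5)
  va <- make_va(ph$masks$lv_ed[1, , ], ph$masks$rv_ed[1, , ])
  cm <- correlation_map(sl, ref, va)
  oracle <- pearson_loop_map(sl, unclass(ref), va$mask, 0.5, cfg$dt)
  expect_equal(cm$values, oracle, tolerance = 1e-10)
  expect_gte(spatial_coherence(cm), 0.8)
})

test_that("healthy preset scores above HF preset at matched seeds", {
  tp <- matrix(NA_real_, 6, 2, dimnames = list(NULL, c("healthy", "hf")))
  sc <- tp
  for (s in 1:6) {
    for (w in c("healthy", "hf")) {
      ph <- generate_series(small_preset(w, seed = 100 + s))
      ag <- characterize_subject(ph$series, ph$masks)$aggregated
      tp[s, w] <- mean(ag$periodicity); sc[s, w] <- mean(ag$coherence)
    }
  }
  expect_gt(mean(tp[, "healthy"]), mean(tp[, "hf"]))
  expect_gt(mean(sc[, "healthy"]), mean(sc[, "hf"]))
})
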