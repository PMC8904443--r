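# wallmotion

Temporospatial characterization of left- and right-ventricular wall motion
from real-time (ungated, free-breathing) short-axis cardiac MRI.

Real-time acquisitions record a complex image series across several
sequential heartbeats instead of one ECG-gated virtual cycle. Beyond the
standard volumetric indices (EDV, ESV, SV, EF), such series expose *how*
the ventricle moves over time and space. `wallmotion` computes two indices
per chamber from the complex series and ED/ES endocardial segmentations:

* **Temporal periodicity** — the fraction of spectral energy of the
  high-pass-filtered reference wall-motion signal concentrated at the
  cardiac frequency,

  ```
  TP = sqrt(|S(f_c)|^2 + |S(-f_c)|^2) / sqrt(sum_n |S(f_n)|^2 + |S(-f_n)|^2)
  ```

  where `S` is the DFT of the ROI-averaged complex signal (the ROI is the
  ED-minus-ES annulus the moving wall sweeps) and `f_c` the dominant
  in-band spectral peak. Positive and negative frequencies enter
  separately because complex image data have non-conjugate-symmetric
  spectra. TP is in [0, 1]; heartbeat variability and contraction
  inconsistency leak energy away from `f_c` and lower it.

* **Spatial coherence** — the mean, over the ventricular anatomy
  `VA = LV_ED ∪ RV_ED` (M voxels), of the per-voxel Pearson correlation
  `R(x, y)` between each (filtered) voxel time series and the reference:

  ```
  SC = (1/M) * sum_{(x,y) in VA} R(x, y)
  ```

  In the default modulus mode `R = |r|` on complex samples, so SC is in
  [0, 1]; it is higher the more widely wall motion spreads over the
  anatomy.

The package also provides a synthetic beating-heart phantom (ground-truth
masks, RR schedules, respiration, noise, regional desynchronization),
method-of-slices volumetrics, SNR/CNR image-quality metrics, a statistics
layer (Anderson–Darling normality, one-tailed Welch t, index
cross-correlation, exact 2-D linear-separability checks), minimal NIfTI-1
I/O and a CLI. See the methods vignette
(`vignettes/wallmotion-methods.Rmd`) for the model, parameter rationale
and known limitations.

## Worked example

```r
library(wallmotion)

ph  <- generate_series(phantom_config(seed = 1))   # healthy defaults
res <- characterize_subject(ph$series, ph$masks)
res
#> <temporospatial_result>
#>  chamber periodicity coherence   f_c_hz
#>       LV   0.6908828 0.5374452 1.171875
#>       RV   0.6961549 0.5349437 1.171875

volumetric_indices(ph$masks)
#>   chamber edv_ml esv_ml sv_ml   ef_pct
#> 1      LV 30.375 10.395 19.98 65.77778
#> 2      RV 16.875  7.425  9.45 56.00000

hf <- generate_series(phantom_preset("hf", seed = 1))
characterize_subject(hf$series, hf$masks)$aggregated
#>   chamber periodicity coherence   f_c_hz
#> 1      LV   0.5746295 0.2136581 1.171875
#> 2      RV   0.6215315 0.1909059 1.171875
```

Reading the output: the detected cardiac frequency 1.17 Hz is within one
DFT bin (0.13 Hz at 384 frames x 20 ms) of the configured 72 bpm
(1.2 Hz). The failing-heart preset (more RR jitter, weaker contraction,
a desynchronized wall sector) scores lower on both indices — periodicity
0.57 vs 0.69 and coherence 0.21 vs 0.54 for the LV — the qualitative
ordering the indices are designed to detect. (The phantom chambers are
small disks, so the volumes are not adult-scale; EF is in the normal
range by construction.)

Cohort-level use:

```r
cfg <- run_config(n_per_group = 12, seed = 1)
res <- run_pipeline(cfg, "out/")   # cohort.csv, summaries, Welch tests,
                                   # scatter data, run_meta.json
```

A CLI wrapping the same pipeline is installed at
`system.file("cli", "wallmotion", package = "wallmotion")` with
subcommands `simulate`, `roi`, `characterize`, `volumetrics`, `compare`,
`run`.

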