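# Scaled-down phantom geometries that keep the suite inside its time
# budget. Only sizes are reduced; preset physiology (sigma_RR, contraction
# scale, desync fraction) is never touched here.

small_args <- function(...) {
  utils::modifyList(
    list(rows = 48L, cols = 48L, n_slices = 1L, n_frames = 256L,
         lv_r_ed = 9, lv_r_es = 5.5, rv_r_ed = 7, rv_r_es = 4.5,
         wall_px = 2.5),
    list(...))
}

small_config <- function(...) do.call(phantom_config, small_args(...))

small_preset <- function(which, ...)
  do.call(phantom_preset, c(list(which = which), small_args(...)))

tiny_args <- function(...) {
  utils::modifyList(
    list(rows = 28L, cols = 28L, n_slices = 1L, n_frames = 64L, dt = 0.05,
         lv_r_ed = 5, lv_r_es = 3, rv_r_ed = 4, rv_r_es = 2.5,
         wall_px = 1.5),
    list(...))
}

tiny_config <- function(...) do.call(phantom_config, tiny_args(...))
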