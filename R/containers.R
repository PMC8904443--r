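#' Complex real-time image series
#'
#' The raw substrate of all analysis: a complex 4-D array with dimensions
#' (slice, frame, row, col), plus the acquisition geometry needed
#' downstream (frame spacing, pixel spacing, slice thickness and gap).
#'
#' @param data complex (or numeric) 4-D array, dim (n_slices, n_frames,
#'   rows, cols).
#' @param dt frame spacing (s).
#' @param pixel_mm in-plane pixel spacing (mm).
#' @param thickness_mm slice thickness (mm).
#' @param gap_mm inter-slice gap (mm).
#' @param magnitude_only TRUE if the series was loaded without phase
#'   information (imaginary part assumed zero).
#' @return An object of class \code{rt_series}.
#' @export
rt_series <- function(data, dt, pixel_mm = NA_real_, thickness_mm = NA_real_,
                      gap_mm = NA_real_, magnitude_only = FALSE) {
  if (length(dim(data)) != 4L)
    stop("series data must be a 4-D array (slice, frame, row, col)",
         call. = FALSE)
  if (!is.complex(data)) data <- array(as.complex(data), dim(data))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number (seconds)", call. = FALSE)
  structure(list(data = data, dt = dt, pixel_mm = pixel_mm,
                 thickness_mm = thickness_mm, gap_mm = gap_mm,
                 magnitude_only = isTRUE(magnitude_only)),
            class = "rt_series")
}

#' @export
print.rt_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<rt_series> ", d[1], " slice(s) x ", d[2], " frames x ",
      d[3], "x", d[4], " px, dt = ", x$dt * 1000, " ms",
      if (x$magnitude_only) " (magnitude only)", "\n", sep = "")
  invisible(x)
}

#' Dimensions of an rt_series
#' @param x an \code{rt_series}.
#' @return Integer vector (n_slices, n_frames, rows, cols).
#' @export
series_dim <- function(x) dim(x$data)

#' Extract one slice of a series as a (frame, row, col) array
#' @param x an \code{rt_series}.
#' @param slice 1-based slice index.
#' @return Complex 3-D array (n_frames, rows, cols).
#' @export
series_slice <- function(x, slice) {
  d <- dim(x$data)
  if (slice < 1L || slice > d[1]) stop("slice index out of range", call. = FALSE)
  array(x$data[slice, , , ], d[2:4])
}

#' End-diastolic / end-systolic endocardial mask set
#'
#' Binary LV and RV endocardial masks at end-diastole and end-systole for
#' every slice, stored as (slice, row, col) arrays of 0/1, plus voxel
#' geometry. The source of the per-chamber ROI and of the ventricular
#' anatomy VA.
#'
#' @param lv_ed,lv_es,rv_ed,rv_es binary (slice, row, col) arrays.
#' @param pixel_mm,thickness_mm,gap_mm voxel geometry (mm).
#' @return An object of class \code{mask_set}.
#' @export
mask_set <- function(lv_ed, lv_es, rv_ed, rv_es,
                     pixel_mm = NA_real_, thickness_mm = NA_real_,
                     gap_mm = NA_real_) {
  ms <- list(lv_ed = lv_ed, lv_es = lv_es, rv_ed = rv_ed, rv_es = rv_es)
  shp <- dim(lv_ed)
  for (nm in names(ms)) {
    m <- ms[[nm]]
    if (length(dim(m)) != 3L || !identical(dim(m), shp))
      stop("all masks must be 3-D (slice, row, col) arrays of one shape",
           call. = FALSE)
    if (!all(m %in% c(0L, 1L)))
      stop("mask values must be 0 or 1 (", nm, ")", call. = FALSE)
    storage.mode(ms[[nm]]) <- "integer"
  }
  structure(c(ms, list(pixel_mm = pixel_mm, thickness_mm = thickness_mm,
                       gap_mm = gap_mm)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  d <- dim(x$lv_ed)
  cat("<mask_set> ", d[1], " slice(s) x ", d[2], "x", d[3], " px; ",
      "LV ED/ES ", sum(x$lv_ed), "/", sum(x$lv_es), " vox, ",
      "RV ED/ES ", sum(x$rv_ed), "/", sum(x$rv_es), " vox\n", sep = "")
  invisible(x)
}
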