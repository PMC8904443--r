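#' Per-chamber ROI from ED and ES segmentations
#'
#' The region of interest for a chamber is the end-diastolic endocardial
#' mask minus the end-systolic one: the annular band swept by the moving
#' wall over the cardiac cycle. The spatially averaged time series inside
#' this band is the reference wall-motion signal.
#'
#' With real (noisy) segmentations ES need not be a subset of ED; the ROI
#' is still literally `ED & !ES`, and a warning reports how many ES voxels
#' fall outside ED.
#'
#' @param ed_mask,es_mask binary matrices (or arrays) of one shape.
#' @return An object of class \code{roi_mask}: list with \code{mask}
#'   (binary, same shape) and \code{n_voxels}.
#' @export
make_roi <- function(ed_mask, es_mask) {
  if (!identical(dim(ed_mask), dim(es_mask)))
    stop("ED and ES masks must share one shape", call. = FALSE)
  outside <- sum(es_mask == 1L & ed_mask == 0L)
  if (outside > 0)
    warning(outside, " ES voxel(s) lie outside the ED mask", call. = FALSE)
  roi <- (ed_mask == 1L & es_mask == 0L) * 1L
  n <- sum(roi)
  if (n == 0L)
    stop("empty ROI: ED minus ES leaves no voxels", call. = FALSE)
  structure(list(mask = roi, n_voxels = n), class = "roi_mask")
}

#' Ventricular anatomy (VA) mask
#'
#' The union of the LV and RV end-diastolic endocardial masks; the domain
#' over which the correlation map is computed and averaged. `M` is its
#' voxel count.
#'
#' @param lv_ed_mask,rv_ed_mask binary matrices (or arrays) of one shape.
#' @return An object of class \code{va_mask}: list with \code{mask} and
#'   \code{M} (total voxel count).
#' @export
make_va <- function(lv_ed_mask, rv_ed_mask) {
  if (!identical(dim(lv_ed_mask), dim(rv_ed_mask)))
    stop("LV and RV ED masks must share one shape", call. = FALSE)
  va <- (lv_ed_mask == 1L | rv_ed_mask == 1L) * 1L
  m <- sum(va)
  if (m == 0L) stop("empty ventricular anatomy", call. = FALSE)
  structure(list(mask = va, M = m), class = "va_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", x$n_voxels, " voxel(s)\n", sep = "")
  invisible(x)
}

#' @export
print.va_mask <- function(x, ...) {
  cat("<va_mask> M = ", x$M, " voxel(s)\n", sep = "")
  invisible(x)
}
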