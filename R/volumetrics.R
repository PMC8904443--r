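#' Chamber volume by the method of slices
#'
#' Sums, over slices, mask area times slab height. The slab height is
#' slice thickness plus inter-slice gap, matching a gapped short-axis
#' acquisition (e.g. 8 mm slices with 2 mm gaps cover 10 mm of
#' long-axis extent each).
#'
#' @param masks binary (slice, row, col) array, or a list of binary
#'   matrices, one per slice.
#' @param pixel_mm in-plane pixel spacing (mm).
#' @param thickness_mm slice thickness (mm).
#' @param gap_mm inter-slice gap (mm).
#' @return Volume in ml, with attribute \code{slice_area_mm2} (numeric
#'   vector of per-slice areas).
#' @export
chamber_volume <- function(masks, pixel_mm, thickness_mm, gap_mm = 0) {
  if (is.list(masks)) counts <- vapply(masks, sum, numeric(1))
  else if (length(dim(masks)) == 3L) counts <- apply(masks, 1, sum)
  else if (length(dim(masks)) == 2L) counts <- sum(masks)
  else stop("masks must be a 3-D array, matrix, or list of matrices",
            call. = FALSE)
  if (length(counts) == 0L) stop("empty mask stack", call. = FALSE)
  if (pixel_mm <= 0 || thickness_mm <= 0 || gap_mm < 0)
    stop("geometry must be positive (gap >= 0)", call. = FALSE)
  areas <- counts * pixel_mm^2
  vol <- sum(areas * (thickness_mm + gap_mm)) / 1000
  structure(vol, slice_area_mm2 = areas)
}

#' Stroke volume and ejection fraction
#'
#' @param edv end-diastolic volume (ml), > 0.
#' @param esv end-systolic volume (ml), >= 0.
#' @return List with \code{sv} (ml) and \code{ef} (percent).
#' @export
ejection_fraction <- function(edv, esv) {
  if (!is.numeric(edv) || edv <= 0) stop("EDV must be positive", call. = FALSE)
  if (!is.numeric(esv) || esv < 0) stop("ESV must be >= 0", call. = FALSE)
  sv <- edv - esv
  list(sv = sv, ef = 100 * sv / edv)
}

#' Volumetric indices (EDV, ESV, SV, EF) for both chambers
#'
#' @param masks a \code{mask_set} with geometry filled in.
#' @return data.frame with one row per chamber: edv_ml, esv_ml, sv_ml,
#'   ef_pct.
#' @export
volumetric_indices <- function(masks) {
  one <- function(ch) {
    edv <- as.numeric(chamber_volume(masks[[paste0(ch, "_ed")]],
                                     masks$pixel_mm, masks$thickness_mm,
                                     masks$gap_mm))
    esv <- as.numeric(chamber_volume(masks[[paste0(ch, "_es")]],
                                     masks$pixel_mm, masks$thickness_mm,
                                     masks$gap_mm))
    e <- ejection_fraction(edv, esv)
    data.frame(chamber = toupper(ch), edv_ml = edv, esv_ml = esv,
               sv_ml = e$sv, ef_pct = e$ef)
  }
  rbind(one("lv"), one("rv"))
}

#' Blood-pool SNR and blood-myocardium CNR
#'
#' SNR = mean blood-pool magnitude over the background magnitude SD;
#' CNR = (mean blood - mean myocardium magnitude) over the same SD. The
#' noise estimate comes from a background (air) region of the magnitude
#' image; on magnitude images background noise is Rayleigh rather than
#' Gaussian, and the optional correction rescales the background SD by
#' sqrt(2/(4 - pi)) to recover the underlying Gaussian sigma.
#'
#' @param frame complex or numeric matrix (one image frame).
#' @param blood_roi,myo_roi,background_roi binary masks, pairwise
#'   disjoint, non-empty.
#' @param rayleigh_correction apply the magnitude-noise correction
#'   (default FALSE; recorded in the result).
#' @return List with \code{snr}, \code{cnr}, component means/SD and the
#'   convention flags.
#' @export
snr_cnr <- function(frame, blood_roi, myo_roi, background_roi,
                    rayleigh_correction = FALSE) {
  rois <- list(blood = blood_roi, myocardium = myo_roi,
               background = background_roi)
  for (nm in names(rois))
    if (sum(rois[[nm]]) == 0L) stop("empty ", nm, " ROI", call. = FALSE)
  if (sum(blood_roi & myo_roi) + sum(blood_roi & background_roi) +
      sum(myo_roi & background_roi) > 0)
    stop("ROIs must be pairwise disjoint", call. = FALSE)
  mag <- Mod(frame)
  mb <- mean(mag[blood_roi == 1L])
  mm <- mean(mag[myo_roi == 1L])
  sdbg <- stats::sd(mag[background_roi == 1L])
  if (sdbg == 0) stop("zero background standard deviation", call. = FALSE)
  if (rayleigh_correction) sdbg <- sdbg * sqrt(2 / (4 - pi))
  out <- list(snr = mb / sdbg, cnr = (mb - mm) / sdbg,
              mean_blood = mb, mean_myocardium = mm, sd_background = sdbg,
              rayleigh_correction = rayleigh_correction,
              myocardium_brighter = mm > mb)
  if (out$myocardium_brighter)
    warning("myocardium brighter than blood pool: CNR is negative",
            call. = FALSE)
  out
}
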