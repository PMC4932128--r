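#' Partial-volume correction configuration
#'
#' @param psf_fwhm_mm Assumed scanner point-spread FWHM in mm (scalar or
#'   per-axis), default 8 mm.
#' @param gm_threshold GM probability below which corrected voxels are
#'   masked out, default 0.3.
#' @param wm_erosion_mm Erosion depth for the pure-white-matter estimate,
#'   default 6 mm.
#' @param gm_floor Floor on the blurred GM map used as the division
#'   denominator, default 0.1; voxels below it are masked and counted.
#' @return A list of class `pvc_config`.
#' @export
pvc_config <- function(psf_fwhm_mm = 8, gm_threshold = 0.3,
                       wm_erosion_mm = 6, gm_floor = 0.1) {
  if (any(psf_fwhm_mm < 0)) stop("psf_fwhm_mm must be >= 0")
  if (gm_threshold < 0 || gm_threshold > 1) {
    stop("gm_threshold must lie in [0, 1]")
  }
  structure(list(psf_fwhm_mm = psf_fwhm_mm, gm_threshold = gm_threshold,
                 wm_erosion_mm = wm_erosion_mm, gm_floor = gm_floor),
            class = "pvc_config")
}

#' Estimate the pure white-matter activity
#'
#' Mean of the image over voxels with white-matter probability >= 0.99
#' after binary erosion by `wm_erosion_mm`, i.e. deep white matter far
#' enough from tissue boundaries to be unaffected by spill-in.
#'
#' @param vol 3D activity image.
#' @param wm_map 3D WM probability map.
#' @param config A [pvc_config()].
#' @param voxel_mm Voxel size in mm.
#' @return Scalar WM activity estimate.
#' @export
estimate_wm_value <- function(vol, wm_map, config = pvc_config(),
                              voxel_mm = c(2, 2, 2)) {
  check_same_dim(vol, wm_map, "image/wm_map")
  core <- erode_mask(wm_map >= 0.99, config$wm_erosion_mm, voxel_mm)
  if (!any(core)) {
    stop("no pure-WM voxels remain after erosion; reduce wm_erosion_mm")
  }
  mean(vol[core])
}

#' Mueller-Gartner partial-volume correction
#'
#' Two-compartment Mueller-Gartner correction of a 3D parametric or static
#' image: the white-matter spill-in is removed and the remainder is
#' compensated for grey-matter spill-out,
#' `corrected = (vol - C_WM * (wm (x) PSF)) / (gm (x) PSF)`,
#' where `(x)` is Gaussian convolution with the scanner PSF. CSF is assumed
#' activity-free. Voxels with GM probability below `gm_threshold`, or whose
#' blurred-GM denominator falls below `gm_floor`, are set to `NA` (the
#' latter counted in attribute `n_floored`).
#'
#' @param vol 3D image to correct (e.g. a DVR map).
#' @param gm_map,wm_map 3D tissue probability maps aligned with `vol`.
#' @param config A [pvc_config()].
#' @param c_wm Pure-WM activity; estimated by [estimate_wm_value()] when
#'   `NULL`.
#' @param voxel_mm Voxel size in mm.
#' @return Corrected 3D array (`NA` outside the reported GM mask) with
#'   attributes `c_wm` and `n_floored`.
#' @export
muller_gartner <- function(vol, gm_map, wm_map, config = pvc_config(),
                           c_wm = NULL, voxel_mm = c(2, 2, 2)) {
  check_same_dim(vol, gm_map, "image/gm_map")
  check_same_dim(vol, wm_map, "image/wm_map")
  if (!any(gm_map > 0)) stop("GM map is all zero")
  if (is.null(c_wm)) {
    c_wm <- estimate_wm_value(vol, wm_map, config, voxel_mm)
  }
  if (all(config$psf_fwhm_mm == 0)) {
    gm_blur <- gm_map
    wm_blur <- wm_map
  } else {
    gm_blur <- smooth_image(gm_map, config$psf_fwhm_mm, voxel_mm)
    wm_blur <- smooth_image(wm_map, config$psf_fwhm_mm, voxel_mm)
  }
  corrected <- (vol - c_wm * wm_blur) / pmax(gm_blur, config$gm_floor)
  keep <- gm_map >= config$gm_threshold
  floored <- keep & gm_blur < config$gm_floor
  corrected[!keep | floored] <- NA_real_
  attr(corrected, "c_wm") <- c_wm
  attr(corrected, "n_floored") <- sum(floored)
  corrected
}
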