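#' Duration-weighted frame average over a time window
#'
#' Averages the frames of a dynamic image that overlap a `[t0, t1]` minute
#' window, weighting each frame by the length of its overlap with the
#' window (so partially-covered frames contribute proportionally). This is
#' how static SUV images (e.g. 40--60 min) are built from dynamic data.
#'
#' @param dyn A `dynamic_image` (see [render_dynamic_image()]) or a 4D array
#'   plus `schedule`.
#' @param window_min Length-2 numeric, window in minutes from injection.
#' @param schedule Required if `dyn` is a bare array.
#' @return A 3D array.
#' @export
frame_average <- function(dyn, window_min, schedule = NULL) {
  if (inherits(dyn, "dynamic_image")) {
    schedule <- dyn$schedule
    dat <- dyn$data
  } else {
    if (is.null(schedule)) stop("schedule required for a bare array")
    dat <- dyn
  }
  w <- frame_window_overlap_min(schedule, window_min)
  if (sum(w) <= 0) stop("window overlaps no frame")
  w <- w / sum(w)
  d <- dim(dat)[1:3]
  out <- array(0, d)
  for (fr in which(w > 0)) out <- out + w[fr] * dat[, , , fr]
  out
}

#' Extract a region-mean time-activity curve
#'
#' @param dyn A `dynamic_image`.
#' @param mask Logical or 0/1 3D array selecting the voxels.
#' @return A `tac` (frame mid-times, durations and mask-mean values).
#' @export
extract_tac <- function(dyn, mask) {
  stopifnot(inherits(dyn, "dynamic_image"))
  mask <- mask != 0
  check_same_dim(array(0, dim(dyn$data)[1:3]), mask, "image/mask")
  if (!any(mask)) stop("mask is empty")
  nfr <- nrow(dyn$schedule)
  vals <- vapply(seq_len(nfr), function(fr) mean(dyn$data[, , , fr][mask]),
                 numeric(1))
  new_tac(dyn$schedule, vals)
}

#' Reference Logan graphical estimate of the distribution volume ratio
#'
#' Fits the reference Logan plot: for frames whose mid-time lies in the
#' `tstar_window`, regresses
#' `y(t) = int_0^t C(s) ds / C(t)` on `x(t) = int_0^t C_ref(s) ds / C(t)`
#' by ordinary least squares; the slope is the DVR (the simplified form
#' without a population k2' term). Integrals are trapezoidal on frame
#' mid-times with a leading triangle from (0, 0). Frames with non-positive
#' target activity inside the window are dropped and counted.
#'
#' @param tac,ref_tac Target and reference `tac`s on the same schedule.
#' @param tstar_window Fit window in minutes, default `c(30, 60)`.
#' @return A list of class `logan_fit`: `dvr`, `intercept`, `r_squared`,
#'   `n_points_used`, `n_dropped`, `tstar_window`.
#' @examples
#' sch <- thk_frame_schedule()
#' ref <- simulate_reference_tac(20, 4, sch)
#' tgt <- simulate_target_tac(kinetic_params(dvr = 1.5), sch, 20, 4)
#' logan_dvr(tgt, ref)$dvr
#' @export
logan_dvr <- function(tac, ref_tac, tstar_window = c(30, 60)) {
  stopifnot(inherits(tac, "tac"), inherits(ref_tac, "tac"))
  if (nrow(tac) != nrow(ref_tac) ||
      any(abs(tac$mid_min - ref_tac$mid_min) > 1e-9)) {
    stop("target and reference TACs must share the frame schedule")
  }
  if (tstar_window[1] < 0 || tstar_window[2] <= tstar_window[1] ||
      tstar_window[2] > max(tac$mid_min + tac$dur_min / 2) + 1e-9) {
    stop("tstar_window must lie within the scan span")
  }
  t <- tac$mid_min
  in_win <- t >= tstar_window[1] & t <= tstar_window[2]
  if (any(ref_tac$value[in_win] <= 0)) {
    stop("reference TAC must be positive inside the fit window")
  }
  cum_t <- cumtrapz_from_zero(t, tac$value)
  cum_r <- cumtrapz_from_zero(t, ref_tac$value)
  usable <- in_win & tac$value > 0
  n_dropped <- sum(in_win) - sum(usable)
  if (sum(usable) < 2L) stop("fewer than 2 usable frames in the fit window")
  y <- cum_t[usable] / tac$value[usable]
  x <- cum_r[usable] / tac$value[usable]
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(dvr = slope, intercept = unname(fit$coefficients[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points_used = sum(usable), n_dropped = n_dropped,
                 tstar_window = tstar_window),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf(
    "Reference Logan fit: DVR = %.4f (intercept %.3f, R^2 %.4f, %d frames, %d dropped, window %g-%g min)\n",
    x$dvr, x$intercept, x$r_squared, x$n_points_used, x$n_dropped,
    x$tstar_window[1], x$tstar_window[2]))
  invisible(x)
}

#' Voxel-wise reference Logan DVR image
#'
#' The reference TAC is the mask-mean curve; every voxel is then fitted
#' with [logan_dvr()] in fully vectorised form. Voxels with any
#' non-positive in-window activity fail the fit preconditions and are set
#' to `NA` (their count is reported in the `n_failed` attribute).
#'
#' @param dyn A `dynamic_image`.
#' @param ref_mask Logical/0-1 3D array, the reference region (non-empty).
#' @param tstar_window Fit window in minutes.
#' @param mask Optional analysis mask; voxels outside are `NA`.
#' @return 3D DVR array with attribute `n_failed`.
#' @export
logan_dvr_image <- function(dyn, ref_mask, tstar_window = c(30, 60),
                            mask = NULL) {
  stopifnot(inherits(dyn, "dynamic_image"))
  ref_tac <- extract_tac(dyn, ref_mask)
  t <- ref_tac$mid_min
  in_win <- t >= tstar_window[1] & t <= tstar_window[2]
  if (sum(in_win) < 2L) stop("fewer than 2 frames in the fit window")
  if (any(ref_tac$value[in_win] <= 0)) {
    stop("reference TAC must be positive inside the fit window")
  }
  d <- dim(dyn$data)[1:3]
  nvox <- prod(d)
  if (is.null(mask)) mask <- array(TRUE, d) else mask <- mask != 0
  V <- matrix(dyn$data, nvox, length(t))  # voxels x frames
  sel <- which(as.vector(mask))
  V <- V[sel, , drop = FALSE]
  cum_t <- cumtrapz_from_zero(t, V)
  cum_r <- cumtrapz_from_zero(t, ref_tac$value)
  Vw <- V[, in_win, drop = FALSE]
  ok <- rowSums(Vw <= 0) == 0
  Y <- cum_t[, in_win, drop = FALSE] / Vw
  X <- matrix(cum_r[in_win], nrow(V), sum(in_win), byrow = TRUE) / Vw
  n <- sum(in_win)
  sx <- rowSums(X); sy <- rowSums(Y)
  sxx <- rowSums(X^2); sxy <- rowSums(X * Y)
  slope <- (sxy - sx * sy / n) / (sxx - sx^2 / n)
  slope[!ok] <- NA_real_
  out <- array(NA_real_, d)
  out[sel] <- slope
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Standardised uptake value image
#'
#' SUV = activity concentration divided by injected dose over body weight:
#' `SUV = C / (dose / weight)`. With `C` in MBq/mL, dose in MBq and weight
#' in kg, the SUV carries units of kg/mL times 1000 ~ g/mL under the usual
#' 1 kg ~ 1000 mL convention.
#'
#' @param vol 3D activity-concentration array.
#' @param dose_MBq Injected dose in MBq, > 0.
#' @param weight_kg Body weight in kg, > 0.
#' @return 3D SUV array.
#' @export
suv_image <- function(vol, dose_MBq, weight_kg) {
  if (is.null(dose_MBq) || is.na(dose_MBq) || dose_MBq <= 0) {
    stop("dose_MBq must be a positive number")
  }
  if (is.null(weight_kg) || is.na(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be a positive number")
  }
  vol / (dose_MBq / weight_kg)
}

#' Standardised uptake value ratio image
#'
#' Divides a static image voxel-wise by the unweighted mean of the
#' reference-region voxels (e.g. cerebellar grey matter for tau and amyloid
#' tracers, pons for FDG).
#'
#' @param vol 3D array.
#' @param ref_mask Logical/0-1 3D array, non-empty, with positive mean.
#' @return 3D SUVR array with attribute `ref_mean`.
#' @export
suvr_image <- function(vol, ref_mask) {
  ref_mask <- ref_mask != 0
  check_same_dim(vol, ref_mask, "image/ref_mask")
  if (!any(ref_mask)) stop("reference mask is empty")
  m <- mean(vol[ref_mask])
  if (!is.finite(m) || m <= 0) stop("reference mean must be positive")
  out <- vol / m
  attr(out, "ref_mean") <- m
  out
}

#' Amyloid positivity classification from an SUVR value
#'
#' @param suvr Isocortical SUVR value(s).
#' @param threshold Positivity cut-off, default 1.41.
#' @return Logical: `suvr > threshold`.
#' @export
classify_amyloid <- function(suvr, threshold = 1.41) {
  suvr > threshold
}
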