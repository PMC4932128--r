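#' Kinetic parameters for a simulated tissue region
#'
#' Parameters of the simplified reference tissue model (SRTM) used as the
#' phantom's forward model: `R1` is the delivery ratio relative to the
#' reference region, `k2` the reference-region efflux rate in 1/min, and
#' `bp_nd` the non-displaceable binding potential. The distribution volume
#' ratio is `dvr = 1 + bp_nd`.
#'
#' @param R1 Delivery ratio, > 0.
#' @param k2 Efflux rate constant in 1/min, > 0.
#' @param bp_nd Binding potential, >= 0. Give either `bp_nd` or `dvr`.
#' @param dvr Distribution volume ratio, >= 1; overrides `bp_nd` if given.
#' @return A list of class `kinetic_params` with fields `R1`, `k2`, `bp_nd`
#'   and `dvr` (kept consistent: `dvr == 1 + bp_nd`).
#' @export
kinetic_params <- function(R1 = 1, k2 = 0.1, bp_nd = NULL, dvr = NULL) {
  if (is.null(bp_nd) && is.null(dvr)) bp_nd <- 0
  if (!is.null(dvr)) {
    if (dvr < 1) stop("dvr must be >= 1")
    bp_nd <- dvr - 1
  }
  if (R1 <= 0) stop("R1 must be > 0")
  if (k2 <= 0) stop("k2 must be > 0")
  if (bp_nd < 0) stop("bp_nd must be >= 0")
  structure(list(R1 = R1, k2 = k2, bp_nd = bp_nd, dvr = 1 + bp_nd),
            class = "kinetic_params")
}

# Continuous gamma-variate reference curve C_R(t) = A * t * exp(-t / tau),
# t and tau in minutes, A in activity units per minute.
gamma_variate <- function(t_min, amplitude, tau_min) {
  amplitude * t_min * exp(-t_min / tau_min)
}

# Exact antiderivative of A * t * exp(-t/tau):
# integral = -A * tau * exp(-t/tau) * (t + tau).
gamma_variate_integral <- function(t_min, amplitude, tau_min) {
  -amplitude * tau_min * exp(-t_min / tau_min) * (t_min + tau_min)
}

#' Simulate a reference-region time-activity curve
#'
#' The reference region follows a gamma-variate curve
#' `C_R(t) = A * t * exp(-t/tau)` (peak at `t = tau`). Frame values are the
#' analytic within-frame time averages of the continuous curve, matching how
#' scanners report frame data.
#'
#' @param amplitude Curve amplitude `A` (activity units per minute), > 0;
#'   0 is accepted and yields an all-zero curve.
#' @param tau_min Time-to-peak `tau` in minutes, > 0.
#' @param schedule A [frame_schedule()].
#' @return A data frame of class `tac` with columns `mid_min`, `dur_min`
#'   and `value`.
#' @examples
#' tac <- simulate_reference_tac(20, 4, thk_frame_schedule())
#' plot(tac$mid_min, tac$value, type = "b")
#' @export
simulate_reference_tac <- function(amplitude, tau_min, schedule) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (tau_min <= 0) stop("tau_min must be > 0")
  t0 <- schedule$start_s / 60
  t1 <- (schedule$start_s + schedule$duration_s) / 60
  vals <- (gamma_variate_integral(t1, amplitude, tau_min) -
             gamma_variate_integral(t0, amplitude, tau_min)) / (t1 - t0)
  new_tac(schedule, pmax(vals, 0))
}

new_tac <- function(schedule, values) {
  out <- data.frame(
    mid_min = schedule$mid_min,
    dur_min = schedule$duration_s / 60,
    value   = as.numeric(values)
  )
  class(out) <- c("tac", "data.frame")
  out
}

# Continuous SRTM target curve for a gamma-variate reference input,
# via the closed-form convolution
#   C_T(t) = R1 C_R(t) + (k2 - R1 k2a) * (C_R (x) exp(-k2a t))(t),
# with k2a = k2 / (1 + bp_nd). For C_R = A s exp(-s/tau) the convolution is
#   A exp(-k2a t) (exp(bt)(bt - 1) + 1) / b^2,  b = k2a - 1/tau,
# with the b -> 0 limit A exp(-k2a t) t^2 / 2.
srtm_curve <- function(t_min, params, amplitude, tau_min) {
  k2a <- params$k2 / (1 + params$bp_nd)
  if (k2a <= 0) stop("k2a must be > 0")
  b <- k2a - 1 / tau_min
  conv <- if (abs(b) > 1e-8) {
    amplitude * exp(-k2a * t_min) * (expm1(b * t_min) * (b * t_min - 1) +
                                       b * t_min) / b^2
  } else {
    amplitude * exp(-k2a * t_min) * t_min^2 / 2
  }
  params$R1 * gamma_variate(t_min, amplitude, tau_min) +
    (params$k2 - params$R1 * k2a) * conv
}

#' Simulate a target-region time-activity curve (SRTM forward model)
#'
#' Generates the noiseless target-tissue curve implied by the simplified
#' reference tissue model given a gamma-variate reference input, and reports
#' its within-frame time averages on the acquisition schedule. The
#' convolution with the efflux kernel is evaluated in closed form; frame
#' averages are taken on a dense sub-frame grid.
#'
#' @param params A [kinetic_params()].
#' @param schedule A [frame_schedule()].
#' @param ref_amplitude,ref_tau_min Gamma-variate reference curve parameters
#'   (see [simulate_reference_tac()]).
#' @param n_sub Number of sub-samples per frame used for the within-frame
#'   average (trapezoid); default 64.
#' @return A `tac` on the schedule.
#' @export
simulate_target_tac <- function(params, schedule, ref_amplitude, ref_tau_min,
                                n_sub = 64L) {
  stopifnot(inherits(params, "kinetic_params"))
  if (ref_amplitude < 0) stop("ref_amplitude must be >= 0")
  if (ref_tau_min <= 0) stop("ref_tau_min must be > 0")
  t0 <- schedule$start_s / 60
  t1 <- (schedule$start_s + schedule$duration_s) / 60
  vals <- vapply(seq_len(nrow(schedule)), function(i) {
    tt <- seq(t0[i], t1[i], length.out = n_sub + 1L)
    y <- srtm_curve(tt, params, ref_amplitude, ref_tau_min)
    # trapezoid average over the frame
    sum((y[-1] + y[-length(y)]) / 2 * diff(tt)) / (t1[i] - t0[i])
  }, numeric(1))
  new_tac(schedule, pmax(vals, 0))
}

#' Construct a synthetic phantom scene
#'
#' A phantom scene couples tissue-probability maps (grey matter, white
#' matter, CSF), an integer label atlas, per-region kinetic parameters and
#' the reference-region label. It is the ground truth that rendered dynamic
#' images are later checked against.
#'
#' @param gm_map,wm_map,csf_map 3D probability volumes in `[0, 1]` whose
#'   voxel-wise sum must not exceed 1.
#' @param atlas 3D integer label volume (0 = background).
#' @param region_params Named list mapping label (as character) to a
#'   [kinetic_params()]; every non-zero atlas label must be present.
#' @param region_names Named character vector mapping label to region name.
#' @param region_tissue Named character vector mapping label to `"gm"` or
#'   `"wm"`: which probability map carries the region's activity.
#' @param reference_label Integer label of the reference region (cerebellar
#'   grey matter surrogate); must have `bp_nd = 0`.
#' @param ref_amplitude,ref_tau_min Parameters of the gamma-variate
#'   reference input curve.
#' @param voxel_mm Voxel size in mm (length 3).
#' @return A list of class `phantom_scene`.
#' @export
phantom_scene <- function(gm_map, wm_map, csf_map, atlas, region_params,
                          region_names, region_tissue, reference_label,
                          ref_amplitude = 20, ref_tau_min = 10,
                          voxel_mm = c(2, 2, 2)) {
  stop_if_not_3d(atlas)
  check_same_dim(gm_map, atlas, "gm_map/atlas")
  check_same_dim(wm_map, atlas, "wm_map/atlas")
  check_same_dim(csf_map, atlas, "csf_map/atlas")
  if (any(gm_map < 0 | gm_map > 1) || any(wm_map < 0 | wm_map > 1) ||
      any(csf_map < 0 | csf_map > 1)) {
    stop("tissue probability maps must lie in [0, 1]")
  }
  if (any(gm_map + wm_map + csf_map > 1 + 1e-9)) {
    stop("tissue probabilities must sum to <= 1 voxel-wise")
  }
  labs <- sort(unique(as.integer(atlas[atlas != 0])))
  missing <- setdiff(as.character(labs), names(region_params))
  if (length(missing)) {
    stop("missing kinetic params for labels: ", paste(missing, collapse = ", "))
  }
  if (!as.character(reference_label) %in% as.character(labs)) {
    stop("reference_label not present in atlas")
  }
  if (region_params[[as.character(reference_label)]]$bp_nd != 0) {
    stop("reference region must have bp_nd = 0 (dvr = 1)")
  }
  structure(list(
    gm_map = gm_map, wm_map = wm_map, csf_map = csf_map, atlas = atlas,
    region_params = region_params, region_names = region_names,
    region_tissue = region_tissue, reference_label = as.integer(reference_label),
    ref_amplitude = ref_amplitude, ref_tau_min = ref_tau_min,
    voxel_mm = voxel_mm
  ), class = "phantom_scene")
}

#' Default 12-region brain-like phantom
#'
#' Builds a small brain-like scene on a cubic grid: an ellipsoidal brain
#' with a basal cerebellar grey-matter slab (the reference region), a
#' central white-matter compartment, four deep grey structures (hippocampus,
#' amygdala, parahippocampal and fusiform gyri -- the limbic composite
#' members), four isocortical sectors (frontal, temporal, parietal and
#' occipital), a precentral gyrus (excluded from the isocortical composite)
#' and a putamen. Tissue maps are binary (pure tissue per voxel); soft maps
#' for partial-volume experiments can be made by blurring them.
#'
#' @param dim Grid dimensions, default `c(48, 48, 48)`.
#' @param voxel_mm Voxel size in mm, default 2 mm isotropic.
#' @param region_dvr Named numeric vector of true DVR per region name;
#'   defaults to 1 everywhere (a null brain). Names must match
#'   `default_region_names()`. The reference and any unnamed region get 1.
#' @param R1,k2 SRTM nuisance parameters shared by all regions.
#' @param wm_dvr DVR of the white-matter compartment (tau tracers show
#'   nonspecific white-matter retention), default 1.25.
#' @param ref_amplitude,ref_tau_min Reference input curve parameters.
#' @return A `phantom_scene`.
#' @export
default_phantom_scene <- function(dim = c(48, 48, 48), voxel_mm = c(2, 2, 2),
                                  region_dvr = NULL, R1 = 1, k2 = 0.15,
                                  wm_dvr = 1.25,
                                  ref_amplitude = 20, ref_tau_min = 10) {
  nm <- default_region_names()
  d <- as.integer(dim)
  idx <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  # normalised coordinates in [-1, 1] about the grid centre
  u <- (idx$x - (d[1] + 1) / 2) / (d[1] / 2)
  v <- (idx$y - (d[2] + 1) / 2) / (d[2] / 2)
  w <- (idx$z - (d[3] + 1) / 2) / (d[3] / 2)

  brain <- (u / 0.85)^2 + (v / 0.9)^2 + (w / 0.85)^2 <= 1
  cereb <- brain & w < -0.55 & abs(u) < 0.5 & abs(v) < 0.5
  wm <- brain & !cereb &
    ((u / 0.62)^2 + (v / 0.68)^2 + ((w - 0.05) / 0.62)^2 <= 1)

  lab <- integer(nrow(idx))
  lab[cereb] <- 1L
  lab[wm] <- 2L

  in_box <- function(uc, vc, wc, half) {
    abs(u - uc) <= half[1] & abs(v - vc) <= half[2] & abs(w - wc) <= half[3]
  }
  # deep grey nuclei at the lower/lateral edge of the white-matter
  # territory, leaving a solid deep-WM core for the pure-WM estimate
  lab[wm & in_box(-0.34, -0.2, -0.38, c(0.12, 0.15, 0.10))] <- 8L    # hippocampus
  lab[wm & in_box(0.34, -0.2, -0.38, c(0.10, 0.10, 0.08))] <- 11L    # amygdala
  lab[wm & in_box(-0.34, 0.25, -0.38, c(0.12, 0.12, 0.08))] <- 9L    # parahippocampal
  lab[wm & in_box(0.34, 0.25, -0.38, c(0.12, 0.12, 0.08))] <- 10L    # fusiform
  lab[wm & in_box(0.0, 0.38, 0.12, c(0.12, 0.10, 0.10))] <- 12L      # putamen

  shell <- brain & lab == 0L
  assign_shell <- function(cond, label) lab[shell & cond] <<- label
  assign_shell(v > 0.30, 3L)                       # frontal (anterior)
  assign_shell(v < -0.55, 6L)                      # occipital (posterior)
  assign_shell(lab == 0L & shell & w > 0.40 & v > 0.05, 7L)  # precentral band
  assign_shell(lab == 0L & shell & w > 0.40, 5L)   # parietal (superior)
  lab[shell & lab == 0L] <- 4L                     # temporal (remainder)

  atlas <- array(lab, dim = d)
  gm <- array(0, d); wm_map <- array(0, d); csf <- array(0, d)
  gm[atlas != 0L & atlas != 2L] <- 1
  wm_map[atlas == 2L] <- 1

  dvr <- stats::setNames(rep(1, length(nm)), nm)
  if (!is.null(region_dvr)) {
    unknown <- setdiff(names(region_dvr), nm)
    if (length(unknown)) stop("unknown region names: ",
                              paste(unknown, collapse = ", "))
    dvr[names(region_dvr)] <- region_dvr
  }
  dvr["cerebellum_gm"] <- 1
  dvr["white_matter"] <- wm_dvr
  params <- lapply(seq_along(nm), function(l) {
    kinetic_params(R1 = R1, k2 = k2, dvr = unname(dvr[nm[l]]))
  })
  names(params) <- as.character(seq_along(nm))

  tissue <- stats::setNames(rep("gm", length(nm)), as.character(seq_along(nm)))
  tissue["2"] <- "wm"

  phantom_scene(gm, wm_map, csf, atlas, params,
                region_names = stats::setNames(nm, as.character(seq_along(nm))),
                region_tissue = tissue, reference_label = 1L,
                ref_amplitude = ref_amplitude, ref_tau_min = ref_tau_min,
                voxel_mm = voxel_mm)
}

#' @rdname default_phantom_scene
#' @export
default_region_names <- function() {
  c("cerebellum_gm", "white_matter", "frontal_cortex", "temporal_cortex",
    "parietal_cortex", "occipital_cortex", "precentral_gyrus",
    "hippocampus", "parahippocampal_gyrus", "fusiform_gyrus",
    "amygdala", "putamen")
}

# Noiseless regional TACs for every label of a scene, as a matrix
# (labels x frames) with rownames the label ids.
scene_region_tacs <- function(scene, schedule) {
  labs <- names(scene$region_params)
  out <- t(vapply(labs, function(l) {
    simulate_target_tac(scene$region_params[[l]], schedule,
                        scene$ref_amplitude, scene$ref_tau_min)$value
  }, numeric(nrow(schedule))))
  rownames(out) <- labs
  out
}

#' Render a 4D dynamic image from a phantom scene
#'
#' Each voxel's noiseless value per frame is the tissue-probability-weighted
#' mix of its region's time-activity curve (grey-matter regions are weighted
#' by the GM probability, the white-matter compartment by the WM
#' probability; CSF carries no activity). Each frame is then blurred with an
#' isotropic Gaussian point-spread function and, if requested, degraded with
#' additive zero-mean Gaussian noise whose standard deviation is
#' `noise_scale * sqrt(value) / sqrt(frame duration in minutes)` -- the
#' usual variance model for reconstructed PET.
#'
#' @param scene A [phantom_scene()].
#' @param schedule A [frame_schedule()].
#' @param psf_fwhm_mm Scanner PSF full width at half maximum in mm (>= 0).
#' @param noise_scale Noise magnitude in activity units; 0 = noiseless.
#' @param seed Integer seed fixing the noise; same seed, same image.
#' @return A list of class `dynamic_image` with fields `data` (4D array,
#'   x,y,z,frame), `schedule` and `voxel_mm`.
#' @export
render_dynamic_image <- function(scene, schedule, psf_fwhm_mm = 0,
                                 noise_scale = 0, seed = NULL) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  tacs <- scene_region_tacs(scene, schedule)
  d <- dim(scene$atlas)
  nfr <- nrow(schedule)
  dat <- array(0, c(d, nfr))
  lab_chr <- rownames(tacs)
  # per-label mixing weights, fixed across frames
  weights <- lapply(lab_chr, function(l) {
    m <- scene$atlas == as.integer(l)
    p <- if (scene$region_tissue[[l]] == "wm") scene$wm_map else scene$gm_map
    w <- m * p
    if (!any(w > 0)) NULL else w
  })
  names(weights) <- lab_chr
  dur_min <- schedule$duration_s / 60
  for (fr in seq_len(nfr)) {
    vol <- array(0, d)
    for (l in lab_chr) {
      if (!is.null(weights[[l]])) vol <- vol + weights[[l]] * tacs[l, fr]
    }
    if (psf_fwhm_mm > 0) {
      vol <- smooth_image(vol, psf_fwhm_mm, scene$voxel_mm)
    }
    dat[, , , fr] <- vol
  }
  if (noise_scale > 0) {
    dat <- with_seed(seed, {
      sd_arr <- array(0, c(d, nfr))
      for (fr in seq_len(nfr)) {
        sd_arr[, , , fr] <- noise_scale * sqrt(pmax(dat[, , , fr], 0)) /
          sqrt(dur_min[fr])
      }
      dat + array(stats::rnorm(length(dat)), c(d, nfr)) * sd_arr
    })
  }
  structure(list(data = dat, schedule = schedule, voxel_mm = scene$voxel_mm),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Dynamic image: %dx%dx%d voxels, %d frames, %.0f s span\n",
              d[1], d[2], d[3], d[4], sum(x$schedule$duration_s)))
  invisible(x)
}

#' Cohort configuration for the phantom generator
#'
#' Declares, per diagnostic group, the number of subjects and the
#' distribution (mean, SD) of the true DVR per region. Per-subject region
#' DVRs are drawn from those normal distributions truncated at 1.
#'
#' @param groups Named list: group name -> list with `n` (subjects),
#'   `dvr` (named numeric, region -> mean DVR) and optional `dvr_sd`
#'   (scalar or named, default 0.05).
#' @param dim,voxel_mm Phantom grid geometry.
#' @param psf_fwhm_mm Scanner blur applied at rendering, default 5 mm
#'   (typical clinical PET resolution).
#' @param noise_scale Noise magnitude, default 1 (see
#'   [render_dynamic_image()]; gives late-frame voxel-level coefficients of
#'   variation of roughly 10--20 %, typical of reconstructed dynamic PET).
#' @param dose_MBq_mean,dose_MBq_sd Injected dose distribution (default
#'   212 +/- 42 MBq).
#' @param weight_kg_mean,weight_kg_sd Body weight distribution.
#' @param seed Integer master seed; fixes every draw.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(groups, dim = c(48, 48, 48), voxel_mm = c(2, 2, 2),
                          psf_fwhm_mm = 5, noise_scale = 1,
                          dose_MBq_mean = 212, dose_MBq_sd = 42,
                          weight_kg_mean = 75, weight_kg_sd = 12,
                          seed = 1L) {
  if (!length(groups)) stop("at least one group must be declared")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list")
  }
  for (g in names(groups)) {
    if (is.null(groups[[g]]$n) || groups[[g]]$n < 1) {
      stop("group ", g, " must declare n >= 1")
    }
    if (any(groups[[g]]$dvr < 1)) stop("group DVR means must be >= 1")
  }
  structure(list(groups = groups, dim = dim, voxel_mm = voxel_mm,
                 psf_fwhm_mm = psf_fwhm_mm, noise_scale = noise_scale,
                 dose_MBq_mean = dose_MBq_mean, dose_MBq_sd = dose_MBq_sd,
                 weight_kg_mean = weight_kg_mean, weight_kg_sd = weight_kg_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default three-group study configuration
#'
#' Healthy controls with near-null tau binding, prodromal AD with limbic
#' DVR elevation, and AD dementia with limbic and isocortical elevation;
#' regional means qualitatively span the control ~1.0--1.1 and AD
#' isocortical ~1.1--1.4 (pre-correction) ranges typical of this tracer.
#'
#' @param n_per_group Named integer vector of subjects per group.
#' @param ... Passed to [cohort_config()].
#' @export
default_cohort_config <- function(n_per_group = c(HC = 9, prodromal_AD = 11,
                                                  AD_dementia = 9), ...) {
  lim <- c("hippocampus", "parahippocampal_gyrus", "fusiform_gyrus", "amygdala")
  iso <- c("frontal_cortex", "temporal_cortex", "parietal_cortex",
           "occipital_cortex", "precentral_gyrus")
  mk <- function(lv, iv, pv) {
    v <- c(stats::setNames(rep(lv, length(lim)), lim),
           stats::setNames(rep(iv, length(iso)), iso),
           putamen = pv)
    v
  }
  groups <- list(
    HC           = list(n = n_per_group[["HC"]],
                        dvr = mk(1.02, 1.02, 1.25), dvr_sd = 0.03),
    prodromal_AD = list(n = n_per_group[["prodromal_AD"]],
                        dvr = mk(1.20, 1.12, 1.45), dvr_sd = 0.05),
    AD_dementia  = list(n = n_per_group[["AD_dementia"]],
                        dvr = mk(1.25, 1.25, 1.50), dvr_sd = 0.06)
  )
  cohort_config(groups, ...)
}

#' Generate a synthetic cohort of dynamic PET subjects
#'
#' Draws per-subject true regional DVRs from the configured group
#' distributions (normal, truncated at 1), renders each subject's dynamic
#' image and records the ground truth.
#'
#' @param config A [cohort_config()].
#' @return A list of class `phantom_cohort` with elements `subjects` (each a
#'   list with `record` -- subject_id, group, dose_MBq, weight_kg, seed --,
#'   `image`, `scene` and `truth`, a named vector of true regional DVRs) and
#'   `manifest`, a data frame of the records.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- list()
  rows <- list()
  sid <- 0L
  for (g in names(config$groups)) {
    spec <- config$groups[[g]]
    sd_vec <- spec$dvr_sd
    if (is.null(sd_vec)) sd_vec <- 0.05
    for (i in seq_len(spec$n)) {
      sid <- sid + 1L
      sseed <- child_seed(config$seed, sid)
      drawn <- with_seed(sseed, {
        s <- if (length(sd_vec) == 1L) rep(sd_vec, length(spec$dvr)) else
          sd_vec[names(spec$dvr)]
        pmax(1, stats::rnorm(length(spec$dvr), spec$dvr, s))
      })
      names(drawn) <- names(spec$dvr)
      demo <- with_seed(child_seed(sseed, 1L), c(
        dose = max(50, stats::rnorm(1, config$dose_MBq_mean, config$dose_MBq_sd)),
        weight = max(35, stats::rnorm(1, config$weight_kg_mean, config$weight_kg_sd))
      ))
      scene <- default_phantom_scene(dim = config$dim,
                                     voxel_mm = config$voxel_mm,
                                     region_dvr = drawn)
      img <- render_dynamic_image(scene, thk_frame_schedule(),
                                  psf_fwhm_mm = config$psf_fwhm_mm,
                                  noise_scale = config$noise_scale,
                                  seed = child_seed(sseed, 2L))
      record <- list(subject_id = sprintf("sub-%03d", sid), group = g,
                     dose_MBq = unname(demo["dose"]),
                     weight_kg = unname(demo["weight"]), seed = sseed)
      subjects[[sid]] <- list(record = record, image = img, scene = scene,
                              truth = drawn)
      rows[[sid]] <- data.frame(subject_id = record$subject_id, group = g,
                                dose_MBq = record$dose_MBq,
                                weight_kg = record$weight_kg, seed = sseed)
    }
  }
  structure(list(subjects = subjects, manifest = do.call(rbind, rows),
                 config = config),
            class = "phantom_cohort")
}
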