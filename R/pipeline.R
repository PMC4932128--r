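#' Pipeline configuration
#'
#' Gathers every fixed analysis constant: the Logan fit window, the SUV
#' averaging window, per-tracer reference regions, and the statistical
#' thresholds (amyloid positivity 1.41, abnormality z 1.96, pairwise
#' corrected alpha 0.008, FDR q 0.05, cluster extent 20 voxels, smoothing
#' FWHM 8 mm).
#'
#' @param tstar_window Logan fit window in minutes, default `c(30, 60)`.
#' @param suv_window SUV averaging window in minutes, default `c(40, 60)`.
#' @param reference_region Named character: reference region per tracer.
#' @param amyloid_threshold SUVR positivity cut-off, default 1.41.
#' @param z_threshold Abnormality z threshold, default 1.96.
#' @param alpha_corrected Pairwise corrected alpha, default
#'   [corrected_alpha()] = 0.05/6.
#' @param fdr_q Voxel-wise FDR level, default 0.05.
#' @param cluster_extent Minimum cluster size in voxels, default 20.
#' @param fwhm_mm Smoothing kernel FWHM in mm, default 8.
#' @param n_permutations Permutations for voxel-wise tests, default 10000.
#' @param gm_binarise_threshold GM mask binarisation threshold, default 0.5.
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(tstar_window = c(30, 60), suv_window = c(40, 60),
                            reference_region = c(THK5317 = "cerebellum_gm",
                                                 PIB = "cerebellum_gm",
                                                 FDG = "pons"),
                            amyloid_threshold = 1.41, z_threshold = 1.96,
                            alpha_corrected = corrected_alpha(),
                            fdr_q = 0.05, cluster_extent = 20, fwhm_mm = 8,
                            n_permutations = 10000,
                            gm_binarise_threshold = 0.5, seed = 1L) {
  if (tstar_window[2] <= tstar_window[1] || suv_window[2] <= suv_window[1]) {
    stop("windows must be increasing intervals")
  }
  if (amyloid_threshold <= 0 || z_threshold <= 0 || fdr_q <= 0 ||
      cluster_extent <= 0 || fwhm_mm < 0) {
    stop("thresholds must be positive")
  }
  structure(list(tstar_window = tstar_window, suv_window = suv_window,
                 reference_region = reference_region,
                 amyloid_threshold = amyloid_threshold,
                 z_threshold = z_threshold,
                 alpha_corrected = alpha_corrected, fdr_q = fdr_q,
                 cluster_extent = cluster_extent, fwhm_mm = fwhm_mm,
                 n_permutations = n_permutations,
                 gm_binarise_threshold = gm_binarise_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Chains simulate -> quantify -> partial-volume correct -> ROI extraction
#' -> group statistics on a phantom cohort, writing tidy TSV tables, NIfTI
#' maps and a provenance record to `out_dir`. Outputs are deterministic
#' given the configuration seeds.
#'
#' @param cohort_cfg A [cohort_config()]; the cohort is generated from it.
#' @param pipe_cfg A [pipeline_config()].
#' @param out_dir Output directory.
#' @param contrast Length-2 character vector: the two groups compared
#'   voxel-wise; defaults to the first and last configured group.
#' @param control_group Group treated as controls for z-maps and AUC,
#'   default the first configured group.
#' @param write_images Write per-subject NIfTI maps (slower), default
#'   FALSE: tables and group maps only.
#' @return Invisibly, a list with the ROI table (`roi`), the group AUC
#'   table (`auc`), the rank-test results (`stats`), the permutation test
#'   (`perm`), the abnormality count map (`counts`) and the output paths.
#' @export
run_pipeline <- function(cohort_cfg, pipe_cfg = pipeline_config(),
                         out_dir, contrast = NULL, control_group = NULL,
                         write_images = FALSE) {
  stopifnot(inherits(cohort_cfg, "cohort_config"),
            inherits(pipe_cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()["elapsed"]
  log_stage <- function(fmt, ...) {
    message(sprintf("[taupet %7.1fs] ", proc.time()["elapsed"] - t0),
            sprintf(fmt, ...))
  }

  log_stage("simulating cohort (%d groups, seed %d)",
            length(cohort_cfg$groups), cohort_cfg$seed)
  cohort <- make_cohort(cohort_cfg)
  groups <- vapply(cohort$subjects, function(s) s$record$group, character(1))
  if (is.null(control_group)) control_group <- names(cohort_cfg$groups)[1]
  if (is.null(contrast)) {
    contrast <- c(control_group,
                  names(cohort_cfg$groups)[length(cohort_cfg$groups)])
  }

  scene <- cohort$subjects[[1]]$scene
  ref_lab <- scene$reference_label
  ref_mask <- scene$atlas == ref_lab
  # the white-matter compartment is (correctly) emptied by GM masking
  atlas <- composite_rois(suppressWarnings(
    build_gm_atlas(scene_atlas(scene), scene$gm_map,
                   pipe_cfg$gm_binarise_threshold)))

  log_stage("quantifying %d subjects (Logan %g-%g min, PVC)",
            length(cohort$subjects), pipe_cfg$tstar_window[1],
            pipe_cfg$tstar_window[2])
  roi_rows <- list()
  dvr_maps <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    dvr <- logan_dvr_image(s$image, ref_mask, pipe_cfg$tstar_window)
    late <- frame_average(s$image, pipe_cfg$suv_window)
    suvr <- suvr_image(late, ref_mask)
    pcfg <- pvc_config(psf_fwhm_mm = max(cohort_cfg$psf_fwhm_mm, 1e-8))
    dvr_pvc <- tryCatch(
      muller_gartner(dvr, s$scene$gm_map, s$scene$wm_map, pcfg,
                     voxel_mm = s$scene$voxel_mm),
      error = function(e) NULL)
    sid <- s$record$subject_id
    roi_rows[[length(roi_rows) + 1L]] <-
      extract_roi_means(dvr, atlas, sid, "dvr")
    roi_rows[[length(roi_rows) + 1L]] <-
      extract_roi_means(suvr, atlas, sid, "suvr")
    if (!is.null(dvr_pvc)) {
      roi_rows[[length(roi_rows) + 1L]] <-
        suppressWarnings(extract_roi_means(dvr_pvc, atlas, sid, "dvr_pvc"))
    }
    dvr_maps[[i]] <- dvr
    if (write_images) {
      write_volume(dvr, file.path(out_dir, paste0(sid, "_dvr.nii.gz")),
                   s$scene$voxel_mm)
    }
  }
  roi_tab <- do.call(rbind, roi_rows)
  utils::write.table(roi_tab, file.path(out_dir, "roi_values.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  log_stage("group statistics (contrast %s vs %s)", contrast[1], contrast[2])
  dvr_roi <- roi_tab[roi_tab$quantification == "dvr", ]
  comp <- dvr_roi[dvr_roi$roi_name %in% c("limbic", "isocortical"), ]
  subj_group <- stats::setNames(groups,
                                cohort$manifest$subject_id)[comp$subject_id]
  is_patient <- subj_group != control_group
  auc_rows <- lapply(split(seq_len(nrow(comp)), comp$roi_name), function(ix) {
    data.frame(roi_name = comp$roi_name[ix[1]],
               auc = roc_auc(comp$value[ix], is_patient[ix]))
  })
  auc_tab <- do.call(rbind, auc_rows)
  utils::write.table(auc_tab, file.path(out_dir, "auc.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stats_res <- kruskal_mannwhitney(comp$value, subj_group, comp$roi_name,
                                   alpha_corrected = pipe_cfg$alpha_corrected)
  utils::write.table(stats_res$pairwise,
                     file.path(out_dir, "pairwise_tests.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  smoothed <- lapply(dvr_maps, function(m) {
    m[!is.finite(m)] <- 1
    smooth_image(m, pipe_cfg$fwhm_mm, scene$voxel_mm)
  })
  gm_mask <- scene$gm_map >= pipe_cfg$gm_binarise_threshold
  perm <- permutation_twosample(smoothed[groups == contrast[2]],
                                smoothed[groups == contrast[1]],
                                n_permutations = pipe_cfg$n_permutations,
                                seed = child_seed(pipe_cfg$seed, 11L),
                                fdr_q = pipe_cfg$fdr_q, mask = gm_mask)
  write_volume(perm$t, file.path(out_dir, "contrast_t.nii.gz"),
               scene$voxel_mm)
  write_volume(perm$p_fdr, file.path(out_dir, "contrast_p_fdr.nii.gz"),
               scene$voxel_mm)

  ctrl_idx <- which(groups == control_group)
  ctrl_stack <- simplify2array(smoothed[ctrl_idx])
  ctrl_mean <- apply(ctrl_stack, 1:3, mean)
  ctrl_sd <- apply(ctrl_stack, 1:3, stats::sd)
  binmaps <- lapply(which(groups == contrast[2]), function(i) {
    zscore_map(smoothed[[i]], ctrl_mean, ctrl_sd,
               pipe_cfg$z_threshold)$abnormal & gm_mask
  })
  counts <- abnormality_count_map(binmaps)
  write_volume(counts, file.path(out_dir, "abnormality_count.nii.gz"),
               scene$voxel_mm)

  cfg_json <- file.path(out_dir, "provenance.json")
  prov <- list(
    package_version = as.character(utils::packageVersion("taupet")),
    cohort_config = cohort_cfg[setdiff(names(cohort_cfg), "groups")],
    groups = lapply(cohort_cfg$groups, function(g)
      list(n = g$n, dvr = as.list(g$dvr), dvr_sd = g$dvr_sd)),
    pipeline_config = unclass(pipe_cfg),
    contrast = contrast, control_group = control_group
  )
  jsonlite::write_json(prov, cfg_json, auto_unbox = TRUE, digits = NA)
  prov_hash <- unname(tools::md5sum(cfg_json))
  writeLines(prov_hash, file.path(out_dir, "provenance.md5"))
  log_stage("done; outputs in %s (config hash %s)", out_dir, prov_hash)

  invisible(list(roi = roi_tab, auc = auc_tab, stats = stats_res,
                 perm = perm, counts = counts, cohort = cohort,
                 out_dir = out_dir))
}
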