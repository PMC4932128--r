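#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping voxel size (mm) attached. 4D dynamic
#' images travel with a tab-separated frame-timing sidecar
#' (`frame_index`, `start_s`, `duration_s`).
#'
#' @param vol 3D numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_mm Voxel size in mm.
#' @return The path, invisibly (writers); an array or `dynamic_image`
#'   (readers).
#' @export
write_volume <- function(vol, path, voxel_mm = c(2, 2, 2)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' @rdname write_volume
#' @param dyn A `dynamic_image`.
#' @export
write_dynamic_image <- function(dyn, path) {
  stopifnot(inherits(dyn, "dynamic_image"))
  img <- RNifti::asNifti(dyn$data)
  RNifti::pixdim(img) <- c(dyn$voxel_mm, 1)
  RNifti::writeNifti(img, path)
  write_frame_timing(dyn$schedule, timing_path_for(path))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_dynamic_image <- function(path) {
  img <- RNifti::readNifti(path)
  sched <- read_frame_timing(timing_path_for(path))
  d <- dim(img)
  if (length(d) != 4L || d[4] != nrow(sched)) {
    stop("image is not 4D or frame count disagrees with the timing sidecar")
  }
  structure(list(data = array(as.numeric(img), d), schedule = sched,
                 voxel_mm = RNifti::pixdim(img)[1:3]),
            class = "dynamic_image")
}

timing_path_for <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_timing.tsv")
}

#' Write a phantom cohort to disk
#'
#' Per subject: 4D NIfTI + timing sidecar and a truth TSV of the drawn
#' regional DVRs; per cohort: tissue maps, label atlas, atlas name table,
#' and a manifest TSV (`subject_id`, `group`, `dose_MBq`, `weight_kg`,
#' `seed`, `dynamic_file`, `truth_file`).
#'
#' @param cohort A `phantom_cohort` from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scene <- cohort$subjects[[1]]$scene
  write_volume(scene$gm_map, file.path(dir, "gm.nii.gz"), scene$voxel_mm)
  write_volume(scene$wm_map, file.path(dir, "wm.nii.gz"), scene$voxel_mm)
  write_volume(scene$atlas, file.path(dir, "atlas.nii.gz"), scene$voxel_mm)
  utils::write.table(
    data.frame(label = as.integer(names(scene$region_names)),
               name = unname(scene$region_names)),
    file.path(dir, "atlas_names.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  man <- cohort$manifest
  man$dynamic_file <- NA_character_
  man$truth_file <- NA_character_
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    dyn_file <- file.path(dir, paste0(s$record$subject_id, "_dyn.nii.gz"))
    truth_file <- file.path(dir, paste0(s$record$subject_id, "_truth.tsv"))
    write_dynamic_image(s$image, dyn_file)
    utils::write.table(
      data.frame(roi_name = names(s$truth), true_dvr = unname(s$truth)),
      truth_file, sep = "\t", row.names = FALSE, quote = FALSE)
    man$dynamic_file[i] <- basename(dyn_file)
    man$truth_file[i] <- basename(truth_file)
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}
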