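#' Label atlas with region names and composite definitions
#'
#' @param labels 3D integer array, 0 = background.
#' @param names Named character vector: label id (as character) -> region
#'   name.
#' @param composites Named list: composite name -> integer vector of member
#'   labels (every member must be a named label).
#' @return A list of class `label_atlas`.
#' @export
label_atlas <- function(labels, names, composites = list()) {
  stop_if_not_3d(labels)
  present <- sort(unique(as.integer(labels[labels != 0])))
  for (cn in base::names(composites)) {
    bad <- setdiff(as.character(composites[[cn]]), base::names(names))
    if (length(bad)) {
      stop("composite ", cn, " references unnamed labels: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(labels = labels, names = names, composites = composites,
                 present = present),
            class = "label_atlas")
}

#' Atlas view of a phantom scene
#'
#' @param scene A `phantom_scene`.
#' @param composites Optional composite definitions; defaults to
#'   [default_composites()] restricted to regions present.
#' @return A `label_atlas`.
#' @export
scene_atlas <- function(scene, composites = NULL) {
  if (is.null(composites)) composites <- default_composites(scene$region_names)
  label_atlas(scene$atlas, scene$region_names, composites)
}

#' Composite Braak-stage region definitions
#'
#' The limbic composite (Braak stages III--IV) gathers the hippocampus,
#' amygdala, and parahippocampal and fusiform gyri (in a full clinical
#' atlas also the middle-inferior temporal, orbital and straight frontal
#' gyri, temporal poles and parietal-temporal-occipital junctions); the
#' isocortical composite (Braak stages V--VI) gathers all isocortical
#' regions except the precentral and postcentral gyri.
#'
#' @param region_names Named character vector (label -> name).
#' @return Named list of integer label vectors.
#' @export
default_composites <- function(region_names) {
  limbic_members <- c("hippocampus", "amygdala", "parahippocampal_gyrus",
                      "fusiform_gyrus", "middle_inferior_temporal_gyrus",
                      "orbital_gyrus", "straight_frontal_gyrus",
                      "temporal_pole", "parietal_temporal_occipital_junction")
  iso_all <- c("frontal_cortex", "temporal_cortex", "parietal_cortex",
               "occipital_cortex", "insular_cortex", "precentral_gyrus",
               "postcentral_gyrus")
  iso_members <- setdiff(iso_all, c("precentral_gyrus", "postcentral_gyrus"))
  lab_of <- function(members) {
    as.integer(names(region_names)[match(members, region_names, nomatch = 0)])
  }
  list(limbic = lab_of(limbic_members), isocortical = lab_of(iso_members))
}

#' Mask an atlas to grey matter
#'
#' Retains labels only where the GM probability is at least the binarising
#' threshold, mirroring the construction of individual GM atlases from a
#' probabilistic atlas and a binarised GM mask. Regions left empty by the
#' masking are reported with a warning.
#'
#' @param atlas A `label_atlas`.
#' @param gm_map 3D GM probability map.
#' @param threshold Binarisation threshold in `[0, 1]`, default 0.5.
#' @return A GM-masked `label_atlas` with attribute `emptied` listing the
#'   regions that lost all voxels.
#' @export
build_gm_atlas <- function(atlas, gm_map, threshold = 0.5) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  check_same_dim(atlas$labels, gm_map, "atlas/gm_map")
  labs <- atlas$labels
  labs[gm_map < threshold] <- 0L
  before <- atlas$present
  after <- sort(unique(as.integer(labs[labs != 0])))
  emptied <- setdiff(before, after)
  if (length(emptied)) {
    warning("regions emptied by GM masking: ",
            paste(atlas$names[as.character(emptied)], collapse = ", "))
  }
  out <- label_atlas(labs, atlas$names, atlas$composites)
  attr(out, "emptied") <- unname(atlas$names[as.character(emptied)])
  out
}

#' Add limbic and isocortical composite ROIs to an atlas
#'
#' Attaches the Braak-stage composites ([default_composites()]) or a
#' user-supplied membership list. Members missing from the atlas are
#' reported with a warning and the composite is built from the rest; a
#' composite with no available member is an error.
#'
#' @param atlas A `label_atlas`.
#' @param composites Named list of member label vectors; defaults to
#'   [default_composites()] on the atlas names.
#' @return The atlas with its `composites` field populated.
#' @export
composite_rois <- function(atlas, composites = NULL) {
  stopifnot(inherits(atlas, "label_atlas"))
  if (is.null(composites)) composites <- default_composites(atlas$names)
  kept <- list()
  for (cn in names(composites)) {
    members <- composites[[cn]]
    avail <- intersect(members, atlas$present)
    if (!length(avail)) stop("composite ", cn, " has no available members")
    if (length(avail) < length(members)) {
      warning("composite ", cn, " missing members: ",
              paste(setdiff(members, avail), collapse = ", "))
    }
    kept[[cn]] <- avail
  }
  atlas$composites <- kept
  atlas
}

#' Per-region means of a 3D image
#'
#' Unweighted mean over in-region voxels with finite values, for every
#' atlas label and composite. Non-finite voxels are excluded and counted;
#' empty regions are omitted with a warning.
#'
#' @param vol 3D image.
#' @param atlas A `label_atlas` (with composites, if wanted).
#' @param subject_id,quantification Provenance columns added to the table.
#' @return A data frame (one row per region): `subject_id`, `roi_name`,
#'   `value`, `n_voxels`, `n_excluded`, `quantification`.
#' @export
extract_roi_means <- function(vol, atlas, subject_id = NA_character_,
                              quantification = NA_character_) {
  stopifnot(inherits(atlas, "label_atlas"))
  check_same_dim(vol, atlas$labels, "image/atlas")
  units <- c(
    stats::setNames(as.list(atlas$present), atlas$names[as.character(atlas$present)]),
    atlas$composites
  )
  rows <- list()
  skipped <- character()
  for (rn in names(units)) {
    m <- atlas$labels %in% units[[rn]]
    vals <- vol[m]
    fin <- is.finite(vals)
    if (!any(fin)) {
      skipped <- c(skipped, rn)
      next
    }
    rows[[rn]] <- data.frame(
      subject_id = subject_id, roi_name = rn, value = mean(vals[fin]),
      n_voxels = sum(fin), n_excluded = sum(!fin),
      quantification = quantification
    )
  }
  if (length(skipped)) {
    warning("empty ROIs omitted: ", paste(skipped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
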