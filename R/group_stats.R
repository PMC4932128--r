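#' Area under the ROC curve via the rank identity
#'
#' AUC for discriminating a positive from a negative class by a scalar
#' value, computed through the Mann-Whitney identity
#' `AUC = U / (n1 * n0)`: the fraction of (positive, negative) pairs in
#' which the positive scores higher, ties counting one half (midranks).
#'
#' @param values Numeric scores, higher = more "positive".
#' @param labels Logical (or coercible) class labels, `TRUE` = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(values)  # midranks: ties contribute 1/2
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bonferroni-corrected alpha for pairwise group comparisons over ROIs
#'
#' For `k` groups compared two by two in `m` regions there are
#' `choose(k, 2) * m` pairwise tests; the family-wise alpha is divided by
#' that count (for 3 groups and 2 composite regions: 0.05 / 6, reported as
#' 0.008).
#'
#' @param alpha Family-wise alpha, default 0.05.
#' @param n_groups Number of diagnostic groups.
#' @param n_rois Number of regions tested.
#' @export
corrected_alpha <- function(alpha = 0.05, n_groups = 3, n_rois = 2) {
  alpha / (choose(n_groups, 2) * n_rois)
}

#' Kruskal-Wallis omnibus with Mann-Whitney post-hoc tests per ROI
#'
#' For each region, tests the omnibus group difference with the
#' Kruskal-Wallis rank ANOVA and, pairwise, with two-sided Mann-Whitney
#' (Wilcoxon rank-sum) tests; pairwise significance is flagged at a
#' Bonferroni-corrected alpha (default [corrected_alpha()] for the design
#' at hand).
#'
#' @param values Numeric vector of per-subject regional values.
#' @param group Factor/character of group membership (>= 2 groups, each
#'   with >= 2 subjects).
#' @param roi Character of region names, same length.
#' @param alpha Family-wise alpha, default 0.05.
#' @param alpha_corrected Per-test alpha; computed from the design when
#'   `NULL`.
#' @return A list with `omnibus` (data frame: roi, kw_p) and `pairwise`
#'   (data frame: roi, group1, group2, mw_p, significant, alpha_corrected).
#' @export
kruskal_mannwhitney <- function(values, group, roi, alpha = 0.05,
                                alpha_corrected = NULL) {
  group <- as.character(group)
  gl <- sort(unique(group))
  if (length(gl) < 2) stop("need >= 2 groups")
  tab <- table(group)
  if (any(tab < 2)) stop("every group needs >= 2 subjects")
  rois <- sort(unique(roi))
  if (is.null(alpha_corrected)) {
    alpha_corrected <- corrected_alpha(alpha, length(gl), length(rois))
  }
  pairs <- utils::combn(gl, 2)
  omni <- list(); pw <- list()
  for (rn in rois) {
    sel <- roi == rn
    omni[[rn]] <- data.frame(
      roi = rn,
      kw_p = stats::kruskal.test(values[sel], factor(group[sel]))$p.value
    )
    for (j in seq_len(ncol(pairs))) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      p <- suppressWarnings(stats::wilcox.test(
        values[sel & group == g1], values[sel & group == g2]
      )$p.value)
      pw[[paste(rn, j)]] <- data.frame(
        roi = rn, group1 = g1, group2 = g2, mw_p = p,
        significant = p < alpha_corrected,
        alpha_corrected = alpha_corrected
      )
    }
  }
  list(omnibus = do.call(rbind, c(omni, make.row.names = FALSE)),
       pairwise = do.call(rbind, c(pw, make.row.names = FALSE)))
}

#' Patient-versus-controls z-score map
#'
#' `z = (patient - control mean) / control SD` voxel-wise, with a floor on
#' the SD where it vanishes, and a one-sided binary map of abnormally high
#' values (`z > threshold`).
#'
#' @param patient_vol,control_mean_vol,control_sd_vol Aligned 3D arrays.
#' @param z_threshold Abnormality threshold, default 1.96 (one-sided 97.5th
#'   percentile of the standard normal).
#' @param sd_floor Minimum SD used in the division.
#' @return List with `z` (3D array) and `abnormal` (logical 3D array).
#' @export
zscore_map <- function(patient_vol, control_mean_vol, control_sd_vol,
                       z_threshold = 1.96, sd_floor = sqrt(.Machine$double.eps)) {
  check_same_dim(patient_vol, control_mean_vol, "patient/control mean")
  check_same_dim(patient_vol, control_sd_vol, "patient/control SD")
  z <- (patient_vol - control_mean_vol) / pmax(control_sd_vol, sd_floor)
  list(z = z, abnormal = z > z_threshold)
}

#' Sum of binarised abnormality maps
#'
#' Voxel-wise count, across subjects, of abnormally high values -- the
#' group-level illustration of where patients exceed the control range.
#'
#' @param binary_maps List of aligned logical/0-1 3D arrays.
#' @return Integer 3D count array (max = number of maps).
#' @export
abnormality_count_map <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1)
  out <- array(0L, dim(binary_maps[[1]]))
  for (m in binary_maps) {
    check_same_dim(out, m, "count/map")
    out <- out + (m != 0)
  }
  out
}

# Indicator matrix (n x n_arrangements) of which subjects fall in group A,
# either all distinct assignments of size nA (exhaustive) or a seeded
# random sample with the observed labelling first.
permutation_assignments <- function(n, nA, n_permutations, seed) {
  total <- choose(n, nA)
  if (n_permutations >= total) {
    combs <- utils::combn(n, nA)
    A <- matrix(0, n, ncol(combs))
    A[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = nA))] <- 1
    list(A = A, exhaustive = TRUE)
  } else {
    A <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        a <- numeric(n); a[sample.int(n, nA)] <- 1; a
      }, numeric(n))
    })
    list(A = A, exhaustive = FALSE)
  }
}

#' Voxel-wise two-sample permutation test with FDR control
#'
#' Computes the pooled-variance two-sample T statistic per voxel and its
#' permutation p-value from random relabelings of the group memberships
#' (two-sided; the observed labelling is included in the null count, so
#' `p >= 1/(n_permutations + 1)`). If more permutations are requested than
#' there are distinct assignments, all assignments are enumerated instead
#' (reported via `exhaustive`). Voxel p-values are then
#' Benjamini-Hochberg-adjusted and thresholded at `fdr_q`.
#'
#' @param images_a,images_b Lists of aligned 3D arrays (the two groups,
#'   each >= 2 subjects), smoothed upstream if desired.
#' @param n_permutations Number of random permutations, default 10000.
#' @param seed Integer seed for the relabelings.
#' @param fdr_q FDR level, default 0.05.
#' @param mask Optional logical 3D analysis mask.
#' @return List of class `perm_test`: `t` (3D), `p` (3D permutation
#'   p-values), `p_fdr` (BH-adjusted), `significant` (logical 3D),
#'   `exhaustive`, `n_null`.
#' @export
permutation_twosample <- function(images_a, images_b, n_permutations = 10000,
                                  seed = 1L, fdr_q = 0.05, mask = NULL) {
  nA <- length(images_a); nB <- length(images_b)
  if (nA < 2 || nB < 2) stop("both groups need >= 2 images")
  d <- dim(images_a[[1]])
  X <- vapply(c(images_a, images_b), function(v) {
    check_same_dim(images_a[[1]], v, "group images")
    as.vector(v)
  }, numeric(prod(d)))
  if (is.null(mask)) mask <- array(TRUE, d)
  sel <- which(as.vector(mask != 0))
  X <- X[sel, , drop = FALSE]
  n <- nA + nB

  t_for <- function(A) {
    # A: n x K indicator of group-A membership; pooled-variance T per voxel
    K <- ncol(A)
    SA <- X %*% A; SB <- X %*% (1 - A)
    QA <- (X^2) %*% A; QB <- (X^2) %*% (1 - A)
    mA <- SA / nA; mB <- SB / nB
    vA <- (QA - nA * mA^2) / (nA - 1)
    vB <- (QB - nB * mB^2) / (nB - 1)
    sp <- sqrt(((nA - 1) * vA + (nB - 1) * vB) / (n - 2))
    (mA - mB) / (sp * sqrt(1 / nA + 1 / nB))
  }

  obs_ind <- matrix(c(rep(1, nA), rep(0, nB)), ncol = 1)
  t_obs <- t_for(obs_ind)[, 1]
  perms <- permutation_assignments(n, nA, n_permutations, seed)
  a_obs <- abs(t_obs)
  # relative slack: the observed labelling must count as >= itself despite
  # BLAS rounding differences between the single- and multi-column paths
  thresh <- a_obs * (1 - 1e-9) - 1e-12
  # chunk over relabelings to bound memory at large permutation counts
  n_cols <- ncol(perms$A)
  exceed <- numeric(length(a_obs))
  for (first in seq(1L, n_cols, by = 512L)) {
    cols <- first:min(first + 511L, n_cols)
    Tn <- abs(t_for(perms$A[, cols, drop = FALSE]))
    Tn[!is.finite(Tn)] <- Inf  # zero-variance relabelings count as extreme
    exceed <- exceed + rowSums(Tn >= thresh)
  }
  p <- if (perms$exhaustive) {
    exceed / n_cols  # observed labelling is one of the arrangements
  } else {
    (1 + exceed) / (n_cols + 1)
  }
  p_fdr <- stats::p.adjust(p, "BH")

  to_vol <- function(v, fill = NA_real_) {
    out <- array(fill, d); out[sel] <- v; out
  }
  structure(list(
    t = to_vol(t_obs), p = to_vol(p, 1), p_fdr = to_vol(p_fdr, 1),
    significant = to_vol(p_fdr, 1) <= fdr_q & !is.na(to_vol(t_obs)),
    exhaustive = perms$exhaustive, n_null = n_cols
  ), class = "perm_test")
}

# 26-connectivity connected components of a logical 3D mask.
# Returns an integer label array (0 = background) plus component sizes.
label_clusters <- function(mask, connectivity = 26) {
  stop_if_not_3d(mask)
  mask <- mask != 0 & !is.na(mask)
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(list(labels = lab, sizes = integer(0)))
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  if (connectivity == 6) off <- off[abs(off$dx) + abs(off$dy) + abs(off$dz) == 1, ]
  ar <- arrayInd(idx, d)
  pos <- array(0L, d); pos[idx] <- seq_along(idx)
  cur <- 0L
  lab_v <- integer(length(idx))
  for (s in seq_along(idx)) {
    if (lab_v[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab_v[s] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      for (k in seq_len(nrow(off))) {
        nx <- ar[q, 1] + off$dx[k]; ny <- ar[q, 2] + off$dy[k]
        nz <- ar[q, 3] + off$dz[k]
        if (nx < 1 || ny < 1 || nz < 1 || nx > d[1] || ny > d[2] || nz > d[3]) next
        pn <- pos[nx, ny, nz]
        if (pn != 0L && lab_v[pn] == 0L) {
          lab_v[pn] <- cur
          queue <- c(queue, pn)
        }
      }
    }
  }
  lab[idx] <- lab_v
  list(labels = lab, sizes = tabulate(lab_v, cur))
}

#' Voxel-wise cross-modality correlation with cluster-extent thresholds
#'
#' Per-voxel Pearson correlation across subjects between two image
#' modalities (e.g. tau DVR vs FDG SUVR), with parametric two-sided
#' p-values from the t transform. For each requested p threshold, positive
#' and negative correlations are masked separately and reduced to
#' 26-connected clusters of at least `cluster_extent` voxels.
#'
#' @param maps_a,maps_b Lists of aligned 3D arrays, same subjects in the
#'   same order, n >= 3.
#' @param p_thresholds Uncorrected p thresholds, default
#'   `c(0.001, 0.01, 0.05)`.
#' @param cluster_extent Minimum cluster size in voxels, default 20.
#' @param mask Optional logical 3D analysis mask.
#' @return List: `r` (3D), `p` (3D), `masks` (named list
#'   `p<thr`/sign -> logical 3D cluster-thresholded map) and `clusters`
#'   (data frame: threshold, sign, cluster_id, size_voxels, peak_r, and the
#'   0-based `peak_i`, `peak_j`, `peak_k` voxel indices).
#' @export
voxelwise_correlation <- function(maps_a, maps_b,
                                  p_thresholds = c(0.001, 0.01, 0.05),
                                  cluster_extent = 20, mask = NULL) {
  n <- length(maps_a)
  if (length(maps_b) != n) stop("modality lists must pair the same subjects")
  if (n < 3) stop("need >= 3 subjects")
  d <- dim(maps_a[[1]])
  A <- vapply(maps_a, as.vector, numeric(prod(d)))
  B <- vapply(maps_b, as.vector, numeric(prod(d)))
  if (is.null(mask)) mask <- array(TRUE, d)
  sel <- as.vector(mask != 0)
  cA <- A - rowMeans(A); cB <- B - rowMeans(B)
  num <- rowSums(cA * cB)
  den <- sqrt(rowSums(cA^2) * rowSums(cB^2))
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  r[!sel] <- NA_real_; p[!sel] <- NA_real_
  r_vol <- array(r, d); p_vol <- array(p, d)

  masks <- list(); clust_rows <- list()
  for (thr in p_thresholds) {
    for (sgn in c("positive", "negative")) {
      m <- !is.na(p_vol) & p_vol < thr &
        (if (sgn == "positive") r_vol > 0 else r_vol < 0)
      cc <- label_clusters(m, 26)
      keep_ids <- which(cc$sizes >= cluster_extent)
      keep <- array(cc$labels %in% keep_ids, d)
      masks[[sprintf("p<%g_%s", thr, sgn)]] <- keep
      for (id in keep_ids) {
        in_cl <- which(cc$labels == id)
        pk <- in_cl[which.max(abs(r_vol[in_cl]))]
        ijk <- arrayInd(pk, d) - 1L  # 0-based voxel indices
        clust_rows[[length(clust_rows) + 1L]] <- data.frame(
          threshold = thr, sign = sgn, cluster_id = id,
          size_voxels = cc$sizes[id], peak_r = r_vol[pk],
          peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3]
        )
      }
    }
  }
  clusters <- if (length(clust_rows)) {
    do.call(rbind, clust_rows)
  } else {
    data.frame(threshold = numeric(0), sign = character(0),
               cluster_id = integer(0), size_voxels = integer(0),
               peak_r = numeric(0), peak_i = integer(0),
               peak_j = integer(0), peak_k = integer(0))
  }
  list(r = r_vol, p = p_vol, masks = masks, clusters = clusters)
}

#' ROI-by-ROI Pearson correlation matrix between two quantifications
#'
#' Across the subjects shared by two ROI tables (e.g. tau DVR vs FDG
#' SUVR), computes the Pearson correlation and its two-sided p-value for
#' every pair of regions.
#'
#' @param table_a,table_b ROI tables as returned by [extract_roi_means()]
#'   (columns `subject_id`, `roi_name`, `value`).
#' @return List of matrices `r` and `p` (rows = regions of `table_a`,
#'   columns = regions of `table_b`) plus `n`, the number of shared
#'   subjects.
#' @export
roi_correlation_matrix <- function(table_a, table_b) {
  shared <- intersect(unique(table_a$subject_id), unique(table_b$subject_id))
  if (length(shared) < 3) stop("need >= 3 shared subjects")
  wide <- function(tab) {
    tab <- tab[tab$subject_id %in% shared, ]
    stats::xtabs(value ~ subject_id + roi_name, data = tab)[shared, , drop = FALSE]
  }
  A <- wide(table_a); B <- wide(table_b)
  r <- stats::cor(A, B)
  n <- length(shared)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, n = n)
}
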