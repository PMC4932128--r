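test_that("AUC equals exhaustive pair counting, with ties at one half", {
  # 4-vs-4 toy with one tied pair
  vals <- c(1.0, 1.2, 1.4, 1.6, 1.4, 1.7, 1.8, 1.9)
  labs <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  pairs <- expand.grid(p = which(labs), n = which(!labs))
  u <- sum(ifelse(vals[pairs$p] > vals[pairs$n], 1,
                  ifelse(vals[pairs$p] == vals[pairs$n], 0.5, 0)))
  expect_equal(roc_auc(vals, labs), u / 16)
  # perfectly separated groups
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  # label inversion: AUC -> 1 - AUC
  expect_equal(roc_auc(vals, !labs), 1 - roc_auc(vals, labs))
  # labels independent of values: chance level at large n
  set.seed(3)
  v <- rnorm(4000); l <- rep(c(TRUE, FALSE), 2000)
  expect_lt(abs(roc_auc(v, l) - 0.5), 0.03)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "classes")
})

test_that("rank tests flag nothing on identical groups and match enumeration", {
  set.seed(5)
  base <- rnorm(6)
  vals <- rep(base, 3); grp <- rep(c("a", "b", "c"), each = 6)
  roi <- rep("limbic", 18)
  res <- kruskal_mannwhitney(vals, grp, roi)
  expect_false(any(res$pairwise$significant))
  # corrected alpha for the 3-group x 2-ROI design prints as 0.008
  expect_equal(round(corrected_alpha(0.05, 3, 2), 3), 0.008)
  # tiny 3+3 instance: Mann-Whitney p equals exhaustive rank-permutation
  x <- c(1.1, 2.3, 3.1); y <- c(4.2, 5.0, 6.7)
  res2 <- kruskal_mannwhitney(c(x, y), rep(c("g1", "g2"), each = 3),
                              rep("r", 6))
  combs <- utils::combn(6, 3)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[1:3]) - 6
  u_all <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - 6)
  p_exh <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))  # two-sided, U symmetric about n1*n2/2
  expect_equal(res2$pairwise$mw_p, p_exh)
})

test_that("z-score maps flag one-sided abnormally high voxels", {
  d <- c(6, 6, 6)
  mu <- array(1, d); sdv <- array(0.1, d)
  same <- zscore_map(mu, mu, sdv)
  expect_equal(sum(same$abnormal), 0)
  high <- zscore_map(mu + 2 * sdv, mu, sdv, z_threshold = 1.96)
  expect_true(all(high$abnormal))
  # abnormally LOW values are never flagged (one-sided contract)
  low <- zscore_map(mu - 5 * sdv, mu, sdv)
  expect_equal(sum(low$abnormal), 0)
  # control-like subject: flagged fraction ~ 2.5 % one-sided
  set.seed(8)
  flagged <- replicate(40, {
    patient <- array(rnorm(prod(d), 1, 0.1), d)
    mean(zscore_map(patient, mu, sdv)$abnormal)
  })
  expect_lt(abs(mean(flagged) - 0.025), 0.005)
})

test_that("abnormality counts sum binary maps voxel-wise", {
  d <- c(5, 5, 5)
  zeros <- lapply(1:3, function(i) array(FALSE, d))
  expect_true(all(abnormality_count_map(zeros) == 0))
  ones <- lapply(1:4, function(i) array(TRUE, d))
  expect_true(all(abnormality_count_map(ones) == 4))
  set.seed(12)
  rnd <- lapply(1:5, function(i) array(runif(prod(d)) > 0.5, d))
  counts <- abnormality_count_map(rnd)
  expect_equal(counts[2, 3, 4], sum(vapply(rnd, function(m) m[2, 3, 4], logical(1))))
  expect_lte(max(counts), 5)
})

test_that("smoothing is an identity at fwhm 0 and delivers the requested width", {
  set.seed(2)
  vol <- array(rnorm(20^3), c(20, 20, 20))
  expect_identical(smooth_image(vol, 0, c(2, 2, 2)), vol)
  # delta input: measured FWHM of the impulse response within 5 %
  delta <- array(0, c(41, 41, 41)); delta[21, 21, 21] <- 1
  sm <- smooth_image(delta, 8, c(1, 1, 1))
  prof <- sm[, 21, 21]
  half <- max(prof) / 2
  above <- range(which(prof >= half))
  # sub-voxel interpolation of the half-maximum crossings
  lo <- above[1] - (prof[above[1]] - half) / (prof[above[1]] - prof[above[1] - 1])
  hi <- above[2] + (prof[above[2]] - half) / (prof[above[2]] - prof[above[2] + 1])
  expect_lt(abs((hi - lo) - 8) / 8, 0.05)
  expect_equal(sum(sm), 1, tolerance = 1e-6)  # kernel normalisation
  expect_error(smooth_image(vol, -2, 2), "fwhm")
})

test_that("permutation p-values match exhaustive enumeration at 3-vs-3", {
  set.seed(14)
  ga <- lapply(1:3, function(i) array(rnorm(6^3), c(6, 6, 6)))
  gb <- lapply(1:3, function(i) array(rnorm(6^3), c(6, 6, 6)))
  pt <- permutation_twosample(ga, gb, n_permutations = 500, seed = 1)
  expect_true(pt$exhaustive)
  expect_equal(pt$n_null, 20L)
  # manual enumeration at a handful of voxels
  tstat <- function(a, b) {
    sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
    (mean(a) - mean(b)) / (sp * sqrt(2 / 3))
  }
  combs <- utils::combn(6, 3)
  for (vox in c(1L, 57L, 200L)) {
    x <- vapply(c(ga, gb), function(v) v[vox], numeric(1))
    tn <- apply(combs, 2, function(ix) abs(tstat(x[ix], x[-ix])))
    expect_equal(pt$p[vox], mean(tn >= abs(tstat(x[1:3], x[4:6])) - 1e-9))
  }
  # p-values never reach 0 and the FDR mask is a subset of p < 0.05
  expect_true(all(pt$p > 0))
  expect_true(all(which(pt$significant) %in% which(pt$p < 0.05)))
})

test_that("an extreme group shift flags every in-mask voxel", {
  set.seed(15)
  ga <- lapply(1:5, function(i) array(rnorm(6^3), c(6, 6, 6)))
  gb <- lapply(1:5, function(i) array(rnorm(6^3) + 10, c(6, 6, 6)))
  pt <- permutation_twosample(ga, gb, n_permutations = 500, seed = 2)
  expect_true(all(pt$significant))
  expect_identical(pt$p,
                   permutation_twosample(ga, gb, 500, seed = 2)$p)  # seeded
})

test_that("voxel-wise correlation matches the direct formula and cluster extents gate blobs", {
  set.seed(16)
  d <- c(12, 12, 6)
  n <- 8
  maps_a <- lapply(1:n, function(i) array(rnorm(prod(d)), d))
  maps_b <- lapply(seq_len(n), function(i) maps_a[[i]] * 0.5 +
                     array(rnorm(prod(d), 0, 0.8), d))
  vc <- voxelwise_correlation(maps_a, maps_b, p_thresholds = 0.05,
                              cluster_extent = 1)
  # direct-formula oracle at 50 random voxels
  for (vox in sample(prod(d), 50)) {
    xa <- vapply(maps_a, function(m) m[vox], numeric(1))
    xb <- vapply(maps_b, function(m) m[vox], numeric(1))
    expect_equal(vc$r[vox], cor(xa, xb), tolerance = 1e-12)
    expect_equal(vc$p[vox], cor.test(xa, xb)$p.value, tolerance = 1e-9)
  }
  # identical modalities give r = 1 everywhere
  vc1 <- voxelwise_correlation(maps_a, maps_a, p_thresholds = 0.05,
                               cluster_extent = 1)
  expect_true(all(abs(vc1$r - 1) < 1e-12))

  # a 19-voxel blob dies at extent 20; a 20-voxel blob survives
  blob <- function(n_vox) {
    m <- array(0, d)
    m[seq_len(n_vox)] <- 1  # contiguous under 26-connectivity (column fill)
    m
  }
  for (nv in c(19, 20)) {
    sig <- blob(nv)
    a2 <- lapply(1:n, function(i) array(rnorm(prod(d), 0, 0.01), d) +
                   sig * (i / n))
    b2 <- lapply(1:n, function(i) array(rnorm(prod(d), 0, 0.01), d) +
                   sig * (i / n))
    vc2 <- voxelwise_correlation(a2, b2, p_thresholds = 0.001,
                                 cluster_extent = 20)
    keep <- vc2$masks[["p<0.001_positive"]]
    if (nv == 19) expect_equal(sum(keep), 0)
    else expect_gte(sum(keep), 20)
  }
})

test_that("ROI correlation matrices reduce to the direct covariance computation", {
  set.seed(17)
  subj <- sprintf("s%02d", 1:9)
  rois <- c("frontal_cortex", "temporal_cortex", "parietal_cortex")
  base <- matrix(rnorm(27), 9, 3, dimnames = list(subj, rois))
  tab_a <- data.frame(subject_id = rep(subj, 3),
                      roi_name = rep(rois, each = 9),
                      value = as.vector(base))
  tab_b <- tab_a
  tab_b$value <- -tab_a$value
  out <- roi_correlation_matrix(tab_a, tab_b)
  expect_equal(unname(diag(out$r)), rep(-1, 3), tolerance = 1e-12)
  out2 <- roi_correlation_matrix(tab_a, tab_a)
  expect_equal(out2$r["frontal_cortex", "temporal_cortex"],
               cor(base[, 1], base[, 2]), tolerance = 1e-12)
  expect_equal(out2$p["frontal_cortex", "temporal_cortex"],
               cor.test(base[, 1], base[, 2])$p.value, tolerance = 1e-9)
  tab_c <- tab_b
  tab_c$subject_id <- paste0("other_", tab_c$subject_id)
  expect_error(roi_correlation_matrix(tab_a, tab_c), "shared")
})
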