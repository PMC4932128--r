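test_that("pure-WM estimate is exact on unblurred phantoms", {
  ph <- slab_phantom(gm_value = 1, wm_value = 2)
  expect_equal(estimate_wm_value(array(5, dim(ph$vol)), ph$wm,
                                 pvc_config(wm_erosion_mm = 4),
                                 voxel_mm = c(2, 2, 2)), 5)
  expect_equal(estimate_wm_value(ph$vol, ph$wm,
                                 pvc_config(wm_erosion_mm = 4),
                                 voxel_mm = c(2, 2, 2)), 2)
  expect_error(estimate_wm_value(ph$vol, ph$wm,
                                 pvc_config(wm_erosion_mm = 40),
                                 voxel_mm = c(2, 2, 2)), "erosion")
})

test_that("erosion uses true Euclidean depth", {
  m <- array(FALSE, c(15, 15, 15)); m[3:13, 3:13, 3:13] <- TRUE
  # "at least 2 mm deep": face voxels (1 mm from background) go, the
  # second layer (exactly 2 mm) stays
  e <- taupet:::erode_mask(m, 2, c(1, 1, 1))
  expect_equal(sum(e), 9^3)
  # distances: centre of an 11-cube is 6 voxels from background (5 inside + 1)
  d <- taupet:::distance_to_background_mm(m, c(1, 1, 1))
  expect_equal(d[8, 8, 8], 6)
  expect_equal(d[3, 8, 8], 1)
  expect_equal(d[1, 1, 1], 0)
})

test_that("Mueller-Gartner with a delta PSF inverts the mixing identity", {
  ph <- slab_phantom(gm_value = 1.4, wm_value = 1.0)
  cfg <- pvc_config(psf_fwhm_mm = 0, gm_threshold = 0.3, wm_erosion_mm = 4)
  corr <- muller_gartner(ph$vol, ph$gm, ph$wm, cfg, voxel_mm = c(2, 2, 2))
  # pure-GM voxel: corrected equals the observed value
  expect_equal(corr[5, 10, 10], 1.4)
  # gm = 0 voxel is masked, never a division blow-up
  expect_true(is.na(corr[14, 10, 10]))
  expect_true(all(is.finite(corr[ph$gm >= 0.3])))
  expect_error(muller_gartner(ph$vol, array(0, dim(ph$vol)), ph$wm, cfg),
               "GM map")
})

test_that("Mueller-Gartner restores GM values under an 8-mm PSF", {
  sc <- default_phantom_scene(dim = c(32, 32, 32))
  truth <- 1.4 * sc$gm_map + 1.0 * sc$wm_map
  blurred <- smooth_image(truth, 8, sc$voxel_mm)
  cfg <- pvc_config(psf_fwhm_mm = 8, wm_erosion_mm = 6)
  cwm <- estimate_wm_value(blurred, sc$wm_map, cfg, sc$voxel_mm)
  expect_lt(abs(cwm - 1.0), 0.02)  # within 2 % of the true WM value
  corr <- muller_gartner(blurred, sc$gm_map, sc$wm_map, cfg,
                         voxel_mm = sc$voxel_mm)
  gm_vox <- sc$gm_map >= 0.99
  expect_lt(abs(mean(corr[gm_vox], na.rm = TRUE) - 1.4) / 1.4, 0.03)
})

test_that("correction is linear and widens the ROI dynamic range", {
  dvr <- c(frontal_cortex = 1.35, temporal_cortex = 1.25,
           parietal_cortex = 1.15, occipital_cortex = 1.05)
  sc <- default_phantom_scene(dim = c(32, 32, 32), region_dvr = dvr)
  atlas <- scene_atlas(sc)
  truth_vol <- array(0, dim(sc$atlas))
  for (l in names(sc$region_params)) {
    w <- if (sc$region_tissue[[l]] == "wm") sc$wm_map else sc$gm_map
    truth_vol <- truth_vol + (sc$atlas == as.integer(l)) * w *
      sc$region_params[[l]]$dvr
  }
  blurred <- smooth_image(truth_vol, 8, sc$voxel_mm)
  cfg <- pvc_config(psf_fwhm_mm = 8, wm_erosion_mm = 6)
  corr <- muller_gartner(blurred, sc$gm_map, sc$wm_map, cfg,
                         voxel_mm = sc$voxel_mm)
  roi_unc <- suppressWarnings(extract_roi_means(blurred, atlas))
  roi_cor <- suppressWarnings(extract_roi_means(corr, atlas))
  iso <- c("frontal_cortex", "temporal_cortex", "parietal_cortex",
           "occipital_cortex")
  unc <- roi_unc$value[match(iso, roi_unc$roi_name)]
  cor_ <- roi_cor$value[match(iso, roi_cor$roi_name)]
  # corrected values exceed uncorrected where GM is hotter than WM,
  # and span a wider range across regions
  expect_true(all(cor_[1:3] > unc[1:3]))
  expect_gt(diff(range(cor_)), diff(range(unc)))
  # linearity: scaling image and C_WM scales the correction
  corr2 <- muller_gartner(2 * blurred, sc$gm_map, sc$wm_map, cfg,
                          c_wm = 2 * attr(corr, "c_wm"),
                          voxel_mm = sc$voxel_mm)
  expect_equal(corr2, 2 * corr, tolerance = 1e-12, ignore_attr = TRUE)
})
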