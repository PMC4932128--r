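sch <- thk_frame_schedule()

test_that("frame averaging is duration-weighted with partial overlaps", {
  d <- c(4, 4, 4)
  vals <- seq_len(22)
  dat <- array(rep(vals, each = prod(d)), c(d, 22))
  dyn <- structure(list(data = dat, schedule = sch, voxel_mm = c(2, 2, 2)),
                   class = "dynamic_image")
  # constant image: any window returns the constant
  const <- structure(list(data = array(3, c(d, 22)), schedule = sch,
                          voxel_mm = c(2, 2, 2)), class = "dynamic_image")
  expect_equal(unique(as.vector(frame_average(const, c(7, 41)))), 3)
  # window covering exactly the last three 600-s frames: equal weights
  expect_equal(frame_average(dyn, c(30, 60))[1, 1, 1], mean(20:22))
  # brute-force fine-grid oracle for a partial-overlap window
  w <- c(8.4, 47.2)
  fine_t <- seq(w[1], w[2], by = 1 / 600)
  fidx <- findInterval(fine_t * 60, sch$start_s, rightmost.closed = TRUE)
  expect_equal(frame_average(dyn, w)[1, 1, 1], mean(vals[fidx]),
               tolerance = 1e-3)
  expect_error(frame_average(dyn, c(70, 80)), "within|overlap|frame")
})

test_that("Logan DVR is exact for identity and recovers SRTM ground truth", {
  ref <- simulate_reference_tac(20, 10, sch)
  f <- logan_dvr(ref, ref)
  expect_equal(f$dvr, 1, tolerance = 1e-6)
  expect_equal(f$intercept, 0, tolerance = 1e-6)
  # the documented slow-efflux example
  tgt <- simulate_target_tac(kinetic_params(R1 = 1, k2 = 0.1, dvr = 1.5),
                             sch, 20, 10)
  expect_lt(abs(logan_dvr(tgt, ref, c(30, 60))$dvr - 1.5) / 1.5, 0.02)
  # sweep at the phantom's default efflux rate
  for (dvr_true in c(1.0, 1.25, 1.5, 2.0)) {
    tgt <- simulate_target_tac(kinetic_params(R1 = 1, k2 = 0.15,
                                              dvr = dvr_true), sch, 20, 10)
    est <- logan_dvr(tgt, ref, c(30, 60))$dvr
    expect_lt(abs(est - dvr_true) / dvr_true, 0.02)
  }
})

test_that("Logan slope scales with the target and is invariant to common rescaling", {
  ref <- simulate_reference_tac(20, 10, sch)
  tgt <- simulate_target_tac(kinetic_params(R1 = 1, k2 = 0.1, dvr = 1.5),
                             sch, 20, 10)
  base <- logan_dvr(tgt, ref)$dvr
  tgt3 <- tgt; tgt3$value <- 3 * tgt$value
  expect_equal(logan_dvr(tgt3, ref)$dvr, 3 * base, tolerance = 1e-9)
  # common rescaling of target and reference leaves DVR unchanged
  ref3 <- ref; ref3$value <- 3 * ref$value
  expect_equal(logan_dvr(tgt3, ref3)$dvr, base, tolerance = 1e-9)
})

test_that("Logan rejects bad windows and drops non-positive frames", {
  ref <- simulate_reference_tac(20, 10, sch)
  expect_error(logan_dvr(ref, ref, c(30, 90)), "scan span")
  tgt <- simulate_target_tac(kinetic_params(dvr = 1.2), sch, 20, 10)
  tgt$value[21] <- -1  # corrupt one in-window frame
  f <- logan_dvr(tgt, ref, c(30, 60))
  expect_equal(f$n_dropped, 1L)
  expect_equal(f$n_points_used, 2L)
})

test_that("voxel-wise Logan equals the ROI-level fit and recovers the phantom", {
  sc <- tiny_scene(region_dvr = c(frontal_cortex = 1.3, temporal_cortex = 1.15))
  img <- render_dynamic_image(sc, sch, 0, 0)
  ref_mask <- sc$atlas == 1L
  dvr_map <- logan_dvr_image(img, ref_mask, mask = sc$atlas != 0L)
  expect_equal(attr(dvr_map, "n_failed"), 0L)
  for (lab in c(3L, 4L, 8L)) {
    truth <- sc$region_params[[as.character(lab)]]$dvr
    expect_lt(abs(mean(dvr_map[sc$atlas == lab]) - truth) / truth, 0.02)
    # ROI-TAC-first route agrees with the map's ROI mean within 1 %
    roi_fit <- logan_dvr(extract_tac(img, sc$atlas == lab),
                         extract_tac(img, ref_mask))$dvr
    expect_lt(abs(mean(dvr_map[sc$atlas == lab]) - roi_fit) / roi_fit, 0.01)
  }
  # an image whose every voxel equals the reference TAC maps to DVR 1
  flat <- img
  ref_tac <- extract_tac(img, ref_mask)
  flat$data <- array(rep(ref_tac$value, each = prod(dim(sc$atlas))),
                     dim(img$data))
  flat_map <- logan_dvr_image(flat, ref_mask)
  expect_equal(range(flat_map), c(1, 1), tolerance = 1e-9)
  expect_error(logan_dvr_image(img, array(FALSE, dim(sc$atlas))), "empty")
})

test_that("SUV arithmetic follows its definition", {
  vol <- array(2, c(3, 3, 3))
  expect_equal(suv_image(vol, dose_MBq = 100, weight_kg = 50)[1, 1, 1], 1)
  expect_equal(suv_image(vol, 100, 100), 2 * suv_image(vol, 100, 50))
  expect_error(suv_image(vol, NA, 50), "dose")
  expect_error(suv_image(vol, 100, -3), "weight")
})

test_that("SUVR normalises by the reference mean and classifies amyloid", {
  vol <- array(2, c(4, 4, 4))
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, , ] <- TRUE
  expect_equal(unique(as.vector(suvr_image(vol, mask))), 1)
  vol[3, 1, 1] <- 3.0
  expect_equal(suvr_image(vol, mask)[3, 1, 1], 1.5, tolerance = 1e-6)
  # reference region itself averages to 1 by construction
  out <- suvr_image(vol, mask)
  expect_equal(mean(out[mask]), 1, tolerance = 1e-6)
  expect_error(suvr_image(-vol, mask), "positive")
  expect_true(classify_amyloid(1.42))
  expect_false(classify_amyloid(1.41))
  expect_false(classify_amyloid(1.30))
})
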