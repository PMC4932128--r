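sch <- thk_frame_schedule()

test_that("reference TAC frame values match fine-grid numerical averaging", {
  tac <- simulate_reference_tac(1, 10, sch)
  fine <- vapply(seq_len(nrow(sch)), function(i) {
    tt <- seq(sch$start_s[i], sch$start_s[i] + sch$duration_s[i], by = 0.1) / 60
    mean(tt * exp(-tt / 10))
  }, numeric(1))
  expect_lt(max(abs(tac$value - fine) / pmax(fine, 1e-12)), 1e-3)  # 0.1 %
})

test_that("reference TAC degenerate and shape properties hold", {
  expect_equal(simulate_reference_tac(0, 10, sch)$value, rep(0, 22))
  expect_error(simulate_reference_tac(-1, 10, sch), "amplitude")
  expect_error(simulate_reference_tac(1, 0, sch), "tau")
  # peak of t*exp(-t/tau) at t = tau: on a fine schedule the frame holding
  # tau is maximal
  fine_sch <- frame_schedule(rep(30, 120))  # 0.5-min frames over 60 min
  tac <- simulate_reference_tac(5, 10, fine_sch)
  expect_equal(findInterval(10, fine_sch$start_s / 60),
               which.max(tac$value))
})

test_that("SRTM forward model matches a brute-force convolution oracle", {
  p <- kinetic_params(R1 = 1, k2 = 0.1, bp_nd = 0.5)
  k2a <- 0.1 / 1.5
  tg <- seq(0, 60, by = 0.01)
  cr <- 20 * tg * exp(-tg / 10)
  conv <- convolve(cr, rev(exp(-k2a * tg)), type = "open")[seq_along(tg)] * 0.01
  ct_oracle <- p$R1 * cr + (p$k2 - p$R1 * k2a) * conv
  ct <- taupet:::srtm_curve(tg, p, 20, 10)
  sel <- tg > 1
  expect_lt(max(abs(ct - ct_oracle)[sel] / ct_oracle[sel]), 5e-3)  # 0.5 %
})

test_that("SRTM degenerate case R1=1, bp=0 reproduces the reference", {
  tgt <- simulate_target_tac(kinetic_params(R1 = 1, k2 = 0.1, bp_nd = 0),
                             sch, 20, 10)
  ref <- simulate_reference_tac(20, 10, sch)
  expect_equal(tgt$value, ref$value, tolerance = 1e-4)
  expect_true(all(tgt$value >= 0))
  expect_error(kinetic_params(k2 = -1), "k2")
  expect_error(kinetic_params(dvr = 0.5), "dvr")
})

test_that("rendering without blur or noise reproduces regional TACs exactly", {
  sc <- tiny_scene(region_dvr = c(frontal_cortex = 1.3))
  img <- render_dynamic_image(sc, sch, psf_fwhm_mm = 0, noise_scale = 0)
  tacs <- taupet:::scene_region_tacs(sc, sch)
  for (lab in c(1L, 3L, 4L)) {
    vox <- which(sc$atlas == lab)[1]
    got <- vapply(seq_len(22), function(fr) img$data[, , , fr][vox], numeric(1))
    expect_equal(got, unname(tacs[as.character(lab), ]), tolerance = 1e-12)
  }
})

test_that("rendering is linear and blurring conserves total activity", {
  sc <- tiny_scene()
  img1 <- render_dynamic_image(sc, sch, 0, 0)
  sc2 <- sc
  sc2$ref_amplitude <- 2 * sc$ref_amplitude  # doubles every regional TAC
  img2 <- render_dynamic_image(sc2, sch, 0, 0)
  expect_equal(img2$data, 2 * img1$data, tolerance = 1e-12)

  blurred <- render_dynamic_image(sc, sch, psf_fwhm_mm = 6, noise_scale = 0)
  f <- 20
  expect_equal(sum(blurred$data[, , , f]), sum(img1$data[, , , f]),
               tolerance = 0.02)
})

test_that("the same seed renders bit-identical images and different seeds differ", {
  sc <- tiny_scene(dim = c(10, 10, 10))
  a <- render_dynamic_image(sc, sch, 0, 1, seed = 42)
  b <- render_dynamic_image(sc, sch, 0, 1, seed = 42)
  c <- render_dynamic_image(sc, sch, 0, 1, seed = 43)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("noise SD across repeated seeds follows the declared model", {
  sc <- tiny_scene(dim = c(10, 10, 10))
  clean <- render_dynamic_image(sc, sch, 0, 0)
  frame <- 20  # a 300-s frame
  vox <- which(sc$atlas == 4L)[1]
  vals <- vapply(seq_len(1000), function(i) {
    render_dynamic_image(sc, sch, 0, noise_scale = 1,
                         seed = 10000L + i)$data[, , , frame][vox]
  }, numeric(1))
  expected_sd <- sqrt(clean$data[, , , frame][vox]) /
    sqrt(sch$duration_s[frame] / 60)
  expect_lt(abs(sd(vals) - expected_sd) / expected_sd, 0.10)
})

test_that("cohort draws respect group means and the truncation at 1", {
  grp <- list(A = list(n = 20, dvr = c(frontal_cortex = 1.3), dvr_sd = 0.05),
              B = list(n = 2, dvr = c(frontal_cortex = 1.0), dvr_sd = 0))
  cfg <- cohort_config(grp, dim = c(10, 10, 10), psf_fwhm_mm = 0,
                       noise_scale = 0, seed = 11)
  coh <- make_cohort(cfg)
  expect_equal(nrow(coh$manifest), 22L)
  truths <- vapply(coh$subjects[1:20], function(s)
    s$truth[["frontal_cortex"]], numeric(1))
  se <- 0.05 / sqrt(20)
  expect_lt(abs(mean(truths) - 1.3), 3 * se)
  expect_true(all(truths >= 1))
  # SD = 0 group: every subject's truth equals the configured mean
  b_truths <- vapply(coh$subjects[21:22], function(s)
    s$truth[["frontal_cortex"]], numeric(1))
  expect_equal(unname(b_truths), c(1, 1))
  expect_error(cohort_config(list()), "group")
})
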