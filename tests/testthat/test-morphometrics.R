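test_that("noiseless synthetic eyes reproduce their configured truth exactly", {
  cases <- list(
    list(tilt = 3.4, rot = 36.7, ov = 0.85),
    list(tilt = 1.7, rot = 36.1, ov = 0.88),
    list(tilt = 12.5, rot = 72.4, ov = 0.82),
    list(tilt = 0.4, rot = 5, ov = 0.95)
  )
  for (cs in cases) {
    eye <- noiseless_eye(cs$tilt, cs$rot, cs$ov)
    m <- compute_bmo_morphometrics(eye$scans)
    expect_equal(m$tilt_deg, cs$tilt, tolerance = 1e-6)
    expect_equal(m$rotation_deg, cs$rot, tolerance = 1e-6)
    expect_equal(m$ovality_index, cs$ov, tolerance = 1e-6)
    expect_equal(m$bmo_area_mm2, eye$truth$bmo_area_mm2, tolerance = 1e-6)
  }
})

test_that("a flat circular opening gives zero tilt and ovality one", {
  eye <- noiseless_eye(tilt = 0, rot = 0, ovality = 1)
  m <- compute_bmo_morphometrics(eye$scans)
  expect_equal(m$tilt_deg, 0, tolerance = 1e-7)
  expect_equal(m$ovality_index, 1, tolerance = 1e-7)
  expect_true(m$rotation_circular)
  expect_equal(m$rotation_deg, 0)
})

test_that("recovered tilt is unbiased under measurement noise", {
  p <- synthetic_eye_params(true_tilt_deg = 3.4, true_rotation_deg = 36.7,
                            true_ovality = 0.85, point_noise_sd_um = 5)
  tilt <- vapply(1:150, function(i) {
    compute_bmo_morphometrics(simulate_eye(p, seed = i)$scans)$tilt_deg
  }, numeric(1))
  expect_lt(abs(mean(tilt) - 3.4), 0.1)
})

test_that("morphometrics are scale invariant (area quadratic) and", {
  eye <- noiseless_eye(4.2, 55, 0.8)
  m1 <- compute_bmo_morphometrics(eye$scans)
  m2 <- compute_bmo_morphometrics(scale_scan_set(eye$scans, 1.7))
  expect_equal(m2$tilt_deg, m1$tilt_deg, tolerance = 1e-6)
  expect_equal(m2$ovality_index, m1$ovality_index, tolerance = 1e-6)
  expect_equal(m2$rotation_deg, m1$rotation_deg, tolerance = 1e-6)
  expect_equal(m2$bmo_area_mm2, 1.7^2 * m1$bmo_area_mm2, tolerance = 1e-6)
})

test_that("en-face rotation with matching FoBMO shift leaves rotation fixed", {
  # untilted opening: the reference plane is en-face and equivariance is exact
  flat <- noiseless_eye(0, 55, 0.8)
  f1 <- compute_bmo_morphometrics(flat$scans)
  f2 <- compute_bmo_morphometrics(rotate_scan_set(flat$scans, 23,
                                                  shift = c(0, 0, 140)))
  expect_equal(f2$rotation_deg, f1$rotation_deg, tolerance = 1e-6)

  # tilted opening: the in-plane axis convention distorts en-face angles at
  # second order in the tilt, so equivariance holds to within that distortion
  eye <- noiseless_eye(4.2, 55, 0.8)
  m1 <- compute_bmo_morphometrics(eye$scans)
  m2 <- compute_bmo_morphometrics(rotate_scan_set(eye$scans, 23,
                                                  shift = c(0, 0, 140)))
  expect_equal(m2$rotation_deg, m1$rotation_deg, tolerance = 0.005)
  expect_equal(m2$ovality_index, m1$ovality_index, tolerance = 1e-6)
  expect_equal(m2$bmo_area_mm2, m1$bmo_area_mm2, tolerance = 1e-6)
  expect_equal(m2$tilt_deg, m1$tilt_deg, tolerance = 1e-5)
})

test_that("OS eyes yield the same morphometrics as their OD mirror", {
  for (seed in c(3, 9)) {
    pod <- synthetic_eye_params(true_tilt_deg = 3.1, true_rotation_deg = 28,
                                true_ovality = 0.86, laterality = "OD",
                                point_noise_sd_um = 0, boundary_noise_sd_um = 0)
    pos <- synthetic_eye_params(true_tilt_deg = 3.1, true_rotation_deg = 28,
                                true_ovality = 0.86, laterality = "OS",
                                point_noise_sd_um = 0, boundary_noise_sd_um = 0)
    mod <- compute_bmo_morphometrics(simulate_eye(pod, seed = seed)$scans)
    mos <- compute_bmo_morphometrics(simulate_eye(pos, seed = seed)$scans)
    expect_equal(mos$ovality_index, mod$ovality_index, tolerance = 1e-6)
    expect_equal(mos$tilt_deg, mod$tilt_deg, tolerance = 1e-6)
    expect_equal(mos$rotation_deg, mod$rotation_deg, tolerance = 1e-6)
    expect_equal(mos$bmo_area_mm2, mod$bmo_area_mm2, tolerance = 1e-6)
  }
})

test_that("morphometric outputs respect their ranges on noisy eyes", {
  p <- synthetic_eye_params(point_noise_sd_um = 20)
  for (i in 1:25) {
    m <- compute_bmo_morphometrics(simulate_eye(p, seed = i)$scans)
    expect_gt(m$ovality_index, 0); expect_lte(m$ovality_index, 1)
    expect_gte(m$tilt_deg, 0); expect_lte(m$tilt_deg, 90)
    expect_gte(m$rotation_deg, 0); expect_lte(m$rotation_deg, 90)
    expect_gt(m$bmo_area_mm2, 0)
  }
})

test_that("quality gate rejects low-quality scan sets", {
  eye <- simulate_eye(synthetic_eye_params(quality_score_db = 10), seed = 1)
  expect_error(compute_bmo_morphometrics(eye$scans), "quality score",
               class = "onhmorph_validation_error")
  expect_silent(compute_bmo_morphometrics(eye$scans, quality_threshold_db = -Inf))
})

test_that("cross-validation tilt equals the primary tilt on planar membranes", {
  eye <- noiseless_eye(3.4, 36.7, 0.85)
  m <- compute_bmo_morphometrics(eye$scans)
  expect_equal(crossval_tilt(eye$scans), m$tilt_deg, tolerance = 1e-6)

  flat <- noiseless_eye(0, 10, 0.9)
  expect_equal(crossval_tilt(flat$scans), 0, tolerance = 1e-7)

  expect_error(crossval_tilt(eye$scans, ring_um = 4000),
               class = "onhmorph_range_error")
})
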