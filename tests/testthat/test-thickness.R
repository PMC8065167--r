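make_profile <- function(n = 768, fobmo = 0, lat = "OD",
                         rnfl = function(psi) rep(67.5, length(psi)),
                         pct = function(psi) rep(109.8, length(psi)),
                         bm = function(ang) rep(400, length(ang))) {
  ang <- (0:(n - 1)) * 360 / n
  psi <- (ang - fobmo) %% 360
  circle_scan_profile("t", lat, fobmo, ang,
                      ilm = rep(150, n),
                      rnfl_posterior = 150 + rnfl(psi),
                      bm_posterior = bm(ang),
                      choroid_posterior = bm(ang) + pct(psi))
}

test_that("sectorize partitions the circle and averages members", {
  s <- sectorize(rep(5.5, 360), 0:359)
  expect_equal(s$global_um, 5.5)
  expect_equal(unname(s$sectors_um), rep(5.5, 6))
  expect_equal(sum(s$n), 360)
  expect_equal(unname(s$n), c(90, 40, 40, 110, 40, 40))

  # indicator profile on [50, 80): brute-force membership oracle
  vals <- as.numeric(0:359 >= 50 & 0:359 < 80)
  s2 <- sectorize(vals, 0:359)
  oracle <- brute_sector_means(vals, 0:359)
  expect_equal(s2$sectors_um, oracle, tolerance = 1e-12)
  expect_equal(unname(s2$sectors_um["ST"]), 30 / 40)
})

test_that("sector means match the brute-force oracle with FoBMO offsets", {
  set.seed(5)
  for (fobmo in c(-7, 0, 13.2)) {
    ang <- (0:767) * 360 / 768
    vals <- runif(768, 40, 110)
    s <- sectorize(vals, ang, fobmo_deg = fobmo)
    expect_equal(s$sectors_um, brute_sector_means(vals, ang - fobmo),
                 tolerance = 1e-12)
    # global is the count-weighted mean of sector means
    expect_equal(s$global_um, sum(s$sectors_um * s$n) / sum(s$n),
                 tolerance = 1e-12)
  }
})

test_that("quality filter excludes strictly below threshold", {
  expect_false(as.logical(quality_filter(14.9)))
  expect_true(as.logical(quality_filter(15.0)))
  expect_true(as.logical(quality_filter(25)))
  expect_match(attr(quality_filter(10), "reason"), "quality score")
})

test_that("MRW is the shortest distance from BMO point to the ILM polyline", {
  # flat ILM 200 um directly anterior, laid along each scan's own direction
  flat <- noiseless_eye(tilt = 0, rot = 0, ovality = 1)
  fscans <- flat$scans
  for (i in seq_along(fscans$scans)) {
    phi <- fscans$scans[[i]]$scan_angle_deg * pi / 180
    s <- seq(-2000, 2000, length.out = 41)
    fscans$scans[[i]]$ilm <- cbind(s * cos(phi), s * sin(phi), -200)
  }
  mrw <- compute_mrw(fscans)
  expect_equal(unname(mrw$values$mrw_um), rep(200, 48), tolerance = 1e-9)
  expect_equal(mrw$summary$global_um, 200, tolerance = 1e-9)

  # an ILM inclined at 45 deg through the flat case's closest point is nearer
  # than the vertical offset: shortest distance <= any fixed-direction distance
  s1 <- normalize_laterality(flat$scans)$scans[[1]]
  p <- s1$bmo[1, ]
  s <- seq(-1500, 1500, length.out = 301)
  incl <- cbind(p[1] + s, p[2], p[3] - 200 + s)
  d <- onhmorph:::point_polyline_distance(p, incl)
  expect_equal(d, 200 / sqrt(2), tolerance = 1e-9)
  expect_lt(d, 200)
})

test_that("MRW matches a dense brute-force sampling oracle on a curve", {
  # one synthetic eye; oracle: 1e5 points sampled along each ILM polyline
  eye <- noiseless_eye()
  scans <- normalize_laterality(eye$scans)
  s <- scans$scans[[5]]
  for (i in 1:2) {
    p <- s$bmo[i, ]
    seg <- s$ilm
    t <- seq(0, 1, length.out = ceiling(1e5 / (nrow(seg) - 1)))
    dmin <- Inf
    for (j in seq_len(nrow(seg) - 1)) {
      pts <- outer(1 - t, seg[j, ]) + outer(t, seg[j + 1, ])
      dmin <- min(dmin, sqrt(min(colSums((t(pts) - p)^2))))
    }
    direct <- onhmorph:::point_polyline_distance(p, seg)
    expect_equal(direct, dmin, tolerance = 0.1)
  }
})

test_that("RNFL thickness is the ILM-to-posterior separation per A-scan", {
  s <- compute_rnfl_thickness(make_profile())
  expect_equal(s$global_um, 67.5, tolerance = 1e-9)
  expect_equal(unname(s$sectors_um), rep(67.5, 6), tolerance = 1e-9)

  z <- compute_rnfl_thickness(make_profile(rnfl = function(psi) rep(0, length(psi))))
  expect_equal(z$global_um, 0)

  expect_error(
    circle_scan_profile("t", "OD", 0, c(0, 90, 180, 270, 300, 350),
                        ilm = rep(10, 6), rnfl_posterior = rep(5, 6),
                        bm_posterior = rep(20, 6), choroid_posterior = rep(30, 6)),
    class = "onhmorph_segmentation_error")
})

test_that("choroidal thickness handles flat, empty and inclined membranes", {
  flat <- compute_pct(make_profile())
  expect_equal(flat$global_um, 109.8, tolerance = 1e-9)

  zero <- compute_pct(make_profile(pct = function(psi) rep(0, length(psi))))
  expect_equal(zero$global_um, 0)

  # membrane inclined at a constant slope in the unrolled plane with uniform
  # axial separation d: normal-mode PCT = d * cos(phi) away from endpoints
  n <- 768; r <- 1750
  ang <- (0:(n - 1)) * 360 / n
  arc <- ang * pi / 180 * r
  slope <- 0.4
  phi <- atan(slope)
  prof <- circle_scan_profile("t", "OD", 0, ang, ilm = rep(0, n),
                              rnfl_posterior = rep(10, n),
                              bm_posterior = 100 + slope * arc,
                              choroid_posterior = 100 + slope * arc + 80)
  s <- compute_pct(prof)
  # interior A-scans follow the closed form exactly; the circular profile has
  # a seam at the endpoints where one-sided differences apply
  sep <- 80 * cos(phi)
  interior <- sectorize(rep(sep, n), ang)
  expect_equal(s$sectors_um[c("ST", "SN", "N", "IN", "IT")],
               interior$sectors_um[c("ST", "SN", "N", "IN", "IT")],
               tolerance = 1e-6)
  axial <- compute_pct(prof, mode = "axial")
  expect_equal(axial$global_um, 80, tolerance = 1e-9)
})

test_that("mirrored OS profiles give identical sector summaries", {
  rnfl_fun <- function(psi) 60 + 25 * sin(psi * pi / 180) + 10 * cos(2 * psi * pi / 180)
  od <- make_profile(fobmo = -7, rnfl = rnfl_fun)
  eye_os <- simulate_eye(synthetic_eye_params(laterality = "OS",
                                              rnfl_profile_um = rnfl_fun,
                                              point_noise_sd_um = 0,
                                              boundary_noise_sd_um = 0), seed = 1)
  eye_od <- simulate_eye(synthetic_eye_params(laterality = "OD",
                                              rnfl_profile_um = rnfl_fun,
                                              point_noise_sd_um = 0,
                                              boundary_noise_sd_um = 0), seed = 1)
  sos <- compute_rnfl_thickness(eye_os$circle)
  sod <- compute_rnfl_thickness(eye_od$circle)
  expect_equal(sos$sectors_um, sod$sectors_um, tolerance = 1e-9)
  expect_equal(sos$global_um, sod$global_um, tolerance = 1e-9)
  mos <- compute_mrw(eye_os$scans)
  mod <- compute_mrw(eye_od$scans)
  expect_equal(mos$summary$sectors_um, mod$summary$sectors_um, tolerance = 1e-6)
})

test_that("sector means are stable under A-scan refinement", {
  smooth <- function(psi) 100 + 30 * sin(psi * pi / 180)
  s1 <- compute_rnfl_thickness(make_profile(n = 768, rnfl = smooth))
  s2 <- compute_rnfl_thickness(make_profile(n = 1536, rnfl = smooth))
  expect_true(all(abs(s1$sectors_um - s2$sectors_um) <= 0.5))
  # and the global mean of a smooth profile approaches its circular integral
  integral <- integrate(function(x) smooth(x) / 360, 0, 360,
                        subdivisions = 1000)$value
  expect_lt(abs(s2$global_um - integral), 0.1)
})
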