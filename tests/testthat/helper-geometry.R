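# Shared fixtures, built in code.

# Points on an ellipse (optionally rotated), n uniform parameter angles.
ellipse_points <- function(a, b, angle_deg = 0, n = 48, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- angle_deg * pi / 180
  x <- a * cos(t)
  y <- b * sin(t)
  cbind(center[1] + x * cos(th) - y * sin(th),
        center[2] + x * sin(th) + y * cos(th))
}

# A noiseless synthetic eye with the given truths.
noiseless_eye <- function(tilt = 3.4, rotation = 36.7, ovality = 0.85, ...) {
  simulate_eye(synthetic_eye_params(
    true_tilt_deg = tilt, true_rotation_deg = rotation, true_ovality = ovality,
    point_noise_sd_um = 0, boundary_noise_sd_um = 0, ...), seed = 1)
}

# Independent orthogonal-regression plane oracle: SVD of centered points.
svd_plane_oracle <- function(points) {
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))
  n <- sv$v[, 3]
  if (n[3] < 0) n <- -n
  list(centroid = ctr, normal = n)
}

# Brute-force Garway-Heath membership oracle (independent of gh_sector_of).
brute_sector_means <- function(values, psi) {
  psi <- psi %% 360
  sec <- character(length(psi))
  for (i in seq_along(psi)) {
    p <- psi[i]
    sec[i] <-
      if (p >= 315 || p < 45) "T"
      else if (p < 85) "ST"
      else if (p < 125) "SN"
      else if (p < 235) "N"
      else if (p < 275) "IN"
      else "IT"
  }
  vapply(c("T", "ST", "SN", "N", "IN", "IT"),
         function(s) mean(values[sec == s]), numeric(1))
}

# Apply an en-face rotation (about z) plus translation to every point of a
# radial scan set, adjusting fobmo by the same rotation.
rotate_scan_set <- function(scans, delta_deg, shift = c(0, 0, 0)) {
  th <- delta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  scans$scans <- lapply(scans$scans, function(s) {
    s$bmo <- sweep(s$bmo %*% t(R), 2, shift, "+")
    s$bmb <- sweep(s$bmb %*% t(R), 2, shift, "+")
    s$ilm <- sweep(s$ilm %*% t(R), 2, shift, "+")
    s
  })
  scans$fobmo_deg <- scans$fobmo_deg + delta_deg
  scans
}

# Tempfile cleaned up when the calling test finishes.
withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), paste0(sample.int(1e9, 1), "-", name))
  withr::defer(unlink(path), envir = env)
  path
}

scale_scan_set <- function(scans, k) {
  scans$scans <- lapply(scans$scans, function(s) {
    s$bmo <- s$bmo * k; s$bmb <- s$bmb * k; s$ilm <- s$ilm * k; s
  })
  scans
}
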