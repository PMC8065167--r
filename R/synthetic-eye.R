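# Synthetic scan-geometry generator. Emulates the segmented geometry an OCT
# radial-circle acquisition yields for one eye -- 24 radial B-scans with two
# BMO and two Bruch's-membrane-boundary points each plus an ILM polyline, and
# one 3.5 mm circle-scan boundary profile -- with known ground truth for every
# downstream metric.

#' Parameters of a synthetic eye
#'
#' Ground-truth morphometrics and thickness profiles for [simulate_eye()].
#' Thickness profiles (`mrw_profile`, `rnfl_profile_um`, `choroid_profile_um`)
#' may each be a single number (constant), a named 6-vector over the
#' Garway-Heath sectors (`T`, `ST`, `SN`, `N`, `IN`, `IT`; piecewise constant
#' in FoBMO-relative angle), or a function of the FoBMO-relative angle in
#' degrees returning micrometers. Defaults reflect a typical non-myopic
#' glaucomatous eye (ovality 0.88, tilt 1.7 deg, rotation 36.1 deg, BMO area
#' 2.11 mm^2, sector profiles of a moderately damaged eye).
#'
#' @param true_tilt_deg tilt of the BMO plane vs the membrane plane, degrees
#'   in \[0, 90).
#' @param true_rotation_deg FoBMO-adjusted major-axis rotation truth, degrees
#'   in \[0, 90\].
#' @param true_ovality minor/major axis ratio in (0, 1\].
#' @param bmo_semimajor_um BMO ellipse semi-major axis (um).
#' @param bmb_ring_radius_um en-face radius of the scan-edge membrane points
#'   (um); must exceed `bmo_semimajor_um`.
#' @param mrw_profile,rnfl_profile_um,choroid_profile_um thickness profiles,
#'   see Details above (um, all values must be >= 0).
#' @param fobmo_deg FoBMO-center axis angle, degrees.
#' @param laterality "OD" or "OS"; OS eyes are emitted in the mirrored device
#'   frame to exercise laterality handling.
#' @param point_noise_sd_um isotropic Gaussian noise SD added to every BMO,
#'   BMB and ILM vertex coordinate (um).
#' @param boundary_noise_sd_um Gaussian noise SD added to each circle-scan
#'   boundary depth (um).
#' @param quality_score_db simulated scan quality score (dB).
#' @param tilt_azimuth_deg en-face direction towards which the BMO plane is
#'   depressed, degrees.
#' @param n_ascans number of A-scans on the circle profile.
#' @param ilm_slope_deg inclination of the ILM rim segment within each radial
#'   scan plane, degrees.
#' @param eye_id identifier.
#' @return a validated list of class `synthetic_eye_params`.
#' @export
synthetic_eye_params <- function(true_tilt_deg = 1.7,
                                 true_rotation_deg = 36.1,
                                 true_ovality = 0.88,
                                 bmo_semimajor_um = sqrt(2.11e6 / (pi * 0.88)),
                                 bmb_ring_radius_um = 2500,
                                 mrw_profile = c(T = 148.9, ST = 179.4, SN = 226.9,
                                                 N = 226.2, IN = 243.9, IT = 182.4),
                                 rnfl_profile_um = c(T = 52.6, ST = 85.9, SN = 77.4,
                                                     N = 57.6, IN = 73.4, IT = 89.9),
                                 choroid_profile_um = c(T = 140.8, ST = 152.5, SN = 152.8,
                                                        N = 142.7, IN = 111.2, IT = 106.5),
                                 fobmo_deg = -7,
                                 laterality = "OD",
                                 point_noise_sd_um = 5,
                                 boundary_noise_sd_um = 3,
                                 quality_score_db = 25,
                                 tilt_azimuth_deg = 90,
                                 n_ascans = 768L,
                                 ilm_slope_deg = 15,
                                 eye_id = "synthetic") {
  check_number(true_tilt_deg, "true_tilt_deg", lo = 0, hi = 90, hi_open = TRUE)
  check_number(true_rotation_deg, "true_rotation_deg", lo = 0, hi = 90)
  check_number(true_ovality, "true_ovality", lo = 0, hi = 1, lo_open = TRUE)
  check_number(bmo_semimajor_um, "bmo_semimajor_um", lo = 0, lo_open = TRUE)
  check_number(bmb_ring_radius_um, "bmb_ring_radius_um", lo = 0, lo_open = TRUE)
  if (bmb_ring_radius_um <= bmo_semimajor_um) {
    stop_validation("`bmb_ring_radius_um` must exceed `bmo_semimajor_um`")
  }
  check_number(point_noise_sd_um, "point_noise_sd_um", lo = 0)
  check_number(boundary_noise_sd_um, "boundary_noise_sd_um", lo = 0)
  check_number(fobmo_deg, "fobmo_deg")
  check_number(quality_score_db, "quality_score_db")
  check_number(tilt_azimuth_deg, "tilt_azimuth_deg")
  check_number(ilm_slope_deg, "ilm_slope_deg", lo = 0, hi = 60)
  check_laterality(laterality)
  n_ascans <- as.integer(n_ascans)
  if (n_ascans < 24L) stop_validation("`n_ascans` must be at least 24")
  for (nm in c("mrw_profile", "rnfl_profile_um", "choroid_profile_um")) {
    check_profile_spec(get(nm), nm)
  }
  structure(list(
    true_tilt_deg = true_tilt_deg, true_rotation_deg = true_rotation_deg,
    true_ovality = true_ovality, bmo_semimajor_um = bmo_semimajor_um,
    bmb_ring_radius_um = bmb_ring_radius_um, mrw_profile = mrw_profile,
    rnfl_profile_um = rnfl_profile_um, choroid_profile_um = choroid_profile_um,
    fobmo_deg = fobmo_deg, laterality = laterality,
    point_noise_sd_um = point_noise_sd_um,
    boundary_noise_sd_um = boundary_noise_sd_um,
    quality_score_db = quality_score_db,
    tilt_azimuth_deg = tilt_azimuth_deg, n_ascans = n_ascans,
    ilm_slope_deg = ilm_slope_deg, eye_id = as.character(eye_id)
  ), class = "synthetic_eye_params")
}

check_profile_spec <- function(p, name) {
  if (is.function(p)) return(invisible(p))
  if (is.numeric(p) && length(p) == 1L && is.finite(p) && p >= 0) return(invisible(p))
  if (is.numeric(p) && length(p) == 6L && all(is.finite(p)) && all(p >= 0) &&
      setequal(names(p), GH_SECTOR_NAMES)) {
    return(invisible(p))
  }
  stop_validation(sprintf(
    "`%s` must be a non-negative scalar, a named 6-vector over sectors (%s), or a function",
    name, paste(GH_SECTOR_NAMES, collapse = ", ")))
}

# Evaluate a thickness profile at FoBMO-relative angles (degrees).
eval_profile <- function(p, psi) {
  out <- if (is.function(p)) {
    p(psi %% 360)
  } else if (length(p) == 1L) {
    rep(as.numeric(p), length(psi))
  } else {
    as.numeric(p[as.character(gh_sector_of(psi))])
  }
  if (any(!is.finite(out)) || any(out < 0)) {
    stop_validation("thickness profile produced negative or non-finite values")
  }
  out
}

#' Simulate one synthetic eye
#'
#' Builds the BMO ellipse with the configured ovality in its own plane,
#' tilted by `true_tilt_deg` about an in-plane axis relative to the membrane
#' (BMB) plane, with the semimajor axis oriented so that the en-face
#' measurement convention (fold of axis angle minus FoBMO) returns exactly
#' `true_rotation_deg`. Each radial scan contributes the two ellipse points
#' lying along its en-face direction, the two membrane points on the
#' `bmb_ring_radius_um` circle at the scan edges, and an ILM polyline whose
#' rim segment sits at exactly the configured minimum-rim-width distance from
#' the true BMO point. The circle profile carries the configured per-angle
#' thicknesses. Isotropic Gaussian noise is then added to every point and
#' boundary; with all noise at zero every downstream metric reproduces its
#' truth to numerical precision. Identical seeds give identical output.
#'
#' @param params a [synthetic_eye_params()].
#' @param seed integer seed (the caller's RNG state is preserved).
#' @return list with `scans` (a `radial_scan_set`), `circle` (a
#'   `circle_scan_profile`) and `truth` (list of the configured morphometrics
#'   and `sector_summary` truths for MRW, RNFL and PCT).
#' @examples
#' eye <- simulate_eye(synthetic_eye_params(point_noise_sd_um = 0), seed = 1)
#' compute_bmo_morphometrics(eye$scans)
#' @export
simulate_eye <- function(params, seed = 1L) {
  if (!inherits(params, "synthetic_eye_params")) {
    stop_validation("`params` must come from synthetic_eye_params()")
  }
  with_seed(seed, simulate_eye_impl(params))
}

simulate_eye_impl <- function(params) {
  a <- params$bmo_semimajor_um
  b <- a * params$true_ovality
  tilt <- params$true_tilt_deg * DEG2RAD
  az <- params$tilt_azimuth_deg * DEG2RAD
  n <- c(sin(tilt) * cos(az), sin(tilt) * sin(az), cos(tilt))

  # in-plane basis anchored to the temporal axis, as used by the measurement
  e1 <- unit(c(1, 0, 0) - n[1] * n)
  e2 <- cross3(n, e1)
  theta_ax <- (params$true_rotation_deg + params$fobmo_deg) * DEG2RAD
  U <- cos(theta_ax) * e1 + sin(theta_ax) * e2
  V <- -sin(theta_ax) * e1 + cos(theta_ax) * e2

  sd_pt <- params$point_noise_sd_um
  phi_all <- (0:(N_RADIAL_SCANS - 1)) * RADIAL_STEP_DEG
  scans <- vector("list", N_RADIAL_SCANS)
  for (k in seq_len(N_RADIAL_SCANS)) {
    phi <- phi_all[k]
    d <- c(cos(phi * DEG2RAD), sin(phi * DEG2RAD))
    p_pos <- ellipse_point_along(a, b, U, V, d)
    p_neg <- ellipse_point_along(a, b, U, V, -d)
    bmo_true <- rbind(p_pos, p_neg)
    bmb_true <- rbind(c(params$bmb_ring_radius_um * d, 0),
                      c(-params$bmb_ring_radius_um * d, 0))
    psi <- (c(phi, phi + 180) - params$fobmo_deg) %% 360
    m <- eval_profile(params$mrw_profile, psi)
    ilm <- build_ilm_polyline(bmo_true, phi, m, params$ilm_slope_deg)

    bmo <- bmo_true + matrix(stats::rnorm(6, sd = sd_pt), 2, 3)
    bmb <- bmb_true + matrix(stats::rnorm(6, sd = sd_pt), 2, 3)
    ilm[, 3] <- ilm[, 3] + stats::rnorm(nrow(ilm), sd = sd_pt)
    dimnames(bmo) <- dimnames(bmb) <- dimnames(ilm) <- NULL
    scans[[k]] <- list(scan_angle_deg = phi, bmo = bmo, bmb = bmb, ilm = ilm)
  }

  ang <- (0:(params$n_ascans - 1)) * 360 / params$n_ascans
  psi_c <- (ang - params$fobmo_deg) %% 360
  rnfl_true <- eval_profile(params$rnfl_profile_um, psi_c)
  pct_true <- eval_profile(params$choroid_profile_um, psi_c)
  sd_b <- params$boundary_noise_sd_um
  ilm_d <- 150 + stats::rnorm(params$n_ascans, sd = sd_b)
  rnfl_d <- 150 + rnfl_true + stats::rnorm(params$n_ascans, sd = sd_b)
  bm_d <- 400 + stats::rnorm(params$n_ascans, sd = sd_b)
  chor_d <- 400 + pct_true + stats::rnorm(params$n_ascans, sd = sd_b)
  # enforce physical boundary ordering (relevant only for extreme noise)
  rnfl_d <- pmax(rnfl_d, ilm_d)
  bm_d <- pmax(bm_d, rnfl_d)
  chor_d <- pmax(chor_d, bm_d)

  scan_set <- radial_scan_set(params$eye_id, "OD", params$fobmo_deg, scans,
                              quality_score_db = params$quality_score_db,
                              normalized = FALSE)
  circle <- circle_scan_profile(params$eye_id, "OD", params$fobmo_deg,
                                angle_deg = ang, ilm = ilm_d,
                                rnfl_posterior = rnfl_d, bm_posterior = bm_d,
                                choroid_posterior = chor_d,
                                quality_score_db = params$quality_score_db)

  truth <- eye_truth(params, psi_c)
  if (params$laterality == "OS") {
    scan_set <- mirror_to_os(scan_set)
    circle <- mirror_to_os(circle)
  }
  list(scans = scan_set, circle = circle, truth = truth)
}

# True ellipse point whose en-face projection lies along direction `d`
# from the BMO center.
ellipse_point_along <- function(a, b, U, V, d) {
  A <- a * (U[1] * d[2] - U[2] * d[1])
  B <- b * (V[1] * d[2] - V[2] * d[1])
  t <- atan2(-A, B)
  p <- a * cos(t) * U + b * sin(t) * V
  if (p[1] * d[1] + p[2] * d[2] < 0) {
    p <- a * cos(t + pi) * U + b * sin(t + pi) * V
  }
  p
}

# ILM polyline across one radial scan. Per half-scan the rim is a straight
# segment whose perpendicular distance from the true BMO point equals the
# configured rim width exactly (foot of the perpendicular at the segment
# center); connector vertices are placed far enough anterior / peripheral
# that they can never be the closest feature for rim widths < ~500 um.
build_ilm_polyline <- function(bmo_true, phi_deg, m, slope_deg,
                               seg_len = 800, cup_drop = 600) {
  beta <- slope_deg * DEG2RAD
  nu <- c(sin(beta), -cos(beta))      # outward, anterior (z grows posterior)
  tau <- c(cos(beta), sin(beta))
  side <- function(i, sgn) {
    phr <- (phi_deg + if (sgn > 0) 0 else 180) * DEG2RAD
    rho_hat <- c(cos(phr), sin(phr))
    p <- bmo_true[i, ]
    rho_b <- p[1] * rho_hat[1] + p[2] * rho_hat[2]
    q <- c(rho_b, p[3]) + m[i] * nu
    ei <- q - (seg_len / 2) * tau
    eo <- q + (seg_len / 2) * tau
    v_cup <- c(max(rho_b - 900, 40), ei[2] - cup_drop)
    v_out <- c(rho_b + 1400, eo[2] + 30)
    loc <- rbind(v_cup, ei, q, eo, v_out)   # ordered inner -> outer
    cbind(loc[, 1] * rho_hat[1], loc[, 1] * rho_hat[2], loc[, 2])
  }
  neg <- side(2L, -1)
  pos <- side(1L, +1)
  rbind(neg[rev(seq_len(nrow(neg))), ], pos)
}

# Ground-truth metric values in the normalized frame.
eye_truth <- function(params, psi_c) {
  psi_pts <- (c(rbind((0:(N_RADIAL_SCANS - 1)) * RADIAL_STEP_DEG,
                      (0:(N_RADIAL_SCANS - 1)) * RADIAL_STEP_DEG + 180)) -
                params$fobmo_deg) %% 360
  mrw_vals <- eval_profile(params$mrw_profile, psi_pts)
  list(
    ovality_index = params$true_ovality,
    tilt_deg = params$true_tilt_deg,
    rotation_deg = if (params$true_ovality > 0.99) 0 else params$true_rotation_deg,
    bmo_area_mm2 = pi * params$bmo_semimajor_um^2 * params$true_ovality / 1e6,
    mrw = sectorize(mrw_vals, psi_pts, fobmo_deg = 0),
    rnfl = sectorize(eval_profile(params$rnfl_profile_um, psi_c), psi_c, fobmo_deg = 0),
    pct = sectorize(eval_profile(params$choroid_profile_um, psi_c), psi_c, fobmo_deg = 0)
  )
}

# Emit an OD-frame object in the mirrored OS device frame (inverse of
# normalize_laterality; the normalized flag is cleared).
mirror_to_os <- function(x) {
  if (inherits(x, "radial_scan_set")) mirror_scans_to_os(x) else mirror_circle_to_os(x)
}

mirror_scans_to_os <- function(x) {
  x$scans <- lapply(x$scans, function(s) {
    s$bmo[, 1] <- -s$bmo[, 1]
    s$bmb[, 1] <- -s$bmb[, 1]
    s$ilm[, 1] <- -s$ilm[, 1]
    s$scan_angle_deg <- (180 - s$scan_angle_deg) %% 180
    s
  })
  x$scans <- x$scans[order(vapply(x$scans, function(s) s$scan_angle_deg, numeric(1)))]
  x$fobmo_deg <- -x$fobmo_deg
  x$laterality <- "OS"
  x$normalized <- FALSE
  x
}

mirror_circle_to_os <- function(x) {
  ang <- (180 - x$angle_deg) %% 360
  ord <- order(ang)
  x$angle_deg <- ang[ord]
  x$ilm <- x$ilm[ord]
  x$rnfl_posterior <- x$rnfl_posterior[ord]
  x$bm_posterior <- x$bm_posterior[ord]
  x$choroid_posterior <- x$choroid_posterior[ord]
  x$fobmo_deg <- -x$fobmo_deg
  x$laterality <- "OS"
  x$normalized <- FALSE
  x
}
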