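#' Compute BMO morphometrics for one eye
#'
#' The full BMO pipeline: normalize laterality into the internal OD frame,
#' pool the 48 BMO and 48 BMB points over the 24 radial scans, fit an
#' orthogonal least-squares plane to each point set, take the tilt angle
#' between the two plane normals, project the BMO points onto the BMO plane,
#' fit a direct least-squares ellipse, and derive the ovality index, the
#' FoBMO-adjusted rotation angle and the BMO area from the fitted ellipse.
#'
#' @param scans a [radial_scan_set()].
#' @param quality_threshold_db eyes with quality score strictly below this are
#'   rejected (dB); set to `-Inf` to disable the check.
#' @return object of class `bmo_morphometrics`: list with `ovality_index`,
#'   `tilt_deg`, `rotation_deg`, `bmo_area_mm2`, plus the fitted `ellipse`,
#'   `bmo_plane` and `bmb_plane` and a `rotation_circular` flag.
#' @seealso [crossval_tilt()] for the independent fixed-radius tilt variant.
#' @export
compute_bmo_morphometrics <- function(scans, quality_threshold_db = 15) {
  if (!inherits(scans, "radial_scan_set")) {
    stop_validation("`scans` must be a `radial_scan_set`")
  }
  if (!quality_filter(scans$quality_score_db, quality_threshold_db)) {
    stop_validation(sprintf(
      "eye %s excluded: quality score %.1f dB below threshold %.1f dB",
      scans$eye_id, scans$quality_score_db, quality_threshold_db))
  }
  scans <- normalize_laterality(scans)
  bmo <- do.call(rbind, lapply(scans$scans, function(s) s$bmo))
  bmb <- do.call(rbind, lapply(scans$scans, function(s) s$bmb))

  bmo_plane <- with_scan_context(scans, fit_plane(bmo))
  bmb_plane <- with_scan_context(scans, fit_plane(bmb))
  tilt <- angle_between_planes(bmo_plane, bmb_plane)

  pts2d <- project_to_plane(bmo, bmo_plane)
  ell <- with_scan_context(scans, fit_ellipse_2d(pts2d))
  rot <- compute_rotation_angle(ell, scans$fobmo_deg)

  structure(list(
    eye_id = scans$eye_id,
    ovality_index = compute_ovality(ell),
    tilt_deg = tilt,
    rotation_deg = as.numeric(rot),
    rotation_circular = isTRUE(attr(rot, "circular")),
    bmo_area_mm2 = compute_bmo_area(ell),
    ellipse = ell,
    bmo_plane = bmo_plane,
    bmb_plane = bmb_plane
  ), class = "bmo_morphometrics")
}

# Re-raise fit errors with the eye id attached.
with_scan_context <- function(scans, expr) {
  tryCatch(expr, onhmorph_error = function(e) {
    stop_onhmorph(sprintf("eye %s: %s", scans$eye_id, conditionMessage(e)),
                  class = class(e)[1])
  })
}

#' Cross-validation tilt at a fixed reference radius
#'
#' An independent tilt estimate that replaces the scan-edge BMB points by
#' reference points taken at a fixed en-face distance (default 1700 um) from
#' the BMO center along each radial scan direction, with the Bruch's membrane
#' surface interpolated linearly along the scan between (or beyond) its two
#' BMB points. The tilt is then the angle between the plane fit to these
#' reference points and the BMO plane, exactly as in the primary pipeline.
#' On a planar membrane the two estimates coincide.
#'
#' @param scans a [radial_scan_set()].
#' @param ring_um reference radius from the BMO center, micrometers.
#' @param quality_threshold_db as in [compute_bmo_morphometrics()].
#' @return tilt angle in degrees.
#' @export
crossval_tilt <- function(scans, ring_um = 1700, quality_threshold_db = 15) {
  if (!inherits(scans, "radial_scan_set")) {
    stop_validation("`scans` must be a `radial_scan_set`")
  }
  check_number(ring_um, "ring_um", lo = 0, lo_open = TRUE)
  if (!quality_filter(scans$quality_score_db, quality_threshold_db)) {
    stop_validation(sprintf(
      "eye %s excluded: quality score %.1f dB below threshold %.1f dB",
      scans$eye_id, scans$quality_score_db, quality_threshold_db))
  }
  scans <- normalize_laterality(scans)
  bmo <- do.call(rbind, lapply(scans$scans, function(s) s$bmo))
  center_xy <- colMeans(bmo[, 1:2, drop = FALSE])

  ref <- lapply(scans$scans, function(s) {
    d <- c(cos(s$scan_angle_deg * DEG2RAD), sin(s$scan_angle_deg * DEG2RAD))
    # signed position of each BMB point along the scan direction
    svals <- as.numeric((s$bmb[, 1:2, drop = FALSE] -
                           matrix(center_xy, 2, 2, byrow = TRUE)) %*% d)
    if (max(abs(svals)) < ring_um) {
      stop_onhmorph(sprintf(
        "eye %s, scan %.1f deg: reference ring %.0f um exceeds BM extent (%.0f um)",
        scans$eye_id, s$scan_angle_deg, ring_um, max(abs(svals))),
        class = "onhmorph_range_error")
    }
    if (abs(diff(svals)) < 1e-6) {
      stop_onhmorph("degenerate BM geometry along scan", class = "onhmorph_degenerate_error")
    }
    zf <- function(sv) {
      w <- (sv - svals[1]) / (svals[2] - svals[1])
      s$bmb[1, 3] + w * (s$bmb[2, 3] - s$bmb[1, 3])
    }
    rbind(c(center_xy + ring_um * d, zf(ring_um)),
          c(center_xy - ring_um * d, zf(-ring_um)))
  })
  ref <- do.call(rbind, ref)
  bmo_plane <- fit_plane(bmo)
  ref_plane <- fit_plane(ref)
  angle_between_planes(bmo_plane, ref_plane)
}

#' @exportS3Method base::print
print.bmo_morphometrics <- function(x, ...) {
  cat(sprintf(
    "BMO morphometrics, eye %s:\n  ovality index %.3f | tilt %.2f deg | rotation %.1f deg%s | area %.3f mm^2\n",
    x$eye_id, x$ovality_index, x$tilt_deg, x$rotation_deg,
    if (x$rotation_circular) " (circular)" else "", x$bmo_area_mm2))
  invisible(x)
}
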