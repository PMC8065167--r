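# Containers for segmented scan geometry. All coordinates are physical
# micrometers in a right-handed frame: x en-face temporal->nasal (after
# laterality normalization), y en-face inferior->superior, z axial
# anterior->posterior. Angles are degrees.

N_RADIAL_SCANS <- 24L
RADIAL_STEP_DEG <- 7.5

#' Construct a radial scan set
#'
#' One eye's 24 radial B-scans: per scan two BMO points, two
#' Bruch's-membrane-boundary (BMB) points at the scan edges, and an ILM
#' polyline, all as 3D points in micrometers. This is the input to all BMO
#' morphometrics and to minimum-rim-width computation.
#'
#' @param eye_id character identifier.
#' @param laterality "OD" or "OS". OS geometry is stored in device (mirrored)
#'   coordinates unless `normalized` is TRUE.
#' @param fobmo_deg FoBMO-center axis angle vs the en-face horizontal, degrees.
#' @param scans list of 24 records, each a list with `scan_angle_deg`,
#'   `bmo` (2 x 3 matrix), `bmb` (2 x 3 matrix), `ilm` (n x 3 matrix polyline).
#' @param quality_score_db scan quality score (dB).
#' @param normalized has the eye already been mirrored into the internal OD
#'   frame?
#' @return object of class `radial_scan_set`.
#' @export
radial_scan_set <- function(eye_id, laterality, fobmo_deg, scans,
                            quality_score_db = 25, normalized = FALSE) {
  check_laterality(laterality)
  check_number(fobmo_deg, "fobmo_deg")
  check_number(quality_score_db, "quality_score_db")
  x <- structure(list(
    eye_id = as.character(eye_id),
    laterality = laterality,
    fobmo_deg = fobmo_deg,
    scans = scans,
    quality_score_db = quality_score_db,
    normalized = isTRUE(normalized)
  ), class = "radial_scan_set")
  validate_radial_scan_set(x)
  x
}

validate_radial_scan_set <- function(x) {
  if (length(x$scans) != N_RADIAL_SCANS) {
    stop_validation(sprintf("scans: expected %d radial scans, got %d",
                            N_RADIAL_SCANS, length(x$scans)))
  }
  angles <- vapply(x$scans, function(s) s$scan_angle_deg, numeric(1))
  expected <- (seq_len(N_RADIAL_SCANS) - 1) * RADIAL_STEP_DEG
  if (max(abs(sort(angles) - expected)) > 1e-9) {
    stop_validation("scan angles must be {k * 7.5 deg : k = 0..23}")
  }
  for (i in seq_along(x$scans)) {
    s <- x$scans[[i]]
    for (fld in c("bmo", "bmb")) {
      m <- s[[fld]]
      if (!is.matrix(m) || !identical(dim(m), c(2L, 3L)) || any(!is.finite(m))) {
        stop_validation(sprintf("scan %d: `%s` must be a finite 2 x 3 matrix", i, fld))
      }
    }
    if (!is.matrix(s$ilm) || ncol(s$ilm) != 3L || nrow(s$ilm) < 2L) {
      stop_validation(sprintf("scan %d: `ilm` must be an n x 3 polyline with n >= 2", i))
    }
    r_bmo <- sqrt(rowSums(s$bmo[, 1:2, drop = FALSE]^2))
    r_bmb <- sqrt(rowSums(s$bmb[, 1:2, drop = FALSE]^2))
    if (min(r_bmb) <= max(r_bmo)) {
      stop_validation(sprintf(
        "scan %d: BMB points must lie at larger en-face radius than the BMO points", i))
    }
  }
  invisible(x)
}

#' Mirror an OS eye into the internal OD frame
#'
#' Left-eye (OS) geometry is acquired in a mirrored en-face frame. All
#' measurements are defined in a single internal OD frame, so OS eyes are
#' mirrored exactly once on ingest: en-face x is negated for every point and
#' the FoBMO angle changes sign. The operation is guarded by the `normalized`
#' flag so a double application is impossible.
#'
#' @param x a `radial_scan_set` or `circle_scan_profile`.
#' @return the object in the internal OD frame with `normalized = TRUE`.
#' @export
normalize_laterality <- function(x) UseMethod("normalize_laterality")

#' @export
normalize_laterality.radial_scan_set <- function(x) {
  if (x$normalized || x$laterality == "OD") {
    x$normalized <- TRUE
    return(x)
  }
  x$scans <- lapply(x$scans, function(s) {
    s$bmo[, 1] <- -s$bmo[, 1]
    s$bmb[, 1] <- -s$bmb[, 1]
    s$ilm[, 1] <- -s$ilm[, 1]
    s$scan_angle_deg <- (180 - s$scan_angle_deg) %% 180
    s
  })
  # keep scans ordered by angle
  x$scans <- x$scans[order(vapply(x$scans, function(s) s$scan_angle_deg, numeric(1)))]
  x$fobmo_deg <- -x$fobmo_deg
  x$normalized <- TRUE
  validate_radial_scan_set(x)
  x
}

#' Construct a circle-scan boundary profile
#'
#' Per-A-scan boundary depths on the 3.5 mm peripapillary circle scan:
#' internal limiting membrane, RNFL posterior boundary, Bruch's membrane
#' posterior boundary and choroid posterior boundary, each in micrometers of
#' axial depth (anterior -> posterior). Input to RNFL and choroidal thickness.
#'
#' @param eye_id character identifier.
#' @param laterality "OD" or "OS".
#' @param fobmo_deg FoBMO angle, degrees.
#' @param angle_deg strictly increasing en-face angles in \[0, 360).
#' @param ilm,rnfl_posterior,bm_posterior,choroid_posterior depth vectors (um),
#'   one value per A-scan, ordered anterior to posterior.
#' @param diameter_mm scan circle diameter, default 3.5.
#' @param quality_score_db quality score (dB).
#' @param normalized already in the internal OD frame?
#' @return object of class `circle_scan_profile`.
#' @export
circle_scan_profile <- function(eye_id, laterality, fobmo_deg, angle_deg,
                                ilm, rnfl_posterior, bm_posterior,
                                choroid_posterior, diameter_mm = 3.5,
                                quality_score_db = 25, normalized = FALSE) {
  check_laterality(laterality)
  check_number(fobmo_deg, "fobmo_deg")
  check_number(diameter_mm, "diameter_mm", lo = 0, lo_open = TRUE)
  x <- structure(list(
    eye_id = as.character(eye_id),
    laterality = laterality,
    fobmo_deg = fobmo_deg,
    diameter_mm = diameter_mm,
    angle_deg = as.numeric(angle_deg),
    ilm = as.numeric(ilm),
    rnfl_posterior = as.numeric(rnfl_posterior),
    bm_posterior = as.numeric(bm_posterior),
    choroid_posterior = as.numeric(choroid_posterior),
    quality_score_db = quality_score_db,
    normalized = isTRUE(normalized)
  ), class = "circle_scan_profile")
  validate_circle_scan_profile(x)
  x
}

validate_circle_scan_profile <- function(x) {
  n <- length(x$angle_deg)
  lens <- c(length(x$ilm), length(x$rnfl_posterior),
            length(x$bm_posterior), length(x$choroid_posterior))
  if (any(lens != n)) {
    stop_validation("circle profile: all boundary vectors must match `angle_deg` length")
  }
  if (n < 6L) stop_validation("circle profile: too few A-scans")
  if (any(x$angle_deg < 0 | x$angle_deg >= 360) || any(diff(x$angle_deg) <= 0)) {
    stop_validation("circle profile: angles must be strictly increasing within [0, 360)")
  }
  bad <- x$ilm > x$rnfl_posterior | x$rnfl_posterior > x$bm_posterior |
    x$bm_posterior > x$choroid_posterior
  if (any(bad)) {
    stop_onhmorph(sprintf(
      "segmentation error: boundary ordering ilm <= rnfl <= bm <= choroid violated at %d A-scan(s)",
      sum(bad)), class = "onhmorph_segmentation_error")
  }
  invisible(x)
}

#' @export
normalize_laterality.circle_scan_profile <- function(x) {
  if (x$normalized || x$laterality == "OD") {
    x$normalized <- TRUE
    return(x)
  }
  ang <- (180 - x$angle_deg) %% 360
  ord <- order(ang)
  x$angle_deg <- ang[ord]
  x$ilm <- x$ilm[ord]
  x$rnfl_posterior <- x$rnfl_posterior[ord]
  x$bm_posterior <- x$bm_posterior[ord]
  x$choroid_posterior <- x$choroid_posterior[ord]
  x$fobmo_deg <- -x$fobmo_deg
  x$normalized <- TRUE
  validate_circle_scan_profile(x)
  x
}

#' @exportS3Method base::print
print.radial_scan_set <- function(x, ...) {
  cat(sprintf("Radial scan set: eye %s (%s), %d scans, FoBMO %.1f deg, quality %.1f dB%s\n",
              x$eye_id, x$laterality, length(x$scans), x$fobmo_deg,
              x$quality_score_db,
              if (x$normalized) " [normalized frame]" else ""))
  invisible(x)
}

#' @exportS3Method base::print
print.circle_scan_profile <- function(x, ...) {
  cat(sprintf("Circle scan profile: eye %s (%s), %.1f mm, %d A-scans, quality %.1f dB%s\n",
              x$eye_id, x$laterality, x$diameter_mm, length(x$angle_deg),
              x$quality_score_db,
              if (x$normalized) " [normalized frame]" else ""))
  invisible(x)
}
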