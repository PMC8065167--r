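# Garway-Heath sector map (instrument reporting convention), FoBMO-relative degrees,
# counterclockwise from the temporal horizontal in the normalized OD frame.
GH_SECTORS <- list(
  T  = c(315, 45),   # wraps through 0; width 90
  ST = c(45, 85),
  SN = c(85, 125),
  N  = c(125, 235),
  IN = c(235, 275),
  IT = c(275, 315)
)
GH_SECTOR_NAMES <- names(GH_SECTORS)

gh_sector_of <- function(psi) {
  psi <- psi %% 360
  out <- character(length(psi))
  out[psi >= 315 | psi < 45] <- "T"
  out[psi >= 45 & psi < 85] <- "ST"
  out[psi >= 85 & psi < 125] <- "SN"
  out[psi >= 125 & psi < 235] <- "N"
  out[psi >= 235 & psi < 275] <- "IN"
  out[psi >= 275 & psi < 315] <- "IT"
  factor(out, levels = GH_SECTOR_NAMES)
}

#' Summarize a thickness profile globally and by Garway-Heath sector
#'
#' Assigns each measurement to one of the six Garway-Heath sectors by its
#' FoBMO-relative en-face angle \eqn{\psi = (\theta - \mathrm{FoBMO})
#' \bmod 360} and returns the per-sector arithmetic means together with the
#' global mean over all measurements. Sector limits (temporal 90 deg,
#' superotemporal/superonasal/inferonasal/inferotemporal 40 deg each,
#' nasal 110 deg) follow the instrument's published convention: T
#' \[315, 45), ST \[45, 85), SN \[85, 125), N \[125, 235), IN \[235, 275),
#' IT \[275, 315).
#'
#' @param values numeric vector of per-measurement thicknesses (um).
#' @param angle_deg en-face angle of each measurement (degrees, device frame
#'   after laterality normalization).
#' @param fobmo_deg FoBMO angle (degrees).
#' @param laterality "OD" or "OS"; OS inputs are mirrored
#'   (\eqn{\theta \to 180 - \theta}, FoBMO sign flipped) before sectorization.
#' @return object of class `sector_summary`: list with `global_um`,
#'   `sectors_um` (named 6-vector) and `n` (counts per sector).
#' @export
sectorize <- function(values, angle_deg, fobmo_deg = 0, laterality = "OD") {
  if (length(values) != length(angle_deg)) {
    stop_validation("`values` and `angle_deg` must have equal length")
  }
  if (any(!is.finite(values)) || any(!is.finite(angle_deg))) {
    stop_validation("`values` and `angle_deg` must be finite")
  }
  check_laterality(laterality)
  if (laterality == "OS") {
    angle_deg <- (180 - angle_deg) %% 360
    fobmo_deg <- -fobmo_deg
  }
  psi <- (angle_deg - fobmo_deg) %% 360
  sec <- gh_sector_of(psi)
  n <- table(sec)
  empty <- GH_SECTOR_NAMES[n == 0]
  if (length(empty) > 0) {
    stop_validation(sprintf("empty sector(s): %s", paste(empty, collapse = ", ")))
  }
  means <- tapply(values, sec, mean)
  structure(list(
    global_um = mean(values),
    sectors_um = as.numeric(means)[match(GH_SECTOR_NAMES, names(means))] |>
      stats::setNames(GH_SECTOR_NAMES),
    n = as.integer(n)[match(GH_SECTOR_NAMES, names(n))] |>
      stats::setNames(GH_SECTOR_NAMES)
  ), class = "sector_summary")
}

#' Image-quality inclusion decision
#'
#' Scans with a quality score strictly below the threshold are excluded;
#' a score exactly at the threshold is included.
#'
#' @param quality_score_db scan quality score (dB), vectorized.
#' @param threshold_db exclusion threshold (dB), default 15.
#' @return logical: TRUE = include, FALSE = exclude, with attribute `reason`.
#' @export
quality_filter <- function(quality_score_db, threshold_db = 15) {
  # -Inf is a valid threshold (disables the filter)
  if (!is.numeric(threshold_db) || length(threshold_db) != 1L || is.na(threshold_db)) {
    stop_validation("`threshold_db` must be a single number")
  }
  include <- quality_score_db >= threshold_db
  structure(include, reason = ifelse(include, "",
    sprintf("quality score %.1f dB < %.1f dB", quality_score_db, threshold_db)))
}

#' BMO minimum rim width (MRW)
#'
#' For each of the 48 BMO points the shortest Euclidean distance, within the
#' radial scan plane, from the point to the scan's ILM polyline (minimum over
#' point-to-segment projections). The global value is the mean of all 48
#' distances; sector means assign each BMO point to a Garway-Heath sector by
#' its FoBMO-relative en-face angle about the BMO centroid.
#'
#' @param scans a [radial_scan_set()].
#' @param quality_threshold_db quality exclusion threshold (dB).
#' @return list with `values` (data.frame: scan_angle_deg, point, psi_deg,
#'   mrw_um) and `summary` (a `sector_summary`).
#' @export
compute_mrw <- function(scans, quality_threshold_db = 15) {
  if (!inherits(scans, "radial_scan_set")) {
    stop_validation("`scans` must be a `radial_scan_set`")
  }
  if (!quality_filter(scans$quality_score_db, quality_threshold_db)) {
    stop_validation(sprintf(
      "eye %s excluded: quality score %.1f dB below threshold %.1f dB",
      scans$eye_id, scans$quality_score_db, quality_threshold_db))
  }
  scans <- normalize_laterality(scans)
  bmo_all <- do.call(rbind, lapply(scans$scans, function(s) s$bmo))
  center_xy <- colMeans(bmo_all[, 1:2, drop = FALSE])

  rows <- lapply(scans$scans, function(s) {
    if (nrow(s$ilm) < 2L) {
      stop_onhmorph(sprintf("eye %s: degenerate ILM curve at scan %.1f deg",
                            scans$eye_id, s$scan_angle_deg),
                    class = "onhmorph_segmentation_error")
    }
    d <- vapply(1:2, function(i) point_polyline_distance(s$bmo[i, ], s$ilm),
                numeric(1))
    ang <- atan2(s$bmo[, 2] - center_xy[2], s$bmo[, 1] - center_xy[1]) * RAD2DEG
    data.frame(scan_angle_deg = s$scan_angle_deg, point = 1:2,
               angle_deg = ang %% 360, mrw_um = d)
  })
  values <- do.call(rbind, rows)
  summ <- sectorize(values$mrw_um, values$angle_deg,
                    fobmo_deg = scans$fobmo_deg, laterality = "OD")
  values$psi_deg <- (values$angle_deg - scans$fobmo_deg) %% 360
  list(values = values, summary = summ)
}

# Minimum distance from a 3D point to a polyline (min over segments).
point_polyline_distance <- function(p, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  ap <- sweep(-a, 2, p, "+")
  len2 <- rowSums(ab^2)
  t <- ifelse(len2 > 0, rowSums(ap * ab) / len2, 0)
  t <- clamp(t, 0, 1)
  closest <- a + ab * t
  sqrt(min(rowSums(sweep(closest, 2, p)^2)))
}

#' Circumpapillary RNFL thickness
#'
#' Per A-scan thickness is the axial separation between the ILM and the RNFL
#' posterior boundary on the 3.5 mm circle scan, summarized globally and by
#' Garway-Heath sector.
#'
#' @param p a [circle_scan_profile()].
#' @param quality_threshold_db quality exclusion threshold (dB).
#' @return a `sector_summary` (um).
#' @export
compute_rnfl_thickness <- function(p, quality_threshold_db = 15) {
  p <- check_profile(p, quality_threshold_db)
  thick <- p$rnfl_posterior - p$ilm
  sectorize(thick, p$angle_deg, fobmo_deg = p$fobmo_deg, laterality = "OD")
}

#' Peripapillary choroidal thickness (PCT)
#'
#' Perpendicular distance between the posterior Bruch's membrane boundary and
#' the posterior choroidal boundary on the circle scan. In `"normal"` mode the
#' axial separation is multiplied by \eqn{\cos\varphi}, where \eqn{\varphi} is
#' the local inclination of the BM boundary in the unrolled B-scan plane
#' (central differences along the arc; one-sided at the profile endpoints),
#' giving the distance along the local BM normal. `"axial"` mode
#' (\eqn{\varphi \equiv 0}) returns the plain axial separation.
#'
#' @param p a [circle_scan_profile()].
#' @param mode "normal" (local-normal distance) or "axial".
#' @param quality_threshold_db quality exclusion threshold (dB).
#' @return a `sector_summary` (um).
#' @export
compute_pct <- function(p, mode = c("normal", "axial"),
                        quality_threshold_db = 15) {
  mode <- match.arg(mode)
  p <- check_profile(p, quality_threshold_db)
  sep <- p$choroid_posterior - p$bm_posterior
  if (mode == "normal") {
    radius_um <- p$diameter_mm * 1000 / 2
    arc <- p$angle_deg * DEG2RAD * radius_um
    slope <- finite_diff(p$bm_posterior, arc)
    sep <- sep * cos(atan(slope))
  }
  sectorize(sep, p$angle_deg, fobmo_deg = p$fobmo_deg, laterality = "OD")
}

# Central differences, one-sided at the endpoints.
finite_diff <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

check_profile <- function(p, quality_threshold_db) {
  if (!inherits(p, "circle_scan_profile")) {
    stop_validation("`p` must be a `circle_scan_profile`")
  }
  if (!quality_filter(p$quality_score_db, quality_threshold_db)) {
    stop_validation(sprintf(
      "eye %s excluded: quality score %.1f dB below threshold %.1f dB",
      p$eye_id, p$quality_score_db, quality_threshold_db))
  }
  validate_circle_scan_profile(p)
  normalize_laterality(p)
}

#' @exportS3Method base::print
print.sector_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Sector summary (um): global %.*f\n", digits, x$global_um))
  print(round(x$sectors_um, digits))
  invisible(x)
}

#' @export
as.data.frame.sector_summary <- function(x, ...) {
  as.data.frame(c(list(global = x$global_um), as.list(x$sectors_um)))
}
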