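# Geometry interchange: a schema-versioned JSON document carrying one eye's
# radial scans and circle profile, plus YAML cohort specifications and CSV
# tabular outputs. Units are declared in the document header (micrometers,
# degrees); unknown schema versions are rejected.

GEOMETRY_SCHEMA_VERSION <- "1.0"

#' Write an eye's geometry to JSON
#'
#' @param scans a [radial_scan_set()].
#' @param circle a [circle_scan_profile()] (optional).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(scans, circle = NULL, path) {
  if (!inherits(scans, "radial_scan_set")) {
    stop_validation("`scans` must be a `radial_scan_set`")
  }
  doc <- list(
    schema_version = GEOMETRY_SCHEMA_VERSION,
    units = list(length = "um", angle = "deg"),
    eye = list(eye_id = scans$eye_id, laterality = scans$laterality,
               fobmo_deg = scans$fobmo_deg,
               quality_score_db = scans$quality_score_db,
               frame = if (scans$normalized) "normalized_od" else "device"),
    radial_scans = lapply(scans$scans, function(s) list(
      scan_angle_deg = s$scan_angle_deg,
      bmo = unname(apply(s$bmo, 1, as.numeric, simplify = FALSE)),
      bmb = unname(apply(s$bmb, 1, as.numeric, simplify = FALSE)),
      ilm = unname(apply(s$ilm, 1, as.numeric, simplify = FALSE))
    ))
  )
  if (!is.null(circle)) {
    if (!inherits(circle, "circle_scan_profile")) {
      stop_validation("`circle` must be a `circle_scan_profile`")
    }
    doc$circle_scan <- list(
      diameter_mm = circle$diameter_mm,
      frame = if (circle$normalized) "normalized_od" else "device",
      angle_deg = circle$angle_deg, ilm_um = circle$ilm,
      rnfl_posterior_um = circle$rnfl_posterior,
      bm_posterior_um = circle$bm_posterior,
      choroid_posterior_um = circle$choroid_posterior,
      quality_score_db = circle$quality_score_db
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read an eye's geometry from JSON
#'
#' Parses and schema-validates a geometry document, enforces all container
#' invariants, and mirrors OS eyes recorded in the device frame into the
#' internal OD frame exactly once (documents already marked
#' `frame = "normalized_od"` are left untouched, so a read-write-read cycle
#' is idempotent).
#'
#' @param path JSON file path.
#' @return list with `scans` (a `radial_scan_set`, normalized frame) and
#'   `circle` (a `circle_scan_profile` or NULL).
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop_validation(
                    sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  for (fld in c("schema_version", "units", "eye", "radial_scans")) {
    if (is.null(doc[[fld]])) {
      stop_validation(sprintf("schema violation at /%s: field missing", fld))
    }
  }
  if (!identical(doc$schema_version, GEOMETRY_SCHEMA_VERSION)) {
    stop_validation(sprintf("unknown schema_version `%s` (supported: %s)",
                            doc$schema_version, GEOMETRY_SCHEMA_VERSION))
  }
  eye <- doc$eye
  for (fld in c("eye_id", "laterality", "fobmo_deg")) {
    if (is.null(eye[[fld]])) {
      stop_validation(sprintf("schema violation at /eye/%s: field missing", fld))
    }
  }
  if (length(doc$radial_scans) != N_RADIAL_SCANS) {
    stop_validation(sprintf("scans: expected %d, got %d",
                            N_RADIAL_SCANS, length(doc$radial_scans)))
  }
  scans <- lapply(seq_along(doc$radial_scans), function(i) {
    s <- doc$radial_scans[[i]]
    for (fld in c("scan_angle_deg", "bmo", "bmb", "ilm")) {
      if (is.null(s[[fld]])) {
        stop_validation(sprintf("schema violation at /radial_scans/%d/%s: field missing",
                                i, fld))
      }
    }
    list(scan_angle_deg = as.numeric(s$scan_angle_deg),
         bmo = json_points(s$bmo, sprintf("/radial_scans/%d/bmo", i)),
         bmb = json_points(s$bmb, sprintf("/radial_scans/%d/bmb", i)),
         ilm = json_points(s$ilm, sprintf("/radial_scans/%d/ilm", i)))
  })
  normalized <- identical(eye$frame, "normalized_od")
  rset <- radial_scan_set(eye$eye_id, eye$laterality, as.numeric(eye$fobmo_deg),
                          scans,
                          quality_score_db = as.numeric(eye$quality_score_db %||% 25),
                          normalized = normalized)
  rset <- normalize_laterality(rset)

  circle <- NULL
  if (!is.null(doc$circle_scan)) {
    cs <- doc$circle_scan
    circle <- circle_scan_profile(
      eye$eye_id, eye$laterality, as.numeric(eye$fobmo_deg),
      angle_deg = as.numeric(unlist(cs$angle_deg)),
      ilm = as.numeric(unlist(cs$ilm_um)),
      rnfl_posterior = as.numeric(unlist(cs$rnfl_posterior_um)),
      bm_posterior = as.numeric(unlist(cs$bm_posterior_um)),
      choroid_posterior = as.numeric(unlist(cs$choroid_posterior_um)),
      diameter_mm = as.numeric(cs$diameter_mm %||% 3.5),
      quality_score_db = as.numeric(cs$quality_score_db %||% 25),
      normalized = identical(cs$frame, "normalized_od"))
    circle <- normalize_laterality(circle)
  }
  list(scans = rset, circle = circle)
}

json_points <- function(x, where) {
  m <- tryCatch(do.call(rbind, lapply(x, function(p) as.numeric(unlist(p)))),
                error = function(e) NULL)
  if (is.null(m) || ncol(m) != 3L || any(!is.finite(m))) {
    stop_validation(sprintf("schema violation at %s: expected finite [x, y, z] triplets",
                            where))
  }
  m
}

#' Read a cohort specification from YAML
#'
#' Expected layout: top-level `seed`, `groups` (named maps with n_patients,
#' n_eyes, al_mean, al_sd, ...), and optional `outcomes` (named maps with
#' mean — scalar or per-group map —, sd, patient_sd, slope_al, intercept,
#' lower, upper).
#'
#' @param path YAML file path.
#' @return a [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop_validation("cohort spec: `groups` missing")
  # YAML 1.1 reads a bare `no:` key as a boolean; map it back to the group name
  names(y$groups)[names(y$groups) %in% c("FALSE", "false")] <- "no"
  groups <- lapply(y$groups, function(g) do.call(group_spec, g))
  outcomes <- lapply(y$outcomes %||% list(), function(o) {
    if (!is.null(o$mean) && is.list(o$mean)) {
      names(o$mean)[names(o$mean) %in% c("FALSE", "false")] <- "no"
      o$mean <- unlist(o$mean)
    }
    do.call(outcome_spec, o)
  })
  cohort_spec(groups = groups, outcomes = outcomes, seed = y$seed %||% 1L)
}

#' Write a cohort or metrics table to CSV
#'
#' @param table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
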