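# End-to-end pipeline: simulate a cohort with geometry, apply the quality
# filter, compute morphometrics and thickness metrics per eye, and run the
# cohort statistics. Every artifact is a pure function of (config, seed).

#' Pipeline run configuration
#'
#' @param spec a [cohort_spec()] or path to a YAML cohort specification.
#' @param seed simulation seed.
#' @param quality_threshold_db exclusion threshold, dB (scans scoring below
#'   are excluded and logged).
#' @param pct_mode "normal" or "axial" choroidal thickness mode.
#' @param crossval_ring_um reference radius for the cross-validation tilt.
#' @param out_dir output directory (created if needed).
#' @param point_noise_sd_um,boundary_noise_sd_um simulated measurement noise.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec, seed = 1L, quality_threshold_db = 15,
                       pct_mode = "normal", crossval_ring_um = 1700,
                       out_dir = tempfile("onhmorph-run-"),
                       point_noise_sd_um = 5, boundary_noise_sd_um = 3) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  if (!inherits(spec, "cohort_spec")) {
    stop_validation("`spec` must be a `cohort_spec` or a YAML path")
  }
  check_number(quality_threshold_db, "quality_threshold_db")
  check_number(crossval_ring_um, "crossval_ring_um", lo = 0, lo_open = TRUE)
  pct_mode <- match.arg(pct_mode, c("normal", "axial"))
  structure(list(spec = spec, seed = as.integer(seed),
                 quality_threshold_db = quality_threshold_db,
                 pct_mode = pct_mode, crossval_ring_um = crossval_ring_um,
                 out_dir = out_dir,
                 point_noise_sd_um = point_noise_sd_um,
                 boundary_noise_sd_um = boundary_noise_sd_um),
            class = "run_config")
}

#' Run the full simulation-analysis pipeline
#'
#' Stages: (1) simulate the cohort with per-eye scan geometry; (2) apply the
#' image-quality filter, logging every excluded eye with its reason; (3)
#' compute BMO morphometrics, cross-validation tilt, MRW, RNFL and choroidal
#' thickness per included eye; (4) group comparisons and axial-length
#' association models. Writes `cohort.csv`, `metrics.csv`, `exclusions.csv`,
#' `stats_groups.csv` and `stats_al.csv` into the output directory. Progress
#' and timings go to stderr; results never do. Every eye of the input appears
#' either in the metrics output or in the exclusion log.
#'
#' @param config a [run_config()].
#' @return list with `cohort`, `metrics`, `exclusions`, `stats_groups`,
#'   `stats_al` and `out_dir`, invisibly writable as CSV.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    stop_validation("`config` must come from run_config()")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) {
    message(sprintf(paste0("[onhmorph] ", fmt), ...))
  }
  log_stage("seed %d", config$seed)

  t0 <- proc.time()[3]
  cohort <- simulate_cohort(config$spec, seed = config$seed, geometry = TRUE,
                            point_noise_sd_um = config$point_noise_sd_um,
                            boundary_noise_sd_um = config$boundary_noise_sd_um)
  geoms <- attr(cohort, "geometries")
  log_stage("simulate: %d eyes, %d patients (%.1f s)", nrow(cohort),
            length(unique(cohort$patient_id)), proc.time()[3] - t0)

  t0 <- proc.time()[3]
  metrics <- list()
  exclusions <- list()
  for (i in seq_len(nrow(cohort))) {
    eye_id <- cohort$eye_id[i]
    g <- geoms[[eye_id]]
    ok <- quality_filter(g$scans$quality_score_db, config$quality_threshold_db)
    if (!ok) {
      exclusions[[eye_id]] <- data.frame(eye_id = eye_id,
                                         reason = attr(ok, "reason"))
      next
    }
    row <- tryCatch({
      morph <- compute_bmo_morphometrics(g$scans, config$quality_threshold_db)
      cv_tilt <- crossval_tilt(g$scans, config$crossval_ring_um,
                               config$quality_threshold_db)
      mrw <- compute_mrw(g$scans, config$quality_threshold_db)
      rnfl <- compute_rnfl_thickness(g$circle, config$quality_threshold_db)
      pct <- compute_pct(g$circle, mode = config$pct_mode,
                         quality_threshold_db = config$quality_threshold_db)
      cbind(data.frame(eye_id = eye_id,
                       ovality_index = morph$ovality_index,
                       tilt_deg = morph$tilt_deg,
                       rotation_deg = morph$rotation_deg,
                       bmo_area_mm2 = morph$bmo_area_mm2,
                       crossval_tilt_deg = cv_tilt),
            prefix_summary(mrw$summary, "mrw"),
            prefix_summary(rnfl, "rnfl"),
            prefix_summary(pct, "pct"))
    }, onhmorph_error = function(e) {
      stop_onhmorph(sprintf("stage metrics, eye %s: %s", eye_id,
                            conditionMessage(e)), class = class(e)[1])
    })
    metrics[[eye_id]] <- row
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(eye_id = character(), reason = character())
  rownames(exclusions) <- NULL
  log_stage("metrics: %d eyes included, %d excluded (%.1f s)",
            if (is.null(metrics)) 0L else nrow(metrics), nrow(exclusions),
            proc.time()[3] - t0)
  if (is.null(metrics)) {
    stop_stats("empty cohort: every eye was excluded by the quality filter")
  }
  rownames(metrics) <- NULL

  cohort_out <- as.data.frame(cohort)
  analysis <- merge(cohort_out[, setdiff(names(cohort_out),
                                         intersect(names(cohort_out), names(metrics)[-1]))],
                    metrics, by = "eye_id")

  t0 <- proc.time()[3]
  stats_groups <- pipeline_group_stats(analysis)
  stats_al <- pipeline_al_stats(analysis)
  log_stage("stats: %d outcomes (%.1f s)", nrow(stats_groups), proc.time()[3] - t0)

  write_cohort_csv(cohort_out, file.path(config$out_dir, "cohort.csv"))
  write_cohort_csv(metrics, file.path(config$out_dir, "metrics.csv"))
  write_cohort_csv(exclusions, file.path(config$out_dir, "exclusions.csv"))
  write_cohort_csv(stats_groups, file.path(config$out_dir, "stats_groups.csv"))
  write_cohort_csv(stats_al, file.path(config$out_dir, "stats_al.csv"))
  log_stage("wrote outputs to %s", config$out_dir)

  invisible(list(cohort = cohort_out, metrics = metrics, exclusions = exclusions,
                 stats_groups = stats_groups, stats_al = stats_al,
                 out_dir = config$out_dir))
}

prefix_summary <- function(s, prefix) {
  df <- as.data.frame(s)
  names(df) <- paste(prefix, names(df), sep = "_")
  df
}

# Group-comparison table: mean (95% CI) per group plus overall/pairwise p.
pipeline_group_stats <- function(analysis) {
  outcomes <- intersect(c("ovality_index", "tilt_deg", "rotation_deg",
                          "bmo_area_mm2", "mrw_global", "rnfl_global",
                          "pct_global"), names(analysis))
  rows <- lapply(outcomes, function(oc) {
    gc <- tryCatch(group_comparison(analysis, oc), onhmorph_error = function(e) NULL)
    if (is.null(gc)) return(NULL)
    fit <- fit_lmm(analysis, oc, fixed = "myopia_group")
    cf <- fit$coefficients
    icpt <- cf$estimate[cf$term == "(Intercept)"]
    means <- gc$estimates
    data.frame(outcome = oc,
               mean_no = unname(means["no"]), mean_mild = unname(means["mild"]),
               mean_high = unname(means["high"]),
               overall_p = gc$overall_p,
               p_no_vs_mild = unname(gc$pairwise["no_vs_mild"]),
               p_no_vs_high = unname(gc$pairwise["no_vs_high"]),
               p_mild_vs_high = unname(gc$pairwise["mild_vs_high"]))
  })
  do.call(rbind, rows)
}

# Axial-length association: univariate and age/VF-adjusted slopes with
# Edwards semi-partial R-squared.
pipeline_al_stats <- function(analysis) {
  outcomes <- intersect(c("ovality_index", "tilt_deg", "rotation_deg",
                          "mrw_global", "rnfl_global", "pct_global"),
                        names(analysis))
  rows <- lapply(outcomes, function(oc) {
    uni <- fit_lmm(analysis, oc, fixed = "al_mm")
    adj <- fit_lmm(analysis, oc, fixed = c("al_mm", "age_yr", "vf_md_db"))
    cu <- uni$coefficients[uni$coefficients$term == "al_mm", ]
    ca <- adj$coefficients[adj$coefficients$term == "al_mm", ]
    data.frame(outcome = oc,
               slope = cu$estimate, ci_lo = cu$ci_lo, ci_hi = cu$ci_hi,
               r2 = semi_partial_r2(uni, "al_mm"), p = cu$p,
               slope_adj = ca$estimate, ci_lo_adj = ca$ci_lo,
               ci_hi_adj = ca$ci_hi,
               r2_adj = semi_partial_r2(adj, "al_mm"), p_adj = ca$p)
  })
  do.call(rbind, rows)
}
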