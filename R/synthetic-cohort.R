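# Cohort-level simulation: axial-myopia groups with truncated-Gaussian axial
# length, two-eyes-per-patient clustering, and per-outcome patient random
# intercepts, emulating the statistical structure of a clinical OCT cohort.

AL_BOUNDS <- list(no = c(-Inf, 24), mild = c(24, 26), high = c(26, Inf))
MYOPIA_LEVELS <- c("no", "mild", "high")

#' Specify one myopia group of a synthetic cohort
#'
#' @param n_patients,n_eyes group sizes; `n_patients <= n_eyes <= 2 * n_patients`.
#' @param al_mean,al_sd axial length mean and latent SD (mm). Values are drawn
#'   from a Gaussian truncated to the group's interval, with the latent
#'   location solved so the *truncated* mean equals `al_mean`.
#' @param age_mean,age_sd patient age (years).
#' @param vf_md_mean,vf_md_sd visual field mean deviation (dB).
#' @param quality_mean,quality_sd scan quality score (dB).
#' @return list of class `group_spec`.
#' @export
group_spec <- function(n_patients, n_eyes, al_mean, al_sd,
                       age_mean = 72, age_sd = 11,
                       vf_md_mean = -6.5, vf_md_sd = 8,
                       quality_mean = 25, quality_sd = 0) {
  n_patients <- as.integer(n_patients)
  n_eyes <- as.integer(n_eyes)
  if (n_eyes < n_patients || n_eyes > 2L * n_patients) {
    stop_validation("`n_eyes` must satisfy n_patients <= n_eyes <= 2 * n_patients")
  }
  check_number(al_sd, "al_sd", lo = 0, lo_open = TRUE)
  check_number(age_sd, "age_sd", lo = 0)
  check_number(vf_md_sd, "vf_md_sd", lo = 0)
  check_number(quality_sd, "quality_sd", lo = 0)
  structure(list(n_patients = n_patients, n_eyes = n_eyes,
                 al_mean = al_mean, al_sd = al_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 vf_md_mean = vf_md_mean, vf_md_sd = vf_md_sd,
                 quality_mean = quality_mean, quality_sd = quality_sd),
            class = "group_spec")
}

#' Specify one simulated outcome
#'
#' An outcome value for eye \eqn{i} of patient \eqn{j} in group \eqn{g} is
#' \deqn{y_{ij} = \mu_g + b_j + e_{ij}, \quad b_j \sim N(0, \sigma_p^2),
#'   \; e_{ij} \sim N(0, \sigma^2),}
#' or, when a linear link to axial length is requested,
#' \eqn{y_{ij} = \alpha + \beta \cdot AL_{ij} + b_j + e_{ij}}.
#'
#' @param mean group truth means: scalar or named vector over groups
#'   (`no`, `mild`, `high`). Ignored when `slope_al` is given and `intercept`
#'   is supplied.
#' @param sd residual (within-eye) SD.
#' @param patient_sd patient random-intercept SD.
#' @param slope_al optional slope of the truth on axial length (units per mm).
#' @param intercept intercept of the AL link; if `NULL` it is derived so the
#'   eye-weighted overall mean of the linked truth matches the overall mean of
#'   `mean` at the groups' configured AL means.
#' @param lower,upper optional truncation bounds applied to the generated
#'   values (e.g. ovality in (0, 1\]).
#' @return list of class `outcome_spec`.
#' @export
outcome_spec <- function(mean, sd = 1, patient_sd = 0,
                         slope_al = NULL, intercept = NULL,
                         lower = -Inf, upper = Inf) {
  check_number(sd, "sd", lo = 0)
  check_number(patient_sd, "patient_sd", lo = 0)
  if (!is.null(slope_al)) check_number(slope_al, "slope_al")
  if (!is.null(intercept)) check_number(intercept, "intercept")
  structure(list(mean = mean, sd = sd, patient_sd = patient_sd,
                 slope_al = slope_al, intercept = intercept,
                 lower = lower, upper = upper),
            class = "outcome_spec")
}

#' Specify a synthetic cohort
#'
#' @param groups named list of [group_spec()]s; names must be among
#'   `no`, `mild`, `high`.
#' @param outcomes named list of [outcome_spec()]s.
#' @param seed default simulation seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, outcomes = list(), seed = 1L) {
  if (!all(names(groups) %in% MYOPIA_LEVELS) || length(groups) == 0) {
    stop_validation("`groups` must be a named list with names among no/mild/high")
  }
  for (g in groups) {
    if (!inherits(g, "group_spec")) stop_validation("each group must be a `group_spec`")
  }
  for (o in outcomes) {
    if (!inherits(o, "outcome_spec")) stop_validation("each outcome must be an `outcome_spec`")
  }
  structure(list(groups = groups, outcomes = outcomes, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default cohort specification mirroring the study population
#'
#' Group sizes, axial length, age and visual-field distributions, and the
#' group-level morphometric truths of a glaucoma cohort stratified into
#' no / mild / high axial myopia (81/145, 128/214 and 68/93 patients/eyes).
#' Group SDs are derived from the reported 95% confidence intervals.
#'
#' @param seed simulation seed.
#' @return a [cohort_spec()].
#' @export
table1_cohort_spec <- function(seed = 1L) {
  cohort_spec(
    groups = list(
      no   = group_spec(81, 145, al_mean = 23.4, al_sd = 0.61,
                        age_mean = 77.2, age_sd = 11.2,
                        vf_md_mean = -6.09, vf_md_sd = 8.1),
      mild = group_spec(128, 214, al_mean = 24.8, al_sd = 0.75,
                        age_mean = 73.0, age_sd = 11.0,
                        vf_md_mean = -6.90, vf_md_sd = 8.1),
      high = group_spec(68, 93, al_mean = 26.7, al_sd = 0.74,
                        age_mean = 65.6, age_sd = 12.8,
                        vf_md_mean = -7.34, vf_md_sd = 7.8)
    ),
    outcomes = list(
      tilt_deg = outcome_spec(mean = c(no = 1.7, mild = 2.0, high = 3.4),
                              sd = 1.3, patient_sd = 0.6, lower = 0, upper = 89),
      ovality_index = outcome_spec(mean = c(no = 0.88, mild = 0.89, high = 0.85),
                                   sd = 0.06, patient_sd = 0.03,
                                   lower = 0.3, upper = 1),
      rotation_deg = outcome_spec(mean = c(no = 36.1, mild = 35.0, high = 36.7),
                                  sd = 18, patient_sd = 8, lower = 0, upper = 90)
    ),
    seed = seed
  )
}

#' Simulate a cohort table
#'
#' Draws the configured number of patients and eyes per group: patients are
#' filled with two eyes until the eye budget forces one-eye patients (so the
#' eye/patient ratio is reproduced deterministically), axial length comes from
#' the group's mean-calibrated truncated Gaussian, eyes of the same patient
#' share a patient random intercept per outcome, and outcome truths optionally
#' depend linearly on axial length. Optionally attaches full synthetic scan
#' geometry per eye.
#'
#' @param spec a [cohort_spec()].
#' @param seed seed overriding `spec$seed`.
#' @param geometry if TRUE, each row gains a `geometry` entry (in the returned
#'   `geometries` list) from [simulate_eye()], with the eye's sampled truths.
#' @param point_noise_sd_um,boundary_noise_sd_um measurement noise for
#'   generated geometry.
#' @return a `data.frame` (class `cohort_table`) with one row per eye:
#'   patient_id, eye_id, laterality, myopia_group, al_mm, age_yr, vf_md_db,
#'   quality_score_db and one column per outcome. When `geometry = TRUE` the
#'   result has an attribute `geometries`, a list of [simulate_eye()] outputs
#'   indexed by eye_id.
#' @export
simulate_cohort <- function(spec, seed = NULL, geometry = FALSE,
                            point_noise_sd_um = 5, boundary_noise_sd_um = 3) {
  if (!inherits(spec, "cohort_spec")) {
    stop_validation("`spec` must come from cohort_spec()")
  }
  seed <- seed %||% spec$seed
  with_seed(seed, simulate_cohort_impl(spec, seed, geometry,
                                       point_noise_sd_um, boundary_noise_sd_um))
}

simulate_cohort_impl <- function(spec, seed, geometry,
                                 point_noise_sd_um, boundary_noise_sd_um) {
  rows <- list()
  pid0 <- 0L
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    bounds <- AL_BOUNDS[[gname]]
    # patients with two eyes first, then one-eye patients
    n2 <- g$n_eyes - g$n_patients
    eyes_per_patient <- c(rep(2L, n2), rep(1L, g$n_patients - n2))
    patient_id <- rep(pid0 + seq_len(g$n_patients), times = eyes_per_patient)
    age <- rep(stats::rnorm(g$n_patients, g$age_mean, g$age_sd), times = eyes_per_patient)
    al <- rtruncnorm_meancal(g$n_eyes, g$al_mean, g$al_sd, bounds[1], bounds[2])
    vf <- stats::rnorm(g$n_eyes, g$vf_md_mean, g$vf_md_sd)
    qual <- stats::rnorm(g$n_eyes, g$quality_mean, g$quality_sd)
    lat <- ifelse(seq_len(g$n_eyes) %% 2L == 0L, "OS", "OD")
    rows[[gname]] <- data.frame(
      patient_id = sprintf("P%04d", patient_id),
      eye_id = sprintf("P%04d-%s-%s", patient_id, lat, gname),
      laterality = lat, myopia_group = gname,
      al_mm = al, age_yr = age, vf_md_db = vf, quality_score_db = qual,
      stringsAsFactors = FALSE
    )
    pid0 <- pid0 + g$n_patients
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$eye_id <- make.unique(tab$eye_id, sep = "-")
  tab$myopia_group <- factor(tab$myopia_group, levels = MYOPIA_LEVELS)

  group_al_means <- vapply(spec$groups, function(g) g$al_mean, numeric(1))
  group_eyes <- vapply(spec$groups, function(g) g$n_eyes, numeric(1))
  for (oname in names(spec$outcomes)) {
    o <- spec$outcomes[[oname]]
    mu <- outcome_truth_mean(o, tab, group_al_means, group_eyes)
    b <- stats::rnorm(length(unique(tab$patient_id)), 0, o$patient_sd)
    names(b) <- unique(tab$patient_id)
    y <- mu + b[tab$patient_id] + stats::rnorm(nrow(tab), 0, o$sd)
    tab[[oname]] <- clamp(y, o$lower, o$upper)
  }

  if (geometry) {
    geoms <- vector("list", nrow(tab))
    names(geoms) <- tab$eye_id
    for (i in seq_len(nrow(tab))) {
      pars <- synthetic_eye_params(
        true_tilt_deg = clamp(tab$tilt_deg[i] %||% 1.7, 0, 89.9),
        true_rotation_deg = clamp(tab$rotation_deg[i] %||% 36, 0, 90),
        true_ovality = clamp(tab$ovality_index[i] %||% 0.88, 0.3, 1),
        laterality = tab$laterality[i],
        point_noise_sd_um = point_noise_sd_um,
        boundary_noise_sd_um = boundary_noise_sd_um,
        quality_score_db = tab$quality_score_db[i],
        eye_id = tab$eye_id[i]
      )
      geoms[[i]] <- simulate_eye(pars, seed = derive_seed(seed, i))
    }
    attr(tab, "geometries") <- geoms
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

outcome_truth_mean <- function(o, tab, group_al_means, group_eyes) {
  if (!is.null(o$slope_al)) {
    icpt <- o$intercept
    if (is.null(icpt)) {
      mean_by_group <- expand_group_means(o$mean, names(group_al_means))
      overall_mean <- sum(mean_by_group * group_eyes) / sum(group_eyes)
      overall_al <- sum(group_al_means * group_eyes) / sum(group_eyes)
      icpt <- overall_mean - o$slope_al * overall_al
    }
    icpt + o$slope_al * tab$al_mm
  } else {
    mean_by_group <- expand_group_means(o$mean, names(group_al_means))
    as.numeric(mean_by_group[as.character(tab$myopia_group)])
  }
}

expand_group_means <- function(m, group_names) {
  if (length(m) == 1L && is.null(names(m))) {
    stats::setNames(rep(as.numeric(m), length(group_names)), group_names)
  } else {
    if (!all(group_names %in% names(m))) {
      stop_validation("outcome `mean` must name every simulated group")
    }
    m[group_names]
  }
}

# Truncated-normal sampler (inverse CDF) whose realized mean equals
# `target_mean`: the latent Gaussian location is solved by root finding.
rtruncnorm_meancal <- function(n, target_mean, sd, lo, hi) {
  if (sd <= 0) stop_validation("impossible truncation: `al_sd` must be > 0")
  if (is.finite(lo) && target_mean <= lo || is.finite(hi) && target_mean >= hi) {
    stop_validation(sprintf(
      "target mean %g is outside the truncation interval (%g, %g]", target_mean, lo, hi))
  }
  tmean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    # far outside the interval the truncated mass piles onto the near bound
    if (!is.finite(z) || z < 1e-12) return(clamp(mu, lo, hi))
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  mu <- stats::uniroot(function(m) tmean(m) - target_mean,
                       interval = target_mean + c(-1, 1) * 20 * sd,
                       tol = 1e-10)$root
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}
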