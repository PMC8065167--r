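make_clustered <- function(n_pat = 40, eyes_each = 2, sd_p = 1, sd_e = 1,
                           beta = 0, seed = 1) {
  set.seed(seed)
  pid <- rep(seq_len(n_pat), each = eyes_each)
  al <- rnorm(n_pat * eyes_each, 24.5, 1.2)
  b <- rnorm(n_pat, 0, sd_p)
  data.frame(patient_id = sprintf("P%03d", pid), al_mm = al,
             y = 2 + beta * al + b[pid] + rnorm(n_pat * eyes_each, 0, sd_e))
}

test_that("myopia groups follow the axial-length cut points", {
  expect_equal(as.character(assign_myopia_group(c(23.4, 24.0, 24.01, 26.0,
                                                  26.01, 26.7))),
               c("no", "no", "mild", "mild", "high", "high"))
  expect_true(is.na(assign_myopia_group(NA_real_)))
  expect_true(is.na(assign_myopia_group(Inf)))
})

test_that("one eye per patient collapses the mixed model to exact OLS", {
  dat <- make_clustered(n_pat = 60, eyes_each = 1, sd_p = 0, beta = 0.4)
  res <- fit_lmm(dat, "y", fixed = "al_mm")
  expect_true(res$ols)
  ols <- lm(y ~ al_mm, data = dat)
  sm <- coef(summary(ols))
  expect_equal(res$coefficients$estimate, unname(sm[, "Estimate"]), tolerance = 1e-10)
  expect_equal(res$coefficients$se, unname(sm[, "Std. Error"]), tolerance = 1e-10)
  expect_equal(res$coefficients$df, rep(ols$df.residual, 2))

  # intercept-only: estimate is the sample mean, df = n - 1
  res0 <- fit_lmm(dat, "y")
  expect_equal(res0$coefficients$estimate, mean(dat$y), tolerance = 1e-10)
  expect_equal(res0$coefficients$df, nrow(dat) - 1)
})

test_that("zero residual spread pushes everything into the patient intercept", {
  # balanced two-eyes-per-patient, outcome constant within patient: fixed
  # estimates equal OLS on the patient means (closed-form balanced case)
  set.seed(4)
  n_pat <- 30
  alp <- rnorm(n_pat, 24.5, 1)
  yp <- 1.5 + 0.45 * alp + rnorm(n_pat, 0, 0.8)
  dat <- data.frame(patient_id = rep(sprintf("P%02d", 1:n_pat), each = 2),
                    al_mm = rep(alp, each = 2), y = rep(yp, each = 2))
  res <- fit_lmm(dat, "y", fixed = "al_mm")
  pm <- lm(yp ~ alp)
  expect_equal(res$coefficients$estimate, unname(coef(pm)), tolerance = 1e-6)
  expect_gt(res$varcomp$patient_sd, 0)
  expect_lt(res$varcomp$residual_sd, 1e-3)
})

test_that("Satterthwaite df stay in range and approach OLS df", {
  dat <- make_clustered(n_pat = 50, eyes_each = 2, sd_p = 1, sd_e = 1, seed = 2)
  res <- fit_lmm(dat, "y", fixed = "al_mm")
  expect_true(all(res$coefficients$df > 0))
  expect_true(all(res$coefficients$df <= res$n_eyes - 2 + 1e-9))

  # negligible clustering: df close to the OLS residual df
  dat2 <- make_clustered(n_pat = 50, eyes_each = 2, sd_p = 1e-4, sd_e = 1, seed = 3)
  res2 <- fit_lmm(dat2, "y", fixed = "al_mm")
  expect_gt(min(res2$coefficients$df), 0.85 * (nrow(dat2) - 2))
})

test_that("mixed-model slope recovery is unbiased over replicates", {
  sl <- vapply(1:30, function(r) {
    dat <- make_clustered(n_pat = 120, eyes_each = 2, sd_p = 0.5, sd_e = 1,
                          beta = 0.45, seed = 100 + r)
    res <- fit_lmm(dat, "y", fixed = "al_mm")
    res$coefficients$estimate[res$coefficients$term == "al_mm"]
  }, numeric(1))
  mc_se <- sd(sl) / sqrt(length(sl))
  expect_lt(abs(mean(sl) - 0.45), 3 * mc_se + 0.01)
})

test_that("Edwards R2 follows its closed form and limits", {
  expect_equal(edwards_r2(0, 1, 100), 0)
  expect_gt(edwards_r2(1e12, 1, 100), 1 - 1e-9)
  # independent algebraic route: R2 = 1 / (1 + nu2 / (nu1 * F))
  alt <- function(f, n1, n2) 1 / (1 + n2 / (n1 * f))
  for (f in c(0.5, 3, 34.8)) {
    expect_equal(edwards_r2(f, 1, 300), alt(f, 1, 300), tolerance = 1e-12)
  }
  expect_equal(round(100 * edwards_r2(34.8, 1, 300), 1), 10.4)
  # monotone in F, invariant to outcome rescaling (F unchanged by scaling)
  fs <- c(0.1, 1, 5, 50)
  expect_true(all(diff(edwards_r2(fs, 2, 80)) > 0))
})

test_that("semi-partial R2 lookup works on fitted models and errors otherwise", {
  dat <- make_clustered(n_pat = 40, eyes_each = 2, beta = 0.45, seed = 9)
  res <- fit_lmm(dat, "y", fixed = "al_mm")
  an <- res$anova[res$anova$effect == "al_mm", ]
  expect_equal(semi_partial_r2(res, "al_mm"),
               edwards_r2(an$F, an$ndf, an$ddf))
  expect_error(semi_partial_r2(res, "age"), class = "onhmorph_stats_error")
})

test_that("group comparison flags separated means and not constant data", {
  spec <- cohort_spec(
    groups = list(no = group_spec(40, 70, 23.4, 0.6),
                  mild = group_spec(40, 70, 24.8, 0.75),
                  high = group_spec(40, 70, 26.7, 0.74)),
    outcomes = list(tilt_deg = outcome_spec(mean = c(no = 1.7, mild = 2.0, high = 3.4),
                                            sd = 0.2, patient_sd = 0.1)))
  tab <- simulate_cohort(spec, seed = 21)
  gc <- group_comparison(tab, "tilt_deg")
  expect_lt(gc$overall_p, 0.001)
  expect_true(all(gc$significant))

  tab$const <- 5
  # constant outcome: fits are degenerate by construction; must not come out
  # spuriously significant
  gc0 <- suppressWarnings(group_comparison(tab, "const"))
  expect_false(isTRUE(gc0$overall_p < 0.05))
})

test_that("patient-level ANOVA and chi-squared comparisons run", {
  tab <- simulate_cohort(table1_cohort_spec(), seed = 3)
  gc <- group_comparison(tab, "age_yr", level = "patient")
  expect_lt(gc$overall_p, 0.01)   # configured age means differ across groups
  set.seed(8)
  tab$sex <- sample(c("F", "M"), nrow(tab), replace = TRUE)
  gcc <- group_comparison(tab, "sex", level = "categorical")
  expect_true(is.finite(gcc$overall_p))
})

test_that("missing outcomes are dropped listwise and counted", {
  dat <- make_clustered(n_pat = 30, eyes_each = 2, seed = 12)
  dat$y[c(3, 10, 11)] <- NA
  res <- fit_lmm(dat, "y", fixed = "al_mm")
  expect_equal(res$n_missing, 3)
  expect_equal(res$n_eyes, nrow(dat) - 3)
})

test_that("singular designs raise an aliasing error", {
  dat <- make_clustered(n_pat = 30, eyes_each = 2, seed = 13)
  dat$al_copy <- dat$al_mm
  expect_error(fit_lmm(dat, "y", fixed = c("al_mm", "al_copy")),
               "aliased", class = "onhmorph_stats_error")
})

test_that("Pearson correlation matches its contracts", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_corr(x, x)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  expect_error(pearson_corr(x, rep(2, 5)), class = "onhmorph_stats_error")
  expect_error(pearson_corr(x, 1:4))

  # bivariate normal with rho = -0.23 at the study's sample size
  set.seed(31)
  rs <- vapply(1:500, function(i) {
    z1 <- rnorm(374); z2 <- -0.23 * z1 + sqrt(1 - 0.23^2) * rnorm(374)
    pearson_corr(z1, z2)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) + 0.23), 3 * sd(rs) / sqrt(500) + 0.005)
})

test_that("within-patient correlation rises with the intercept SD", {
  icc_of <- function(psd, seed) {
    spec <- cohort_spec(groups = list(mild = group_spec(150, 300, 24.8, 0.75)),
                        outcomes = list(y = outcome_spec(mean = 10, sd = 1,
                                                         patient_sd = psd)))
    tab <- simulate_cohort(spec, seed = seed)
    res <- fit_lmm(tab, "y")
    v <- res$varcomp
    v$patient_sd^2 / (v$patient_sd^2 + v$residual_sd^2)
  }
  i0 <- icc_of(0.3, 41)
  i1 <- icc_of(1.5, 41)
  expect_gt(i1, i0)
  expect_gt(i1, 0.5)
})
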