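# Cohort statistics: myopia grouping, eye-level linear mixed models with a
# patient random intercept (REML, Satterthwaite denominator df), pairwise
# group contrasts, Edwards semi-partial R-squared, Pearson correlation, and
# patient-level ANOVA / chi-squared comparisons.

#' Assign the axial myopia group
#'
#' No axial myopia: AL <= 24.0 mm; mild: 24.0 < AL <= 26.0 mm;
#' high: AL > 26.0 mm. Non-finite axial lengths return `NA` (record flagged
#' as missing, excluded from grouping).
#'
#' @param al_mm axial length in millimeters (vectorized).
#' @return factor with levels `no`, `mild`, `high`.
#' @examples
#' assign_myopia_group(c(23.4, 24, 26, 26.7))
#' @export
assign_myopia_group <- function(al_mm) {
  out <- rep(NA_character_, length(al_mm))
  ok <- is.finite(al_mm) & al_mm > 0
  out[ok & al_mm <= 24] <- "no"
  out[ok & al_mm > 24 & al_mm <= 26] <- "mild"
  out[ok & al_mm > 26] <- "high"
  factor(out, levels = MYOPIA_LEVELS)
}

#' Fit an eye-level linear mixed model with a patient random intercept
#'
#' Fits `outcome ~ fixed effects + (1 | patient)` by REML, with t-tests and
#' type-III F-tests using Satterthwaite denominator degrees of freedom, 95%
#' confidence intervals from the t quantile at the per-contrast df, variance
#' components, and the Edwards semi-partial R-squared for each fixed effect.
#' Rows with missing values in the model variables are dropped listwise and
#' counted. When every patient contributes a single eye the random intercept
#' is unidentifiable and the model collapses to ordinary least squares; this
#' degenerate case is detected and the OLS fit (with exact residual df) is
#' returned, flagged in the result.
#'
#' @param table data.frame with one row per eye.
#' @param outcome name of the numeric outcome column.
#' @param fixed character vector of fixed-effect columns (may include factors).
#' @param grouping name of the patient identifier column.
#' @return object of class `lmm_result`: list with `coefficients` (term,
#'   estimate, se, df, ci_lo, ci_hi, p), `anova` (effect, F, ndf, ddf,
#'   r2_semipartial, p), `varcomp` (patient_sd, residual_sd, boundary flag),
#'   `n_patients`, `n_eyes`, `n_missing`, `ols` flag, and the fitted `model`.
#' @export
fit_lmm <- function(table, outcome, fixed = character(),
                    grouping = "patient_id") {
  cols <- c(outcome, fixed, grouping)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    stop_stats(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  dat <- table[, cols, drop = FALSE]
  cc <- stats::complete.cases(dat)
  n_missing <- sum(!cc)
  dat <- droplevels(dat[cc, , drop = FALSE])
  dat[[grouping]] <- factor(dat[[grouping]])
  if (nlevels(dat[[grouping]]) < 2L) stop_stats("need at least 2 patients")
  if (!is.numeric(dat[[outcome]])) stop_stats("`outcome` must be numeric")

  rhs <- if (length(fixed) > 0) paste(fixed, collapse = " + ") else "1"
  fixed_formula <- stats::as.formula(paste(outcome, "~", rhs))
  check_aliasing(fixed_formula, dat)

  singleton <- max(table(dat[[grouping]])) == 1L
  if (singleton) {
    res <- fit_lmm_ols(fixed_formula, dat, outcome)
  } else if (cluster_constant(fixed_formula, dat, grouping)) {
    # outcome and covariates are exactly constant within every patient: the
    # model degenerates to the patient-level regression (residual variance 0,
    # all spread in the intercept); REML optimizers break down at this
    # boundary, while the collapsed fit is exact
    res <- fit_lmm_ols(fixed_formula, dat[!duplicated(dat[[grouping]]), ,
                                          drop = FALSE], outcome)
    res$varcomp$patient_sd <- res$varcomp$residual_sd
    res$varcomp$residual_sd <- 0
    res$ols <- FALSE
  } else {
    res <- fit_lmm_reml(fixed_formula, dat, outcome, grouping)
  }
  res$n_patients <- nlevels(dat[[grouping]])
  res$n_eyes <- nrow(dat)
  res$n_missing <- n_missing
  res$outcome <- outcome
  class(res) <- "lmm_result"
  res
}

# TRUE when outcome and model-matrix columns never vary within a cluster.
cluster_constant <- function(formula, dat, grouping) {
  mf <- stats::model.frame(formula, dat)
  X <- cbind(stats::model.response(mf), stats::model.matrix(formula, mf))
  g <- dat[[grouping]]
  all(vapply(seq_len(ncol(X)), function(j) {
    rng <- tapply(X[, j], g, function(v) max(v) - min(v))
    max(rng) == 0
  }, logical(1)))
}

check_aliasing <- function(formula, dat) {
  X <- stats::model.matrix(formula, dat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_stats(sprintf("singular design: aliased columns %s",
                       paste(aliased, collapse = ", ")))
  }
}

fit_lmm_reml <- function(fixed_formula, dat, outcome, grouping) {
  full <- stats::update(fixed_formula,
                        paste(". ~ . + (1 |", grouping, ")"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(full, data = dat, REML = TRUE, control = ctrl)),
    error = function(e) stop_stats(sprintf("mixed model failed to converge: %s",
                                           conditionMessage(e))))
  smr <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(smr), estimate = smr[, "Estimate"],
    se = smr[, "Std. Error"], df = smr[, "df"],
    p = smr[, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE)
  an <- tryCatch(stats::anova(fit, type = 3), error = function(e) NULL)
  if (!is.null(an) && nrow(an) > 0) {
    an <- data.frame(effect = rownames(an), F = an[["F value"]],
                     ndf = an[["NumDF"]], ddf = an[["DenDF"]],
                     p = an[["Pr(>F)"]], row.names = NULL,
                     stringsAsFactors = FALSE)
  } else {
    an <- NULL
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  patient_sd <- vc$sdcor[vc$grp == grouping][1]
  resid_sd <- vc$sdcor[vc$grp == "Residual"][1]
  finalize_lmm(coefs, an, patient_sd, resid_sd,
               boundary = lme4::isSingular(fit), ols = FALSE, model = fit)
}

fit_lmm_ols <- function(fixed_formula, dat, outcome) {
  fit <- stats::lm(fixed_formula, data = dat)
  smr <- summary(fit)$coefficients
  rdf <- fit$df.residual
  coefs <- data.frame(
    term = rownames(smr), estimate = smr[, "Estimate"],
    se = smr[, "Std. Error"], df = rdf, p = smr[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  an <- NULL
  labs <- attr(stats::terms(fixed_formula), "term.labels")
  if (length(labs) > 0) {
    dr <- tryCatch(stats::drop1(fit, scope = fixed_formula, test = "F"),
                   error = function(e) NULL)
    if (!is.null(dr)) {
      keep <- rownames(dr) != "<none>"
      an <- data.frame(effect = rownames(dr)[keep],
                       F = dr$`F value`[keep], ndf = dr$Df[keep],
                       ddf = rdf, p = dr$`Pr(>F)`[keep],
                       row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  finalize_lmm(coefs, an, patient_sd = 0, resid_sd = summary(fit)$sigma,
               boundary = TRUE, ols = TRUE, model = fit)
}

finalize_lmm <- function(coefs, an, patient_sd, resid_sd, boundary, ols, model) {
  tq <- stats::qt(0.975, coefs$df)
  coefs$ci_lo <- coefs$estimate - tq * coefs$se
  coefs$ci_hi <- coefs$estimate + tq * coefs$se
  coefs <- coefs[, c("term", "estimate", "se", "df", "ci_lo", "ci_hi", "p")]
  if (!is.null(an)) {
    an$r2_semipartial <- edwards_r2(an$F, an$ndf, an$ddf)
  }
  list(coefficients = coefs, anova = an,
       varcomp = list(patient_sd = max(patient_sd, 0),
                      residual_sd = resid_sd, boundary = boundary),
       ols = ols, model = model)
}

#' Edwards semi-partial R-squared
#'
#' Effect-size measure for a fixed effect in a mixed model, computed from its
#' F statistic and degrees of freedom:
#' \deqn{R^2_\beta = \frac{(\nu_1/\nu_2)\,F}{1 + (\nu_1/\nu_2)\,F},}
#' with \eqn{\nu_1} the numerator and \eqn{\nu_2} the (Satterthwaite)
#' denominator degrees of freedom. Monotone in F, bounded in \[0, 1\],
#' invariant to rescaling of the outcome.
#'
#' @param f F statistic(s).
#' @param nu1 numerator df.
#' @param nu2 denominator df.
#' @return semi-partial R-squared in \[0, 1\].
#' @export
edwards_r2 <- function(f, nu1, nu2) {
  q <- (nu1 / nu2) * f
  q / (1 + q)
}

#' Semi-partial R-squared of a fitted effect
#'
#' Looks up the type-III F test of `effect` in a [fit_lmm()] result and
#' returns its Edwards semi-partial R-squared.
#'
#' @param res an `lmm_result`.
#' @param effect name of a fixed effect present in the model.
#' @return fraction in \[0, 1\].
#' @export
semi_partial_r2 <- function(res, effect) {
  if (!inherits(res, "lmm_result")) stop_validation("`res` must be an `lmm_result`")
  if (is.null(res$anova) || !(effect %in% res$anova$effect)) {
    stop_stats(sprintf("effect `%s` not present in the fitted model", effect))
  }
  res$anova$r2_semipartial[res$anova$effect == effect]
}

#' Compare an outcome across the myopia groups
#'
#' For eye-level outcomes, fits the mixed model with the 3-level myopia group
#' as a fixed factor (plus optional adjustment covariates): the overall p
#' comes from the type-III F-test (Satterthwaite denominator df) and pairwise
#' group p-values from t-tests of the corresponding regression contrasts,
#' refitting with the relevant reference level. For patient-level continuous
#' variables a one-way ANOVA on one row per patient is used; for categorical
#' patient-level variables a chi-squared test. No multiplicity adjustment is
#' applied; pairwise significance is marked at p < 0.05.
#'
#' @param table cohort data.frame with `myopia_group` and `patient_id`.
#' @param outcome outcome column name.
#' @param adjust character vector of adjustment covariates (eye-level only).
#' @param level "eye" (mixed model), "patient" (ANOVA on first record per
#'   patient), or "categorical" (chi-squared on first record per patient).
#' @param pairwise compute pairwise contrasts? Skipping them saves three
#'   model refits when only the overall test is needed.
#' @return list with `overall_p`, `pairwise` (named vector: no_vs_mild,
#'   no_vs_high, mild_vs_high, where present), `significant` (logical markers
#'   at p < 0.05), `estimates` (group means for eye level) and `fit`.
#' @export
group_comparison <- function(table, outcome, adjust = character(),
                             level = c("eye", "patient", "categorical"),
                             pairwise = TRUE) {
  level <- match.arg(level)
  if (!("myopia_group" %in% names(table))) {
    stop_stats("`table` must contain `myopia_group`")
  }
  table$myopia_group <- droplevels(factor(table$myopia_group, levels = MYOPIA_LEVELS))
  groups <- levels(table$myopia_group)
  if (length(groups) < 2L) stop_stats("group comparison needs at least 2 groups")

  if (level == "categorical") {
    first <- table[!duplicated(table$patient_id), ]
    tabxt <- table(first$myopia_group, first[[outcome]])
    ct <- suppressWarnings(stats::chisq.test(tabxt))
    return(list(overall_p = ct$p.value, pairwise = NULL,
                significant = NULL, estimates = tabxt, fit = ct))
  }
  if (level == "patient") {
    first <- table[!duplicated(table$patient_id), ]
    fit <- stats::aov(stats::as.formula(paste(outcome, "~ myopia_group")), data = first)
    overall_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- if (pairwise) {
      pairwise_from_refits(first, outcome, character(), groups, eye_level = FALSE)
    } else NULL
    return(list(overall_p = overall_p, pairwise = pw,
                significant = pw < 0.05,
                estimates = tapply(first[[outcome]], first$myopia_group, mean),
                fit = fit))
  }

  res <- fit_lmm(table, outcome, fixed = c("myopia_group", adjust))
  if (is.null(res$anova) || !("myopia_group" %in% res$anova$effect)) {
    stop_stats("overall F-test for myopia_group unavailable")
  }
  overall_p <- res$anova$p[res$anova$effect == "myopia_group"]
  pw <- if (pairwise) {
    pairwise_from_refits(table, outcome, adjust, groups, eye_level = TRUE)
  } else NULL
  means <- tapply(table[[outcome]], table$myopia_group, mean, na.rm = TRUE)
  # degenerate data (zero residual spread) can yield NaN statistics; report
  # them as missing rather than as spurious significance
  list(overall_p = overall_p, pairwise = pw,
       significant = !is.na(pw) & pw < 0.05, estimates = means, fit = res)
}

pairwise_from_refits <- function(table, outcome, adjust, groups, eye_level) {
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  out <- stats::setNames(rep(NA_real_, length(pairs)),
                         vapply(pairs, function(p) paste(p, collapse = "_vs_"),
                                character(1)))
  for (i in seq_along(pairs)) {
    ref <- pairs[[i]][1]; other <- pairs[[i]][2]
    tab2 <- table
    tab2$myopia_group <- stats::relevel(droplevels(tab2$myopia_group), ref = ref)
    term <- paste0("myopia_group", other)
    p <- if (eye_level) {
      r <- fit_lmm(tab2, outcome, fixed = c("myopia_group", adjust))
      r$coefficients$p[r$coefficients$term == term]
    } else {
      f <- stats::lm(stats::as.formula(paste(outcome, "~ myopia_group")), data = tab2)
      stats::coef(summary(f))[term, "Pr(>|t|)"]
    }
    out[i] <- if (length(p) == 1) p else NA_real_
  }
  out
}

#' Pearson correlation with t-test p-value
#'
#' Standard product-moment correlation with a two-sided t-test.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_validation("`x` and `y` must have equal length")
  if (length(x) < 3) stop_validation("correlation needs at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_validation("`x` and `y` must be finite")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_stats("undefined correlation: zero variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' @exportS3Method base::print
print.lmm_result <- function(x, ...) {
  cat(sprintf("Linear mixed model for `%s` (%s): %d eyes, %d patients, %d dropped\n",
              x$outcome, if (x$ols) "OLS degenerate case" else "REML, Satterthwaite df",
              x$n_eyes, x$n_patients, x$n_missing))
  cat(sprintf("  patient SD %.4g, residual SD %.4g%s\n",
              x$varcomp$patient_sd, x$varcomp$residual_sd,
              if (x$varcomp$boundary) " (boundary)" else ""))
  print(x$coefficients, digits = 4)
  if (!is.null(x$anova)) {
    cat("Type-III tests:\n")
    print(x$anova, digits = 4)
  }
  invisible(x)
}
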