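#' Association of risk-score categories with weight-response outcomes
#'
#' Regresses each outcome on the score category (high vs low), adjusted for
#' the covariate set (sex, age, initial BMI, T2D, HTN, surgery type):
#' linear models for quantitative outcomes (adjusted mean difference,
#' high minus low, with 95% CI) and logistic models for the binary codings
#' (odds ratio for the high category relative to low, with 95% CI). For odds
#' ratios below 1 the reciprocal is also reported as the "times more likely
#' *not* to achieve the outcome" restatement.
#'
#' @param scored a categorized `scored_cohort` (from [categorize_scores()])
#'   or any data.frame with `patient_id` and a low/high `category` column.
#' @param phenotypes a `phenotype_table`.
#' @param covariates covariate table, or `NULL` for unadjusted contrasts.
#' @param outcomes outcome columns to analyse; binary columns are detected
#'   automatically.
#' @return a `data.frame` of class `rs_effects`: `outcome, family, n_low,
#'   n_high, estimate, ci_lo, ci_hi, p_value, odds_ratio, or_lo, or_hi,
#'   reciprocal_or`.
#' @export
rs_effect_analysis <- function(scored, phenotypes, covariates = NULL,
                               outcomes = c("twl_nadir", "twl_6y", "wr_mwl",
                                            "ewl6y_gt50", "wr_gt20")) {
  assert_that("category" %in% names(scored),
              "scored must carry a category column (run categorize_scores)")
  assert_that(all(outcomes %in% names(phenotypes)),
              "outcomes must be columns of the phenotype table")
  ids <- intersect(scored$patient_id, phenotypes$patient_id)
  if (!is.null(covariates)) ids <- intersect(ids, covariates$patient_id)
  cat_v <- factor(scored$category[match(ids, scored$patient_id)],
                  levels = c("low", "high"))
  ph <- phenotypes[match(ids, phenotypes$patient_id), , drop = FALSE]
  cv <- if (!is.null(covariates))
    covariate_frame(covariates[match(ids, covariates$patient_id), , drop = FALSE])
  if (any(table(cat_v) == 0))
    abort("refused: one score category is empty", "bariGRS_empty_category")

  res <- lapply(outcomes, function(oc) {
    y <- ph[[oc]]
    binary <- is.logical(y) || all(y %in% c(0, 1, NA))
    df <- data.frame(y = as.numeric(y), category = cat_v)
    if (!is.null(cv)) df <- cbind(df, cv)
    cc <- stats::complete.cases(df)
    df <- df[cc, , drop = FALSE]
    fit <- if (binary) stats::glm(y ~ ., data = df, family = stats::binomial(),
                                  control = stats::glm.control(epsilon = 1e-12))
           else stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients["categoryhigh", ]
    crit <- if (binary) stats::qnorm(0.975) else stats::qt(0.975, fit$df.residual)
    est <- sm[1]; lo <- sm[1] - crit * sm[2]; hi <- sm[1] + crit * sm[2]
    or <- or_lo <- or_hi <- recip <- NA_real_
    if (binary) {
      or <- exp(est); or_lo <- exp(lo); or_hi <- exp(hi)
      if (or < 1) recip <- 1 / or
      est <- lo <- hi <- NA_real_        # report binary outcomes as ORs
    }
    data.frame(outcome = oc, family = if (binary) "logistic" else "linear",
               n_low = sum(df$category == "low"),
               n_high = sum(df$category == "high"),
               estimate = est, ci_lo = lo, ci_hi = hi, p_value = sm[4],
               odds_ratio = or, or_lo = or_lo, or_hi = or_hi,
               reciprocal_or = recip, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("rs_effects", class(out))
  out
}

#' Restate an odds ratio below 1 as "times more likely" for the complement
#'
#' An OR of `x < 1` for achieving an outcome in the high category equals an
#' OR of `1/x` for *failing* to achieve it: e.g. OR 0.46 for reaching the
#' excess-weight-loss target means high scorers are 2.17 times more likely
#' to miss it.
#'
#' @param or odds ratio(s).
#' @return `1 / or`.
#' @export
times_more_likely <- function(or) {
  assert_that(all(or > 0), "odds ratios must be positive")
  1 / or
}

#' Compare pre-surgery profiles across score categories
#'
#' One row per pre-surgery variable with per-category summaries and a
#' two-group p-value: Welch's t-test for continuous variables
#' (mean (SD) shown) and a chi-square test without continuity correction for
#' categorical ones (n (%) shown; surgery type contributes one row per
#' class). Tests that need within-group variance report `NA` when a category
#' has fewer than 2 observations.
#'
#' @param scored a categorized `scored_cohort`.
#' @param covariates covariate table.
#' @return a `data.frame`: `variable, low, high, p_value`.
#' @export
compare_profiles <- function(scored, covariates) {
  assert_that("category" %in% names(scored),
              "scored must carry a category column")
  ids <- intersect(scored$patient_id, covariates$patient_id)
  grp <- factor(scored$category[match(ids, scored$patient_id)],
                levels = c("low", "high"))
  cv <- covariates[match(ids, covariates$patient_id), , drop = FALSE]
  if (any(table(grp) == 0))
    abort("refused: one score category is empty", "bariGRS_empty_category")

  cont_row <- function(name, x) {
    p <- if (min(table(grp[!is.na(x)])) >= 2 &&
             all(tapply(x, grp, function(v) stats::var(v, na.rm = TRUE)) > 0))
      stats::t.test(x ~ grp)$p.value else NA_real_
    data.frame(variable = name,
               low = sprintf("%.2f (%.2f)", mean(x[grp == "low"], na.rm = TRUE),
                             stats::sd(x[grp == "low"], na.rm = TRUE)),
               high = sprintf("%.2f (%.2f)", mean(x[grp == "high"], na.rm = TRUE),
                              stats::sd(x[grp == "high"], na.rm = TRUE)),
               p_value = p, stringsAsFactors = FALSE)
  }
  cat_row <- function(name, flag) {
    tab <- table(grp, factor(flag, levels = c(FALSE, TRUE)))
    p <- if (all(rowSums(tab) > 0) && length(unique(flag[!is.na(flag)])) > 1)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    else NA_real_
    data.frame(variable = name,
               low = fmt_n_pct(sum(flag[grp == "low"], na.rm = TRUE),
                               sum(grp == "low")),
               high = fmt_n_pct(sum(flag[grp == "high"], na.rm = TRUE),
                                sum(grp == "high")),
               p_value = p, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    cont_row("bmi0", cv$bmi0),
    cont_row("age", cv$age),
    cat_row("female", cv$sex == "female"),
    cat_row("t2d", as.logical(cv$t2d)),
    cat_row("htn", as.logical(cv$htn)),
    cat_row("restrictive", cv$surgery == "restrictive"),
    cat_row("mixed", cv$surgery == "mixed"),
    cat_row("malabsorptive", cv$surgery == "malabsorptive")
  )
  rows
}
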