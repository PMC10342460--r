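#' Locate the postoperative weight nadir
#'
#' The nadir is the lowest weight over all available postoperative visits
#' (visit year >= 1); ties are broken toward the earliest year.
#'
#' @param trajectory a `data.frame` with columns `visit_year` and `weight_kg`
#'   for one patient.
#' @return a list with `nadir_weight` (kg) and `nadir_year` (integer).
#' @examples
#' tr <- data.frame(visit_year = 0:4, weight_kg = c(120, 85, 80, 82, 84))
#' find_nadir(tr)  # 80 kg in year 2
#' @export
find_nadir <- function(trajectory) {
  post <- trajectory[trajectory$visit_year >= 1, , drop = FALSE]
  if (nrow(post) == 0)
    abort("no postoperative weight record", "bariGRS_insufficient_data")
  assert_that(!anyDuplicated(post$visit_year),
              "visit years must be unique within a patient")
  i <- order(post$weight_kg, post$visit_year)[1]
  list(nadir_weight = post$weight_kg[i],
       nadir_year = as.integer(post$visit_year[i]))
}

#' Weight-response metrics for a single time point
#'
#' Computes, for a weight `wt` observed after surgery:
#' \itemize{
#'   \item `twl`: percentage of total weight lost, `100 (w0 - wt) / w0`;
#'   \item `ewl`: percentage of excess weight lost,
#'     `100 (w0 - wt) / (w0 - 25 h^2)`, with ideal weight defined at
#'     BMI 25 kg/m2;
#'   \item `wr_mwl`: weight regained from the nadir as a percentage of the
#'     maximum weight lost, `100 (wt - nadir) / (w0 - nadir)`.
#' }
#'
#' @param w0 pre-surgery weight, kg (> 0).
#' @param wt weight at the time point, kg.
#' @param nadir nadir weight, kg (must satisfy `nadir < w0` for `wr_mwl`).
#' @param height height in metres (> 0).
#' @return a list with `twl`, `ewl`, `wr_mwl` (percent).
#' @examples
#' compute_weight_metrics(120, 80, 75, 1.70)
#' @export
compute_weight_metrics <- function(w0, wt, nadir, height) {
  assert_that(is.numeric(w0) && w0 > 0, "w0 must be positive")
  assert_that(is.numeric(height) && height > 0, "height must be positive")
  ideal <- 25 * height^2
  if (w0 <= ideal)
    abort(sprintf("EWL undefined: w0 (%.1f kg) <= ideal weight (%.1f kg)",
                  w0, ideal), "bariGRS_undefined_ewl")
  if (w0 == nadir)
    abort("WR undefined: no weight was lost (w0 == nadir)",
          "bariGRS_undefined_wr")
  list(twl = 100 * (w0 - wt) / w0,
       ewl = 100 * (w0 - wt) / (w0 - ideal),
       wr_mwl = 100 * (wt - nadir) / (w0 - nadir))
}

## vectorised, NA-safe variant used by derive_phenotypes
weight_metrics_safe <- function(w0, wt, nadir, height) {
  ideal <- 25 * height^2
  list(twl = 100 * (w0 - wt) / w0,
       ewl = ifelse(w0 > ideal, 100 * (w0 - wt) / (w0 - ideal), NA_real_),
       wr_mwl = ifelse(w0 > nadir, 100 * (wt - nadir) / (w0 - nadir),
                       NA_real_))
}

#' Derive the weight-response phenotype table
#'
#' For each patient: finds the nadir over all postoperative visits, selects
#' the end-of-follow-up weight as the visit closest to `followup_year` within
#' `[followup_year - window, followup_year + window]` (ties toward the later
#' visit), and computes %TWL and %EWL at both time points, weight regain
#' (`wr_mwl`, % of maximum weight lost, at end of follow-up) and the binary
#' codings `ewl6y_gt50` (`ewl_6y > 50`) and `wr_gt20` (`wr_mwl > 20`), both
#' strict inequalities. Patients lacking a window visit are excluded from the
#' year-6 phenotypes but retained for nadir phenotypes; exclusions are
#' recorded, never silently dropped.
#'
#' @param trajectories long `data.frame` (`patient_id, visit_year, weight_kg`).
#' @param covariates covariate table with `patient_id` and `height`.
#' @param followup_year end of follow-up (default 6, the common follow-up
#'   period of the cohort).
#' @param window half-width in years of the accepted visit window (default 1,
#'   i.e. years 5-7).
#' @return a `data.frame` of class `phenotype_table`, one row per patient:
#'   `patient_id, w0, height, nadir_weight, nadir_year, w6, w6_year,
#'   twl_nadir, ewl_nadir, twl_6y, ewl_6y, wr_mwl, ewl6y_gt50, wr_gt20,
#'   included_nadir, included_6y, exclusion_reason`.
#' @export
derive_phenotypes <- function(trajectories, covariates,
                              followup_year = 6L, window = 1) {
  assert_that(is_count(followup_year) && followup_year >= 1,
              "followup_year must be a positive integer")
  assert_that(window >= 0, "window must be non-negative")
  pid <- as.character(trajectories$patient_id)
  yr <- trajectories$visit_year
  assert_that(!anyDuplicated(paste(pid, yr)),
              "visit years must be unique within a patient")
  ids <- unique(pid)
  f <- factor(pid, levels = ids)
  height <- covariates$height[match(ids, covariates$patient_id)]

  ## vectorised per-patient extraction via ordered first-match lookups
  first_by <- function(keys, ord) {
    ## index of the first trajectory row per patient under ordering `ord`
    k <- keys[ord]
    ord[!duplicated(k)][match(ids, k[!duplicated(k)])]
  }
  i0 <- match(ids, pid[yr == 0])                         # baseline rows
  w0 <- trajectories$weight_kg[which(yr == 0)][i0]
  post <- which(yr >= 1)
  ## nadir: minimum weight, earliest year on ties
  ord_nad <- post[order(f[post], trajectories$weight_kg[post], yr[post])]
  i_nad <- first_by(pid, ord_nad)
  nadir_weight <- trajectories$weight_kg[i_nad]
  nadir_year <- as.integer(yr[i_nad])
  ## end-of-follow-up visit: closest to followup_year within the window,
  ## ties toward the later visit
  inwin <- post[abs(yr[post] - followup_year) <= window]
  ord_w6 <- inwin[order(f[inwin], abs(yr[inwin] - followup_year),
                        -yr[inwin])]
  i_w6 <- first_by(pid, ord_w6)
  w6 <- trajectories$weight_kg[i_w6]
  w6_year <- as.integer(yr[i_w6])

  has_baseline <- !is.na(w0)
  has_post <- !is.na(nadir_weight) & has_baseline
  has_w6 <- !is.na(w6) & has_post
  nadir_weight[!has_baseline] <- NA
  nadir_year[!has_baseline] <- NA

  mn <- weight_metrics_safe(w0, nadir_weight, nadir_weight, height)
  m6 <- weight_metrics_safe(w0, w6, nadir_weight, height)
  blank <- function(x, keep) ifelse(keep, x, NA)
  reasons <- paste0(
    ifelse(has_baseline, "", "no baseline (year 0) weight"),
    ifelse(has_baseline & !has_post, "no postoperative weight", ""),
    ifelse(has_post & !has_w6, "no follow-up weight in window", ""),
    ifelse(has_post & is.na(mn$ewl), "; EWL undefined (w0 <= ideal weight)", ""))
  ph <- data.frame(
    patient_id = ids, w0 = w0, height = height,
    nadir_weight = nadir_weight, nadir_year = nadir_year,
    w6 = blank(w6, has_w6), w6_year = as.integer(blank(w6_year, has_w6)),
    twl_nadir = blank(mn$twl, has_post), ewl_nadir = blank(mn$ewl, has_post),
    twl_6y = blank(m6$twl, has_w6), ewl_6y = blank(m6$ewl, has_w6),
    wr_mwl = blank(m6$wr_mwl, has_w6),
    ewl6y_gt50 = as.logical(blank(m6$ewl > 50, has_w6)),
    wr_gt20 = as.logical(blank(m6$wr_mwl > 20, has_w6)),
    included_nadir = has_post, included_6y = has_w6,
    exclusion_reason = sub("^; ", "", reasons), stringsAsFactors = FALSE)
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Cohort summary table (demographics and weight response)
#'
#' Reproduces the shape of a demographic/weight-response description table:
#' mean +/- SD for approximately normal variables, median (IQR) for weight
#' regain, and n (%) for binary codings. Percentages are computed over the
#' patients with a non-missing value for the variable.
#'
#' @param phenotypes a `phenotype_table`.
#' @param covariates covariate table.
#' @return a `data.frame` with columns `variable, value, n, pct, mean, sd`,
#'   where `value` is the formatted display string and the numeric columns
#'   carry the unformatted statistics (`pct` rounded to 2 decimals).
#' @export
cohort_summary <- function(phenotypes, covariates) {
  stat_row <- function(variable, x, type) {
    n <- NA_integer_; pct <- NA_real_; mu <- NA_real_; sdv <- NA_real_
    x <- x[!is.na(x)]
    value <- switch(type,
      mean_sd = { mu <- mean(x); sdv <- stats::sd(x); fmt_mean_sd(x) },
      median_iqr = sprintf("%.2f (%.2f-%.2f)", stats::median(x),
                           stats::quantile(x, 0.25), stats::quantile(x, 0.75)),
      n_pct = { n <- sum(x); pct <- round(100 * sum(x) / length(x), 2)
                fmt_n_pct(sum(x), length(x)) })
    data.frame(variable = variable, value = value, n = n, pct = pct,
               mean = mu, sd = sdv, stringsAsFactors = FALSE)
  }
  rbind(
    stat_row("age_years", covariates$age, "mean_sd"),
    stat_row("female", covariates$sex == "female", "n_pct"),
    stat_row("bmi0", covariates$bmi0, "mean_sd"),
    stat_row("t2d", covariates$t2d, "n_pct"),
    stat_row("htn", covariates$htn, "n_pct"),
    stat_row("twl_nadir", phenotypes$twl_nadir, "mean_sd"),
    stat_row("ewl_nadir", phenotypes$ewl_nadir, "mean_sd"),
    stat_row("twl_6y", phenotypes$twl_6y, "mean_sd"),
    stat_row("ewl_6y", phenotypes$ewl_6y, "mean_sd"),
    stat_row("ewl6y_gt50", phenotypes$ewl6y_gt50, "n_pct"),
    stat_row("wr_mwl", phenotypes$wr_mwl, "median_iqr"),
    stat_row("wr_gt20", phenotypes$wr_gt20, "n_pct")
  )
}
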