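#' Simulation configuration for a synthetic bariatric-surgery cohort
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults reproduce
#' the statistical structure of the study cohort: 375 patients, 69% female,
#' pre-surgery BMI 44.87 +/- 6.59 kg/m2, 35.7% with type 2 diabetes, 49% with
#' hypertension, surgery mix 16% restrictive / 54.66% mixed / 29.34%
#' malabsorptive, annual weight visits in years 0-8, and a weight trajectory
#' that falls to a nadir in year 1 or 2 and then partially regains (median
#' regain 15.76% of maximum weight lost).
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer master seed; all generator randomness derives from it.
#' @param female_frac,t2d_frac,htn_frac marginal fractions in `[0, 1]`.
#' @param bmi_mean,bmi_sd pre-surgery BMI distribution (kg/m2), truncated to
#'   `[35, 70]`.
#' @param age_mean,age_sd age distribution (years), truncated to `[18, 65]`.
#' @param surgery_fracs named fractions for `restrictive`, `mixed`,
#'   `malabsorptive`; must sum to 1 (tolerance 1e-9).
#' @param effect_spec `NULL` or a data.frame with columns `rsid`, `target`
#'   (one of `twl_nadir`, `twl_6y`, `wr_mwl`), `model` (a single-column
#'   inheritance encoding: `dominant`, `recessive`, `overdominant`,
#'   `log_additive`) and `effect` (phenotype units: percentage points). Each
#'   row shifts the latent phenotype of every patient by
#'   `effect * encoding(genotype)` before noise.
#' @param noise_sd patient-level Gaussian noise on the latent nadir %TWL, in
#'   percentage points (default 8).
#' @param visit_noise_sd per-visit Gaussian measurement noise in kg
#'   (default 0; see the methods vignette for why).
#' @param wr_median,wr_sdlog log-normal weight-regain distribution (% of
#'   maximum weight lost): median and log-sd. `wr_sdlog = 0` makes regain
#'   deterministic.
#' @param nadir_year_probs probabilities that the nadir falls in year 1 or 2.
#' @param visit_years integer follow-up years including 0 (pre-surgery).
#' @param missing_genotype_rate fraction of genotype calls set missing
#'   (default 0.02, below the 5% QC threshold).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 375L, seed = 1L,
                       female_frac = 0.69,
                       bmi_mean = 44.87, bmi_sd = 6.59,
                       age_mean = 44.79, age_sd = 11.99,
                       t2d_frac = 0.357, htn_frac = 0.49,
                       surgery_fracs = c(restrictive = 0.16, mixed = 0.5466,
                                         malabsorptive = 0.2934),
                       effect_spec = NULL,
                       noise_sd = 8, visit_noise_sd = 0,
                       wr_median = 15.76, wr_sdlog = 0.77,
                       nadir_year_probs = c(0.5, 0.5),
                       visit_years = 0:8,
                       missing_genotype_rate = 0.02) {
  assert_that(is_count(n_patients) && n_patients >= 1, "n_patients must be >= 1")
  assert_that(is_fraction(female_frac) && is_fraction(t2d_frac) &&
                is_fraction(htn_frac) && is_fraction(missing_genotype_rate),
              "fractions must lie in [0, 1]")
  assert_that(length(surgery_fracs) == 3 &&
                all(c("restrictive", "mixed", "malabsorptive") %in%
                      names(surgery_fracs)) &&
                abs(sum(surgery_fracs) - 1) <= 1e-9,
              "surgery_fracs must name restrictive/mixed/malabsorptive and sum to 1")
  assert_that(0 %in% visit_years && any(visit_years >= 1) &&
                !anyDuplicated(visit_years),
              "visit_years must include 0 and at least one postoperative year")
  assert_that(noise_sd >= 0 && visit_noise_sd >= 0 && wr_sdlog >= 0 &&
                wr_median > 0, "noise parameters must be non-negative")
  if (!is.null(effect_spec)) {
    assert_that(is.data.frame(effect_spec) &&
                  all(c("rsid", "target", "model", "effect") %in%
                        names(effect_spec)),
                "effect_spec needs columns rsid, target, model, effect")
    assert_that(all(effect_spec$target %in% c("twl_nadir", "twl_6y", "wr_mwl")),
                "effect_spec target must be twl_nadir, twl_6y or wr_mwl")
    assert_that(all(effect_spec$model %in%
                      c("dominant", "recessive", "overdominant", "log_additive")),
                "effect_spec model must be a single-column encoding")
  }
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              female_frac = female_frac, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              age_mean = age_mean, age_sd = age_sd,
              t2d_frac = t2d_frac, htn_frac = htn_frac,
              surgery_fracs = surgery_fracs[c("restrictive", "mixed",
                                              "malabsorptive")],
              effect_spec = effect_spec, noise_sd = noise_sd,
              visit_noise_sd = visit_noise_sd,
              wr_median = wr_median, wr_sdlog = wr_sdlog,
              nadir_year_probs = nadir_year_probs / sum(nadir_year_probs),
              visit_years = sort(as.integer(visit_years)),
              missing_genotype_rate = missing_genotype_rate)
  class(cfg) <- "sim_config"
  cfg
}

#' Genotype matrix container
#'
#' Stores per-patient biallelic genotype calls as alternate-allele dosages
#' (0 = reference homozygote, 1 = heterozygote, 2 = alternate homozygote,
#' `NA` = missing call), oriented to the manifest's reference allele.
#'
#' @param dosage integer matrix, patients x SNPs, values in `{0, 1, 2, NA}`;
#'   column names are rsids present in `manifest`.
#' @param manifest the [snp_manifest] the columns refer to.
#' @param patient_ids character vector of unique patient ids (defaults to
#'   `rownames(dosage)`).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, manifest, patient_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  assert_that(!is.null(colnames(dosage)) &&
                all(colnames(dosage) %in% manifest$rsid),
              "dosage columns must be rsids present in the manifest",
              class = "bariGRS_unknown_snp")
  assert_that(all(dosage %in% c(0L, 1L, 2L) | is.na(dosage)),
              "dosages must be 0, 1, 2 or NA")
  assert_that(!is.null(patient_ids) && !anyDuplicated(patient_ids),
              "patient ids must be unique and non-null")
  rownames(dosage) <- patient_ids
  man <- manifest[match(colnames(dosage), manifest$rsid), , drop = FALSE]
  rownames(man) <- NULL
  structure(list(dosage = dosage, manifest = validate_manifest(man),
                 patient_ids = as.character(patient_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d patients x %d SNPs; call rate %.3f\n",
              nrow(x$dosage), ncol(x$dosage), mean(!is.na(x$dosage))))
  invisible(x)
}

#' Per-SNP call rates and genotype counts
#'
#' @param gm a [genotype_matrix].
#' @return `call_rates`: named numeric vector of per-SNP non-missing
#'   fractions. `genotype_counts`: integer matrix with columns
#'   `n_ref_hom, n_het, n_alt_hom`, one row per SNP.
#' @export
call_rates <- function(gm) colMeans(!is.na(gm$dosage))

#' @rdname call_rates
#' @export
genotype_counts <- function(gm) {
  t(apply(gm$dosage, 2, function(d)
    c(n_ref_hom = sum(d == 0L, na.rm = TRUE),
      n_het = sum(d == 1L, na.rm = TRUE),
      n_alt_hom = sum(d == 2L, na.rm = TRUE))))
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Each SNP column is drawn i.i.d. with genotype probabilities
#' `(1-q)^2, 2q(1-q), q^2` for alternate-allele frequency `q = maf`; SNPs are
#' independent (no linkage disequilibrium). Missing calls are inserted
#' uniformly at `missing_rate`.
#'
#' @param manifest an [snp_manifest] (MAFs must be non-missing).
#' @param n number of patients (>= 1).
#' @param seed integer seed; output is bit-reproducible given it.
#' @param missing_rate fraction of calls set to `NA`.
#' @return a [genotype_matrix] with patient ids `P0001, P0002, ...`.
#' @export
simulate_genotypes <- function(manifest, n, seed, missing_rate = 0) {
  manifest <- validate_manifest(as.data.frame(manifest))
  assert_that(is_count(n) && n >= 1, "n must be >= 1")
  assert_that(is_fraction(missing_rate), "missing_rate must lie in [0, 1]")
  assert_that(!anyNA(manifest$maf), "manifest maf must be set for simulation")
  ids <- sprintf("P%04d", seq_len(n))
  dosage <- with_local_seed(seed, {
    m <- vapply(manifest$maf, function(q)
      sample(0:2, n, replace = TRUE,
             prob = c((1 - q)^2, 2 * q * (1 - q), q^2)),
      integer(n))
    if (missing_rate > 0)
      m[stats::runif(length(m)) < missing_rate] <- NA_integer_
    m
  })
  dim(dosage) <- c(n, nrow(manifest))
  colnames(dosage) <- manifest$rsid
  rownames(dosage) <- ids
  genotype_matrix(dosage, manifest, ids)
}

#' Simulate pre-surgery covariates
#'
#' Draws age, sex, pre-surgery BMI, height, diabetes and hypertension status
#' and surgery type with the configured marginals. Height is
#' Normal(1.65, 0.09) m truncated to `[1.40, 2.10]` and exists only to define
#' the ideal weight (BMI 25 kg/m2) needed by the excess-weight-loss metric.
#'
#' @param config a [sim_config].
#' @return a `data.frame` with columns `patient_id, age, sex, bmi0, height,
#'   t2d, htn, surgery`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  ## truncation shifts the realized mean; recentre the location so the
  ## configured marginal means are attained in expectation
  age_mu <- trunc_norm_location(config$age_mean, config$age_sd, 18, 65)
  bmi_mu <- trunc_norm_location(config$bmi_mean, config$bmi_sd, 35, 70)
  with_local_seed(config$seed, {
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = round(rtrunc_norm(n, age_mu, config$age_sd, 18, 65), 1),
      sex = factor(ifelse(stats::runif(n) < config$female_frac,
                          "female", "male"), levels = c("female", "male")),
      bmi0 = round(rtrunc_norm(n, bmi_mu, config$bmi_sd, 35, 70), 2),
      height = round(rtrunc_norm(n, 1.65, 0.09, 1.40, 2.10), 3),
      t2d = stats::runif(n) < config$t2d_frac,
      htn = stats::runif(n) < config$htn_frac,
      surgery = factor(sample(names(config$surgery_fracs), n, replace = TRUE,
                              prob = config$surgery_fracs),
                       levels = c("restrictive", "mixed", "malabsorptive")),
      stringsAsFactors = FALSE
    )
  })
}

## Covariate-driven expectation of nadir %TWL. Effects are modest and fixed:
## malabsorptive procedures lose most, restrictive least; older, heavier,
## diabetic patients lose slightly less. Values chosen once to keep the
## cohort mean near 38.8% with SD dominated by noise_sd.
baseline_twl_nadir <- function(cov) {
  38.8 +
    c(restrictive = -3, mixed = 0, malabsorptive = 2)[as.character(cov$surgery)] -
    0.08 * (cov$age - 44.79) -
    0.05 * (cov$bmi0 - 44.87) +
    0.8 * (cov$sex == "female") - 0.55 -
    1.5 * cov$t2d - 0.5 * cov$htn
}

## effect_spec -> per-patient latent shifts, one column per target
planted_shifts <- function(gm, effect_spec) {
  shifts <- matrix(0, nrow(gm$dosage), 3,
                   dimnames = list(NULL, c("twl_nadir", "twl_6y", "wr_mwl")))
  if (is.null(effect_spec) || nrow(effect_spec) == 0) return(shifts)
  missing_rs <- setdiff(effect_spec$rsid, colnames(gm$dosage))
  if (length(missing_rs))
    abort(paste0("effect_spec rsid(s) not in genotypes: ",
                 paste(missing_rs, collapse = ", ")), "bariGRS_unknown_snp")
  for (i in seq_len(nrow(effect_spec))) {
    d <- gm$dosage[, effect_spec$rsid[i]]
    enc <- encode_inheritance(d, model = effect_spec$model[i])[, 1]
    enc[is.na(enc)] <- 0          # missing call contributes no genetic shift
    tgt <- effect_spec$target[i]
    shifts[, tgt] <- shifts[, tgt] + effect_spec$effect[i] * enc
  }
  shifts
}

#' Simulate longitudinal weight trajectories
#'
#' Generates one weight record per configured visit year for each patient.
#' The year-0 weight equals `bmi0 * height^2`. The latent nadir %TWL is a
#' covariate-driven baseline plus planted genetic shifts plus
#' `Normal(0, noise_sd)`; latent weight regain (% of maximum weight lost) is
#' log-normal with configured median and log-sd; the latent year-6 %TWL is
#' `twl_nadir * (1 - wr/100)` plus any planted year-6 shifts. The weight
#' curve declines exponentially to the nadir (year 1 or 2), then regains
#' linearly through the end of follow-up. Optional per-visit Gaussian
#' measurement noise (kg) is added to postoperative visits.
#'
#' @param genotypes a [genotype_matrix] (patient ids must match `covariates`).
#' @param covariates covariate table from [simulate_covariates()].
#' @param config a [sim_config]; randomness uses `config$seed`.
#' @return a long `data.frame` of class `weight_trajectories` with columns
#'   `patient_id, visit_year, weight_kg`, plus attribute `latent` holding the
#'   generating per-patient phenotype values (for parameter-recovery tests).
#' @export
simulate_trajectories <- function(genotypes, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(identical(sort(genotypes$patient_ids),
                        sort(covariates$patient_id)),
              "genotype and covariate patient ids must match")
  cov <- covariates[match(genotypes$patient_ids, covariates$patient_id), ]
  n <- nrow(cov)
  shifts <- planted_shifts(genotypes, config$effect_spec)
  with_local_seed(config$seed + 2L, {
    twl_nadir <- baseline_twl_nadir(cov) + shifts[, "twl_nadir"] +
      stats::rnorm(n, 0, config$noise_sd)
    twl_nadir <- pmin(pmax(twl_nadir, 5), 80)
    wr <- config$wr_median *
      exp(config$wr_sdlog * stats::rnorm(n)) + shifts[, "wr_mwl"]
    wr <- pmin(pmax(wr, 0), 95)
    twl_6y <- twl_nadir * (1 - wr / 100) + shifts[, "twl_6y"]
    twl_6y <- pmin(pmax(twl_6y, 1), 80)
    nadir_year <- sample(c(1L, 2L), n, replace = TRUE,
                         prob = config$nadir_year_probs)

    w0 <- cov$bmi0 * cov$height^2
    w_nadir <- w0 * (1 - twl_nadir / 100)
    w6 <- w0 * (1 - twl_6y / 100)
    yrs <- config$visit_years
    weight <- matrix(NA_real_, n, length(yrs))
    cshape <- 1.5                       # exponential decline shape
    for (j in seq_along(yrs)) {
      t <- yrs[j]
      pre <- t <= nadir_year
      frac <- (1 - exp(-cshape * t)) / (1 - exp(-cshape * nadir_year))
      w_pre <- w0 - (w0 - w_nadir) * frac
      slope <- (w6 - w_nadir) / (6 - nadir_year)
      w_post <- w_nadir + slope * (t - nadir_year)
      weight[, j] <- ifelse(pre, w_pre, w_post)
    }
    weight[, yrs == 0] <- w0            # exact baseline, never noisy
    if (config$visit_noise_sd > 0) {
      post <- yrs >= 1
      weight[, post] <- weight[, post] +
        stats::rnorm(n * sum(post), 0, config$visit_noise_sd)
    }
    out <- data.frame(
      patient_id = rep(cov$patient_id, each = length(yrs)),
      visit_year = rep(yrs, times = n),
      weight_kg = round(as.vector(t(weight)), 4)
    )
    attr(out, "latent") <- data.frame(
      patient_id = cov$patient_id, twl_nadir = twl_nadir,
      twl_6y = twl_6y, wr_mwl = wr, nadir_year = nadir_year)
    class(out) <- c("weight_trajectories", "data.frame")
    out
  })
}

#' Simulate a complete synthetic cohort
#'
#' Wraps [simulate_covariates()], [simulate_genotypes()] and
#' [simulate_trajectories()] under one master seed. Optionally writes the
#' cohort to `out_dir` in the package's external formats (manifest TSV,
#' genotype TSV and VCF, covariate CSV, trajectory CSV).
#'
#' @param config a [sim_config].
#' @param manifest an [snp_manifest]; default the packaged 48-SNP panel.
#' @param out_dir optional directory for fixture files.
#' @return a list with elements `genotypes`, `covariates`, `trajectories`,
#'   `config`, `manifest`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 50, seed = 7))
#' nrow(cohort$covariates)
#' @export
simulate_cohort <- function(config = sim_config(),
                            manifest = default_snp_manifest(),
                            out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  covariates <- simulate_covariates(config)
  genotypes <- simulate_genotypes(manifest, config$n_patients,
                                  seed = config$seed + 1L,
                                  missing_rate = config$missing_genotype_rate)
  trajectories <- simulate_trajectories(genotypes, covariates, config)
  cohort <- list(genotypes = genotypes, covariates = covariates,
                 trajectories = trajectories, config = config,
                 manifest = genotypes$manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_snp_manifest(manifest, file.path(out_dir, "snp_manifest.tsv"))
    write_genotype_tsv(genotypes, file.path(out_dir, "genotypes.tsv"))
    write_genotype_vcf(genotypes, file.path(out_dir, "genotypes.vcf"))
    write_covariates(covariates, file.path(out_dir, "covariates.csv"))
    write_trajectories(trajectories, file.path(out_dir, "trajectories.csv"))
  }
  cohort
}
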