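make_assoc_data <- function(n = 240, maf = 0.3, beta_dom = 0, seed = 5,
                            sd = 6) {
  set.seed(seed)
  d <- sample(0:2, n, TRUE, c((1 - maf)^2, 2 * maf * (1 - maf), maf^2))
  cv <- test_covariates(n)
  y <- 38 - 0.05 * cv$age + 2 * (cv$surgery == "malabsorptive") -
    1.5 * cv$t2d + beta_dom * (d >= 1) + rnorm(n, 0, sd)
  list(d = d, y = y, cv = cv)
}

test_that("unadjusted log-additive fit equals simple regression on dose", {
  dat <- make_assoc_data(60)
  fit <- fit_inheritance_models(dat$d, dat$y, covariates = NULL)
  ref <- stats::lm(dat$y ~ dat$d)
  la <- fit$fits$log_additive
  expect_equal(la$coef$estimate, unname(coef(ref)[2]))
  expect_equal(la$coef$se, unname(sqrt(diag(vcov(ref)))[2]))
  expect_equal(la$p_value, anova(stats::lm(dat$y ~ 1), ref)[2, "Pr(>F)"])
})

test_that("fits are invariant to patient order", {
  dat <- make_assoc_data(200)
  f1 <- fit_inheritance_models(dat$d, dat$y, dat$cv)
  perm <- sample(200)
  f2 <- fit_inheritance_models(dat$d[perm], dat$y[perm], dat$cv[perm, ])
  for (m in names(f1$fits)) {
    expect_equal(f1$fits[[m]]$aic, f2$fits[[m]]$aic)
    expect_equal(f1$fits[[m]]$p_value, f2$fits[[m]]$p_value)
    expect_equal(f1$fits[[m]]$coef$estimate, f2$fits[[m]]$coef$estimate)
  }
  expect_identical(f1$best_model, f2$best_model)
})

test_that("AIC selection breaks ties by genetic df then fixed model order", {
  sel <- bariGRS:::select_best_model
  aic <- c(codominant = 1000.2, dominant = 998.1, recessive = 1001.0,
           overdominant = 999.3, log_additive = 998.1)
  kg <- c(codominant = 2, dominant = 1, recessive = 1, overdominant = 1,
          log_additive = 1)
  ## exact AIC tie, equal genetic df: fixed order prefers log-additive
  expect_identical(sel(aic, kg), "log_additive")
  ## tie between a 1-df and the 2-df codominant model: fewer parameters win
  aic2 <- c(codominant = 998.1, dominant = 998.1, recessive = 1001)
  kg2 <- c(codominant = 2, dominant = 1, recessive = 1)
  expect_identical(sel(aic2, kg2), "dominant")
  ## no tie: plain argmin
  aic[["recessive"]] <- 990
  expect_identical(sel(aic, kg), "recessive")
})

test_that("degenerate encodings are skipped, empty designs error", {
  dat <- make_assoc_data(200)
  d_no_hom <- pmin(dat$d, 1L)           # no alternate homozygotes
  fit <- fit_inheritance_models(d_no_hom, dat$y, dat$cv)
  expect_match(fit$skipped[["recessive"]], "non-estimable")
  expect_false("recessive" %in% names(fit$fits))
  ## monomorphic column: nothing estimable
  expect_error(fit_inheritance_models(rep(0L, 200), dat$y, dat$cv),
               class = "bariGRS_no_result")
  expect_error(fit_inheritance_models(rep(NA_integer_, 200), dat$y, dat$cv),
               class = "bariGRS_insufficient_data")
})

test_that("a planted dominant effect is detected with the right risk allele", {
  dat <- make_assoc_data(375, beta_dom = -5, seed = 12, sd = 8)
  fit <- fit_inheritance_models(dat$d, dat$y, dat$cv, rsid = "rs1")
  expect_true(fit$significant)
  expect_lt(fit$estimate, 0)
  expect_true(fit$best_model %in% c("dominant", "log_additive", "codominant"))
  ## carriers lose less -> alternate allele is the risk allele (loss direction)
  rc <- call_risk_allele(fit, "loss", ref = "A", alt = "G")
  expect_identical(rc$risk_allele, "G")
  expect_equal(rc$points, c(0, 1, 2))
  ## same fit read as a regain phenotype flips the call
  rc2 <- call_risk_allele(fit, "regain", ref = "A", alt = "G")
  expect_identical(rc2$risk_allele, "A")
  expect_equal(rc2$points, c(2, 1, 0))
  ## non-significant fits return no risk allele
  null_fit <- fit
  null_fit$significant <- FALSE
  expect_true(is.na(call_risk_allele(null_fit, "loss", "A", "G")$risk_allele))
})

test_that("logistic family gives odds ratios consistent with glm", {
  set.seed(31)
  n <- 300
  d <- sample(0:2, n, TRUE, c(0.49, 0.42, 0.09))
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * (d >= 1)))
  fit <- fit_inheritance_models(d, y, covariates = NULL, family = "logistic")
  ref <- stats::glm(y ~ I(d >= 1), family = binomial())
  dom <- fit$fits$dominant
  expect_equal(dom$coef$estimate, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(dom$coef$or, exp(unname(coef(ref)[2])), tolerance = 1e-6)
  expect_equal(dom$p_value,
               pchisq(ref$null.deviance - ref$deviance, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("association scan shapes, QC and risk-allele gating", {
  man <- test_manifest(4, maf = c(0.3, 0.25, 0.4, 0.35))
  cfg <- sim_config(n_patients = 150, seed = 44, missing_genotype_rate = 0)
  cohort <- simulate_cohort(cfg, manifest = man)
  ## force one SNP below the call-rate threshold
  set.seed(1)
  cohort$genotypes$dosage[sample(150, 15), "rs2"] <- NA
  ph <- derive_phenotypes(cohort$trajectories, cohort$covariates)
  scan <- run_association_scan(cohort$genotypes, ph, cohort$covariates)
  expect_equal(nrow(scan), 4 * 3)
  expect_false(scan$qc_pass[scan$rsid == "rs2"][1])
  ## QC-failing SNPs never receive a risk allele
  expect_true(all(is.na(scan$risk_allele[!scan$qc_pass])))
  expect_true(all(scan$hwe_p >= 0 & scan$hwe_p <= 1))
  ## model table covers the fitted models and flags exactly one selection
  mt <- attr(scan, "model_table")
  sel <- tapply(mt$selected, paste(mt$rsid, mt$phenotype), sum)
  expect_true(all(sel == 1))
  s <- summary(scan)
  expect_equal(s$n_tests, 12)
  ## BH option: adjusted gate is never more liberal than the raw one
  scan_fdr <- run_association_scan(cohort$genotypes, ph, cohort$covariates,
                                   fdr = TRUE)
  expect_true(all(scan_fdr$p_adj >= scan_fdr$p_value - 1e-12, na.rm = TRUE))
  expect_lte(sum(scan_fdr$significant, na.rm = TRUE),
             sum(scan$significant, na.rm = TRUE))
})

test_that("the full 48-SNP x 3-phenotype scan emits 144 rows", {
  cfg <- sim_config(n_patients = 120, seed = 77)
  cohort <- simulate_cohort(cfg)
  ph <- derive_phenotypes(cohort$trajectories, cohort$covariates)
  scan <- run_association_scan(cohort$genotypes, ph, cohort$covariates)
  expect_equal(nrow(scan), 144)
  expect_equal(length(unique(scan$rsid)), 48)
})
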