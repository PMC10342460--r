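test_that("simulate_genotypes honours MAF, shape and determinism", {
  man0 <- test_manifest(2, maf = c(0, 0.3))
  gm <- simulate_genotypes(man0, 100, seed = 3)
  expect_true(all(gm$dosage[, "rs1"] == 0L))   # maf 0: all ref-homozygous

  gm48 <- simulate_genotypes(default_snp_manifest(), 375, seed = 5)
  expect_equal(dim(gm48$dosage), c(375L, 48L))

  ## maf 0.5, n = 10000: class fractions within 3 binomial SEs of 1/4, 1/2, 1/4
  gmh <- simulate_genotypes(test_manifest(1, maf = 0.5), 10000, seed = 9)
  frac <- tabulate(gmh$dosage[, 1] + 1L, 3) / 10000
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
  expect_true(all(abs(frac - c(0.25, 0.5, 0.25)) <= 3 * se))

  expect_identical(simulate_genotypes(man0, 50, seed = 7, missing_rate = 0.1),
                   simulate_genotypes(man0, 50, seed = 7, missing_rate = 0.1))
  expect_error(simulate_genotypes(man0, 0, seed = 1), "n must be")
})

test_that("missingness is inserted near the requested rate", {
  gm <- simulate_genotypes(test_manifest(10), 2000, seed = 2,
                           missing_rate = 0.02)
  expect_lt(abs(mean(is.na(gm$dosage)) - 0.02), 0.005)
})

test_that("covariate marginals match the configuration in expectation", {
  cfg <- sim_config(n_patients = 100000L, seed = 21)
  cv <- simulate_covariates(cfg)
  expect_lt(abs(mean(cv$sex == "female") - 0.69), 0.01)
  expect_lt(abs(mean(cv$t2d) - 0.357), 0.01)
  expect_lt(abs(mean(cv$htn) - 0.49), 0.01)
  expect_lt(abs(mean(cv$surgery == "mixed") - 0.5466), 0.01)
  expect_lt(abs(mean(cv$bmi0) - 44.87), 0.1)
  expect_true(all(cv$height >= 1.40 & cv$height <= 2.10))
})

test_that("trajectories are covariate-determined when all noise is off", {
  man <- test_manifest(1)
  cfg <- sim_config(n_patients = 6, seed = 4, noise_sd = 0, wr_sdlog = 0,
                    nadir_year_probs = c(1, 0), missing_genotype_rate = 0)
  gm <- simulate_genotypes(man, 6, seed = 5)
  cv <- test_covariates(6)
  cv[] <- lapply(cv, function(x) if (is.factor(x)) x else x)  # keep types
  ## make patients 1 and 4 identical in covariates
  cv[4, -1] <- cv[1, -1]
  tr <- simulate_trajectories(gm, cv, cfg)
  w1 <- tr$weight_kg[tr$patient_id == cv$patient_id[1]]
  w4 <- tr$weight_kg[tr$patient_id == cv$patient_id[4]]
  expect_identical(w1, w4)
  ## year-0 weight is exactly bmi0 * height^2
  w0 <- tr$weight_kg[tr$visit_year == 0]
  expect_equal(w0, round(cv$bmi0 * cv$height^2, 4))
})

test_that("planted dominant effect shifts carriers by exactly the effect size", {
  man <- test_manifest(1, maf = 0.4)
  n <- 400
  cfg <- sim_config(n_patients = n, seed = 8, noise_sd = 0, wr_sdlog = 0,
                    nadir_year_probs = c(1, 0), missing_genotype_rate = 0,
                    effect_spec = data.frame(rsid = "rs1", target = "twl_6y",
                                             model = "dominant", effect = -5))
  gm <- simulate_genotypes(man, n, seed = 9)
  cv <- test_covariates(n)
  cv[-1] <- lapply(cv[-1], function(x) rep(x[1], n))   # identical covariates
  tr <- simulate_trajectories(gm, cv, cfg)
  ph <- derive_phenotypes(tr, cv)
  carrier <- gm$dosage[, 1] >= 1
  diff <- mean(ph$twl_6y[carrier]) - mean(ph$twl_6y[!carrier])
  expect_equal(diff, -5, tolerance = 1e-3)
})

test_that("unknown effect_spec rsid raises an unknown-SNP error", {
  man <- test_manifest(1)
  gm <- simulate_genotypes(man, 10, seed = 1)
  cfg <- sim_config(n_patients = 10, seed = 1,
                    effect_spec = data.frame(rsid = "rs999", target = "twl_6y",
                                             model = "dominant", effect = -5))
  expect_error(simulate_trajectories(gm, test_covariates(10), cfg),
               class = "bariGRS_unknown_snp")
})

test_that("simulate_cohort is bit-reproducible and matches its latents", {
  cfg <- sim_config(n_patients = 40, seed = 33)
  man <- test_manifest(3)
  c1 <- simulate_cohort(cfg, manifest = man)
  c2 <- simulate_cohort(cfg, manifest = man)
  expect_identical(c1, c2)
  ## derived phenotypes agree with the generating latent values (weights are
  ## rounded to 4 decimals when written into the trajectory table)
  ph <- derive_phenotypes(c1$trajectories, c1$covariates)
  lat <- attr(c1$trajectories, "latent")
  expect_equal(ph$twl_nadir, lat$twl_nadir, tolerance = 1e-4)
  expect_equal(ph$twl_6y, lat$twl_6y, tolerance = 1e-4)
  expect_equal(ph$nadir_year, lat$nadir_year)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(surgery_fracs = c(restrictive = 0.5, mixed = 0.5,
                                            malabsorptive = 0.1)), "sum to 1")
  expect_error(sim_config(effect_spec = data.frame(rsid = "rs1",
                                                   target = "bogus",
                                                   model = "dominant",
                                                   effect = 1)),
               "target")
})
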