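test_that("find_nadir returns the minimum postoperative weight, earliest tie", {
  tr <- function(w) data.frame(visit_year = seq_along(w) - 1, weight_kg = w)
  expect_equal(find_nadir(tr(c(120, 85, 80, 82, 84))),
               list(nadir_weight = 80, nadir_year = 2L))
  expect_equal(find_nadir(tr(c(120, 90, 90, 90))),
               list(nadir_weight = 90, nadir_year = 1L))
  expect_equal(find_nadir(tr(c(120, 100, 95, 90))),
               list(nadir_weight = 90, nadir_year = 3L))
  expect_error(find_nadir(tr(120)), class = "bariGRS_insufficient_data")
})

test_that("compute_weight_metrics implements the three formulas", {
  m <- compute_weight_metrics(w0 = 120, wt = 80, nadir = 75, height = 1.70)
  expect_equal(m$twl, 100 * 40 / 120)
  expect_equal(m$ewl, 100 * 40 / (120 - 25 * 1.7^2))  # 83.77 to 2 dp
  expect_equal(round(m$ewl, 2), 83.77)
  expect_equal(m$wr_mwl, 100 * 5 / 45)                # 11.11 to 2 dp
  ## boundary cases
  expect_equal(compute_weight_metrics(120, 80, 80, 1.7)$wr_mwl, 0)
  none <- compute_weight_metrics(120, 120, 80, 1.7)
  expect_equal(none$twl, 0)
  expect_equal(none$ewl, 0)
  ## error contracts
  expect_error(compute_weight_metrics(70, 60, 55, 1.70),
               class = "bariGRS_undefined_ewl")   # w0 <= ideal weight
  expect_error(compute_weight_metrics(120, 80, 120, 1.70),
               class = "bariGRS_undefined_wr")
})

test_that("window rule selects closest-to-year-6 visit, later on ties", {
  cv <- test_covariates(3)
  tr <- rbind(
    data.frame(patient_id = "P0001", visit_year = c(0, 1, 5, 7),
               weight_kg = c(120, 90, 95, 93)),
    data.frame(patient_id = "P0002", visit_year = 0:3,
               weight_kg = c(130, 100, 95, 96)),
    data.frame(patient_id = "P0003", visit_year = c(0, 2, 5),
               weight_kg = c(110, 80, 85)))
  ph <- derive_phenotypes(tr, cv, followup_year = 6, window = 1)
  ## P0001: years 5 and 7 tie in distance -> later visit (year 7)
  expect_equal(ph$w6_year[ph$patient_id == "P0001"], 7L)
  expect_equal(ph$w6[ph$patient_id == "P0001"], 93)
  ## P0002: no visit in [5, 7] -> excluded from year-6, retained for nadir
  p2 <- ph[ph$patient_id == "P0002", ]
  expect_false(p2$included_6y)
  expect_true(p2$included_nadir)
  expect_match(p2$exclusion_reason, "no follow-up weight in window")
  expect_true(is.na(p2$twl_6y))
  expect_false(is.na(p2$twl_nadir))
  ## P0003: single window visit at year 5
  expect_equal(ph$w6_year[ph$patient_id == "P0003"], 5L)
})

test_that("binary codings use strict inequalities", {
  cv <- test_covariates(1)
  cv$height <- 1.70   # ideal weight 72.25
  ## engineer ewl_6y exactly 50: w0 - w6 = 0.5 * (w0 - 72.25)
  w0 <- 130; w6 <- w0 - 0.5 * (w0 - 25 * 1.7^2)
  tr <- data.frame(patient_id = "P0001", visit_year = c(0, 1, 6),
                   weight_kg = c(w0, w6 - 10, w6))
  ph <- derive_phenotypes(tr, cv)
  expect_equal(ph$ewl_6y, 50)
  expect_false(ph$ewl6y_gt50)   # boundary falls in the negative class
  ## engineer wr_mwl exactly 20
  nadir <- 80; w6b <- nadir + 0.2 * (w0 - nadir)
  tr2 <- data.frame(patient_id = "P0001", visit_year = c(0, 1, 6),
                    weight_kg = c(w0, nadir, w6b))
  ph2 <- derive_phenotypes(tr2, cv)
  expect_equal(ph2$wr_mwl, 20)
  expect_false(ph2$wr_gt20)
})

test_that("phenotype invariants hold on random trajectories", {
  set.seed(71)
  cv <- test_covariates(30)
  for (rep in 1:20) {
    i <- sample(30, 1)
    yrs <- sort(sample(1:8, sample(3:8, 1)))
    w0 <- runif(1, 90, 180)
    w <- c(w0, w0 * runif(length(yrs), 0.55, 0.99))
    tr <- data.frame(patient_id = cv$patient_id[i],
                     visit_year = c(0, yrs), weight_kg = w)
    ph <- derive_phenotypes(tr, cv[i, , drop = FALSE])
    ## twl at nadir is the max per-visit twl
    expect_equal(ph$twl_nadir, max(100 * (w0 - w[-1]) / w0))
    ## wr_mwl is scale-invariant
    tr2 <- tr; tr2$weight_kg <- tr$weight_kg * 1.37
    ph2 <- derive_phenotypes(tr2, cv[i, , drop = FALSE])
    expect_equal(ph2$wr_mwl, ph$wr_mwl, tolerance = 1e-10)
    ## ewl exceeds twl whenever defined (smaller denominator)
    if (!is.na(ph$ewl_nadir) && ph$twl_nadir > 0)
      expect_gt(ph$ewl_nadir, ph$twl_nadir)
  }
})

test_that("patients without baseline or postoperative weights are flagged", {
  cv <- test_covariates(2)
  tr <- rbind(
    data.frame(patient_id = "P0001", visit_year = c(1, 2),
               weight_kg = c(90, 85)),                       # no year 0
    data.frame(patient_id = "P0002", visit_year = 0, weight_kg = 120))
  ph <- derive_phenotypes(tr, cv)
  expect_match(ph$exclusion_reason[ph$patient_id == "P0001"], "baseline")
  expect_match(ph$exclusion_reason[ph$patient_id == "P0002"], "postoperative")
  expect_false(any(ph$included_nadir))
  expect_equal(nrow(ph), 2)   # recorded, never dropped
})
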