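make_def <- function(rsids, pts = matrix(rep(c(0, 1, 2), length(rsids)),
                                         ncol = 3, byrow = TRUE)) {
  rs_definition("twl_6y", data.frame(
    rsid = rsids, gene = "G", risk_allele = "G", rule = "alt-risk",
    pts0 = pts[, 1], pts1 = pts[, 2], pts2 = pts[, 3],
    p_value = 0.01, best_model = "dominant", flagged = FALSE,
    stringsAsFactors = FALSE))
}

make_gm_multi <- function(dosage) {
  m <- ncol(dosage)
  man <- test_manifest(m)
  colnames(dosage) <- man$rsid
  rownames(dosage) <- sprintf("P%04d", seq_len(nrow(dosage)))
  genotype_matrix(dosage, man)
}

test_that("published score definitions reproduce the printed ranges", {
  def6 <- rs_definition_from_reported("twl_6y")
  expect_equal(nrow(def6$entries), 6)
  expect_equal(def6$max_score, 12L)
  defn <- rs_definition_from_reported("twl_nadir")
  expect_equal(nrow(defn$entries), 3)
  expect_equal(defn$max_score, 6L)
  defw <- rs_definition_from_reported("wr_mwl")
  expect_equal(nrow(defw$entries), 3)
  expect_equal(defw$max_score, 6L)
})

test_that("scoring applies the 2/1/0 rule with missing-as-zero", {
  dos <- rbind(c(2L, 2L, 2L),    # risk-homozygous everywhere
               c(0L, 0L, 0L),    # no risk alleles
               c(1L, 0L, 0L),    # one heterozygote
               c(NA, 2L, 1L))    # one missing call
  gm <- make_gm_multi(dos)
  def <- make_def(paste0("rs", 1:3))
  sc <- score_patients(gm, def)
  expect_equal(sc$score, c(6L, 0L, 1L, 3L))
  expect_equal(sc$n_missing_snps, c(0L, 0L, 0L, 1L))
  ## exclude policy blanks patients with missing scored genotypes
  sc2 <- score_patients(gm, def, missing_policy = "exclude")
  expect_equal(is.na(sc2$score), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("scores are additive over disjoint definitions and bounded", {
  set.seed(12)
  dos <- matrix(sample(c(0:2, NA), 40 * 4, TRUE, prob = c(.4, .3, .2, .1)),
                40, 4)
  gm <- make_gm_multi(dos)
  defA <- make_def(c("rs1", "rs2"))
  defB <- make_def(c("rs3", "rs4"))
  defAB <- make_def(paste0("rs", 1:4))
  sA <- score_patients(gm, defA)$score
  sB <- score_patients(gm, defB)$score
  sAB <- score_patients(gm, defAB)$score
  expect_equal(sAB, sA + sB)
  expect_true(all(sAB >= 0 & sAB <= defAB$max_score))
  ## permutation of entries leaves scores unchanged
  defP <- make_def(c("rs4", "rs2", "rs3", "rs1"))
  expect_equal(score_patients(gm, defP)$score, sAB)
})

test_that("scoring refuses empty definitions and unknown SNPs", {
  gm <- make_gm_multi(matrix(0L, 3, 2))
  empty <- rs_definition("twl_6y", make_def("rs1")$entries[0, ])
  expect_error(score_patients(gm, empty), class = "bariGRS_empty_definition")
  expect_error(score_patients(gm, make_def("rs99")),
               class = "bariGRS_unknown_snp")
  ## a scan with no significant SNPs warns and yields an empty definition
  scan <- data.frame(rsid = "rs1", gene = "G", phenotype = "twl_6y",
                     significant = FALSE, qc_pass = TRUE,
                     risk_allele = NA, risk_rule = NA,
                     pts0 = NA_real_, pts1 = NA_real_, pts2 = NA_real_,
                     p_value = 0.5, best_model = "dominant")
  expect_warning(def <- build_rs_definition(scan, "twl_6y"), "empty")
  expect_equal(nrow(def$entries), 0)
})

test_that("percentile categorization follows the hand-computed oracle", {
  res <- categorize_scores(c(4, 4, 5, 5, 6, 6, 7, 8))
  ## linear-interpolation 75th percentile of the 8 ordered scores: 6.25
  expect_equal(res$cutoff, 6.25)
  expect_equal(as.character(res$category),
               c("low", "low", "low", "low", "low", "low", "high", "high"))
  expect_equal(res$realized_threshold, 7L)
  ## permutation invariance of the cutoff
  expect_equal(categorize_scores(c(8, 5, 6, 4, 7, 4, 6, 5))$cutoff, 6.25)
  ## no score at or below the cutoff is ever high
  set.seed(9)
  for (i in 1:20) {
    s <- sample(0:12, 30, TRUE)
    r <- categorize_scores(s)
    expect_true(all(s[r$category == "high"] > r$cutoff))
  }
})

test_that("degenerate score distributions warn and stay low", {
  expect_warning(res <- categorize_scores(rep(5, 10)), "distinct")
  expect_true(all(res$category == "low"))
  expect_true(is.na(res$realized_threshold))
})

test_that("a scored_cohort round-trips through categorize and JSON/CSV io", {
  dos <- matrix(sample(0:2, 30, TRUE), 10, 3)
  gm <- make_gm_multi(dos)
  def <- make_def(paste0("rs", 1:3))
  scored <- categorize_scores(score_patients(gm, def), percentile = 75)
  expect_s3_class(scored, "scored_cohort")
  expect_true("category" %in% names(scored))
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(p1, p2)))
  write_rs_definition(def, p1)
  def2 <- read_rs_definition(p1)
  expect_equal(def2$max_score, def$max_score)
  expect_equal(def2$entries$rsid, def$entries$rsid)
  write_scores(scored, p2)
  back <- read_scores(p2)
  expect_equal(back$score, scored$score)
  expect_equal(as.character(back$category), as.character(scored$category))
})
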