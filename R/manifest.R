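#' SNP panel manifest
#'
#' A manifest describes the candidate panel: one row per biallelic variant
#' with its gene, rsid, reference and alternate allele letters and a minor
#' (alternate) allele frequency used by the simulator. The packaged default
#' panel covers the 48 variants across 13 appetite-regulation genes (ghrelin,
#' incretin, neuropeptide Y, clock and related pathways) analysed by this
#' pipeline; variants are keyed by rsid and allele letters, not genomic
#' coordinates.
#'
#' @param gene character vector of gene symbols.
#' @param rsid character vector of unique rsids.
#' @param ref,alt single-letter alleles in `A/C/G/T`; `ref != alt` per row.
#' @param maf alternate-allele frequency in `[0, 0.5]`.
#' @return a `data.frame` of class `snp_manifest` with columns
#'   `gene, rsid, ref, alt, maf`.
#' @examples
#' snp_manifest("FTO", "rs9939609", "T", "A", 0.4)
#' @export
snp_manifest <- function(gene, rsid, ref, alt, maf) {
  df <- data.frame(gene = as.character(gene), rsid = as.character(rsid),
                   ref = as.character(ref), alt = as.character(alt),
                   maf = as.numeric(maf), stringsAsFactors = FALSE)
  validate_manifest(df)
}

validate_manifest <- function(df) {
  assert_that(all(c("gene", "rsid", "ref", "alt", "maf") %in% names(df)),
              "manifest must have columns gene, rsid, ref, alt, maf")
  assert_that(!anyDuplicated(df$rsid), "manifest rsids must be unique")
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  assert_that(all(ok_allele(df$ref)) && all(ok_allele(df$alt)),
              "alleles must be one of A/C/G/T")
  assert_that(all(df$ref != df$alt), "ref and alt alleles must differ")
  assert_that(all(is.na(df$maf) | (df$maf >= 0 & df$maf <= 0.5)),
              "maf must lie in [0, 0.5]")
  class(df) <- c("snp_manifest", "data.frame")
  df
}

#' Read / write a SNP manifest TSV
#'
#' The on-disk dialect is a UTF-8 tab-separated file with header
#' `gene  rsid  ref  alt  maf`. Missing MAFs may be left blank; [default_snp_manifest()]
#' fills them uniformly in `[0.1, 0.45]` (the panel was restricted to common
#' variants, frequency above 10%).
#'
#' @param path file path.
#' @return `read_snp_manifest`: an `snp_manifest`.
#' @export
read_snp_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(maf = "numeric"))
  validate_manifest(df)
}

#' @rdname read_snp_manifest
#' @param manifest an `snp_manifest`.
#' @export
write_snp_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The packaged default 48-SNP / 13-gene panel
#'
#' Gene, rsid and reference allele follow the published candidate panel. The
#' alternate alleles and MAFs are *synthetic* defaults (the study reported
#' neither): alt is the transition partner of the reference allele except
#' where a published risk allele pins it, and MAFs were drawn once, uniformly
#' in `[0.1, 0.45]`, and frozen into the packaged file.
#'
#' @param fill_maf if `TRUE` (default), any missing MAF is filled uniformly in
#'   `[0.1, 0.45]` using `maf_seed`.
#' @param maf_seed seed for MAF filling.
#' @return an `snp_manifest` with 48 rows across 13 genes.
#' @export
default_snp_manifest <- function(fill_maf = TRUE, maf_seed = 4288L) {
  path <- system.file("extdata", "snp_panel_synthetic.tsv",
                      package = "bariGRS", mustWork = TRUE)
  m <- read_snp_manifest(path)
  if (fill_maf && anyNA(m$maf)) {
    idx <- which(is.na(m$maf))
    m$maf[idx] <- with_local_seed(maf_seed,
                                  round(stats::runif(length(idx), 0.1, 0.45), 3))
  }
  m
}

#' Published per-SNP association summary
#'
#' The eight variants reported as significantly associated with weight
#' response in the source cohort (adjusted mean differences between risk and
#' baseline genotype groups, 95% CI and p), one row per SNP-phenotype pair,
#' together with the published risk allele. These are *inputs* (printed
#' summary statistics), not results of this package; they seed
#' [rs_definition_from_reported()] and the acceptance checks.
#'
#' @return a `data.frame` with columns `gene, rsid, phenotype, mean_diff,
#'   ci_lo, ci_hi, p_value, risk_allele`.
#' @export
reported_associations <- function() {
  df <- read.delim(system.file("extdata", "reported_associations.tsv",
                               package = "bariGRS", mustWork = TRUE),
                   stringsAsFactors = FALSE)
  df
}

#' Published risk-score-level effect estimates
#'
#' Effects of the high risk-score category (score at or above the realized
#' 7-point threshold) versus the low category on weight-response outcomes, as
#' published: adjusted mean differences for quantitative outcomes and odds
#' ratios for the binary codings, with 95% CI and p.
#'
#' @return a `data.frame` with columns `score, outcome, type, estimate,
#'   ci_lo, ci_hi, p_value`.
#' @export
reported_rs_effects <- function() {
  data.frame(
    score = c("RS_TWL_6y", "RS_TWL_6y", "RS_WR_MWL", "RS_WR_MWL"),
    outcome = c("twl_6y", "ewl6y_gt50", "wr_mwl", "wr_gt20"),
    type = c("mean_difference", "odds_ratio", "mean_difference", "odds_ratio"),
    estimate = c(-5.37, 0.46, 7.06, 2.01),
    ci_lo = c(-7.97, 0.23, 2.80, 1.22),
    ci_hi = c(-3.62, 0.90, 11.31, 3.31),
    p_value = c(0.0001, 0.026, 0.0012, 0.0059),
    stringsAsFactors = FALSE
  )
}

#' Published cohort counts (demographic / weight-response table)
#'
#' The count/percentage pairs printed for the source cohort of 375 patients,
#' used by the acceptance suite to check that the package's summary
#' arithmetic reproduces the printed percentages exactly.
#'
#' @return a list with `n_total` and named counts.
#' @export
reported_cohort_counts <- function() {
  list(n_total = 375L,
       female = 259L,        # printed 69%
       ewl6y_gt50 = 311L,    # printed 82.93%
       wr_gt20 = 154L)       # printed 41.1%
}
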