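#' Build a phenotype-specific unweighted risk-score definition
#'
#' Collects every QC-passing SNP significantly associated with the phenotype
#' in an association scan, together with its risk allele and per-genotype
#' point values (2 for the risk-allele homozygote, 1 for the heterozygote,
#' 0 otherwise; over-dominant entries score the adverse genotype class with
#' 1 point and are flagged). The maximum attainable score is the sum of the
#' per-entry maxima (2 per allele-directional entry).
#'
#' @param scan a `grs_scan` from [run_association_scan()].
#' @param phenotype phenotype name the score targets.
#' @return an object of class `rs_definition`: `phenotype`, `entries` (a
#'   data.frame with `rsid, gene, risk_allele, rule, pts0, pts1, pts2,
#'   p_value, best_model, flagged`) and `max_score`. With no significant
#'   SNPs a zero-entry definition is returned with a warning; scoring such a
#'   definition is refused.
#' @export
build_rs_definition <- function(scan, phenotype) {
  rows <- scan[scan$phenotype == phenotype & !is.na(scan$significant) &
                 scan$significant & scan$qc_pass & !is.na(scan$pts0), ,
               drop = FALSE]
  entries <- data.frame(
    rsid = rows$rsid, gene = rows$gene, risk_allele = rows$risk_allele,
    rule = rows$risk_rule, pts0 = rows$pts0, pts1 = rows$pts1,
    pts2 = rows$pts2, p_value = rows$p_value, best_model = rows$best_model,
    flagged = is.na(rows$risk_allele), stringsAsFactors = FALSE)
  if (nrow(entries) == 0)
    warning(sprintf("no significant QC-passing SNPs for phenotype '%s'; ",
                    phenotype), "empty risk-score definition", call. = FALSE)
  rs_definition(phenotype, entries)
}

#' @rdname build_rs_definition
#' @param entries entry data.frame (see above); `rs_definition()` is the
#'   low-level constructor.
#' @export
rs_definition <- function(phenotype, entries) {
  needed <- c("rsid", "risk_allele", "pts0", "pts1", "pts2")
  assert_that(all(needed %in% names(entries)),
              paste("entries must have columns", paste(needed, collapse = ", ")))
  assert_that(!anyDuplicated(entries$rsid), "entry rsids must be unique")
  pts <- as.matrix(entries[, c("pts0", "pts1", "pts2")])
  assert_that(nrow(entries) == 0 ||
                all(pts %in% 0:2), "points must be integers in 0..2")
  structure(list(phenotype = phenotype, entries = entries,
                 max_score = if (nrow(entries)) as.integer(sum(apply(pts, 1, max)))
                             else 0L),
            class = "rs_definition")
}

#' @export
print.rs_definition <- function(x, ...) {
  cat(sprintf("<rs_definition> %s: %d SNPs, max score %d\n",
              x$phenotype, nrow(x$entries), x$max_score))
  if (nrow(x$entries))
    print(x$entries[, c("rsid", "risk_allele", "pts0", "pts1", "pts2")])
  invisible(x)
}

#' Risk-score definitions from the published association table
#'
#' Builds the three published phenotype-specific score definitions from the
#' packaged per-SNP association summary ([reported_associations()]): the six
#' SNPs associated with %TWL at year 6 (maximum 12 points), the three SNPs
#' associated with %TWL at nadir (maximum 6 points) and the three SNPs
#' associated with weight regain. Points follow the 2/1/0 rule applied to
#' the published risk allele, oriented by the manifest's allele letters.
#'
#' @param phenotype one of `"twl_nadir"`, `"twl_6y"`, `"wr_mwl"`.
#' @param manifest an [snp_manifest] providing ref/alt orientation.
#' @return an `rs_definition`.
#' @examples
#' rs_definition_from_reported("twl_6y")$max_score   # 12
#' @export
rs_definition_from_reported <- function(phenotype = c("twl_6y", "twl_nadir",
                                                      "wr_mwl"),
                                        manifest = default_snp_manifest()) {
  phenotype <- match.arg(phenotype)
  rep_tab <- reported_associations()
  rows <- rep_tab[rep_tab$phenotype == phenotype, , drop = FALSE]
  mm <- manifest[match(rows$rsid, manifest$rsid), ]
  assert_that(!anyNA(mm$rsid), "reported SNP missing from manifest",
              class = "bariGRS_unknown_snp")
  risk_is_alt <- rows$risk_allele == mm$alt
  assert_that(all(risk_is_alt | rows$risk_allele == mm$ref),
              "published risk allele matches neither manifest allele",
              class = "bariGRS_allele_mismatch")
  entries <- data.frame(
    rsid = rows$rsid, gene = rows$gene, risk_allele = rows$risk_allele,
    rule = ifelse(risk_is_alt, "alt-risk 0/1/2", "ref-risk 2/1/0"),
    pts0 = ifelse(risk_is_alt, 0, 2), pts1 = 1,
    pts2 = ifelse(risk_is_alt, 2, 0),
    p_value = rows$p_value, best_model = NA_character_, flagged = FALSE,
    stringsAsFactors = FALSE)
  rs_definition(phenotype, entries)
}

#' Score patients against a risk-score definition
#'
#' Sums the per-SNP points over the definition's entries for each patient.
#' Missing genotypes contribute 0 points by default (conservative: biases
#' toward the low-score class) and are counted per patient; with
#' `missing_policy = "exclude"` patients missing any scored SNP get `NA`.
#'
#' @param genotypes a [genotype_matrix] containing every definition rsid.
#' @param rs_def an `rs_definition` with at least one entry.
#' @param missing_policy `"zero"` (default) or `"exclude"`.
#' @return a `data.frame` of class `scored_cohort`: `patient_id, score,
#'   n_missing_snps`, with the definition attached as attribute `rs_def`.
#' @export
score_patients <- function(genotypes, rs_def,
                           missing_policy = c("zero", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  assert_that(inherits(rs_def, "rs_definition"), "rs_def must be an rs_definition")
  if (nrow(rs_def$entries) == 0)
    abort("scoring refused: risk-score definition has no entries",
          "bariGRS_empty_definition")
  absent <- setdiff(rs_def$entries$rsid, colnames(genotypes$dosage))
  if (length(absent))
    abort(paste("rsid(s) absent from genotype matrix:",
                paste(absent, collapse = ", ")), "bariGRS_unknown_snp")
  d <- genotypes$dosage[, rs_def$entries$rsid, drop = FALSE]
  pts <- as.matrix(rs_def$entries[, c("pts0", "pts1", "pts2")])
  scored <- vapply(seq_len(nrow(rs_def$entries)), function(j) {
    p <- pts[j, ][d[, j] + 1L]
    p[is.na(p)] <- 0
    p
  }, numeric(nrow(d)))
  scored <- matrix(scored, nrow = nrow(d))
  score <- as.integer(rowSums(scored))
  n_missing <- as.integer(rowSums(is.na(d)))
  if (missing_policy == "exclude") score[n_missing > 0] <- NA_integer_
  out <- data.frame(patient_id = genotypes$patient_ids, score = score,
                    n_missing_snps = n_missing, stringsAsFactors = FALSE)
  attr(out, "rs_def") <- rs_def
  class(out) <- c("scored_cohort", "data.frame")
  out
}

#' Categorize risk scores at a cohort percentile
#'
#' The cutoff is the empirical percentile of the score distribution
#' (linear-interpolation convention, `stats::quantile` type 7); the high
#' category is every score *strictly greater* than the cutoff. The realized
#' integer threshold — the smallest score in the high class — is reported so
#' the grouping can be compared with a published "at least k points" rule.
#'
#' @param scores an integer vector of scores, or a `scored_cohort` (then the
#'   categorized data.frame is returned with attributes).
#' @param percentile percentile in (0, 100); default 75.
#' @return for a vector: a list with `category` (factor low/high), `cutoff`,
#'   `realized_threshold`, `percentile`. For a `scored_cohort`: the input
#'   with a `category` column added and the same values as attributes.
#' @examples
#' categorize_scores(c(4, 4, 5, 5, 6, 6, 7, 8))  # cutoff 6.25, high = {7, 8}
#' @export
categorize_scores <- function(scores, percentile = 75) {
  assert_that(percentile > 0 && percentile < 100,
              "percentile must be in (0, 100)")
  if (inherits(scores, "scored_cohort") || is.data.frame(scores)) {
    res <- categorize_scores(scores$score, percentile)
    scores$category <- res$category
    attr(scores, "cutoff") <- res$cutoff
    attr(scores, "realized_threshold") <- res$realized_threshold
    attr(scores, "percentile") <- percentile
    return(scores)
  }
  ok <- !is.na(scores)
  if (length(unique(scores[ok])) < 2)
    warning("fewer than 2 distinct scores: all patients fall in the low class",
            call. = FALSE)
  cutoff <- unname(stats::quantile(scores[ok], percentile / 100, type = 7))
  category <- factor(ifelse(scores > cutoff, "high", "low"),
                     levels = c("low", "high"))
  high <- scores[ok][scores[ok] > cutoff]
  list(category = category, cutoff = cutoff,
       realized_threshold = if (length(high)) as.integer(min(high)) else NA_integer_,
       percentile = percentile)
}
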