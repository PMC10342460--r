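#' Read and write genotype matrices (TSV dialect and VCF v4.2)
#'
#' The TSV dialect is tab-separated UTF-8 with a mandatory header: first
#' column `patient_id`, one column per rsid, cells `"X/Y"` allele pairs or
#' `"./."` for missing. The VCF writer emits a minimal VCF v4.2 with GT
#' fields and one sample per patient; the panel has no published genomic
#' coordinates, so synthetic positions (chromosome `1`, consecutive
#' positions in manifest order) are written. Readers validate every rsid
#' and allele letter against the manifest and orient dosages to the
#' manifest's reference allele by allele *letter*, not column order, so a
#' VCF with swapped REF/ALT is re-oriented rather than misread.
#'
#' @param gm a [genotype_matrix].
#' @param path file path.
#' @param manifest an [snp_manifest] to validate against.
#' @return readers return a [genotype_matrix]; writers return `path`
#'   invisibly. Round-tripping a matrix through writer and reader is
#'   lossless.
#' @name genotype_io
NULL

#' @rdname genotype_io
#' @export
write_genotype_tsv <- function(gm, path) {
  man <- gm$manifest
  cells <- vapply(seq_len(ncol(gm$dosage)), function(j)
    dosage_to_calls(gm$dosage[, j], man$ref[j], man$alt[j]),
    character(nrow(gm$dosage)))
  cells <- matrix(cells, nrow = nrow(gm$dosage))
  df <- data.frame(patient_id = gm$patient_ids, cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("patient_id", colnames(gm$dosage))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_genotype_tsv <- function(path, manifest) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(names(df)[1] == "patient_id",
              "first TSV column must be patient_id")
  rsids <- names(df)[-1]
  unknown <- setdiff(rsids, manifest$rsid)
  if (length(unknown))
    abort(paste("rsid(s) not in manifest:", paste(unknown, collapse = ", ")),
          "bariGRS_unknown_snp")
  man <- manifest[match(rsids, manifest$rsid), ]
  dosage <- vapply(seq_along(rsids), function(j)
    calls_to_dosage(df[[rsids[j]]], man$ref[j], man$alt[j]),
    integer(nrow(df)))
  dosage <- matrix(as.integer(dosage), nrow = nrow(df),
                   dimnames = list(df$patient_id, rsids))
  genotype_matrix(dosage, manifest, df$patient_id)
}

#' @rdname genotype_io
#' @export
write_genotype_vcf <- function(gm, path) {
  man <- gm$manifest
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bariGRS",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$patient_ids), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(gm$dosage))) {
    d <- gm$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c("1", j, man$rsid[j], man$ref[j], man$alt[j], ".", ".",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname genotype_io
#' @export
read_genotype_vcf <- function(path, manifest) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    abort("reading VCF requires the VariantAnnotation package",
          "bariGRS_missing_dependency")
  vcf <- VariantAnnotation::readVcf(path)
  rsids <- rownames(vcf)
  unknown <- setdiff(rsids, manifest$rsid)
  if (length(unknown))
    abort(paste("rsid(s) not in manifest:", paste(unknown, collapse = ", ")),
          "bariGRS_unknown_snp")
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  gt <- VariantAnnotation::geno(vcf)$GT     # SNPs x samples
  man <- manifest[match(rsids, manifest$rsid), ]
  dosage <- matrix(NA_integer_, ncol(gt), length(rsids),
                   dimnames = list(colnames(gt), rsids))
  for (j in seq_along(rsids)) {
    d <- rep(NA_integer_, ncol(gt))
    g <- gsub("|", "/", gt[j, ], fixed = TRUE)
    d[g %in% c("0/0")] <- 0L
    d[g %in% c("0/1", "1/0")] <- 1L
    d[g %in% c("1/1")] <- 2L
    if (ref[j] == man$ref[j] && alt[j] == man$alt[j]) {
      ## orientation matches the manifest
    } else if (ref[j] == man$alt[j] && alt[j] == man$ref[j]) {
      d <- 2L - d                           # swapped REF/ALT: re-orient
    } else {
      abort(sprintf("allele mismatch at %s: VCF %s/%s vs manifest %s/%s",
                    rsids[j], ref[j], alt[j], man$ref[j], man$alt[j]),
            "bariGRS_allele_mismatch")
    }
    dosage[, j] <- d
  }
  genotype_matrix(dosage, manifest, colnames(gt))
}

#' @rdname genotype_io
#' @export
read_genotype_matrix <- function(path, manifest) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_genotype_vcf(path, manifest)
  else read_genotype_tsv(path, manifest)
}

#' Read / write covariate and trajectory CSV files
#'
#' Covariates: one row per patient (`patient_id, age, sex, bmi0, height,
#' t2d, htn, surgery`). Trajectories: long format
#' (`patient_id, visit_year, weight_kg`).
#'
#' @param x the table to write.
#' @param path file path.
#' @return readers return validated data.frames; writers return `path`.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_covariates <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("patient_id", "age", "sex", "bmi0", "height", "t2d",
                    "htn", "surgery") %in% names(df)),
              "covariate file is missing required columns")
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$surgery <- factor(df$surgery,
                       levels = c("restrictive", "mixed", "malabsorptive"))
  df$t2d <- as.logical(df$t2d)
  df$htn <- as.logical(df$htn)
  assert_that(all(df$height > 0) && all(df$bmi0 > 0),
              "height and bmi0 must be positive")
  assert_that(!anyDuplicated(df$patient_id), "duplicate patient ids")
  df
}

#' @rdname table_io
#' @export
write_trajectories <- function(x, path) {
  utils::write.csv(x[, c("patient_id", "visit_year", "weight_kg")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_trajectories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("patient_id", "visit_year", "weight_kg") %in% names(df)),
              "trajectory file must have patient_id, visit_year, weight_kg")
  assert_that(all(df$weight_kg > 0), "weights must be positive")
  class(df) <- c("weight_trajectories", "data.frame")
  df
}

#' Write association-scan results to a directory
#'
#' Emits `association_results.tsv` (best-model rows, sorted by phenotype,
#' gene, rsid), `model_aic.tsv` (the per-model AIC/p table) and
#' `summary.json` (significant counts, thresholds, seed and an FNV-1a
#' fingerprint of the configuration) with deterministic content: identical
#' inputs produce byte-identical files.
#'
#' @param scan a `grs_scan` (possibly with zero rows).
#' @param out_dir output directory, created if needed.
#' @param config optional configuration list echoed into the summary.
#' @param seed optional seed recorded in the summary.
#' @return invisibly, the paths written.
#' @export
write_results <- function(scan, out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- as.data.frame(scan)
  res <- res[order(res$phenotype, res$gene, res$rsid), , drop = FALSE]
  p1 <- file.path(out_dir, "association_results.tsv")
  utils::write.table(res, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- attr(scan, "model_table")
  if (is.null(mt))
    mt <- data.frame(rsid = character(), gene = character(),
                     phenotype = character(), model = character(),
                     aic = numeric(), p_value = numeric(),
                     n_used = integer(), selected = logical())
  mt <- mt[order(mt$phenotype, mt$gene, mt$rsid, mt$model), , drop = FALSE]
  p2 <- file.path(out_dir, "model_aic.tsv")
  utils::write.table(mt, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, null = "null",
                               digits = NA)
  summ <- list(
    n_snps = length(unique(res$rsid)), n_tests = nrow(res),
    n_significant = sum(res$significant, na.rm = TRUE),
    unique_significant_snps = length(unique(res$rsid[which(res$significant)])),
    alpha = attr(scan, "alpha"), call_rate_threshold = attr(scan, "call_rate_threshold"),
    fdr = isTRUE(attr(scan, "fdr")), seed = seed,
    config_hash = fnv1a_hash(as.character(cfg_json)), config = config)
  p3 <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, p3, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(p1, p2, p3))
}

#' Serialize a risk-score definition as JSON
#'
#' @param rs_def an `rs_definition`.
#' @param path file path.
#' @return `read_rs_definition` returns an `rs_definition`.
#' @export
write_rs_definition <- function(rs_def, path) {
  jsonlite::write_json(list(phenotype = rs_def$phenotype,
                            max_score = rs_def$max_score,
                            entries = rs_def$entries),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rs_definition
#' @export
read_rs_definition <- function(path) {
  x <- jsonlite::fromJSON(path)
  rs_definition(x$phenotype, as.data.frame(x$entries))
}

#' Write / read patient scores
#'
#' CSV with columns `patient_id, score, category, n_missing_snps`.
#'
#' @param scored a categorized `scored_cohort`.
#' @param path file path.
#' @export
write_scores <- function(scored, path) {
  utils::write.csv(scored[, c("patient_id", "score", "category",
                              "n_missing_snps")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$category <- factor(df$category, levels = c("low", "high"))
  class(df) <- c("scored_cohort", "data.frame")
  df
}

#' Read a pipeline run configuration (JSON)
#'
#' Fills defaults for any omitted parameter: `alpha` 0.05,
#' `call_rate_threshold` 0.95, `percentile` 75, `followup_year` 6,
#' `window` 1, `seed` 1, `n_patients` 375.
#'
#' @param path JSON file; may also contain a `simulate` block with
#'   [sim_config()] arguments and an `effect_spec` data.frame.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else jsonlite::fromJSON(path)
  defaults <- list(alpha = 0.05, call_rate_threshold = 0.95, percentile = 75,
                   followup_year = 6L, window = 1, seed = 1L,
                   n_patients = 375L, fdr = FALSE,
                   phenos = c("twl_nadir", "twl_6y", "wr_mwl"))
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  class(cfg) <- c("run_config", "list")
  cfg
}
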