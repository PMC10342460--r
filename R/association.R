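#' Direction of a weight-response phenotype
#'
#' Weight-regain phenotypes (`wr_*`) are adverse when *higher*; weight-loss
#' phenotypes (`twl_*`, `ewl_*`, and the achievement coding `ewl6y_gt50`)
#' are adverse when *lower*. The risk allele is the one associated with
#' lower weight loss or higher weight regain.
#'
#' @param phenotype phenotype name.
#' @return `"loss"` or `"regain"`.
#' @export
phenotype_direction <- function(phenotype) {
  ifelse(startsWith(phenotype, "wr"), "regain", "loss")
}

## covariate adjustment set: sex, age, initial BMI, T2D, HTN and surgery
## type (two indicator contrasts against a restrictive baseline)
COVARIATE_SET <- c("sex", "age", "bmi0", "t2d", "htn", "surgery")

covariate_frame <- function(covariates) {
  assert_that(all(COVARIATE_SET %in% names(covariates)),
              paste("covariates must contain", paste(COVARIATE_SET, collapse = ", ")))
  cv <- covariates[, COVARIATE_SET]
  cv$sex <- factor(cv$sex, levels = c("female", "male"))
  cv$surgery <- factor(cv$surgery,
                       levels = c("restrictive", "mixed", "malabsorptive"))
  cv$t2d <- as.logical(cv$t2d)
  cv$htn <- as.logical(cv$htn)
  cv
}

select_best_model <- function(aic, k_genetic) {
  ## lowest AIC; ties (to 1e-6) -> fewer genetic parameters -> fixed order
  ord <- order(round(aic, 6), k_genetic, MODEL_TIE_ORDER[names(aic)])
  names(aic)[ord[1]]
}

#' Fit the five inheritance models for one SNP
#'
#' Fits codominant, dominant, recessive, over-dominant and log-additive
#' encodings of one SNP against a phenotype, each adjusted for the covariate
#' set (sex, age, initial BMI, T2D, HTN, surgery type), on complete cases.
#' The genetic-term p-value is a likelihood-ratio test of the model against
#' the covariate-only model: the exact F form for the Gaussian family, the
#' asymptotic chi-square for the binomial family. Model selection minimises
#' `AIC = 2k - 2 logLik` with `k` the number of fitted regression
#' coefficients; ties break toward fewer genetic parameters, then a fixed
#' model order (log-additive, dominant, recessive, over-dominant,
#' codominant). Degenerate encodings (constant columns, e.g. recessive at a
#' SNP with no alternate homozygotes) are skipped and recorded.
#'
#' @param dosage integer alternate-allele dosages (0/1/2/NA).
#' @param phenotype numeric (linear family) or logical/0-1 (logistic).
#' @param covariates covariate table aligned with `dosage`, or `NULL` for an
#'   unadjusted fit.
#' @param family `"linear"` or `"logistic"`; default guessed from the
#'   phenotype.
#' @param alpha significance level for the best model's genetic term.
#' @param rsid label carried into the result.
#' @return an object of class `assoc_fit`: per-model fits (`$fits`, each with
#'   `aic`, `p_value`, `n_used`, a coefficient table with 95% CI), skipped
#'   models with reasons, `best_model`, `p_value`, `estimate`/`ci_lo`/`ci_hi`
#'   for the best model's primary genotype contrast, and `significant`.
#' @export
fit_inheritance_models <- function(dosage, phenotype, covariates = NULL,
                                   family = NULL, alpha = 0.05,
                                   rsid = "SNP") {
  if (is.null(family))
    family <- if (is.logical(phenotype) ||
                  all(phenotype %in% c(0, 1, NA))) "logistic" else "linear"
  family <- match.arg(family, c("linear", "logistic"))
  y <- if (is.logical(phenotype)) as.numeric(phenotype) else phenotype
  assert_that(length(y) == length(dosage),
              "phenotype and dosage must be aligned")
  base <- data.frame(y = y, .dose = as.integer(dosage))
  if (!is.null(covariates)) {
    assert_that(nrow(covariates) == length(y),
                "covariates must be aligned with the phenotype")
    base <- cbind(base, covariate_frame(covariates))
  }
  cc <- stats::complete.cases(base)
  dat <- base[cc, , drop = FALSE]
  n_used <- nrow(dat)
  covnames <- setdiff(names(dat), c("y", ".dose"))

  fit_one <- function(df) {
    if (family == "linear") stats::lm(y ~ ., data = df)
    else stats::glm(y ~ ., data = df, family = stats::binomial())
  }
  if (n_used == 0)
    abort("no complete cases", "bariGRS_insufficient_data")
  null_df <- dat[, c("y", covnames), drop = FALSE]
  fit0 <- fit_one(null_df)
  k_cov <- sum(!is.na(stats::coef(fit0)))   # intercept + covariate terms

  fits <- list(); skipped <- character()
  for (m in INHERITANCE_MODELS) {
    G <- encode_inheritance(dat$.dose, model = m)
    colnames(G) <- paste0("gen_", colnames(G))
    if (any(apply(G, 2, function(g) stats::var(g) == 0))) {
      skipped[m] <- "non-estimable: constant genetic encoding"
      next
    }
    n_par <- k_cov + ncol(G)
    if (n_used < 10 * n_par) {
      skipped[m] <- sprintf("insufficient data: %d complete cases for %d parameters",
                            n_used, n_par)
      next
    }
    df <- cbind(dat[, c("y", covnames), drop = FALSE], as.data.frame(G))
    fit <- fit_one(df)
    cf <- stats::coef(fit)
    gen_terms <- colnames(G)
    if (any(is.na(cf[gen_terms]))) {
      skipped[m] <- "non-estimable: rank-deficient design"
      next
    }
    k <- sum(!is.na(cf))
    aic <- 2 * k - 2 * as.numeric(stats::logLik(fit))
    p_val <- if (family == "linear") {
      stats::anova(fit0, fit)[2, "Pr(>F)"]
    } else {
      stats::pchisq(fit0$deviance - fit$deviance, df = ncol(G),
                    lower.tail = FALSE)
    }
    sm <- summary(fit)$coefficients[gen_terms, , drop = FALSE]
    crit <- if (family == "linear") stats::qt(0.975, fit$df.residual)
            else stats::qnorm(0.975)
    coef_tab <- data.frame(
      term = sub("^gen_", "", gen_terms),
      estimate = sm[, 1], se = sm[, 2],
      ci_lo = sm[, 1] - crit * sm[, 2],
      ci_hi = sm[, 1] + crit * sm[, 2],
      p_wald = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
    if (family == "logistic") {
      coef_tab$or <- exp(coef_tab$estimate)
      coef_tab$or_lo <- exp(coef_tab$ci_lo)
      coef_tab$or_hi <- exp(coef_tab$ci_hi)
    }
    fits[[m]] <- list(model = m, aic = aic, p_value = p_val,
                      n_used = n_used, k_genetic = ncol(G), coef = coef_tab)
  }
  if (!length(fits))
    abort(sprintf("%s: no inheritance model could be fitted (%s)", rsid,
                  paste(unique(skipped), collapse = "; ")),
          "bariGRS_no_result")
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  kg <- vapply(fits, `[[`, numeric(1), "k_genetic")
  best <- select_best_model(aics, kg)
  bf <- fits[[best]]
  prim <- if (best == "codominant") {
    bf$coef[bf$coef$term == "alt_hom", , drop = FALSE]
  } else bf$coef[1, , drop = FALSE]
  structure(list(rsid = rsid, family = family, alpha = alpha,
                 fits = fits, skipped = skipped,
                 best_model = best, p_value = bf$p_value,
                 significant = bf$p_value < alpha,
                 estimate = prim$estimate, ci_lo = prim$ci_lo,
                 ci_hi = prim$ci_hi, n_used = n_used),
            class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit> %s (%s): best model %s, p = %.4g%s\n",
              x$rsid, x$family, x$best_model, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Call the risk allele from a fitted SNP association
#'
#' For weight-loss phenotypes the risk side is the genotype group with the
#' *lower* adjusted mean (a negative contrast against the reference-homozygote
#' baseline makes the alternate allele the risk allele; a positive contrast
#' makes the reference allele the risk allele). For regain phenotypes the
#' rule is reversed. A non-significant fit returns no risk allele. The
#' returned `points` vector maps dosage 0/1/2 to risk-score points
#' (2 risk-homozygote, 1 heterozygote, 0 otherwise). An over-dominant winner
#' has no allele-dose direction: the adverse genotype class is scored instead
#' (heterozygote = 1 when the heterozygote is the adverse class) and the
#' entry is flagged.
#'
#' @param fit an `assoc_fit`.
#' @param direction `"loss"` or `"regain"` (see [phenotype_direction()]).
#' @param ref,alt the SNP's allele letters.
#' @return a list: `risk_allele` (letter or `NA`), `rule` (human-readable
#'   genotype rule), `points` (numeric length-3, dosage 0/1/2 order, or
#'   `NULL`), `flagged` (TRUE for over-dominant entries).
#' @export
call_risk_allele <- function(fit, direction = c("loss", "regain"), ref, alt) {
  direction <- match.arg(direction)
  none <- list(risk_allele = NA_character_, rule = "none", points = NULL,
               flagged = FALSE)
  if (!isTRUE(fit$significant)) return(none)
  beta <- fit$estimate
  if (is.na(beta) || beta == 0) return(none)
  adverse_alt_side <- (direction == "loss" && beta < 0) ||
    (direction == "regain" && beta > 0)
  if (fit$best_model == "overdominant") {
    if (adverse_alt_side)   # heterozygote is the adverse class
      list(risk_allele = NA_character_, rule = "heterozygote = 1 point",
           points = c(0, 1, 0), flagged = TRUE)
    else
      list(risk_allele = NA_character_, rule = "homozygotes = 1 point",
           points = c(1, 0, 1), flagged = TRUE)
  } else if (adverse_alt_side) {
    list(risk_allele = alt,
         rule = sprintf("%s/%s = 2, %s/%s = 1, %s/%s = 0", alt, alt, ref, alt, ref, ref),
         points = c(0, 1, 2), flagged = FALSE)
  } else {
    list(risk_allele = ref,
         rule = sprintf("%s/%s = 2, %s/%s = 1, %s/%s = 0", ref, ref, ref, alt, alt, alt),
         points = c(2, 1, 0), flagged = FALSE)
  }
}

#' Scan every SNP-phenotype pair
#'
#' Applies per-SNP QC (call rate against `call_rate_threshold`; the
#' Hardy-Weinberg exact test is reported but not exclusionary), fits the five
#' inheritance models for every SNP x phenotype pair with covariate
#' adjustment, selects the best model by AIC, and calls risk alleles for
#' significant, QC-passing SNPs. No multiple-testing correction is applied by
#' default; `fdr = TRUE` switches the significance gate to
#' Benjamini-Hochberg-adjusted p-values.
#'
#' @param genotypes a [genotype_matrix].
#' @param phenotypes a `phenotype_table` (or any data.frame with
#'   `patient_id` and the phenotype columns).
#' @param covariates covariate table, or `NULL` for unadjusted fits.
#' @param phenos phenotype columns to scan (binary columns are fitted by
#'   logistic regression automatically).
#' @param alpha significance level (default 0.05).
#' @param call_rate_threshold per-SNP call-rate QC threshold (default 0.95).
#' @param fdr apply Benjamini-Hochberg adjustment to the significance gate.
#' @return a `data.frame` of class `grs_scan`, one best-model row per
#'   SNP x phenotype, with QC columns, the selected model, its primary
#'   contrast estimate and CI, LRT p-value, significance, risk allele and
#'   scoring rule. Attributes: `fits` (the full `assoc_fit` objects, keyed
#'   `rsid|phenotype`) and `model_table` (long per-model AIC/p table).
#' @export
run_association_scan <- function(genotypes, phenotypes, covariates = NULL,
                                 phenos = c("twl_nadir", "twl_6y", "wr_mwl"),
                                 alpha = 0.05, call_rate_threshold = 0.95,
                                 fdr = FALSE) {
  assert_that(all(phenos %in% names(phenotypes)),
              "phenos must be columns of the phenotype table")
  ids <- intersect(genotypes$patient_ids, phenotypes$patient_id)
  if (!is.null(covariates)) ids <- intersect(ids, covariates$patient_id)
  assert_that(length(ids) > 0, "no overlapping patient ids")
  dos <- genotypes$dosage[match(ids, genotypes$patient_ids), , drop = FALSE]
  ph <- phenotypes[match(ids, phenotypes$patient_id), , drop = FALSE]
  cv <- if (!is.null(covariates))
    covariates[match(ids, covariates$patient_id), , drop = FALSE]
  man <- genotypes$manifest

  cr <- colMeans(!is.na(dos))
  hwe <- vapply(seq_len(ncol(dos)), function(j) {
    d <- dos[, j]
    hwe_exact_test(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                   sum(d == 2L, na.rm = TRUE))
  }, numeric(1))

  rows <- list(); fits <- list(); model_rows <- list()
  for (j in seq_len(ncol(dos))) {
    rs <- colnames(dos)[j]
    gene <- man$gene[man$rsid == rs]
    for (p in phenos) {
      key <- paste0(rs, "|", p)
      row <- data.frame(rsid = rs, gene = gene, phenotype = p,
                        direction = phenotype_direction(p),
                        family = NA_character_, n_used = NA_integer_,
                        call_rate = cr[j], qc_pass = cr[j] >= call_rate_threshold,
                        hwe_p = hwe[j], best_model = NA_character_,
                        estimate = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p_value = NA_real_, significant = NA,
                        risk_allele = NA_character_, risk_rule = NA_character_,
                        pts0 = NA_real_, pts1 = NA_real_, pts2 = NA_real_,
                        note = "", stringsAsFactors = FALSE)
      fit <- tryCatch(
        fit_inheritance_models(dos[, j], ph[[p]], covariates = cv,
                               alpha = alpha, rsid = rs),
        bariGRS_error = function(e) e)
      if (inherits(fit, "assoc_fit")) {
        fits[[key]] <- fit
        row$family <- fit$family
        row$n_used <- fit$n_used
        row$best_model <- fit$best_model
        row$estimate <- fit$estimate
        row$ci_lo <- fit$ci_lo
        row$ci_hi <- fit$ci_hi
        row$p_value <- fit$p_value
        if (length(fit$skipped))
          row$note <- paste(names(fit$skipped), unname(fit$skipped),
                            sep = ": ", collapse = "; ")
        for (m in names(fit$fits)) {
          f <- fit$fits[[m]]
          model_rows[[paste0(key, "|", m)]] <- data.frame(
            rsid = rs, gene = gene, phenotype = p, model = m,
            aic = f$aic, p_value = f$p_value, n_used = f$n_used,
            selected = m == fit$best_model, stringsAsFactors = FALSE)
        }
      } else {
        row$note <- conditionMessage(fit)
      }
      rows[[key]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (fdr) {
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  } else {
    res$significant <- !is.na(res$p_value) & res$p_value < alpha
  }
  ## risk alleles only for significant, QC-passing SNPs
  for (i in seq_len(nrow(res))) {
    key <- paste0(res$rsid[i], "|", res$phenotype[i])
    if (!isTRUE(res$significant[i]) || !isTRUE(res$qc_pass[i]) ||
        is.null(fits[[key]])) next
    mrow <- man[man$rsid == res$rsid[i], ]
    fit <- fits[[key]]
    fit$significant <- res$significant[i]  # honour the (possibly FDR) gate
    rc <- call_risk_allele(fit, res$direction[i], mrow$ref, mrow$alt)
    res$risk_allele[i] <- rc$risk_allele
    res$risk_rule[i] <- rc$rule
    if (!is.null(rc$points)) {
      res$pts0[i] <- rc$points[1]
      res$pts1[i] <- rc$points[2]
      res$pts2[i] <- rc$points[3]
    }
  }
  attr(res, "fits") <- fits
  attr(res, "model_table") <- do.call(rbind, c(model_rows,
                                               make.row.names = FALSE))
  attr(res, "alpha") <- alpha
  attr(res, "call_rate_threshold") <- call_rate_threshold
  attr(res, "fdr") <- fdr
  class(res) <- c("grs_scan", class(res))
  res
}

#' Summarise an association scan
#'
#' Reports both counting conventions for significant findings: the number of
#' unique significant SNPs overall and per phenotype, and the split between
#' weight-loss and weight-regain phenotypes (a SNP associated with both is
#' counted on both sides).
#'
#' @param object a `grs_scan`.
#' @param ... unused.
#' @return a list with `n_snps`, `n_tests`, `n_significant_rows`,
#'   `unique_significant_snps`, `per_phenotype` and `per_direction` counts.
#' @export
summary.grs_scan <- function(object, ...) {
  sig <- object[which(object$significant), , drop = FALSE]
  out <- list(
    n_snps = length(unique(object$rsid)),
    n_tests = nrow(object),
    n_significant_rows = nrow(sig),
    unique_significant_snps = length(unique(sig$rsid)),
    per_phenotype = table(factor(sig$phenotype,
                                 levels = unique(object$phenotype))),
    per_direction = table(factor(sig$direction[!duplicated(paste(sig$rsid, sig$direction))],
                                 levels = c("loss", "regain")))
  )
  class(out) <- "summary.grs_scan"
  out
}

#' @export
print.summary.grs_scan <- function(x, ...) {
  cat(sprintf("Association scan: %d SNPs, %d tests, %d significant rows (%d unique SNPs)\n",
              x$n_snps, x$n_tests, x$n_significant_rows,
              x$unique_significant_snps))
  cat("Per phenotype:\n"); print(x$per_phenotype)
  cat("Per direction (unique SNPs):\n"); print(x$per_direction)
  invisible(x)
}
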