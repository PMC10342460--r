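INHERITANCE_MODELS <- c("codominant", "dominant", "recessive",
                        "overdominant", "log_additive")

## fixed preference order used to break AIC ties (after genetic-parameter
## count): simplest conventional coding first
MODEL_TIE_ORDER <- c(log_additive = 1L, dominant = 2L, recessive = 3L,
                     overdominant = 4L, codominant = 5L)

#' Convert allele-pair calls to alternate-allele dosages
#'
#' Calls are unordered allele pairs such as `"T/A"`; `"./."`, `""` and `NA`
#' are missing. Orientation is by allele letter: the dosage counts copies of
#' `alt` regardless of the order written in the call.
#'
#' @param calls character vector of `"X/Y"` calls.
#' @param ref,alt the SNP's reference and alternate allele letters.
#' @return integer vector of dosages in `{0, 1, 2, NA}`.
#' @export
calls_to_dosage <- function(calls, ref, alt) {
  calls <- as.character(calls)
  miss <- is.na(calls) | calls %in% c("./.", ".", "")
  parts <- strsplit(calls[!miss], "/", fixed = TRUE)
  bad_shape <- lengths(parts) != 2
  alleles <- unlist(parts)
  bad <- setdiff(unique(alleles), c(ref, alt))
  if (length(bad) || any(bad_shape)) {
    offending <- unique(calls[!miss][bad_shape |
      vapply(parts, function(p) any(!p %in% c(ref, alt)), logical(1))])
    abort(sprintf("allele mismatch for ref=%s alt=%s in call(s): %s",
                  ref, alt, paste(offending, collapse = ", ")),
          "bariGRS_allele_mismatch")
  }
  d <- rep(NA_integer_, length(calls))
  d[!miss] <- vapply(parts, function(p) sum(p == alt), integer(1))
  d
}

## dosage -> display call strings
dosage_to_calls <- function(dosage, ref, alt) {
  out <- rep("./.", length(dosage))
  ok <- !is.na(dosage)
  out[ok] <- c(paste0(ref, "/", ref), paste0(ref, "/", alt),
               paste0(alt, "/", alt))[dosage[ok] + 1L]
  out
}

#' Encode genotypes under an inheritance model
#'
#' Builds the genetic design column(s) for one SNP relative to the
#' reference-allele homozygote baseline:
#' \describe{
#'   \item{dominant}{1 if the call carries any alternate allele.}
#'   \item{recessive}{1 if alternate-homozygous.}
#'   \item{overdominant}{1 if heterozygous.}
#'   \item{log_additive}{alternate-allele count 0/1/2.}
#'   \item{codominant}{two indicator columns, `het` and `alt_hom`.}
#' }
#' Missing calls propagate as `NA`.
#'
#' @param calls either an integer dosage vector (`0/1/2/NA`) or a character
#'   vector of allele-pair calls (then `ref_allele` and `alt_allele` are
#'   required).
#' @param ref_allele,alt_allele allele letters, used only for character calls.
#' @param model one of `r paste(INHERITANCE_MODELS, collapse = ", ")`.
#' @return a numeric matrix with one column (two for codominant) named after
#'   the genotype contrast(s).
#' @examples
#' encode_inheritance(c("T/T", "T/A", "A/A"), "T", "A", model = "dominant")
#' @export
encode_inheritance <- function(calls, ref_allele = NULL, alt_allele = NULL,
                               model = INHERITANCE_MODELS) {
  model <- match.arg(model)
  d <- if (is.character(calls) || is.factor(calls)) {
    assert_that(!is.null(ref_allele) && !is.null(alt_allele),
                "ref_allele and alt_allele are required for character calls")
    calls_to_dosage(calls, ref_allele, alt_allele)
  } else {
    assert_that(all(calls %in% c(0, 1, 2) | is.na(calls)),
                "numeric calls must be dosages 0, 1, 2 or NA")
    as.integer(calls)
  }
  switch(model,
    dominant = cbind(carrier = as.numeric(d >= 1)),
    recessive = cbind(alt_hom = as.numeric(d == 2)),
    overdominant = cbind(het = as.numeric(d == 1)),
    log_additive = cbind(dose = as.numeric(d)),
    codominant = cbind(het = as.numeric(d == 1), alt_hom = as.numeric(d == 2))
  )
}
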