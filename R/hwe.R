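#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test for a biallelic genotype table. Conditional on the
#' observed allele counts, the number of heterozygotes follows
#' `P(n_het) = C(N; n_aa, n_het, n_bb) 2^n_het / C(2N, n_a)`; the p-value is
#' the summed probability of all heterozygote counts no more probable than
#' the observed one. The full conditional distribution is enumerated via a
#' stable multiplicative recurrence (probabilities are built from the ratio
#' `P(h+2)/P(h) = 4 n_aa n_bb / ((h+1)(h+2))` and normalised), so the test is
#' exact for any table size.
#'
#' @param n_ref_hom,n_het,n_alt_hom non-negative genotype counts
#'   (total >= 1).
#' @return the exact p-value in `(0, 1]`. Monomorphic tables return 1.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(100, 0, 0)   # monomorphic: p = 1
#' @export
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom) {
  counts <- c(n_ref_hom, n_het, n_alt_hom)
  assert_that(length(counts) == 3 && all(!is.na(counts)) && all(counts >= 0) &&
                all(counts == floor(counts)),
              "genotype counts must be non-negative integers")
  n <- sum(counts)
  assert_that(n >= 1, "total genotype count must be >= 1")
  na <- 2 * n_alt_hom + n_het          # alt allele count
  rare <- min(na, 2 * n - na)          # conditional distribution depends on
  dist <- hwe_het_distribution(rare, n) # the rarer allele count only
  p_obs <- dist$prob[match(n_het, dist$het)]
  if (is.na(p_obs))
    abort("heterozygote count inconsistent with allele counts",
          "bariGRS_invalid_argument")
  min(1, sum(dist$prob[dist$prob <= p_obs * (1 + 1e-7)]))
}

#' Conditional heterozygote-count distribution under HWE
#'
#' Enumerates the exact conditional distribution of the heterozygote count
#' given `n` genotypes and `n_rare` copies of the rarer allele.
#'
#' @param n_rare rarer-allele count (`0 <= n_rare <= n`... up to `2n`, but
#'   only `n_rare <= n` is a "rare" side; either side gives the same
#'   distribution).
#' @param n total number of genotypes.
#' @return a list with integer vector `het` (attainable heterozygote counts,
#'   stepping by 2) and numeric vector `prob` summing to 1.
#' @keywords internal
hwe_het_distribution <- function(n_rare, n) {
  n_other <- 2 * n - n_rare
  hmax <- min(n_rare, n_other)
  het <- seq.int(hmax %% 2, hmax, by = 2)
  if (hmax < 2) return(list(het = het, prob = rep(1, length(het))))
  ## unnormalised probs via the ratio recurrence, anchored at the largest
  ## attainable het count (log scale for stability at large n)
  lp <- numeric(length(het))
  for (k in seq_along(het)[-1]) {
    h <- het[k - 1]
    naa <- (n_rare - h) / 2            # rare-allele homozygotes at h
    nbb <- n - naa - h
    lp[k] <- lp[k - 1] + log(4 * naa * nbb) - log((h + 1) * (h + 2))
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  list(het = het, prob = p / sum(p))
}
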