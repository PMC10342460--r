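## Independent brute-force oracle for the exact Hardy-Weinberg test: direct
## lgamma evaluation of every conditional term (the package implementation
## uses a multiplicative recurrence instead; the two routes share no code).
hwe_oracle <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na <- 2 * naa + nab
  nb <- 2 * n - na
  hs <- seq.int(min(na, nb) %% 2, min(na, nb), by = 2)
  lp <- vapply(hs, function(h) {
    a <- (na - h) / 2
    b <- (nb - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(lp)
  pobs <- p[match(nab, hs)]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

## full p-value vector over every attainable heterozygote count, oracle route
hwe_oracle_all <- function(n_rare, n) {
  nb <- 2 * n - n_rare
  hs <- seq.int(min(n_rare, nb) %% 2, min(n_rare, nb), by = 2)
  lp <- lgamma(n + 1) - lgamma((n_rare - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((nb - hs) / 2 + 1) + hs * log(2) +
    lgamma(n_rare + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  p <- exp(lp)
  vapply(p, function(po) min(1, sum(p[p <= po * (1 + 1e-7)])), 0)
}

## small deterministic manifest for unit tests
test_manifest <- function(m = 4, maf = rep(0.3, m)) {
  snp_manifest(gene = paste0("G", seq_len(m)),
               rsid = paste0("rs", seq_len(m)),
               ref = rep(c("A", "C", "G", "T"), length.out = m),
               alt = rep(c("G", "T", "A", "C"), length.out = m),
               maf = maf)
}

## deterministic covariate table without touching the RNG
test_covariates <- function(n) {
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = 30 + (seq_len(n) %% 30),
    sex = factor(rep(c("female", "female", "male"), length.out = n),
                 levels = c("female", "male")),
    bmi0 = 40 + (seq_len(n) %% 10),
    height = 1.5 + 0.01 * (seq_len(n) %% 30),
    t2d = seq_len(n) %% 3 == 0,
    htn = seq_len(n) %% 2 == 0,
    surgery = factor(rep(c("restrictive", "mixed", "malabsorptive"),
                         length.out = n),
                     levels = c("restrictive", "mixed", "malabsorptive")),
    stringsAsFactors = FALSE)
}

## wrap a dosage vector into a one-SNP genotype matrix
test_gm <- function(dosage, ref = "A", alt = "G", rsid = "rs1",
                    ids = sprintf("P%04d", seq_along(dosage))) {
  man <- snp_manifest("G1", rsid, ref, alt, 0.3)
  genotype_matrix(matrix(as.integer(dosage), ncol = 1,
                         dimnames = list(ids, rsid)), man, ids)
}
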