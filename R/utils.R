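#' @keywords internal
"_PACKAGE"

## Shared internal helpers: argument checking, seeded evaluation, small
## formatting utilities. Nothing here is exported.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "bariGRS_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "bariGRS_invalid_argument") {
  if (!isTRUE(ok)) abort(msg, class)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x)

is_fraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

#' Evaluate code under a fixed RNG state without disturbing the caller's
#'
#' Sets the Mersenne-Twister generator with the given seed, runs `code`, and
#' restores the caller's `.Random.seed`. All randomness in the package flows
#' through this helper so that outputs are bit-reproducible given a seed.
#'
#' @param seed integer scalar in `[0, 2^31 - 1)`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  assert_that(is_count(seed) && seed >= 0 && seed < 2^31 - 1,
              "seed must be a non-negative integer below 2^31 - 1")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  code
}

## truncated-normal sampler by rejection; vectorized, loops only on rejects
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits; used to stamp
## result files with a configuration fingerprint (no digest dependency).
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261            # FNV offset basis, kept as a double
  for (b in bytes) {
    ## xor only touches the low byte (b < 256); keep h a double throughout
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    ## 32-bit modular multiply by the FNV prime via 16-bit split (the full
    ## product would overflow double precision)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## location parameter making a truncated Normal(mu, sd) on [lo, hi] attain a
## target mean; closed-form truncated-normal mean inside uniroot
trunc_norm_location <- function(target_mean, sd, lo, hi) {
  tmean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) /
      (stats::pnorm(b) - stats::pnorm(a))
  }
  stats::uniroot(function(mu) tmean(mu) - target_mean,
                 interval = c(lo, hi), tol = 1e-10)$root
}

fmt_mean_sd <- function(x, digits = 2) {
  sprintf("%.*f ± %.*f", digits, mean(x), digits, stats::sd(x))
}

fmt_n_pct <- function(n, total, digits = 2) {
  sprintf("%d (%.*f)", n, digits, 100 * n / total)
}
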