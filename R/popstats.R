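#' @include AllGenerics.R
NULL

#' Exact two-sided binomial test for gain-vs-loss bias
#'
#' Tests whether chromosome gains and losses occur at equal frequency:
#' exact binomial with success probability 0.5, two-sided p-value equal
#' to the sum of all outcome probabilities not exceeding that of the
#' observed count (the standard minimum-likelihood rule, with the usual
#' 1 + 1e-7 relative tolerance for floating-point ties).
#'
#' @param gains,losses non-negative event counts.
#' @return two-sided p-value.
#' @examples
#' binomialGainLoss(49, 35)  # ~0.156
#' @export
binomialGainLoss <- function(gains, losses) {
  n <- gains + losses
  if (n <= 0) kError("gains + losses must be positive", "karyoValidationError")
  d <- stats::dbinom(0:n, n, 0.5)
  min(1, sum(d[d <= d[gains + 1L] * (1 + 1e-7)]))
}

#' Exact two-sided Poisson test
#'
#' Exact test of an observed event count against a Poisson expectation:
#' the two-sided p-value sums the Poisson masses not exceeding the mass
#' at the observed count.
#'
#' @param observed non-negative integer count.
#' @param expected positive Poisson rate.
#' @return two-sided p-value.
#' @export
exactPoissonTest <- function(observed, expected) {
  if (expected <= 0) kError("expected rate must be positive",
                            "karyoValidationError")
  kmax <- max(observed, ceiling(expected + 20 * sqrt(expected) + 50))
  d <- stats::dpois(0:kmax, expected)
  min(1, sum(d[d <= stats::dpois(observed, expected) * (1 + 1e-7)]))
}

#' Poisson-permutation prone/resistant classification
#'
#' Under the null, the 12 per-chromosome aneuploidy-event counts are iid
#' Poisson with rate lambda = their observed mean. Each permutation draws
#' 12 Poisson(lambda) values; the pooled draws yield the 95%-probability
#' upper and 5%-probability lower thresholds (nearest-rank percentiles).
#' A chromosome with an observed count above the upper threshold is
#' "prone", below the lower threshold "resistant", otherwise "neutral".
#'
#' @param counts named numeric(12) per-chromosome event counts.
#' @param nPerm number of permutations (default 10,000).
#' @param seed integer seed.
#' @param truncated draw zero-truncated ("positive integers") Poisson
#'   values instead of plain Poisson.
#' @param pooled pool all nPerm x 12 draws for the percentile thresholds
#'   (default); otherwise use nearest-rank percentiles of the
#'   per-permutation maxima (upper) and minima (lower).
#' @return data.frame(chrom, count, classification) with attributes
#'   \code{upper}, \code{lower}, \code{lambda}, \code{nPerm}, \code{seed}.
#' @export
propensityClassification <- function(counts, nPerm = 10000L,
                                     seed = NA_integer_, truncated = FALSE,
                                     pooled = TRUE) {
  counts <- as.numeric(counts)
  if (length(counts) != 12L)
    kError("counts must cover the 12 chromosomes", "karyoValidationError")
  if (nPerm < 100L) kError("nPerm must be >= 100", "karyoValidationError")
  lambda <- mean(counts)
  if (lambda <= 0) kError("all-zero counts: degenerate Poisson rate",
                          "karyoDegenerateLambda")
  draws <- withSeed(seed, {
    x <- stats::rpois(nPerm * 12L, lambda)
    if (truncated) {
      while (any(zero <- x == 0L)) x[zero] <- stats::rpois(sum(zero), lambda)
    }
    x
  })
  nearestRank <- function(v, p) sort(v)[ceiling(p * length(v))]
  if (pooled) {
    upper <- nearestRank(draws, 0.95)
    lower <- nearestRank(draws, 0.05)
  } else {
    m <- matrix(draws, nrow = 12L)
    upper <- nearestRank(apply(m, 2, max), 0.95)
    lower <- nearestRank(apply(m, 2, min), 0.05)
  }
  cls <- ifelse(counts > upper, "prone",
                ifelse(counts < lower, "resistant", "neutral"))
  out <- data.frame(chrom = chromNames(), count = counts,
                    classification = cls)
  attr(out, "upper") <- upper
  attr(out, "lower") <- lower
  attr(out, "lambda") <- lambda
  attr(out, "nPerm") <- as.integer(nPerm)
  attr(out, "seed") <- seed
  out
}

#' Reciprocal-cross aneuploidy bias test
#'
#' Pearson's chi-squared test (1 df) on a 2x2 table of aneuploid/euploid
#' counts by cross direction; continuity correction off by default.
#'
#' @param tab 2x2 matrix or table of counts.
#' @param correct apply Yates continuity correction.
#' @return htest from [stats::chisq.test()].
#' @export
reciprocalBiasTest <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0))
    kError("a 2x2 table of non-negative counts is required",
           "karyoValidationError")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    kError("zero margin in the 2x2 table", "karyoValidationError")
  stats::chisq.test(tab, correct = correct)
}

#' Correlation of aneuploidy frequency with a chromosome-level factor
#'
#' Pearson correlation (two-sided p from the t distribution with n-2 df)
#' between per-chromosome aneuploidy frequencies and a candidate
#' constraint such as resident gene count or predicted inter-chromosome
#' functional links.
#'
#' @param frequencies numeric(12) per-chromosome aneuploidy frequencies.
#' @param factorValues numeric(12) factor values.
#' @param name factor label.
#' @return data.frame(factor, r, p, n).
#' @export
frequencyFactorCorrelation <- function(frequencies, factorValues,
                                       name = "factor") {
  if (length(frequencies) != length(factorValues))
    kError("frequencies and factor values must be paired",
           "karyoValidationError")
  if (any(!is.finite(factorValues)) || any(!is.finite(frequencies)))
    kError("factor values must be finite", "karyoValidationError")
  if (stats::sd(frequencies) == 0 || stats::sd(factorValues) == 0)
    kError("zero variance in one of the vectors", "karyoValidationError")
  ct <- stats::cor.test(frequencies, factorValues, method = "pearson")
  data.frame(factor = name, r = unname(ct$estimate), p = ct$p.value,
             n = length(frequencies))
}
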