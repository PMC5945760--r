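test_that("exact binomial test agrees with independent oracles", {
  # published counts
  expect_equal(signif(binomialGainLoss(49, 35), 3), 0.156)
  expect_equal(signif(binomialGainLoss(58, 20), 4), 1.952e-05)
  # brute-force mass enumeration oracle
  expect_equal(binomialGainLoss(58, 20), oracleBinom(58, 20),
               tolerance = 1e-12)
  # symmetric counts give p = 1
  expect_equal(binomialGainLoss(17, 17), 1)
  expect_error(binomialGainLoss(0, 0), class = "karyoValidationError")
})

test_that("binomial p matches stats::binom.test over a grid", {
  withr::with_seed(3, {
    for (i in 1:40) {
      n <- sample(2:200, 1)
      gains <- sample(0:n, 1)
      expect_equal(binomialGainLoss(gains, n - gains),
                   stats::binom.test(gains, n, 0.5)$p.value,
                   tolerance = 1e-12, info = paste(gains, n))
    }
  })
})

test_that("exact Poisson test agrees with stats::poisson.test and oracle", {
  expect_equal(exactPoissonTest(10, 2), oraclePoisson(10, 2),
               tolerance = 1e-12)
  expect_equal(exactPoissonTest(5, 5), 1)
  expect_equal(exactPoissonTest(0, 0.1), 1)
  withr::with_seed(5, {
    for (i in 1:40) {
      m <- stats::runif(1, 0.2, 60)
      obs <- sample(0:200, 1)
      expect_equal(exactPoissonTest(obs, m),
                   stats::poisson.test(obs, r = m)$p.value,
                   tolerance = 1e-12, info = paste(obs, round(m, 3)))
    }
  })
  expect_error(exactPoissonTest(3, 0), class = "karyoValidationError")
})

test_that("propensity classification flags clear outliers only", {
  counts <- rep(8, 12)
  res <- propensityClassification(counts, nPerm = 4000L, seed = 7L)
  expect_true(all(res$classification == "neutral"))

  counts2 <- c(rep(3, 11), 30)  # lambda ~5.25, one count at ~10x lambda
  res2 <- propensityClassification(counts2, nPerm = 4000L, seed = 7L)
  expect_equal(res2$classification[12], "prone")

  expect_error(propensityClassification(rep(0, 12), seed = 1L),
               class = "karyoDegenerateLambda")
  expect_error(propensityClassification(rep(5, 12), nPerm = 10L, seed = 1L),
               class = "karyoValidationError")
})

test_that("propensity thresholds are deterministic and stable", {
  a <- propensityClassification(c(2, 5, 9, 4, 6, 7, 3, 5, 6, 8, 4, 5),
                                nPerm = 2000L, seed = 11L)
  b <- propensityClassification(c(2, 5, 9, 4, 6, 7, 3, 5, 6, 8, 4, 5),
                                nPerm = 2000L, seed = 11L)
  expect_identical(a$classification, b$classification)
  expect_identical(attr(a, "upper"), attr(b, "upper"))

  # doubling nPerm rarely changes the classification
  withr::with_seed(13, {
    same <- vapply(1:40, function(i) {
      counts <- stats::rpois(12, 10)
      if (mean(counts) == 0) return(TRUE)
      r1 <- propensityClassification(counts, nPerm = 1000L, seed = 100L + i)
      r2 <- propensityClassification(counts, nPerm = 2000L, seed = 200L + i)
      identical(r1$classification, r2$classification)
    }, logical(1))
    expect_gte(mean(same), 0.95)
  })
})

test_that("null Poisson populations are flagged near the nominal rate", {
  withr::with_seed(17, {
    prone <- resistant <- 0
    nPop <- 500
    for (i in 1:nPop) {
      counts <- stats::rpois(12, 8)
      if (mean(counts) == 0) next
      res <- propensityClassification(counts, nPerm = 300L,
                                      seed = 1000L + i)
      prone <- prone + sum(res$classification == "prone")
      resistant <- resistant + sum(res$classification == "resistant")
    }
    # per chromosome per side, at the 95%/5% nearest-rank rule on a
    # discrete null, flag rates stay near (at most ~12%) nominal
    expect_lte(prone / (nPop * 12), 0.12)
    expect_lte(resistant / (nPop * 12), 0.12)
    expect_gt(prone + resistant, 0)  # the rule does flag at some rate
  })
})

test_that("zero-truncated and per-permutation-extrema variants run", {
  counts <- c(2, 5, 9, 4, 6, 7, 3, 5, 6, 8, 4, 5)
  rT <- propensityClassification(counts, nPerm = 1000L, seed = 19L,
                                 truncated = TRUE)
  expect_true(all(rT$classification %in% c("prone", "resistant", "neutral")))
  rE <- propensityClassification(counts, nPerm = 1000L, seed = 19L,
                                 pooled = FALSE)
  # extrema thresholds are at least as wide as pooled ones
  rP <- propensityClassification(counts, nPerm = 1000L, seed = 19L)
  expect_gte(attr(rE, "upper"), attr(rP, "upper"))
  expect_lte(attr(rE, "lower"), attr(rP, "lower"))
})

test_that("reciprocal-cross test matches the Pearson chi-squared formula", {
  tab <- matrix(c(49, 59, 75, 129), 2, byrow = TRUE)
  res <- reciprocalBiasTest(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(res$statistic), sum((tab - E)^2 / E))
  # swapping rows leaves the statistic unchanged
  res2 <- reciprocalBiasTest(tab[2:1, ])
  expect_equal(unname(res2$statistic), unname(res$statistic))

  # identical proportions give statistic 0 and p = 1
  res0 <- reciprocalBiasTest(matrix(c(10, 30, 20, 60), 2, byrow = TRUE))
  expect_equal(unname(res0$statistic), 0)
  expect_equal(res0$p.value, 1)

  expect_error(reciprocalBiasTest(matrix(c(0, 0, 5, 5), 2)),
               class = "karyoValidationError")
})

test_that("factor correlation recovers exact and noisy relationships", {
  f <- c(5, 8, 2, 9, 4, 7, 6, 3, 10, 1, 11, 12)
  r1 <- frequencyFactorCorrelation(f, f, "self")
  expect_equal(r1$r, 1)
  r2 <- frequencyFactorCorrelation(f, -f + 20, "anti")
  expect_equal(r2$r, -1)

  withr::with_seed(23, {
    freq <- stats::runif(12, 0, 1)
    fac <- -3 * freq + stats::rnorm(12, sd = 0.3)
    res <- frequencyFactorCorrelation(freq, fac, "noisy")
    expect_lt(res$r, -0.5)
    expect_equal(res$n, 12)
  })
  expect_error(frequencyFactorCorrelation(rep(1, 12), f),
               class = "karyoValidationError")
})

test_that("observed involvement counts classify the published chromosomes", {
  s <- tabulateKaryotypes(riceKaryotypeTable(), nEuploid = 188L)
  res <- propensityClassification(s$perChromosome$combined,
                                  nPerm = 10000L, seed = 29L)
  expect_setequal(which(res$classification == "resistant"), c(1, 3))
  expect_setequal(which(res$classification == "prone"), c(4, 9, 11))
})
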