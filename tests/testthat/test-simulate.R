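g <- tinyGenome()
win <- genomeWindows(g)

test_that("dosage weights scale windows by local dosage", {
  wEu <- dosageWeights(Karyotype(), g, win)
  expect_equal(wEu, GenomicRanges::width(win) * 1.0)

  k11 <- Karyotype(whole = c("11" = 1))
  w11 <- dosageWeights(k11, g, win)
  on11 <- as.character(GenomeInfoDb::seqnames(win)) == "chr11"
  expect_equal(w11[on11] / wEu[on11], rep(1.25, sum(on11)))
  expect_equal(w11[!on11], wEu[!on11])

  kL <- parseKaryotype("-1L Chr. 11")
  wL <- dosageWeights(kL, g, win)
  mc <- S4Vectors::mcols(win)
  # fully long-arm windows at 3/4, fully short-arm at 1
  fullL <- on11 & mc$sOvl == 0
  fullS <- on11 & mc$lOvl == 0
  expect_equal(wL[fullL] / wEu[fullL], rep(0.75, sum(fullL)))
  expect_equal(wL[fullS] / wEu[fullS], rep(1.00, sum(fullS)))
  # the centromere-spanning window is weighted by its split parts
  span <- on11 & mc$sOvl > 0 & mc$lOvl > 0
  expect_true(any(span))
  expect_equal(wL[span], mc$sOvl[span] * 1.0 + mc$lOvl[span] * 0.75)
})

test_that("arm dosage cannot go below zero", {
  expect_error(new("Karyotype", whole = c(-4L, integer(11)),
                   shortArm = c(-1L, integer(11)), longArm = integer(12)),
               "dosage")
})

test_that("multinomial simulation conserves the total read count", {
  cfg <- SimConfig(g, meanDepth = 0.5, seed = 3L)
  p <- simulateProfile(Karyotype(), cfg, windows = win)
  N <- round(0.5 * sum(chromLengths(g)) / 125)
  expect_equal(totalCount(p), N)
  expect_equal(sum(S4Vectors::mcols(depthWindows(p))$count), N)
})

test_that("simulation is deterministic given a seed", {
  cfg <- SimConfig(g, seed = 11L)
  p1 <- simulateProfile(Karyotype(whole = c("3" = 1)), cfg, windows = win)
  p2 <- simulateProfile(Karyotype(whole = c("3" = 1)), cfg, windows = win)
  expect_identical(S4Vectors::mcols(depthWindows(p1))$count,
                   S4Vectors::mcols(depthWindows(p2))$count)
})

test_that("doubling mean depth doubles expected window counts", {
  c1 <- SimConfig(g, meanDepth = 1, noise = "none")
  c2 <- SimConfig(g, meanDepth = 2, noise = "none")
  p1 <- simulateProfile(Karyotype(), c1, windows = win)
  p2 <- simulateProfile(Karyotype(), c2, windows = win)
  expect_equal(S4Vectors::mcols(depthWindows(p2))$count,
               2 * S4Vectors::mcols(depthWindows(p1))$count,
               tolerance = 1e-6)
})

test_that("window counts converge to expectation at high depth", {
  cfg <- SimConfig(g, meanDepth = 50, seed = 5L)
  p <- simulateProfile(Karyotype(), cfg, windows = win)
  expW <- dosageWeights(Karyotype(), g, win)
  expCnt <- totalCount(p) * expW / sum(expW)
  ratio <- S4Vectors::mcols(depthWindows(p))$count / expCnt
  # ~4000 counts per window at 50x: relative sd ~1.6%
  expect_true(max(abs(ratio - 1)) < 0.12)
  expect_equal(mean(ratio), 1, tolerance = 0.005)
})

test_that("a gained chromosome shows the analytic 1.25 depth ratio", {
  cfg <- SimConfig(g, meanDepth = 4, seed = 9L)
  p <- simulateProfile(Karyotype(whole = c("9" = 1)), cfg, windows = win)
  cc <- chromCounts(p)
  len <- chromLengths(g)
  dens9 <- cc[9] / len[9]
  densOther <- sum(cc[-9]) / sum(len[-9])
  ratio <- unname(dens9 / densOther)
  # ~11k reads on chr09 at 4x: se of the ratio is ~0.012
  expect_lt(abs(ratio - 1.25), 3 * 0.012)
})

test_that("poisson noise matches the multinomial means", {
  cfg <- SimConfig(g, meanDepth = 2, noise = "poisson", seed = 13L)
  p <- simulateProfile(Karyotype(), cfg, windows = win)
  N <- round(2 * sum(chromLengths(g)) / 125)
  expect_equal(totalCount(p) / N, 1, tolerance = 0.01)
})

test_that("mappability weights are reproducible and default to unity", {
  expect_equal(mappabilityWeights(g, 0, windows = win), rep(1, length(win)))
  w1 <- mappabilityWeights(g, 0.2, seed = 21L, windows = win)
  w2 <- mappabilityWeights(g, 0.2, seed = 21L, windows = win)
  expect_identical(w1, w2)
  expect_true(sd(w1) > 0)
})

test_that("simulated populations carry retrievable truth", {
  cfg <- SimConfig(g, seed = 31L)
  pop <- simulatePopulation(c(WT = 1.0), 5, cfg)
  expect_length(profiles(pop), 5)
  expect_true(all(vapply(trueKaryotypes(pop), isEuploid, logical(1))))
  expect_true(all(karyotypeLabels(pop) == "WT"))

  freqs <- karyotypeFrequencies()
  pop2 <- simulatePopulation(freqs, 150, cfg)
  expect_length(trueKaryotypes(pop2), 150)
  expect_true(all(vapply(seq_len(150), function(i)
    identical(formatKaryotype(trueKaryotypes(pop2)[[i]]),
              karyotypeLabels(pop2)[i]) ||
      (karyotypeLabels(pop2)[i] == "WT" &&
         isEuploid(trueKaryotypes(pop2)[[i]])), logical(1))))
  # aneuploid fraction ~ 124/312 within ~3 binomial SE at n = 150
  frac <- mean(karyotypeLabels(pop2) != "WT")
  expect_lt(abs(frac - 124 / 312), 3 * sqrt(0.397 * 0.603 / 150) + 1e-9)
})

test_that("population simulation is reproducible and validates input", {
  cfg <- SimConfig(g, seed = 17L)
  popA <- simulatePopulation(c(WT = 0.5, "+1Chr05" = 0.5), 8, cfg)
  popB <- simulatePopulation(c(WT = 0.5, "+1Chr05" = 0.5), 8, cfg)
  expect_identical(karyotypeLabels(popA), karyotypeLabels(popB))
  expect_identical(chromCounts(profiles(popA)[[3]]),
                   chromCounts(profiles(popB)[[3]]))
  expect_error(simulatePopulation(c(WT = 0.7), 5, cfg),
               class = "karyoValidationError")
  expect_error(simulatePopulation(c(WT = 1.0), 0, cfg),
               class = "karyoValidationError")
})

test_that("trait simulation recovers injected effects", {
  mod <- TraitEffectModel(
    specificEffects = data.frame(karyotype = "+1Chr07", trait = 3,
                                 shift = 2))
  labels <- c(rep("WT", 200), rep("+1Chr07", 40), rep("-1Chr04", 40))
  tr <- simulateTraits(mod, labels, seed = 5L)
  expect_equal(dim(tr), c(280, 21))
  carriers <- labels == "+1Chr07"
  # trait 3: general -1 plus specific +2 relative to euploid baseline
  diff3 <- mean(tr[carriers, 3]) - mean(tr[labels == "WT", 3])
  se <- sqrt(1 / 40 + 1 / 200)
  expect_lt(abs(diff3 - 1), 2 * se + 0.15)
  # trait 13 has no general effect
  diff13 <- mean(tr[labels != "WT", 13]) - mean(tr[labels == "WT", 13])
  expect_lt(abs(diff13), 0.4)
})
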