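g <- tinyGenome()
thrCF <- closedFormThresholds()

test_that("neutral values produce no calls; threshold crossing is inclusive", {
  expect_equal(unname(callWholeChromosomes(rep(1, 12), thrCF)), rep(0L, 12))

  # a value exactly on the gain threshold is called (inclusive comparison)
  v <- rep(48 / 49, 12); v[2] <- 60 / 49
  expect_equal(callWholeChromosomes(v, thrCF)[["chr02"]], 1L)
  v <- rep(48 / 47, 12); v[8] <- 36 / 47
  expect_equal(callWholeChromosomes(v, thrCF)[["chr08"]], -1L)
})

test_that("magnitude assignment picks the nearest expected level", {
  v <- rep(1, 12); v[4] <- 1.40   # between +1 (1.2245) and +2 (1.44)
  expect_equal(callWholeChromosomes(v, thrCF)[["chr04"]], 2L)
  v[4] <- 1.30
  expect_equal(callWholeChromosomes(v, thrCF)[["chr04"]], 1L)
  v[4] <- 0.55                    # near the -2 level (0.5217)
  expect_equal(callWholeChromosomes(v, thrCF)[["chr04"]], -2L)
})

test_that("noise-free single whole-chromosome karyotypes are recovered", {
  for (chrom in c(1, 5, 9, 12)) {
    for (delta in c(-2, -1, 1, 2)) {
      k <- Karyotype(whole = stats::setNames(delta, chrom))
      p <- simulateProfile(k, SimConfig(g, noise = "none"))
      call <- callIndividual(p, g, thrCF)
      expect_equal(calledKaryotype(call)@whole, k@whole,
                   info = sprintf("chr%02d delta %+d", chrom, delta))
      expect_equal(calledKaryotype(call)@shortArm, integer(12))
    }
  }
})

test_that("noise-free arm karyotypes are recovered with whole calls zero", {
  for (chrom in c(4, 10, 11)) {
    for (arm in c("S", "L")) {
      for (delta in c(-2, -1, 1, 2)) {
        k <- if (arm == "S") Karyotype(shortArm = stats::setNames(delta, chrom))
             else Karyotype(longArm = stats::setNames(delta, chrom))
        p <- simulateProfile(k, SimConfig(g, noise = "none"))
        call <- callIndividual(p, g, thrCF)
        expect_equal(calledKaryotype(call)@whole, integer(12),
                     info = sprintf("chr%02d %s%+d whole", chrom, arm, delta))
        got <- if (arm == "S") calledKaryotype(call)@shortArm
               else calledKaryotype(call)@longArm
        expect_equal(got, k@shortArm + k@longArm,
                     info = sprintf("chr%02d %s%+d arm", chrom, arm, delta))
      }
    }
  }
})

test_that("compound and hidden karyotypes are recovered noise-free", {
  hid <- parseKaryotype("+1 Chr01; -1 Chr10")
  call <- callIndividual(simulateProfile(hid, SimConfig(g, noise = "none")),
                         g, thrCF)
  expect_equal(calledKaryotype(call)@whole, hid@whole)
  expect_equal(classification(call)@category, "compound")
  expect_true(classification(call)@isHidden)
  expect_equal(classification(call)@chromosomeNumber, 48L)

  # multi-gain compounds rely on the baseline refinement
  tri <- parseKaryotype("+1 Chr04; +1 Chr07; +1 Chr11")
  call <- callIndividual(simulateProfile(tri, SimConfig(g, noise = "none")),
                         g, thrCF)
  expect_equal(calledKaryotype(call)@whole, tri@whole)
  expect_equal(classification(call)@chromosomeNumber, 51L)
})

test_that("simulated gains are recovered at 1x depth", {
  cfg <- SimConfig(g, meanDepth = 1, seed = 41L)
  p <- simulateProfile(Karyotype(whole = c("9" = 1)), cfg)
  call <- callIndividual(p, g, thrCF)
  expect_equal(unname(wholeDelta(calledKaryotype(call))),
               c(rep(0L, 8), 1L, 0L, 0L, 0L))

  cfg2 <- SimConfig(g, meanDepth = 1, seed = 43L)
  p2 <- simulateProfile(Karyotype(whole = c("10" = 2)), cfg2)
  expect_equal(wholeDelta(calledKaryotype(callIndividual(p2, g,
                                                         thrCF)))[["chr10"]],
               2L)
})

test_that("called delta is monotone in true dosage", {
  prev <- -99L
  for (delta in -2:2) {
    d <- rep(4, 12); d[5] <- 4 + delta
    call <- callIndividual(profileFromDosage(g, d), g, thrCF)
    now <- calledKaryotype(call)@whole[5]
    expect_gte(now, prev)
    prev <- now
  }
})

test_that("euploid profiles yield no arm calls", {
  p <- simulateProfile(Karyotype(), SimConfig(g, meanDepth = 1, seed = 47L))
  call <- callIndividual(p, g, thrCF)
  expect_true(isEuploid(calledKaryotype(call)))
  expect_equal(nrow(callEvents(call)), 0L)
})

test_that("arms with too few windows are not called", {
  gShort <- GenomeSpec(chromLengths(g),
                       replace(unname(centromeres(g)), 9, 25000),
                       windowSize = windowSize(g))
  k <- Karyotype(shortArm = c("9" = 1))
  p <- simulateProfile(k, SimConfig(gShort, noise = "none"))
  call <- callIndividual(p, gShort, thrCF)
  expect_equal(calledKaryotype(call)@shortArm[9], 0L)
  expect_true(any(grepl("too short", call@notes)))
})

test_that("inconsistent window support downgrades an arm call", {
  win <- genomeWindows(g)
  counts <- GenomicRanges::width(win) * 1.0
  # windows fully contained in the chr11 long arm
  sel <- which(as.character(GenomeInfoDb::seqnames(win)) == "chr11" &
                 S4Vectors::mcols(win)$sOvl == 0)
  # a third of the long arm at dosage 1, the rest euploid: the arm mean
  # crosses the loss threshold but window support is far below 0.8
  third <- sel[seq_len(floor(length(sel) / 3))]
  counts[third] <- counts[third] * 0.25
  # adjust remaining L windows so the arm mean dosage is exactly 3
  rest <- setdiff(sel, third)
  need <- 3 / 4 * sum(GenomicRanges::width(win)[sel]) - sum(counts[third])
  counts[rest] <- need / length(rest)
  call <- callIndividual(profileFromCounts(g, counts), g, thrCF)
  expect_equal(calledKaryotype(call)@longArm[11], 0L)
  expect_true(any(grepl("downgraded", call@notes)))
})

test_that("population calling summarizes and recovers truth", {
  freqs <- c(WT = 0.4, "+1Chr09" = 0.2, "-1Chr04" = 0.2,
             "+1Chr01; -1Chr10" = 0.1, "-1LChr11" = 0.1)
  # 4x depth keeps per-chromosome noise well inside the calling margins
  # on this deliberately small test genome
  pop <- simulatePopulation(freqs, 30, SimConfig(g, meanDepth = 4,
                                                 seed = 53L))
  calls <- callPopulation(pop, thrCF)
  expect_length(calls, 30)
  expect_gte(wholeRecoveryRate(pop, calls), 0.95)
  cs <- callSummary(calls)
  expect_setequal(names(cs), c("individual_id", "karyotype_string",
                               "category", "is_segmental", "is_hidden",
                               "chromosome_number"))
  expect_equal(nrow(cs), 30)
})
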