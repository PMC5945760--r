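#' @include AllGenerics.R
NULL

#' Run the full karyotyping pipeline on a simulated population
#'
#' Convenience orchestrator tying the stages together: simulate a
#' population, derive calling thresholds, call every individual, compute
#' the population-level statistics and (when an effect model is given)
#' the phenotype comparisons. All outputs, together with a provenance
#' JSON (package version, configuration, seed), are written under
#' \code{outDir}; the intermediate objects are returned invisibly.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed; drives every stochastic stage.
#' @param genome a [GenomeSpec-class] (default [riceGenome()]).
#' @param n population size.
#' @param meanDepth simulated fold-coverage.
#' @param noise simulator noise model.
#' @param nReps threshold-derivation replicates.
#' @param nPerm propensity permutations.
#' @param alpha significance level for trait comparisons.
#' @param freqs karyotype frequencies (default: the bundled table's
#'   relative frequencies plus 188 euploids).
#' @param effectModel optional [TraitEffectModel-class].
#' @return invisibly, a list with the population, thresholds, calls and
#'   statistic tables.
#' @export
runPipeline <- function(outDir, seed, genome = riceGenome(), n = 100L,
                        meanDepth = 1.0, noise = "multinomial", nReps = 3L,
                        nPerm = 10000L, alpha = 0.05,
                        freqs = karyotypeFrequencies(),
                        effectModel = TraitEffectModel()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- subSeeds(seed, 3L)
  cfg <- SimConfig(genome, meanDepth = meanDepth, noise = noise,
                   seed = seeds[1])
  thr <- deriveThresholds(genome, SimConfig(genome, meanDepth = meanDepth,
                                            noise = noise, seed = seeds[2]),
                          nReps = nReps)
  writeThresholds(thr, file.path(outDir, "thresholds.csv"))
  pop <- simulatePopulation(freqs, n, cfg, effectModel = effectModel)
  writeTruth(pop, file.path(outDir, "truth.csv"))
  calls <- callPopulation(pop, thr)
  writeCalls(calls, file.path(outDir, "calls.csv"))
  cs <- callSummary(calls)

  called <- lapply(calls, calledKaryotype)
  gain <- loss <- comb <- numeric(12)
  for (k in called) {
    g <- k@whole > 0L | k@shortArm > 0L | k@longArm > 0L
    l <- k@whole < 0L | k@shortArm < 0L | k@longArm < 0L
    gain <- gain + g
    loss <- loss + l
    comb <- comb + (g | l)
  }
  aneu <- cs$category != "euploid"
  stats <- list(
    n = n,
    aneuploid_individuals = sum(aneu),
    aneuploid_fraction = mean(aneu),
    simple_gain_vs_loss = list(
      gains = sum(cs$category == "simple_gain"),
      losses = sum(cs$category == "simple_loss"),
      p = binomialGainLoss(sum(cs$category == "simple_gain"),
                           sum(cs$category == "simple_loss"))),
    recovery = wholeRecoveryRate(pop, calls))
  prop <- if (sum(comb) > 0)
    propensityClassification(comb, nPerm = nPerm, seed = seeds[3])
  else NULL
  if (!is.null(prop))
    utils::write.csv(prop, file.path(outDir, "propensity.csv"),
                     row.names = FALSE)
  pheno <- if (!is.null(traitMatrix(pop))) {
    cmp <- compareEuploidAneuploid(traitMatrix(pop),
                                   karyotypeLabels(pop) != "WT",
                                   alpha = alpha)
    utils::write.csv(cmp, file.path(outDir, "trait_comparison.csv"),
                     row.names = FALSE)
    cmp
  } else NULL
  jsonlite::write_json(
    list(package = "karyoDosage",
         version = as.character(utils::packageVersion("karyoDosage")),
         r_version = R.version.string,
         seed = seed, n = n, meanDepth = meanDepth, noise = noise,
         nReps = nReps, nPerm = nPerm, alpha = alpha),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(stats, file.path(outDir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(population = pop, thresholds = thr, calls = calls,
                 summary = cs, stats = stats, propensity = prop,
                 traitComparison = pheno))
}
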