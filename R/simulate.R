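#' @include AllGenerics.R
NULL

READ_LENGTH <- 125  # bp contributed by one counted read

#' Construct a SimConfig
#'
#' @param genome a [GenomeSpec-class].
#' @param meanDepth target mean fold-coverage of the haploid reference;
#'   1.0 is the calibration regime used for threshold derivation.
#' @param noise "multinomial", "poisson" or "none" (exact expected counts).
#' @param mappabilitySd sd of the per-window log-normal weight multiplier.
#' @param seed integer master seed (NA = use current RNG state).
#' @return a [SimConfig-class].
#' @export
SimConfig <- function(genome, meanDepth = 1.0, noise = "multinomial",
                      mappabilitySd = 0, seed = NA_integer_) {
  new("SimConfig", genome = genome, meanDepth = as.numeric(meanDepth),
      noise = match.arg(noise, c("multinomial", "poisson", "none")),
      mappabilitySd = as.numeric(mappabilitySd), seed = as.integer(seed))
}

withSeed <- function(seed, expr) {
  if (is.na(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## Deterministic sub-seeds below 2^31 derived from a master seed.
subSeeds <- function(seed, n) {
  if (is.na(seed)) return(rep(NA_integer_, n))
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

#' Per-window dosage weights of a karyotype
#'
#' The expected read mass of a window is proportional to its length times
#' the local dosage / 4. Windows spanning the centromere are split at the
#' centromere, each part weighted by its own arm dosage.
#'
#' @param k a [Karyotype-class].
#' @param genome a [GenomeSpec-class].
#' @param windows optional precomputed [genomeWindows()] result.
#' @return numeric weight per window (bp-dosage units).
#' @export
dosageWeights <- function(k, genome, windows = NULL) {
  stopifnot(is(k, "Karyotype"))
  if (is.null(windows)) windows <- genomeWindows(genome)
  id <- chromId(as.character(GenomeInfoDb::seqnames(windows)))
  dS <- BASELINE_DOSAGE + k@whole[id] + k@shortArm[id]
  dL <- BASELINE_DOSAGE + k@whole[id] + k@longArm[id]
  if (any(dS < 0) || any(dL < 0))
    kError("karyotype implies negative dosage on some arm",
           "karyoInfeasibleKaryotype")
  mc <- S4Vectors::mcols(windows)
  mc$sOvl * dS / 4 + mc$lOvl * dL / 4
}

#' Simulate a binned depth profile
#'
#' Count-level stand-in for read simulation plus alignment: the total
#' number of "reads" is \code{round(meanDepth * genome length / 125)}
#' (125-bp reads, each contributing one count to its window), distributed
#' over windows in proportion to [dosageWeights()] (times optional
#' mappability weights). Multinomial noise conserves the total exactly;
#' Poisson noise draws independent window counts with the same means;
#' "none" returns the exact expectations.
#'
#' @param k a [Karyotype-class].
#' @param cfg a [SimConfig-class].
#' @param id individual label.
#' @param windows optional precomputed [genomeWindows()] result.
#' @param mapWeights optional per-window mappability multipliers (fixed
#'   per genome instance; see [mappabilityWeights()]).
#' @return a [DepthProfile-class].
#' @export
simulateProfile <- function(k, cfg, id = "sim", windows = NULL,
                            mapWeights = NULL) {
  genome <- cfg@genome
  if (is.null(windows)) windows <- genomeWindows(genome)
  w <- dosageWeights(k, genome, windows)
  if (!is.null(mapWeights)) w <- w * mapWeights
  N <- round(cfg@meanDepth * sum(chromLengths(genome)) / READ_LENGTH)
  p <- w / sum(w)
  counts <- switch(cfg@noise,
    multinomial = withSeed(cfg@seed,
      as.numeric(stats::rmultinom(1L, N, p))),
    poisson = withSeed(cfg@seed, stats::rpois(length(p), N * p)),
    none = N * p)
  gr <- windows
  S4Vectors::mcols(gr)$count <- counts
  new("DepthProfile", individualId = as.character(id), windows = gr,
      totalCount = sum(counts))
}

#' Per-window mappability weights
#'
#' Log-normal multipliers emulating window-to-window mappability
#' variation (the irregular per-window scatter seen over real
#' subgenome copy-number variants); fixed per genome instance.
#'
#' @param genome a [GenomeSpec-class].
#' @param sd log-scale standard deviation.
#' @param seed integer seed.
#' @param windows optional precomputed windows.
#' @return numeric multiplier per window (all 1 when \code{sd == 0}).
#' @export
mappabilityWeights <- function(genome, sd = 0, seed = NA_integer_,
                               windows = NULL) {
  if (is.null(windows)) windows <- genomeWindows(genome)
  n <- length(windows)
  if (sd == 0) return(rep(1, n))
  withSeed(seed, exp(stats::rnorm(n, mean = -sd^2 / 2, sd = sd)))
}

#' Construct a TraitEffectModel
#'
#' Defaults mirror the measured-trait design: 21 traits, a negative
#' general aneuploidy effect of one residual standard deviation on the
#' first 12 traits, unit residual sd.
#'
#' @param nTraits number of traits.
#' @param traitNames optional trait names.
#' @param baseline euploid means (recycled).
#' @param generalEffect per-trait shift applied to every aneuploid
#'   individual; default -1 on traits 1..12, 0 elsewhere.
#' @param specificEffects data.frame(karyotype, trait, shift) with
#'   canonical karyotype strings (see [formatKaryotype()]).
#' @param noiseSd residual sd per trait (recycled).
#' @return a [TraitEffectModel-class].
#' @export
TraitEffectModel <- function(nTraits = 21L, traitNames = NULL, baseline = 0,
                             generalEffect = NULL,
                             specificEffects = NULL, noiseSd = 1) {
  nTraits <- as.integer(nTraits)
  if (is.null(traitNames)) traitNames <- sprintf("trait%02d", seq_len(nTraits))
  if (is.null(generalEffect)) {
    generalEffect <- numeric(nTraits)
    generalEffect[seq_len(min(12L, nTraits))] <- -1
  }
  if (is.null(specificEffects))
    specificEffects <- data.frame(karyotype = character(), trait = integer(),
                                  shift = numeric())
  new("TraitEffectModel", traitNames = traitNames,
      baseline = rep_len(as.numeric(baseline), nTraits),
      generalEffect = rep_len(as.numeric(generalEffect), nTraits),
      specificEffects = specificEffects,
      noiseSd = rep_len(as.numeric(noiseSd), nTraits))
}

#' Simulate a trait matrix for given karyotype labels
#'
#' trait = baseline + general effect (aneuploid individuals) + matching
#' specific effects + Gaussian noise.
#'
#' @param model a [TraitEffectModel-class].
#' @param labels canonical karyotype strings ("WT" = euploid).
#' @param seed integer seed.
#' @return numeric matrix individuals x traits.
#' @export
simulateTraits <- function(model, labels, seed = NA_integer_) {
  n <- length(labels)
  p <- length(model@traitNames)
  mu <- matrix(rep(model@baseline, each = n), n, p)
  aneu <- labels != "WT"
  mu[aneu, ] <- mu[aneu, , drop = FALSE] +
    matrix(rep(model@generalEffect, each = sum(aneu)), sum(aneu), p)
  se <- model@specificEffects
  for (j in seq_len(nrow(se))) {
    ti <- if (is.character(se$trait[j])) match(se$trait[j], model@traitNames)
          else as.integer(se$trait[j])
    hit <- labels == se$karyotype[j]
    mu[hit, ti] <- mu[hit, ti] + se$shift[j]
  }
  eps <- withSeed(seed,
    matrix(stats::rnorm(n * p, sd = rep(model@noiseSd, each = n)), n, p))
  out <- mu + eps
  colnames(out) <- model@traitNames
  out
}

#' Karyotype frequencies of the observed population
#'
#' Relative frequencies of the parseable bundled aneuploid karyotypes
#' plus the euploid class, for population simulation.
#'
#' @param records karyotype table (default the bundled table).
#' @param nEuploid euploid individuals to include (default 188).
#' @return named probability vector over canonical karyotype strings
#'   (including "WT").
#' @export
karyotypeFrequencies <- function(records = riceKaryotypeTable(),
                                 nEuploid = 188L) {
  ks <- lapply(records$karyotype_string, function(s)
    tryCatch(parseKaryotype(s), karyoDosageError = function(e) NULL))
  keep <- !vapply(ks, is.null, logical(1))
  lab <- vapply(ks[keep], formatKaryotype, character(1))
  w <- as.numeric(records$n_plants[keep])
  freq <- c(stats::setNames(w, lab), WT = as.numeric(nEuploid))
  freq / sum(freq)
}

#' Simulate a population of depth profiles with ground truth
#'
#' Karyotypes are drawn from \code{freqs}; each individual's profile uses
#' a sub-seed derived deterministically from the master seed, so the
#' whole population is reproducible. Cross direction is drawn with the
#' observed reciprocal proportions by default.
#'
#' @param freqs named probability vector over canonical karyotype strings
#'   ("WT" = euploid); must sum to 1.
#' @param n number of individuals.
#' @param cfg a [SimConfig-class] (its seed is the master seed).
#' @param effectModel optional [TraitEffectModel-class]; when supplied a
#'   trait matrix is simulated.
#' @param crossProb probability of the "NN99" cross direction.
#' @return a [SimulatedPopulation-class].
#' @export
simulatePopulation <- function(freqs, n, cfg, effectModel = NULL,
                               crossProb = 108 / 312) {
  if (n <= 0) kError("n must be positive", "karyoValidationError")
  if (abs(sum(freqs) - 1) > 1e-8)
    kError("karyotype frequencies must sum to 1", "karyoValidationError")
  genome <- cfg@genome
  windows <- genomeWindows(genome)
  mapW <- if (cfg@mappabilitySd > 0)
    mappabilityWeights(genome, cfg@mappabilitySd,
                       subSeeds(cfg@seed, 1L), windows) else NULL
  draws <- withSeed(cfg@seed, {
    lab <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    cd <- sample(c("NN99", "99NN"), n, replace = TRUE,
                 prob = c(crossProb, 1 - crossProb))
    list(lab = lab, cd = cd, seeds = sample.int(2147483646L, n + 1L))
  })
  truth <- lapply(draws$lab, parseKaryotype)
  profs <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci@seed <- if (is.na(cfg@seed)) NA_integer_ else draws$seeds[i]
    profs[[i]] <- simulateProfile(truth[[i]], ci,
                                  id = sprintf("ind%03d", i),
                                  windows = windows, mapWeights = mapW)
  }
  traits <- if (!is.null(effectModel))
    simulateTraits(effectModel, draws$lab,
                   if (is.na(cfg@seed)) NA_integer_ else draws$seeds[n + 1L])
  else NULL
  if (!is.null(traits)) rownames(traits) <- vapply(profs, individualId, "")
  new("SimulatedPopulation", profiles = profs, truth = truth,
      karyotypeLabels = draws$lab, traits = traits,
      crossDirection = draws$cd, genome = genome)
}

#' @rdname accessors
#' @export
setMethod("individualId", "DepthProfile", function(x) x@individualId)
#' @rdname accessors
#' @export
setMethod("depthWindows", "DepthProfile", function(x) x@windows)
#' @rdname accessors
#' @export
setMethod("totalCount", "DepthProfile", function(x) x@totalCount)
#' @rdname accessors
#' @export
setMethod("chromCounts", "DepthProfile", function(x) {
  cnt <- S4Vectors::mcols(x@windows)$count
  sn <- as.character(GenomeInfoDb::seqnames(x@windows))
  out <- stats::setNames(numeric(12), chromNames())
  agg <- tapply(cnt, sn, sum)
  out[names(agg)] <- agg
  out
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile", object@individualId, "-", length(object@windows),
      "windows,", format(object@totalCount, big.mark = ","), "reads\n")
})

#' @rdname accessors
#' @export
setMethod("profiles", "SimulatedPopulation", function(x) x@profiles)
#' @rdname accessors
#' @export
setMethod("trueKaryotypes", "SimulatedPopulation", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("karyotypeLabels", "SimulatedPopulation", function(x)
  x@karyotypeLabels)
#' @rdname accessors
#' @export
setMethod("traitMatrix", "SimulatedPopulation", function(x) x@traits)
#' @rdname accessors
#' @export
setMethod("crossDirection", "SimulatedPopulation", function(x)
  x@crossDirection)

setMethod("show", "SimulatedPopulation", function(object) {
  n <- length(object@profiles)
  cat("SimulatedPopulation:", n, "individuals,",
      sum(object@karyotypeLabels != "WT"), "aneuploid,",
      if (is.null(object@traits)) "no traits"
      else paste(ncol(object@traits), "traits"), "\n")
})
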