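#' @include AllGenerics.R
NULL

CALL_RANGE <- 2L          # largest |delta| assigned by the caller
CONSISTENCY_CUTOFF <- 0.8 # arm calls below this support are downgraded
MIN_ARM_WINDOWS <- 3L

## Threshold rule for one normalized value: inclusive comparison against
## the chromosome's gain/loss thresholds, then nearest expected level
## among the crossed side's candidates.
.levelOf <- function(value, gainT, lossT) {
  if (value >= gainT) {
    cand <- seq_len(CALL_RANGE)
  } else if (value <= lossT) {
    cand <- -seq_len(CALL_RANGE)
  } else return(0L)
  cand[which.min(abs(value - expectedThreshold(cand)))]
}

#' Whole-chromosome dosage calls from normalized coverage
#'
#' A chromosome is called aneuploid when its normalized value reaches the
#' gain threshold or the loss threshold (inclusive comparison). The
#' magnitude is the integer delta (up to |2|) whose closed-form expected
#' value is nearest, with the sign forced to the crossed side.
#'
#' @param nc a [NormalizedCoverage-class] (or numeric(12) of values).
#' @param thresholds a [ThresholdSet-class].
#' @param average use the averaged thresholds instead of per-chromosome
#'   ones (the dashed-line convention of per-individual coverage plots).
#' @return named integer(12) of called deltas.
#' @export
callWholeChromosomes <- function(nc, thresholds, average = FALSE) {
  values <- if (is(nc, "NormalizedCoverage")) nc@values else as.numeric(nc)
  gT <- if (average) rep(thresholds@averageGain, 12) else thresholds@gain
  lT <- if (average) rep(thresholds@averageLoss, 12) else thresholds@loss
  stats::setNames(vapply(1:12, function(i)
    .levelOf(values[i], gT[i], lT[i]), integer(1)), chromNames())
}

## Iterative mean-dosage baseline refinement: find the scale m (mean
## dosage estimate) under which value * m rounds to a stable integer
## dosage vector. Noise-free profiles converge in one step.
.refineBaseline <- function(values, maxIter = 32L) {
  m <- 4
  for (it in seq_len(maxIter)) {
    d <- pmin(12, pmax(0, round(values * m)))
    m2 <- mean(d)
    if (m2 <= 0) return(4)
    if (m2 == m) break
    m <- m2
  }
  m
}

## Per-arm normalized values on the same scale as whole-chromosome
## values: arm Key = R_arm * 12 / R_total / (arm length / length(chr1)),
## divided by the mean of the 12 whole-chromosome Keys. Only windows
## fully contained in one arm contribute, with the effective arm length
## matched to those windows, so centromere-spanning windows (dosage
## mixtures) never bias the arm values. Also returns the number of fully
## contained windows per arm.
.armValues <- function(profile, genome) {
  mc <- S4Vectors::mcols(profile@windows)
  sn <- as.character(GenomeInfoDb::seqnames(profile@windows))
  wlen <- mc$sOvl + mc$lOvl
  fullS <- mc$lOvl == 0
  fullL <- mc$sOvl == 0
  armR <- armLen <- nWin <-
    matrix(0, 12, 2, dimnames = list(chromNames(), c("S", "L")))
  for (a in c("S", "L")) {
    sel <- if (a == "S") fullS else fullL
    cnt <- tapply(mc$count[sel], sn[sel], sum)
    ln <- tapply(wlen[sel], sn[sel], sum)
    nw <- tapply(rep(1L, sum(sel)), sn[sel], sum)
    armR[names(cnt), a] <- cnt
    armLen[names(ln), a] <- ln
    nWin[names(nw), a] <- nw
  }
  total <- profile@totalCount
  len <- chromLengths(genome)
  keyArm <- armR * 12 / total / (armLen / len[1])
  keyArm[armLen == 0] <- NA_real_
  keyWhole <- chromCounts(profile) * 12 / total / relativeSizes(genome)
  list(values = keyArm / mean(keyWhole), nWindows = nWin)
}

## Fraction of an event's windows whose depth ratio (window density over
## the genome's median window density) lies on the called side of the
## midpoint between the called dosage level and the adjacent level
## toward euploidy.
.consistency <- function(ratios, delta) {
  lev <- (4 + delta) / 4
  adj <- (4 + delta - sign(delta)) / 4
  boundary <- (lev + adj) / 2
  if (delta > 0) mean(ratios > boundary) else mean(ratios < boundary)
}

#' Arm-level (segmental) calls: the windowed second criterion
#'
#' Computes arm-level normalized values from arm window sums using the
#' same Key formula with arm lengths. When the two arms of a chromosome
#' fall into different dosage levels the whole-chromosome call is
#' replaced by per-arm calls; arm calls whose window support is below the
#' consistency cutoff are downgraded to no-call, and arms with fewer than
#' 3 windows are never called.
#'
#' @param profile a [DepthProfile-class].
#' @param genome a [GenomeSpec-class].
#' @param thresholds a [ThresholdSet-class].
#' @param wholeCalls integer(12) from [callWholeChromosomes()].
#' @param scale baseline-refinement scale factor applied to arm values
#'   (1 = none).
#' @details When the two arms land in different dosage levels, the arm
#'   explanation must also fit the two arm values better (smaller summed
#'   distance to the expected levels) than the whole-chromosome call; and
#'   every nonzero arm call must pass the window checks, otherwise the
#'   whole-chromosome call is kept and a note is recorded.
#' @return list(whole, shortArm, longArm, events, notes): adjusted call
#'   vectors, an event table with consistency fractions, and warnings.
#' @export
callArms <- function(profile, genome, thresholds, wholeCalls, scale = 1) {
  av <- .armValues(profile, genome)
  armVals <- av$values * scale
  mc <- S4Vectors::mcols(profile@windows)
  sn <- as.character(GenomeInfoDb::seqnames(profile@windows))
  wlen <- GenomicRanges::width(profile@windows)
  dens <- mc$count / wlen
  base <- stats::median(dens)
  ratios <- if (base > 0) dens / base else dens
  whole <- as.integer(wholeCalls)
  sa <- la <- integer(12)
  events <- list()
  notes <- character()
  for (i in 1:12) {
    vS <- armVals[i, "S"]; vL <- armVals[i, "L"]
    if (is.na(vS) || is.na(vL)) next
    levS <- .levelOf(vS, thresholds@gain[i], thresholds@loss[i])
    levL <- .levelOf(vL, thresholds@gain[i], thresholds@loss[i])
    if (levS == levL) {
      if (whole[i] != 0L) {
        cons <- .consistency(ratios[sn == chromNames()[i]], whole[i])
        events[[length(events) + 1L]] <- data.frame(
          chrom = chromNames()[i], arm = "", delta = whole[i],
          value = NA_real_, consistency = cons)
      }
      next
    }
    # arms disagree: accept the arm explanation only when it fits the two
    # arm values better than the whole-chromosome call does
    resWhole <- abs(vS - expectedThreshold(whole[i])) +
      abs(vL - expectedThreshold(whole[i]))
    resArm <- abs(vS - expectedThreshold(levS)) +
      abs(vL - expectedThreshold(levL))
    if (resArm >= resWhole) next
    ok <- TRUE
    armEvents <- list()
    for (a in c("S", "L")) {
      lev <- if (a == "S") levS else levL
      if (lev == 0L) next
      if (av$nWindows[i, a] < MIN_ARM_WINDOWS) {
        notes <- c(notes, sprintf(
          "%s %s arm: fewer than %d windows, arm too short for calling",
          chromNames()[i], a, MIN_ARM_WINDOWS))
        ok <- FALSE
        next
      }
      sel <- sn == chromNames()[i] & mc$arm == a
      cons <- .consistency(ratios[sel], lev)
      if (cons < CONSISTENCY_CUTOFF) {
        notes <- c(notes, sprintf(
          "%s %s arm: consistency %.2f below %.2f, call downgraded",
          chromNames()[i], a, cons, CONSISTENCY_CUTOFF))
        ok <- FALSE
        next
      }
      armEvents[[a]] <- data.frame(
        chrom = chromNames()[i], arm = a, delta = lev,
        value = armVals[i, a], consistency = cons)
    }
    if (ok) {
      whole[i] <- 0L
      sa[i] <- levS
      la[i] <- levL
      events <- c(events, unname(armEvents))
    }
  }
  events <- if (length(events)) do.call(rbind, events)
  else data.frame(chrom = character(), arm = character(), delta = integer(),
                  value = numeric(), consistency = numeric())
  list(whole = whole, shortArm = sa, longArm = la, events = events,
       notes = notes)
}

#' Call one individual's karyotype from a binned depth profile
#'
#' Applies the two calling criteria in sequence: whole-chromosome calls
#' from thresholded normalized coverage, then arm-level refinement from
#' the 10-kb window distributions. By default the normalization baseline
#' is first refined by an iterative integer-dosage fit across the 12
#' chromosomes, which keeps compound karyotypes (several co-gained
#' chromosomes inflate the plain mean) on the calling scale; set
#' \code{refine = FALSE} for the raw mean-normalized rule.
#'
#' @param profile a [DepthProfile-class].
#' @param genome a [GenomeSpec-class].
#' @param thresholds a [ThresholdSet-class].
#' @param refine apply baseline refinement (default TRUE).
#' @param average use averaged instead of per-chromosome thresholds.
#' @return a [KaryotypeCall-class].
#' @export
callIndividual <- function(profile, genome, thresholds, refine = TRUE,
                           average = FALSE) {
  nc <- normalizedCoverage(profile, genome)
  scale <- if (refine) .refineBaseline(nc@values) / 4 else 1
  adj <- nc@values * scale
  whole <- callWholeChromosomes(adj, thresholds, average = average)
  arms <- callArms(profile, genome, thresholds, whole, scale = scale)
  k <- new("Karyotype", whole = as.integer(arms$whole),
           shortArm = arms$shortArm, longArm = arms$longArm)
  new("KaryotypeCall", individualId = profile@individualId, karyotype = k,
      wholeValues = stats::setNames(adj, chromNames()),
      armValues = .armValues(profile, genome)$values * scale,
      events = arms$events, classification = classifyKaryotype(k),
      notes = arms$notes)
}

#' Call every individual of a simulated population
#'
#' @param pop a [SimulatedPopulation-class].
#' @param thresholds a [ThresholdSet-class].
#' @param ... passed to [callIndividual()].
#' @return list of [KaryotypeCall-class] objects.
#' @export
callPopulation <- function(pop, thresholds, ...) {
  lapply(pop@profiles, callIndividual, genome = pop@genome,
         thresholds = thresholds, ...)
}

#' Exact whole-chromosome recovery rate of calls against truth
#'
#' Fraction of individuals whose called whole-chromosome delta vector
#' equals the true one (arm-level deltas are not compared; segmental
#' truths have all-zero whole vectors).
#'
#' @param pop a [SimulatedPopulation-class].
#' @param calls list of [KaryotypeCall-class] from [callPopulation()].
#' @return numeric fraction in [0, 1].
#' @export
wholeRecoveryRate <- function(pop, calls) {
  ok <- vapply(seq_along(calls), function(i)
    identical(calls[[i]]@karyotype@whole, pop@truth[[i]]@whole), logical(1))
  mean(ok)
}

#' Summarize a list of karyotype calls as a data.frame
#'
#' One row per individual: canonical karyotype string, category,
#' segmental/hidden flags and chromosome number.
#'
#' @param calls list of [KaryotypeCall-class].
#' @return data.frame.
#' @export
callSummary <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) data.frame(
    individual_id = cl@individualId,
    karyotype_string = formatKaryotype(cl@karyotype),
    category = cl@classification@category,
    is_segmental = cl@classification@isSegmental,
    is_hidden = cl@classification@isHidden,
    chromosome_number = cl@classification@chromosomeNumber)))
}

#' @rdname accessors
#' @export
setMethod("individualId", "KaryotypeCall", function(x) x@individualId)
#' @rdname accessors
#' @export
setMethod("calledKaryotype", "KaryotypeCall", function(x) x@karyotype)
#' @rdname accessors
#' @export
setMethod("classification", "KaryotypeCall", function(x) x@classification)
#' @rdname accessors
#' @export
setMethod("callEvents", "KaryotypeCall", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("coverageValues", "KaryotypeCall", function(x) x@wholeValues)

setMethod("show", "KaryotypeCall", function(object) {
  cat("KaryotypeCall", object@individualId, "->",
      formatKaryotype(object@karyotype),
      sprintf("(%s)\n", object@classification@category))
  if (length(object@notes)) cat(" notes:", object@notes, sep = "\n  ")
})
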