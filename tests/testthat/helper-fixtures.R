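# Shared fixtures and independent oracles, all built in code.

# A small 12-chromosome genome (~4.3 Mb) for cheap simulations; centromeres
# deliberately off window boundaries so centromere-spanning windows exist.
tinyGenome <- function(windowSize = 1e4) {
  GenomeSpec(
    lengths = c(500000, 440000, 460000, 430000, 360000, 380000,
                355000, 340000, 280000, 285000, 350000, 330000),
    centromeres = c(195000, 175000, 245000, 115000, 145000, 185000,
                    145000, 155000, 35000, 95000, 145000, 135000),
    windowSize = windowSize)
}

# Build a DepthProfile from explicit window counts.
profileFromCounts <- function(genome, counts, id = "manual") {
  w <- genomeWindows(genome)
  stopifnot(length(counts) == length(w))
  S4Vectors::mcols(w)$count <- counts
  new("DepthProfile", individualId = id, windows = w,
      totalCount = sum(counts))
}

# Exact expected-count profile for a per-chromosome dosage vector
# (dosage 4 = euploid), proportional sampling.
profileFromDosage <- function(genome, dosage, total = 1e6) {
  w <- genomeWindows(genome)
  id <- as.integer(sub("chr", "", as.character(GenomeInfoDb::seqnames(w))))
  wt <- GenomicRanges::width(w) * dosage[id] / 4
  profileFromCounts(genome, total * wt / sum(wt), id = "dosage")
}

# Independent arithmetic oracle for the normalized-coverage statistic,
# straight from per-chromosome counts and relative sizes.
oracleNormalized <- function(counts, relSizes) {
  key <- counts * 12 / sum(counts) / relSizes
  key / mean(key)
}

# Brute-force two-sided exact binomial p (minimum-likelihood rule).
oracleBinom <- function(g, l) {
  n <- g + l
  d <- vapply(0:n, function(k) choose(n, k) / 2^n, numeric(1))
  sum(d[d <= d[g + 1] * (1 + 1e-7)])
}

# Brute-force two-sided exact Poisson p by mass enumeration over 0..kmax.
oraclePoisson <- function(obs, m, kmax = 500) {
  d <- exp(-m) * m^(0:kmax) / factorial(0:kmax)
  dobs <- exp(-m) * m^obs / factorial(obs)
  min(1, sum(d[d <= dobs * (1 + 1e-7)]))
}

# Random feasible karyotype for round-trip properties.
randomKaryotype <- function() {
  whole <- integer(12); sa <- integer(12); la <- integer(12)
  nW <- sample(0:3, 1)
  if (nW > 0) whole[sample(1:12, nW)] <- sample(c(-2:-1, 1:2), nW,
                                                replace = TRUE)
  nA <- sample(0:2, 1)
  if (nA > 0) {
    for (i in sample(1:12, nA)) {
      d <- sample(c(-1, 1, 2), 1)
      if (4 + whole[i] + d < 0) d <- 1
      if (stats::runif(1) < 0.5) sa[i] <- d else la[i] <- d
    }
  }
  new("Karyotype", whole = whole, shortArm = as.integer(sa),
      longArm = as.integer(la))
}
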