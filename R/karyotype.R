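#' @include AllGenerics.R
NULL

#' Construct a Karyotype
#'
#' Deltas are relative to the euploid tetraploid baseline of 4 copies per
#' chromosome. Scalars are recycled; named vectors assign by chromosome id.
#'
#' @param whole,shortArm,longArm integer deltas, either length-12 vectors
#'   in id order or named vectors like \code{c("9" = 1)}.
#' @return a [Karyotype-class].
#' @examples
#' Karyotype(whole = c("9" = 1))      # trisomy-like gain of chromosome 9
#' parseKaryotype("+ 1 Chr. 11")
#' @export
Karyotype <- function(whole = 0L, shortArm = 0L, longArm = 0L) {
  expand <- function(v) {
    if (!is.null(names(v))) {
      out <- integer(12)
      out[chromId(names(v))] <- as.integer(v)
      out
    } else as.integer(rep_len(v, 12L))
  }
  new("Karyotype", whole = expand(whole), shortArm = expand(shortArm),
      longArm = expand(longArm))
}

#' @rdname accessors
#' @export
setMethod("wholeDelta", "Karyotype", function(x)
  stats::setNames(x@whole, chromNames()))
#' @rdname accessors
#' @export
setMethod("shortArmDelta", "Karyotype", function(x)
  stats::setNames(x@shortArm, chromNames()))
#' @rdname accessors
#' @export
setMethod("longArmDelta", "Karyotype", function(x)
  stats::setNames(x@longArm, chromNames()))
#' @rdname accessors
#' @export
setMethod("isEuploid", "Karyotype", function(x)
  all(x@whole == 0L) && all(x@shortArm == 0L) && all(x@longArm == 0L))

setMethod("show", "Karyotype", function(object)
  cat("Karyotype:", formatKaryotype(object), "\n"))

kError <- function(msg, class) {
  stop(structure(class = c(class, "karyoDosageError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Parse a karyotype string
#'
#' Reads the field notation of the karyotype table: semicolon-separated
#' terms of sign, copy magnitude, optional arm letter (S = short arm,
#' L = long arm), and chromosome id, e.g. \code{"+ 1 Chr. 11"} or
#' \code{"- 1S Chr. 04; +2S Chr. 11; - 1L Chr. 11"}. Whitespace, periods
#' after "Chr" and the typographic minus are tolerated; \code{"WT"} or an
#' empty string denotes the euploid baseline.
#'
#' @param text a single karyotype string.
#' @return a [Karyotype-class].
#' @seealso [formatKaryotype()] for the canonical inverse.
#' @export
parseKaryotype <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("−", "-", text)          # typographic minus
  s <- trimws(s)
  if (s == "" || toupper(s) %in% c("WT", "EUPLOID"))
    return(Karyotype())
  terms <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  whole <- integer(12); sa <- integer(12); la <- integer(12)
  for (term in terms) {
    t0 <- gsub("[ .]", "", term)
    if (grepl("/", t0, fixed = TRUE))
      kError(paste0("unsupported fractional-arm notation in term '", term, "'"),
             "karyoUnsupportedNotation")
    m <- regmatches(t0, regexec("^([+-])([0-9]+)(S|L)?[Cc][Hh][Rr]([0-9]{1,2})$",
                                t0))[[1]]
    if (length(m) == 0L)
      kError(paste0("malformed karyotype term '", term, "'"), "karyoParseError")
    sign <- if (m[2] == "+") 1L else -1L
    mag <- as.integer(m[3])
    arm <- m[4]
    id <- as.integer(m[5])
    if (id < 1L || id > 12L)
      kError(paste0("chromosome id out of range 1..12 in term '", term, "'"),
             "karyoRangeError")
    d <- sign * mag
    if (arm == "") whole[id] <- whole[id] + d
    else if (arm == "S") sa[id] <- sa[id] + d
    else la[id] <- la[id] + d
  }
  new("Karyotype", whole = whole, shortArm = sa, longArm = la)
}

#' Format a karyotype as its canonical string
#'
#' Canonical grammar: terms \code{([+-])(\\d+)(S|L)?Chr(\\d{2})} joined by
#' \code{"; "}; the euploid karyotype formats as \code{"WT"}.
#' \code{parseKaryotype(formatKaryotype(k))} round-trips exactly.
#'
#' @param k a [Karyotype-class].
#' @return character(1).
#' @export
formatKaryotype <- function(k) {
  stopifnot(is(k, "Karyotype"))
  terms <- character()
  for (i in 1:12) {
    if (k@whole[i] != 0L)
      terms <- c(terms, sprintf("%+dChr%02d", k@whole[i], i))
    if (k@shortArm[i] != 0L)
      terms <- c(terms, sprintf("%+dSChr%02d", k@shortArm[i], i))
    if (k@longArm[i] != 0L)
      terms <- c(terms, sprintf("%+dLChr%02d", k@longArm[i], i))
  }
  if (!length(terms)) "WT" else paste(terms, collapse = "; ")
}

#' Classify a karyotype
#'
#' Categories: \emph{euploid}; \emph{simple_gain}/\emph{simple_loss}
#' (exactly one chromosome altered by one whole copy, no arm terms);
#' everything else is \emph{compound} (including multi-copy changes of a
#' single chromosome and purely segmental karyotypes). A compound
#' karyotype is \emph{hidden} when whole-chromosome gains and losses
#' balance to a normal chromosome number of 48 with no arm terms.
#' The chromosome number (48 + net whole-chromosome change) is defined
#' only for karyotypes without arm-level terms.
#'
#' @param k a [Karyotype-class].
#' @return a [KaryotypeClass-class].
#' @export
classifyKaryotype <- function(k) {
  stopifnot(is(k, "Karyotype"))
  armAltered <- any(k@shortArm != 0L) || any(k@longArm != 0L)
  altered <- which(k@whole != 0L)
  category <-
    if (!armAltered && length(altered) == 0L) "euploid"
    else if (!armAltered && length(altered) == 1L &&
             abs(k@whole[altered]) == 1L) {
      if (k@whole[altered] > 0L) "simple_gain" else "simple_loss"
    } else "compound"
  hidden <- !armAltered && any(k@whole > 0L) && any(k@whole < 0L) &&
    sum(k@whole) == 0L
  chromNum <- if (armAltered) NA_integer_ else 48L + sum(k@whole)
  new("KaryotypeClass", category = category, isSegmental = armAltered,
      isHidden = hidden, chromosomeNumber = chromNum)
}

setMethod("show", "KaryotypeClass", function(object) {
  cat("KaryotypeClass:", object@category,
      if (object@isSegmental) "[segmental]" else "",
      if (object@isHidden) "[hidden]" else "",
      "chromosomes:",
      if (is.na(object@chromosomeNumber)) "undefined"
      else object@chromosomeNumber, "\n")
})

#' Read a karyotype table
#'
#' CSV with header \code{karyotype_id,karyotype_string,n_plants}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readKaryotypeTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("karyotype_id", "karyotype_string", "n_plants")
  if (!all(need %in% names(df)))
    kError(paste("karyotype table needs columns:", paste(need, collapse = ",")),
           "karyoValidationError")
  df
}

#' The bundled aneuploid karyotype table
#'
#' The 55 distinct aneuploid karyotypes observed in the S4 segmental
#' allotetraploid rice population, with the number of plants carrying
#' each. Record #55 contains a fractional-arm term that the grammar does
#' not interpret; it is kept raw and flagged unparseable by
#' [tabulateKaryotypes()].
#'
#' @return data.frame(karyotype_id, karyotype_string, n_plants).
#' @export
riceKaryotypeTable <- function() {
  readKaryotypeTable(system.file("extdata", "aneuploid_karyotypes.csv",
                                 package = "karyoDosage", mustWork = TRUE))
}

#' Aggregate a karyotype table
#'
#' Per-category plant totals, distinct-karyotype count, per-chromosome
#' gain/loss/combined involvement counts (each karyotype contributes its
#' \code{n_plants} weight), and the chromosome-number range over
#' karyotypes with a defined chromosome number. Records whose string
#' cannot be parsed are kept for plant totals (and counted segmental when
#' their raw string carries arm terms) but excluded from all
#' dosage-dependent tallies.
#'
#' @param records data.frame as returned by [readKaryotypeTable()].
#' @param nEuploid number of euploid individuals in the population
#'   (used for the aneuploid-fraction summary), default 0.
#' @return a list with elements \code{aneuploidPlants},
#'   \code{distinctKaryotypes}, \code{categoryPlants},
#'   \code{segmentalPlants}, \code{hiddenPlants}, \code{perChromosome}
#'   (data.frame chrom, gain, loss, combined), \code{chromosomeNumberRange},
#'   \code{aneuploidFraction}, \code{unparseable}.
#' @export
tabulateKaryotypes <- function(records, nEuploid = 0L) {
  if (anyDuplicated(records$karyotype_id))
    kError("duplicate karyotype_id in records", "karyoValidationError")
  n <- nrow(records)
  parsed <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    parsed[i] <- list(tryCatch(parseKaryotype(records$karyotype_string[i]),
                               karyoDosageError = function(e) NULL))
    ok[i] <- !is.null(parsed[[i]])
  }
  w <- as.integer(records$n_plants)
  euploid <- ok & vapply(seq_len(n), function(i)
    ok[i] && isEuploid(parsed[[i]]), logical(1))
  aneu <- !euploid

  cls <- lapply(seq_len(n), function(i)
    if (ok[i]) classifyKaryotype(parsed[[i]]) else NULL)
  catOf <- vapply(cls, function(cl) if (is.null(cl)) NA_character_
                  else cl@category, character(1))
  categoryPlants <- vapply(c("simple_gain", "simple_loss", "compound"),
    function(cc) sum(w[!is.na(catOf) & catOf == cc]), numeric(1))

  segRaw <- grepl("[0-9](S|L)", gsub("[ .]", "",
                                     records$karyotype_string))
  segmental <- vapply(seq_len(n), function(i)
    if (ok[i]) cls[[i]]@isSegmental else segRaw[i], logical(1))
  hidden <- vapply(seq_len(n), function(i)
    if (ok[i]) cls[[i]]@isHidden else FALSE, logical(1))

  gain <- loss <- comb <- stats::setNames(numeric(12), chromNames())
  for (i in which(ok & aneu)) {
    k <- parsed[[i]]
    g <- k@whole > 0L | k@shortArm > 0L | k@longArm > 0L
    l <- k@whole < 0L | k@shortArm < 0L | k@longArm < 0L
    gain <- gain + w[i] * g
    loss <- loss + w[i] * l
    comb <- comb + w[i] * (g | l)
  }

  cn <- vapply(seq_len(n), function(i)
    if (ok[i] && aneu[i]) cls[[i]]@chromosomeNumber else NA_integer_,
    integer(1))
  cnRange <- if (all(is.na(cn))) c(NA_integer_, NA_integer_)
             else range(cn, na.rm = TRUE)

  aneuPlants <- sum(w[aneu])
  total <- aneuPlants + sum(w[euploid]) + nEuploid
  list(
    aneuploidPlants = aneuPlants,
    distinctKaryotypes = sum(aneu),
    categoryPlants = categoryPlants,
    segmentalPlants = sum(w[segmental & aneu]),
    hiddenPlants = sum(w[hidden]),
    perChromosome = data.frame(chrom = chromNames(), gain = as.numeric(gain),
                               loss = as.numeric(loss),
                               combined = as.numeric(comb)),
    chromosomeNumberRange = cnRange,
    aneuploidFraction = if (total > 0) aneuPlants / total else NA_real_,
    unparseable = records$karyotype_id[!ok])
}
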