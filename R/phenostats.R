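#' @include AllGenerics.R
NULL

#' Average replicate trait measurements per individual
#'
#' Traits measured in multiple batches (e.g. seed traits measured on
#' three independent batches) are averaged per individual before group
#' testing.
#'
#' @param traits data.frame with an id column and numeric trait columns.
#' @param idCol name of the individual-id column.
#' @return data.frame with one row per individual (means of replicates).
#' @export
collapseReplicates <- function(traits, idCol = "individual_id") {
  stopifnot(idCol %in% names(traits))
  num <- setdiff(names(traits), idCol)
  agg <- stats::aggregate(traits[num], by = traits[idCol], FUN = mean)
  agg
}

#' Euploid-vs-aneuploid trait comparison
#'
#' Per-trait two-sample Student's t test (pooled variance by default,
#' Welch via \code{welch = TRUE}) comparing euploid and aneuploid group
#' means; traits with fewer than 2 observations in either group are
#' skipped with a warning.
#'
#' @param traits numeric matrix or data.frame, individuals x traits.
#' @param aneuploid logical vector: TRUE for aneuploid individuals.
#' @param alpha significance level for the significant-trait count.
#' @param welch use Welch's unequal-variance t test.
#' @return data.frame(trait, mean_euploid, mean_aneuploid, t, p,
#'   direction, significant) with attribute \code{nSignificant}.
#' @export
compareEuploidAneuploid <- function(traits, aneuploid, alpha = 0.05,
                                    welch = FALSE) {
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) == length(aneuploid))
  aneuploid <- as.logical(aneuploid)
  rows <- lapply(seq_len(ncol(traits)), function(j) {
    y <- traits[, j]
    e <- y[!aneuploid & !is.na(y)]
    a <- y[aneuploid & !is.na(y)]
    if (length(e) < 2L || length(a) < 2L) {
      warning("trait ", colnames(traits)[j],
              " skipped: fewer than 2 observations in a group")
      return(NULL)
    }
    tt <- stats::t.test(a, e, var.equal = !welch)
    diff <- mean(a) - mean(e)
    data.frame(trait = colnames(traits)[j], mean_euploid = mean(e),
               mean_aneuploid = mean(a), t = unname(tt$statistic),
               p = tt$p.value,
               direction = if (diff < 0) "lower" else "higher",
               significant = tt$p.value < alpha)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trait = character(), mean_euploid = numeric(),
                      mean_aneuploid = numeric(), t = numeric(),
                      p = numeric(), direction = character(),
                      significant = logical())
  attr(out, "nSignificant") <- sum(out$significant)
  attr(out, "alpha") <- alpha
  out
}

#' Karyotype-specific trait association screen
#'
#' A deliberately simple association screen for chromosome-specific
#' trait effects (a labeled approximation standing in for a multi-locus
#' mixed-model scan): each karyotype carried by at least \code{minGroup}
#' individuals is compared against the euploid individuals, per trait,
#' with a linear model including cross direction as a fixed covariate;
#' p-values are Benjamini-Hochberg adjusted across all tested
#' (karyotype, trait) pairs.
#'
#' @param traits numeric matrix, individuals x traits.
#' @param labels canonical karyotype strings per individual ("WT" =
#'   euploid).
#' @param cross cross-direction covariate per individual.
#' @param minGroup minimum carriers for a karyotype to be screened.
#' @return data.frame(karyotype, trait, n_carriers, effect, p, padj),
#'   empty (with a warning) when no karyotype passes the filter.
#' @export
karyotypeAssociation <- function(traits, labels, cross = NULL,
                                 minGroup = 3L) {
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) == length(labels))
  if (is.null(cross)) cross <- rep("pooled", length(labels))
  tabs <- table(labels[labels != "WT"])
  groups <- names(tabs)[tabs >= minGroup]
  empty <- data.frame(karyotype = character(), trait = character(),
                      n_carriers = integer(), effect = numeric(),
                      p = numeric(), padj = numeric())
  if (!length(groups)) {
    warning("no karyotype has at least ", minGroup, " carriers")
    return(empty)
  }
  rows <- list()
  for (g in groups) {
    sel <- labels == "WT" | labels == g
    isG <- as.integer(labels[sel] == g)
    cv <- factor(cross[sel])
    useCov <- nlevels(droplevels(cv)) > 1L
    for (j in seq_len(ncol(traits))) {
      y <- traits[sel, j]
      fit <- if (useCov) stats::lm(y ~ isG + cv) else stats::lm(y ~ isG)
      co <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        karyotype = g, trait = colnames(traits)[j],
        n_carriers = sum(isG), effect = co["isG", "Estimate"],
        p = co["isG", "Pr(>|t|)"])
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
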