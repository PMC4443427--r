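# Iterative conditional scanning, reciprocal conditioning, and
# multiple-testing bookkeeping.

#' Stepwise conditional association scan
#'
#' Round 1 tests every candidate marker against intercept + covariates; the
#' most significant marker below the entry threshold is added as a fixed
#' effect, and subsequent rounds re-test the remaining markers conditioned
#' on all previous winners, until no marker reaches the threshold (stop
#' reason `"no-significant"`) or `maxRounds` is hit (`"max-rounds"`). Ties
#' on P are broken by larger chi-squared, then lexicographically by marker
#' id, so ledgers are reproducible.
#'
#' Two thresholds are in common use: 1e-5 for an MHC-wide scan (Bonferroni
#' for ~5,000 independent tests, see [bonferroniThreshold()]) and 1e-3 for
#' a restricted panel such as the 38 four-digit HLA-B alleles.
#'
#' @param x an [HlaDosageSet-class].
#' @param candidates character vector of candidate marker ids.
#' @param pheno,covar as in [testMarker()].
#' @param threshold entry threshold on the P scale (default 1e-5);
#'   comparisons are done in log10 space.
#' @param maxRounds cap on the number of rounds (default 20).
#' @return a [ConditionalLedger-class].
#' @export
stepwiseScan <- function(x, candidates, pheno, covar = NULL,
                         threshold = 1e-5, maxRounds = 20L) {
  if (length(candidates) == 0L) stop("empty candidate marker set")
  log10thr <- log10(threshold)
  winners <- character(0)
  rows <- list()
  stop <- "no-significant"
  for (round in seq_len(maxRounds)) {
    remaining <- setdiff(candidates, winners)
    if (length(remaining) == 0L) break
    scan <- do.call(rbind, lapply(remaining, function(mk) {
      testMarker(x, mk, pheno, covar, conditioning = winners)
    }))
    ok <- scan$testable & !is.na(scan$log10P) & scan$log10P < log10thr
    if (!any(ok)) break
    sc <- scan[ok, , drop = FALSE]
    best <- sc[order(sc$log10P, -sc$chisq, sc$id), , drop = FALSE][1L, ]
    rows[[round]] <- S4Vectors::DataFrame(
      round = round, marker = best$id, or = best$or, ciLow = best$ciLow,
      ciHigh = best$ciHigh, beta = best$beta, se = best$se,
      chisq = best$chisq, df = best$df, log10P = best$log10P,
      conditioning = paste(winners, collapse = ","))
    winners <- c(winners, best$id)
    if (round == maxRounds) stop <- "max-rounds"
  }
  roundsDF <- if (length(rows)) do.call(rbind, rows) else
    S4Vectors::DataFrame(
      round = integer(0), marker = character(0), or = numeric(0),
      ciLow = numeric(0), ciHigh = numeric(0), beta = numeric(0),
      se = numeric(0), chisq = numeric(0), df = integer(0),
      log10P = numeric(0), conditioning = character(0))
  new("ConditionalLedger", rounds = roundsDF, stopReason = stop,
      thresholdLog10P = log10thr)
}

#' Reciprocal conditioning between two signals
#'
#' Asks whether signal b statistically explains signal a: tests a
#' conditioned on b and b conditioned on a (each side may be a single
#' marker or a set of residue markers, tested jointly as in
#' [omnibusTest()]). Verdicts at significance `alpha` (default 0.05):
#' `"b-explains-a"` when a is extinguished given b but not vice versa,
#' `"a-explains-b"` for the reverse, `"both-independent"` when both survive
#' conditioning, `"indistinguishable"` when neither does or the pair is
#' collinear.
#'
#' @param x an [HlaDosageSet-class].
#' @param a,b character vectors of marker ids (a position's residues or a
#'   single allele/SNP).
#' @param pheno,covar as in [testMarker()].
#' @param alpha residual-significance cutoff (default 0.05).
#' @return a list with `pAgivenB`, `pBgivenA` (P-values) and `verdict`.
#' @export
reciprocalConditioning <- function(x, a, b, pheno, covar = NULL,
                                   alpha = 0.05) {
  al <- .alignCohort(x, pheno, covar)
  testGiven <- function(term, given) {
    res <- suppressWarnings(
      .conditionalLRT(al$y, al$covar, al$dosage(given), al$dosage(term)))
    if (!res$testable) NA_real_ else res$p
  }
  pAB <- testGiven(a, b)
  pBA <- testGiven(b, a)
  verdict <- if (is.na(pAB) || is.na(pBA)) "indistinguishable"
  else if (pAB >= alpha && pBA < alpha) "b-explains-a"
  else if (pBA >= alpha && pAB < alpha) "a-explains-b"
  else if (pAB < alpha && pBA < alpha) "both-independent"
  else "indistinguishable"
  list(pAgivenB = pAB, pBgivenA = pBA, verdict = verdict)
}

#' Count statistically independent tests by greedy LD pruning
#'
#' Walks markers in genomic-position order and keeps a marker iff its
#' dosage r2 with every already-kept marker is below `r2Cut`; the count of
#' kept markers is the number of independent tests for Bonferroni
#' correction. Two tests are considered independent when the pairwise
#' dosage correlation r2 is below 0.90.
#'
#' @param x an [HlaDosageSet-class].
#' @param markers marker ids to prune (default: all markers in `x`).
#' @param r2Cut independence cutoff (default 0.90).
#' @return integer count of independent tests.
#' @export
countIndependentTests <- function(x, markers = rownames(x), r2Cut = 0.90) {
  if (length(markers) == 0L) stop("at least one marker required")
  info <- SummarizedExperiment::rowData(x)[markers, , drop = FALSE]
  ord <- order(info$position, markers, na.last = TRUE)
  markers <- markers[ord]
  d <- dosages(x)[markers, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_along(markers)) {
    indep <- TRUE
    for (j in kept) {
      r2 <- suppressWarnings(ldR2(d[i, ], d[j, ]))
      if (!is.na(r2) && r2 >= r2Cut) { indep <- FALSE; break }
    }
    if (indep) kept <- c(kept, i)
  }
  length(kept)
}

#' Bonferroni significance threshold
#'
#' `alpha / nTests`; with the conventional alpha = 0.05 over 5,000
#' independent MHC tests this gives the 1e-5 threshold used for MHC-wide
#' scans.
#'
#' @param alpha familywise error rate (default 0.05).
#' @param nTests number of independent tests.
#' @return the per-test significance threshold.
#' @examples
#' bonferroniThreshold(0.05, 5000)  # 1e-5
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  stopifnot(nTests >= 1)
  alpha / nTests
}
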