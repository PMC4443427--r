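# HLA-stratified effect estimation and formal interaction tests for a
# candidate SNP (ERAP1 rs30187-style) and for classical allele pairs.

#' Hard-call imputed dosages to genotype counts
#'
#' Best-guess genotype from an expected dosage: `floor(dosage + 0.5)`
#' (i.e. rounding, with the half-point rounding up deterministically).
#' A sample is a carrier when its hard-called count is at least 1.
#'
#' @param dosage numeric vector/matrix of dosages in \[0, 2\].
#' @return integer counts in \{0, 1, 2\} of the same shape.
#' @examples
#' hardCall(c(0.4, 1.7))  # 0, 2
#' @export
hardCall <- function(dosage) {
  stopifnot(all(dosage >= 0 & dosage <= 2, na.rm = TRUE))
  out <- floor(dosage + 0.5)
  storage.mode(out) <- "integer"
  out
}

#' Build the standard HLA-B27/B40 interaction strata
#'
#' The four mutually exclusive, exhaustive carrier strata used to
#' characterise the ERAP1-HLA interaction: B27 carriers; B27-negative
#' carriers of B*40:01; B27-negative carriers of B*40:02; and samples
#' carrying neither B27 nor B40. Samples carrying both B*40:01 and B*40:02
#' (without B27) fall in the B*40:01 stratum.
#'
#' @param b27 marker ids whose carriers define the B27-positive stratum.
#' @param b4001,b4002 marker ids of the two B40 four-digit alleles.
#' @return a named list of predicate functions over a hard-called dosage
#'   matrix (samples x markers), suitable for [assignStrata()].
#' @export
b27B40Strata <- function(b27 = c("HLA_B_2705", "HLA_B_2702"),
                         b4001 = "HLA_B_4001", b4002 = "HLA_B_4002") {
  carrier <- function(calls, ids) {
    ids <- intersect(ids, colnames(calls))
    if (length(ids) == 0L) return(rep(FALSE, nrow(calls)))
    rowSums(calls[, ids, drop = FALSE] >= 1) > 0
  }
  list(
    "B27+" = function(calls) carrier(calls, b27),
    "B27-/B40:01+" = function(calls)
      !carrier(calls, b27) & carrier(calls, b4001),
    "B27-/B40:02+" = function(calls)
      !carrier(calls, b27) & !carrier(calls, b4001) & carrier(calls, b4002),
    "B27-/B40-" = function(calls)
      !carrier(calls, b27) & !carrier(calls, b4001) & !carrier(calls, b4002))
}

#' Assign each sample to exactly one carrier stratum
#'
#' Hard-calls the classical allele dosages and evaluates the stratum
#' predicates; errors if any sample matches zero or more than one stratum
#' (strata must be mutually exclusive and exhaustive).
#'
#' @param x an [HlaDosageSet-class] containing the classical allele markers
#'   the predicates reference.
#' @param definitions named list of predicate functions over the
#'   hard-called samples x markers count matrix, e.g. from [b27B40Strata()].
#' @return a factor of stratum labels (levels in definition order), named
#'   by sample id.
#' @export
assignStrata <- function(x, definitions = b27B40Strata()) {
  stopifnot(is(x, "HlaDosageSet"), length(definitions) > 0L,
            !is.null(names(definitions)))
  calls <- t(hardCall(dosages(x)))
  hits <- vapply(definitions, function(f) {
    v <- f(calls)
    stopifnot(is.logical(v), length(v) == nrow(calls))
    v
  }, logical(nrow(calls)))
  if (!is.matrix(hits)) hits <- matrix(hits, nrow = nrow(calls))
  nhit <- rowSums(hits)
  if (any(nhit > 1L))
    stop("overlapping stratum definitions for sample(s): ",
         paste(utils::head(colnames(x)[nhit > 1L], 5L), collapse = ", "))
  if (any(nhit == 0L))
    stop("stratum definitions are not exhaustive; unassigned sample(s): ",
         paste(utils::head(colnames(x)[nhit == 0L], 5L), collapse = ", "))
  lab <- names(definitions)[apply(hits, 1L, which)]
  factor(stats::setNames(lab, colnames(x)), levels = names(definitions))
}

#' Per-stratum effect of a candidate SNP
#'
#' Within each carrier stratum, a 1-df conditional test of the SNP dosage
#' with covariates (the forest-plot analysis behind ERAP1 x HLA-B
#' epistasis). Strata lacking a case or a control are flagged untestable
#' rather than failing.
#'
#' @param x an [HlaDosageSet-class].
#' @param snp marker id of the candidate SNP.
#' @param strata factor of stratum labels named by sample id, from
#'   [assignStrata()].
#' @param pheno,covar as in [testMarker()].
#' @return a `DataFrame` with one row per stratum: `stratum`, `nControls`,
#'   `nCases`, `or`, `ciLow`, `ciHigh`, `beta`, `se`, `chisq`, `df`,
#'   `log10P`, `p`, `testable`. Stratum sample counts sum to the analysed
#'   cohort size.
#' @export
stratifiedEffect <- function(x, snp, strata, pheno, covar = NULL) {
  .checkPhenotypeTable(pheno)
  if (is.null(names(strata))) stop("strata must be named by sample id")
  miss <- setdiff(pheno$sample_id, names(strata))
  if (length(miss) > 0L)
    stop("samples without a stratum label: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  out <- lapply(levels(strata), function(s) {
    ids <- names(strata)[strata == s]
    ph <- pheno[pheno$sample_id %in% ids, , drop = FALSE]
    nCase <- sum(ph$status == 1); nCtl <- sum(ph$status == 0)
    if (nCase == 0L || nCtl == 0L) {
      return(S4Vectors::DataFrame(
        stratum = s, nControls = nCtl, nCases = nCase, or = NA_real_,
        ciLow = NA_real_, ciHigh = NA_real_, beta = NA_real_, se = NA_real_,
        chisq = NA_real_, df = NA_integer_, log10P = NA_real_, p = NA_real_,
        testable = FALSE))
    }
    cv <- if (is.null(covar)) NULL else
      covar[covar$sample_id %in% ids, , drop = FALSE]
    r <- suppressWarnings(testMarker(x, snp, ph, cv))
    S4Vectors::DataFrame(
      stratum = s, nControls = nCtl, nCases = nCase, or = r$or,
      ciLow = r$ciLow, ciHigh = r$ciHigh, beta = r$beta, se = r$se,
      chisq = r$chisq, df = r$df, log10P = r$log10P, p = r$p,
      testable = r$testable)
  })
  do.call(rbind, out)
}

#' Product-term interaction test between a SNP and an allele carrier state
#'
#' Likelihood-ratio test (1 df) comparing the main-effects model
#' (SNP dosage + carrier indicator + covariates) against the model adding
#' the SNP-dosage x carrier-indicator product, the formal counterpart of a
#' stratum-restricted SNP effect.
#'
#' @param x an [HlaDosageSet-class].
#' @param snp marker id of the candidate SNP.
#' @param carrierMarker classical allele marker id; the carrier indicator
#'   is its hard-called count >= 1.
#' @param pheno,covar as in [testMarker()].
#' @return a list with `chisq`, `df` (= 1), `log10P`, `p` and `n`. Errors
#'   when the product column is collinear with the main effects (e.g. the
#'   SNP is the carrier marker itself).
#' @export
interactionTest <- function(x, snp, carrierMarker, pheno, covar = NULL) {
  al <- .alignCohort(x, pheno, covar)
  g <- al$dosage(snp)[, 1L]
  carrier <- as.numeric(hardCall(al$dosage(carrierMarker)[, 1L]) >= 1L)
  main <- cbind(g, carrier)
  colnames(main) <- c(snp, paste0(carrierMarker, "_carrier"))
  prod <- cbind(g * carrier)
  colnames(prod) <- paste0(snp, ":", carrierMarker)
  res <- suppressWarnings(.conditionalLRT(al$y, al$covar, main, prod))
  if (!res$testable)
    stop("interaction product column is collinear with the main effects")
  list(chisq = res$chisq, df = res$df, log10P = res$log10P, p = res$p,
       n = res$n)
}

#' Interaction test between two classical alleles
#'
#' Tests whether two allele dosages jointly increase disease risk beyond
#' their additive (log-odds) main effects, via a 1-df LRT on the dosage
#' product term.
#'
#' @param x an [HlaDosageSet-class].
#' @param alleleA,alleleB classical allele marker ids.
#' @param pheno,covar as in [testMarker()].
#' @return a list with `chisq`, `df`, `log10P`, `p`, `n` and `testable`;
#'   `testable = FALSE` (with `NA` statistics) when the product carries no
#'   information, e.g. no sample carries both alleles.
#' @export
allelePairInteraction <- function(x, alleleA, alleleB, pheno, covar = NULL) {
  al <- .alignCohort(x, pheno, covar)
  gA <- al$dosage(alleleA)[, 1L]
  gB <- al$dosage(alleleB)[, 1L]
  main <- cbind(gA, gB)
  colnames(main) <- c(alleleA, alleleB)
  prod <- cbind(gA * gB)
  colnames(prod) <- paste0(alleleA, ":", alleleB)
  res <- suppressWarnings(.conditionalLRT(al$y, al$covar, main, prod))
  list(chisq = res$chisq, df = res$df, log10P = res$log10P, p = res$p,
       n = res$n, testable = res$testable)
}
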