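#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

# ---------------------------------------------------------------------------
# HlaDosageSet
# ---------------------------------------------------------------------------

#' Container for SNP, classical HLA allele and amino-acid residue dosages
#'
#' `HlaDosageSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `"dosage"` assay holding expected allele counts in \[0, 2\]
#' (fractional after imputation), markers as rows and samples as columns.
#' Per-marker metadata lives in `rowData`: `kind` (one of `"snp"`,
#' `"classical_allele"`, `"aa_residue"`), `locus` (e.g. `"HLA-B"`), `position`
#' (genomic bp for SNPs/classical alleles, protein position for residues),
#' `alleleLabel` (e.g. `"27:05"`, `"97:Asn"`, `"T"`) and `imputationR2` (the
#' per-marker imputation quality score, `NA` for genotyped markers).
#'
#' @param dosage numeric matrix (markers x samples) with rownames (marker
#'   ids) and colnames (sample ids); values in \[0, 2\] or `NA`.
#' @param markerInfo optional `data.frame`/`DataFrame` of per-marker
#'   metadata. Missing columns are inferred from the marker id prefix
#'   (`AA_` = amino-acid residue, `HLA_` = classical allele, otherwise SNP).
#' @param x an `HlaDosageSet`.
#'
#' @return `HlaDosageSet()` returns a validated `HlaDosageSet`; `dosages()`
#'   the dosage matrix; `markerInfo()` the marker metadata `DataFrame`.
#'
#' @examples
#' d <- matrix(c(2, 0, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("HLA_B_2705", "rs30187"), c("s1", "s2")))
#' x <- HlaDosageSet(d)
#' markerInfo(x)$kind
#' @aliases dosages markerInfo
#' @export
HlaDosageSet <- function(dosage, markerInfo = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    stop("dosage matrix must have marker ids as rownames")
  if (is.null(colnames(dosage)))
    stop("dosage matrix must have sample ids as colnames")
  ids <- rownames(dosage)
  info <- DataFrame(row.names = ids)
  if (!is.null(markerInfo)) {
    markerInfo <- DataFrame(markerInfo)
    if (!is.null(markerInfo$marker)) rownames(markerInfo) <- markerInfo$marker
    if (is.null(rownames(markerInfo)))
      stop("markerInfo must carry marker ids (rownames or 'marker' column)")
    markerInfo <- markerInfo[intersect(rownames(markerInfo), ids), , drop = FALSE]
    for (col in setdiff(colnames(markerInfo), "marker"))
      info[rownames(markerInfo), col] <- markerInfo[[col]]
  }
  if (is.null(info$kind) || anyNA(info$kind)) {
    guess <- .inferMarkerKind(ids)
    info$kind <- if (is.null(info$kind)) guess else
      ifelse(is.na(info$kind), guess, info$kind)
  }
  if (is.null(info$locus)) info$locus <- .inferMarkerLocus(ids)
  if (is.null(info$position)) info$position <- .inferMarkerPosition(ids)
  if (is.null(info$alleleLabel)) info$alleleLabel <- .inferAlleleLabel(ids)
  if (is.null(info$imputationR2)) info$imputationR2 <- NA_real_
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = info)
  new("HlaDosageSet", se)
}

#' @rdname HlaDosageSet-class
#' @exportClass HlaDosageSet
setClass("HlaDosageSet", contains = "SummarizedExperiment")

setValidity("HlaDosageSet", function(object) {
  msg <- character(0)
  if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "must contain a 'dosage' assay")
  else {
    d <- assay(object, "dosage")
    if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "dosages must lie in [0, 2] or be NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate marker ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  info <- rowData(object)
  if (!("kind" %in% colnames(info)))
    msg <- c(msg, "rowData must have a 'kind' column")
  else if (!all(info$kind %in% c("snp", "classical_allele", "aa_residue")))
    msg <- c(msg, "kind must be snp, classical_allele or aa_residue")
  else {
    aa <- info$kind == "aa_residue"
    if (any(aa) && (anyNA(info$locus[aa]) || anyNA(info$position[aa])))
      msg <- c(msg, "aa_residue markers require locus and protein position")
  }
  if (length(msg) > 0) msg else TRUE
})

#' @rdname HlaDosageSet-class
#' @export
setMethod("dosages", "HlaDosageSet", function(x) assay(x, "dosage"))

#' @rdname HlaDosageSet-class
#' @export
setMethod("markerInfo", "HlaDosageSet", function(x) rowData(x))

setMethod("show", "HlaDosageSet", function(object) {
  kinds <- table(factor(rowData(object)$kind,
                        c("snp", "classical_allele", "aa_residue")))
  cat("HlaDosageSet with", nrow(object), "markers x", ncol(object),
      "samples\n")
  cat(sprintf("  %d SNP, %d classical allele, %d amino-acid residue markers\n",
              kinds[["snp"]], kinds[["classical_allele"]],
              kinds[["aa_residue"]]))
})

# ---------------------------------------------------------------------------
# AlleleProteinMap
# ---------------------------------------------------------------------------

#' Classical allele to protein residue lookup
#'
#' Maps classical HLA alleles to the amino-acid residue they carry at each
#' polymorphic protein position, the input required to expand classical
#' allele dosages into residue dosages. One residue per (allele, position)
#' pair; conflicting duplicates are rejected.
#'
#' @param entries `data.frame` with columns `allele` (e.g. `"B*27:05"`),
#'   `position` (1-based protein position) and `residue` (one- or
#'   three-letter amino-acid code).
#' @param x an `AlleleProteinMap`.
#' @param allele,position scalar allele name / protein position.
#' @param locus locus name such as `"HLA-B"` (alleles `B*...`).
#'
#' @return `AlleleProteinMap()` a validated map; `mapEntries()` the entry
#'   `DataFrame` (residues one-letter); `mappedPositions()` the integer
#'   positions mapped at a locus; `residueAt()` the one-letter residue.
#' @examples
#' m <- AlleleProteinMap(data.frame(allele = c("B*27:05", "B*07:02"),
#'                                  position = 97, residue = c("Asn", "Ser")))
#' residueAt(m, "B*27:05", 97)
#' @aliases mapEntries mappedPositions residueAt
#' @export
AlleleProteinMap <- function(entries) {
  entries <- as.data.frame(entries)
  stopifnot(all(c("allele", "position", "residue") %in% colnames(entries)))
  df <- DataFrame(allele = as.character(entries$allele),
                  position = as.integer(entries$position),
                  residue = aaOneLetter(as.character(entries$residue)))
  new("AlleleProteinMap", entries = df)
}

#' @rdname AlleleProteinMap-class
#' @exportClass AlleleProteinMap
setClass("AlleleProteinMap", representation(entries = "DataFrame"))

setValidity("AlleleProteinMap", function(object) {
  e <- object@entries
  key <- paste(e$allele, e$position)
  dup <- duplicated(key)
  if (any(dup)) {
    agree <- vapply(unique(key[dup]), function(k) {
      length(unique(e$residue[key == k])) == 1L
    }, logical(1))
    if (!all(agree))
      return(paste("conflicting residue entries for:",
                   paste(unique(key[dup])[!agree], collapse = ", ")))
  }
  TRUE
})

#' @rdname AlleleProteinMap-class
#' @export
setMethod("mapEntries", "AlleleProteinMap", function(x) x@entries)

#' @rdname AlleleProteinMap-class
#' @export
setMethod("mappedPositions", "AlleleProteinMap", function(x, locus) {
  pre <- paste0(sub("^HLA-", "", locus), "*")
  sort(unique(x@entries$position[startsWith(x@entries$allele, pre)]))
})

#' @rdname AlleleProteinMap-class
#' @export
setMethod("residueAt", "AlleleProteinMap", function(x, allele, position) {
  e <- x@entries
  hit <- e$allele == allele & e$position == position
  if (!any(hit)) return(NA_character_)
  e$residue[which(hit)[1L]]
})

setMethod("show", "AlleleProteinMap", function(object) {
  e <- object@entries
  cat("AlleleProteinMap:", length(unique(e$allele)), "alleles,",
      length(unique(paste(sub("\\*.*", "", e$allele), e$position))),
      "locus-positions\n")
})

# ---------------------------------------------------------------------------
# LogisticFit
# ---------------------------------------------------------------------------

#' Maximum-likelihood logistic regression fit
#'
#' Result of [fitLogistic()]: coefficient estimates (intercept = sampling
#' fraction, principal-component effects, per-allele log-odds effects),
#' their covariance, the maximized Bernoulli log-likelihood, and diagnostic
#' flags for non-convergence and quasi-complete separation.
#'
#' @slot coefficients named numeric vector of estimates.
#' @slot se named numeric vector of standard errors.
#' @slot vcov estimated covariance matrix of the coefficients.
#' @slot logLik maximized log-likelihood (always <= 0).
#' @slot n number of samples used (after complete-case filtering).
#' @slot converged logical; IRLS convergence flag.
#' @slot separation logical; `TRUE` when some |beta| > 15 without
#'   convergence, the signature of (quasi-)complete separation.
#' @slot dropped ids of design columns dropped for zero variance or exact
#'   collinearity.
#' @exportClass LogisticFit
setClass("LogisticFit", representation(
  coefficients = "numeric", se = "numeric", vcov = "matrix",
  logLik = "numeric", n = "integer", converged = "logical",
  separation = "logical", dropped = "character"))

#' @describeIn LogisticFit-class coefficient estimates
#' @param object,x a `LogisticFit`
#' @param ... ignored
#' @export
setMethod("coef", "LogisticFit", function(object, ...) object@coefficients)

#' @describeIn LogisticFit-class maximized log-likelihood
#' @export
setMethod("logLik", "LogisticFit", function(object, ...) object@logLik)

#' @describeIn LogisticFit-class number of samples in the fit
#' @export
setMethod("nobs", "LogisticFit", function(object, ...) object@n)

#' @describeIn LogisticFit-class coefficient covariance matrix
#' @export
setMethod("vcov", "LogisticFit", function(object, ...) object@vcov)

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit:", length(object@coefficients), "coefficients, n =",
      object@n, "\n  logLik =", format(object@logLik),
      if (!object@converged) " [not converged]" else "",
      if (object@separation) " [separation]" else "", "\n")
})

# ---------------------------------------------------------------------------
# ConditionalLedger
# ---------------------------------------------------------------------------

#' Record of a stepwise conditional association scan
#'
#' One row per round: the winning marker, its conditional odds ratio with
#' Wald 95% CI, likelihood-ratio chi-squared, degrees of freedom, log10
#' P-value and the conditioning set in force when it was tested. The
#' conditioning set of round r is exactly the winners of rounds 1..r-1.
#'
#' @slot rounds `DataFrame` with columns `round`, `marker`, `or`, `ciLow`,
#'   `ciHigh`, `beta`, `se`, `chisq`, `df`, `log10P`, `conditioning`.
#' @slot stopReason `"no-significant"` or `"max-rounds"`.
#' @slot thresholdLog10P entry threshold on the log10 P scale.
#' @param x a `ConditionalLedger`.
#' @aliases rounds stopReason
#' @exportClass ConditionalLedger
setClass("ConditionalLedger", representation(
  rounds = "DataFrame", stopReason = "character",
  thresholdLog10P = "numeric"))

setValidity("ConditionalLedger", function(object) {
  msg <- character(0)
  if (!(object@stopReason %in% c("no-significant", "max-rounds")))
    msg <- c(msg, "stopReason must be 'no-significant' or 'max-rounds'")
  r <- object@rounds
  if (nrow(r) > 0) {
    if (any(r$log10P >= object@thresholdLog10P))
      msg <- c(msg, "recorded rounds must all be below the entry threshold")
    for (i in seq_len(nrow(r))) {
      expected <- paste(r$marker[seq_len(i - 1L)], collapse = ",")
      if (!identical(r$conditioning[i], expected))
        msg <- c(msg, sprintf("round %d conditioning set mismatch", i))
    }
  }
  if (length(msg) > 0) msg else TRUE
})

#' @rdname ConditionalLedger-class
#' @export
setMethod("rounds", "ConditionalLedger", function(x) x@rounds)

#' @rdname ConditionalLedger-class
#' @export
setMethod("stopReason", "ConditionalLedger", function(x) x@stopReason)

setMethod("show", "ConditionalLedger", function(object) {
  cat("ConditionalLedger:", nrow(object@rounds), "round(s), stop:",
      object@stopReason, sprintf("(threshold log10P < %.3g)\n",
                                 object@thresholdLog10P))
  if (nrow(object@rounds) > 0) {
    df <- as.data.frame(object@rounds[, c("round", "marker", "or", "ciLow",
                                          "ciHigh", "log10P")])
    df$or <- signif(df$or, 4); df$ciLow <- signif(df$ciLow, 4)
    df$ciHigh <- signif(df$ciHigh, 4); df$log10P <- signif(df$log10P, 4)
    print(df, row.names = FALSE)
  }
})

# ---------------------------------------------------------------------------
# QCReport
# ---------------------------------------------------------------------------

#' Post-imputation quality-control report
#'
#' Records what a QC filter removed: samples whose cumulative four-digit
#' classical dosage exceeded the cutoff at some HLA locus, and markers whose
#' imputation quality r2 fell below the cutoff.
#'
#' @slot removedSamples `DataFrame` with `sample_id`, `locus`,
#'   `cumulativeDosage`.
#' @slot removedMarkers `DataFrame` with `marker`, `imputationR2`.
#' @slot description one-line summary of the filter applied.
#' @param x a `QCReport`.
#' @aliases removedSamples removedMarkers
#' @exportClass QCReport
setClass("QCReport", representation(
  removedSamples = "DataFrame", removedMarkers = "DataFrame",
  description = "character"))

#' @rdname QCReport-class
#' @export
setMethod("removedSamples", "QCReport", function(x) x@removedSamples)

#' @rdname QCReport-class
#' @export
setMethod("removedMarkers", "QCReport", function(x) x@removedMarkers)

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@description, "\n  removed",
      nrow(object@removedSamples), "sample(s),",
      nrow(object@removedMarkers), "marker(s)\n")
})

# ---------------------------------------------------------------------------
# SimTruth
# ---------------------------------------------------------------------------

#' Ground truth of a simulated case-control cohort
#'
#' Everything the generator knows that an analyst would not: the latent
#' haplotype alleles per sample, the injected log odds-ratio for every
#' marker, the stratum-specific interaction-SNP log odds-ratios, the
#' interaction-stratum label and subpopulation of each sample.
#'
#' @slot coefficients named numeric; injected per-dosage log odds ratios.
#' @slot interactionLogOR named numeric; injected interaction-SNP log
#'   odds-ratio per stratum.
#' @slot strata character; interaction stratum label per sample.
#' @slot subpopulation integer subpopulation index per sample.
#' @slot haplotypes list (per HLA locus) of samples x 2 character matrices
#'   of classical allele names.
#' @slot config the `SimConfig` the cohort was generated from.
#' @exportClass SimTruth
setClass("SimTruth", representation(
  coefficients = "numeric", interactionLogOR = "numeric",
  strata = "character", subpopulation = "integer",
  haplotypes = "list", config = "list"))

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@strata), "samples,",
      sum(object@coefficients != 0), "non-null injected effects\n")
})
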