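# Post-imputation dosage QC: sample-level cumulative-dosage filter,
# marker-level imputation-quality filter, and imputation accuracy metrics.

#' Remove samples with excess cumulative classical dosage
#'
#' Imputed four-digit classical allele dosages at one locus should sum to
#' about 2 per diploid sample; a clearly larger sum indicates a poorly
#' imputed sample. A sample is removed when its cumulative four-digit
#' dosage is strictly above `maxCumulative` at any one HLA locus.
#'
#' @param x an [HlaDosageSet-class] with four-digit classical markers.
#' @param maxCumulative removal cutoff (default 2.5; a sum of exactly 2.5 is
#'   retained, the rule being strictly "above").
#' @return a list with `dosages` (the filtered [HlaDosageSet-class], all
#'   markers, offending samples dropped) and `report` (a
#'   [QCReport-class] listing each removed sample with the offending locus
#'   and its cumulative dosage).
#' @export
filterSamplesByCumulativeDosage <- function(x, maxCumulative = 2.5) {
  stopifnot(is(x, "HlaDosageSet"))
  info <- SummarizedExperiment::rowData(x)
  four <- .isFourDigit(x)
  if (!any(four)) stop("no four-digit classical allele markers present")
  d <- dosages(x)
  loci <- unique(info$locus[four])
  bad <- list()
  for (locus in loci) {
    sel <- four & info$locus == locus
    cum <- colSums(d[sel, , drop = FALSE], na.rm = TRUE)
    off <- which(cum > maxCumulative)
    if (length(off) > 0L)
      bad[[locus]] <- S4Vectors::DataFrame(
        sample_id = colnames(x)[off], locus = locus,
        cumulativeDosage = unname(cum[off]))
  }
  removed <- if (length(bad) > 0L) do.call(rbind, bad) else
    S4Vectors::DataFrame(sample_id = character(0), locus = character(0),
                         cumulativeDosage = numeric(0))
  keep <- setdiff(colnames(x), removed$sample_id)
  report <- new("QCReport", removedSamples = removed,
                removedMarkers = S4Vectors::DataFrame(
                  marker = character(0), imputationR2 = numeric(0)),
                description = sprintf(
                  "cumulative four-digit dosage > %.3g at any HLA locus",
                  maxCumulative))
  list(dosages = x[, keep], report = report)
}

#' Remove markers with poor imputation quality
#'
#' Markers are excluded when their imputation r2 quality score is strictly
#' below `minR2`. Markers without a score (genotyped, or score not
#' recorded) are retained: the rule applies to imputation quality scores.
#'
#' @param x an [HlaDosageSet-class].
#' @param minR2 exclusion cutoff (default 0.2; a score of exactly 0.2 is
#'   retained).
#' @return a list with `dosages` (filtered set) and `report`
#'   (a [QCReport-class]).
#' @export
filterMarkersByImputationR2 <- function(x, minR2 = 0.2) {
  stopifnot(is(x, "HlaDosageSet"))
  r2 <- SummarizedExperiment::rowData(x)$imputationR2
  drop <- !is.na(r2) & r2 < minR2
  report <- new("QCReport",
                removedSamples = S4Vectors::DataFrame(
                  sample_id = character(0), locus = character(0),
                  cumulativeDosage = numeric(0)),
                removedMarkers = S4Vectors::DataFrame(
                  marker = rownames(x)[drop], imputationR2 = r2[drop]),
                description = sprintf("imputation r2 < %.3g", minR2))
  list(dosages = x[!drop, ], report = report)
}

#' Per-allele sensitivity and specificity of imputed classical calls
#'
#' Compares best-guess imputed allele copy counts against known truth,
#' counting at the copy level: for allele a, sensitivity is the fraction of
#' true copies that were called (sum over samples of min(true, called)
#' divided by the total true copies) and specificity the fraction of truly
#' absent copies (out of 2 per sample) that were correctly not called.
#' Median sensitivity is taken over alleles with at least one true copy;
#' median specificity over all alleles with at least one truly absent copy.
#'
#' @param truth,imputed integer matrices (samples x alleles) of per-sample
#'   allele copy counts over the same allele set, with sample rownames.
#' @return a list with `table` (per-allele `data.frame`: `allele`,
#'   `trueCopies`, `calledCopies`, `sensitivity`, `specificity`),
#'   `medianSensitivity` and `medianSpecificity`.
#' @export
imputationAccuracy <- function(truth, imputed) {
  truth <- as.matrix(truth); imputed <- as.matrix(imputed)
  if (is.null(rownames(truth)) || is.null(rownames(imputed)))
    stop("truth and imputed must have sample rownames")
  common <- intersect(rownames(truth), rownames(imputed))
  if (length(common) == 0L)
    stop("truth and imputed share no samples")
  alleles <- colnames(truth)
  if (!setequal(alleles, colnames(imputed)))
    stop("truth and imputed must cover the same allele set")
  t <- truth[common, alleles, drop = FALSE]
  c_ <- imputed[common, alleles, drop = FALSE]
  sens <- spec <- numeric(length(alleles))
  for (j in seq_along(alleles)) {
    trueCopies <- sum(t[, j])
    absentCopies <- sum(2 - t[, j])
    sens[j] <- if (trueCopies > 0) sum(pmin(t[, j], c_[, j])) / trueCopies
               else NA_real_
    spec[j] <- if (absentCopies > 0)
      sum(pmin(2 - t[, j], 2 - c_[, j])) / absentCopies else NA_real_
  }
  tab <- data.frame(allele = alleles,
                    trueCopies = colSums(t), calledCopies = colSums(c_),
                    sensitivity = sens, specificity = spec,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       medianSensitivity = stats::median(sens, na.rm = TRUE),
       medianSpecificity = stats::median(spec, na.rm = TRUE))
}
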