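# Readers and writers for the on-disk formats: dosage TSV (SNP2HLA-style),
# phenotype TSV, covariate TSV, allele-protein map TSV, results TSV.

#' Read a SNP2HLA-style dosage file
#'
#' The dosage dialect is tab-separated with header
#' `marker alleleA alleleB <sample ids...>`; each body row holds one marker
#' and per-sample expected counts of alleleA in \[0, 2\] (`NA` for missing).
#' Marker kinds are inferred from the id prefix (`AA_` amino-acid residue,
#' `HLA_` classical allele, otherwise SNP) unless overridden by a marker-info
#' sidecar table with columns `marker`, `kind`, `locus`, `position`,
#' `alleleLabel`, `imputationR2`.
#'
#' @param path path to the dosage TSV.
#' @param markerInfo optional sidecar: a path to a TSV or a `data.frame`.
#' @return an [HlaDosageSet-class].
#' @seealso [writeDosageFile()]
#' @export
readDosageFile <- function(path, markerInfo = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty dosage file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L || header[1L] != "marker")
    stop("malformed dosage header; expected 'marker alleleA alleleB <samples>'")
  samples <- header[-(1:3)]
  if (anyDuplicated(samples)) stop("duplicate sample ids in dosage header")
  n <- length(samples)
  body <- lines[-1L]
  ids <- character(length(body))
  alleleA <- character(length(body)); alleleB <- character(length(body))
  mat <- matrix(NA_real_, nrow = length(body), ncol = n)
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n + 3L)
      stop(sprintf("parse error at line %d: expected %d fields, found %d",
                   i + 1L, n + 3L, length(f)))
    ids[i] <- f[1L]; alleleA[i] <- f[2L]; alleleB[i] <- f[3L]
    v <- suppressWarnings(as.numeric(f[-(1:3)]))
    bad <- is.na(v) & f[-(1:3)] != "NA"
    if (any(bad))
      stop(sprintf("parse error at line %d: non-numeric dosage '%s'",
                   i + 1L, f[-(1:3)][bad][1L]))
    out <- !is.na(v) & (v < 0 | v > 2)
    if (any(out))
      stop(sprintf("dosage outside [0,2] at line %d (marker %s): %s",
                   i + 1L, ids[i], format(v[out][1L])))
    mat[i, ] <- v
  }
  if (anyDuplicated(ids))
    stop("duplicate marker id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dimnames(mat) <- list(ids, samples)
  if (is.character(markerInfo)) {
    markerInfo <- utils::read.table(markerInfo, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  }
  x <- HlaDosageSet(mat, markerInfo = markerInfo)
  info <- SummarizedExperiment::rowData(x)
  info$alleleA <- alleleA
  info$alleleB <- alleleB
  SummarizedExperiment::rowData(x) <- info
  x
}

#' Write a dosage file
#'
#' Inverse of [readDosageFile()]: a file written here and read back yields
#' the same object, and re-writing the result reproduces the file
#' byte-identically.
#'
#' @param x an [HlaDosageSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDosageFile <- function(x, path) {
  stopifnot(is(x, "HlaDosageSet"))
  info <- SummarizedExperiment::rowData(x)
  aA <- if (!is.null(info$alleleA)) info$alleleA else rep("P", nrow(x))
  aB <- if (!is.null(info$alleleB)) info$alleleB else rep("A", nrow(x))
  d <- dosages(x)
  lines <- c(paste(c("marker", "alleleA", "alleleB", colnames(x)),
                   collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i) {
               v <- d[i, ]
               s <- ifelse(is.na(v), "NA", as.character(v))
               paste(c(rownames(x)[i], aA[i], aB[i], s), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read phenotype, covariate and allele-protein map tables
#'
#' All three are tab-separated with a header row. Phenotypes: columns
#' `sample_id`, `status` with status 0 (control) or 1 (case). Covariates:
#' `sample_id` plus numeric columns (by default 10 genotype principal
#' components). Allele-protein map: `allele`, `position`, `residue`
#' (one- or three-letter codes; e.g. `B*27:05  97  Asn`).
#'
#' @param path path to the TSV.
#' @return `readPhenotypes()` and `readCovariates()` return `data.frame`s;
#'   `readAlleleProteinMap()` an [AlleleProteinMap-class].
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% colnames(df)))
    stop("phenotype file must have columns 'sample_id' and 'status'")
  df$sample_id <- as.character(df$sample_id)
  .checkPhenotypeTable(df)
  df
}

#' @rdname readPhenotypes
#' @export
readCovariates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  .checkCovariateMatrix(df)
  df
}

#' @rdname readPhenotypes
#' @export
readAlleleProteinMap <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("allele", "position", "residue") %in% colnames(df)))
    stop("allele-protein map must have columns 'allele', 'position', 'residue'")
  AlleleProteinMap(df)
}

#' @rdname readPhenotypes
#' @param pheno a phenotype `data.frame`.
#' @param covar a covariate `data.frame`.
#' @param map an [AlleleProteinMap-class].
#' @export
writePhenotypes <- function(pheno, path) {
  .checkPhenotypeTable(pheno)
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readPhenotypes
#' @export
writeCovariates <- function(covar, path) {
  .checkCovariateMatrix(covar)
  utils::write.table(covar, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readPhenotypes
#' @export
writeAlleleProteinMap <- function(map, path) {
  stopifnot(is(map, "AlleleProteinMap"))
  e <- as.data.frame(mapEntries(map))
  e$residue <- aaThreeLetter(e$residue)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association results or a conditional ledger to TSV
#'
#' Emits one row per test with marker id, odds ratio, 95% CI bounds,
#' chi-squared, degrees of freedom, P-value on the log10 scale (so values
#' far below the double underflow limit, such as 1e-3221, survive) and the
#' conditioning set.
#'
#' @param results a `DataFrame`/`data.frame` of association results, or a
#'   [ConditionalLedger-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
  if (is(results, "ConditionalLedger")) results <- rounds(results)
  df <- as.data.frame(results)
  keep <- intersect(c("round", "id", "marker", "stratum", "reference", "or",
                      "ciLow", "ciHigh", "beta", "se", "chisq", "df",
                      "log10P", "p", "nCases", "nControls", "n", "testable",
                      "conditioning"), colnames(df))
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
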