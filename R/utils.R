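# Shared helpers: amino-acid code tables, marker id conventions, alignment.

.AA_ONE_TO_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
  Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
  L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
  S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val"
)
.AA_THREE_TO_ONE <- stats::setNames(names(.AA_ONE_TO_THREE), .AA_ONE_TO_THREE)

#' Convert amino-acid residue codes
#'
#' Residues are stored internally as one-letter codes; marker labels use
#' three-letter codes (e.g. `Asn`).
#'
#' @param residue character vector of one- or three-letter residue codes.
#' @return `aaOneLetter` returns one-letter codes, `aaThreeLetter`
#'   three-letter codes.
#' @examples
#' aaOneLetter("Asn")
#' aaThreeLetter("N")
#' @export
aaOneLetter <- function(residue) {
  out <- ifelse(nchar(residue) == 1L,
                toupper(residue),
                unname(.AA_THREE_TO_ONE[paste0(
                  toupper(substr(residue, 1, 1)),
                  tolower(substr(residue, 2, 3)))]))
  bad <- is.na(out) | !(out %in% names(.AA_ONE_TO_THREE))
  if (any(bad))
    stop("unknown amino-acid residue code(s): ",
         paste(unique(residue[bad]), collapse = ", "))
  out
}

#' @rdname aaOneLetter
#' @export
aaThreeLetter <- function(residue) {
  unname(.AA_ONE_TO_THREE[aaOneLetter(residue)])
}

#' Convert between classical allele names and marker identifiers
#'
#' Marker identifiers follow the SNP2HLA convention: the classical allele
#' `B*27:05` corresponds to marker id `HLA_B_2705`, the two-digit family
#' `B*27` to `HLA_B_27`.
#'
#' @param allele classical allele names such as `"B*27:05"` or `"DPB1*04:01"`.
#' @param id marker identifiers such as `"HLA_B_2705"`.
#' @return character vector of identifiers (or allele names).
#' @examples
#' alleleToMarkerId("B*27:05")
#' markerIdToAllele("HLA_B_2705")
#' @export
alleleToMarkerId <- function(allele) {
  parts <- strsplit(allele, "*", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L)
      stop("malformed classical allele name: ", paste(p, collapse = "*"))
    paste0("HLA_", p[1L], "_", gsub(":", "", p[2L], fixed = TRUE))
  }, character(1))
}

#' @rdname alleleToMarkerId
#' @export
markerIdToAllele <- function(id) {
  vapply(id, function(x) {
    p <- strsplit(x, "_", fixed = TRUE)[[1L]]
    if (length(p) < 3L || p[1L] != "HLA")
      stop("not a classical allele marker id: ", x)
    code <- p[length(p)]
    locus <- paste(p[-c(1L, length(p))], collapse = "_")
    if (nchar(code) >= 4L)
      code <- paste0(substr(code, 1, 2), ":", substr(code, 3, nchar(code)))
    paste0(locus, "*", code)
  }, character(1), USE.NAMES = FALSE)
}

# Marker kind from the id prefix (SNP2HLA naming convention).
.inferMarkerKind <- function(id) {
  ifelse(startsWith(id, "AA_"), "aa_residue",
         ifelse(startsWith(id, "HLA_"), "classical_allele", "snp"))
}

# Locus string ("HLA-B") from a classical or amino-acid marker id; NA for SNPs.
.inferMarkerLocus <- function(id) {
  vapply(id, function(x) {
    p <- strsplit(x, "_", fixed = TRUE)[[1L]]
    if (p[1L] == "HLA" && length(p) >= 3L)
      paste0("HLA-", paste(p[2:(length(p) - 1L)], collapse = "_"))
    else if (p[1L] == "AA" && length(p) >= 4L)
      paste0("HLA-", p[2L])
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

.inferMarkerPosition <- function(id) {
  vapply(id, function(x) {
    p <- strsplit(x, "_", fixed = TRUE)[[1L]]
    if (p[1L] == "AA" && length(p) >= 4L) as.integer(p[3L]) else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

.inferAlleleLabel <- function(id) {
  kind <- .inferMarkerKind(id)
  out <- rep(NA_character_, length(id))
  cl <- kind == "classical_allele"
  if (any(cl)) {
    lab <- vapply(id[cl], function(x) {
      tryCatch(markerIdToAllele(x), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    out[cl] <- sub("^[^*]+\\*", "", lab)
  }
  aa <- kind == "aa_residue"
  if (any(aa)) {
    out[aa] <- vapply(id[aa], function(x) {
      p <- strsplit(x, "_", fixed = TRUE)[[1L]]
      if (length(p) >= 4L) paste0(p[3L], ":", p[4L]) else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

# Four-digit classical allele markers (those whose code has protein-level
# resolution, i.e. the allele label contains a colon).
.isFourDigit <- function(x) {
  info <- SummarizedExperiment::rowData(x)
  info$kind == "classical_allele" & grepl(":", info$alleleLabel %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Align dosages, phenotypes and optional covariates on sample ids.
# The phenotype table's sample order is canonical; every phenotype sample
# must be present in the dosage matrix (and covariates), or this fails
# listing the offending ids. Never reorders silently.
.alignCohort <- function(x, pheno, covar = NULL) {
  stopifnot(is(x, "HlaDosageSet"))
  .checkPhenotypeTable(pheno)
  ids <- pheno$sample_id
  missing <- setdiff(ids, colnames(x))
  if (length(missing) > 0L)
    stop("samples present in phenotypes but absent from dosages: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  C <- NULL
  if (!is.null(covar)) {
    .checkCovariateMatrix(covar)
    missc <- setdiff(ids, covar$sample_id)
    if (length(missc) > 0L)
      stop("samples present in phenotypes but absent from covariates: ",
           paste(utils::head(missc, 10L), collapse = ", "),
           if (length(missc) > 10L) ", ...")
    C <- as.matrix(covar[match(ids, covar$sample_id),
                         setdiff(colnames(covar), "sample_id"), drop = FALSE])
    rownames(C) <- ids
    storage.mode(C) <- "double"
  }
  list(ids = ids,
       y = as.integer(pheno$status),
       covar = C,
       dosage = function(markers) {
         missing <- setdiff(markers, rownames(x))
         if (length(missing) > 0L)
           stop("marker(s) not found in dosage matrix: ",
                paste(missing, collapse = ", "))
         t(dosages(x)[markers, ids, drop = FALSE])
       })
}

.checkPhenotypeTable <- function(pheno) {
  if (!is.data.frame(pheno) ||
      !all(c("sample_id", "status") %in% colnames(pheno)))
    stop("phenotype table must have columns 'sample_id' and 'status'")
  if (anyDuplicated(pheno$sample_id))
    stop("duplicate sample ids in phenotype table")
  if (!all(pheno$status %in% c(0L, 1L)))
    stop("phenotype status must be 0 (control) or 1 (case); offending ",
         "values: ", paste(unique(setdiff(pheno$status, 0:1)), collapse = ", "))
  invisible(TRUE)
}

.checkCovariateMatrix <- function(covar) {
  if (!is.data.frame(covar) || !("sample_id" %in% colnames(covar)))
    stop("covariate table must have a 'sample_id' column")
  vals <- covar[, setdiff(colnames(covar), "sample_id"), drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1))) ||
      !all(is.finite(as.matrix(vals))))
    stop("covariate values must be finite numerics")
  invisible(TRUE)
}
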