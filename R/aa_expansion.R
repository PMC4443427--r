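# Expansion of classical-allele dosages into amino-acid residue dosages and
# binary allele-presence (two-digit family) markers.

#' Expand classical HLA allele dosages into amino-acid residue dosages
#'
#' Classical alleles determine the amino-acid sequence of the HLA protein,
#' so the expected count of residue r at protein position p in a sample is
#' the sum of that sample's dosages over all classical alleles carrying r at
#' p. For every locus with four-digit classical markers in `x` and every
#' position mapped for that locus, one `aa_residue` marker is emitted per
#' residue observed among the cohort's alleles (id `AA_<locus>_<pos>_<Res>`,
#' three-letter residue labels). Positions where all alleles share one
#' residue are kept but flagged `monomorphic` in `rowData` so that position
#' inventories still match the map.
#'
#' Conservation holds by construction: per sample and position, the residue
#' dosages sum to the total classical dosage at the locus.
#'
#' @param x an [HlaDosageSet-class] containing four-digit classical allele
#'   markers (others are ignored).
#' @param map an [AlleleProteinMap-class]; every four-digit classical allele
#'   in `x` at a mapped locus must appear with a residue at each mapped
#'   position, or the expansion errors naming the allele.
#' @return an [HlaDosageSet-class] of amino-acid residue markers.
#' @examples
#' d <- matrix(c(2, 1, 0, 1), 2, dimnames = list(
#'   c("HLA_B_2705", "HLA_B_0702"), c("s1", "s2")))
#' m <- AlleleProteinMap(data.frame(allele = c("B*27:05", "B*07:02"),
#'                                  position = 97, residue = c("Asn", "Ser")))
#' dosages(expandAminoAcids(HlaDosageSet(d), m))
#' @export
expandAminoAcids <- function(x, map) {
  stopifnot(is(x, "HlaDosageSet"), is(map, "AlleleProteinMap"))
  info <- SummarizedExperiment::rowData(x)
  four <- .isFourDigit(x)
  if (!any(four)) stop("no four-digit classical allele markers to expand")
  loci <- unique(info$locus[four])
  entries <- mapEntries(map)
  rows <- list(); meta <- list()
  d <- dosages(x)
  for (locus in loci) {
    positions <- mappedPositions(map, locus)
    if (length(positions) == 0L) next
    sel <- which(four & info$locus == locus)
    alleles <- markerIdToAllele(rownames(x)[sel])
    short <- sub("^HLA-", "", locus)
    for (pos in positions) {
      res <- vapply(alleles, function(a) residueAt(map, a, pos), character(1))
      if (anyNA(res))
        stop("allele(s) absent from the allele-protein map at ", locus,
             " position ", pos, ": ",
             paste(alleles[is.na(res)], collapse = ", "))
      ures <- sort(unique(res))
      mono <- length(ures) == 1L
      for (r in ures) {
        id <- sprintf("AA_%s_%d_%s", short, pos, aaThreeLetter(r))
        rows[[id]] <- colSums(d[sel[res == r], , drop = FALSE])
        meta[[id]] <- data.frame(
          marker = id, kind = "aa_residue", locus = locus,
          position = as.integer(pos),
          alleleLabel = paste0(pos, ":", aaThreeLetter(r)),
          imputationR2 = NA_real_, monomorphic = mono,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    stop("allele-protein map covers no locus present in the dosage matrix")
  mat <- do.call(rbind, rows)
  colnames(mat) <- colnames(x)
  HlaDosageSet(mat, markerInfo = do.call(rbind, meta))
}

#' Encode binary allele-presence markers at two-digit resolution
#'
#' For association testing, each classical allele is coded by a marker for
#' the presence of that allele. Four-digit markers pass through unchanged;
#' in addition one two-digit family marker per allele family (e.g.
#' `HLA_B_27`) is emitted whose dosage is the sum of the family's four-digit
#' dosages capped at 2, since a diplotype cannot carry more than two copies.
#'
#' @param x an [HlaDosageSet-class] with four-digit classical allele markers.
#' @return an [HlaDosageSet-class] with the four-digit markers followed by
#'   the two-digit family markers.
#' @export
encodePresenceMarkers <- function(x) {
  stopifnot(is(x, "HlaDosageSet"))
  info <- SummarizedExperiment::rowData(x)
  four <- .isFourDigit(x)
  if (!any(four)) stop("no four-digit classical allele markers present")
  d4 <- dosages(x)[four, , drop = FALSE]
  fam <- vapply(strsplit(rownames(d4), "_", fixed = TRUE), function(p) {
    code <- p[length(p)]
    paste(c(p[-length(p)], substr(code, 1, 2)), collapse = "_")
  }, character(1))
  famIds <- unique(fam)
  fmat <- matrix(0, length(famIds), ncol(x),
                 dimnames = list(famIds, colnames(x)))
  for (f in famIds)
    fmat[f, ] <- pmin(colSums(d4[fam == f, , drop = FALSE]), 2)
  mat <- rbind(d4, fmat)
  minfo <- data.frame(
    marker = rownames(mat),
    kind = "classical_allele",
    locus = c(info$locus[four], .inferMarkerLocus(famIds)),
    position = c(info$position[four], rep(NA_integer_, length(famIds))),
    alleleLabel = .inferAlleleLabel(rownames(mat)),
    imputationR2 = c(info$imputationR2[four], rep(NA_real_, length(famIds))),
    stringsAsFactors = FALSE)
  HlaDosageSet(mat, markerInfo = minfo)
}
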