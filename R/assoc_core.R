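# Maximum-likelihood logistic association machinery: single-marker and
# omnibus multi-allelic likelihood-ratio tests, principal-component
# covariates, pairwise LD.

#' Fit a logistic disease model by maximum likelihood
#'
#' Fits `logit P(y=1) = theta + X beta` by iteratively reweighted least
#' squares (convergence when the relative log-likelihood change falls below
#' 1e-8, at most 100 iterations). The intercept `theta` absorbs the
#' case-control sampling fraction; under case-control ascertainment the
#' remaining coefficients remain consistent for the population log
#' odds-ratios. Zero-variance and exactly collinear columns are dropped
#' with a warning; quasi-complete separation (some |beta| > 15 without
#' convergence) is flagged, not penalized, matching the plain-MLE treatment
#' of very large HLA effects.
#'
#' @param y binary phenotype: a 0/1 vector or a phenotype `data.frame` with
#'   a `status` column. Must contain at least one case and one control.
#' @param X design matrix (samples x terms) of covariates and dosage terms,
#'   or `NULL` for an intercept-only model. An intercept column is added
#'   automatically.
#' @return a [LogisticFit-class].
#' @examples
#' y <- rep(c(1, 1, 0, 0), c(40, 10, 25, 25))
#' g <- rep(c(1, 0, 1, 0), c(40, 10, 25, 25))
#' exp(coef(fitLogistic(y, cbind(g = g)))["g"])  # 2x2 odds ratio = 4
#' @export
fitLogistic <- function(y, X = NULL) {
  if (is.data.frame(y)) y <- y$status
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop("phenotype must be 0/1 with no missing values")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one case and one control")
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (nrow(X) != n) stop("design matrix rows must match phenotype length")
    if (anyNA(X)) stop("design matrix contains missing values; apply ",
                       "complete-case filtering first")
    X <- cbind(`(Intercept)` = 1, X)
  }
  dropped <- character(0)
  zv <- apply(X, 2, function(v) diff(range(v)) == 0)
  zv["(Intercept)"] <- FALSE
  if (any(zv)) {
    dropped <- colnames(X)[zv]
    warning("zero-variance column(s) dropped: ", paste(dropped, collapse = ", "))
    X <- X[, !zv, drop = FALSE]
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    keep <- q$pivot[seq_len(q$rank)]
    coll <- colnames(X)[-keep]
    warning("collinear column(s) dropped: ", paste(coll, collapse = ", "))
    dropped <- c(dropped, coll)
    X <- X[, sort(keep), drop = FALSE]
  }
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = list(epsilon = 1e-8, maxit = 100,
                                       trace = FALSE))
  beta <- fit$coefficients
  ll <- -fit$deviance / 2
  p1 <- seq_len(fit$rank)
  covPiv <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  piv <- fit$qr$pivot[p1]
  vc <- matrix(NA_real_, ncol(X), ncol(X),
               dimnames = list(colnames(X), colnames(X)))
  vc[piv, piv] <- covPiv
  new("LogisticFit",
      coefficients = beta,
      se = sqrt(diag(vc)),
      vcov = vc,
      logLik = ll,
      n = as.integer(n),
      converged = isTRUE(fit$converged),
      separation = !isTRUE(fit$converged) && any(abs(beta) > 15),
      dropped = dropped)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' The test statistic 2(l1 - l0) is chi-squared with degrees of freedom
#' equal to the difference in coefficient count. P-values are carried on
#' the log10 scale so that statistics like chi-squared = 14,857 on 5 df
#' yield a finite log10 bound (about -3226) instead of underflowing to 0.
#'
#' @param null,alt [LogisticFit-class] objects on the same samples, with
#'   `null` nested in `alt`.
#' @return a list with `chisq`, `df`, `log10P` and `p` (`p` underflows to 0
#'   for extreme statistics; `log10P` is authoritative).
#' @export
lrt <- function(null, alt) {
  stopifnot(is(null, "LogisticFit"), is(alt, "LogisticFit"))
  if (nobs(null) != nobs(alt))
    stop("models fit on different samples are not nested (n = ",
         nobs(null), " vs ", nobs(alt), ")")
  df <- length(coef(alt)) - length(coef(null))
  if (df < 0)
    stop("alternative model has fewer coefficients than the null")
  delta <- 2 * (logLik(alt) - logLik(null))
  if (delta < -1e-6)
    warning("alternative log-likelihood below null by ", format(-delta / 2),
            "; nested-model ordering violated (non-convergence?)")
  chisq <- max(0, delta)
  if (df == 0L) {
    log10P <- 0
  } else {
    log10P <- stats::pchisq(chisq, df, lower.tail = FALSE,
                            log.p = TRUE) / log(10)
  }
  list(chisq = chisq, df = df, log10P = log10P, p = 10^log10P)
}

# Shared engine: LRT of adding `term` columns to intercept + covar + cond.
# All inputs are sample-aligned matrices/vectors; complete-case rows only.
.conditionalLRT <- function(y, covar, cond, term) {
  used <- cbind(covar, cond, term)
  cc <- stats::complete.cases(used)
  y <- y[cc]
  if (sum(y) == 0 || sum(y) == length(y))
    stop("no cases or no controls after complete-case filtering")
  base <- cbind(covar, cond)[cc, , drop = FALSE]
  term <- term[cc, , drop = FALSE]
  fit0 <- suppressWarnings(fitLogistic(y, if (is.null(base) || ncol(base) == 0)
    NULL else base))
  keptBase <- setdiff(names(coef(fit0)), "(Intercept)")
  Xbase <- if (length(keptBase)) base[, keptBase, drop = FALSE] else NULL
  rank0 <- length(coef(fit0))
  rankFull <- qr(cbind(1, Xbase, term))$rank
  if (rankFull <= rank0)
    return(list(testable = FALSE, fit0 = fit0, fit1 = NULL,
                chisq = NA_real_, df = NA_integer_,
                log10P = NA_real_, p = NA_real_, n = length(y)))
  fit1 <- suppressWarnings(fitLogistic(y, cbind(Xbase, term)))
  lr <- lrt(fit0, fit1)
  c(list(testable = TRUE, fit0 = fit0, fit1 = fit1, n = length(y)), lr)
}

#' Test a single marker for association, optionally conditioned
#'
#' One-degree-of-freedom likelihood-ratio test of adding the marker's
#' dosage to a null model of intercept, covariates (principal components)
#' and any conditioning markers, which enter both the null and alternative
#' models as fixed effects. The odds ratio is `exp(beta)` with a Wald 95%
#' confidence interval.
#'
#' @param x an [HlaDosageSet-class].
#' @param marker marker id to test (one dosage column).
#' @param pheno phenotype `data.frame` (`sample_id`, `status`).
#' @param covar optional covariate `data.frame` (`sample_id` + numeric
#'   columns, typically 10 genotype principal components).
#' @param conditioning character vector of marker ids held as fixed effects.
#' @return a one-row `DataFrame` with `id`, `or`, `ciLow`, `ciHigh`,
#'   `beta`, `se`, `chisq`, `df`, `log10P`, `p`, `n`, `separation`,
#'   `testable` and `conditioning`. A marker collinear with the null design
#'   (for instance conditioned on itself) is returned with
#'   `testable = FALSE` and `NA` statistics.
#' @export
testMarker <- function(x, marker, pheno, covar = NULL,
                       conditioning = character(0)) {
  stopifnot(length(marker) == 1L)
  al <- .alignCohort(x, pheno, covar)
  g <- al$dosage(marker)
  cond <- if (length(conditioning)) al$dosage(conditioning) else NULL
  res <- .conditionalLRT(al$y, al$covar, cond, g)
  condStr <- paste(conditioning, collapse = ",")
  if (!res$testable)
    return(S4Vectors::DataFrame(
      id = marker, or = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
      beta = NA_real_, se = NA_real_, chisq = NA_real_, df = NA_integer_,
      log10P = NA_real_, p = NA_real_, n = res$n, separation = NA,
      testable = FALSE, conditioning = condStr))
  beta <- unname(coef(res$fit1)[marker])
  se <- unname(res$fit1@se[marker])
  zc <- stats::qnorm(0.975)
  S4Vectors::DataFrame(
    id = marker, or = exp(beta), ciLow = exp(beta - zc * se),
    ciHigh = exp(beta + zc * se), beta = beta, se = se,
    chisq = res$chisq, df = res$df, log10P = res$log10P, p = res$p,
    n = res$n, separation = res$fit1@separation, testable = TRUE,
    conditioning = condStr)
}

#' Omnibus multi-allelic likelihood-ratio test at a position
#'
#' Joint test of a multi-allelic position (typically the amino-acid
#' residues observed at one protein position): the alternative model adds
#' m-1 residue dosage columns, the most common residue serving as the
#' reference, and the likelihood-ratio statistic is chi-squared with m-1
#' degrees of freedom. Residues with no carriers among analysed samples are
#' excluded from m with a warning; a monomorphic position (m = 1) is
#' returned untestable.
#'
#' @param x an [HlaDosageSet-class].
#' @param pheno,covar,conditioning as in [testMarker()].
#' @param markers character vector of the position's residue (or allele)
#'   marker ids; alternatively give `locus` and `position` to select all
#'   `aa_residue` markers at that protein position.
#' @param locus,position locus name (e.g. `"HLA-B"`) and protein position,
#'   used when `markers` is `NULL`.
#' @return a one-row `DataFrame` with `id`, `reference`, `m`, `chisq`,
#'   `df` (= m-1), `log10P`, `p`, `n`, `testable`, `conditioning`, and a
#'   list column `betas` of per-allele effects relative to the reference.
#' @export
omnibusTest <- function(x, pheno, markers = NULL, covar = NULL,
                        conditioning = character(0), locus = NULL,
                        position = NULL) {
  info <- SummarizedExperiment::rowData(x)
  if (is.null(markers)) {
    if (is.null(locus) || is.null(position))
      stop("give either residue marker ids or locus and position")
    markers <- rownames(x)[info$kind == "aa_residue" &
                             info$locus == locus &
                             !is.na(info$position) &
                             info$position == position]
    if (length(markers) == 0L)
      stop("no aa_residue markers at ", locus, " position ", position)
  }
  posId <- if (!is.null(locus)) paste0(locus, ":", position) else
    paste(markers, collapse = "|")
  al <- .alignCohort(x, pheno, covar)
  G <- al$dosage(markers)
  cond <- if (length(conditioning)) al$dosage(conditioning) else NULL
  cc <- stats::complete.cases(cbind(al$covar, cond, G))
  tot <- colSums(G[cc, , drop = FALSE])
  absent <- tot <= 0
  if (any(absent)) {
    warning("residue(s) with no carriers among analysed samples excluded: ",
            paste(markers[absent], collapse = ", "))
    markers <- markers[!absent]
    G <- G[, !absent, drop = FALSE]
    tot <- tot[!absent]
  }
  m <- length(markers)
  condStr <- paste(conditioning, collapse = ",")
  empty <- S4Vectors::DataFrame(
    id = posId, reference = NA_character_, m = m, chisq = NA_real_,
    df = NA_integer_, log10P = NA_real_, p = NA_real_, n = sum(cc),
    testable = FALSE, conditioning = condStr)
  empty$betas <- list(numeric(0))
  if (m < 2L) return(empty)
  # reference = most common; frequency ties broken lexicographically
  ref <- markers[order(-tot, markers)][1L]
  tested <- setdiff(markers, ref)
  res <- .conditionalLRT(al$y, al$covar, cond, G[, tested, drop = FALSE])
  if (!res$testable) return(empty)
  betas <- coef(res$fit1)[intersect(tested, names(coef(res$fit1)))]
  out <- S4Vectors::DataFrame(
    id = posId, reference = ref, m = m, chisq = res$chisq,
    df = res$df, log10P = res$log10P, p = res$p, n = res$n,
    testable = TRUE, conditioning = condStr)
  out$betas <- list(betas)
  out
}

#' Principal-component covariates from unlinked genotypes
#'
#' Computes the top k principal components of the samples-by-markers dosage
#' matrix after per-marker mean imputation of missing values and
#' standardization, the standard adjustment for population stratification.
#' Scores are deterministic up to sign; the sign is fixed so that each
#' component's largest-magnitude marker loading is positive.
#'
#' @param x an [HlaDosageSet-class] of (ideally unlinked, non-MHC) SNPs.
#' @param k number of components (default 10). Errors if `k` exceeds the
#'   rank of the standardized matrix (e.g. identical samples).
#' @return a covariate `data.frame`: `sample_id`, `PC1` ... `PCk`.
#' @export
pcaCovariates <- function(x, k = 10) {
  stopifnot(is(x, "HlaDosageSet"))
  G <- t(dosages(x))
  if (nrow(G) < k) stop("fewer samples than requested components")
  for (j in seq_len(ncol(G))) {
    miss <- is.na(G[, j])
    if (any(miss)) G[miss, j] <- mean(G[, j], na.rm = TRUE)
  }
  mu <- colMeans(G)
  sdv <- apply(G, 2, stats::sd)
  keep <- sdv > 0
  G <- sweep(sweep(G[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  if (ncol(G) == 0L) stop("all markers are monomorphic; rank 0 < k")
  ev <- eigen(crossprod(G), symmetric = TRUE)
  tol <- max(dim(G)) * .Machine$double.eps * max(ev$values, 0)
  rank <- sum(ev$values > max(tol, 1e-8))
  if (k > rank)
    stop("k = ", k, " exceeds the rank (", rank, ") of the genotype matrix")
  V <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(V[, j]))
    if (V[i0, j] < 0) V[, j] <- -V[, j]
  }
  scores <- G %*% V
  out <- data.frame(sample_id = colnames(x), scores,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("sample_id", paste0("PC", seq_len(k)))
  rownames(out) <- NULL
  out
}

#' Pairwise linkage disequilibrium as squared correlation
#'
#' Squared Pearson correlation of two dosage vectors over their shared
#' non-missing samples.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r2 in \[0, 1\], or `NA` with a warning when either vector is
#'   constant on the shared samples (r2 undefined).
#' @export
ldR2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  cc <- !is.na(a) & !is.na(b)
  a <- a[cc]; b <- b[cc]
  if (length(a) < 2L || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("r2 undefined for constant dosage vector")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}
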