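test_that("a single binary predictor reproduces the closed-form 2x2 OR", {
  co <- make2x2Cohort(40L, 10L, 25L, 25L)
  fit <- fitLogistic(co$pheno$status,
                     cbind(g = dosages(co$dosages)["rsX", ]))
  expect_equal(unname(coef(fit)["g"]), log(4), tolerance = 1e-6)
  # and through the marker-test interface, OR with Wald CI containing it
  res <- testMarker(co$dosages, "rsX", co$pheno)
  expect_equal(res$or, 4, tolerance = 1e-5)
  expect_true(res$ciLow < 4 && res$ciHigh > 4)
})

test_that("intercept-only balanced fit gives theta 0 and logLik -n log 2", {
  y <- rep(c(1, 0), 25)
  fit <- fitLogistic(y)
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-8)
  expect_equal(logLik(fit), -50 * log(2), tolerance = 1e-8)
  expect_error(fitLogistic(rep(1, 10)), "case and .*control")
})

test_that("collinear and constant design columns are dropped, fit unchanged", {
  co <- make2x2Cohort()
  g <- dosages(co$dosages)["rsX", ]
  X2 <- cbind(g = g, gdup = g, flat = rep(1.5, length(g)))
  expect_warning(expect_warning(fit2 <- fitLogistic(co$pheno$status, X2),
                                "zero-variance"), "collinear")
  fit1 <- fitLogistic(co$pheno$status, cbind(g = g))
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-8)
  expect_setequal(fit2@dropped, c("flat", "gdup"))
})

test_that("likelihood-ratio machinery handles identical, extreme and 1-df cases", {
  co <- make2x2Cohort()
  g <- dosages(co$dosages)["rsX", ]
  fit0 <- fitLogistic(co$pheno$status)
  fit1 <- fitLogistic(co$pheno$status, cbind(g = g))
  self <- lrt(fit1, fit1)
  expect_equal(self$chisq, 0)
  expect_equal(self$p, 1)

  lr <- lrt(fit0, fit1)
  expect_equal(lr$df, 1L)
  expect_gt(lr$chisq, 0)
  # agreement with an independent chi-squared tail evaluation
  expect_equal(lr$log10P,
               pchisq(lr$chisq, 1, lower.tail = FALSE, log.p = TRUE) / log(10))

  # a chi-squared of 14,857 on 5 df must survive as a log10 bound, not 0
  big0 <- new("LogisticFit", coefficients = c(a = 0), se = c(a = 1),
              vcov = diag(1), logLik = -10000, n = 100L, converged = TRUE,
              separation = FALSE, dropped = character(0))
  big1 <- new("LogisticFit",
              coefficients = setNames(rep(0, 6), letters[1:6]),
              se = setNames(rep(1, 6), letters[1:6]), vcov = diag(6),
              logLik = -10000 + 14857 / 2, n = 100L, converged = TRUE,
              separation = FALSE, dropped = character(0))
  lrBig <- lrt(big0, big1)
  expect_equal(lrBig$chisq, 14857)
  # finite log10 bound; its scientific-notation exponent is -3221
  expect_equal(lrBig$log10P, -3220.474, tolerance = 1e-3)
  expect_identical(floor(lrBig$log10P), -3221)

  expect_error(lrt(big0, new("LogisticFit", coefficients = c(a = 0),
                             se = c(a = 1), vcov = diag(1), logLik = -1,
                             n = 99L, converged = TRUE, separation = FALSE,
                             dropped = character(0))), "different samples")
})

test_that("a marker conditioned on itself is flagged not-testable", {
  x <- makeToySet(nSamples = 40L, seed = 9L)
  ph <- data.frame(sample_id = colnames(x),
                   status = rep_len(c(1L, 0L), ncol(x)))
  res <- testMarker(x, "rs100", ph, conditioning = "rs100")
  expect_false(res$testable)
  expect_true(is.na(res$p))
})

test_that("IRLS log-likelihood matches a grid-search oracle on tiny cohorts", {
  set.seed(11)
  for (rep in 1:6) {
    co <- makeTinyCohort(sample(4:8, 1))
    fit <- suppressWarnings(fitLogistic(co$y, cbind(g = co$g)))
    oracle <- gridSearchLogLik(co$y, cbind(1, co$g))
    expect_equal(logLik(fit), oracle$logLik, tolerance = 1e-4)
  }
})

test_that("nested conditioning preserves the likelihood ordering", {
  x <- makeToySet(nSamples = 120L, seed = 21L)
  ph <- data.frame(sample_id = colnames(x),
                   status = rep_len(c(1L, 0L, 0L), ncol(x))[1:ncol(x)])
  al <- hlaFineMap:::.alignCohort(x, ph)
  g1 <- al$dosage("rs100"); g2 <- al$dosage("rs200")
  f0 <- fitLogistic(al$y)
  f1 <- fitLogistic(al$y, g1)
  f12 <- fitLogistic(al$y, cbind(g1, g2))
  expect_gte(logLik(f1), logLik(f0) - 1e-8)
  expect_gte(logLik(f12), logLik(f1) - 1e-8)
})

test_that("omnibus test reduces to the single-marker test when m = 2", {
  mat <- rbind(HLA_B_2705 = c(2, 1, 0, 0, 1, 0, 2, 0),
               HLA_B_0702 = c(0, 1, 2, 2, 1, 2, 0, 2))
  colnames(mat) <- paste0("s", 1:8)
  x <- HlaDosageSet(mat)
  aa <- expandAminoAcids(x, toyMap())
  ph <- data.frame(sample_id = colnames(x),
                   status = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L))
  omni <- omnibusTest(aa, ph, locus = "HLA-B", position = 97L)
  expect_identical(omni$df, 1L)
  # reference is the most common residue (Ser here); the minor residue is
  # the tested column, so the 1-df marker test must agree exactly
  expect_identical(omni$reference, "AA_B_97_Ser")
  single <- testMarker(aa, "AA_B_97_Asn", ph)
  expect_equal(omni$chisq, single$chisq, tolerance = 1e-9)
  expect_equal(omni$log10P, single$log10P, tolerance = 1e-9)
})

test_that("omnibus on residues equals omnibus on 1:1 matching alleles", {
  # residues partition the two alleles one-to-one, so the design matrices
  # span the same space and the LRT must coincide
  set.seed(31)
  n <- 60
  # haplotype-consistent dosages: the two allele counts sum to 2
  g1 <- sample(0:2, n, TRUE, c(.45, .35, .2))
  mat <- rbind(HLA_B_2705 = g1, HLA_B_0702 = 2 - g1)
  colnames(mat) <- paste0("s", seq_len(n))
  x <- HlaDosageSet(mat)
  aa <- expandAminoAcids(x, toyMap())
  ph <- data.frame(sample_id = colnames(x), status = rep_len(c(1L, 0L), n))
  omniRes <- omnibusTest(aa, ph, locus = "HLA-B", position = 97L)
  omniAll <- omnibusTest(x, ph, markers = rownames(x))
  expect_equal(omniRes$chisq, omniAll$chisq, tolerance = 1e-8)
  expect_equal(omniRes$df, omniAll$df)
})

test_that("monomorphic positions and absent residues are handled", {
  mat <- rbind(HLA_B_2705 = c(1, 0, 2, 1), HLA_B_0702 = c(1, 2, 0, 1))
  colnames(mat) <- paste0("s", 1:4)
  aa <- expandAminoAcids(HlaDosageSet(mat), toyMap())
  ph <- data.frame(sample_id = colnames(mat), status = c(1L, 0L, 1L, 0L))
  mono <- omnibusTest(aa, ph, locus = "HLA-B", position = 67L)
  expect_false(mono$testable)   # single residue, m = 1
})

test_that("genotype PCs separate discrete subpopulations and are equivariant", {
  cfg <- simConfig(nCases = 150L, nControls = 150L,
                   loci = list("HLA-B" = list(
                     alleles = c("B*27:05", "B*99:01"), freq = c(.1, .9))),
                   seed = 77L, structure = list(nSnps = 300L, fst = 0.15),
                   theta = 0, nPcs = 5L)
  sim <- simulateCohort(cfg)
  structIds <- grep("^rsBG", rownames(sim$dosages), value = TRUE)
  pcs <- pcaCovariates(sim$dosages[structIds, ], k = 5)
  r <- cor(pcs$PC1, sim$truth@subpopulation)
  expect_gt(abs(r), 0.9)

  # permutation equivariance
  xs <- sim$dosages[structIds, ]
  perm <- rev(seq_len(ncol(xs)))
  pcsPerm <- pcaCovariates(xs[, perm], k = 5)
  expect_equal(pcsPerm$PC1, pcs$PC1[perm], tolerance = 1e-8)

  # degenerate inputs: identical samples have rank 0; k above rank errors
  flat <- matrix(1, 5, 8, dimnames = list(paste0("m", 1:5), paste0("s", 1:8)))
  expect_error(pcaCovariates(HlaDosageSet(flat), k = 2), "monomorphic|rank")
  two <- rbind(m1 = c(0, 2, 0, 2, 0, 2), m2 = c(0, 2, 0, 2, 0, 2))
  colnames(two) <- paste0("s", 1:6)
  expect_error(pcaCovariates(HlaDosageSet(two), k = 3), "rank")
})

test_that("dosage r2 matches hand-computed Pearson correlation", {
  expect_equal(ldR2(c(0, 1, 2, 2), c(0, 1, 2, 2)), 1)
  expect_equal(ldR2(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
  # hand computation: cov = 2/3, var_a = 2.75/3, var_b = 2/3 -> r2 = 8/11
  expect_equal(ldR2(c(0, 1, 2, 2), c(0, 1, 1, 2)), 8 / 11, tolerance = 1e-12)
  expect_warning(r <- ldR2(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_true(is.na(r))
})
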