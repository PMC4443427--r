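# Config with two causal HLA-B alleles and a pure tag of the stronger one.
twoCausalConfig <- function(seed) {
  simConfig(
    nCases = 2500L, nControls = 2500L,
    loci = list("HLA-B" = list(
      alleles = c("B*27:05", "B*40:01", "B*07:02", "B*99:01"),
      freq = c(0.15, 0.20, 0.15, 0.50), basePosition = 31431000L)),
    seed = seed,
    logOR = c(HLA_B_2705 = log(3.0), HLA_B_4001 = log(1.5)),
    tagSnps = data.frame(id = "rsTag", locus = "HLA-B",
                         targets = "B*27:05", r2 = 0.9,
                         position = 31430000L),
    structure = list(nSnps = 60L, fst = 0.05),
    theta = -2, nPcs = 5L)
}

test_that("stepwise scan recovers causal alleles and never their tags", {
  for (seed in c(101L, 202L, 303L)) {
    sim <- simulateCohort(twoCausalConfig(seed))
    cand <- c("HLA_B_2705", "HLA_B_4001", "HLA_B_0702", "HLA_B_9901",
              "rsTag")
    led <- stepwiseScan(sim$dosages, cand, sim$pheno, sim$covar,
                        threshold = 1e-3)
    r <- rounds(led)
    expect_identical(r$marker[1], "HLA_B_2705")
    expect_true("HLA_B_4001" %in% r$marker)
    expect_false("rsTag" %in% r$marker)        # pure tag never enters
    expect_false("HLA_B_9901" %in% r$marker)   # null allele never enters
    expect_identical(stopReason(led), "no-significant")
    # injected signs are recovered
    expect_gt(r$or[r$marker == "HLA_B_2705"], 1)
    expect_gt(r$or[r$marker == "HLA_B_4001"], 1)
    # conditioning bookkeeping: round r conditions on winners of 1..r-1
    expect_identical(r$conditioning[2],
                     paste(r$marker[1], collapse = ","))
  }
})

test_that("a null cohort yields an empty ledger", {
  cfg <- simConfig(
    nCases = 400L, nControls = 400L,
    loci = list("HLA-B" = list(
      alleles = c("B*27:05", "B*40:01", "B*99:01"),
      freq = c(0.15, 0.2, 0.65))),
    seed = 55L, theta = 0, structure = list(nSnps = 40L, fst = 0.02),
    nPcs = 5L)
  sim <- simulateCohort(cfg)
  led <- stepwiseScan(sim$dosages,
                      c("HLA_B_2705", "HLA_B_4001", "HLA_B_9901"),
                      sim$pheno, sim$covar, threshold = 1e-3)
  expect_identical(nrow(rounds(led)), 0L)
  expect_identical(stopReason(led), "no-significant")
  expect_error(stepwiseScan(sim$dosages, character(0), sim$pheno),
               "empty")
})

test_that("conditioning on all injected causal markers leaves no signal", {
  sim <- simulateCohort(twoCausalConfig(404L))
  causal <- c("HLA_B_2705", "HLA_B_4001")
  others <- c("HLA_B_0702", "HLA_B_9901", "rsTag")
  for (mk in others) {
    res <- testMarker(sim$dosages, mk, sim$pheno, sim$covar,
                      conditioning = causal)
    expect_true(!res$testable || res$log10P >= -3)
  }
})

test_that("ledgers are reproducible from identical inputs", {
  sim <- simulateCohort(twoCausalConfig(77L))
  cand <- c("HLA_B_2705", "HLA_B_4001", "HLA_B_0702", "rsTag")
  l1 <- stepwiseScan(sim$dosages, cand, sim$pheno, sim$covar,
                     threshold = 1e-3)
  l2 <- stepwiseScan(sim$dosages, cand, sim$pheno, sim$covar,
                     threshold = 1e-3)
  expect_identical(as.data.frame(rounds(l1)), as.data.frame(rounds(l2)))
})

test_that("reciprocal conditioning distinguishes explaining signals", {
  # residue Asn97 is carried by both B27 alleles and both are causal with
  # the same effect, so the residue explains the single allele but the
  # allele cannot explain the residue
  cfg <- simConfig(
    nCases = 2500L, nControls = 2500L,
    loci = list("HLA-B" = list(
      alleles = c("B*27:05", "B*27:02", "B*07:02", "B*99:01"),
      freq = c(0.10, 0.10, 0.20, 0.60))),
    seed = 88L,
    logOR = c(HLA_B_2705 = log(3.0), HLA_B_2702 = log(3.0)),
    aaMap = data.frame(allele = c("B*27:05", "B*27:02", "B*07:02", "B*99:01"),
                       position = 97L,
                       residue = c("Asn", "Asn", "Ser", "Arg")),
    structure = list(nSnps = 40L, fst = 0.02), theta = -2, nPcs = 5L)
  sim <- simulateCohort(cfg)
  info <- markerInfo(sim$dosages)
  bIds <- rownames(sim$dosages)[info$kind == "classical_allele"]
  aa <- expandAminoAcids(sim$dosages[bIds, ], sim$map)
  x <- HlaDosageSet(rbind(dosages(sim$dosages), dosages(aa)),
                    markerInfo = rbind(
                      as.data.frame(info)[, c("kind", "locus", "position")],
                      as.data.frame(markerInfo(aa))[, c("kind", "locus",
                                                        "position")]))
  v <- reciprocalConditioning(x, a = "HLA_B_2705", b = "AA_B_97_Asn",
                              sim$pheno, sim$covar)
  expect_identical(v$verdict, "b-explains-a")
  expect_gte(v$pAgivenB, 0.05)
  expect_lt(v$pBgivenA, 0.05)

  # a marker against itself is indistinguishable (collinear)
  self <- reciprocalConditioning(x, "HLA_B_2705", "HLA_B_2705",
                                 sim$pheno, sim$covar)
  expect_identical(self$verdict, "indistinguishable")

  # two independent causal signals survive each other
  sim2 <- simulateCohort(twoCausalConfig(99L))
  both <- reciprocalConditioning(sim2$dosages, "HLA_B_2705", "HLA_B_4001",
                                 sim2$pheno, sim2$covar)
  expect_identical(both$verdict, "both-independent")
})

test_that("independent-test counting follows the greedy r2 rule", {
  expect_equal(bonferroniThreshold(0.05, 5000), 1e-5)

  # three mutually identical markers collapse to one test
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  mat <- rbind(a = g, b = g, c = g)
  colnames(mat) <- paste0("s", 1:8)
  info <- data.frame(marker = c("a", "b", "c"), position = 1:3)
  expect_equal(countIndependentTests(HlaDosageSet(mat, info)), 1L)

  # five markers with structured correlation: compare against an
  # exhaustive re-implementation of the greedy rule
  set.seed(13)
  base <- rnorm(200)
  mk <- function(rho) pmin(2, pmax(0, 1 + rho * base +
                                     sqrt(1 - rho^2) * rnorm(200) * 1))
  mat5 <- rbind(m1 = mk(1), m2 = mk(0.98), m3 = mk(0.5), m4 = mk(0.97),
                m5 = mk(0.1))
  colnames(mat5) <- paste0("s", 1:200)
  info5 <- data.frame(marker = rownames(mat5), position = 1:5)
  x5 <- HlaDosageSet(mat5, info5)
  # brute-force greedy in position order
  kept <- integer(0)
  for (i in 1:5) {
    ok <- all(vapply(kept, function(j)
      cor(mat5[i, ], mat5[j, ])^2 < 0.9, logical(1)))
    if (ok) kept <- c(kept, i)
  }
  expect_equal(countIndependentTests(x5), length(kept))
  expect_equal(countIndependentTests(x5, r2Cut = 1.01), 5L)
})
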