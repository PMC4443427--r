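---
title: "Fine-mapping MHC association signals from HLA dosages"
author: "hlaFineMap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-mapping MHC association signals from HLA dosages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlaFineMap)
```

## The problem

The major histocompatibility complex is the most association-dense region
of the human genome, and in HLA-driven diseases such as ankylosing
spondylitis the lead signal (here, HLA-B27) is so strong that it masks
every other signal in the region. Disentangling which classical alleles,
amino-acid positions and SNPs carry statistically independent effects
requires three ingredients that this package implements as a pipeline:

1. **Amino-acid expansion.** Classical alleles determine the protein
   sequence, so per-sample expected counts (dosages) of each residue at
   each polymorphic protein position can be computed by summing
   classical-allele dosages over the alleles carrying that residue
   (`expandAminoAcids()`). Binary allele-presence markers at two-digit
   family resolution come from `encodePresenceMarkers()`.
2. **Omnibus and conditional logistic tests.** Disease status for sample
   $i$ is modelled as
   $$\operatorname{logit} P(y_i = 1) \;=\; \theta + \sum_k \pi_k p_{i,k}
     + \sum_a \beta_a g_{a,i},$$
   where $p_{i,k}$ are genotype principal components, $g_{a,i}$ is the
   dosage of allele (or residue, or SNP) $a$, and $\theta$ absorbs the
   case-control sampling fraction. A multi-allelic position with $m$
   observed alleles is tested by a likelihood-ratio test adding $m-1$
   dosage columns — the most common allele is the reference — giving a
   $\chi^2$ statistic with $m-1$ degrees of freedom (`omnibusTest()`).
   Single markers are 1-df tests (`testMarker()`); previously established
   signals enter both null and alternative models as fixed effects.
3. **Stepwise conditional scanning.** `stepwiseScan()` repeats the scan,
   each round adding the most significant marker below an entry threshold
   to the conditioning set, until nothing passes. `reciprocalConditioning()`
   formalises "position X explains allele Y": Y is extinguished given X
   while X survives given Y.

Epistasis between a candidate SNP (the ERAP1 missense variant rs30187 is
the motivating case) and HLA alleles is assessed two ways that must agree:
per-stratum effect estimates over the four carrier strata B27+,
B27−/B40:01+, B27−/B40:02+ and B27−/B40− (`stratifiedEffect()` over
`assignStrata()`), and a formal 1-df product-term likelihood-ratio test
(`interactionTest()`, `allelePairInteraction()`).

## Data model

`HlaDosageSet` extends `SummarizedExperiment`: markers are rows with
metadata (`kind`, `locus`, `position`, `alleleLabel`, `imputationR2`),
samples are columns, and the single `dosage` assay holds expected allele
counts in $[0, 2]$. Phenotypes and covariates are plain tables keyed by
`sample_id`; every join validates sample alignment and fails loudly,
never reordering silently. On-disk formats are tab-separated (see
`readDosageFile()`), with marker kinds inferred from SNP2HLA-style id
prefixes (`AA_`, `HLA_`, otherwise SNP) and overridable via a sidecar
table.

## Quality control

Two post-imputation filters mirror standard practice for imputed HLA
dosages: samples whose four-digit classical dosages at any one locus sum
to more than 2.5 are removed (`filterSamplesByCumulativeDosage()`), and
markers with imputation quality $r^2 < 0.2$ are excluded
(`filterMarkersByImputationR2()`). Both cutoffs are strict readings of
"above"/"below", so sums of exactly 2.5 and scores of exactly 0.2 are
retained; markers without a recorded score (genotyped) are retained.
`imputationAccuracy()` scores best-guess calls against truth per allele at
the copy level — for allele $a$, sensitivity is
$\sum_i \min(t_{ia}, c_{ia}) / \sum_i t_{ia}$ and specificity the
analogous fraction of the $2 - t_{ia}$ truly absent copies — because the
copy level is the stricter, well-defined choice when the carrier/copy
convention is not recorded. The sensitivity median is taken over alleles
with at least one true copy.

## Numerical choices

* **Fitting.** Maximum likelihood by iteratively reweighted least squares
  (`stats::glm.fit`; relative tolerance $10^{-8}$, at most 100
  iterations). Zero-variance and exactly collinear design columns are
  dropped with a warning; a marker collinear with its conditioning set is
  flagged not-testable rather than fitted. Quasi-complete separation is
  flagged (some $|\beta| > 15$ without convergence) but not penalized —
  no Firth correction — because plain logistic fits remain the reference
  treatment for very large HLA effects at these sample sizes.
* **P-values in log10 space.** Omnibus statistics at a locus like HLA-B
  reach $\chi^2 \approx 15{,}000$, for which the tail probability
  ($\sim 10^{-3220}$) underflows doubles. All P-values are therefore
  carried as `log10P` (computed via `pchisq(..., log.p = TRUE)`), with
  the linear-scale `p` column provided for convenience and allowed to
  underflow to 0.
* **Confidence intervals.** Wald 95% intervals on the log-odds scale,
  the standard companion to likelihood-ratio P-values in this literature;
  profile-likelihood intervals are not computed.
* **Ties.** The omnibus reference allele is the most common; frequency
  ties break lexicographically. Stepwise winners tie-break by larger
  $\chi^2$, then lexicographic marker id, so ledgers are byte-reproducible.
* **Missing dosages** are handled by complete-case filtering per test —
  the simplest auditable policy; imputed dosage sets rarely contain
  missing entries.
* **Independent-test counting** (`countIndependentTests()`) walks markers
  in genomic-position order and keeps a marker iff $r^2 < 0.90$ against
  every kept marker. The greedy order is a package choice (deterministic
  and auditable); other orders reproduce the rule but not necessarily the
  same count. `bonferroniThreshold(0.05, 5000)` gives the conventional
  $10^{-5}$ MHC-wide threshold; a restricted panel of ~38 HLA-B alleles
  is usually held to $10^{-3}$.
* **Carrier hard calls** round dosages (`floor(d + 0.5)`); a carrier has
  a hard-called count of at least 1.

## The synthetic cohort generator

Real MHC case-control genotypes cannot be redistributed, so the package
ships a generator (`simulateCohort()`) that reproduces the statistical
structure the analysis assumes, with known truth for recovery testing:

* two subpopulations (weights 0.6/0.4) whose differentiation enters
  through a panel of unlinked Balding-Nichols SNPs ($F_{ST} = 0.02$,
  200 SNPs by default — a deliberately scaled-down stand-in for a
  genome-wide panel, sufficient for the top components to capture a
  two-population structure). HLA allele frequencies are shared across
  subpopulations; structure is confined to the SNP panel.
* four classical loci (HLA-B, -A, -DPB1, -DRB1) with two haplotype draws
  per sample from European-style frequency tables;
* additive log-odds disease model: $\theta$ plus injected per-dosage
  $\beta_a$ for effect alleles/SNPs, plus a stratum-specific slope for
  the interaction SNP;
* case-control ascertainment by rejection sampling until the quotas are
  met, with a bounded draw budget;
* tag SNPs synthesized per haplotype by copying the target-allele
  indicator with probability $\sqrt{r^2_{target}}$ (else redrawing from
  the background frequency), which makes the realized dosage $r^2$
  concentrate on the target;
* a synthetic allele→residue map in which the position-97 analog carries
  six residues partitioning HLA-B exactly as configured (Asn confined to
  B27), so omnibus bookkeeping and explained-signal analyses have a
  defined truth. The map is a constructed partition, not an IMGT
  alignment.

`defaultPaperConfig()` fixes the study-like conditions used throughout
the tests: 8,000 cases / 12,000 controls, the nine published HLA-B
stepwise odds ratios (62.41, 43.41, 0.82, 0.75, 1.33, 2.35, 1.59, 1.43,
1.22), HLA-A\*02:01 at 1.22, two class-II SNP effects (1.21, 1.16), and
an rs30187 analog (frequency 0.35) with OR 1.40 in B27 carriers and 1.41
in B27-negative B\*40:01 carriers. The baseline intercept $\theta = -7$
puts population prevalence near 0.5% with B27 carriers at roughly 5%
risk, matching the epidemiology of an HLA-B27-driven arthritis. Allele
frequencies are package defaults taken from European frequency compendia
— the source cohort's control frequencies are not published numerically —
and are deliberately not tuned.

**Interaction parameterization.** The stratum-specific SNP term enters
the linear predictor with the SNP dosage centered at its expectation
$2f$:
$\beta_{strat(i)} \,(g_{snp,i} - 2f)$. Centering leaves every
within-stratum slope — the quantity the stratified analysis estimates —
exactly $\beta_{strat}$, while removing the stratum-level mean shift an
uncentered term would add; without it, the B\*40:01 carrier stratum would
absorb an extra $2f\,\beta$ of log-odds and the allele's recovered
conditional odds ratio would no longer equal its configured value. This
keeps both truths well defined at once: allele main effects equal the
configured odds ratios, and stratified SNP effects equal the configured
stratum slopes.

### What the generator does and does not emulate

It reproduces additive dosage effects, intra-locus dosage competition
(haplotype slots), carrier-stratum interactions, simple LD tags and
population structure. It does **not** model coalescent-realistic LD
across the MHC, reference-panel imputation error structure (optional
Gaussian blur is available but off by default), haplotype phase effects,
genotyping batch artefacts or ancestry outliers. Recovery of injected
parameters on these cohorts therefore validates the estimation and
bookkeeping machinery — it does not certify performance on the messier
LD structure of real MHC data.

## Stepwise thresholds and what recovery shows

A caution on interpreting round-1 (marginal) effect sizes: a stepwise
scan's first round estimates each allele's *marginal* odds ratio, and at
a multi-allelic locus the dosage-0 reference group contains carriers of
every other allele. When a second risk allele at the same locus is rare
but strong — the B\*27:02 configuration here, frequency 0.0025 with OR
43 — those carriers inflate the reference group's disease odds and
attenuate the lead allele's marginal estimate by on the order of 15%,
even though the fully specified model (all effect alleles plus the
interaction term) recovers every injected coefficient essentially
exactly. This is a structural feature of marginal estimation, not an
estimator defect; it applies equally to published marginal estimates
from real cohorts, and it disappears as soon as the competing allele
enters the conditioning set in round 2.

At the panel threshold $10^{-3}$ over the HLA-B four-digit alleles, a
20,000-sample cohort reliably yields the very strong signals (the two
B27 analogs, B\*07:02, B\*47:01) in the ledger; alleles with odds ratios
near 1.2–1.6 at these frequencies have conditional P-values in the
$10^{-2}$–$10^{-3}$ range (as their published confidence intervals imply)
and enter only sporadically. Their effect sizes are therefore reported as
conditional estimates given all selected alleles when they are not
themselves selected — the same quantity the stepwise round would have
estimated, without the winner's-curse selection bias a hard threshold
imposes. The acceptance script (`scripts/acceptance.R`) reports exactly
these quantities, averaged over ten generator seeds; each seed's
simulation plus scan takes well under a minute, and the script's full
recomputation (ten 20,000-sample cohorts, scans, stratified fits) runs in
a few minutes on one CPU. The type-I-error checks in the test suite use
2,000 null replicates of 2,000 samples each, the problem size at which
the whole suite still completes comfortably.

## Known limitations

* Plain MLE near separation: odds ratios for alleles approaching
  separation are reported with a flag, not regularized.
* The greedy independent-test count depends on marker order (documented
  above).
* Sensitivity/specificity are copy-level; carrier-level definitions would
  differ for homozygote-rich alleles.
* The generator's `B*99:01`-style pooled "other" alleles are synthetic
  constructs that absorb residual frequency mass; they carry the default
  residue at mapped positions.
* Phased-haplotype analyses are out of scope; residue-level omnibus tests
  on dosages cover the analysis intent.
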