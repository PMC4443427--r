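# hlaFineMap

Fine-mapping of disease association signals across the major
histocompatibility complex (MHC) from imputed SNP, classical HLA allele
and amino-acid residue dosages — the analysis problem posed by diseases
such as ankylosing spondylitis, where one enormous signal (HLA-B27)
masks every other effect in the region. The package is aimed at
statistical geneticists working with SNP2HLA-style dosage data who need
to (i) resolve classical-allele signals to amino-acid positions,
(ii) identify statistically independent effects by conditional analysis,
and (iii) test carrier-stratified gene–gene interactions such as
ERAP1 × HLA-B.

## The model

Disease status is modelled by additive-dosage logistic regression

logit P(y_i = 1) = θ + Σ_k π_k p_{i,k} + Σ_a β_a g_{a,i}

with p_{i,k} the genotype principal components and g_{a,i} ∈ [0, 2] the
dosage of allele/residue/SNP a in sample i. A multi-allelic position with
m observed alleles is tested by an omnibus likelihood-ratio test adding
m − 1 dosage columns (most common allele as reference): χ² with m − 1 df.
Established signals are added to both null and alternative models as
fixed effects; the stepwise scan repeats until no marker passes the entry
threshold (10⁻⁵ MHC-wide via Bonferroni over ~5,000 independent tests,
counted by greedy r² < 0.90 pruning; 10⁻³ for a restricted HLA-B allele
panel). P-values are carried in log10 space so that omnibus statistics
like χ² ≈ 15,000 yield finite bounds (~10⁻³²²⁰) instead of underflowing.
Epistasis is assessed per carrier stratum (B27+, B27−/B40:01+,
B27−/B40:02+, B27−/B40−) and by a 1-df product-term LRT.

Because real MHC case-control genotypes cannot be redistributed, the
package includes a cohort generator (`simulateCohort()`) with known
ground truth; `defaultPaperConfig()` injects the nine published HLA-B
stepwise odds ratios (B*27:05 62.41 ... B*40:01 1.22) and a
stratum-restricted ERAP1-analog SNP effect (OR 1.41 in B27−/B40:01+).

## Worked example

```r
library(hlaFineMap)

cfg <- defaultPaperConfig(seed = 7L, nCases = 1500L, nControls = 2500L)
sim <- simulateCohort(cfg)
sim$dosages
#> HlaDosageSet with 241 markers x 4000 samples
#>   205 SNP, 36 classical allele, 0 amino-acid residue markers

info  <- markerInfo(sim$dosages)
bPanel <- rownames(sim$dosages)[info$kind == "classical_allele" &
                                info$locus == "HLA-B"]
stepwiseScan(sim$dosages, bPanel, sim$pheno, sim$covar, threshold = 1e-3)
#> ConditionalLedger: 3 round(s), stop: no-significant (threshold log10P < -3)
#>  round     marker      or   ciLow  ciHigh   log10P
#>      1 HLA_B_2705 57.9700 46.9100 71.6500 -569.400
#>      2 HLA_B_2702 25.5300 14.7200 44.2900  -34.380
#>      3 HLA_B_0702  0.6354  0.4862  0.8304   -3.185
```

Round 1 recovers the dominant risk allele (injected OR 62.41; at 4,000
samples the estimate is noisy), round 2 the second B27 allele, round 3
the protective B*07:02 analog; the remaining injected effects (OR
1.2–1.6) sit below the 10⁻³ panel threshold at this sample size, which
is why the full-scale analyses use 20,000 samples. Expanding to
amino-acid residues and testing the six-residue position-97 analog:

```r
aa <- expandAminoAcids(sim$dosages[bPanel, ], sim$map)
omnibusTest(aa, sim$pheno, covar = sim$covar,
            locus = "HLA-B", position = 97L)
#> position 97 omnibus: m = 6, chisq = 2767.8, df = 5, log10P = -596.4
```

The omnibus df equals residues-minus-one (6 residues → 5 df). The
stratified interaction analysis:

```r
st <- assignStrata(sim$dosages)
stratifiedEffect(sim$dosages, "rs30187", st, sim$pheno, sim$covar)
#>        stratum nControls nCases    or ciLow ciHigh      p
#>           B27+       172   1271 1.170 0.931  1.472 0.1765
#>   B27-/B40:01+       240     23 0.912 0.486  1.713 0.7746
#>   B27-/B40:02+        55     13 0.314 0.094  1.051 0.0412
#>      B27-/B40-      2033    193 1.350 1.092  1.670 0.0060
```

(Per-stratum estimates need the full cohort size to stabilise; the
20,000-sample runs recover the injected 1.41 in the B27−/B40:01+
stratum.)

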