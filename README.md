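# founderscan

Screening population-isolate case-control SNP cohorts for founder
variants.

In an isolate, a single ancestral mutation can explain many cases of a
disease. On array data it leaves one of two signatures: a **dominant**
founder variant makes affected carriers share one long haplotype, visible
as excess identity-by-state (IBS) among case pairs in a genomic window;
a **recessive** founder variant makes carriers autozygous, visible as
runs of homozygosity (ROH) piling up over the same interval in cases.
`founderscan` implements both scans with label-swap permutation
inference, plus the supporting pipeline an array cohort needs:

* PLINK ped/map and binary bed/bim/fam IO, MACH-style imputed-dosage IO,
  and two-platform consensus merging with allele harmonisation;
* sample/SNP quality control (call rate, MAF, exact Hardy–Weinberg tests
  stratified by case status, differential and haplotype-conditional
  missingness), method-of-moments relatedness (`pi_hat`) with greedy
  pruning, and classical-MDS ancestry covariates;
* variance-inflation-factor LD pruning over sliding 50-SNP windows
  (VIF > 1.05);
* per-SNP dosage logistic regression with MDS covariates, Wald CIs,
  genome-wide flagging at 5e-8 and the genomic inflation factor
  (median chi-square / 0.4549);
* cumulative risk-allele profile scores over a published locus table
  (13 Parkinson's disease GWAS loci bundled), quintile odds ratios,
  trend test and c-index;
* 500 kb / 250 kb sliding-window IBS with 10,000-permutation pointwise
  and maxT family-wise p-values, and a genome-wide IBS comparison;
* ROH calling (≥ 1 Mb, ≥ 50 SNPs, ≤ 2 missing, ≤ 1 heterozygote),
  per-sample burden and Fhat, burden logistic regression, consensus
  regions (≥ 3 SNPs, ≥ 100 kb, ≥ 3 carriers) and a maxT-corrected
  excess-case-carrier test;
* a seeded synthetic-cohort generator (haplotype-block LD from founder
  haplotype pools, Balding–Nichols substructure, planted dominant and
  recessive signals, risk loci at published odds ratios, missingness,
  related pairs) so the whole pipeline is testable without external
  data.

The central statistics: per window, `delta = mean case-pair share − mean
control-pair share` with `share = (IBS2 + 0.5·IBS1) / n`, tested
one-sided by redrawing case labels; per consensus region, the one-sided
proportion z for excess case carriers, maxT-corrected by recording each
permutation's maximum z over regions. The bundled 2,645 Mb autosome
model tiles into exactly 10,580 windows, giving the per-window Bonferroni
threshold 0.05 / 10,580 ≈ 5e-6.

## Worked example

Simulate a 100 + 100 cohort on two 12.5 Mb chromosomes (~10,000 common
SNPs), plant a dominant founder haplotype spanning chr2:5–7 Mb in 40% of
cases, and scan:

```r
library(founderscan)

cfg <- simulationConfig(n_cases = 100, n_controls = 100,
                        chrom_lengths = c("1" = 12500000, "2" = 12500000),
                        snp_spacing_mean = 2500, block_length_mean = 2000,
                        haplotypes_per_block = 8, maf_range = c(0.2, 0.5),
                        missing_rate = 0.005, seed = 11)
panel <- simulateBasePanel(cfg)
panel <- assignPhenotypes(panel, list(), 100, 100, rng_seed = 12)
panel
#> GenotypePanel: 200 samples (100 cases / 100 controls) x 10009 SNPs
#>   chromosomes 1-2; missing rate 0.0050

signal <- plantedSignal("dominant_haplotype", chrom = 2,
                        start_bp = 5e6, end_bp = 7e6,
                        case_carrier_fraction = 0.4)
panel <- plantSignal(panel, signal, rng_seed = 13)

scan <- windowPermutationTest(panel, n_perm = 1000, seed = 14,
                              chrom_lengths = cfg$chrom_lengths)
head(scan[order(scan$p_empirical, -scan$delta), ], 5)
#>  chrom start_bp  end_bp n_snps case_ibs control_ibs  delta p_empirical   p_maxt
#>      2  6500001 7000000    186    0.752       0.733 0.0185    0.000999 0.000999
#>      2  5000001 5500000    178    0.742       0.726 0.0162    0.000999 0.000999
#>      2  6250001 6750000    170    0.750       0.737 0.0140    0.000999 0.000999
#>      2  5250001 5750000    191    0.737       0.723 0.0132    0.000999 0.000999
#>      2  6000001 6500000    182    0.733       0.720 0.0129    0.000999 0.000999
```

Every top window sits inside the planted region: case pairs share ~1.4–
1.9% more alleles there than control pairs, and no permutation of the
case labels reaches the observed difference (`p = 1/1001`, pointwise and
family-wise).

Cumulative risk profile at the bundled published odds ratios, on a
simulated 400 + 500 cohort:

```r
rc <- simulateRiskCohort(pdRiskLoci(), 400, 500, seed = 15)
prof <- riskProfile(rc$dosages, rc$risk_loci)
prof$quintile_or[, c("quintile", "or_", "ci_low", "ci_high")]
#>  quintile  or_ ci_low ci_high
#>         1 1.00     NA      NA
#>         2 1.38   0.89    2.13
#>         3 1.66   1.07    2.55
#>         4 1.94   1.26    2.98
#>         5 3.82   2.47    5.92
sprintf("trend p = %.3g, AUC (c-index) = %.3f", prof$trend_p, prof$auc)
#> "trend p = 2.65e-11, AUC (c-index) = 0.624"
```

Disease odds rise monotonically across score quintiles — a ~3.8-fold
difference between the top and bottom fifth — with c-index ≈ 0.62, the
discrimination scale these 13 modest-effect loci support.

`runPipeline(pipelineConfig(out_dir = "..."))` chains all stages
(simulate → QC → prune → GWAS → profile → IBS scan → ROH scan) with one
seed, writes per-stage TSVs, a log and a MANIFEST.

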