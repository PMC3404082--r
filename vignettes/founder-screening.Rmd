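---
title: "Screening an isolate case-control cohort for founder variants"
author: "founderscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening an isolate case-control cohort for founder variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderscan)
```

## The problem

In a population isolate, a single ancestral ("founder") mutation can
account for an appreciable share of a disease cohort.  Two genetic
signatures betray it on ordinary SNP-array data, without sequencing:

* a **dominant** founder variant rides on one long shared haplotype, so
  affected carriers show excess *identity by state* (IBS) with each other
  in the region — more proportional allele sharing among case pairs than
  among control pairs;
* a **recessive** founder variant requires two copies, so affected
  carriers are autozygous across the region: their genotypes form long
  *runs of homozygosity* (ROH) that pile up over the same interval.

`founderscan` implements both scans with label-swap permutation inference,
together with everything a case-control SNP panel needs on the way there:
quality control, relatedness pruning, multidimensional-scaling (MDS)
covariates, variance-inflation-factor (VIF) LD pruning, per-SNP dosage
logistic association with genomic-control diagnostics, and cumulative
risk-allele profile analysis.  A seeded cohort simulator generates panels
with the statistical structure the analyses assume, so every stage is
testable end to end; no external data are required.

## The data model

A `GenotypePanel` holds a sample table (id, case/control phenotype, birth
year), an autosomal SNP map sorted by (chromosome, position), and a
samples x SNPs matrix of codes counting copies of allele 1 (0/1/2,
`NA` = missing — missingness is never conflated with a homozygous call).
A `DosageSet` carries imputed non-integer allele dosages in [0, 2] with
per-SNP imputation quality (RSQR) and frequency.  Readers and writers
cover PLINK ped/map, SNP-major binary bed/bim/fam, and MACH-style dosage
tables with info sidecars.  Two genotyping platforms are merged by
physical position, with codes flipped where allele labels are swapped;
strand-ambiguous (A/T, C/G) and irreconcilable sites are dropped and
counted — the safest default when array strand conventions differ.

## Quality control

The default thresholds are the standard array-QC battery: per-sample call
rate ≥ 0.95; per-SNP call rate ≥ 0.95; MAF ≥ 0.01; Hardy–Weinberg
equilibrium tested by the **exact conditional test** (all heterozygote
counts compatible with the allele counts are enumerated and tables no
more probable than the observed one are summed), with separate thresholds
in controls (p ≥ 1e-4) and cases (p ≥ 1e-7) so that true risk loci,
which deviate in cases, are not discarded wholesale; differential
case/control missingness (1-df chi-square, p ≥ 1e-5); and
haplotype-conditional missingness (independence of a SNP's missingness
from the joint genotypes of its two immediate flanks, p ≥ 1e-5).  The
exact HWE test is preferred to the chi-square because the case threshold
sits at 1e-7, far into the tail where the asymptotic approximation fails
at QC-boundary allele frequencies.  MAF is computed on the merged cohort
(not per platform); the QC report records this.

Relatedness is estimated by method-of-moments IBD: per pair, observed
IBS0/1/2 proportions are solved against their expectations under 0, 1 or
2 alleles shared identically by descent, with each power of the allele
frequency replaced by its unbiased finite-sample estimator (the code
documents the formulas).  Pairs with `pi_hat` > 0.15 are pruned greedily
— the member with more flagged partners goes first, ties broken by lower
call rate then id — which removes one member of each first-degree pair
while keeping probands.  Population structure is summarised by Torgerson
classical MDS on the distance 1 − IBS; the first two components are the
default covariates for every regression, mirroring common GWAS practice
in single-population cohorts.

## LD pruning, and a small-cohort caveat

For IBS, IBD and ROH work the marker set should be approximately
independent.  `vifPrune()` slides a 50-SNP window in steps of 5 along
each chromosome and repeatedly removes the SNP whose variance inflation
factor 1/(1 − R²) against the rest of the window exceeds 1.05, until the
window is clean; sweeps repeat to a fixpoint so the bound holds
everywhere.  Missing genotypes are mean-imputed within the window and a
1e-8 ridge keeps the correlation matrix invertible (results are
insensitive to the ridge at the 1e-6 level).

One property of this statistic deserves emphasis: the sample multiple R²
of one SNP on `w − 1` others has a noise floor of roughly
`(w − 1)/(n − 1)` even for independent markers.  With 50-SNP windows the
VIF-1.05 rule is therefore only meaningful when the cohort is much larger
than the window (at n ≈ 900, the scale this procedure is designed for,
the floor is ~0.055).  The simulated cohorts used in the test suite are
10–20× smaller, so they either prune with proportionally smaller windows
or generate near-independent markers directly (LD blocks shorter than
the marker spacing) — pruning is then a no-op by construction.  The
permutation tests downstream are valid under any LD, so this choice
affects efficiency, not calibration.

## Association and risk profile

`logisticDosageScan()` fits phenotype ~ dosage + MDS components per SNP
by IRLS (tolerance 1e-8, ≤ 50 iterations), reporting Wald p-values and
95% CIs as `exp(beta ± 1.96 se)`; constant dosages, non-convergence and
separation (detected on the per-SD scale so covariate units do not
matter) are flagged rather than reported.  `genomicLambda()` is the
median association chi-square over 0.4549, and `flagGenomewide()` applies
the 5e-8 convention.

The cumulative risk profile sums risk-allele dosages over a published
locus table (13 Parkinson's disease loci are bundled, with their
replication-phase odds ratios).  A published OR below 1 means the listed
allele is protective, so the complementary dosage `2 − d` is summed.  The
sum is unweighted by default — the profile machinery this follows used
plain allele counts, and an |log OR|-weighted variant is available behind
a flag.  Samples are ranked, split into quintiles (sizes as equal as
possible, larger groups first from the bottom, stable ties), and
per-quintile ORs are estimated against quintile 1 by adjusted logistic
regression.  The trend p-value is the Wald test of the continuous score;
discrimination is the concordance (c-index) of the adjusted model's
fitted probabilities, with the score-only c-index reported alongside
because reasonable implementations differ on which to quote.

## The windowed IBS scan

`makeWindows()` tiles each chromosome with 500 kb windows stepped by
250 kb, starting at bp 0 — anchoring windows to the chromosome origin
rather than the first marker makes the count `sum(ceil(span / step))`
depend only on the genome, and the bundled 2,645 Mb autosome model tiles
to exactly 10,580 windows, giving a per-window Bonferroni threshold of
0.05 / 10,580 ≈ 5e-6.  Pairwise shares use the PLINK convention
`(IBS2 + 0.5 IBS1) / joint calls`.  Per window, the statistic is
`delta` = mean case-pair share − mean control-pair share (mixed pairs are
excluded); windows with fewer than 10 SNPs are emitted but flagged
untestable.

Inference is by label swap: case labels are redrawn (preserving the case
count) with a single shared label stream per permutation, so
between-window correlation survives into the null and a family-wise maxT
p-value comes for free alongside the pointwise empirical p.  Per-pair
window share sums are precomputed once on non-overlapping half-window
segments; each permutation is then two matrix products, which makes
10,000 permutations on a 200-sample, 10,000-SNP panel a matter of
seconds.  Empirical p-values use add-one smoothing, `p = (1 + #{delta* ≥
delta}) / (1 + B)`, so they are never zero; the test is one-sided (cases
sharing more than controls) by default, matching the founder hypothesis,
with a two-sided flag.  A caveat stated plainly: with B = 10,000 the
smallest attainable pointwise p is ~1e-4, which can never cross the 5e-6
Bonferroni line — family-wise decisions should use the maxT column, and
both are reported.

## ROH calling and homozygosity mapping

A run of homozygosity is a maximal stretch of consecutive SNPs spanning
≥ 1 Mb with ≥ 50 SNPs, at most 2 missing calls and at most 1
heterozygote, beginning and ending on a homozygous call.  The caller
implements this definition *directly*: for every homozygous start the
largest admissible end is found (the position before the 2nd heterozygote
or 3rd missing call), and first-start-per-distinct-end de-duplication
yields exactly the maximal qualifying intervals — a property checked in
the suite against an exhaustive every-interval oracle on hundreds of
random instances.  This is a deliberate departure from scanning-window
proportion heuristics used by some toolchains: the criteria are the
definition, so the definition is what runs.

Per-sample burden is the summed ROH length over the 2,645 Mb autosomal
genome (`genome_fraction`) and the segment count; both are regressed on
phenotype with birth year and two MDS components as covariates.  The
inbreeding coefficient `Fhat` is the method-of-moments contrast of
observed versus expected homozygous calls, with the `2n/(2n − 1)`
small-sample factor on expected heterozygosity and cohort-monomorphic
SNPs excluded.

Consensus regions partition the genome at all segment breakpoints and
merge adjacent intervals with identical carrier sets; intervals carried
by ≥ 3 samples, containing ≥ 3 SNPs over ≥ 100 kb, are tested.  A
carrier must cover the whole region (partial overlap is available behind
a flag).  The association statistic is the one-sided z for excess case
carrier proportion — the test borrowed from copy-number analysis does not
pin down its internal statistic, so the proportion z is the default and a
raw case-count statistic is selectable.  maxT correction records the
maximum statistic over regions per label swap (50,000 permutations at
full scale); corrected p-values are never smaller than pointwise ones.

## The simulator and what it does (and does not) emulate

`simulateBasePanel()` builds LD from finite founder-haplotype pools:
block boundaries follow an exponential length distribution, each block
carries K haplotypes with Dirichlet(1) frequencies, and every individual
draws two haplotypes per block independently.  This one mechanism yields
the three structures the pipeline consumes: within-block LD (shared
haplotypes), background autozygosity (both draws coinciding — abundant
when K is small and blocks long, vanishing when K is large and blocks
short), and realistic IBS variation.  Substructure is Balding–Nichols:
two subpopulations whose block haplotype frequencies are Dirichlet
perturbations with concentration `(1 − Fst)/Fst`.  Phenotypes follow an
additive logistic model on risk-allele counts; exactly the requested
case count is drawn by odds-weighted sampling without replacement (the
retrospective case-control construction), which hits cohort sizes
deterministically while preserving per-allele odds ratios — the test
suite verifies a planted OR = 2 locus is recovered within [1.5, 2.6] in
over 95% of repetitions.  Birth years are age-discrepant (young-onset
cases around 1948 ± 10, elderly controls around 1930 ± 10) but
deliberately overlapping: fully separated arms would make every
birth-year-adjusted logistic model formally non-identifiable (complete
separation), a pathology of the real design that the simulator does not
reproduce because it would leave nothing estimable to test.

Planted signals write a founder haplotype into a region: one copy per
carrier for dominant signals (the other copy re-drawn from the carrier's
own genotype), both copies for recessive signals.  Related individuals
share one haplotype per block with a named sample (pi-hat 0.5), or both
for duplicates.

Default scale mirrors an isolate array study: ~400 + 500 samples and
~302,000 autosomal SNPs (8.75 kb mean spacing over 2,645 Mb).  The test
suite and acceptance script run deliberately smaller *study conditions*,
fixed once and stated here:

* **window-scan cohorts**: 100 + 100 samples, two 12.5 Mb chromosomes at
  2.5 kb spacing (~10,000 SNPs, 100 windows), common alleles
  (MAF 0.2–0.5) and near-independent markers.  Dense, common markers are
  what give a 500 kb window discriminating power at n = 200: the
  case-pair share lift from a planted haplotype is diluted by the
  carrier-pair fraction, and window-level noise falls with the number of
  informative markers per window.  Planted dominant haplotypes span 2 Mb
  — a realistic founder-haplotype scale in a young isolate — in 30% of
  cases.
* **ROH-null cohorts** (for family-wise error calibration): 50 + 50
  samples, 2-haplotype 500 kb blocks, which produce abundant background
  ROH and therefore plenty of null consensus regions to test.
* **ROH-signal cohorts**: 100 + 100 samples, 6-haplotype 50 kb blocks,
  where background autozygosity is rare and a planted 2 Mb recessive
  segment in 25% of cases stands out the way a founder mutation would.
* **burden-regression cohorts**: 4-haplotype 200 kb blocks, an
  intermediate background so that both arms carry some ROH and the
  adjusted logistic fit stays identifiable.

Passing tests on these cohorts show the machinery is correct and
calibrated under the stated structure; they do not certify behaviour on
real arrays, whose LD decays smoothly rather than in blocks, whose
missingness is platform-clustered rather than uniform, and whose
population history is richer than two Balding–Nichols demes.

## Numerical and procedural choices

* Coordinates are 1-based inclusive (PLINK map convention); BED exports
  are 0-based half-open behind a flag.
* SNP identity for merging is (chromosome, bp); ids are reporting-only.
* All empirical p-values use add-one smoothing; permutation label
  streams are seeded and shared across windows/regions within a run.
* The IBS window origin is bp 0 per chromosome, making window counts a
  function of the genome alone.
* Greedy deterministic tie-breaking everywhere: highest VIF first (ties:
  lower MAF, then position), relatedness pruning by degree, call rate,
  then id; quintile remainders to the lowest quintiles first.
* Logistic fits: IRLS epsilon 1e-8, 50 iterations; separation flagged on
  the per-SD scale; flagged fits report missing estimates, never numbers.
* Stage seeds in `runPipeline()` derive from the global seed plus a
  character-code hash of the stage name, so any stage can be reproduced
  in isolation.

## Problem sizes used by the checks

The acceptance script (`scripts/acceptance.R`) and the acceptance test
file run, per invocation: one null window scan (10,000 SNPs, 1,000
permutations); 100–200 null ROH cohorts at 1,000 permutations each;
30–100 planted dominant cohorts at 499 permutations; 30–50 planted
recessive cohorts at 1,999 permutations; 15–30 published-OR risk cohorts
of 900 samples; and single larger panels for the relatedness and
inbreeding estimators.  These sizes keep the whole battery in the
minutes range while leaving each check comfortably powered.

## Known limitations

* Imputation itself is out of scope: `DosageSet`s are consumed, not
  produced.  Sex chromosomes are excluded throughout.
* The ped/map dialect does not carry allele orientation; a1 is the first
  allele observed in file order, so orientation round-trips only after
  one normalising read (bed/bim/fam round-trips exactly).
* `pairwiseIBD()` averages expected IBS-state probabilities over SNPs,
  which assumes missingness is unrelated to genotype; heavily
  differential missingness should be filtered first (as the QC order
  does).
* With ~10,000 pointwise permutations the windowed scan cannot reach
  Bonferroni-scale thresholds; use the maxT column for family-wise
  claims.
* The burden regression reports odds ratios per unit of genome fraction;
  on cohorts where one arm has essentially no ROH the fit is flagged as
  separated rather than estimated.
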