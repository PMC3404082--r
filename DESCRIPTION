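Package: founderscan
Title: Founder-Variant Screening in Population-Isolate Case-Control SNP Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening case-control SNP-array cohorts from population
    isolates for dominant and recessive founder variants. Implements
    genotype-panel and imputed-dosage containers with PLINK ped/map and
    bed/bim/fam and MACH-style dosage readers and writers, two-platform panel
    merging, sample and SNP quality control (call rate, minor allele frequency,
    exact Hardy-Weinberg tests, differential and haplotype-conditional
    missingness), method-of-moments relatedness estimation and pruning,
    classical multidimensional-scaling covariates, variance-inflation-factor
    linkage-disequilibrium pruning, per-SNP dosage logistic association with
    genomic-inflation estimation, cumulative risk-allele profile scoring with
    quintile odds ratios and concordance statistics, sliding-window
    identity-by-state mapping with label-swap permutation and maxT correction,
    and runs-of-homozygosity calling with consensus-region extraction and
    maxT-corrected association. A seeded synthetic-cohort generator with
    haplotype-block linkage disequilibrium, Balding-Nichols substructure,
    planted founder signals and published-odds-ratio risk loci makes every
    stage testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
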