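# repqtl — genetic determinants of the CD8+ T cell receptor repertoire

Immune checkpoint blockade works through T cells, and which T cell
receptors (TCRs) an individual's repertoire contains is itself partly
heritable: polymorphism near the TRAV/TRBV loci shifts the propensity to
recombine particular V-genes (cis effects), and classical HLA alleles
shape which clones survive selection and antigen-driven expansion (trans
effects). `repqtl` implements the full quantitative-trait analysis of
this problem for researchers with paired germline genotypes and bulk or
single-cell TCR sequencing: it turns clone tables into per-individual
traits, maps them genome-wide and against the MHC, and carries the
fitted HLA/V-gene pairings through to clone stability, single-cell
tumour reactivity and overall survival.

## The model

For individual *i* and V-gene *g*, the trait is the number of *unique*
productive clones using *g* — clones keyed by `(chain, v_gene, cdr3_aa)`
with multiplicities ignored — TMM-normalised to counts-per-million,
batch-corrected, and mapped through the rank-based inverse normal
transformation (INRT). Each trait is then fitted by OLS:

```
usage_INRT ~ dosage + 2 genetic PCs + 2 TCR PCs + age + sex + cancer type
```

with `dosage` a SNP dosage (0–2), a classical HLA allele dosage, or an
amino-acid residue dosage; multi-residue positions get a joint
(k−1)-df omnibus F-test. Family-wise significance comes from permuting
phenotype rows (features move together, preserving their correlation)
and taking the 5% quantile of per-permutation minimum p-values. CDR3
7-mer traits run through the identical machinery against HLA
predictors. Downstream, each significantly associated V-gene is paired
with its top classical allele; clones carrying such a pairing in a
carrier individual are "HLA-matched" and are tracked across treatment
(unstable / novel / persistent), scored with a 20-gene tumour
reactivity score (TRS) at the single-cell level, and related to overall
survival by Kaplan–Meier / log-rank analysis.

A seeded synthetic-cohort generator (`simulate_cohort()`) produces the
whole study — genotypes, HLA haplotypes with a residue map, paired
pre/post repertoires with HLA-dependent persistence, single-cell tables
with a planted TRS shift, and survival records — with effects planted
on a latent log scale calibrated so recovered coefficients are directly
comparable to the planted values.

## Worked example

Simulate a cohort with one planted cis effect (SNP `var00042` on
*TRBV28*, β = −0.9) and one trans effect (HLA-B\*44 on *TRBV19*,
β = 0.8), build the β-chain phenotype, and scan:

```r
library(repqtl)

cfg <- sim_config(
  n_individuals = 120, n_variants = 300, clones_per_sample = 800,
  cis_effects   = data.frame(variant = "var00042", v_gene = "TRBV28", beta = -0.9),
  trans_effects = data.frame(hla_allele = "B*44",  v_gene = "TRBV19", beta = 0.8),
  seed = 42)
co <- simulate_cohort(cfg)

counts <- count_vgene_usage(co$clones, "beta", "C1")
ph  <- phenotype_pipeline(counts, batch = setNames(co$covariates$batch,
                                                   co$covariates$individual_id))
gp  <- genetic_pcs(co$genotypes, 2); colnames(gp) <- c("genetic_pc1", "genetic_pc2")
tp  <- tcr_pcs(ph$corrected, 2);     colnames(tp) <- c("tcr_pc1", "tcr_pc2")
ids <- rownames(ph$inrt$values)
covs <- cbind(co$covariates[match(ids, co$covariates$individual_id),
                            c("individual_id", "age", "sex", "cancer_type")],
              gp[ids, ], tp[ids, ])

scan <- assoc_scan(ph$inrt, co$genotypes, covs)
null <- permutation_threshold(ph$inrt, co$genotypes, covs, B = 200, seed = 43)
scan[!is.na(scan$p) & scan$p < null$threshold, c("feature", "predictor", "beta", "se", "p")]
```

This prints

```
permutation_null: B = 200, alpha = 0.05, threshold = 4.42e-06
     feature predictor   beta    se        p
6042  TRBV28  var00042 -0.704 0.134 6.73e-07
```

— of 47 × 300 genome-wide tests, the only hit below the permutation
threshold is the causal variant, with the planted negative sign (the
magnitude is attenuated at n = 120 and this sampling depth; the
calibration studies quantify recovery at n = 250). The MHC-focused scan
against classical alleles finds the planted trans pairing:

```r
hla_scan <- assoc_scan(ph$inrt, co$hla$allele_dosage, covs)
hla_scan[which.min(hla_scan$p), c("feature", "predictor", "beta", "p")]
#>     feature predictor  beta        p
#> 384  TRBV19      B*44 0.715 2.18e-09
```

`run_pipeline(pipeline_config(sim = cfg), "out/")` replays the entire
analysis — QC, phenotypes, scans and thresholds, omnibus tests, k-mer
scan, clone dynamics, TRS strata, survival — writing one TSV per stage
plus a checksum manifest, and `inst/cli/repqtl.R` wraps `simulate` and
`pipeline` for shell use.

## Layout

- `R/` — simulation, IO, genotype QC, phenotypes, association engine,
  clone dynamics, single-cell, survival, pipeline, calibration studies
- `vignettes/repertoire-genetics.Rmd` — the methods account: model,
  assumptions, parameter choices, what the generator does and does not
  emulate
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles in `helper-oracles.R`
- `scripts/acceptance.R` — the reproduction script described above
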