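---
title: "Mapping germline determinants of the CD8+ TCR repertoire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping germline determinants of the CD8+ TCR repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`repqtl` treats the composition of a CD8+ T cell receptor repertoire as a
set of quantitative traits and maps them against germline variation. Each
individual's repertoire — the set of productive clones observed by bulk
TCR sequencing at a treatment timepoint — is reduced to per-individual
counts of *unique clones* per V-gene (and per CDR3 7-mer), normalised,
batch-corrected, rank-transformed to normality, and regressed on SNP
dosages, classical HLA allele dosages and HLA amino-acid residue dosages
under an additive model. Family-wise significance is calibrated by
permutation. Downstream, the fitted V-gene/HLA pairings define
*HLA-matched clones*, which are tracked across treatment timepoints,
scored for tumour-reactive expression at the single-cell level, and
related to overall survival.

# The phenotype model

## Unique-clone counting

The analysed trait for V-gene $g$ and individual $i$ is the number of
distinct clones using $g$, where a clone is keyed by
`(chain, v_gene, cdr3_aa)`. Clone multiplicity (read or UMI counts) is
deliberately ignored: weighting every clone equally makes the trait a
measure of *propensity for clonal formation* (recombination plus
selection) rather than of clonal expansion. Only productive clones are
counted. The same unique-clone convention is used everywhere downstream —
clone stability groups, matched-clone proportions and carrier status —
so the package is internally consistent about what "a clone" is. The
nucleotide-level identity of a rearrangement is not represented in the
schema; amino-acid identity is the finest key available and matches the
CDR3-centric analyses.

## 7-mer traits

CDR3 amino-acid sequences of length 12–18 are decomposed into
overlapping 7-mers (a CDR3 of length $L$ yields $L-6$ windows; 7 residues
is the scale of the ITAM signalling motif). The trait for motif $m$ is
again a clone-set cardinality: the number of distinct clones whose CDR3
*contains* $m$, so a motif occurring twice in one CDR3 counts once.
`count_kmers()` optionally restricts the feature space to motifs seen in
at least a fraction `min_prevalence` of individuals; real repertoires
share thousands of recurrent motifs (germline-templated window content),
and the recurrent subset is where cross-individual association is
identifiable. The pipeline default is 0.05.

## Normalisation and transformation

The stage order is enforced by the `phenotype_matrix` container:

1. **TMM** (`tmm_factors()`, via edgeR): trimmed mean of M-values with
   the canonical trims (30% of M-values, 5% of A-values), reference
   sample chosen by upper-quartile proximity, factors rescaled to
   geometric mean 1.
2. **CPM** (`normalize_counts()`): counts per million on the effective
   library (library size x TMM factor).
3. **Batch correction** (`remove_batch()`, via limma): least-squares
   removal of batch main effects, grand level retained. A single batch
   passes through unchanged.
4. **INRT** (`inrt()`): per feature, ranks (ties averaged) mapped through
   $\Phi^{-1}\!\left(\frac{r - 3/8}{n + 1/4}\right)$ — the Blom offset,
   the conventional choice where the transformation is named but not
   parameterised.

Because INRT is rank-based, any monotone rescaling upstream (CPM vs log
CPM, say) yields identical traits; the pipeline's absolute scales only
matter through ranks.

# The association model

Every test is ordinary least squares of one INRT trait on one predictor
dosage with fixed covariates:

$$\text{usage}_{INRT} \sim \text{dosage} + \text{PC}_{1,2}^{genetic} +
\text{PC}_{1,2}^{TCR} + \text{age} + \text{sex} + \text{cancer type}$$

Genotype PCs control population structure; repertoire PCs (computed from
the batch-corrected V-gene usage matrix, pre-INRT, pooling is the
caller's choice) absorb technical repertoire-wide variation. Categorical
covariates become indicators with the largest category as reference.

`assoc_scan()` evaluates the full feature x predictor grid through a
Frisch–Waugh projection: covariates are orthogonalised out of traits and
dosages once, after which every fit is a cross-product. The fast path is
numerically identical to looping `fit_additive()` (tested to 1e-10) and
makes genome-wide x repertoire-wide scans and permutation nulls feasible
at one CPU. Predictors with missing dosages fall back to per-pair
complete-case fits; zero-variance predictors are flagged untestable,
never dropped silently. p-values are capped at 1e-300 and flagged when
the cap binds.

## Permutation thresholds

`permutation_threshold()` permutes whole phenotype *rows* — all features
move together, preserving the inter-feature correlation that makes
per-test Bonferroni conservative — while genotypes and covariates stay
fixed, so the null also preserves the covariate–genotype structure. Per
permutation the minimum p over the full grid is recorded; the threshold
is the empirical `alpha`-quantile of the B minima, with linear
interpolation between order statistics (R quantile type 7, stated so
thresholds are bit-reproducible). The minimum is taken jointly over
features and predictors, because the threshold's purpose is family-wise
control across the whole scan. B >= 20 is required for the quantile to
mean anything; 1000 is the analysis default and 200 is used in the
calibration studies.

## Omnibus amino-acid tests

At an HLA amino-acid position with residues $r_1..r_k$ (per-individual
residue dosages summing to 2), `omnibus_position_test()` compares
covariates + $k-1$ residue-dosage columns (most common residue dropped as
reference) against covariates alone with an F-test on $(k-1, df)$. For
$k=2$ this is exactly the squared-t single-dosage test, which the test
suite asserts to 1e-10; the reference choice is a reparameterisation and
cannot change p. Residue columns collinear with covariates are dropped
with a warning and the numerator df reduced.

## Conditional analysis

`conditional_scan()` appends the dosages of named predictors to the
covariates. Rows testing a conditioned predictor are flagged untestable
(a variant conditioned on itself has zero residual variance). Note the
corollary: a *perfectly* collinear LD proxy is also untestable after
conditioning; the interesting diagnostic is the tight-but-imperfect
proxy, whose conditional p reverts to null.

# Clone dynamics and HLA-matched clones

`classify_clones()` partitions each individual's clone set across paired
timepoints: unstable (pre only), novel (post only), persistent (both) —
set identities hold exactly. Match rules pair a V-gene with its top
associated classical allele (`top_allele_rules()`, smallest p, ties
broken lexicographically); a clone is matched iff its V-gene is in a rule
whose allele the individual carries at dosage >= 1 (carriage, not
homozygosity). Group comparisons of per-individual matched proportions
use a paired Wilcoxon signed-rank test: exact for up to 25 informative
pairs via a dynamic-programming convolution over doubled tie-averaged
ranks (equivalent to enumerating all $2^n$ sign assignments, which the
suite verifies up to n = 12), normal approximation with tie-corrected
variance and continuity correction above.

# Single-cell analyses

Cells pass QC with >= 300 transcripts, <= 20% mitochondrial content and
a chain configuration of 1&alpha;1&beta; or 2&alpha;1&beta;. A
single-cell clone is "same TRA and TRB CDR3 within an individual";
singlets have one cell, expanded clones two or more, and the two strata
partition the QC-passed cells. The tumour reactivity score is the sum of
a user-supplied 20-gene panel, standardised to mean 0, SD 1 across the
analysis set (global standardisation is the default; the synthetic
generator ships its own named panel via `default_trs_panel()`). TRS is
tested against matching status by comparing nested linear models (H1:
TRS ~ status + protocol; H0: TRS ~ protocol) with an F-test. Protocol
enters as fixed indicators: with the small number of protocol levels
typical of these designs, a variance component is weakly identified and
a fixed effect is the stable choice. Where protocol correlates with the
repertoire PCs, `residualize_pcs()` regresses protocol out of the PCs
first, leaving covariates orthogonal to the protocol indicators.

# Survival

`carrier_status()` flags individuals with at least one HLA-matched clone
at the chosen timepoints; `km_estimate()` / `logrank_test()` (backed by
the survival package) compare carriers with non-carriers. At tied times
events precede censorings — the product-limit convention, stated for
bit-reproducibility. Cox modelling is deliberately out of scope; the
comparison of record is the log-rank test.

# The synthetic cohort

`simulate_cohort()` generates the full study under one seed. Design
choices, and what they do and do not emulate:

* **Repertoire sampling.** Clone counts per V-gene are multinomial with
  log-weights = conserved gene baseline + per-feature batch offsets +
  planted cis/trans effects x dosage + individual noise; multiplicities
  are geometric (the empirical clone-size law is unknown to us; geometric
  is a configurable stand-in). CDR3s are germline-like: conserved
  prefix, random core, conserved J-style suffix, lengths 10–20 with 90%
  of mass on 12–18. The conserved termini give the k-mer feature space
  its realistic recurrent backbone; what is *not* emulated is antigen-
  driven convergent selection of full CDR3s.
* **Calibration.** Individual noise SD defaults to 0.9 so that, with
  typical planted effects and counting noise, the latent log-scale trait
  variance is near 1 — making a planted coefficient directly readable on
  the INRT scale, which is what the recovery studies measure. This was
  chosen from the variance budget, not fitted.
* **HLA.** A hand-written catalogue: genes A/B/C, four 2-digit families
  x two 4-digit alleles each, with a residue table covering biallelic
  and multiallelic positions (including one 4-digit split, B*44:02 vs
  B*44:03 at position 156) so both resolutions and the omnibus test are
  exercised. Frequencies are configurable; the defaults are synthetic,
  not population estimates.
* **Persistence.** Per-clone Bernoulli, size-ignored, with clone-level
  beta-distributed heterogeneity (mean = baseline 0.15, concentration
  0.6; HLA-matched clones get mean x multiplier, default 0.6). The
  heterogeneity is what makes persistent clones preferentially
  redetectable at a later cycle — redetection ~0.68 for persistent vs
  ~0.06 for unstable clones in expectation under the defaults — the
  qualitative signature of real longitudinal repertoires.
* **Single cells** are drawn per clone with geometric expansion weights;
  each beta clone has a fixed alpha partner so cells of a clone share
  both chains. Matched cells receive a mean shift of
  `trs_shift`/sqrt(20) per panel gene, i.e. `trs_shift` standardised
  units on the summed score. Planted QC failures (low depth, high
  mitochondrial fraction, aberrant chain counts) exercise the filters.
* **Survival** is exponential with carrier hazard = baseline x hazard
  ratio and uniform censoring — no covariate-dependent hazards.

Because all of this is synthetic, green calibration studies demonstrate
that the *pipeline* is correct and powered under its stated model; they
do not certify performance on real repertoires, where clone identity
error, sampling depth variation and LD structure are richer.

# Problem sizes in the shipped studies

The calibration studies (`recover_vgene_effects()`,
`recover_kmer_effect()`, `fwer_study()`, `trs_recovery_study()`,
`dynamics_ordering_study()`, `survival_power_study()`) default to the
sizes we consider informative at desk scale: 250 individuals and 1500
clones/sample for V-gene recovery (50 seeds); 800 clones/sample with a
0.2 recurrence filter for 7-mer recovery; 100 individuals x 200 variants
x 20 features x B = 200 over 200 replicates for FWER; 5000 cells for TRS
recovery with matched-cell prevalence in the 10–20% range typical of
matched-clone proportions; 100 seeds at hazard ratio 0.5, n = 200 for
survival power. Deeper repertoires tighten recovery (counting noise
scales as one over the per-gene clone count) but cost linearly in time.

# Known limitations

* Amino-acid clone identity merges nucleotide-distinct rearrangements;
  traits are slightly conservative relative to nucleotide-keyed counts.
* The permutation null fixes covariates with genotypes; a
  Freedman–Lane-style residual permutation is not currently implemented.
* Protocol as a fixed effect; a variance-component option is future
  work.
* `min_prevalence = 0` on large cohorts materialises the full private-
  motif tail and is only sensible on small fixtures.
* The generator plants effects on single features; polygenic repertoire
  architectures and LD between variants are not simulated (the
  conditional-analysis studies construct LD explicitly where needed).
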