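#' Calibration and power studies
#'
#' Re-usable Monte-Carlo harnesses that run the full analysis path on
#' synthetic cohorts: planted-effect recovery (cis SNP, trans HLA, CDR3
#' motif), family-wise error calibration of the permutation threshold,
#' TRS-shift recovery, clone-dynamics ordering and survival power. These
#' back the package's acceptance checks and are the recommended way to
#' gauge what the design can detect at a given sample size.
#'
#' @name calibration
NULL

# covariate table with the standard model terms: age, sex, cancer type,
# two genotype PCs, two repertoire PCs
#' @noRd
.assemble_covariates <- function(cohort, corrected) {
  gp <- genetic_pcs(cohort$genotypes, 2)
  colnames(gp) <- c("genetic_pc1", "genetic_pc2")
  tp <- tcr_pcs(corrected, 2)
  colnames(tp) <- c("tcr_pc1", "tcr_pc2")
  ids <- rownames(corrected$values)
  cbind(cohort$covariates[match(ids, cohort$covariates$individual_id),
                          c("individual_id", "age", "sex", "cancer_type")],
        gp[ids, , drop = FALSE], tp[ids, , drop = FALSE])
}

#' Recover planted cis and trans effects on V-gene usage
#'
#' Per seed, simulates a cohort with one cis (SNP dosage) and one trans
#' (classical HLA allele dosage) effect planted on distinct beta-chain
#' V-genes, builds the full phenotype (TMM, CPM, batch correction, INRT)
#' and fits the standard covariate-adjusted additive model at the causal
#' predictor.
#'
#' @param n_seeds number of Monte-Carlo seeds.
#' @param beta planted effect size (latent log scale).
#' @param maf minor-allele frequency of the causal SNP.
#' @param n cohort size.
#' @param depth clones per sample.
#' @param seed0 base seed; seed i is seed0 + i.
#' @return data frame (seed, beta_cis, beta_trans).
#' @export
recover_vgene_effects <- function(n_seeds = 50, beta = 0.5, maf = 0.3,
                                  n = 250, depth = 1500, seed0 = 1000L) {
  out <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(
      n_individuals = n, n_variants = 20, maf_range = c(maf, maf),
      clones_per_sample = depth, chains = "beta", timepoints = "C1",
      with_cells = FALSE, with_survival = FALSE,
      cis_effects = data.frame(variant = "var00003", v_gene = "TRBV7",
                               beta = beta),
      trans_effects = data.frame(hla_allele = "B*44", v_gene = "TRBV19",
                                 beta = beta),
      seed = seed0 + i)
    co <- simulate_cohort(cfg)
    counts <- count_vgene_usage(co$clones, "beta", "C1")
    batch <- setNames(co$covariates$batch, co$covariates$individual_id)
    ph <- phenotype_pipeline(counts, batch = batch)
    cov_df <- .assemble_covariates(co, ph$corrected)
    ids <- rownames(ph$inrt$values)
    b_cis <- fit_additive(ph$inrt$values[, "TRBV7"],
                          co$genotypes$dosage[ids, "var00003"], cov_df)$beta
    b_trans <- fit_additive(ph$inrt$values[, "TRBV19"],
                            co$hla$allele_dosage[ids, "B*44"], cov_df)$beta
    data.frame(seed = seed0 + i, beta_cis = b_cis, beta_trans = b_trans)
  })
  do.call(rbind, out)
}

#' Recover a planted HLA -> CDR3 7-mer effect
#'
#' As [recover_vgene_effects()] but the trait is the motif's unique-clone
#' count after the k-mer phenotype pipeline; the prevalence filter keeps
#' the recurrent-motif feature space that the analysis targets.
#'
#' @param n_seeds,beta,n,seed0 as in [recover_vgene_effects()].
#' @param depth clones per sample.
#' @param min_prevalence recurrence filter for the k-mer feature space.
#' @return data frame (seed, beta_kmer).
#' @export
recover_kmer_effect <- function(n_seeds = 50, beta = 0.5, n = 250,
                                depth = 800, min_prevalence = 0.2,
                                seed0 = 2000L) {
  motif <- "TGDSNQP"
  out <- vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(
      n_individuals = n, n_variants = 20, clones_per_sample = depth,
      chains = "beta", timepoints = "C1",
      with_cells = FALSE, with_survival = FALSE,
      kmer_effects = data.frame(hla_allele = "B*44", motif = motif,
                                beta = beta),
      seed = seed0 + i)
    co <- simulate_cohort(cfg)
    counts <- count_kmers(co$clones, "beta", "C1",
                          min_prevalence = min_prevalence)
    batch <- setNames(co$covariates$batch, co$covariates$individual_id)
    ph <- phenotype_pipeline(counts, batch = batch)
    # repertoire PCs come from V-gene usage, as in the V-gene scans
    vg <- phenotype_pipeline(count_vgene_usage(co$clones, "beta", "C1"),
                             batch = batch)
    cov_df <- .assemble_covariates(co, vg$corrected)
    ids <- rownames(ph$inrt$values)
    fit_additive(ph$inrt$values[, motif],
                 co$hla$allele_dosage[ids, "B*44"], cov_df)$beta
  }, numeric(1))
  data.frame(seed = seed0 + seq_len(n_seeds), beta_kmer = out)
}

#' Family-wise error calibration of the permutation threshold
#'
#' Per replicate, simulates a null cohort (no planted effects), derives
#' the permutation threshold from B phenotype-row permutations, and
#' records whether any real-scan p-value falls below it. The hit rate
#' estimates the FWER at the chosen alpha.
#'
#' @param n_reps outer Monte-Carlo replicates.
#' @param n,n_variants,n_features,depth cohort dimensions.
#' @param B permutations per replicate.
#' @param alpha family-wise error target.
#' @param seed0 base seed.
#' @return logical vector of length n_reps (TRUE = at least one hit).
#' @export
fwer_study <- function(n_reps = 200, n = 100, n_variants = 200,
                       n_features = 20, depth = 400, B = 200,
                       alpha = 0.05, seed0 = 3000L) {
  vapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(
      n_individuals = n, n_variants = n_variants,
      clones_per_sample = depth, n_vgenes_beta = n_features,
      chains = "beta", timepoints = "C1",
      with_cells = FALSE, with_survival = FALSE, seed = seed0 + i)
    co <- simulate_cohort(cfg)
    counts <- count_vgene_usage(co$clones, "beta", "C1")
    batch <- setNames(co$covariates$batch, co$covariates$individual_id)
    ph <- phenotype_pipeline(counts, batch = batch)
    cov_df <- .assemble_covariates(co, ph$corrected)
    scan <- assoc_scan(ph$inrt, co$genotypes, cov_df)
    null <- permutation_threshold(ph$inrt, co$genotypes, cov_df, B = B,
                                  alpha = alpha, seed = seed0 + i)
    min(scan$p, na.rm = TRUE) < null$threshold
  }, logical(1))
}

#' Recover a planted TRS shift between HLA-matched and unmatched cells
#'
#' Per seed, simulates the single-cell table with a planted matched-cell
#' TRS shift, applies cell QC, computes the TRS and fits the nested-model
#' comparison; returns the matching-status coefficient.
#'
#' @param n_seeds Monte-Carlo seeds.
#' @param shift planted standardised TRS difference.
#' @param n_cells approximate number of cells in the analysis set.
#' @param seed0 base seed.
#' @return data frame (seed, beta).
#' @export
trs_recovery_study <- function(n_seeds = 50, shift = 0.3, n_cells = 5000,
                               seed0 = 4000L) {
  n_ind <- 25
  # enough V-gene/allele pairs that matched cells sit in the 10-20%
  # prevalence range typical of matched-clone proportions
  rules <- data.frame(
    hla_allele = c("B*44", "A*02", "B*35", "A*01", "C*04"),
    v_gene = c("TRBV19", "TRBV12", "TRBV28", "TRBV9", "TRBV5"), beta = 0.7)
  out <- vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(
      n_individuals = n_ind, n_variants = 10, clones_per_sample = 400,
      trans_effects = rules,
      trs_shift = shift, timepoints = "C1", with_survival = FALSE,
      n_sc_individuals = n_ind,
      n_cells_per_individual = ceiling(n_cells / n_ind),
      seed = seed0 + i)
    co <- simulate_cohort(cfg)
    cells <- qc_cells(co$cells)
    trs <- compute_trs(cells, default_trs_panel())
    match_st <- cell_match_status(cells, co$truth$rules, co$hla)
    trs_vs_matching(trs, match_st, cells$protocol)$beta
  }, numeric(1))
  data.frame(seed = seed0 + seq_len(n_seeds), beta = out)
}

#' Clone-dynamics ordering under HLA-dependent persistence
#'
#' Per seed, simulates paired C1/C2 repertoires with an HLA-matched
#' persistence multiplier below 1 and asks whether the unstable group's
#' median HLA-matched proportion exceeds the persistent group's.
#'
#' @param n_seeds Monte-Carlo seeds.
#' @param matched_multiplier persistence multiplier for matched clones.
#' @param n cohort size.
#' @param depth clones per sample.
#' @param seed0 base seed.
#' @return data frame (seed, median_unstable, median_persistent).
#' @export
dynamics_ordering_study <- function(n_seeds = 50, matched_multiplier = 0.6,
                                    n = 60, depth = 600, seed0 = 5000L) {
  rules <- data.frame(
    hla_allele = c("B*44", "A*02", "B*35"),
    v_gene = c("TRBV19", "TRBV12", "TRBV28"), beta = 0.5)
  out <- lapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(
      n_individuals = n, n_variants = 10, clones_per_sample = depth,
      chains = "beta", timepoints = c("C1", "C2"),
      trans_effects = rules,
      persistence = list(baseline = 0.15,
                         matched_multiplier = matched_multiplier,
                         concentration = 0.6),
      with_cells = FALSE, with_survival = FALSE, seed = seed0 + i)
    co <- simulate_cohort(cfg)
    prod <- co$clones[co$clones$productive, ]
    labels <- classify_clones(prod[prod$timepoint == "C1", ],
                              prod[prod$timepoint == "C2", ])
    meds <- vapply(c("unstable", "persistent"), function(gp) {
      pr <- hla_matched_proportion(labels[labels$group == gp, ],
                                   co$truth$rules, co$hla)
      median(pr$prop)
    }, numeric(1))
    data.frame(seed = seed0 + i, median_unstable = meds[["unstable"]],
               median_persistent = meds[["persistent"]])
  })
  do.call(rbind, out)
}

#' Log-rank power under a carrier survival benefit
#'
#' Per seed, assigns carrier status to half the cohort, simulates
#' exponential survival with the given hazard ratio and light censoring,
#' and records the log-rank p-value.
#'
#' @param n_seeds Monte-Carlo seeds.
#' @param hazard_ratio carrier hazard multiplier.
#' @param n cohort size.
#' @param seed0 base seed.
#' @return numeric vector of log-rank p-values.
#' @export
survival_power_study <- function(n_seeds = 100, hazard_ratio = 0.5,
                                 n = 200, seed0 = 6000L) {
  vapply(seq_len(n_seeds), function(i) {
    set.seed(seed0 + i)
    carrier <- setNames(sample(rep(c(TRUE, FALSE), n / 2)),
                        sprintf("I%04d", seq_len(n)))
    rec <- simulate_survival(carrier, hazard_ratio, seed = seed0 + i,
                             baseline_hazard = 1 / 730, censor_max = 3650)
    logrank_test(rec)$p
  }, numeric(1))
}
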