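#' End-to-end pipeline driver
#'
#' Replays the whole analysis on a simulated cohort: simulate -> write /
#' re-read tables -> genotype QC -> phenotypes -> genome-wide and
#' HLA-focused scans with permutation thresholds -> omnibus tests ->
#' k-mer scan -> clone dynamics -> single-cell TRS -> survival. Every
#' stage logs counts in/out and any failure halts with a stage-tagged
#' error; a manifest records the config, seeds, versions and per-file
#' checksums so a rerun can be verified byte-for-byte.
#'
#' @name cli_config
NULL

#' Assemble a pipeline configuration
#'
#' @param sim a [sim_config()].
#' @param B permutations for the significance threshold.
#' @param alpha family-wise error target.
#' @param kmer_min_prevalence prevalence filter for k-mer features.
#' @param rule_p_threshold p threshold for extracting match rules from the
#'   HLA scan; NULL (default) uses the beta-chain HLA-scan permutation
#'   threshold, so rules come only from significantly associated V-genes.
#' @param survival_timepoints timepoints defining clone carriage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), B = 200, alpha = 0.05,
                            kmer_min_prevalence = 0.05,
                            rule_p_threshold = NULL,
                            survival_timepoints = c("C1", "C2")) {
  structure(list(sim = sim, B = B, alpha = alpha,
                 kmer_min_prevalence = kmer_min_prevalence,
                 rule_p_threshold = rule_p_threshold,
                 survival_timepoints = survival_timepoints),
            class = "pipeline_config")
}

#' @noRd
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' @noRd
.write_tsv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory for all stage TSVs and the manifest.
#' @param quiet suppress per-stage log lines.
#' @return invisibly, list(manifest, results) where results holds the
#'   in-memory stage outputs.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  files <- character(0)
  results <- list()

  cohort <- .stage("simulate", simulate_cohort(config$sim))
  log_("simulate: %d individuals, %d clone rows",
       nrow(cohort$genotypes$dosage), nrow(cohort$clones))

  files["clones"] <- .write_tsv(cohort$clones, outdir, "clones.tsv")
  files["dosage"] <- .stage("write", {
    write_dosage_matrix(cohort$genotypes, file.path(outdir, "dosage.tsv"))
  })
  files["hla"] <- write_hla_table(cohort$hla, file.path(outdir, "hla.tsv"),
                                  file.path(outdir, "hla_residues.tsv"))
  files["covariates"] <- .write_tsv(cohort$covariates, outdir, "covariates.tsv")
  if (!is.null(cohort$survival)) {
    files["survival"] <- .write_tsv(cohort$survival, outdir, "survival.tsv")
  }

  # read back through the validating readers: the analysis consumes what
  # a real run would load from disk
  clones <- .stage("read", read_clone_table(files[["clones"]]))
  genotypes <- .stage("read", read_dosage_matrix(files[["dosage"]]))
  hla <- .stage("read", read_hla_table(files[["hla"]],
                                       file.path(outdir, "hla_residues.tsv")))
  covariates <- .stage("read", read_covariates(files[["covariates"]]))

  sq <- .stage("sample_qc", sample_qc(genotypes))
  vq <- .stage("variant_qc", variant_qc(sq$genotypes))
  genotypes <- vq$genotypes
  log_("qc: %d samples dropped, %d variants dropped; %d variants remain",
       nrow(sq$report$dropped_samples), nrow(vq$report$dropped_variants),
       ncol(genotypes$dosage))
  qc_tab <- rbind(
    data.frame(level = rep("sample", nrow(sq$report$dropped_samples)),
               sq$report$dropped_samples),
    data.frame(level = rep("variant", nrow(vq$report$dropped_variants)),
               vq$report$dropped_variants))
  files["qc_report"] <- .write_tsv(qc_tab, outdir, "qc_report.tsv")

  gpcs <- .stage("genetic_pcs", genetic_pcs(genotypes, 2))
  ids <- intersect_individuals(genotypes = rownames(genotypes$dosage),
                               clones = unique(clones$individual_id),
                               covariates = covariates$individual_id)

  scans <- list()
  thresholds <- list()
  for (chain in .CHAINS) {
    counts <- .stage("phenotype", count_vgene_usage(
      clones, chain, "C1", individuals = ids))
    batch <- setNames(covariates$batch, covariates$individual_id)[ids]
    ph <- .stage("phenotype", phenotype_pipeline(counts, batch = batch))
    tpcs <- .stage("phenotype", tcr_pcs(ph$corrected, 2))
    colnames(tpcs) <- c("tcr_pc1", "tcr_pc2")
    colnames(gpcs) <- c("genetic_pc1", "genetic_pc2")
    cov_df <- cbind(
      covariates[match(ids, covariates$individual_id),
                 c("individual_id", "age", "sex", "cancer_type")],
      gpcs[ids, , drop = FALSE], tpcs[ids, , drop = FALSE])
    results[[paste0("covariates_", chain)]] <- cov_df

    scan <- .stage("scan", assoc_scan(ph$inrt, genotypes, cov_df))
    null <- .stage("permute", permutation_threshold(
      ph$inrt, genotypes, cov_df, B = config$B, alpha = config$alpha,
      seed = config$sim$seed + 100L))
    log_("%s scan: %d tests, permutation threshold %.3g",
         chain, nrow(scan), null$threshold)
    files[paste0("scan_", chain)] <- .write_tsv(
      scan, outdir, paste0("scan_", chain, ".tsv"))
    files[paste0("null_", chain)] <- .write_tsv(
      data.frame(min_p = null$min_p), outdir,
      paste0("permutation_null_", chain, ".tsv"))
    scans[[chain]] <- scan
    thresholds[[chain]] <- null
    results[[paste0("scan_", chain)]] <- scan
    results[[paste0("null_", chain)]] <- null
    results[[paste0("phenotypes_", chain)]] <- ph

    hla_scan <- .stage("hla_scan", assoc_scan(
      ph$inrt, hla$allele_dosage, cov_df))
    files[paste0("hla_scan_", chain)] <- .write_tsv(
      hla_scan, outdir, paste0("hla_scan_", chain, ".tsv"))
    results[[paste0("hla_scan_", chain)]] <- hla_scan
    results[[paste0("hla_null_", chain)]] <- .stage(
      "permute", permutation_threshold(
        ph$inrt, hla$allele_dosage, cov_df, B = config$B,
        alpha = config$alpha, seed = config$sim$seed + 200L))
  }

  # omnibus tests at every mapped amino-acid position, for the beta-chain
  # feature with the strongest HLA signal
  hs <- results$hla_scan_beta
  top_feat <- hs$feature[which.min(hs$p)]
  ph_beta <- results$phenotypes_beta$inrt
  cov_beta <- results$covariates_beta
  pos_tab <- unique(hla$residue_map[, c("gene", "exon", "position")])
  omni <- do.call(rbind, lapply(seq_len(nrow(pos_tab)), function(i) {
    rd <- hla_residue_dosages(hla, pos_tab$gene[i], pos_tab$exon[i],
                              pos_tab$position[i])[ids, , drop = FALSE]
    r <- omnibus_position_test(ph_beta$values[ids, top_feat], rd, cov_beta,
                               feature = top_feat,
                               predictor = sprintf("%s_ex%d_pos%d",
                                                   pos_tab$gene[i],
                                                   pos_tab$exon[i],
                                                   pos_tab$position[i]))
    r
  }))
  files["omnibus"] <- .write_tsv(omni, outdir, "omnibus.tsv")
  results$omnibus <- omni

  kmer_counts <- .stage("kmer", count_kmers(
    clones, "beta", "C1", min_prevalence = config$kmer_min_prevalence,
    individuals = ids))
  if (ncol(kmer_counts$values) >= 2) {
    kph <- .stage("kmer", phenotype_pipeline(
      kmer_counts, batch = setNames(covariates$batch,
                                    covariates$individual_id)[ids]))
    kscan <- .stage("kmer_scan", kmer_hla_scan(
      kph$inrt, hla$allele_dosage, results$covariates_beta))
    files["kmer_scan"] <- .write_tsv(kscan, outdir, "kmer_scan.tsv")
    results$kmer_scan <- kscan
    log_("kmer scan: %d motifs x %d alleles", ncol(kph$inrt$values),
         ncol(hla$allele_dosage))
  }

  rule_thr <- if (is.null(config$rule_p_threshold)) {
    results$hla_null_beta$threshold
  } else {
    config$rule_p_threshold
  }
  rules <- .stage("rules", top_allele_rules(results$hla_scan_beta, rule_thr))
  files["rules"] <- .write_tsv(rules, outdir, "match_rules.tsv")
  results$rules <- rules

  if (all(c("C1", "C2") %in% config$sim$timepoints)) {
    prod <- clones[clones$productive, ]
    labels <- .stage("dynamics", classify_clones(
      prod[prod$timepoint == "C1", ], prod[prod$timepoint == "C2", ]))
    props <- do.call(rbind, lapply(
      c("unstable", "novel", "persistent"), function(gp) {
        sub <- labels[labels$group == gp & labels$chain == "beta", ]
        pr <- hla_matched_proportion(sub, rules, hla)
        if (nrow(pr) > 0) pr$group <- gp
        pr
      }))
    files["matched_props"] <- .write_tsv(props, outdir,
                                         "matched_proportions.tsv")
    results$matched_proportions <- props
    wide <- merge(props[props$group == "unstable", c("individual_id", "prop")],
                  props[props$group == "novel", c("individual_id", "prop")],
                  by = "individual_id", suffixes = c("_unstable", "_novel"))
    if (nrow(wide) >= 6) {
      results$wilcoxon_unstable_vs_novel <- paired_wilcoxon(
        wide$prop_unstable, wide$prop_novel)
      log_("dynamics: unstable vs novel matched proportion, p = %.3g",
           results$wilcoxon_unstable_vs_novel$p)
    }
    if ("C4" %in% config$sim$timepoints) {
      resamp <- resampling_proportions(
        labels, prod[prod$timepoint == "C4", ])
      files["resampling"] <- .write_tsv(resamp, outdir, "resampling.tsv")
      results$resampling <- resamp
    }
  }

  if (!is.null(cohort$cells)) {
    cells <- .stage("cells", qc_cells(cohort$cells))
    trs <- .stage("trs", compute_trs(cells, .TRS_PANEL))
    match_st <- cell_match_status(cells, rules, hla)
    strata <- .stage("trs", trs_strata(cells, trs, match_st, cells$protocol))
    files["trs"] <- .write_tsv(strata, outdir, "trs_results.tsv")
    results$trs <- strata
    log_("trs: %d cells pass QC, %d strata", nrow(cells), nrow(strata))
  }

  if (!is.null(cohort$survival)) {
    carrier <- .stage("survival", carrier_status(
      clones, config$survival_timepoints, rules, hla,
      individuals = cohort$survival$individual_id))
    surv <- cohort$survival
    surv$group <- ifelse(carrier[surv$individual_id] == 1,
                         "carrier", "non-carrier")
    surv <- surv[!is.na(surv$group), ]
    if (length(unique(surv$group)) == 2 && sum(surv$event) > 0) {
      lr <- .stage("survival", logrank_test(surv))
      results$logrank <- lr
      log_("survival: log-rank chi2 = %.2f, p = %.3g", lr$chi2, lr$p)
    }
    km <- do.call(rbind, lapply(split(surv, surv$group), function(s) {
      k <- km_estimate(s)
      k$group <- s$group[1]
      k
    }))
    files["km"] <- .write_tsv(km, outdir, "km_curves.tsv")
    results$km <- km
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("repqtl")),
    r_version = R.version.string,
    seed = config$sim$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(B = config$B, alpha = config$alpha,
                  n_individuals = config$sim$n_individuals,
                  n_variants = config$sim$n_variants,
                  clones_per_sample = config$sim$clones_per_sample),
    checksums = as.list(tools::md5sum(unname(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, results = results, files = files))
}
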