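#' Synthetic cohort generation
#'
#' A seeded generator for a full repertoire-genetics study: genotypes, HLA
#' haplotypes, paired pre/post-treatment (and later-cycle) CD8+ clone
#' tables, covariates, single-cell tables with a tumour-reactivity gene
#' panel, and overall-survival records. Effects are planted on the latent
#' log scale of clone-formation propensity so that, after the standard
#' phenotype pipeline (unique-clone counting, TMM/CPM, batch correction,
#' inverse normal transformation), a planted coefficient is directly
#' comparable to the regression estimate that recovers it.
#'
#' @name synthetic_cohort
NULL

# CDR3s are built as germline-like prefix + random core + J-segment-like
# suffix; the conserved termini create recurrent 7-mers across individuals,
# as in real repertoires, so the k-mer feature space is non-degenerate.
.CDR3_PREFIX <- list(
  alpha = c("CAVR", "CAGG", "CALS", "CAAS"),
  beta  = c("CASS", "CASR", "CSAR", "CAST"))
.CDR3_SUFFIX <- list(
  alpha = c("GNKLTF", "YGGSQGNLIF", "NTGKLIF", "AGNMLTF", "SGGYQKVTF",
            "NDYKLSF", "GGGNKLTF"),
  beta  = c("NYGYTF", "YNEQFF", "ETQYF", "NTEAFF", "SYEQYF", "QPQHF",
            "GNTIYF", "YGYTF", "NQPQHF"))

# synthetic 20-gene tumour-reactivity panel (plausible exhaustion /
# reactivity markers; the real panel is a user input in applied analyses)
.TRS_PANEL <- c("ENTPD1", "ITGAE", "PDCD1", "CTLA4", "HAVCR2", "LAG3",
                "TIGIT", "TNFRSF9", "TOX", "CXCL13", "GZMB", "PRF1",
                "IFNG", "TNFRSF18", "CD27", "ICOS", "BATF", "RBPJ",
                "DUSP4", "CCL3")

#' Synthetic tumour-reactivity gene panel
#'
#' The 20 gene names used by the simulated single-cell tables. In applied
#' analyses the panel is a user input; this synthetic stand-in uses
#' plausible exhaustion/reactivity marker symbols.
#'
#' @return character vector of 20 gene names.
#' @export
default_trs_panel <- function() .TRS_PANEL

#' Default classical HLA catalogue for simulation
#'
#' A small class I catalogue (genes A, B, C; four 2-digit families per gene,
#' two 4-digit alleles each) with a hand-written residue table at a few
#' polymorphic positions, enough to exercise 2-/4-digit association and the
#' amino-acid omnibus test. This is a synthetic catalogue, not population
#' reference frequencies.
#'
#' @return list with `freqs` (per gene, named 4-digit allele frequencies)
#'   and `residue_map` (data frame gene/exon/position/allele/residue).
#' @export
default_hla_catalogue <- function() {
  freqs <- list(
    A = c("A*01:01" = 0.20, "A*01:02" = 0.05, "A*02:01" = 0.25,
          "A*02:05" = 0.05, "A*03:01" = 0.15, "A*03:02" = 0.05,
          "A*24:02" = 0.15, "A*24:03" = 0.10),
    B = c("B*07:02" = 0.15, "B*07:05" = 0.05, "B*08:01" = 0.15,
          "B*08:02" = 0.05, "B*35:01" = 0.15, "B*35:02" = 0.05,
          "B*44:02" = 0.25, "B*44:03" = 0.15),
    C = c("C*03:03" = 0.20, "C*03:04" = 0.10, "C*04:01" = 0.20,
          "C*04:03" = 0.05, "C*05:01" = 0.20, "C*05:09" = 0.05,
          "C*07:01" = 0.15, "C*07:02" = 0.05))
  # residues per position: distinguish 2-digit families, with one 4-digit
  # split (B*44:02 vs B*44:03 at position 156) so both resolutions matter
  rm_rows <- list(
    c("A", 2, 74, "A*01:01", "D"), c("A", 2, 74, "A*01:02", "D"),
    c("A", 2, 74, "A*02:01", "H"), c("A", 2, 74, "A*02:05", "H"),
    c("A", 2, 74, "A*03:01", "D"), c("A", 2, 74, "A*03:02", "D"),
    c("A", 2, 74, "A*24:02", "Q"), c("A", 2, 74, "A*24:03", "Q"),
    c("A", 2, 97, "A*01:01", "R"), c("A", 2, 97, "A*01:02", "I"),
    c("A", 2, 97, "A*02:01", "R"), c("A", 2, 97, "A*02:05", "R"),
    c("A", 2, 97, "A*03:01", "I"), c("A", 2, 97, "A*03:02", "I"),
    c("A", 2, 97, "A*24:02", "M"), c("A", 2, 97, "A*24:03", "M"),
    c("B", 2, 45, "B*07:02", "E"), c("B", 2, 45, "B*07:05", "E"),
    c("B", 2, 45, "B*08:01", "E"), c("B", 2, 45, "B*08:02", "E"),
    c("B", 2, 45, "B*35:01", "K"), c("B", 2, 45, "B*35:02", "K"),
    c("B", 2, 45, "B*44:02", "K"), c("B", 2, 45, "B*44:03", "K"),
    c("B", 2, 156, "B*07:02", "L"), c("B", 2, 156, "B*07:05", "L"),
    c("B", 2, 156, "B*08:01", "W"), c("B", 2, 156, "B*08:02", "W"),
    c("B", 2, 156, "B*35:01", "L"), c("B", 2, 156, "B*35:02", "R"),
    c("B", 2, 156, "B*44:02", "D"), c("B", 2, 156, "B*44:03", "L"),
    c("C", 2, 99, "C*03:03", "S"), c("C", 2, 99, "C*03:04", "S"),
    c("C", 2, 99, "C*04:01", "Y"), c("C", 2, 99, "C*04:03", "Y"),
    c("C", 2, 99, "C*05:01", "S"), c("C", 2, 99, "C*05:09", "S"),
    c("C", 2, 99, "C*07:01", "Y"), c("C", 2, 99, "C*07:02", "Y"))
  rmap <- do.call(rbind, lapply(rm_rows, function(r) {
    data.frame(gene = r[1], exon = as.integer(r[2]),
               position = as.integer(r[3]), allele = r[4], residue = r[5],
               stringsAsFactors = FALSE)
  }))
  list(freqs = freqs, residue_map = rmap)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic study. Defaults describe the study
#' conditions the package is built around: 250 individuals, V-gene counts
#' of 42 (alpha) and 47 (beta), thousands of clones per sample with
#' geometric clone sizes, latent inter-individual log-propensity noise of
#' SD 0.9 (so total log-scale trait variance sits near 1 and planted betas
#' read on the INRT scale), clone-level beta-distributed persistence with a
#' sub-unity multiplier for HLA-matched clones, and a survival benefit for
#' carriers of HLA-matched clones.
#'
#' @param n_individuals cohort size (>= 2).
#' @param n_variants number of genome-wide SNPs.
#' @param maf_range range of simulated minor-allele frequencies, in (0, 0.5].
#' @param n_vgenes_alpha,n_vgenes_beta V-gene counts per chain.
#' @param clones_per_sample unique clones sampled per individual, chain and
#'   timepoint.
#' @param clone_size_geom_p geometric parameter for clone multiplicity
#'   (count = 1 + Geom(p)).
#' @param cis_effects data frame (variant, v_gene, beta): SNP dosage effects
#'   on log clone-formation propensity.
#' @param trans_effects data frame (hla_allele, v_gene, beta): classical HLA
#'   allele dosage effects; these pairs also define HLA-matched clones.
#' @param kmer_effects data frame (hla_allele, motif, beta); motifs must be
#'   7 residues.
#' @param persistence list(baseline, matched_multiplier, concentration):
#'   mean clone persistence probability, multiplier applied for HLA-matched
#'   clones, and beta-distribution concentration for clone-level
#'   heterogeneity.
#' @param trs_shift mean TRS difference (standardised units) planted for
#'   HLA-matched cells.
#' @param survival_hazard_ratio hazard multiplier for carriers of
#'   HLA-matched clones (< 1 means carriers live longer).
#' @param noise_sd SD of latent per-individual log-propensity noise (shared
#'   by V-gene and motif traits).
#' @param motif_base_rate baseline per-clone probability of carrying a
#'   planted motif in a non-carrier individual.
#' @param n_batches,batch_effect_sd sequencing batches and the SD of their
#'   per-feature log-scale offsets.
#' @param unproductive_rate fraction of clone rows flagged non-productive.
#' @param chains which TCR chains to generate (default both).
#' @param timepoints subset of c("C1","C2","C4") to generate.
#' @param c4_fraction fraction of individuals with a C4 sample.
#' @param with_cells,with_survival generate the single-cell / survival
#'   tables.
#' @param n_sc_individuals,n_cells_per_individual single-cell cohort size
#'   and cells per individual.
#' @param second_alpha_rate fraction of cells with a second alpha chain.
#' @param sc_fail_rate fraction of cells planted to fail each QC filter
#'   (low transcripts, high mitochondrial fraction, aberrant chain count).
#' @param baseline_hazard,censor_max exponential event rate (per day) for
#'   non-carriers and the uniform-censoring horizon (days).
#' @param hla HLA catalogue as from [default_hla_catalogue()].
#' @param individual_ids optional explicit ids (must be unique).
#' @param seed integer seed; all randomness flows from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 250,
                       n_variants = 1000,
                       maf_range = c(0.05, 0.5),
                       n_vgenes_alpha = 42,
                       n_vgenes_beta = 47,
                       clones_per_sample = 2500,
                       clone_size_geom_p = 0.5,
                       cis_effects = NULL,
                       trans_effects = NULL,
                       kmer_effects = NULL,
                       persistence = list(baseline = 0.15,
                                          matched_multiplier = 0.6,
                                          concentration = 0.6),
                       trs_shift = 0.087,
                       survival_hazard_ratio = 0.6,
                       noise_sd = 0.9,
                       motif_base_rate = 0.02,
                       n_batches = 2,
                       batch_effect_sd = 0.3,
                       unproductive_rate = 0.03,
                       chains = c("alpha", "beta"),
                       timepoints = c("C1", "C2", "C4"),
                       c4_fraction = 0.425,
                       with_cells = TRUE,
                       with_survival = TRUE,
                       n_sc_individuals = 59,
                       n_cells_per_individual = 330,
                       second_alpha_rate = 0.08,
                       sc_fail_rate = 0.02,
                       baseline_hazard = 1 / 730,
                       censor_max = 1825,
                       hla = default_hla_catalogue(),
                       individual_ids = NULL,
                       seed = 1L) {
  empty_eff <- function(cols) {
    df <- as.data.frame(setNames(rep(list(character()), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df$beta <- numeric()
    df
  }
  if (is.null(cis_effects)) cis_effects <- empty_eff(c("variant", "v_gene"))
  if (is.null(trans_effects)) trans_effects <- empty_eff(c("hla_allele", "v_gene"))
  if (is.null(kmer_effects)) kmer_effects <- empty_eff(c("hla_allele", "motif"))
  cis_effects <- as.data.frame(cis_effects, stringsAsFactors = FALSE)
  trans_effects <- as.data.frame(trans_effects, stringsAsFactors = FALSE)
  kmer_effects <- as.data.frame(kmer_effects, stringsAsFactors = FALSE)

  if (n_individuals < 2) .stopf("n_individuals must be >= 2")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    .stopf("maf_range must lie in (0, 0.5]")
  }
  betas <- c(cis_effects$beta, trans_effects$beta, kmer_effects$beta)
  if (length(betas) > 0 && !all(is.finite(betas))) .stopf("all betas must be finite")
  if (nrow(kmer_effects) > 0 && any(nchar(kmer_effects$motif) != 7)) {
    .stopf("planted motifs must be exactly 7 residues")
  }
  probs <- c(persistence$baseline, motif_base_rate, unproductive_rate,
             c4_fraction, second_alpha_rate, sc_fail_rate)
  if (any(probs < 0 | probs > 1)) .stopf("probabilities must lie in [0, 1]")
  if (survival_hazard_ratio <= 0) .stopf("survival_hazard_ratio must be > 0")
  if (!is.null(individual_ids)) {
    if (anyDuplicated(individual_ids)) .stopf("duplicate individual identifiers")
    if (length(individual_ids) != n_individuals) {
      .stopf("individual_ids length != n_individuals")
    }
  }
  timepoints <- match.arg(timepoints, .TIMEPOINTS, several.ok = TRUE)
  chains <- match.arg(chains, .CHAINS, several.ok = TRUE)
  if (with_cells && length(chains) < 2) {
    .stopf("single-cell generation needs both chains (paired receptors)")
  }
  structure(as.list(environment())[setdiff(ls(), c("empty_eff", "betas",
                                                   "probs"))],
            class = "sim_config")
}

#' @noRd
.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# vectorised random CDR3s: germline-like prefix + random core + suffix,
# lengths concentrated on 12-18 with light 10/11 and 19/20 tails
#' @noRd
.random_cdr3 <- function(n, chain) {
  if (n == 0) return(character(0))
  pre <- sample(.CDR3_PREFIX[[chain]], n, replace = TRUE)
  suf <- sample(.CDR3_SUFFIX[[chain]], n, replace = TRUE)
  len_support <- 10:20
  len_w <- c(0.025, 0.025, rep(0.9 / 7, 7), 0.025, 0.025)
  lens <- integer(n)
  lo <- nchar(pre) + nchar(suf)
  for (l in unique(lo)) {
    sel <- which(lo == l)
    ok <- len_support >= l
    lens[sel] <- sample(len_support[ok], length(sel), replace = TRUE,
                        prob = len_w[ok])
  }
  m <- lens - lo
  total <- sum(m)
  core <- character(n)
  if (total > 0) {
    pool <- paste(sample(.AA_ALPHABET, total, replace = TRUE), collapse = "")
    ends <- cumsum(m)
    starts <- ends - m + 1
    has <- m > 0
    core[has] <- substring(pool, starts[has], ends[has])
  }
  paste0(pre, core, suf)
}

#' @noRd
.simulate_genotypes <- function(cfg, ids) {
  maf <- runif(cfg$n_variants, cfg$maf_range[1], cfg$maf_range[2])
  dosage <- matrix(rbinom(cfg$n_individuals * cfg$n_variants, 2,
                          rep(maf, each = cfg$n_individuals)),
                   nrow = cfg$n_individuals,
                   dimnames = list(ids, NULL))
  variants <- data.frame(
    id = sprintf("var%05d", seq_len(cfg$n_variants)),
    chrom = "7", pos = 142000000L + 1500L * seq_len(cfg$n_variants),
    ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage * 1.0, variants)
}

#' @noRd
.simulate_hla <- function(cfg, ids) {
  n <- cfg$n_individuals
  mats <- list()
  for (gene in names(cfg$hla$freqs)) {
    fr <- cfg$hla$freqs[[gene]]
    hap <- matrix(sample(names(fr), 2 * n, replace = TRUE, prob = fr), ncol = 2)
    four <- matrix(0L, n, length(fr), dimnames = list(ids, names(fr)))
    for (j in seq_along(fr)) {
      four[, j] <- (hap[, 1] == names(fr)[j]) + (hap[, 2] == names(fr)[j])
    }
    parent <- sub(":[^:]*$", "", colnames(four))
    two <- t(rowsum(t(four), parent))
    mats[[gene]] <- cbind(four, two)
  }
  hla_genotypes(do.call(cbind, mats), cfg$hla$residue_map)
}

# latent per-individual log-propensity over V-genes for one chain:
# conserved gene-level baseline + batch offsets + planted cis/trans effects
# + individual noise
#' @noRd
.latent_eta <- function(cfg, chain, vgenes, genotypes, hla, batch) {
  n <- cfg$n_individuals
  base <- rnorm(length(vgenes), 0, 1)
  batch_off <- matrix(rnorm(cfg$n_batches * length(vgenes), 0,
                            cfg$batch_effect_sd),
                      nrow = cfg$n_batches)
  eta <- matrix(base, n, length(vgenes), byrow = TRUE,
                dimnames = list(rownames(genotypes$dosage), vgenes))
  eta <- eta + batch_off[batch, , drop = FALSE]
  eff <- cfg$cis_effects
  for (i in seq_len(nrow(eff))) {
    if (eff$v_gene[i] %in% vgenes) {
      eta[, eff$v_gene[i]] <- eta[, eff$v_gene[i]] +
        eff$beta[i] * genotypes$dosage[, eff$variant[i]]
    }
  }
  eff <- cfg$trans_effects
  for (i in seq_len(nrow(eff))) {
    if (eff$hla_allele[i] %in% colnames(hla$allele_dosage) &&
        eff$v_gene[i] %in% vgenes) {
      eta[, eff$v_gene[i]] <- eta[, eff$v_gene[i]] +
        eff$beta[i] * hla$allele_dosage[, eff$hla_allele[i]]
    }
  }
  eta + matrix(rnorm(n * length(vgenes), 0, cfg$noise_sd), n)
}

# draws one timepoint's worth of new clones for every individual of one
# chain; returns a registry data frame (no multiplicity yet)
#' @noRd
.draw_clones <- function(cfg, chain, eta, ids, n_clones_per_ind) {
  counts <- vapply(seq_along(ids), function(i) {
    rmultinom(1, n_clones_per_ind[i], .softmax(eta[i, ]))[, 1]
  }, integer(ncol(eta)))
  total <- sum(counts)
  vg <- rep(rep(colnames(eta), length(ids)), as.vector(counts))
  ind <- rep(ids, colSums(counts))
  data.frame(individual_id = ind, chain = chain, v_gene = vg,
             cdr3_aa = .random_cdr3(total, chain),
             stringsAsFactors = FALSE)
}

# overwrite a random in-band window with each planted motif, per clone, at
# an individual rate increasing in beta x allele dosage
#' @noRd
.plant_motifs <- function(cfg, reg, hla, motif_noise) {
  eff <- cfg$kmer_effects
  for (i in seq_len(nrow(eff))) {
    chain <- if (!is.null(eff$chain)) eff$chain[i] else "beta"
    dos <- hla$allele_dosage[, eff$hla_allele[i]]
    rate <- pmin(0.5, cfg$motif_base_rate *
                   exp(eff$beta[i] * dos + motif_noise[, i]))
    L <- nchar(reg$cdr3_aa)
    elig <- which(reg$chain == chain & L >= 12 & L <= 18)
    if (length(elig) == 0) next
    p <- rate[match(reg$individual_id[elig], rownames(hla$allele_dosage))]
    sel <- elig[runif(length(elig)) < p]
    if (length(sel) == 0) next
    start <- 1L + floor(runif(length(sel)) * (nchar(reg$cdr3_aa[sel]) - 6L))
    substr(reg$cdr3_aa[sel], start, start + 6L) <- eff$motif[i]
  }
  reg
}

#' @noRd
.matched_clone <- function(reg, rules, hla) {
  if (nrow(rules) == 0) return(rep(FALSE, nrow(reg)))
  matched <- rep(FALSE, nrow(reg))
  for (i in seq_len(nrow(rules))) {
    carrier <- hla$allele_dosage[, rules$hla_allele[i]] >= 1
    matched <- matched | (reg$v_gene == rules$v_gene[i] &
                            carrier[match(reg$individual_id,
                                          rownames(hla$allele_dosage))])
  }
  matched
}

#' Simulate a full synthetic cohort
#'
#' Deterministic given `config$seed`. Clone counts per V-gene are drawn
#' from a multinomial whose log-weights combine a conserved baseline,
#' batch offsets, planted cis (SNP) and trans (HLA) effects and individual
#' noise; CDR3s are germline-like random peptides with planted 7-mer
#' motifs inserted at an HLA-dosage-dependent rate; later timepoints arise
#' from clone-level Bernoulli persistence with beta-distributed
#' heterogeneity and an HLA-matched multiplier, plus novel draws.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort` with elements genotypes, hla,
#'   clones, covariates, cells, survival, c4_individuals, truth (the
#'   planted effects) and config.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  ids <- if (!is.null(cfg$individual_ids)) cfg$individual_ids else
    sprintf("I%04d", seq_len(cfg$n_individuals))

  genotypes <- .simulate_genotypes(cfg, ids)
  hla <- .simulate_hla(cfg, ids)

  covariates <- data.frame(
    individual_id = ids,
    age = pmin(90, pmax(18, round(rnorm(cfg$n_individuals, 65, 10)))),
    sex = sample(c("M", "F"), cfg$n_individuals, replace = TRUE),
    cancer_type = sample(c("melanoma", "renal", "colorectal"),
                         cfg$n_individuals, replace = TRUE,
                         prob = c(0.924, 0.068, 0.008)),
    batch = sprintf("B%d", sample(cfg$n_batches, cfg$n_individuals,
                                  replace = TRUE)),
    stringsAsFactors = FALSE)
  batch_idx <- as.integer(sub("B", "", covariates$batch))

  rules <- unique(cfg$trans_effects[, c("v_gene", "hla_allele"), drop = FALSE])
  n_eff <- max(1L, nrow(cfg$kmer_effects))
  motif_noise <- matrix(rnorm(cfg$n_individuals * n_eff, 0, cfg$noise_sd),
                        cfg$n_individuals)

  pers <- cfg$persistence
  registries <- list()
  for (chain in cfg$chains) {
    vgenes <- paste0(.chain_prefix(chain),
                     seq_len(cfg[[paste0("n_vgenes_", chain)]]))
    eta <- .latent_eta(cfg, chain, vgenes, genotypes, hla, batch_idx)
    reg <- .draw_clones(cfg, chain, eta, ids,
                        rep(cfg$clones_per_sample, cfg$n_individuals))
    reg <- .plant_motifs(cfg, reg, hla, motif_noise)
    reg$matched <- .matched_clone(reg, rules, hla)
    mu <- ifelse(reg$matched,
                 pmin(0.99, pmax(0.01, pers$baseline * pers$matched_multiplier)),
                 pers$baseline)
    reg$rho <- rbeta(nrow(reg), mu * pers$concentration,
                     (1 - mu) * pers$concentration)
    reg$in_c1 <- TRUE
    reg$in_c2 <- FALSE
    reg$in_c4 <- FALSE

    if ("C2" %in% cfg$timepoints) {
      reg$in_c2 <- runif(nrow(reg)) < reg$rho
      kept <- tapply(reg$in_c2, reg$individual_id, sum)[ids]
      kept[is.na(kept)] <- 0
      novel_n <- pmax(0L, cfg$clones_per_sample - as.integer(kept))
      nov <- .draw_clones(cfg, chain, eta, ids, novel_n)
      nov <- .plant_motifs(cfg, nov, hla, motif_noise)
      nov$matched <- .matched_clone(nov, rules, hla)
      mu_n <- ifelse(nov$matched,
                     pmin(0.99, pmax(0.01, pers$baseline * pers$matched_multiplier)),
                     pers$baseline)
      nov$rho <- rbeta(nrow(nov), mu_n * pers$concentration,
                       (1 - mu_n) * pers$concentration)
      nov$in_c1 <- FALSE
      nov$in_c2 <- TRUE
      nov$in_c4 <- FALSE
      reg <- rbind(reg, nov)
    }
    registries[[chain]] <- reg
  }

  c4_ids <- character(0)
  if ("C4" %in% cfg$timepoints && "C2" %in% cfg$timepoints) {
    c4_ids <- sort(sample(ids, round(cfg$c4_fraction * length(ids))))
    for (chain in names(registries)) {
      reg <- registries[[chain]]
      in_c4_cohort <- reg$individual_id %in% c4_ids
      reg$in_c4 <- in_c4_cohort & (runif(nrow(reg)) < reg$rho)
      registries[[chain]] <- reg
    }
  }

  rows <- list()
  for (chain in names(registries)) {
    reg <- registries[[chain]]
    for (tp in cfg$timepoints) {
      keep <- switch(tp, C1 = reg$in_c1, C2 = reg$in_c2, C4 = reg$in_c4)
      if (!any(keep)) next
      sub <- reg[keep, c("individual_id", "chain", "v_gene", "cdr3_aa")]
      sub$timepoint <- tp
      sub$count <- 1L + rgeom(nrow(sub), cfg$clone_size_geom_p)
      sub$productive <- runif(nrow(sub)) >= cfg$unproductive_rate
      rows[[paste(chain, tp)]] <- sub
    }
  }
  clones <- do.call(rbind, rows)
  clones <- clones[, .CLONE_COLS]
  rownames(clones) <- NULL

  cells <- NULL
  if (cfg$with_cells && cfg$n_sc_individuals > 0) {
    cells <- .simulate_cells(cfg, registries, hla, rules, ids)
  }

  surv <- NULL
  carrier <- NULL
  if (cfg$with_survival) {
    combined <- do.call(rbind, registries)
    any_matched <- tapply(combined$matched, combined$individual_id, any)[ids]
    carrier <- !is.na(any_matched) & any_matched
    names(carrier) <- ids
    surv <- simulate_survival(carrier, cfg$survival_hazard_ratio,
                              seed = cfg$seed + 1L,
                              baseline_hazard = cfg$baseline_hazard,
                              censor_max = cfg$censor_max)
  }

  structure(list(genotypes = genotypes, hla = hla, clones = clones,
                 covariates = covariates, cells = cells, survival = surv,
                 carrier = carrier, c4_individuals = c4_ids,
                 truth = list(cis = cfg$cis_effects, trans = cfg$trans_effects,
                              kmer = cfg$kmer_effects, rules = rules,
                              trs_shift = cfg$trs_shift,
                              survival_hazard_ratio = cfg$survival_hazard_ratio),
                 config = cfg),
            class = "synthetic_cohort")
}

#' @noRd
.simulate_cells <- function(cfg, registries, hla, rules, ids) {
  sc_ids <- ids[seq_len(min(cfg$n_sc_individuals, length(ids)))]
  beta_reg <- registries$beta[registries$beta$in_c1 &
                                registries$beta$individual_id %in% sc_ids, ]
  alpha_reg <- registries$alpha[registries$alpha$in_c1 &
                                  registries$alpha$individual_id %in% sc_ids, ]
  gene_mu <- rnorm(length(.TRS_PANEL), 4, 0.5)
  proto_off <- matrix(rnorm(2 * length(.TRS_PANEL), 0, 0.2), nrow = 2)
  protocol_of <- setNames(sample(c("P1", "P2"), length(sc_ids), replace = TRUE),
                          sc_ids)
  subsets <- c("CD8_TEM", "CD8_TEMRA", "CD8_naive", "CD4")
  subset_p <- c(0.35, 0.20, 0.30, 0.15)

  out <- list()
  for (id in sc_ids) {
    b <- beta_reg[beta_reg$individual_id == id, ]
    a <- alpha_reg[alpha_reg$individual_id == id, ]
    if (nrow(b) == 0 || nrow(a) == 0) next
    # stable alpha partner per beta clone so cells of a clone share TRA+TRB
    partner <- sample(nrow(a), nrow(b), replace = TRUE)
    # clone sizes: sample cells from clones proportional to a geometric
    # expansion weight so both singlets and expanded clones appear
    w <- 1 + rgeom(nrow(b), 0.3)
    pick <- sample(nrow(b), cfg$n_cells_per_individual, replace = TRUE,
                   prob = w)
    nc <- length(pick)
    second <- runif(nc) < cfg$second_alpha_rate
    a2 <- sample(nrow(a), nc, replace = TRUE)
    matched <- .matched_clone(b[pick, ], rules, hla)
    expr <- matrix(rnorm(nc * length(.TRS_PANEL)), nc) +
      matrix(gene_mu, nc, length(.TRS_PANEL), byrow = TRUE) +
      proto_off[rep(if (protocol_of[id] == "P1") 1L else 2L, nc), , drop = FALSE]
    expr[matched, ] <- expr[matched, , drop = FALSE] +
      cfg$trs_shift * sqrt(length(.TRS_PANEL)) / length(.TRS_PANEL)
    expr <- pmax(expr, 0)
    colnames(expr) <- .TRS_PANEL
    df <- data.frame(
      cell_id = paste0(id, "_c", seq_len(nc)),
      individual_id = id,
      subset = sample(subsets, nc, replace = TRUE, prob = subset_p),
      protocol = unname(protocol_of[id]),
      alpha1_v = a$v_gene[partner[pick]],
      alpha1_cdr3 = a$cdr3_aa[partner[pick]],
      alpha2_v = ifelse(second, a$v_gene[a2], NA_character_),
      alpha2_cdr3 = ifelse(second, a$cdr3_aa[a2], NA_character_),
      beta_v = b$v_gene[pick],
      beta_cdr3 = b$cdr3_aa[pick],
      n_alpha = 1L + as.integer(second),
      n_beta = 1L,
      total_transcripts = 300L + rnbinom(nc, mu = 2700, size = 5),
      mito_fraction = rbeta(nc, 2, 30),
      stringsAsFactors = FALSE)
    # planted QC failures: low depth, high mito, aberrant chain multiplicity
    fl <- runif(nc) < cfg$sc_fail_rate
    df$total_transcripts[fl] <- sample(50:299, sum(fl), replace = TRUE)
    fm <- runif(nc) < cfg$sc_fail_rate
    df$mito_fraction[fm] <- runif(sum(fm), 0.21, 0.6)
    fc <- runif(nc) < cfg$sc_fail_rate
    df$n_beta[fc] <- 2L
    out[[id]] <- cbind(df, as.data.frame(expr, row.names = seq_len(nc)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate overall-survival records
#'
#' Exponential event times with carrier hazard = baseline x hazard_ratio
#' and independent uniform censoring on \[0, censor_max\].
#'
#' @param carrier_status named logical vector (TRUE = carries an
#'   HLA-matched clone).
#' @param hazard_ratio positive hazard multiplier for carriers.
#' @param seed integer seed.
#' @param baseline_hazard events per day for non-carriers.
#' @param censor_max censoring horizon in days; must be > 0.
#' @return data frame (individual_id, os_time, event, group).
#' @export
simulate_survival <- function(carrier_status, hazard_ratio, seed = 1L,
                              baseline_hazard = 1 / 730, censor_max = 1825) {
  if (length(carrier_status) == 0) .stopf("empty cohort")
  if (hazard_ratio <= 0) .stopf("hazard_ratio must be > 0")
  if (censor_max <= 0) .stopf("censoring horizon must be positive; all records would be censored at time 0")
  set.seed(seed)
  rate <- baseline_hazard * ifelse(carrier_status, hazard_ratio, 1)
  t_event <- rexp(length(rate), rate)
  t_cens <- runif(length(rate), 0, censor_max)
  ids <- names(carrier_status)
  if (is.null(ids)) ids <- sprintf("I%04d", seq_along(carrier_status))
  data.frame(individual_id = ids,
             os_time = pmin(t_event, t_cens),
             event = t_event <= t_cens,
             group = ifelse(carrier_status, "carrier", "non-carrier"),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d individuals, %d variants, %d clone rows\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              nrow(x$clones)))
  if (!is.null(x$cells)) cat(sprintf("  %d cells from %d individuals\n",
                                     nrow(x$cells),
                                     length(unique(x$cells$individual_id))))
  invisible(x)
}
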