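#' Repertoire phenotype construction
#'
#' Turns clone tables into quantitative traits: per-individual unique-clone
#' counts over V-genes or CDR3 7-mers, normalised by trimmed mean of
#' M-values (TMM) to counts-per-million, batch corrected, and mapped
#' through the rank-based inverse normal transformation (INRT). The stage
#' order raw -> normalized -> batch_corrected -> inrt is enforced.
#'
#' @name phenotypes
NULL

.STAGES <- c("raw_counts", "normalized", "batch_corrected", "inrt")

#' Construct a phenotype matrix
#'
#' @param values numeric matrix individuals x features with dimnames.
#' @param stage one of raw_counts, normalized, batch_corrected, inrt.
#' @param chain "alpha", "beta" or "both".
#' @param feature_type "vgene" or "kmer".
#' @return object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, stage, chain = "beta",
                             feature_type = "vgene") {
  stopifnot(is.matrix(values))
  stage <- match.arg(stage, .STAGES)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    .stopf("phenotype values need individual rownames and feature colnames")
  }
  if (stage == "raw_counts") {
    if (any(values < 0) || any(values != round(values))) {
      .stopf("raw counts must be non-negative integers")
    }
  }
  structure(list(values = values, stage = stage, chain = chain,
                 feature_type = feature_type),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix [%s/%s, stage %s]: %d individuals x %d features\n",
              x$chain, x$feature_type, x$stage,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @noRd
.require_stage <- function(pm, stage, op) {
  stopifnot(inherits(pm, "phenotype_matrix"))
  if (pm$stage != stage) {
    .stopf("%s expects stage '%s' but got '%s' (pipeline order is raw_counts -> normalized -> batch_corrected -> inrt)",
           op, stage, pm$stage)
  }
}

#' @noRd
.unique_clones <- function(clones, chain, timepoint) {
  keep <- clones$productive & clones$chain == chain &
    clones$timepoint == timepoint
  cl <- clones[keep, c("individual_id", "v_gene", "cdr3_aa")]
  key <- paste(cl$individual_id, cl$v_gene, cl$cdr3_aa, sep = "\r")
  cl[!duplicated(key), ]
}

#' V-gene usage as unique-clone counts
#'
#' Cell (i, g) is the number of distinct clones — keyed by
#' (chain, v_gene, cdr3_aa) — of individual i at the timepoint using
#' V-gene g. Clone multiplicity (the count field) is deliberately ignored:
#' the trait measures propensity for clone formation, not expansion. Only
#' productive clones contribute.
#'
#' @param clones validated clone data frame.
#' @param chain "alpha" or "beta".
#' @param timepoint "C1", "C2" or "C4".
#' @param individuals optional id vector fixing row order; individuals with
#'   no clones get zero rows with a warning.
#' @param v_genes optional feature vector fixing column order.
#' @return `phenotype_matrix` at stage raw_counts.
#' @export
count_vgene_usage <- function(clones, chain, timepoint,
                              individuals = NULL, v_genes = NULL) {
  cl <- .unique_clones(clones, chain, timepoint)
  if (is.null(individuals)) individuals <- sort(unique(cl$individual_id))
  if (is.null(v_genes)) v_genes <- sort(unique(cl$v_gene))
  empty <- setdiff(individuals, cl$individual_id)
  if (length(empty) > 0) {
    .warnf("%d individual(s) with no %s clones at %s: zero rows emitted",
           length(empty), chain, timepoint)
  }
  m <- matrix(0L, length(individuals), length(v_genes),
              dimnames = list(individuals, v_genes))
  cl <- cl[cl$individual_id %in% individuals & cl$v_gene %in% v_genes, ]
  if (nrow(cl) > 0) {
    tab <- table(factor(cl$individual_id, levels = individuals),
                 factor(cl$v_gene, levels = v_genes))
    m[] <- as.integer(tab)
  }
  phenotype_matrix(m, "raw_counts", chain, "vgene")
}

#' CDR3 k-mer usage as unique-clone counts
#'
#' Cell (i, m) counts the distinct clones of individual i whose CDR3
#' (length within \[min_len, max_len\]) contains motif m as a contiguous
#' substring; a CDR3 of length L yields L - k + 1 windows and a motif
#' occurring twice in one CDR3 still contributes once (clone presence).
#'
#' @param clones validated clone data frame.
#' @param chain,timepoint as in [count_vgene_usage()].
#' @param k motif length; 7 is the analysis default (a warning is issued
#'   for other k).
#' @param min_len,max_len CDR3 length band included in the analysis.
#' @param min_prevalence drop motifs seen in fewer than this fraction of
#'   individuals (0 keeps everything); a practical control on the feature
#'   space, which real repertoires keep to recurrent motifs.
#' @param individuals optional id vector fixing row order.
#' @return `phenotype_matrix` at stage raw_counts, feature_type "kmer".
#' @export
count_kmers <- function(clones, chain, timepoint, k = 7,
                        min_len = 12, max_len = 18,
                        min_prevalence = 0, individuals = NULL) {
  if (k != 7) .warnf("k = %d differs from the conventional 7-residue motif length", k)
  cl <- .unique_clones(clones, chain, timepoint)
  if (is.null(individuals)) individuals <- sort(unique(cl$individual_id))
  L <- nchar(cl$cdr3_aa)
  cl <- cl[L >= min_len & L <= max_len, ]
  if (nrow(cl) == 0) {
    m <- matrix(0L, length(individuals), 0, dimnames = list(individuals, NULL))
    return(phenotype_matrix(m, "raw_counts", chain, "kmer"))
  }
  L <- nchar(cl$cdr3_aa)
  n_win <- L - k + 1L
  idx <- rep(seq_len(nrow(cl)), n_win)
  start <- sequence(n_win)
  motif <- substr(cl$cdr3_aa[idx], start, start + k - 1L)
  # integer keys keep the window stream fast: clone x motif dedup gives
  # per-clone presence; individual x motif dedup gives prevalence
  umot <- unique(motif)
  mid <- match(motif, umot)
  keep_w <- !duplicated(as.numeric(idx) * length(umot) + mid)
  mid <- mid[keep_w]
  iid <- match(cl$individual_id[idx[keep_w]], individuals)
  ok <- !is.na(iid)
  mid <- mid[ok]; iid <- iid[ok]
  if (min_prevalence > 0) {
    # prevalence filter applied before materialising the matrix, so the
    # feature space never holds the full private-motif tail
    first_pair <- !duplicated(as.numeric(iid) * length(umot) + mid)
    n_carrier <- tabulate(mid[first_pair], nbins = length(umot))
    keep_m <- n_carrier / length(individuals) >= min_prevalence
    sel <- keep_m[mid]
    mid <- mid[sel]; iid <- iid[sel]
  } else {
    keep_m <- rep(TRUE, length(umot))
  }
  motifs <- sort(umot[keep_m])
  mid2 <- match(umot[mid], motifs)
  m <- matrix(0L, length(individuals), length(motifs),
              dimnames = list(individuals, motifs))
  counts <- tabulate((as.numeric(mid2) - 1) * length(individuals) + iid,
                     nbins = length(individuals) * length(motifs))
  m[] <- as.integer(counts)
  phenotype_matrix(m, "raw_counts", chain, "kmer")
}

#' TMM scaling factors
#'
#' Canonical trimmed-mean-of-M-values factors (as used for count
#' normalisation in RNA-seq): the reference is the sample whose
#' upper-quartile is closest to the mean upper-quartile; each sample's
#' factor is the inverse-variance-weighted trimmed mean of log2 ratios
#' after trimming `trim_m` of M-values and `trim_a` of A-values; factors
#' are rescaled to geometric mean 1. Computation is delegated to edgeR.
#'
#' @param counts `phenotype_matrix` at stage raw_counts.
#' @param trim_m,trim_a trim fractions for M- and A-values.
#' @return named numeric vector of per-individual factors.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  .require_stage(counts, "raw_counts", "tmm_factors")
  m <- counts$values
  if (nrow(m) < 2) .stopf("tmm_factors needs >= 2 individuals")
  lib <- rowSums(m)
  if (any(lib == 0)) .stopf("individual(s) with all-zero counts: %s",
                            paste(rownames(m)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(t(m), lib.size = lib, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  bad <- !is.finite(f)
  if (any(bad)) {
    .warnf("%d sample(s) share no co-nonzero features with the reference; factor set to 1",
           sum(bad))
    f[bad] <- 1
  }
  setNames(as.numeric(f), rownames(m))
}

#' Normalise counts to CPM on effective library size
#'
#' value(i, g) = counts(i, g) / (library_size_i x factor_i) x 1e6.
#'
#' @param counts `phenotype_matrix` at stage raw_counts.
#' @param factors factors from [tmm_factors()].
#' @return `phenotype_matrix` at stage normalized.
#' @export
normalize_counts <- function(counts, factors) {
  .require_stage(counts, "raw_counts", "normalize_counts")
  m <- counts$values
  f <- factors[rownames(m)]
  if (anyNA(f)) .stopf("factors missing for some individuals")
  eff <- rowSums(m) * f
  if (any(eff <= 0)) .stopf("zero effective library size")
  out <- m / eff * 1e6
  phenotype_matrix(out, "normalized", counts$chain, counts$feature_type)
}

#' Remove batch main effects
#'
#' Per feature, batch main effects are removed by least squares while the
#' overall level is retained (limma's removeBatchEffect, sum-to-zero batch
#' coding). A single batch passes through unchanged.
#'
#' @param matrix_ `phenotype_matrix` at stage normalized.
#' @param batch batch label per individual (in row order or named).
#' @return `phenotype_matrix` at stage batch_corrected.
#' @export
remove_batch <- function(matrix_, batch) {
  .require_stage(matrix_, "normalized", "remove_batch")
  m <- matrix_$values
  if (!is.null(names(batch))) batch <- batch[rownames(m)]
  if (length(batch) != nrow(m)) .stopf("batch length != individuals")
  batch <- factor(batch)
  if (nlevels(batch) > 1) {
    sizes <- table(batch)
    if (any(sizes < 2)) {
      .stopf("batch(es) with a single individual are confounded: %s",
             paste(names(sizes)[sizes < 2], collapse = ", "))
    }
    m <- t(limma::removeBatchEffect(t(m), batch = batch))
  }
  phenotype_matrix(m, "batch_corrected", matrix_$chain, matrix_$feature_type)
}

#' Rank-based inverse normal transformation
#'
#' Per feature column, ranks (ties averaged) are mapped through
#' qnorm((r - 3/8) / (n + 1/4)) — the Blom offset. Constant columns
#' transform to all zeros with a warning.
#'
#' @param matrix_ `phenotype_matrix` at stage batch_corrected.
#' @return `phenotype_matrix` at stage inrt.
#' @export
inrt <- function(matrix_) {
  .require_stage(matrix_, "batch_corrected", "inrt")
  m <- matrix_$values
  if (nrow(m) < 3) .stopf("inrt needs n >= 3")
  out <- apply(m, 2, .inrt_column)
  dimnames(out) <- dimnames(m)
  phenotype_matrix(out, "inrt", matrix_$chain, matrix_$feature_type)
}

#' @noRd
.inrt_column <- function(x) {
  if (length(unique(x)) == 1) {
    .warnf("constant phenotype column: INRT set to zero")
    return(rep(0, length(x)))
  }
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' TCR principal components
#'
#' PCs of the column-standardised batch-corrected usage matrix (pre-INRT),
#' used downstream as confounder covariates; same sign convention as
#' [genetic_pcs()].
#'
#' @param matrix_ `phenotype_matrix` at stage batch_corrected.
#' @param k number of components.
#' @return matrix individuals x k of scores.
#' @export
tcr_pcs <- function(matrix_, k = 2) {
  .require_stage(matrix_, "batch_corrected", "tcr_pcs")
  .pc_scores(matrix_$values, k, "TCR usage matrix")
}

#' Run the full phenotype pipeline
#'
#' Convenience wrapper: counts -> TMM -> CPM -> batch correction -> INRT.
#'
#' @param counts `phenotype_matrix` at stage raw_counts.
#' @param batch batch labels (NULL for none).
#' @return list(inrt = stage-inrt matrix, corrected = stage-batch_corrected
#'   matrix, factors = TMM factors).
#' @export
phenotype_pipeline <- function(counts, batch = NULL) {
  f <- tmm_factors(counts)
  norm <- normalize_counts(counts, f)
  corrected <- if (is.null(batch)) {
    phenotype_matrix(norm$values, "batch_corrected", norm$chain,
                     norm$feature_type)
  } else {
    remove_batch(norm, batch)
  }
  list(inrt = inrt(corrected), corrected = corrected, factors = f)
}
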