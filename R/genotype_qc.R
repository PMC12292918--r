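#' Genotype quality control
#'
#' Sample and variant filters at the conventional array-QC thresholds
#' (heterozygosity outliers, missingness, MAF, Hardy-Weinberg exact test,
#' call rate), genotype principal components, and pairwise LD.
#'
#' @name genotype_qc
NULL

#' @noRd
.qc_report <- function(dropped_samples, dropped_variants, thresholds) {
  structure(list(dropped_samples = dropped_samples,
                 dropped_variants = dropped_variants,
                 thresholds = thresholds),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d sample(s) dropped, %d variant(s) dropped\n",
              nrow(x$dropped_samples), nrow(x$dropped_variants)))
  invisible(x)
}

#' Sample-level QC
#'
#' Removes samples whose heterozygosity rate (fraction of hard calls equal
#' to 1) lies outside mean +/- `het_sd` SDs, or whose missing-call fraction
#' exceeds `max_missing`. Heterozygosity statistics are computed on the
#' matrix as given (apply [variant_qc()] first if outlier detection should
#' follow variant filtering; the report records the choice).
#'
#' @param g `genotype_matrix`.
#' @param het_sd SD multiplier for the heterozygosity window.
#' @param max_missing maximum tolerated missing fraction per sample.
#' @return list(genotypes = filtered `genotype_matrix`, report = `qc_report`).
#' @export
sample_qc <- function(g, het_sd = 3.5, max_missing = 0.10) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (nrow(g$dosage) < 3) .stopf("sample_qc needs >= 3 samples")
  d <- g$dosage
  miss <- rowMeans(is.na(d))
  hard <- round(d)
  het <- rowMeans(hard == 1, na.rm = TRUE)
  mu <- mean(het)
  sdev <- sd(het)
  het_bad <- if (sdev > 0) abs(het - mu) > het_sd * sdev else rep(FALSE, length(het))
  miss_bad <- miss > max_missing
  drop <- het_bad | miss_bad
  if (all(drop)) .stopf("sample_qc dropped every sample")
  reasons <- ifelse(miss_bad, "missingness", "heterozygosity")
  report <- .qc_report(
    data.frame(id = rownames(d)[drop], reason = reasons[drop],
               stringsAsFactors = FALSE),
    data.frame(id = character(), reason = character()),
    list(het_sd = het_sd, max_missing = max_missing,
         het_mean = mu, het_sd_observed = sdev,
         het_computed_on = "matrix as supplied"))
  list(genotypes = genotype_matrix(d[!drop, , drop = FALSE], g$variants),
       report = report)
}

#' Hardy-Weinberg exact test p-value
#'
#' Conditional exact test on the observed allele counts: enumerates the
#' probability of every heterozygote count consistent with the allele
#' totals and sums those no more probable than the observed configuration.
#' Probabilities follow the stable mode-outward recurrence.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-ref, het, hom-alt).
#' @return two-sided exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab   # count of the first allele
  rare <- min(n_a, 2 * n - n_a)
  het_obs <- n_ab
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  if (length(hets) == 1) return(1)
  probs <- numeric(length(hets))
  # start at the distribution mode, fill outward by recurrence
  mode_h <- round(rare * (2 * n - rare) / (2 * n - 1))
  if (mode_h %% 2 != rare %% 2) mode_h <- mode_h + 1
  mode_idx <- which(hets == mode_h)
  if (length(mode_idx) == 0) mode_idx <- which.min(abs(hets - mode_h))
  probs[mode_idx] <- 1
  # going down: P(h-2)/P(h) = h(h-1) / ((ra - h + 2)(co - h + 2)) with
  # ra = rare homozygotes*2 relation; use genotype-count recurrence
  i <- mode_idx
  while (i > 1) {
    h <- hets[i]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i - 1] <- probs[i] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
    i <- i - 1
  }
  i <- mode_idx
  while (i < length(hets)) {
    h <- hets[i]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i + 1] <- probs[i] * 4 * hom_r * hom_c /
      ((h + 2) * (h + 1))
    i <- i + 1
  }
  probs <- probs / sum(probs)
  p_obs <- probs[hets == het_obs]
  min(1, sum(probs[probs <= p_obs + 1e-12 * p_obs]))
}

#' Variant-level QC
#'
#' Filters variants by call rate, minor-allele frequency and
#' Hardy-Weinberg exact-test p-value. MAF and call rate are computed on
#' all non-missing dosages; the HWE test uses integer hard calls only
#' (fractional imputed dosages are excluded from the test but retained for
#' association). Idempotent: a matrix that passed once passes unchanged.
#'
#' @param g `genotype_matrix`.
#' @param min_maf minimum minor-allele frequency (variant retained if
#'   MAF >= min_maf).
#' @param hwe_p minimum HWE exact p (retained if p >= hwe_p).
#' @param min_call minimum call rate.
#' @return list(genotypes, report) as for [sample_qc()].
#' @export
variant_qc <- function(g, min_maf = 0.01, hwe_p = 1e-6, min_call = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  call_rate <- colMeans(!is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x) & abs(x - round(x)) < 1e-8]
    x <- round(x)
    hwe_exact_p(sum(x == 0), sum(x == 1), sum(x == 2))
  }, numeric(1))
  fail_call <- call_rate < min_call
  fail_maf <- !fail_call & (is.na(maf) | maf < min_maf)
  fail_hwe <- !fail_call & !fail_maf & hwe < hwe_p
  drop <- fail_call | fail_maf | fail_hwe
  reason <- ifelse(fail_call, "call_rate",
                   ifelse(fail_maf, "maf", "hwe"))
  if (all(drop)) .warnf("variant_qc removed every variant")
  report <- .qc_report(
    data.frame(id = character(), reason = character()),
    data.frame(id = g$variants$id[drop], reason = reason[drop],
               stringsAsFactors = FALSE),
    list(min_maf = min_maf, hwe_p = hwe_p, min_call = min_call))
  list(genotypes = genotype_matrix(d[, !drop, drop = FALSE],
                                   g$variants[!drop, , drop = FALSE]),
       report = report)
}

# shared PC machinery: column-standardise (dropping zero-variance
# columns), PCA, fix signs so each PC's largest-|loading| is positive
#' @noRd
.pc_scores <- function(m, k, what = "matrix") {
  if (k == 0) {
    return(matrix(numeric(0), nrow(m), 0, dimnames = list(rownames(m), NULL)))
  }
  sds <- apply(m, 2, sd)
  keep <- !is.na(sds) & sds > 0
  m <- scale(m[, keep, drop = FALSE])
  r <- min(nrow(m) - 1, ncol(m))
  if (k > r) .stopf("k = %d exceeds the rank (%d) of the %s", k, r, what)
  pc <- prcomp(m, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(load[which.max(abs(load[, j])), j])
  }, numeric(1))
  scores <- sweep(scores, 2, flip, `*`)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(m)
  scores
}

#' Genotype principal components
#'
#' PCs of the column-standardised dosage matrix with missing calls
#' mean-imputed (imputation happens only here, never in association).
#'
#' @param g `genotype_matrix` (post-QC).
#' @param k number of components.
#' @return matrix individuals x k of scores, columns `PC1..PCk`.
#' @export
genetic_pcs <- function(g, k = 2) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  .pc_scores(d, k, "genotype matrix")
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of dosages over complete cases.
#'
#' @param g `genotype_matrix`.
#' @param variant_a,variant_b variant ids.
#' @return r-squared in \[0, 1\], or NA (with warning) if either variant has
#'   zero variance over the complete cases.
#' @export
ld_r2 <- function(g, variant_a, variant_b) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (v in c(variant_a, variant_b)) {
    if (!v %in% colnames(g$dosage)) .stopf("variant not present: %s", v)
  }
  x <- g$dosage[, variant_a]
  y <- g$dosage[, variant_b]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) .stopf("fewer than 2 complete observations")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    .warnf("zero variance; LD undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok])^2
}
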