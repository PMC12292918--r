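#' Longitudinal clone dynamics
#'
#' Partitions each individual's clones across paired treatment timepoints
#' into unstable (pre only), novel (post only) and persistent (both),
#' measures redetection of each group at a later cycle, scores HLA-matched
#' clones against V-gene/allele pairing rules, and compares matched
#' proportions between groups with a paired Wilcoxon signed-rank test.
#'
#' @name clone_dynamics
NULL

#' @noRd
.clone_key <- function(df) paste(df$chain, df$v_gene, df$cdr3_aa, sep = "|")

#' @noRd
.dedup_clones <- function(clones, timepoint = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(clones))
  if (!is.null(timepoint)) keep <- keep & clones$timepoint == timepoint
  if (!is.null(chain)) keep <- keep & clones$chain == chain
  cl <- clones[keep, c("individual_id", "chain", "v_gene", "cdr3_aa")]
  key <- paste(cl$individual_id, cl$chain, cl$v_gene, cl$cdr3_aa, sep = "\r")
  cl[!duplicated(key), ]
}

#' Partition clones across two timepoints
#'
#' For each individual: unstable = C1 \ C2, novel = C2 \ C1,
#' persistent = C1 n C2, with clones keyed by (chain, v_gene, cdr3_aa).
#'
#' @param c1,c2 clone data frames (already restricted to the two
#'   timepoints of interest, or carrying timepoint columns that are
#'   ignored here); duplicated keys are collapsed.
#' @return data frame (individual_id, chain, v_gene, cdr3_aa, group).
#' @export
classify_clones <- function(c1, c2) {
  a <- .dedup_clones(c1)
  b <- .dedup_clones(c2)
  ka <- paste(a$individual_id, .clone_key(a))
  kb <- paste(b$individual_id, .clone_key(b))
  a$group <- ifelse(ka %in% kb, "persistent", "unstable")
  b_only <- b[!kb %in% ka, ]
  if (nrow(b_only) > 0) b_only$group <- "novel"
  out <- rbind(a, b_only)
  rownames(out) <- NULL
  out
}

#' Redetection proportions at a later timepoint
#'
#' Fraction of each group's clones present in the later (e.g. C4) sample,
#' per individual. Individuals absent from `c4` and empty groups yield no
#' rows (missing, not zero).
#'
#' @param labels output of [classify_clones()].
#' @param c4 clone data frame for the later timepoint.
#' @return data frame (individual_id, group, n, prop).
#' @export
resampling_proportions <- function(labels, c4) {
  c4u <- .dedup_clones(c4)
  k4 <- paste(c4u$individual_id, .clone_key(c4u))
  labels <- labels[labels$individual_id %in% unique(c4u$individual_id), ]
  if (nrow(labels) == 0) {
    return(data.frame(individual_id = character(), group = character(),
                      n = integer(), prop = numeric()))
  }
  hit <- paste(labels$individual_id, .clone_key(labels)) %in% k4
  agg <- aggregate(cbind(n = rep(1L, nrow(labels)), hits = as.integer(hit)),
                   by = list(individual_id = labels$individual_id,
                             group = labels$group), FUN = sum)
  agg$prop <- agg$hits / agg$n
  agg[order(agg$individual_id, agg$group), c("individual_id", "group", "n", "prop")]
}

#' Extract top HLA allele per V-gene from an association table
#'
#' For each feature (V-gene) the classical allele with the smallest p;
#' ties broken by smallest p then lexicographic allele name. Optionally
#' restricted to features whose best p clears a significance threshold.
#'
#' @param results AssociationResult data frame from an HLA-allele scan.
#' @param p_threshold keep only V-genes whose top allele has p <= this.
#' @return data frame of match rules (v_gene, hla_allele, source).
#' @export
top_allele_rules <- function(results, p_threshold = 1) {
  res <- results[!is.na(results$p), ]
  res <- res[order(res$feature, res$p, res$predictor), ]
  top <- res[!duplicated(res$feature), ]
  top <- top[top$p <= p_threshold, ]
  data.frame(v_gene = top$feature, hla_allele = top$predictor,
             source = rep("top allele for this V-gene", nrow(top)),
             stringsAsFactors = FALSE)
}

#' Per-clone HLA-matched flags
#'
#' A clone is matched iff some rule's v_gene equals the clone's V-gene and
#' the individual's dosage of that rule's allele is >= 1 (carriage, not
#' homozygosity).
#'
#' @param clones clone data frame.
#' @param rules match rules (v_gene, hla_allele).
#' @param hla `hla_genotypes`.
#' @return logical vector along `clones` rows.
#' @export
clone_matched <- function(clones, rules, hla) {
  matched <- rep(FALSE, nrow(clones))
  for (i in seq_len(nrow(rules))) {
    if (!rules$hla_allele[i] %in% colnames(hla$allele_dosage)) next
    carrier <- hla$allele_dosage[, rules$hla_allele[i]] >= 1
    matched <- matched | (clones$v_gene == rules$v_gene[i] &
                            carrier[match(clones$individual_id,
                                          rownames(hla$allele_dosage))])
  }
  matched & !is.na(matched)
}

#' Per-individual proportion of HLA-matched clones
#'
#' @param clones clone data frame for one clone group (deduplicated keys;
#'   duplicates are collapsed defensively).
#' @param rules match rules (v_gene, hla_allele).
#' @param hla `hla_genotypes`.
#' @return data frame (individual_id, n, n_matched, prop); individuals
#'   with an empty group are simply absent.
#' @export
hla_matched_proportion <- function(clones, rules, hla) {
  cl <- .dedup_clones(clones)
  if (nrow(cl) == 0) {
    return(data.frame(individual_id = character(), n = integer(),
                      n_matched = integer(), prop = numeric()))
  }
  m <- clone_matched(cl, rules, hla)
  agg <- aggregate(cbind(n = rep(1L, nrow(cl)), n_matched = as.integer(m)),
                   by = list(individual_id = cl$individual_id), FUN = sum)
  agg$prop <- agg$n_matched / agg$n
  agg[order(agg$individual_id), ]
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided. Zero differences are dropped; with 25 or fewer informative
#' pairs the exact null distribution of the signed-rank statistic is
#' computed by dynamic programming over the (tie-averaged) ranks, which
#' reproduces full enumeration of all 2^n sign assignments; above that, a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y paired numeric vectors.
#' @param exact_limit switch point between exact and approximate branches.
#' @return list(p, statistic = W, n_informative, method).
#' @export
paired_wilcoxon <- function(x, y, exact_limit = 25) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    .warnf("all differences zero: p = 1")
    return(list(p = 1, statistic = NA_real_, n_informative = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    p <- .wilcox_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p = p, statistic = W, n_informative = n, method = method)
}

# exact two-sided signed-rank p via generating-function DP over doubled
# ranks (doubling makes tie-averaged half-ranks integral)
#' @noRd
.wilcox_exact_p <- function(r, W) {
  w2 <- as.integer(round(2 * r))
  total <- sum(w2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (w in w2) {
    g <- f
    g[(w + 1):(total + 1)] <- g[(w + 1):(total + 1)] + f[1:(total + 1 - w)]
    f <- g
  }
  f <- f / 2^length(w2)
  Wi <- as.integer(round(2 * W))
  lower <- sum(f[1:(Wi + 1)])
  upper <- sum(f[(Wi + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Association scan restricted to one clone group
#'
#' Rebuilds V-gene usage from the clones of a single stability group
#' (unstable / novel / persistent), runs the standard phenotype pipeline
#' (TMM, CPM, optional batch correction, INRT) and delegates to
#' [assoc_scan()].
#'
#' @param labels output of [classify_clones()].
#' @param group which group to analyse.
#' @param chain "alpha" or "beta".
#' @param predictors dosage matrix or `genotype_matrix`.
#' @param covariates covariate data frame or design matrix.
#' @param batch optional batch labels for correction.
#' @param v_genes optional fixed feature set.
#' @return data frame of AssociationResult rows.
#' @export
group_association_scan <- function(labels, group, chain, predictors,
                                   covariates = NULL, batch = NULL,
                                   v_genes = NULL) {
  group <- match.arg(group, c("unstable", "novel", "persistent"))
  cl <- labels[labels$group == group & labels$chain == chain, ]
  if (nrow(cl) == 0) .stopf("no %s %s-chain clones", group, chain)
  cl$timepoint <- "C1"
  cl$count <- 1L
  cl$productive <- TRUE
  counts <- count_vgene_usage(cl, chain, "C1", v_genes = v_genes)
  ph <- phenotype_pipeline(counts, batch = batch)
  assoc_scan(ph$inrt, predictors, covariates)
}
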