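#' Additive association engine
#'
#' Ordinary-least-squares scans of inverse-normal-transformed repertoire
#' traits against SNP dosages, classical HLA allele dosages or amino-acid
#' residue dosages, with covariate adjustment, conditional analysis,
#' multi-residue omnibus tests and permutation-derived family-wise
#' significance thresholds. The scan uses the Frisch-Waugh projection so
#' that a full feature x variant grid costs two matrix products per
#' permutation, and is numerically identical to per-pair [fit_additive()].
#'
#' @name association
NULL

#' Build a covariate design matrix
#'
#' Numeric columns pass through; character/factor columns become indicator
#' columns with the largest category as reference. Collinear columns raise
#' an error naming them. `individual_id` is used for rownames, never
#' modelled.
#'
#' @param covariates data frame (or NULL for intercept-only models).
#' @param ids individual ids defining row order (defaults to the
#'   `individual_id` column).
#' @return numeric matrix (possibly 0-column) with id rownames.
#' @export
build_design <- function(covariates, ids = NULL) {
  if (is.null(covariates)) {
    if (is.null(ids)) .stopf("need ids when covariates is NULL")
    return(matrix(numeric(0), length(ids), 0, dimnames = list(ids, NULL)))
  }
  stopifnot(is.data.frame(covariates))
  if (is.null(ids)) {
    ids <- covariates$individual_id
    if (is.null(ids)) .stopf("covariates need an individual_id column")
  }
  rows <- match(ids, covariates$individual_id)
  if (anyNA(rows)) .stopf("covariates missing for %d individual(s)",
                          sum(is.na(rows)))
  df <- covariates[rows, setdiff(names(covariates), "individual_id"),
                   drop = FALSE]
  cols <- list()
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.numeric(x) || is.logical(x)) {
      cols[[nm]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      tab <- sort(table(x), decreasing = TRUE)
      ref <- names(tab)[1]
      for (lev in setdiff(names(tab), ref)) {
        cols[[paste0(nm, lev)]] <- as.numeric(x == lev)
      }
    }
  }
  X <- do.call(cbind, c(cols, list(deparse.level = 0)))
  if (is.null(X)) X <- matrix(numeric(0), length(ids), 0)
  colnames(X) <- names(cols)
  rownames(X) <- ids
  if (ncol(X) > 0) {
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1) {
      dropped <- colnames(X)[q$pivot[seq(q$rank + 1, ncol(X) + 1)] - 1]
      .stopf("collinear covariate column(s): %s",
             paste(dropped, collapse = ", "))
    }
  }
  X
}

#' @noRd
.assoc_row <- function(feature, predictor, beta = NA_real_, se = NA_real_,
                       t = NA_real_, p = NA_real_, n = NA_integer_,
                       df_num = 1L, model = "marginal",
                       conditioned_on = "", note = "") {
  data.frame(feature = feature, predictor = predictor, beta = beta, se = se,
             t = t, p = p, n = n, df_num = df_num, model = model,
             conditioned_on = conditioned_on, note = note,
             stringsAsFactors = FALSE)
}

#' Fit one additive linear association
#'
#' OLS of y ~ intercept + dosage + covariates over complete cases;
#' reports the dosage coefficient, its standard error, t statistic and
#' two-sided p from the t distribution with residual degrees of freedom.
#' p-values below 1e-300 are capped and flagged.
#'
#' @param y numeric response (one INRT phenotype column), named or in id
#'   order.
#' @param dosage numeric predictor vector.
#' @param covariates covariate data frame or prebuilt design matrix
#'   (or NULL).
#' @param feature,predictor labels for the result row.
#' @return one-row data frame (AssociationResult).
#' @export
fit_additive <- function(y, dosage, covariates = NULL,
                         feature = "y", predictor = "dosage") {
  X <- if (is.matrix(covariates)) covariates else if (!is.null(covariates)) {
    build_design(covariates, ids = names(y))
  } else NULL
  n_all <- length(y)
  ok <- !is.na(y) & !is.na(dosage)
  if (!is.null(X)) ok <- ok & rowSums(is.na(X)) == 0
  y <- y[ok]
  dosage <- dosage[ok]
  X <- if (!is.null(X)) X[ok, , drop = FALSE] else NULL
  p_cov <- if (is.null(X)) 0L else ncol(X)
  if (length(y) < p_cov + 3) .stopf("fewer than %d complete cases", p_cov + 3)
  if (var(dosage) == 0) {
    return(.assoc_row(feature, predictor, n = length(y),
                      note = "untestable: zero-variance dosage"))
  }
  M <- cbind(`(Intercept)` = 1, dosage = dosage, X)
  fit <- lm.fit(M, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  R <- qr.R(fit$qr)
  xtx_inv <- chol2inv(R)
  se <- sqrt(rss / df * xtx_inv[2, 2])
  beta <- fit$coefficients[["dosage"]]
  note <- ""
  if (rss <= 1e-12 * max(sum(y^2), .Machine$double.xmin)) {
    # numerically perfect fit: report the capped p rather than an estimate
    # driven by rounding error
    return(.assoc_row(feature, predictor, beta, se, sign(beta) * Inf,
                      .P_UNDERFLOW, length(y), note = "p underflow-capped"))
  }
  if (se == 0 || !is.finite(beta / se)) {
    tval <- sign(beta) * Inf
    p <- .P_UNDERFLOW
    note <- "p underflow-capped"
  } else {
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df)
    if (p < .P_UNDERFLOW) {
      p <- .P_UNDERFLOW
      note <- "p underflow-capped"
    }
  }
  .assoc_row(feature, predictor, beta, se, tval, p, length(y), note = note)
}

# fast-path precomputation: orthonormal basis of [1 | covariates] over
# given rows, plus residualised predictor columns
#' @noRd
.scan_precompute <- function(G, X) {
  Q <- qr.Q(qr(cbind(1, X)))
  Gr <- G - Q %*% crossprod(Q, G)
  den <- colSums(Gr^2)
  list(Q = Q, Gr = Gr, den = den, p_cov = ncol(Q))
}

#' @noRd
.align_matrices <- function(phenos, predictors, covariates) {
  Y <- if (inherits(phenos, "phenotype_matrix")) phenos$values else phenos
  G <- if (inherits(predictors, "genotype_matrix")) predictors$dosage else predictors
  ids <- intersect(rownames(Y), rownames(G))
  if (!is.null(covariates) && !is.matrix(covariates)) {
    ids <- intersect(ids, covariates$individual_id)
  }
  if (length(ids) < 3) .stopf("fewer than 3 shared individuals")
  X <- if (is.matrix(covariates)) covariates[ids, , drop = FALSE] else
    build_design(covariates, ids = ids)
  list(Y = Y[ids, , drop = FALSE], G = G[ids, , drop = FALSE], X = X,
       ids = ids)
}

#' Association scan over a feature x predictor grid
#'
#' Runs [fit_additive()] for every phenotype feature against every
#' predictor column, via a single matrix-projection fast path that is
#' numerically identical to the looped fits. Predictor columns with
#' missing dosages fall back to per-pair complete-case fits; zero-variance
#' predictors are flagged untestable rather than aborting the scan.
#' Output order is deterministic: features outer, predictors inner.
#'
#' @param phenos `phenotype_matrix` (stage inrt) or numeric matrix.
#' @param predictors `genotype_matrix`, or numeric matrix of dosages
#'   (e.g. classical HLA alleles).
#' @param covariates covariate data frame (individual_id + columns) or
#'   design matrix.
#' @param model tag for the result rows.
#' @param conditioned_on tag recording conditioning predictors.
#' @return data frame of AssociationResult rows.
#' @export
assoc_scan <- function(phenos, predictors, covariates = NULL,
                       model = "marginal", conditioned_on = "") {
  if (inherits(phenos, "phenotype_matrix") && phenos$stage != "inrt") {
    .warnf("scanning a phenotype matrix at stage '%s' (expected inrt)",
           phenos$stage)
  }
  al <- .align_matrices(phenos, predictors, covariates)
  Y <- al$Y; G <- al$G; X <- al$X
  n <- nrow(Y)
  complete <- colSums(is.na(G)) == 0
  pre <- .scan_precompute(G[, complete, drop = FALSE], X)
  df <- n - pre$p_cov - 1L
  if (df < 2) .stopf("non-positive residual degrees of freedom")
  Yr <- Y - pre$Q %*% crossprod(pre$Q, Y)
  yss <- colSums(Yr^2)
  num <- crossprod(pre$Gr, Yr)                      # variants x features
  testable <- pre$den > n * 1e-12
  beta <- sweep(num, 1, ifelse(testable, pre$den, NA), `/`)
  rss <- outer(rep(1, nrow(num)), yss) - beta^2 * pre$den
  se <- sqrt(rss / df / pre$den)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)

  feats <- colnames(Y)
  preds_c <- colnames(G)[complete]
  out <- vector("list", length(feats))
  for (fi in seq_along(feats)) {
    rows <- .assoc_row(feats[fi], colnames(G), n = n, model = model,
                       conditioned_on = conditioned_on)
    ci <- match(colnames(G), preds_c)
    has <- !is.na(ci)
    rows$beta[has] <- beta[ci[has], fi]
    rows$se[has] <- se[ci[has], fi]
    rows$t[has] <- tval[ci[has], fi]
    rows$p[has] <- pval[ci[has], fi]
    bad <- rep(FALSE, length(has))
    bad[has] <- !testable[ci[has]]
    rows$note[bad] <- "untestable: zero-variance dosage"
    rows$beta[bad] <- rows$se[bad] <- rows$t[bad] <- rows$p[bad] <- NA
    under <- !is.na(rows$p) & rows$p < .P_UNDERFLOW
    rows$p[under] <- .P_UNDERFLOW
    rows$note[under] <- "p underflow-capped"
    out[[fi]] <- rows
  }
  res <- do.call(rbind, out)
  # per-pair complete-case fallback for predictors with missing dosages
  if (any(!complete)) {
    for (v in colnames(G)[!complete]) {
      for (fi in seq_along(feats)) {
        r <- tryCatch(
          fit_additive(Y[, fi], G[, v], X, feats[fi], v),
          error = function(e) .assoc_row(feats[fi], v, note = conditionMessage(e)))
        r$model <- model
        r$conditioned_on <- conditioned_on
        idx <- which(res$feature == feats[fi] & res$predictor == v)
        res[idx, ] <- r
      }
    }
  }
  rownames(res) <- NULL
  res
}

#' Conditional association scan
#'
#' Re-runs the scan with the dosages of `condition_on` appended to the
#' covariates; rows testing a conditioned predictor are flagged
#' untestable.
#'
#' @param phenos,predictors,covariates as in [assoc_scan()].
#' @param condition_on character vector of predictor ids to adjust for.
#' @return data frame of AssociationResult rows (model "conditional").
#' @export
conditional_scan <- function(phenos, predictors, covariates = NULL,
                             condition_on = character()) {
  G <- if (inherits(predictors, "genotype_matrix")) predictors$dosage else predictors
  miss <- setdiff(condition_on, colnames(G))
  if (length(miss) > 0) .stopf("conditioning predictor(s) absent: %s",
                               paste(miss, collapse = ", "))
  al <- .align_matrices(phenos, predictors, covariates)
  Xc <- cbind(al$X, al$G[, condition_on, drop = FALSE])
  q <- qr(cbind(1, Xc))
  if (q$rank < ncol(Xc) + 1) {
    .stopf("conditioned dosages collinear with covariates")
  }
  res <- assoc_scan(al$Y, al$G, Xc, model = "conditional",
                    conditioned_on = paste(condition_on, collapse = ","))
  self <- res$predictor %in% condition_on
  res$note[self] <- "untestable: conditioned on tested predictor"
  res$beta[self] <- res$se[self] <- res$t[self] <- res$p[self] <- NA
  res
}

#' Residue dosages at one HLA amino-acid position
#'
#' Converts 4-digit classical-allele dosages into per-residue counts at a
#' (gene, exon, position) via the residue map. Per individual the residue
#' dosages sum to 2.
#'
#' @param hla `hla_genotypes`.
#' @param gene,exon,position amino-acid position identifier.
#' @return matrix individuals x residues of counts in 0..2.
#' @export
hla_residue_dosages <- function(hla, gene, exon, position) {
  rm <- hla$residue_map
  rows <- rm$gene == gene & rm$exon == exon & rm$position == position
  if (!any(rows)) .stopf("no residue map entries for %s exon %s position %s",
                         gene, exon, position)
  rm <- rm[rows, ]
  residues <- sort(unique(rm$residue))
  out <- matrix(0, nrow(hla$allele_dosage), length(residues),
                dimnames = list(rownames(hla$allele_dosage), residues))
  for (i in seq_len(nrow(rm))) {
    if (!rm$allele[i] %in% colnames(hla$allele_dosage)) next
    out[, rm$residue[i]] <- out[, rm$residue[i]] +
      hla$allele_dosage[, rm$allele[i]]
  }
  out
}

#' Omnibus test of one amino-acid position
#'
#' F-test comparing covariates + (k - 1) residue-dosage columns (the most
#' common residue dropped as reference) against covariates alone. For a
#' biallelic position this reduces exactly to the squared t-test of the
#' single residue dosage.
#'
#' @param y numeric response.
#' @param residue_dosages matrix individuals x residues, rows summing to 2.
#' @param covariates covariate data frame or design matrix (or NULL).
#' @param feature,predictor labels for the result row.
#' @return one-row data frame (AssociationResult, model "omnibus").
#' @export
omnibus_position_test <- function(y, residue_dosages, covariates = NULL,
                                  feature = "y", predictor = "position") {
  stopifnot(is.matrix(residue_dosages))
  if (any(abs(rowSums(residue_dosages) - 2) > 1e-9)) {
    .stopf("residue dosages must sum to 2 per individual")
  }
  observed <- colSums(residue_dosages) > 0
  R <- residue_dosages[, observed, drop = FALSE]
  k <- ncol(R)
  if (k < 2) {
    return(.assoc_row(feature, predictor, df_num = 0L, model = "omnibus",
                      note = "untestable: single residue"))
  }
  X <- if (is.matrix(covariates)) covariates else if (!is.null(covariates)) {
    build_design(covariates, ids = rownames(R))
  } else NULL
  ok <- !is.na(y)
  if (!is.null(X)) ok <- ok & rowSums(is.na(X)) == 0
  y <- y[ok]
  R <- R[ok, , drop = FALSE]
  X <- if (!is.null(X)) X[ok, , drop = FALSE] else NULL
  ref <- which.max(colSums(R))
  Rk <- R[, -ref, drop = FALSE]
  M0 <- cbind(rep(1, length(y)), X)
  M1 <- cbind(M0, Rk)
  q1 <- qr(M1)
  q0 <- qr(M0)
  aliased <- q1$rank - q0$rank < ncol(Rk)
  if (aliased) {
    .warnf("residue column(s) collinear with covariates; omnibus df reduced")
  }
  q_num <- q1$rank - q0$rank
  if (q_num < 1) {
    return(.assoc_row(feature, predictor, df_num = 0L, model = "omnibus",
                      note = "untestable: residues collinear with covariates"))
  }
  rss0 <- sum(qr.resid(q0, y)^2)
  rss1 <- sum(qr.resid(q1, y)^2)
  df1 <- length(y) - q1$rank
  fstat <- ((rss0 - rss1) / q_num) / (rss1 / df1)
  p <- pf(fstat, q_num, df1, lower.tail = FALSE)
  note <- ""
  if (p < .P_UNDERFLOW) { p <- .P_UNDERFLOW; note <- "p underflow-capped" }
  .assoc_row(feature, predictor, beta = NA, se = NA, t = fstat, p = p,
             n = length(y), df_num = as.integer(q_num), model = "omnibus",
             note = note)
}

#' Permutation-derived family-wise significance threshold
#'
#' Applies B random row permutations to the whole phenotype matrix (all
#' features move together, preserving their correlation) while genotypes
#' and covariates stay fixed; records the minimum p over the full
#' feature x predictor grid per permutation; the threshold is the
#' empirical alpha-quantile (linear interpolation between order
#' statistics, R quantile type 7) of those B minima. Predictors with
#' missing dosages are excluded from the null with a warning.
#'
#' @param phenos,predictors,covariates as in [assoc_scan()].
#' @param B number of permutations (>= 20).
#' @param alpha family-wise error target.
#' @param seed integer seed.
#' @return object of class `permutation_null` with fields B, min_p, alpha,
#'   threshold, seed.
#' @export
permutation_threshold <- function(phenos, predictors, covariates = NULL,
                                  B = 1000, alpha = 0.05, seed = 1L) {
  if (B < 20) .stopf("B must be >= 20 for a stable quantile")
  al <- .align_matrices(phenos, predictors, covariates)
  Y <- al$Y; G <- al$G; X <- al$X
  complete <- colSums(is.na(G)) == 0
  if (any(!complete)) {
    .warnf("%d predictor(s) with missing dosages excluded from the permutation null",
           sum(!complete))
    G <- G[, complete, drop = FALSE]
  }
  pre <- .scan_precompute(G, X)
  keep <- pre$den > nrow(Y) * 1e-12
  Gr <- pre$Gr[, keep, drop = FALSE]
  den <- pre$den[keep]
  df <- nrow(Y) - pre$p_cov - 1L
  set.seed(seed)
  min_p <- numeric(B)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(Y))
    Yb <- Y[idx, , drop = FALSE]
    Yr <- Yb - pre$Q %*% crossprod(pre$Q, Yb)
    yss <- colSums(Yr^2)
    num <- crossprod(Gr, Yr)
    r2 <- sweep(sweep(num^2, 1, den, `/`), 2, yss, `/`)
    r2max <- min(max(r2), 1)
    tmax <- sqrt(df * r2max / max(1 - r2max, 1e-300))
    min_p[b] <- max(2 * pt(-tmax, df), .P_UNDERFLOW)
  }
  threshold <- unname(quantile(min_p, alpha, type = 7))
  structure(list(B = B, min_p = min_p, alpha = alpha, threshold = threshold,
                 seed = seed),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("permutation_null: B = %d, alpha = %g, threshold = %.3g\n",
              x$B, x$alpha, x$threshold))
  invisible(x)
}

#' CDR3 k-mer vs HLA scan
#'
#' Identical machinery to [assoc_scan()]; when `condition_vgene` (a named
#' numeric vector, e.g. one INRT V-gene usage column) is supplied it is
#' appended to the covariates, testing whether a motif association is
#' mediated by V-gene usage.
#'
#' @param kmer_phenos `phenotype_matrix` of k-mer traits (stage inrt).
#' @param predictors HLA allele dosage matrix and/or MHC variants.
#' @param covariates covariate data frame or design matrix.
#' @param condition_vgene optional named numeric vector.
#' @return data frame of AssociationResult rows.
#' @export
kmer_hla_scan <- function(kmer_phenos, predictors, covariates = NULL,
                          condition_vgene = NULL) {
  if (is.null(condition_vgene)) {
    return(assoc_scan(kmer_phenos, predictors, covariates))
  }
  al <- .align_matrices(kmer_phenos, predictors, covariates)
  v <- condition_vgene[al$ids]
  if (anyNA(v)) .stopf("condition_vgene missing for some individuals")
  Xc <- cbind(al$X, vgene_usage = v)
  assoc_scan(al$Y, al$G, Xc, model = "conditional",
             conditioned_on = "vgene_usage")
}
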