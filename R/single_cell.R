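#' Single-cell repertoire analyses
#'
#' Cell-level inclusion filters, per-subset V-gene usage, the 20-gene
#' tumour reactivity score (TRS), nested-model testing of TRS against
#' HLA-matching status, singlet/expanded stratification and TRS vs clone
#' size correlation.
#'
#' @name single_cell
NULL

#' Cell quality-control filters
#'
#' Drops cells with fewer than 300 transcripts or more than 20%
#' mitochondrial content, then cells whose chain multiplicity is not
#' 1 alpha + 1 beta or 2 alpha + 1 beta.
#'
#' @param cells cell data frame (columns total_transcripts, mito_fraction,
#'   n_alpha, n_beta).
#' @param min_transcripts,max_mito filter thresholds.
#' @return filtered cell data frame.
#' @export
qc_cells <- function(cells, min_transcripts = 300, max_mito = 0.20) {
  keep <- cells$total_transcripts >= min_transcripts &
    cells$mito_fraction <= max_mito
  cells <- cells[keep, , drop = FALSE]
  keep <- cells$n_alpha %in% c(1L, 2L) & cells$n_beta == 1L
  cells[keep, , drop = FALSE]
}

#' @noRd
.cell_clone_key <- function(cells) {
  paste(cells$individual_id, cells$alpha1_cdr3, cells$beta_cdr3, sep = "|")
}

#' Per-individual single-cell V-gene usage
#'
#' Cells are collapsed to unique clones (same TRA and TRB CDR3 within an
#' individual); usage is the number of distinct clones per V-gene divided
#' by the total distinct clones of that individual in the chosen subset,
#' so rows sum to 1.
#'
#' @param cells QC-passed cell data frame.
#' @param subset cell subset label (NULL for all cells).
#' @param chain "alpha" or "beta".
#' @return matrix individuals x V-genes of usage fractions; individuals
#'   with no clones in the subset are absent.
#' @export
cell_vgene_usage <- function(cells, subset = NULL, chain = "beta") {
  if (!is.null(subset)) cells <- cells[cells$subset == subset, , drop = FALSE]
  if (nrow(cells) == 0) .stopf("no cells in subset")
  vg <- if (chain == "beta") cells$beta_v else cells$alpha1_v
  cl <- unique(data.frame(individual_id = cells$individual_id,
                          key = .cell_clone_key(cells), v_gene = vg,
                          stringsAsFactors = FALSE))
  ind <- sort(unique(cl$individual_id))
  genes <- sort(unique(cl$v_gene))
  tab <- table(factor(cl$individual_id, levels = ind),
               factor(cl$v_gene, levels = genes))
  m <- matrix(as.numeric(tab), length(ind), length(genes),
              dimnames = list(ind, genes))
  sweep(m, 1, rowSums(m), `/`)
}

#' Residualise TCR PCs on experimental protocol
#'
#' When protocol is highly correlated with the leading repertoire PCs,
#' the protocol is regressed out of each PC and the residuals used as
#' covariates instead.
#'
#' @param pcs matrix individuals x components.
#' @param protocol protocol label per individual (named or in row order).
#' @return matrix of residualised scores (orthogonal to the protocol
#'   indicators).
#' @export
residualize_pcs <- function(pcs, protocol) {
  if (!is.null(names(protocol))) protocol <- protocol[rownames(pcs)]
  stopifnot(length(protocol) == nrow(pcs))
  X <- model.matrix(~ factor(protocol))
  q <- qr(X)
  out <- apply(pcs, 2, function(y) qr.resid(q, y))
  dimnames(out) <- dimnames(pcs)
  out
}

#' Per-subset association between usage and a predictor
#'
#' [assoc_scan()] with the single-cell covariate set: the supplied
#' covariates (age, sex, cancer type, genetic PCs), protocol indicators,
#' and protocol-residualised TCR PCs.
#'
#' @param usage matrix individuals x V-genes from [cell_vgene_usage()]
#'   (INRT-transform upstream if desired).
#' @param predictors dosage matrix or `genotype_matrix`.
#' @param covariates covariate data frame.
#' @param protocol named protocol label per individual.
#' @param tcr_pcs matrix of repertoire PCs (pre-residualisation).
#' @return data frame of AssociationResult rows.
#' @export
subset_association <- function(usage, predictors, covariates, protocol,
                               tcr_pcs = NULL) {
  ids <- rownames(usage)
  df <- covariates[match(ids, covariates$individual_id), , drop = FALSE]
  df$protocol <- protocol[ids]
  if (!is.null(tcr_pcs)) {
    rpc <- residualize_pcs(tcr_pcs[ids, , drop = FALSE], protocol[ids])
    colnames(rpc) <- paste0("tcr_", colnames(rpc), "_resid")
    df <- cbind(df, as.data.frame(rpc))
  }
  assoc_scan(usage, predictors, df)
}

#' Tumour reactivity score
#'
#' Per cell, the sum of the 20 panel genes standardised to mean 0 and SD 1
#' across the analysis set. Expression is assumed already depth-normalised
#' and log-transformed.
#'
#' @param cells cell data frame holding one column per panel gene.
#' @param panel character vector of 20 gene names.
#' @return named numeric vector of TRS per cell.
#' @export
compute_trs <- function(cells, panel) {
  miss <- setdiff(panel, names(cells))
  if (length(miss) > 0) .stopf("panel gene(s) missing from cells: %s",
                               paste(miss, collapse = ", "))
  s <- rowSums(as.matrix(cells[, panel, drop = FALSE]))
  if (sd(s) == 0) .stopf("panel sum has zero variance; TRS undefined")
  setNames((s - mean(s)) / sd(s), cells$cell_id)
}

#' Per-cell HLA-matching status
#'
#' A cell is matched iff its beta-chain V-gene (and, if alpha rules are
#' supplied, either alpha V-gene) pairs with a rule allele the individual
#' carries at dosage >= 1.
#'
#' @param cells cell data frame.
#' @param rules match rules (v_gene, hla_allele).
#' @param hla `hla_genotypes`.
#' @return integer vector (0/1) along cells.
#' @export
cell_match_status <- function(cells, rules, hla) {
  m <- rep(FALSE, nrow(cells))
  dos <- hla$allele_dosage
  irow <- match(cells$individual_id, rownames(dos))
  for (i in seq_len(nrow(rules))) {
    if (!rules$hla_allele[i] %in% colnames(dos)) next
    carrier <- dos[, rules$hla_allele[i]] >= 1
    vg <- rules$v_gene[i]
    uses <- cells$beta_v == vg
    if (startsWith(vg, "TRAV")) {
      uses <- cells$alpha1_v == vg |
        (!is.na(cells$alpha2_v) & cells$alpha2_v == vg)
    }
    m <- m | (uses & carrier[irow])
  }
  as.integer(m)
}

#' Clone size per cell
#'
#' Number of QC-passed cells sharing the cell's clone (same TRA and TRB
#' CDR3 within the individual). Size 1 = singlet; >= 2 = expanded.
#'
#' @param cells cell data frame.
#' @return integer vector along cells.
#' @export
cell_clone_sizes <- function(cells) {
  key <- .cell_clone_key(cells)
  as.integer(table(key)[key])
}

#' TRS vs HLA-matching status, nested-model test
#'
#' Compares H1: TRS ~ matching status + protocol against H0: TRS ~
#' protocol by an F-test (ANOVA between nested linear models), reporting
#' the matching-status coefficient and the comparison p.
#'
#' @param trs numeric TRS per cell.
#' @param match_status 0/1 per cell.
#' @param protocol protocol label per cell.
#' @param stratum label recorded in the result.
#' @return one-row data frame (stratum, beta, p, n_cells, note).
#' @export
trs_vs_matching <- function(trs, match_status, protocol, stratum = "all") {
  res <- data.frame(stratum = stratum, beta = NA_real_, p = NA_real_,
                    n_cells = length(trs), note = "",
                    stringsAsFactors = FALSE)
  if (length(unique(match_status)) < 2) {
    res$note <- "untestable: one matching status absent"
    return(res)
  }
  proto <- factor(protocol)
  if (nlevels(proto) > 1) {
    h1 <- lm(trs ~ match_status + proto)
    h0 <- lm(trs ~ proto)
  } else {
    h1 <- lm(trs ~ match_status)
    h0 <- lm(trs ~ 1)
  }
  an <- anova(h0, h1)
  res$beta <- coef(h1)[["match_status"]]
  res$p <- an[["Pr(>F)"]][2]
  if (all(trs == trs[1])) res$p <- 1
  res
}

#' TRS vs matching status across strata
#'
#' Runs [trs_vs_matching()] on all cells, each subset, singlets only and
#' expanded clones only.
#'
#' @param cells QC-passed cell data frame.
#' @param trs,match_status,protocol per-cell vectors aligned with cells.
#' @return data frame, one row per stratum.
#' @export
trs_strata <- function(cells, trs, match_status, protocol) {
  sizes <- cell_clone_sizes(cells)
  strata <- c(list(all = rep(TRUE, nrow(cells))),
              lapply(setNames(nm = sort(unique(cells$subset))),
                     function(s) cells$subset == s),
              list(singlet = sizes == 1, expanded = sizes >= 2))
  do.call(rbind, lapply(names(strata), function(nm) {
    i <- strata[[nm]]
    if (sum(i) < 4) {
      return(data.frame(stratum = nm, beta = NA_real_, p = NA_real_,
                        n_cells = sum(i), note = "untestable: too few cells",
                        stringsAsFactors = FALSE))
    }
    trs_vs_matching(trs[i], match_status[i], protocol[i], stratum = nm)
  }))
}

#' Spearman correlation between TRS and clone size
#'
#' @param trs numeric TRS per cell.
#' @param clone_sizes integer clone size per cell.
#' @return list(r, p); constant clone sizes give NA with a warning.
#' @export
trs_clone_size_correlation <- function(trs, clone_sizes) {
  if (length(trs) < 3) .stopf("need >= 3 cells")
  if (length(unique(clone_sizes)) < 2) {
    .warnf("constant clone sizes; correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    cor.test(trs, clone_sizes, method = "spearman", exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}
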