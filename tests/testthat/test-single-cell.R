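make_cells <- function(n = 200, seed = 1, shift = 0, matched = NULL,
                       protocol = NULL) {
  set.seed(seed)
  panel <- repqtl:::.TRS_PANEL
  if (is.null(matched)) matched <- rbinom(n, 1, 0.4)
  if (is.null(protocol)) protocol <- sample(c("P1", "P2"), n, TRUE)
  expr <- matrix(rnorm(n * 20, 4), n, dimnames = list(NULL, panel))
  expr <- expr + matched * shift * sqrt(20) / 20
  cells <- data.frame(
    cell_id = sprintf("c%04d", 1:n),
    individual_id = sprintf("I%02d", sample(5, n, TRUE)),
    subset = sample(c("CD8_TEM", "CD8_TEMRA", "CD8_naive"), n, TRUE),
    protocol = protocol,
    alpha1_v = "TRAV1", alpha1_cdr3 = sprintf("CAVR%03dGNKLTF", sample(60, n, TRUE)),
    alpha2_v = NA_character_, alpha2_cdr3 = NA_character_,
    beta_v = sample(c("TRBV19", "TRBV28"), n, TRUE),
    beta_cdr3 = sprintf("CASS%03dYNEQFF", sample(60, n, TRUE)),
    n_alpha = 1L, n_beta = 1L,
    total_transcripts = 3000L, mito_fraction = 0.05,
    stringsAsFactors = FALSE)
  cbind(cells, as.data.frame(expr), matched = matched)
}

test_that("cell QC applies the transcript, mito and chain-multiplicity rules", {
  cells <- make_cells(20)
  cells$total_transcripts[1] <- 299L  # strictly below 300: removed
  cells$total_transcripts[2] <- 300L  # boundary: kept
  cells$mito_fraction[3] <- 0.25
  cells$n_alpha[4] <- 2L              # 2a1b: kept
  cells$n_beta[5] <- 2L               # 2b: removed
  cells$n_alpha[6] <- 0L
  out <- qc_cells(cells)
  expect_false("c0001" %in% out$cell_id)
  expect_true("c0002" %in% out$cell_id)
  expect_false("c0003" %in% out$cell_id)
  expect_true("c0004" %in% out$cell_id)
  expect_false("c0005" %in% out$cell_id)
  expect_false("c0006" %in% out$cell_id)
})

test_that("single-cell V-gene usage rows sum to 1 and match the set-collapse oracle", {
  cells <- make_cells(300, seed = 3)
  usage <- cell_vgene_usage(cells, subset = "CD8_TEM", chain = "beta")
  expect_equal(unname(rowSums(usage)), rep(1, nrow(usage)))
  sub <- cells[cells$subset == "CD8_TEM", ]
  for (id in rownames(usage)) {
    s <- sub[sub$individual_id == id, ]
    clones <- unique(paste(s$alpha1_cdr3, s$beta_cdr3))
    for (vg in colnames(usage)) {
      with_vg <- unique(paste(s$alpha1_cdr3, s$beta_cdr3)[s$beta_v == vg])
      expect_equal(usage[id, vg], length(with_vg) / length(clones))
    }
  }
})

test_that("protocol-residualised PCs are orthogonal to protocol indicators", {
  set.seed(7)
  n <- 40
  pcs <- matrix(rnorm(n * 2), n,
                dimnames = list(sprintf("I%02d", 1:n), c("PC1", "PC2")))
  protocol <- sample(c("P1", "P2", "P3"), n, TRUE)
  r <- residualize_pcs(pcs, protocol)
  for (p in unique(protocol)) {
    ind <- as.numeric(protocol == p)
    expect_lt(abs(crossprod(r[, 1], ind)), 1e-10)
    expect_lt(abs(crossprod(r[, 2], ind)), 1e-10)
  }
})

test_that("TRS is an exact standardisation and location-invariant", {
  cells <- make_cells(500, seed = 11)
  trs <- compute_trs(cells, repqtl:::.TRS_PANEL)
  expect_lt(abs(mean(trs)), 1e-10)
  expect_lt(abs(sd(trs) - 1), 1e-10)
  shifted <- cells
  shifted[, repqtl:::.TRS_PANEL] <- shifted[, repqtl:::.TRS_PANEL] + 3
  expect_equal(compute_trs(shifted, repqtl:::.TRS_PANEL), trs,
               tolerance = 1e-10)
  expect_error(compute_trs(cells[, -match("ENTPD1", names(cells))],
                           repqtl:::.TRS_PANEL), "ENTPD1")
})

test_that("a planted TRS shift moves group means by ~shift/sd", {
  delta <- 0.5
  cells <- make_cells(4000, seed = 13, shift = delta)
  trs <- compute_trs(cells, repqtl:::.TRS_PANEL)
  diff_ <- mean(trs[cells$matched == 1]) - mean(trs[cells$matched == 0])
  # panel sum has SD ~ sqrt(20); planted shift is delta * sqrt(20), so the
  # standardised group difference is ~delta
  expect_lt(abs(diff_ - delta), 0.1)
})

test_that("TRS vs matching status: nested F-test behaves at the null and under signal", {
  cells <- make_cells(2000, seed = 17, shift = 0.4)
  trs <- compute_trs(cells, repqtl:::.TRS_PANEL)
  res <- trs_vs_matching(trs, cells$matched, cells$protocol)
  expect_lt(res$p, 1e-4)
  expect_lt(abs(res$beta - 0.4), 0.15)

  # identical TRS values: p = 1
  same <- trs_vs_matching(rep(0, 100), rbinom(100, 1, 0.5),
                          rep("P1", 100))
  expect_equal(same$p, 1)

  # one status absent: untestable
  one <- trs_vs_matching(rnorm(50), rep(1, 50), rep("P1", 50))
  expect_match(one$note, "untestable")
})

test_that("with one protocol level the F statistic is the squared two-sample t", {
  set.seed(19)
  trs <- rnorm(300)
  match_ <- rbinom(300, 1, 0.5)
  res <- trs_vs_matching(trs, match_, rep("P1", 300))
  tt <- t.test(trs[match_ == 1], trs[match_ == 0], var.equal = TRUE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("singlet and expanded strata partition the cells", {
  cells <- make_cells(400, seed = 23)
  trs <- compute_trs(cells, repqtl:::.TRS_PANEL)
  strata <- trs_strata(cells, trs, cells$matched, cells$protocol)
  n_singlet <- strata$n_cells[strata$stratum == "singlet"]
  n_expanded <- strata$n_cells[strata$stratum == "expanded"]
  expect_equal(n_singlet + n_expanded, nrow(cells))
  sizes <- cell_clone_sizes(cells)
  expect_equal(n_singlet, sum(sizes == 1))
})

test_that("TRS/clone-size Spearman correlation hits the exact endpoints", {
  expect_equal(trs_clone_size_correlation(1:10, 1:10)$r, 1)
  expect_equal(trs_clone_size_correlation(1:10, 10:1)$r, -1)
  set.seed(29)
  null <- trs_clone_size_correlation(rnorm(2000), sample(1:5, 2000, TRUE))
  expect_lt(abs(null$r), 0.05)
  expect_warning(r0 <- trs_clone_size_correlation(rnorm(10), rep(2L, 10)),
                 "constant")
  expect_true(is.na(r0$r))
})

test_that("subset-specific planted effects are strongest in their subset", {
  set.seed(31)
  hits <- 0
  for (s in 1:10) {
    n <- 80
    ids <- sprintf("I%03d", 1:n)
    allele <- rbinom(n, 2, 0.4) * 1.0
    protocol <- setNames(sample(c("P1", "P2"), n, TRUE), ids)
    mk_usage <- function(beta) {
      u <- matrix(plogis(-1 + beta * allele + rnorm(n, 0, 0.5)), n,
                  dimnames = list(ids, "TRBV19"))
      cbind(u, TRBVother = 1 - u[, 1])
    }
    temra <- mk_usage(0.8)
    naive <- mk_usage(0)
    H <- matrix(allele, n, dimnames = list(ids, "B*44"))
    cov_df <- data.frame(individual_id = ids, age = rnorm(n, 60, 8))
    bt <- subset_association(temra, H, cov_df, protocol)
    bn <- subset_association(naive, H, cov_df, protocol)
    if (abs(bt$beta[bt$feature == "TRBV19"]) >
        abs(bn$beta[bn$feature == "TRBV19"])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
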