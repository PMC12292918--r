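test_that("V-gene usage counts unique clones, ignoring multiplicity", {
  cl <- make_clones(
    list("I1", "C1", "beta", "TRBV28", "CASSAYNEQFF", 5L),
    list("I1", "C1", "beta", "TRBV28", "CASSBYNEQFF", 1L),
    list("I1", "C1", "beta", "TRBV19", "CASSCYNEQFF", 2L),
    list("I1", "C1", "beta", "TRBV28", "CASSAYNEQFF", 3L),  # dup clone
    list("I1", "C1", "beta", "TRBV6", "CASSDYNEQFF", 1L, FALSE),  # unproductive
    list("I2", "C1", "beta", "TRBV19", "CASSEYNEQFF", 1L))
  pm <- count_vgene_usage(cl, "beta", "C1")
  expect_equal(pm$stage, "raw_counts")
  expect_equal(pm$values["I1", "TRBV28"], 2L)
  expect_equal(pm$values["I1", "TRBV19"], 1L)
  expect_false("TRBV6" %in% colnames(pm$values))
})

test_that("V-gene counting matches the set-cardinality oracle on random cohorts", {
  set.seed(5)
  for (rep_ in 1:3) {
    cfg <- sim_config(n_individuals = 8, n_variants = 20,
                      clones_per_sample = 60, n_vgenes_beta = 6,
                      n_vgenes_alpha = 5, timepoints = "C1",
                      with_cells = FALSE, with_survival = FALSE,
                      seed = 100L + rep_)
    co <- simulate_cohort(cfg)
    pm <- count_vgene_usage(co$clones, "beta", "C1")
    oracle <- oracle_vgene_counts(co$clones, "beta", "C1",
                                  rownames(pm$values), colnames(pm$values))
    expect_equal(unname(pm$values), unname(oracle))
  }
})

test_that("k-mer windows follow the L-k+1 rule and the length band", {
  cl <- make_clones(
    list("I1", "C1", "beta", "TRBV1", "ACDEFGHIKLMN"),       # L = 12
    list("I2", "C1", "beta", "TRBV1", "ACDEFGHIKLM"))        # L = 11
  pm <- count_kmers(cl, "beta", "C1")
  expect_equal(ncol(pm$values), 6)  # 12 - 7 + 1 windows
  expect_setequal(colnames(pm$values),
                  c("ACDEFGH", "CDEFGHI", "DEFGHIK", "EFGHIKL",
                    "FGHIKLM", "GHIKLMN"))
  expect_equal(sum(pm$values["I2", ]), 0)  # length-11 CDR3 contributes nothing
})

test_that("a motif occurring twice in one CDR3 counts once (clone presence)", {
  cl <- make_clones(
    list("I1", "C1", "beta", "TRBV1", "AAAAAAAAAAAAAA"))   # L = 14
  pm <- count_kmers(cl, "beta", "C1")
  expect_equal(unname(pm$values["I1", "AAAAAAA"]), 1L)
})

test_that("k-mer counting matches the naive substring-search oracle", {
  set.seed(9)
  cfg <- sim_config(n_individuals = 6, n_variants = 10, clones_per_sample = 80,
                    n_vgenes_beta = 5, n_vgenes_alpha = 4, timepoints = "C1",
                    with_cells = FALSE, with_survival = FALSE, seed = 21L)
  co <- simulate_cohort(cfg)
  pm <- count_kmers(co$clones, "beta", "C1")
  oracle <- oracle_kmer_counts(co$clones, "beta", "C1", 7, 12, 18)
  nonzero <- which(pm$values > 0, arr.ind = TRUE)
  expect_equal(sum(pm$values), sum(unlist(oracle)))
  for (r in sample(nrow(nonzero), min(50, nrow(nonzero)))) {
    i <- rownames(pm$values)[nonzero[r, 1]]
    mo <- colnames(pm$values)[nonzero[r, 2]]
    expect_equal(unname(pm$values[i, mo]),
                 oracle[[paste(i, mo, sep = "\r")]])
  }
  expect_warning(count_kmers(co$clones, "beta", "C1", k = 6), "motif length")
})

test_that("TMM factors: identity cases and the hand-stepped trace", {
  ids <- sprintf("I%d", 1:4)
  base <- matrix(rep(c(100L, 50L, 80L, 20L, 60L, 90L), each = 4), 4,
                 dimnames = list(ids, sprintf("g%d", 1:6)))
  pm <- phenotype_matrix(base, "raw_counts")
  expect_equal(unname(tmm_factors(pm)), rep(1, 4), tolerance = 1e-12)

  scaled <- base
  scaled[2, ] <- 3L * base[2, ]   # pure library-size change
  f <- tmm_factors(phenotype_matrix(scaled, "raw_counts"))
  expect_equal(unname(f), rep(1, 4), tolerance = 1e-12)

  set.seed(13)
  bumpy <- matrix(rpois(4 * 40, 60), 4,
                  dimnames = list(ids, sprintf("g%d", 1:40)))
  bumpy[1, 1:8] <- bumpy[1, 1:8] * 6L   # inflated feature block
  pmb <- phenotype_matrix(bumpy, "raw_counts")
  expect_equal(tmm_factors(pmb), oracle_tmm(bumpy), tolerance = 1e-10)
  expect_lt(abs(sum(log(tmm_factors(pmb)))), 1e-10)
})

test_that("CPM normalisation is scale-invariant per individual", {
  ids <- sprintf("I%d", 1:3)
  m <- matrix(c(10L, 20L, 30L, 40L, 10L, 20L, 30L, 40L, 20L, 40L, 60L, 80L),
              3, byrow = TRUE, dimnames = list(ids, sprintf("g%d", 1:4)))
  pm <- phenotype_matrix(m, "raw_counts")
  f <- tmm_factors(pm)
  norm <- normalize_counts(pm, f)
  expect_equal(norm$stage, "normalized")
  # individual 3 = 2x individual 1: normalized rows identical
  expect_equal(norm$values[3, ], norm$values[1, ], tolerance = 1e-12)
  # closed-form division oracle
  lib <- rowSums(m)
  expect_equal(norm$values, m / (lib * f) * 1e6, tolerance = 1e-12)
})

test_that("batch correction removes a planted offset and passes single batch through", {
  set.seed(17)
  n <- 30
  ids <- sprintf("I%04d", 1:n)
  vals <- matrix(rnorm(n * 5, 50, 3), n, dimnames = list(ids, sprintf("g%d", 1:5)))
  batch <- rep(c("B1", "B2"), each = n / 2)
  shifted <- vals
  shifted[batch == "B2", ] <- shifted[batch == "B2", ] + 7
  pm <- phenotype_matrix(shifted, "normalized")
  corr <- remove_batch(pm, batch)
  expect_equal(corr$stage, "batch_corrected")
  for (j in 1:5) {
    expect_equal(mean(corr$values[batch == "B1", j]),
                 mean(corr$values[batch == "B2", j]), tolerance = 1e-10)
  }
  single <- remove_batch(phenotype_matrix(vals, "normalized"), rep("B1", n))
  expect_equal(single$values, vals)
  expect_error(remove_batch(pm, c("Bx", batch[-1])), "single individual")
})

test_that("INRT matches the normal-quantile oracle and is rank-invariant", {
  ids <- sprintf("I%d", 1:3)
  m <- matrix(c(3, 1, 2), 3, dimnames = list(ids, "g1"))
  out <- inrt(phenotype_matrix(m, "batch_corrected"))
  z <- qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4))
  expect_equal(unname(out$values[, 1]), z)
  expect_equal(out$values[1, 1], -out$values[2, 1])  # antisymmetric about 0
  expect_equal(out$values[3, 1], 0)

  set.seed(23)
  x <- matrix(rexp(40), 40, dimnames = list(sprintf("I%d", 1:40), "g"))
  a <- inrt(phenotype_matrix(x, "batch_corrected"))
  b <- inrt(phenotype_matrix(exp(x * 2 + 1), "batch_corrected"))
  expect_equal(a$values, b$values)   # strictly monotone transform
  # ties map to equal outputs
  tied <- matrix(c(1, 5, 5, 2), 4, dimnames = list(sprintf("I%d", 1:4), "g"))
  tt <- inrt(phenotype_matrix(tied, "batch_corrected"))
  expect_equal(tt$values[2, 1], tt$values[3, 1])
  # shape check without ties: mean and skew ~ 0
  v <- a$values[, 1]
  expect_lt(abs(mean(v)), 1e-8)
  expect_lt(abs(mean((v - mean(v))^3)), 1e-8)
})

test_that("pipeline stage order is enforced", {
  ids <- sprintf("I%d", 1:4)
  m <- matrix(1:8 * 1L, 4, dimnames = list(ids, c("g1", "g2")))
  raw <- phenotype_matrix(m, "raw_counts")
  expect_error(inrt(raw), "expects stage")
  expect_error(remove_batch(raw, rep("B1", 4)), "expects stage")
  norm <- normalize_counts(raw, tmm_factors(raw))
  expect_error(normalize_counts(norm, tmm_factors(raw)), "expects stage")
  expect_error(inrt(norm), "expects stage")
})

test_that("TCR PCs recover structure with the fixed sign convention", {
  set.seed(31)
  n <- 50
  ids <- sprintf("I%04d", 1:n)
  # rank-1 + tiny noise: PC1 captures ~all variance
  u <- rnorm(n)
  m <- outer(u, rnorm(8)) + matrix(rnorm(n * 8, 0, 1e-3), n)
  dimnames(m) <- list(ids, sprintf("g%d", 1:8))
  pm <- phenotype_matrix(m, "batch_corrected")
  sc <- tcr_pcs(pm, 2)
  expect_gt(var(sc[, 1]) / (var(sc[, 1]) + var(sc[, 2])), 0.99)
  expect_lt(abs(crossprod(sc[, 1], sc[, 2])), 1e-6)
})
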