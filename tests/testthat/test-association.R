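test_that("fit_additive matches hand-solved normal equations", {
  # textbook 6-point fixture with two covariates
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 12.2)
  dos <- c(0, 1, 2, 0, 1, 2)
  cov_m <- cbind(age = c(50, 60, 55, 70, 65, 58),
                 sexM = c(1, 0, 1, 0, 1, 0))
  rownames(cov_m) <- names(y) <- sprintf("I%d", 1:6)
  res <- fit_additive(y, dos, cov_m)
  oracle <- oracle_ols(y, cbind(1, dos, cov_m))
  expect_equal(res$beta, unname(oracle$beta[2]), tolerance = 1e-12)
  expect_equal(res$se, unname(oracle$se[2]), tolerance = 1e-12)
  expect_equal(res$p, unname(oracle$p[2]), tolerance = 1e-12)
})

test_that("perfect fits cap the p-value and flag it", {
  y <- 0.5 * c(0, 1, 2, 1, 0, 2, 1)
  names(y) <- sprintf("I%d", 1:7)
  res <- fit_additive(y, c(0, 1, 2, 1, 0, 2, 1))
  expect_equal(res$beta, 0.5, tolerance = 1e-12)
  expect_equal(res$p, 1e-300)
  expect_match(res$note, "underflow")
})

test_that("zero-variance dosage is flagged untestable, collinearity errors name columns", {
  y <- rnorm(10)
  names(y) <- sprintf("I%d", 1:10)
  res <- fit_additive(y, rep(1, 10))
  expect_match(res$note, "zero-variance")
  cov_df <- data.frame(individual_id = names(y), age = 1:10,
                       age2 = 2 * (1:10))
  expect_error(build_design(cov_df), "collinear.*age")
})

test_that("the scan fast path equals looped per-pair OLS fits", {
  set.seed(41)
  n <- 40
  ids <- sprintf("I%04d", 1:n)
  Y <- matrix(rnorm(n * 3), n, dimnames = list(ids, c("f1", "f2", "f3")))
  G <- matrix(rbinom(n * 4, 2, 0.4) * 1.0, n,
              dimnames = list(ids, sprintf("v%d", 1:4)))
  G[5, 2] <- NA  # exercise the per-pair fallback
  cov_df <- data.frame(individual_id = ids, age = rnorm(n, 60, 8),
                       sex = sample(c("M", "F"), n, TRUE),
                       cancer_type = sample(c("melanoma", "renal"), n, TRUE))
  res <- assoc_scan(Y, G, cov_df)
  expect_equal(nrow(res), 12)
  X <- build_design(cov_df, ids)
  for (r in seq_len(nrow(res))) {
    yv <- Y[, res$feature[r]]
    dv <- G[, res$predictor[r]]
    ref <- fit_additive(yv, dv, X)
    expect_equal(res$beta[r], ref$beta, tolerance = 1e-10)
    expect_equal(res$se[r], ref$se, tolerance = 1e-10)
    expect_equal(res$p[r], ref$p, tolerance = 1e-10)
  }
})

test_that("scan is invariant to individual order and covariate rescaling", {
  set.seed(43)
  n <- 30
  ids <- sprintf("I%04d", 1:n)
  Y <- matrix(rnorm(n * 2), n, dimnames = list(ids, c("f1", "f2")))
  G <- matrix(rbinom(n * 3, 2, 0.3) * 1.0, n,
              dimnames = list(ids, sprintf("v%d", 1:3)))
  cov_df <- data.frame(individual_id = ids, age = rnorm(n, 60, 8))
  base <- assoc_scan(Y, G, cov_df)
  perm <- sample(n)
  shuffled <- assoc_scan(Y[perm, ], G[perm, ], cov_df[perm, ])
  expect_equal(shuffled$p, base$p, tolerance = 1e-10)
  cov_df2 <- cov_df; cov_df2$age <- cov_df2$age * 13 - 100
  expect_equal(assoc_scan(Y, G, cov_df2)$p, base$p, tolerance = 1e-10)
})

test_that("biallelic omnibus equals the squared-t single-residue test", {
  set.seed(47)
  n <- 80
  ids <- sprintf("I%04d", 1:n)
  dos44 <- rbinom(n, 2, 0.4)
  R <- cbind(K = dos44, E = 2 - dos44)
  rownames(R) <- ids
  y <- 0.3 * dos44 + rnorm(n)
  names(y) <- ids
  cov_df <- data.frame(individual_id = ids, age = rnorm(n, 60, 8))
  om <- omnibus_position_test(y, R, cov_df)
  X <- build_design(cov_df, ids)
  single <- fit_additive(y, R[, "E"], X)  # less common residue is dropped ref's complement
  expect_equal(om$p, single$p, tolerance = 1e-10)
  expect_equal(om$df_num, 1L)
  # reference choice (column order) does not change p
  om2 <- omnibus_position_test(y, R[, c("E", "K")], cov_df)
  expect_equal(om2$p, om$p, tolerance = 1e-10)
})

test_that("omnibus p is uniform under the null (multi-residue)", {
  set.seed(53)
  n <- 120
  ids <- sprintf("I%04d", 1:n)
  ps <- replicate(400, {
    a1 <- sample(c("K", "E", "Q"), n, TRUE, prob = c(0.5, 0.3, 0.2))
    a2 <- sample(c("K", "E", "Q"), n, TRUE, prob = c(0.5, 0.3, 0.2))
    R <- cbind(K = (a1 == "K") + (a2 == "K"),
               E = (a1 == "E") + (a2 == "E"),
               Q = (a1 == "Q") + (a2 == "Q"))
    rownames(R) <- ids
    y <- rnorm(n)
    names(y) <- ids
    omnibus_position_test(y, R)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("single-residue positions are untestable", {
  n <- 20
  R <- cbind(K = rep(2, n))
  rownames(R) <- sprintf("I%d", 1:n)
  y <- rnorm(n)
  names(y) <- rownames(R)
  res <- omnibus_position_test(y, R)
  expect_match(res$note, "single residue")
})

test_that("permutation thresholds are deterministic with quantile endpoints", {
  set.seed(59)
  n <- 40
  ids <- sprintf("I%04d", 1:n)
  Y <- matrix(rnorm(n * 3), n, dimnames = list(ids, sprintf("f%d", 1:3)))
  G <- matrix(rbinom(n * 5, 2, 0.3) * 1.0, n,
              dimnames = list(ids, sprintf("v%d", 1:5)))
  a <- permutation_threshold(Y, G, B = 30, seed = 99L)
  b <- permutation_threshold(Y, G, B = 30, seed = 99L)
  expect_identical(a$min_p, b$min_p)
  expect_equal(a$threshold, unname(quantile(a$min_p, 0.05)))
  full <- permutation_threshold(Y, G, B = 30, alpha = 1, seed = 99L)
  expect_equal(full$threshold, max(full$min_p))
  expect_error(permutation_threshold(Y, G, B = 10), "B must be")
  expect_true(all(a$min_p > 0 & a$min_p <= 1))
})

test_that("conditioning on the causal variant kills its LD proxy's signal", {
  set.seed(61)
  proxies <- numeric(0)
  for (s in 1:12) {
    n <- 200
    ids <- sprintf("I%04d", 1:n)
    causal <- rbinom(n, 2, 0.3) * 1.0
    proxy <- causal                      # tight (not literal) LD: a fully
    flip <- sample(n, n %/% 20)          # collinear copy would be untestable
    proxy[flip] <- rbinom(length(flip), 2, 0.3)
    indep <- rbinom(n, 2, 0.3) * 1.0
    G <- cbind(causal = causal, proxy = proxy, indep = indep)
    rownames(G) <- ids
    y <- 0.8 * causal + rnorm(n)
    Y <- matrix(y, n, dimnames = list(ids, "f"))
    marg <- assoc_scan(Y, G)
    cond <- conditional_scan(Y, G, condition_on = "causal")
    proxies[s] <- cond$p[cond$predictor == "proxy"]
    expect_lt(marg$p[marg$predictor == "proxy"], 1e-6)
    expect_true(is.na(cond$p[cond$predictor == "causal"]))
    # an independent variant is essentially unaffected by conditioning
    expect_lt(abs(cond$beta[cond$predictor == "indep"] -
                    marg$beta[marg$predictor == "indep"]), 0.25)
  }
  expect_gt(median(proxies), 0.01)
})

test_that("a secondary signal survives conditioning on the primary", {
  set.seed(67)
  ps <- vapply(1:10, function(s) {
    n <- 300
    ids <- sprintf("I%04d", 1:n)
    v1 <- rbinom(n, 2, 0.3) * 1.0
    v2 <- rbinom(n, 2, 0.3) * 1.0      # independent second causal variant
    G <- cbind(v1 = v1, v2 = v2)
    rownames(G) <- ids
    Y <- matrix(0.6 * v1 + 0.5 * v2 + rnorm(n), n, dimnames = list(ids, "f"))
    cond <- conditional_scan(Y, G, condition_on = "v1")
    cond$p[cond$predictor == "v2"]
  }, numeric(1))
  expect_lt(median(ps), 1e-4)
})

test_that("kmer scan supports V-gene conditioning through the same machinery", {
  set.seed(71)
  n <- 150
  ids <- sprintf("I%04d", 1:n)
  allele <- rbinom(n, 2, 0.3) * 1.0
  vg_usage <- 0.5 * allele + rnorm(n)    # mediator-ish V-gene usage
  names(vg_usage) <- ids
  kmer <- matrix(1.0 * allele + 0.3 * vg_usage + rnorm(n), n,
                 dimnames = list(ids, "TGDSNQP"))
  H <- matrix(allele, n, dimnames = list(ids, "B*35:01"))
  plain <- kmer_hla_scan(kmer, H)
  cond <- kmer_hla_scan(kmer, H, condition_vgene = vg_usage)
  expect_lt(abs(cond$beta - 1.0), 0.35)    # direct effect retained
  expect_lt(cond$beta, plain$beta)         # attenuated by the mediator
  expect_equal(cond$model, "conditional")
})
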