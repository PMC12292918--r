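test_that("clone partition identities hold exactly", {
  c1 <- make_clones(list("I1", "C1", "beta", "TRBV1", "CASSA"),
                    list("I1", "C1", "beta", "TRBV1", "CASSB"))
  c2 <- make_clones(list("I1", "C2", "beta", "TRBV1", "CASSB"),
                    list("I1", "C2", "beta", "TRBV1", "CASSC"))
  lab <- classify_clones(c1, c2)
  expect_equal(lab$group[lab$cdr3_aa == "CASSA"], "unstable")
  expect_equal(lab$group[lab$cdr3_aa == "CASSB"], "persistent")
  expect_equal(lab$group[lab$cdr3_aa == "CASSC"], "novel")

  # identical sets: everything persistent
  same <- classify_clones(c1, c1)
  expect_true(all(same$group == "persistent"))

  # random sets: |unstable| + |persistent| = |C1|, |novel| + |persistent| = |C2|
  set.seed(73)
  cfg <- sim_config(n_individuals = 6, n_variants = 10, clones_per_sample = 50,
                    n_vgenes_beta = 4, n_vgenes_alpha = 4,
                    timepoints = c("C1", "C2"), with_cells = FALSE,
                    with_survival = FALSE, seed = 5L)
  co <- simulate_cohort(cfg)
  lab <- classify_clones(co$clones[co$clones$timepoint == "C1", ],
                         co$clones[co$clones$timepoint == "C2", ])
  for (id in unique(lab$individual_id)) {
    l <- lab[lab$individual_id == id & lab$chain == "beta", ]
    n1 <- nrow(unique(co$clones[co$clones$individual_id == id &
                                  co$clones$timepoint == "C1" &
                                  co$clones$chain == "beta",
                                c("v_gene", "cdr3_aa")]))
    n2 <- nrow(unique(co$clones[co$clones$individual_id == id &
                                  co$clones$timepoint == "C2" &
                                  co$clones$chain == "beta",
                                c("v_gene", "cdr3_aa")]))
    expect_equal(sum(l$group == "unstable") + sum(l$group == "persistent"), n1)
    expect_equal(sum(l$group == "novel") + sum(l$group == "persistent"), n2)
  }
})

test_that("resampling proportions at C4 behave on hand fixtures", {
  c1 <- make_clones(list("I1", "C1", "beta", "TRBV1", "CASSA"),
                    list("I1", "C1", "beta", "TRBV1", "CASSB"))
  c2 <- make_clones(list("I1", "C2", "beta", "TRBV1", "CASSB"))
  lab <- classify_clones(c1, c2)
  c4 <- make_clones(list("I1", "C4", "beta", "TRBV1", "CASSB"))
  pr <- resampling_proportions(lab, c4)
  expect_equal(pr$prop[pr$group == "persistent"], 1.0)
  expect_equal(pr$prop[pr$group == "unstable"], 0.0)
  # empty C4 sample: all proportions zero
  c4e <- make_clones(list("I1", "C4", "beta", "TRBV9", "CASSZZZ"))
  pre <- resampling_proportions(lab, c4e)
  expect_true(all(pre$prop == 0))
})

test_that("persistent clones are preferentially redetected at C4", {
  wins <- 0
  for (s in 1:12) {
    cfg <- sim_config(n_individuals = 10, n_variants = 10,
                      clones_per_sample = 400, n_vgenes_beta = 5,
                      n_vgenes_alpha = 4, c4_fraction = 1,
                      with_cells = FALSE, with_survival = FALSE,
                      seed = 300L + s)
    co <- simulate_cohort(cfg)
    lab <- classify_clones(co$clones[co$clones$timepoint == "C1", ],
                           co$clones[co$clones$timepoint == "C2", ])
    pr <- resampling_proportions(lab, co$clones[co$clones$timepoint == "C4", ])
    med <- tapply(pr$prop, pr$group, median)
    if (med["persistent"] > med["unstable"]) wins <- wins + 1
  }
  expect_gte(wins, 11)
})

test_that("HLA-matched proportions follow the rule-evaluation oracle", {
  rules <- data.frame(v_gene = "TRBV19", hla_allele = "B*44")
  hla <- make_hla(c(1L, 0L), c(1L, 2L))
  cl <- make_clones(list("I0001", "C1", "beta", "TRBV19", "CASSA"),
                    list("I0001", "C1", "beta", "TRBV1", "CASSB"),
                    list("I0001", "C1", "beta", "TRBV2", "CASSC"),
                    list("I0001", "C1", "beta", "TRBV3", "CASSD"),
                    list("I0002", "C1", "beta", "TRBV19", "CASSA"),
                    list("I0002", "C1", "beta", "TRBV1", "CASSB"))
  pr <- hla_matched_proportion(cl, rules, hla)
  expect_equal(pr$prop[pr$individual_id == "I0001"], 0.25)
  expect_equal(pr$prop[pr$individual_id == "I0002"], 0.0)  # no B*44 carried

  # overlapping rules vs brute-force per-clone evaluation
  rules2 <- rbind(rules,
                  data.frame(v_gene = "TRBV1", hla_allele = "B*35"))
  pr2 <- hla_matched_proportion(cl, rules2, hla)
  brute <- vapply(c("I0001", "I0002"), function(id) {
    sub <- unique(cl[cl$individual_id == id, c("v_gene", "cdr3_aa")])
    hits <- vapply(seq_len(nrow(sub)), function(r) {
      any(vapply(seq_len(nrow(rules2)), function(k) {
        sub$v_gene[r] == rules2$v_gene[k] &&
          hla$allele_dosage[id, rules2$hla_allele[k]] >= 1
      }, logical(1)))
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_equal(setNames(pr2$prop, pr2$individual_id), brute)
})

test_that("paired Wilcoxon exact branch equals full enumeration", {
  set.seed(79)
  for (n in c(6, 9, 12)) {
    for (rep_ in 1:5) {
      x <- rnorm(n); y <- rnorm(n)
      res <- paired_wilcoxon(x, y)
      expect_equal(res$p, oracle_wilcox_enum(x - y), tolerance = 1e-12,
                   label = sprintf("n=%d rep=%d", n, rep_))
    }
    # with ties in |differences|
    x <- rnorm(n); y <- x - sample(c(-2, -1, 1, 2), n, TRUE)
    res <- paired_wilcoxon(x, y)
    expect_equal(res$p, oracle_wilcox_enum(x - y), tolerance = 1e-12)
  }
  # eight all-positive differences: p = 2 / 2^8
  res <- paired_wilcoxon(2:9, 1:8)
  expect_equal(res$p, 2 / 2^8)
  expect_equal(res$method, "exact")
})

test_that("paired Wilcoxon handles degenerate input and branch agreement", {
  expect_warning(res <- paired_wilcoxon(1:5, 1:5), "all differences zero")
  expect_equal(res$p, 1)
  # exact vs normal approximation agree at the switch point
  set.seed(83)
  for (rep_ in 1:10) {
    x <- rnorm(25); y <- rnorm(25)
    ex <- paired_wilcoxon(x, y, exact_limit = 25)
    ap <- paired_wilcoxon(x, y, exact_limit = 10)
    expect_equal(ap$method, "normal approximation")
    expect_lt(abs(ex$p - ap$p), 0.01)
  }
  # agreement with the standard implementation in the tie-free exact regime
  set.seed(89)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(paired_wilcoxon(x, y)$p,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("top_allele_rules picks minimum p with deterministic tie-breaks", {
  res <- data.frame(
    feature = c("TRBV19", "TRBV19", "TRBV28", "TRBV28"),
    predictor = c("B*44", "B*35", "A*02", "A*01"),
    p = c(1e-8, 0.2, 0.5, 0.5))
  rules <- top_allele_rules(res)
  expect_equal(rules$hla_allele[rules$v_gene == "TRBV19"], "B*44")
  expect_equal(rules$hla_allele[rules$v_gene == "TRBV28"], "A*01")  # lexicographic tie-break
  sig <- top_allele_rules(res, p_threshold = 1e-6)
  expect_equal(sig$v_gene, "TRBV19")
})

test_that("group scans pool back to the all-clone scan", {
  set.seed(97)
  cfg <- sim_config(n_individuals = 40, n_variants = 30, clones_per_sample = 150,
                    n_vgenes_beta = 8, n_vgenes_alpha = 6,
                    timepoints = c("C1", "C2"), with_cells = FALSE,
                    with_survival = FALSE, seed = 11L)
  co <- simulate_cohort(cfg)
  prod <- co$clones[co$clones$productive, ]
  lab <- classify_clones(prod[prod$timepoint == "C1", ],
                         prod[prod$timepoint == "C2", ])
  G <- co$genotypes$dosage[, 1:5]
  scans <- lapply(c("unstable", "novel", "persistent"), function(gp) {
    group_association_scan(lab, gp, "beta", G)
  })
  expect_true(all(vapply(scans, nrow, integer(1)) > 0))
  # pooled groups = C1 u C2 clone set: same scan as running on the union
  pooled <- lab
  pooled$timepoint <- "C1"; pooled$count <- 1L; pooled$productive <- TRUE
  counts <- count_vgene_usage(pooled, "beta", "C1")
  ph <- phenotype_pipeline(counts)
  direct <- assoc_scan(ph$inrt, G)
  all_cl <- unique(
    prod[prod$timepoint %in% c("C1", "C2") & prod$chain == "beta",
         c("individual_id", "chain", "v_gene", "cdr3_aa")])
  counts2 <- count_vgene_usage(
    transform(all_cl, timepoint = "C1", count = 1L, productive = TRUE),
    "beta", "C1")
  ph2 <- phenotype_pipeline(counts2)
  expect_equal(assoc_scan(ph2$inrt, G)$p, direct$p, tolerance = 1e-10)
})
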