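# Independent brute-force oracles used to cross-check the implementation.
# Everything here is deliberately naive (loops, enumeration, closed forms)
# and shares no code with the package internals.

# OLS via explicit normal equations / pseudo-inverse
oracle_ols <- function(y, M) {
  xtx <- t(M) %*% M
  beta <- solve(xtx, t(M) %*% y)
  resid <- y - M %*% beta
  df <- length(y) - ncol(M)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  tval <- beta[, 1] / se
  list(beta = beta[, 1], se = se, t = tval,
       p = 2 * pt(-abs(tval), df), df = df)
}

# HWE exact p by direct enumeration over all heterozygote counts, with
# probabilities from the closed-form conditional distribution (log-gamma)
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_ab]
  sum(p[p <= obs + 1e-12 * obs])
}

# unique-clone V-gene counts by explicit per-cell set cardinality
oracle_vgene_counts <- function(clones, chain, timepoint, individuals, genes) {
  m <- matrix(0L, length(individuals), length(genes),
              dimnames = list(individuals, genes))
  for (i in individuals) {
    for (g in genes) {
      sub <- clones[clones$productive & clones$chain == chain &
                      clones$timepoint == timepoint &
                      clones$individual_id == i & clones$v_gene == g, ]
      m[i, g] <- length(unique(paste(sub$v_gene, sub$cdr3_aa)))
    }
  }
  m
}

# k-mer clone-presence counts by naive O(L*k) substring search
oracle_kmer_counts <- function(clones, chain, timepoint, k, min_len, max_len) {
  cl <- unique(clones[clones$productive & clones$chain == chain &
                        clones$timepoint == timepoint,
                      c("individual_id", "v_gene", "cdr3_aa")])
  cl <- cl[nchar(cl$cdr3_aa) >= min_len & nchar(cl$cdr3_aa) <= max_len, ]
  counts <- list()
  for (r in seq_len(nrow(cl))) {
    s <- cl$cdr3_aa[r]
    seen <- character(0)
    for (j in seq_len(nchar(s) - k + 1)) {
      seen <- union(seen, substr(s, j, j + k - 1))
    }
    for (mo in seen) {
      key <- paste(cl$individual_id[r], mo, sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-stepped TMM trace (reference by upper quartile, trimmed weighted
# mean of M-values, geometric-mean-1 rescale)
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- rowSums(counts)
  uq <- apply(counts, 1, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(nrow(counts)), function(i) {
    obs <- counts[i, ]; nO <- lib[i]
    refv <- counts[ref, ]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (length(logR) == 0 || max(logR) - min(logR) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f_ <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f_)) return(1)
    2^f_
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- rownames(counts)
  f
}

# hand product-limit table: events precede censorings at tied times
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events]))
  n <- length(times)
  surv <- numeric(length(ut))
  s <- 1
  for (j in seq_along(ut)) {
    at_risk <- sum(times >= ut[j])
    d <- sum(times == ut[j] & events)
    s <- s * (1 - d / at_risk)
    surv[j] <- s
  }
  data.frame(time = ut, surv = surv)
}

# hand log-rank observed/expected for two groups
oracle_logrank <- function(times, events, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ut <- sort(unique(times[events]))
  O <- c(0, 0); E <- c(0, 0); V <- 0
  for (t_ in ut) {
    n1 <- sum(times >= t_ & group == g[1])
    n2 <- sum(times >= t_ & group == g[2])
    d1 <- sum(times == t_ & events & group == g[1])
    d2 <- sum(times == t_ & events & group == g[2])
    n <- n1 + n2; d <- d1 + d2
    O <- O + c(d1, d2)
    E <- E + c(d * n1 / n, d * n2 / n)
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O[1] - E[1])^2 / V
  list(observed = O, expected = E, chi2 = chi2,
       p = pchisq(chi2, 1, lower.tail = FALSE))
}

# signed-rank exact p by full enumeration of all 2^n sign assignments
oracle_wilcox_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  lower <- mean(ws <= W)
  upper <- mean(ws >= W)
  min(1, 2 * min(lower, upper))
}

# small clone table builder for hand fixtures
make_clones <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(individual_id = r[[1]], timepoint = r[[2]], chain = r[[3]],
               v_gene = r[[4]], cdr3_aa = r[[5]],
               count = if (length(r) >= 6) r[[6]] else 1L,
               productive = if (length(r) >= 7) r[[7]] else TRUE,
               stringsAsFactors = FALSE)
  }))
  df$count <- as.integer(df$count)
  df
}

# tiny deterministic genotype matrix
make_genotypes <- function(dosage) {
  genotype_matrix(dosage, data.frame(
    id = colnames(dosage), chrom = "7",
    pos = seq_len(ncol(dosage)) * 100L, ref = "A", alt = "G",
    stringsAsFactors = FALSE))
}

# small HLA set: one gene, two 2-digit families with one 4-digit child each
make_hla <- function(dos44, dos35, residue_map = NULL) {
  n <- length(dos44)
  ids <- sprintf("I%04d", seq_len(n))
  m <- cbind("B*44:02" = dos44, "B*35:01" = dos35,
             "B*44" = dos44, "B*35" = dos35)
  rownames(m) <- ids
  if (is.null(residue_map)) {
    residue_map <- data.frame(gene = "B", exon = 2L, position = 45L,
                              allele = c("B*44:02", "B*35:01"),
                              residue = c("K", "E"),
                              stringsAsFactors = FALSE)
  }
  hla_genotypes(m, residue_map)
}
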