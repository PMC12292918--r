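#' Domain containers and tabular IO
#'
#' All tables move through plain TSVs with headers so that runs are fully
#' auditable as text. Readers validate type invariants and report offending
#' rows by line number; writers are exact inverses of the readers.
#'
#' @name repertoire_io
NULL

# ---- clone tables ----------------------------------------------------------

# canonical column names; AIRR Rearrangement-style aliases accepted via
# col_map (the upstream MiXCR/AIRR dialect is not reproduced here)
.CLONE_COLS <- c("individual_id", "timepoint", "chain", "v_gene",
                 "cdr3_aa", "count", "productive")
.AIRR_ALIASES <- c(v_gene = "v_call", cdr3_aa = "junction_aa",
                   count = "duplicate_count")

#' Validate a clone table
#'
#' Checks the invariants of a clone record set: known timepoints and chains,
#' CDR3 length >= 1, count >= 1, and chain/V-gene prefix consistency
#' (TRAV with alpha, TRBV with beta).
#'
#' @param clones data frame with canonical clone columns.
#' @return the validated data frame, invisibly typed (count integer,
#'   productive logical).
#' @export
validate_clones <- function(clones) {
  miss <- setdiff(.CLONE_COLS, names(clones))
  if (length(miss) > 0) {
    .stopf("clone table missing column(s): %s", paste(miss, collapse = ", "))
  }
  clones$count <- as.integer(clones$count)
  clones$productive <- as.logical(clones$productive)
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      .stopf("invalid clone rows (%s) at row(s): %s", what,
             paste(head(rows, 10), collapse = ", "))
    }
  }
  bad(!clones$timepoint %in% .TIMEPOINTS, "unknown timepoint")
  bad(!clones$chain %in% .CHAINS, "unknown chain")
  bad(nchar(clones$cdr3_aa) < 1, "empty cdr3_aa")
  bad(clones$count < 1, "count < 1")
  pref <- substr(clones$v_gene, 1, 4)
  expected <- ifelse(clones$chain == "alpha", "TRAV", "TRBV")
  bad(pref != expected, "chain/V-gene prefix mismatch")
  clones
}

#' Read a clone table TSV
#'
#' Accepts the canonical column names or any dialect via `col_map`, a named
#' character vector mapping canonical names to file column names. AIRR
#' Rearrangement-style names (`v_call`, `junction_aa`, `duplicate_count`)
#' are recognised automatically.
#'
#' @param path TSV file with a header row.
#' @param col_map optional named character vector, canonical -> file column.
#' @return validated clone data frame with canonical columns.
#' @export
read_clone_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) .stopf("clone table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (canon in names(.AIRR_ALIASES)) {
    alias <- .AIRR_ALIASES[[canon]]
    if (!canon %in% names(df) && alias %in% names(df)) {
      names(df)[names(df) == alias] <- canon
    }
  }
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df)) {
        names(df)[names(df) == col_map[[canon]]] <- canon
      }
    }
  }
  validate_clones(df[, .CLONE_COLS, drop = FALSE])
}

#' Write a clone table TSV
#'
#' @param clones validated clone data frame.
#' @param path output path.
#' @export
write_clone_table <- function(clones, path) {
  write.table(clones[, .CLONE_COLS, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- genotype matrix -------------------------------------------------------

#' Construct a genotype matrix
#'
#' @param dosage numeric matrix, individuals x variants, additive dosages in
#'   \[0, 2\] with NA for missing calls; rownames are individual ids.
#' @param variants data frame with columns id, chrom, pos (1-based), ref, alt;
#'   one row per dosage column.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) .stopf("variants missing column(s): %s",
                               paste(miss, collapse = ", "))
  if (nrow(variants) != ncol(dosage)) {
    .stopf("dosage has %d columns but variants has %d rows",
           ncol(dosage), nrow(variants))
  }
  if (anyDuplicated(variants$id)) .stopf("duplicate variant ids")
  if (is.null(rownames(dosage))) .stopf("dosage must have individual rownames")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) .stopf("dosages outside [0, 2]")
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read a genotype dosage TSV
#'
#' Layout: metadata columns id, chrom, pos, ref, alt followed by one column
#' per individual holding dosages in \[0, 2\]; empty cells or NA are missing.
#'
#' @param path TSV path.
#' @return `genotype_matrix`.
#' @export
read_dosage_matrix <- function(path) {
  if (!file.exists(path)) .stopf("dosage file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(meta, names(df))
  if (length(miss) > 0) .stopf("dosage file missing column(s): %s",
                               paste(miss, collapse = ", "))
  df$chrom <- as.character(df$chrom)
  ind <- setdiff(names(df), meta)
  dosage <- t(as.matrix(df[, ind, drop = FALSE]))
  mode(dosage) <- "numeric"
  bad <- which(!is.na(dosage) & (dosage < 0 | dosage > 2), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    .stopf("dosage outside [0, 2] for individual %s, variant %s",
           ind[bad[1, 1]], df$id[bad[1, 2]])
  }
  rownames(dosage) <- ind
  genotype_matrix(dosage, df[, meta])
}

#' Write a genotype dosage TSV
#'
#' @param g `genotype_matrix`.
#' @param path output path.
#' @export
write_dosage_matrix <- function(g, path) {
  out <- cbind(g$variants,
               as.data.frame(t(g$dosage), check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- HLA genotypes ---------------------------------------------------------

#' Construct an HLA genotype set
#'
#' Classical-allele dosages at 2- and 4-digit resolution plus an
#' allele-to-residue map per amino-acid position. Per gene and individual,
#' dosages at each resolution must sum to 2 (one allele per haplotype).
#'
#' @param allele_dosage integer matrix individuals x alleles; colnames are
#'   allele names like "B*44" (2-digit) or "B*44:02" (4-digit).
#' @param residue_map data frame with columns gene, exon, position, allele,
#'   residue; alleles here are 4-digit.
#' @return object of class `hla_genotypes`.
#' @export
hla_genotypes <- function(allele_dosage, residue_map) {
  stopifnot(is.matrix(allele_dosage))
  alleles <- colnames(allele_dosage)
  if (is.null(alleles)) .stopf("allele_dosage must have allele colnames")
  info <- .parse_hla_alleles(alleles)
  for (gene in unique(info$gene)) {
    for (res in c("two", "four")) {
      cols <- alleles[info$gene == gene & info$resolution == res]
      if (length(cols) == 0) next
      sums <- rowSums(allele_dosage[, cols, drop = FALSE])
      bad <- which(sums != 2)
      if (length(bad) > 0) {
        .stopf("HLA dosages for gene %s (%s-digit) sum to %g, not 2, for individual %s",
               gene, if (res == "two") "2" else "4",
               sums[bad[1]], rownames(allele_dosage)[bad[1]])
      }
    }
  }
  four <- alleles[info$resolution == "four"]
  parent <- sub(":[^:]*$", "", four)
  orphan <- four[!parent %in% alleles & length(alleles[info$resolution == "two"]) > 0]
  if (length(orphan) > 0 && any(info$resolution == "two")) {
    .stopf("4-digit allele(s) without a 2-digit parent: %s",
           paste(head(orphan, 5), collapse = ", "))
  }
  structure(list(allele_dosage = allele_dosage, alleles = info,
                 residue_map = residue_map),
            class = "hla_genotypes")
}

#' @noRd
.parse_hla_alleles <- function(alleles) {
  gene <- sub("\\*.*$", "", alleles)
  resolution <- ifelse(grepl(":", alleles), "four", "two")
  data.frame(allele = alleles, gene = gene, resolution = resolution,
             stringsAsFactors = FALSE)
}

#' @export
print.hla_genotypes <- function(x, ...) {
  cat(sprintf("hla_genotypes: %d individuals, %d alleles (%d genes), %d mapped residue positions\n",
              nrow(x$allele_dosage), ncol(x$allele_dosage),
              length(unique(x$alleles$gene)),
              nrow(unique(x$residue_map[, c("gene", "exon", "position")]))))
  invisible(x)
}

#' Read an HLA table (long TSV: individual_id, allele, dosage) plus a residue
#' map TSV (gene, exon, position, allele, residue)
#'
#' @param path allele dosage TSV.
#' @param residue_path residue map TSV; optional (empty map if absent).
#' @return `hla_genotypes`.
#' @export
read_hla_table <- function(path, residue_path = NULL) {
  if (!file.exists(path)) .stopf("HLA table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("individual_id", "allele", "dosage")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) .stopf("HLA table missing column(s): %s",
                               paste(miss, collapse = ", "))
  ind <- unique(df$individual_id)
  alleles <- unique(df$allele)
  m <- matrix(0L, length(ind), length(alleles),
              dimnames = list(ind, alleles))
  m[cbind(match(df$individual_id, ind), match(df$allele, alleles))] <-
    as.integer(df$dosage)
  rmap <- if (!is.null(residue_path) && file.exists(residue_path)) {
    read.delim(residue_path, sep = "\t", stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), exon = integer(), position = integer(),
               allele = character(), residue = character())
  }
  hla_genotypes(m, rmap)
}

#' Write an HLA table as long TSV (nonzero dosages only)
#'
#' @param hla `hla_genotypes`.
#' @param path allele dosage output TSV.
#' @param residue_path optional residue map output TSV.
#' @export
write_hla_table <- function(hla, path, residue_path = NULL) {
  idx <- which(hla$allele_dosage != 0, arr.ind = TRUE)
  out <- data.frame(
    individual_id = rownames(hla$allele_dosage)[idx[, 1]],
    allele = colnames(hla$allele_dosage)[idx[, 2]],
    dosage = hla$allele_dosage[idx])
  out <- out[order(out$individual_id, out$allele), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(residue_path)) {
    write.table(hla$residue_map, residue_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

# ---- covariates and survival ----------------------------------------------

#' Read a covariate table
#'
#' One row per individual; modelled columns (age, sex, cancer_type) must be
#' complete.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) .stopf("covariate file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"individual_id" %in% names(df)) .stopf("covariates need individual_id")
  if (anyDuplicated(df$individual_id)) .stopf("duplicate individuals in covariates")
  modeled <- intersect(c("age", "sex", "cancer_type"), names(df))
  for (col in modeled) {
    if (anyNA(df[[col]])) .stopf("missing values in modelled covariate '%s'", col)
  }
  df
}

#' Read a survival table (individual_id, os_time, event, optional group)
#'
#' @param path TSV path.
#' @return data frame with os_time numeric (days) and event logical.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) .stopf("survival file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("individual_id", "os_time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) .stopf("survival table missing column(s): %s",
                               paste(miss, collapse = ", "))
  df$os_time <- as.numeric(df$os_time)
  df$event <- as.logical(df$event)
  if (any(df$os_time < 0)) .stopf("negative os_time")
  df
}

#' Intersect analysis individuals across tables
#'
#' Warns when id sets differ and returns the common ids, the analysis set.
#'
#' @param ... character vectors of individual ids (named args give nicer
#'   warnings).
#' @return character vector of ids present in every input.
#' @export
intersect_individuals <- function(...) {
  sets <- list(...)
  common <- Reduce(intersect, sets)
  nm <- names(sets)
  for (i in seq_along(sets)) {
    extra <- setdiff(sets[[i]], common)
    if (length(extra) > 0) {
      .warnf("%d individual(s) in %s absent from the analysis set",
             length(extra),
             if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste0("table ", i))
    }
  }
  common
}
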