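#' Overall-survival comparison
#'
#' Kaplan-Meier estimation and log-rank comparison of overall survival
#' between carriers and non-carriers of HLA-matched clones. Estimation is
#' delegated to the survival package; at tied times events precede
#' censorings, the product-limit convention.
#'
#' @name os_analysis
NULL

#' Kaplan-Meier curve
#'
#' @param records survival data frame (os_time, event).
#' @return data frame of class `km_curve` (time, n_risk, n_event,
#'   n_censor, surv) with surv non-increasing from 1.
#' @export
km_estimate <- function(records) {
  if (nrow(records) < 1) .stopf("need >= 1 record")
  if (any(records$os_time < 0)) .stopf("negative survival times")
  fit <- survival::survfit(
    survival::Surv(os_time, event) ~ 1,
    data = records, conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test between groups
#'
#' @param records survival data frame (os_time, event).
#' @param group group label per record (defaults to the `group` column).
#' @return list(chi2, df, p, observed, expected) with df = #groups - 1.
#' @export
logrank_test <- function(records, group = NULL) {
  if (is.null(group)) group <- records$group
  g <- factor(group)
  if (nlevels(g) < 2) .stopf("log-rank needs >= 2 groups")
  if (sum(records$event) < 1) .stopf("log-rank needs >= 1 event")
  sd_ <- survival::survdiff(
    survival::Surv(records$os_time, records$event) ~ g)
  df <- nlevels(g) - 1
  list(chi2 = sd_$chisq, df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Carrier status of HLA-matched clones
#'
#' Flag per individual: 1 iff the individual has at least one HLA-matched
#' clone at any of the included timepoints. Individuals absent from the
#' clone table are NA (missing, not non-carrier).
#'
#' @param clones clone data frame.
#' @param timepoints which timepoints count (e.g. c("C1","C2")).
#' @param rules match rules (v_gene, hla_allele).
#' @param hla `hla_genotypes`.
#' @param individuals ids defining the output order (defaults to HLA
#'   individuals).
#' @return named integer vector (0/1/NA).
#' @export
carrier_status <- function(clones, timepoints, rules, hla,
                           individuals = NULL) {
  if (is.null(individuals)) individuals <- rownames(hla$allele_dosage)
  cl <- clones[clones$timepoint %in% timepoints, , drop = FALSE]
  m <- clone_matched(cl, rules, hla)
  has_any <- tapply(m, cl$individual_id, any)
  out <- setNames(rep(NA_integer_, length(individuals)), individuals)
  seen <- intersect(individuals, names(has_any))
  out[seen] <- as.integer(has_any[seen])
  out
}
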