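# Stratified Cox association of breakpoint patterns and expression with
# overall survival, signed-signature derivation, and the two-sample t-score
# signature metric with tertile log-rank testing.

apply_cap <- function(surv, cap_months) {
  if (is.null(cap_months) || !is.finite(cap_months)) return(surv)
  over <- surv$time > cap_months
  surv$time[over] <- cap_months
  surv$event[over] <- 0L
  surv
}

#' Stratified Cox association of one feature with overall survival
#'
#' Proportional-hazards partial likelihood stratified by cancer type
#' (separate baseline hazard per stratum), Breslow tie handling. Follow-up
#' may be capped: times beyond `cap_months` are truncated with the event flag
#' cleared. Returns both the two-sided Wald p and the one-sided p for a
#' positive (hazard-increasing) coefficient,
#' `p_one = p_two / 2` if `coef > 0`, else `1 - p_two / 2`.
#'
#' @param feature Per-patient numeric feature, aligned with `surv` rows.
#' @param surv Survival data frame (`patient_id`, `time`, `event`,
#'   `stratum`).
#' @param strata Stratum labels; defaults to `surv$stratum`.
#' @param cap_months Optional follow-up cap in months.
#' @return One-row data frame: `coef`, `se`, `p_two_sided`,
#'   `p_one_sided_positive`, `n_events`, `untestable`.
#' @export
cox_feature_survival <- function(feature, surv, strata = surv$stratum,
                                 cap_months = NULL) {
  surv <- apply_cap(surv, cap_months)
  untestable <- data.frame(coef = NA_real_, se = NA_real_,
                           p_two_sided = NA_real_,
                           p_one_sided_positive = NA_real_,
                           n_events = sum(surv$event), untestable = TRUE)
  if (length(unique(feature)) < 2 || sum(surv$event) < 2) return(untestable)
  dat <- data.frame(.time = surv$time, .event = surv$event,
                    .feature = feature, .strat = as.character(strata),
                    stringsAsFactors = FALSE)
  fml <- survival::Surv(.time, .event) ~ .feature + survival::strata(.strat)
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = "breslow"),
    error = function(e) NULL,
    warning = function(w) {
      suppressWarnings(survival::coxph(fml, data = dat, ties = "breslow"))
    })
  if (is.null(fit) || is.na(fit$coefficients[1])) return(untestable)
  co <- fit$coefficients[1]
  se <- sqrt(fit$var[1, 1])
  z <- co / se
  p2 <- 2 * stats::pnorm(-abs(z))
  p1 <- if (co > 0) p2 / 2 else 1 - p2 / 2
  data.frame(coef = unname(co), se = unname(se), p_two_sided = p2,
             p_one_sided_positive = p1, n_events = sum(surv$event),
             untestable = FALSE)
}

#' Scan breakpoint matrices for survival associations
#'
#' Runs [cox_feature_survival()] on every gene row of each supplied
#' breakpoint matrix (genes with fewer than `min_carriers` carriers are
#' skipped).
#'
#' @param matrices Named list of `breakpoint_matrix` objects (name = window
#'   label).
#' @param surv Survival data frame; rows are matched to matrix columns by
#'   `patient_id`.
#' @param cap_months Optional follow-up cap.
#' @param min_carriers Minimum carriers per gene (default 3).
#' @return Data frame: `gene_id`, `window`, `coef`, `p_two_sided`,
#'   `p_one_sided_positive`.
#' @export
cox_breakpoint_scan <- function(matrices, surv, cap_months = NULL,
                                min_carriers = 3) {
  out <- list()
  for (w in names(matrices)) {
    M <- matrices[[w]]
    samples <- colnames(M$values)
    s <- surv[match(samples, surv$patient_id), ]
    keep <- M$carrier_counts >= min_carriers
    for (g in rownames(M$values)[keep]) {
      r <- cox_feature_survival(M$values[g, ], s)
      if (r$untestable) next
      out[[paste(g, w)]] <- data.frame(gene_id = g, window = w,
                                       coef = r$coef,
                                       p_two_sided = r$p_two_sided,
                                       p_one_sided_positive = r$p_one_sided_positive,
                                       stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
         else NULL
  if (is.null(res))
    res <- data.frame(gene_id = character(), window = character(),
                      coef = numeric(), p_two_sided = numeric(),
                      p_one_sided_positive = numeric(),
                      stringsAsFactors = FALSE)
  res
}

#' Derive a signed survival gene signature
#'
#' A gene enters the signature iff (a) for some window its breakpoint
#' pattern is positively associated with worse survival (one-sided
#' `p < surv_p`), and (b) for some window its breakpoint pattern is
#' associated with altered expression (two-sided `p < assoc_p`). The gene's
#' direction is the sign of the expression effect in the qualifying window
#' with the smallest p (exact ties broken by larger `|beta|`).
#'
#' @param surv_results Output of [cox_breakpoint_scan()].
#' @param assoc_results Association records pooled over windows.
#' @param surv_p One-sided survival p threshold (default 0.05).
#' @param assoc_p Two-sided expression p threshold (default 0.05).
#' @return A `signed_signature` list: `genes` (named vector of +1/-1),
#'   `provenance` (thresholds), `n_positive`, `n_negative`.
#' @export
derive_signature <- function(surv_results, assoc_results,
                             surv_p = 0.05, assoc_p = 0.05) {
  surv_ok <- surv_results[!is.na(surv_results$p_one_sided_positive) &
                            surv_results$coef > 0 &
                            surv_results$p_one_sided_positive < surv_p, ]
  expr_ok <- assoc_results[!is.na(assoc_results$p) &
                             assoc_results$p < assoc_p &
                             !is.na(assoc_results$direction), ]
  genes <- intersect(unique(surv_ok$gene_id), unique(expr_ok$gene_id))
  if (!length(genes)) {
    warning("no genes satisfy both criteria; empty signature")
    sig <- structure(list(genes = setNames(numeric(0), character(0)),
                          provenance = list(surv_p = surv_p, assoc_p = assoc_p),
                          n_positive = 0L, n_negative = 0L),
                     class = "signed_signature")
    return(sig)
  }
  dir <- vapply(genes, function(g) {
    e <- expr_ok[expr_ok$gene_id == g, ]
    e <- e[order(e$p, -abs(e$beta)), ]
    if (e$beta[1] > 0) 1 else -1
  }, numeric(1))
  structure(list(genes = setNames(dir, genes),
                 provenance = list(surv_p = surv_p, assoc_p = assoc_p),
                 n_positive = sum(dir > 0), n_negative = sum(dir < 0)),
            class = "signed_signature")
}

#' Center log2 expression profiles per gene
#'
#' Converts a linear-scale expression matrix to log2(x + 1) and subtracts
#' the per-gene cohort mean, yielding the differential profiles expected by
#' [tscore()].
#'
#' @param expr_matrix Gene x sample matrix, linear scale.
#' @return Gene x sample matrix of centered log2 values.
#' @export
center_log_expression <- function(expr_matrix) {
  y <- log2(expr_matrix + 1)
  sweep(y, 1, rowMeans(y))
}

#' Signature t-score of one expression profile
#'
#' The two-sided pooled-variance two-sample t statistic comparing the
#' profile's values over the signature's high (+1) genes with its values
#' over the low (-1) genes. Genes missing from the profile are dropped and
#' counted; at least 2 genes per side are required.
#'
#' @param signature A `signed_signature`.
#' @param profile Named per-gene numeric vector of centered differential
#'   values for one sample (see [center_log_expression()]).
#' @return The t statistic, with attributes `n_high`, `n_low`, `n_missing`;
#'   NA (flagged via attribute `reason`) when a side has fewer than 2 genes.
#' @export
tscore <- function(signature, profile) {
  dirs <- signature$genes
  present <- names(dirs)[names(dirs) %in% names(profile)]
  n_missing <- length(dirs) - length(present)
  hi <- profile[present[dirs[present] > 0]]
  lo <- profile[present[dirs[present] < 0]]
  if (length(hi) < 2 || length(lo) < 2)
    return(structure(NA_real_, reason = "fewer than 2 genes on a side",
                     n_high = length(hi), n_low = length(lo),
                     n_missing = n_missing))
  sp2 <- ((length(hi) - 1) * var(hi) + (length(lo) - 1) * var(lo)) /
    (length(hi) + length(lo) - 2)
  d <- mean(hi) - mean(lo)
  t <- if (sp2 == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / sqrt(sp2 * (1 / length(hi) + 1 / length(lo)))
  structure(t, n_high = length(hi), n_low = length(lo),
            n_missing = n_missing,
            zero_variance = sp2 == 0)
}

#' Score every sample of an expression matrix with a signature
#'
#' @param signature A `signed_signature`.
#' @param expr_matrix Gene x sample matrix on the linear scale; profiles are
#'   centered with [center_log_expression()] before scoring.
#' @return Named numeric vector of t-scores per sample.
#' @export
score_cohort <- function(signature, expr_matrix) {
  centered <- center_log_expression(expr_matrix)
  vapply(colnames(centered), function(s) as.numeric(tscore(signature,
                                                           centered[, s])),
         numeric(1))
}

#' Survival separation by signature score
#'
#' Splits patients into tertiles of the score (boundaries at the 1/3 and 2/3
#' empirical quantiles), runs a stratified log-rank test across the three
#' groups and a stratified Cox model on the continuous score.
#'
#' @param scores Per-patient signature scores, aligned with `surv`.
#' @param surv Survival data frame.
#' @param strata Stratum labels; defaults to `surv$stratum`.
#' @param cap_months Optional follow-up cap.
#' @return List `logrank_p`, `cox_p`, `cox_coef`, `groups` (factor
#'   low/intermediate/high).
#' @export
signature_survival <- function(scores, surv, strata = surv$stratum,
                               cap_months = NULL) {
  surv <- apply_cap(surv, cap_months)
  qs <- quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
  if (qs[1] == qs[2])
    stop("tertile boundaries collide at score ", signif(qs[1], 4),
         "; scores too heavily tied")
  groups <- cut(scores, c(-Inf, qs, Inf),
                labels = c("low", "intermediate", "high"))
  if (any(table(groups) < 3))
    stop("fewer than 3 patients in a tertile")
  dat <- data.frame(.time = surv$time, .event = surv$event, .group = groups,
                    .strat = as.character(strata), stringsAsFactors = FALSE)
  sd_fit <- survival::survdiff(
    survival::Surv(.time, .event) ~ .group + survival::strata(.strat),
    data = dat)
  logrank_p <- pchisq(sd_fit$chisq, df = length(levels(groups)) - 1,
                      lower.tail = FALSE)
  cx <- cox_feature_survival(scores, surv, strata)
  list(logrank_p = logrank_p, cox_p = cx$p_two_sided, cox_coef = cx$coef,
       groups = groups)
}
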