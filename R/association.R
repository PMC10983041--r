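# Per-gene linear-model association of log2 expression with breakpoint
# pattern under three covariate models, BH-FDR with the minimum-carrier
# filter, direction counts, and germline/somatic overlap.

ASSOC_MODELS <- c("none", "tissue", "full")

# build the covariate part of the design matrix (everything but the
# breakpoint column and the per-gene copy number); tissue is coded as
# treatment contrasts against the most frequent tissue
covariate_design <- function(covars, model) {
  n <- nrow(covars)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (model %in% c("tissue", "full")) {
    tab <- sort(table(covars$tissue), decreasing = TRUE)
    lev <- names(tab)
    if (length(lev) > 1) {
      tt <- factor(covars$tissue, levels = lev)
      Xt <- stats::model.matrix(~tt)[, -1, drop = FALSE]
      colnames(Xt) <- paste0("tissue", lev[-1])
      X <- cbind(X, Xt)
    } else {
      warning("single-tissue cohort: tissue term dropped")
    }
  }
  if (model == "full") X <- cbind(X, ploidy = covars$ploidy,
                                  purity = covars$purity)
  X
}

# least-squares fit returning the t test for the first column ("bkpt");
# NA p flags an untestable design
bkpt_lm_t <- function(y, X) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X))
    return(list(beta = NA_real_, t = NA_real_, p = NA_real_))
  df <- length(y) - qr_$rank
  if (df <= 0) return(list(beta = NA_real_, t = NA_real_, p = NA_real_))
  coefs <- qr.coef(qr_, y)
  res <- y - X %*% coefs
  rss <- sum(res^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr_))
  se <- sqrt(sigma2 * XtX_inv[1, 1])
  if (!is.finite(se) || se == 0) {
    # zero residual variance: an exact fit gives t = 0 only when beta = 0
    tval <- if (abs(coefs[1]) < 1e-12) 0 else sign(coefs[1]) * Inf
  } else {
    tval <- coefs[1] / se
  }
  p <- 2 * pt(-abs(tval), df)
  list(beta = unname(coefs[1]), t = unname(tval), p = p)
}

#' Associate one gene's expression with its breakpoint pattern
#'
#' Fits `log2(expr + 1) ~ bkpt [+ covariates]` by ordinary least squares and
#' returns the two-sided t test for the breakpoint coefficient. Models:
#' `none` (intercept only), `tissue` (adds tissue indicator contrasts with
#' the most frequent tissue as reference), `full` (tissue plus gene-level
#' copy number, tumor ploidy and tumor purity). With `model = "none"` and a
#' binary breakpoint vector, the p value equals the pooled-variance
#' two-sample t test on the two groups.
#'
#' @param expr Per-sample expression values on the linear scale.
#' @param bkpt Per-sample breakpoint values (0/1 or weights).
#' @param covars Data frame with `tissue`, `ploidy`, `purity` rows aligned
#'   with `expr`; may be NULL for `model = "none"`.
#' @param model `"none"`, `"tissue"` or `"full"`.
#' @param copy_number Per-sample gene-level copy number (required for
#'   `model = "full"`).
#' @return One-row data frame: `beta`, `t`, `p`, `n_carriers`, `direction`.
#'   `p` is NA when the design is rank deficient or expression is constant.
#' @export
fit_gene_association <- function(expr, bkpt, covars = NULL,
                                 model = c("full", "tissue", "none"),
                                 copy_number = NULL) {
  model <- match.arg(model)
  if (length(unique(bkpt)) < 2)
    stop("breakpoint vector must take at least 2 distinct values")
  y <- log2(expr + 1)
  Xc <- if (model == "none")
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  else covariate_design(covars, model)
  if (model == "full") {
    if (is.null(copy_number)) stop("model 'full' requires copy_number")
    Xc <- cbind(Xc, copy_number = copy_number)
  }
  X <- cbind(bkpt = bkpt, Xc)
  if (nrow(X) <= ncol(X))
    return(data.frame(beta = NA_real_, t = NA_real_, p = NA_real_,
                      n_carriers = sum(bkpt > 0),
                      direction = NA_character_, stringsAsFactors = FALSE))
  fit <- bkpt_lm_t(y, X)
  if (stats::var(y) == 0) fit <- list(beta = 0, t = NA_real_, p = NA_real_)
  data.frame(beta = fit$beta, t = fit$t, p = fit$p,
             n_carriers = sum(bkpt > 0),
             direction = if (is.na(fit$beta) || fit$beta == 0) NA_character_
                         else if (fit$beta > 0) "positive" else "negative",
             stringsAsFactors = FALSE)
}

#' Run gene-level SV-expression associations for one window
#'
#' For every gene present in both the breakpoint matrix and the expression
#' matrix, fits [fit_gene_association()] under the requested model. Genes
#' with fewer than `min_carriers` samples carrying a breakpoint in the window
#' are excluded before estimating the false discovery rate; Benjamini-
#' Hochberg q values are computed within the tested gene set of this window.
#' Samples with missing covariates are dropped listwise.
#'
#' @param M A `breakpoint_matrix`.
#' @param expr_matrix Gene x sample expression matrix (linear scale).
#' @param covars Covariate data frame with `patient_id`, `tissue`, `ploidy`,
#'   `purity`.
#' @param model Covariate model (`"none"`, `"tissue"`, `"full"`).
#' @param min_carriers Minimum carrier count (default 3).
#' @param copy_matrix Gene x sample copy-number matrix (required for
#'   `model = "full"`).
#' @return Data frame sorted by p: `gene_id`, `window`, `model`, `beta`,
#'   `t`, `p`, `q`, `n_carriers`, `direction`.
#' @export
run_associations <- function(M, expr_matrix, covars,
                             model = c("full", "tissue", "none"),
                             min_carriers = 3, copy_matrix = NULL) {
  model <- match.arg(model)
  samples <- colnames(M$values)
  miss_e <- setdiff(samples, colnames(expr_matrix))
  if (length(miss_e))
    stop("samples in breakpoint matrix but not expression matrix: ",
         paste(head(miss_e, 10), collapse = ", "))
  if (!identical(sort(samples), sort(covars$patient_id)))
    stop("covariate samples do not match matrix samples: ",
         paste(head(c(setdiff(samples, covars$patient_id),
                      setdiff(covars$patient_id, samples)), 10),
               collapse = ", "))
  covars <- covars[match(samples, covars$patient_id), ]
  ok <- complete.cases(covars[, intersect(c("tissue", "ploidy", "purity"),
                                          names(covars))])
  if (!all(ok)) {
    message(sum(!ok), " samples dropped for missing covariates")
    samples <- samples[ok]
    covars <- covars[ok, ]
  }

  genes <- intersect(rownames(M$values), rownames(expr_matrix))
  B <- M$values[genes, samples, drop = FALSE]
  E <- expr_matrix[genes, samples, drop = FALSE]
  carriers <- rowSums(B > 0)
  cand <- genes[carriers[genes] >= min_carriers]
  # constant breakpoint vectors (e.g. every sample a carrier in a binary
  # window) are untestable and leave the tested set
  tested <- cand[vapply(cand, function(g) {
    v <- B[g, ]; max(v) > min(v)
  }, logical(1))]
  if (!length(tested))
    return(data.frame(gene_id = character(), window = character(),
                      model = character(), beta = numeric(), t = numeric(),
                      p = numeric(), q = numeric(), n_carriers = integer(),
                      direction = character(), stringsAsFactors = FALSE))

  Xc <- if (model == "none")
    matrix(1, length(samples), 1, dimnames = list(NULL, "(Intercept)"))
  else covariate_design(covars, model)
  if (model == "full") {
    if (is.null(copy_matrix)) stop("model 'full' requires copy_matrix")
    copy_matrix <- copy_matrix[genes, samples, drop = FALSE]
  }

  res <- lapply(tested, function(g) {
    X <- cbind(bkpt = B[g, ], Xc)
    if (model == "full") X <- cbind(X, copy_number = copy_matrix[g, ])
    y <- log2(E[g, ] + 1)
    fit <- if (nrow(X) <= ncol(X) || stats::var(y) == 0)
      list(beta = NA_real_, t = NA_real_, p = NA_real_)
    else bkpt_lm_t(y, X)
    data.frame(gene_id = g, window = M$window$label, model = model,
               beta = fit$beta, t = fit$t, p = fit$p,
               n_carriers = unname(carriers[g]),
               direction = if (is.na(fit$beta) || fit$beta == 0) NA_character_
                           else if (fit$beta > 0) "positive" else "negative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- p.adjust(out$p[ok], method = "BH")
  out <- out[order(out$p), c("gene_id", "window", "model", "beta", "t", "p",
                             "q", "n_carriers", "direction")]
  rownames(out) <- NULL
  out
}

#' Count significant genes split by direction
#'
#' @param records Association records with `q` and `direction`.
#' @param q_threshold FDR threshold (default 0.10).
#' @return Named vector `c(n_positive, n_negative)`.
#' @export
count_significant <- function(records, q_threshold = 0.10) {
  if (!nrow(records)) return(c(n_positive = 0L, n_negative = 0L))
  sig <- !is.na(records$q) & records$q < q_threshold & !is.na(records$direction)
  c(n_positive = sum(sig & records$direction == "positive"),
    n_negative = sum(sig & records$direction == "negative"))
}

#' Genes altered by both germline and somatic SVs
#'
#' Intersects germline and somatic association records by (gene, window),
#' requiring the same effect direction and p below `p_threshold` in both.
#'
#' @param germline_records,somatic_records Association records (same model,
#'   typically `full`).
#' @param p_threshold Per-set p cutoff (default 0.01).
#' @return Data frame `gene_id`, `window`, `direction`, `p_germline`,
#'   `p_somatic`.
#' @export
overlap_germline_somatic <- function(germline_records, somatic_records,
                                     p_threshold = 0.01) {
  g <- germline_records[!is.na(germline_records$p) &
                          germline_records$p < p_threshold, ]
  s <- somatic_records[!is.na(somatic_records$p) &
                         somatic_records$p < p_threshold, ]
  m <- merge(g[, c("gene_id", "window", "direction", "p")],
             s[, c("gene_id", "window", "direction", "p")],
             by = c("gene_id", "window"), suffixes = c("_germline", "_somatic"))
  m <- m[m$direction_germline == m$direction_somatic, ]
  out <- data.frame(gene_id = m$gene_id, window = m$window,
                    direction = m$direction_germline,
                    p_germline = m$p_germline, p_somatic = m$p_somatic,
                    stringsAsFactors = FALSE)
  out[order(out$p_germline), ]
}
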