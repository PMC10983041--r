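test_that("equal group means give a zero effect with p = 1", {
  expr <- 2^c(5, 5, 6, 6) - 1
  bkpt <- c(1, 0, 1, 0)
  r <- fit_gene_association(expr, bkpt, model = "none")
  expect_equal(r$beta, 0)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
})

test_that("model none on a binary pattern reproduces the pooled t-test", {
  set.seed(61)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    bkpt <- rbinom(n, 1, 0.3)
    if (sum(bkpt) < 2 || sum(!bkpt) < 2) next
    y <- rnorm(n, 5 + 0.5 * bkpt, 1)
    expr <- 2^y - 1
    r <- fit_gene_association(expr, bkpt, model = "none")
    tt <- t.test(y[bkpt == 1], y[bkpt == 0], var.equal = TRUE)
    expect_lt(abs(r$p - tt$p.value), 1e-10)
    expect_lt(abs(abs(r$t) - abs(tt$statistic)), 1e-8)
  }
})

test_that("q values equal the hand-computed Benjamini-Hochberg adjustment", {
  inst <- random_instance(40, 50, 500, seed = 63)
  set.seed(64)
  expr <- matrix(2^rnorm(40 * 50, 6, 1) - 1, 40, 50,
                 dimnames = list(inst$genes$gene_id, inst$samples))
  covars <- data.frame(patient_id = inst$samples,
                       tissue = rep(c("A", "B"), 25),
                       ploidy = runif(50, 2, 4), purity = runif(50, 0.4, 1))
  M <- build_breakpoint_matrix(inst$cohort, inst$genes, "gene_body",
                               samples = inst$samples)
  res <- run_associations(M, expr, covars, model = "tissue")
  expect_gt(nrow(res), 3)
  expect_equal(res$q, oracle_bh(res$p))
  expect_true(all(res$q >= res$p))
  expect_true(!is.unsorted(res$p))
  expect_true(all(res$n_carriers >= 3))
  expect_equal(res$direction, ifelse(res$beta > 0, "positive", "negative"))
})

test_that("association records are invariant to consistent sample permutation", {
  inst <- random_instance(30, 40, 400, seed = 65)
  set.seed(66)
  expr <- matrix(2^rnorm(30 * 40, 6, 1) - 1, 30, 40,
                 dimnames = list(inst$genes$gene_id, inst$samples))
  covars <- data.frame(patient_id = inst$samples,
                       tissue = sample(c("A", "B", "C"), 40, replace = TRUE),
                       ploidy = runif(40, 2, 4), purity = runif(40, 0.4, 1))
  cn <- matrix(2 + rnorm(30 * 40, 0, 0.2), 30, 40,
               dimnames = dimnames(expr))
  M <- build_breakpoint_matrix(inst$cohort, inst$genes, "gene_body",
                               samples = inst$samples)
  r1 <- run_associations(M, expr, covars, "full", copy_matrix = cn)

  perm <- sample(inst$samples)
  M2 <- M; M2$values <- M$values[, perm]
  r2 <- run_associations(M2, expr[, perm], covars[match(perm, covars$patient_id), ],
                         "full", copy_matrix = cn[, perm])
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("shifting all log-expression values leaves t and p unchanged", {
  set.seed(67)
  bkpt <- rbinom(40, 1, 0.4)
  y <- rnorm(40, 6, 1)
  r1 <- fit_gene_association(2^y - 1, bkpt, model = "none")
  r2 <- fit_gene_association(2^(y + 3) - 1, bkpt, model = "none")
  expect_equal(r1$t, r2$t, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("degenerate designs are flagged, not crashed", {
  # constant expression
  r <- fit_gene_association(rep(7, 20), rbinom(20, 1, 0.5), model = "none")
  expect_true(is.na(r$p))
  # constant breakpoint vector is a precondition violation
  expect_error(fit_gene_association(rnorm(20), rep(1, 20), model = "none"),
               "distinct")
  # single-tissue cohort drops the tissue term with a warning
  covars <- data.frame(tissue = rep("A", 20), ploidy = rep(2, 20),
                       purity = rep(0.8, 20))
  expect_warning(
    r2 <- fit_gene_association(2^rnorm(20, 6) - 1, rbinom(20, 1, 0.5),
                               covars, model = "tissue"),
    "single-tissue")
  expect_false(is.na(r2$p))
})

test_that("all-zero matrices and sample mismatches are handled", {
  genes <- make_genes("chr1", c(1e4, 5e4), c(2e4, 6e4))
  empty <- make_records("chr1", numeric(0), pos_b = numeric(0))
  M <- build_breakpoint_matrix(empty, genes, "gene_body",
                               samples = c("S1", "S2", "S3"))
  expr <- matrix(5, 2, 3, dimnames = list(genes$gene_id, c("S1", "S2", "S3")))
  covars <- data.frame(patient_id = c("S1", "S2", "S3"), tissue = "A",
                       ploidy = 2, purity = 1)
  expect_equal(nrow(run_associations(M, expr, covars, "none")), 0)
  expect_error(run_associations(M, expr[, 1:2], covars, "none"), "S3")
  covars_bad <- covars; covars_bad$patient_id[3] <- "SX"
  expect_error(run_associations(M, expr, covars_bad, "none"), "SX")
})

test_that("count_significant splits by direction at the q threshold", {
  expect_equal(count_significant(data.frame(q = numeric(0),
                                            direction = character(0))),
               c(n_positive = 0L, n_negative = 0L))
  rec <- data.frame(q = c(0.05, 0.2, 0.08), beta = c(1, 1, -1),
                    direction = c("positive", "positive", "negative"))
  expect_equal(count_significant(rec), c(n_positive = 1L, n_negative = 1L))
})

test_that("germline/somatic overlap requires same window and direction", {
  g <- data.frame(gene_id = "g1", window = "gene_body", direction = "positive",
                  p = 0.001, stringsAsFactors = FALSE)
  s <- g
  hit <- overlap_germline_somatic(g, s)
  expect_equal(hit$gene_id, "g1")
  s_neg <- s; s_neg$direction <- "negative"
  expect_equal(nrow(overlap_germline_somatic(g, s_neg)), 0)
  s_win <- s; s_win$window <- "up_100kb"
  expect_equal(nrow(overlap_germline_somatic(g, s_win)), 0)
  s_weak <- s; s_weak$p <- 0.5
  expect_equal(nrow(overlap_germline_somatic(g, s_weak)), 0)
})
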