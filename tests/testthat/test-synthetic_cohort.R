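test_that("simulate_genome satisfies its interval invariants", {
  g <- simulate_genome(2, 200, 50, 10, seed = 7)
  expect_equal(nrow(g$genes), 200)
  expect_true(all(g$genes$start < g$genes$end))
  expect_true(all(g$genes$start >= 0))
  expect_true(all(g$genes$end <= g$chrom_lengths[g$genes$chrom]))
  # genes do not overlap within a chromosome
  for (ch in names(g$chrom_lengths)) {
    sub <- g$genes[g$genes$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # cytobands tile each chromosome exactly, no overlap, no gap
  for (ch in names(g$chrom_lengths)) {
    b <- g$cytobands[g$cytobands$chrom == ch, ]
    b <- b[order(b$start), ]
    expect_equal(b$start[1], 0)
    expect_equal(b$end[nrow(b)], unname(g$chrom_lengths[ch]))
    expect_equal(b$start[-1], b$end[-nrow(b)])
  }
  # enhancers in bounds
  expect_true(all(g$enhancers$end <= g$chrom_lengths[g$enhancers$chrom]))
  # 3' UTR abuts the strand-appropriate gene end and lies within the gene
  u <- g$genes[!is.na(g$genes$utr3_start), ]
  expect_gt(nrow(u), 0)
  expect_true(all(ifelse(u$strand == "+", u$utr3_end == u$end,
                         u$utr3_start == u$start)))
  expect_true(all(u$utr3_start >= u$start & u$utr3_end <= u$end))
})

test_that("minimal genome and infeasible packing behave as specified", {
  g <- simulate_genome(1, 1, 0, 1, seed = 0)
  expect_equal(nrow(g$genes), 1)
  expect_equal(nrow(g$cytobands), 1)
  expect_equal(g$cytobands$start, 0)
  expect_equal(g$cytobands$end, unname(g$chrom_lengths))
  expect_error(simulate_genome(1, 100, 0, 1, seed = 0, chrom_length = 1e5,
                               gene_length_range = c(5e3, 1e4)),
               "infeasible")
})

test_that("the four simulators are deterministic in the seed", {
  g1 <- simulate_genome(2, 50, 20, 4, seed = 42)
  g2 <- simulate_genome(2, 50, 20, 4, seed = 42)
  expect_identical(g1, g2)
  c1 <- simulate_sv_cohort(g1, 30, germline_params = list(n_panel = 50), seed = 9)
  c2 <- simulate_sv_cohort(g2, 30, germline_params = list(n_panel = 50), seed = 9)
  expect_identical(c1, c2)
  e1 <- simulate_expression(g1, c1, seed = 5)
  e2 <- simulate_expression(g2, c2, seed = 5)
  expect_identical(e1, e2)
  s1 <- simulate_survival(NULL, e1$covariates, seed = 3)
  s2 <- simulate_survival(NULL, e2$covariates, seed = 3)
  expect_identical(s1, s2)
})

test_that("panel frequency 1 yields identical breakpoints in every patient", {
  g <- simulate_genome(1, 5, 0, 1, seed = 1)
  co <- simulate_sv_cohort(g, 3,
                           germline_params = list(
                             n_panel = 0,
                             planted = data.frame(gene_id = "gene00001",
                                                  window = "gene_body",
                                                  frequency = 1.0,
                                                  stringsAsFactors = FALSE)),
                           seed = 2)
  expect_equal(nrow(co$germline_a), 3)
  expect_equal(length(unique(co$germline_a$pos_a)), 1)
  rec <- compute_recurrence(co$germline_a, slop_bp = 10)
  expect_true(all(rec$both_shared))
})

test_that("empty germline panel with patients is an error", {
  g <- simulate_genome(1, 5, 0, 1, seed = 1)
  expect_error(simulate_sv_cohort(g, 3, germline_params = list(n_panel = 0)),
               "empty germline panel")
})

test_that("somatic translocation fraction 1 makes every somatic SV interchromosomal", {
  g <- simulate_genome(3, 10, 0, 1, seed = 1)
  co <- simulate_sv_cohort(
    g, 10, germline_params = list(n_panel = 5),
    somatic_params = list(class_fractions = c(DEL = 0, DUP = 0, INV = 0, TRA = 1)),
    seed = 4)
  expect_gt(nrow(co$somatic), 0)
  expect_true(all(co$somatic$chrom_a != co$somatic$chrom_b))
  expect_true(all(co$somatic$sv_class == "TRA"))
})

test_that("germline class fractions and sizes converge to the parameters", {
  g <- simulate_genome(4, 50, 0, 4, seed = 11)
  co <- simulate_sv_cohort(g, 500, seed = 12)
  cf <- table(co$germline_a$sv_class) / nrow(co$germline_a)
  expect_lt(abs(cf[["DEL"]] - 0.78), 0.03)
  expect_lt(abs(cf[["INV"]] - 0.125), 0.03)
  expect_lt(abs(cf[["DUP"]] - 0.093), 0.03)
  med <- median(co$germline_a$pos_b - co$germline_a$pos_a)
  expect_lt(abs(med - 2100) / 2100, 0.25)
  # caller B stays within the jitter bound of caller A coordinates
  m <- merge_callsets(co$germline_a, co$germline_b, slop_bp = 50)
  expect_equal(nrow(m$records), nrow(co$germline_b))
})

test_that("planted effects shift carriers by exactly the effect in log2 units", {
  g <- simulate_genome(1, 5, 0, 1, seed = 1)
  co <- simulate_sv_cohort(g, 20,
                           germline_params = list(
                             n_panel = 0,
                             planted = data.frame(gene_id = "gene00002",
                                                  window = "gene_body",
                                                  frequency = 0.5,
                                                  stringsAsFactors = FALSE)),
                           seed = 2)
  ex <- simulate_expression(
    g, co,
    effect_spec = list(effect_genes = data.frame(gene_id = "gene00002",
                                                 effect = 1.0,
                                                 stringsAsFactors = FALSE),
                       noise_sd = 0, tissue_sd = 0),
    seed = 3)
  carrier <- ex$truth[["gene00002"]]
  expect_true(any(carrier) && any(!carrier))
  y <- log2(ex$expression["gene00002", ] + 1)
  expect_equal(unname(y[carrier] - mean(y[!carrier])),
               rep(1.0, sum(carrier)), tolerance = 1e-12)
})

test_that("a planted effect with zero carriers warns but still emits the gene", {
  g <- simulate_genome(1, 5, 0, 1, seed = 1)
  co <- simulate_sv_cohort(g, 5,
                           germline_params = list(
                             n_panel = 0,
                             planted = data.frame(gene_id = "gene00001",
                                                  window = "gene_body",
                                                  frequency = 1e-9,
                                                  stringsAsFactors = FALSE)),
                           seed = 2)
  expect_warning(
    ex <- simulate_expression(
      g, co,
      effect_spec = list(effect_genes = data.frame(gene_id = "gene00001",
                                                   effect = 1,
                                                   stringsAsFactors = FALSE)),
      seed = 3),
    "zero carriers")
  expect_true("gene00001" %in% rownames(ex$expression))
})

test_that("survival generator honors censoring and follow-up caps", {
  g <- simulate_genome(1, 3, 0, 1, seed = 1)
  co <- simulate_sv_cohort(g, 50, germline_params = list(n_panel = 5), seed = 2)
  ex <- simulate_expression(g, co, seed = 3)
  s0 <- simulate_survival(NULL, ex$covariates,
                          hazard_spec = list(censoring_rate = 0,
                                             max_followup = Inf),
                          seed = 4)
  expect_true(all(s0$event == 1))
  s1 <- simulate_survival(NULL, ex$covariates,
                          hazard_spec = list(max_followup = 24), seed = 4)
  expect_true(all(s1$time <= 24))
  expect_true(all(s1$event[s1$time == 24] == 0))
  expect_true(all(s1$stratum == ex$covariates$tissue))
})

test_that("null hazards give uniform log-rank p values over seeds", {
  g <- simulate_genome(1, 3, 0, 1, seed = 1)
  co <- simulate_sv_cohort(g, 100, germline_params = list(n_panel = 5), seed = 2)
  ex <- simulate_expression(g, co, seed = 3)
  grp <- rep(c("a", "b"), 50)
  ps <- vapply(1:20, function(s) {
    sv <- simulate_survival(NULL, ex$covariates, seed = 100 + s)
    fit <- survival::survdiff(survival::Surv(sv$time, sv$event) ~ grp)
    pchisq(fit$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
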