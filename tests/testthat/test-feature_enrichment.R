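test_that("enrichment_chisq reproduces the Pearson statistic", {
  flat <- enrichment_chisq(rep(c(TRUE, FALSE), each = 20),
                           rep(c(TRUE, FALSE), 20))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  diag <- enrichment_chisq(rep(c(TRUE, FALSE), each = 20),
                           rep(c(TRUE, FALSE), each = 20))
  expect_equal(diag$chi2, 40)  # N(ad-bc)^2 / (r1 r2 c1 c2)
  expect_true(diag$enriched)
  # agrees with the stock implementation without continuity correction
  ct <- stats::chisq.test(diag$counts, correct = FALSE)
  expect_equal(diag$chi2, unname(ct$statistic))
  expect_equal(diag$p, ct$p.value)

  # transposition invariance
  set.seed(71)
  m <- runif(80) < 0.4; o <- runif(80) < 0.5
  expect_equal(enrichment_chisq(m, o)$chi2, enrichment_chisq(o, m)$chi2)

  degen <- enrichment_chisq(rep(TRUE, 10), runif(10) < 0.5)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p))
})

test_that("enhancer-duplication classification follows its five conditions", {
  gene <- make_genes("chr1", 5e5, 6e5, strand = "+")[1, ]
  enh <- data.frame(chrom = "chr1", start = 48e4, end = 48.2e4)
  dup <- make_records("chr1", 47e4, pos_b = 49e4, sv_class = "DUP")[1, ]
  expect_true(classify_enhancer_duplication(dup, gene, enh))

  del <- dup; del$sv_class <- "DEL"
  expect_false(classify_enhancer_duplication(del, gene, enh))
  # enhancer only partially inside the SV
  clipped <- dup; clipped$pos_b <- 48.1e4
  expect_false(classify_enhancer_duplication(clipped, gene, enh))
  expect_true(classify_enhancer_duplication(clipped, gene, enh, partial = TRUE))
  # breakpoint inside the gene
  in_gene <- dup; in_gene$pos_b <- 5.5e5
  expect_false(classify_enhancer_duplication(in_gene, gene, enh))
  # SV spanning the gene
  span <- dup; span$pos_b <- 7e5
  expect_false(classify_enhancer_duplication(span, gene, enh))
  # breakpoints beyond the flank
  far <- dup; far$pos_a <- 3.5e5
  expect_false(classify_enhancer_duplication(far, gene, enh))

  # monotone in enhancer set inclusion, and equal to the literal reimplementation
  inst <- random_instance(20, 10, 300, seed = 73)
  set.seed(74)
  enhancers <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                          start = floor(runif(40, 0, 1.9e6)))
  enhancers$end <- enhancers$start + 1500
  intra <- inst$cohort[inst$cohort$chrom_a == inst$cohort$chrom_b, ]
  for (k in sample(nrow(intra), 150)) {
    sv <- intra[k, ]
    g <- inst$genes[sample(nrow(inst$genes), 1), ]
    got <- classify_enhancer_duplication(sv, g, enhancers)
    expect_equal(got, oracle_enh_dup(sv, g, enhancers))
    if (got)
      expect_true(classify_enhancer_duplication(sv, g,
                                                rbind(enhancers, enhancers)))
  }
})

test_that("duplications enrich among increased and deletions among decreased expression", {
  genome <- simulate_genome(2, 300, 0, 5, seed = 771)
  set.seed(772)
  up_genes <- sample(genome$genes$gene_id, 12)
  dup_genes <- up_genes[1:6]; del_genes <- up_genes[7:12]
  planted <- data.frame(gene_id = up_genes, window = "up_100kb",
                        frequency = runif(12, 0.1, 0.4),
                        sv_class = rep(c("DUP", "DEL"), each = 6),
                        span_enhancer = FALSE, stringsAsFactors = FALSE)
  effects <- data.frame(gene_id = up_genes,
                        effect = rep(c(1, -1), each = 6),
                        stringsAsFactors = FALSE)
  hits_dup <- hits_del <- 0L
  for (i in 1:20) {
    seed <- 7000 + 10 * i
    co <- simulate_sv_cohort(genome, 150,
                             germline_params = list(n_panel = 150,
                                                    planted = planted),
                             seed = seed)
    ex <- simulate_expression(genome, co,
                              effect_spec = list(effect_genes = effects,
                                                 noise_sd = 0.5),
                              seed = seed + 1)
    M <- build_breakpoint_matrix(co$germline_a, genome$genes, "up_100kb",
                                 samples = co$patients)
    assoc <- run_associations(M, ex$expression, ex$covariates,
                              model = "tissue")
    cls <- sv_class_direction_enrichment(assoc, co$germline_a, genome$genes,
                                         window = "up_100kb")
    if (!is.na(cls$DUP$p) && cls$DUP$p < 0.05 && isTRUE(cls$DUP$enriched))
      hits_dup <- hits_dup + 1L
    if (!is.na(cls$DEL$p) && cls$DEL$p < 0.05 && !isTRUE(cls$DEL$enriched))
      hits_del <- hits_del + 1L
  }
  expect_gte(hits_dup, 18)  # DUP carriers sit in the increased direction
  expect_gte(hits_del, 18)  # DEL carriers sit in the decreased direction
})

test_that("cytoband enrichment flags concentrated breakpoints", {
  bands <- data.frame(band = sprintf("b%02d", 1:10), chrom = "chr1",
                      start = seq(0, 9e5, 1e5), end = seq(1e5, 1e6, 1e5),
                      stringsAsFactors = FALSE)
  # 50 SVs (100 breakpoints) all inside band 3
  conc <- make_records("chr1", floor(runif(50, 2e5, 2.9e5)),
                       pos_b = floor(runif(50, 2e5, 2.9e5)) + 500,
                       patient_id = "P1")
  res <- cytoband_enrichment(conc, bands)
  expect_lt(res$p[res$band == "b03"], 1e-4)
  expect_true(res$enriched[res$band == "b03"])

  # uniform breakpoints: no band enriched beyond chance
  set.seed(75)
  upos <- floor(runif(200, 0, 1e6 - 200))
  unif <- make_records("chr1", upos, pos_b = upos + 100, patient_id = "P1")
  res_u <- cytoband_enrichment(unif, bands)
  expect_true(all(res_u$p > 1e-4))

  # zero-SV patient yields no tested bands; high min_patients empties summary
  expect_equal(nrow(cytoband_enrichment(conc[0, ], bands)), 0)
  co <- conc; co$patient_id <- rep(c("P1", "P2"), 25)
  expect_equal(nrow(cytoband_cohort_summary(co, bands, min_patients = 50)), 0)
  summ <- cytoband_cohort_summary(co, bands, min_patients = 2)
  expect_equal(summ$band, "b03")
})

test_that("copy categories use the exact printed cutoffs", {
  expect_equal(copy_category(6), "amplification")
  expect_equal(copy_category(5), "copy_gain")
  expect_equal(copy_category(3), "copy_gain")
  expect_equal(copy_category(2), "neutral")
  expect_equal(copy_category(1.5), "neutral")
  expect_equal(copy_category(1), "copy_loss")
  expect_equal(copy_category(0), "copy_loss")
  # ploidy correction: 6 copies in a tetraploid tumor are diploid-neutral
  expect_equal(copy_category(6, ploidy = 4), "copy_gain")
  expect_equal(copy_category(4, ploidy = 4), "neutral")
})

test_that("gene-spanning DUP/DEL events crosstab against copy categories", {
  genes <- make_genes("chr1", c(1e4, 5e4), c(2e4, 6e4))
  co <- rbind(make_records("chr1", 5e3, pos_b = 2.5e4, sv_class = "DUP",
                           patient_id = "S1", sv_id = "a"),
              make_records("chr1", 4.5e4, pos_b = 6.5e4, sv_class = "DEL",
                           patient_id = "S2", sv_id = "b"))
  cn <- matrix(c(4.2, 2, 2, 0.8), 2, 2,
               dimnames = list(genes$gene_id, c("S1", "S2")))
  covars <- data.frame(patient_id = c("S1", "S2"), ploidy = c(2, 2))
  ct <- copy_category_crosstab(co, genes, cn, covars)
  expect_equal(unname(ct$crosstab["DUP", "copy_gain"]), 1)
  expect_equal(unname(ct$crosstab["DEL", "copy_loss"]), 1)
  expect_equal(ct$events$gene_id, c("g001", "g002"))
})

test_that("essentiality crossing applies both thresholds strictly", {
  ess <- rbind(g1 = c(rep(-1, 6), rep(0, 94)),   # 6% essential
               g2 = c(rep(-1, 5), rep(0, 95)),   # 5% (not > 5%)
               g3 = rep(0, 100),                 # never essential
               g4 = c(rep(-0.7, 50), rep(0, 50)))  # scores above -0.75
  out <- cross_essentiality(c("g1", "g2", "g3", "g4", "gX"), ess)
  expect_equal(out$gene_id, "g1")
  expect_equal(out$essential_fraction, 0.06)
})
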