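test_that("degenerate matrices behave as specified", {
  genes <- make_genes("chr1", c(1000, 5000), c(3000, 9000))
  empty <- make_records("chr1", numeric(0), pos_b = numeric(0))
  M <- build_breakpoint_matrix(empty, genes, "gene_body", samples = c("S1", "S2"))
  expect_true(all(M$values == 0))
  expect_equal(dim(M$values), c(2, 2))

  one <- make_records("chr1", 1200, pos_b = 2500, patient_id = "S1")
  M1 <- build_breakpoint_matrix(one, genes, "gene_body", samples = c("S1", "S2"))
  expect_equal(sum(M1$values), 1)
  expect_equal(M1$values["g001", "S1"], 1)
  expect_equal(unname(M1$carrier_counts), c(1, 0))
})

test_that("every window matches the nested-loop oracle on a random instance", {
  inst <- random_instance(50, 40, 300, seed = 7)
  for (w in c("gene_body", "up_100kb", "down_100kb", "up_2kb", "utr3")) {
    M <- build_breakpoint_matrix(inst$cohort, inst$genes, w,
                                 samples = inst$samples)
    expect_equal(M$values, oracle_matrix(inst$cohort, inst$genes, w,
                                         inst$samples),
                 label = paste("window", w))
    expect_equal(unname(M$carrier_counts), unname(rowSums(M$values > 0)))
  }
  W <- build_weighted_matrix(inst$cohort, inst$genes, extent_bp = 2e5,
                             samples = inst$samples)
  expect_equal(W$values, oracle_weighted(inst$cohort, inst$genes,
                                         inst$samples, extent = 2e5))
  expect_true(all(W$values >= 0 & W$values <= 1))
})

test_that("weighted entries follow the linear decay from the gene start", {
  genes <- make_genes("chr1", 5e5, 6e5, strand = "+")
  ext <- 1e5
  at <- function(pos) {
    co <- make_records("chr1", pos, pos_b = pos, sv_class = "INV",
                       patient_id = "S1")
    build_weighted_matrix(co, genes, ext, samples = "S1")$values[1, 1]
  }
  expect_equal(at(5e5), 1.0)          # breakpoint at the gene start
  expect_equal(at(5e5 - ext), 0.0)    # at the extent boundary
  expect_equal(at(5e5 - ext / 2), 0.5)
  expect_equal(at(5e5 - ext - 1), 0.0)  # beyond the extent
  # monotone: closer breakpoints never decrease the entry
  expect_true(at(5e5 - 100) > at(5e5 - 5000))
})

test_that("flank windows are strand-aware and exclude the gene body", {
  gplus <- make_genes("chr1", 5e5, 6e5, strand = "+")
  gminus <- make_genes("chr1", 5e5, 6e5, strand = "-")
  up_bp <- make_records("chr1", 5e5 - 5000, pos_b = 5e5 - 4000,
                        patient_id = "S1")
  Mp <- build_breakpoint_matrix(up_bp, gplus, "up_100kb", samples = "S1")
  Mm <- build_breakpoint_matrix(up_bp, gminus, "up_100kb", samples = "S1")
  expect_equal(Mp$values[1, 1], 1)
  expect_equal(Mm$values[1, 1], 0)
  Dm <- build_breakpoint_matrix(up_bp, gminus, "down_100kb", samples = "S1")
  expect_equal(Dm$values[1, 1], 1)
  # a breakpoint inside the gene counts for gene_body only
  inside <- make_records("chr1", 5.5e5, pos_b = 5.6e5 + 1e4, patient_id = "S1")
  expect_equal(build_breakpoint_matrix(inside, gplus, "up_100kb",
                                       samples = "S1")$values[1, 1], 0)
  expect_equal(build_breakpoint_matrix(inside, gplus, "gene_body",
                                       samples = "S1")$values[1, 1], 1)
})

test_that("matrices are monotone in the cohort and blind to class and mate order", {
  inst <- random_instance(30, 20, 200, seed = 17)
  M_all <- build_breakpoint_matrix(inst$cohort, inst$genes, "gene_body",
                                   samples = inst$samples)
  M_sub <- build_breakpoint_matrix(inst$cohort[1:150, ], inst$genes,
                                   "gene_body", samples = inst$samples)
  expect_true(all(M_all$values >= M_sub$values))

  relabeled <- inst$cohort
  relabeled$sv_class <- ifelse(relabeled$chrom_a == relabeled$chrom_b, "INV",
                               "TRA")
  M_rel <- build_breakpoint_matrix(relabeled, inst$genes, "gene_body",
                                   samples = inst$samples)
  expect_equal(M_rel$values, M_all$values)

  swapped <- inst$cohort
  tmp_c <- swapped$chrom_a; swapped$chrom_a <- swapped$chrom_b
  swapped$chrom_b <- tmp_c
  tmp_p <- swapped$pos_a; swapped$pos_a <- swapped$pos_b; swapped$pos_b <- tmp_p
  M_sw <- build_breakpoint_matrix(swapped, inst$genes, "gene_body",
                                  samples = inst$samples)
  expect_equal(M_sw$values, M_all$values)
})

test_that("utr3 window skips genes lacking an annotated 3' UTR", {
  genes <- make_genes("chr1", c(1e4, 5e4), c(2e4, 6e4),
                      utr3_start = c(18e3, NA), utr3_end = c(2e4, NA))
  co <- make_records("chr1", 19e3, pos_b = 3e4, patient_id = "S1")
  M <- build_breakpoint_matrix(co, genes, "utr3", samples = "S1")
  expect_equal(rownames(M$values), "g001")
  expect_equal(M$values[1, 1], 1)
})

test_that("classify_sv_gene_relation matches a literal reimplementation", {
  gene <- make_genes("chr1", 1e5, 2e5, strand = "+",
                     utr3_start = 1.95e5, utr3_end = 2e5)[1, ]
  mid <- classify_sv_gene_relation(
    make_records("chr1", 1.5e5, pos_b = 1.6e5)[1, ], gene)
  expect_equal(mid$relation_a, "breakpoint_in_gene")
  span <- classify_sv_gene_relation(
    make_records("chr1", 5e4, pos_b = 3e5)[1, ], gene)
  expect_true(span$spans_gene)
  utr <- classify_sv_gene_relation(
    make_records("chr1", 1.96e5, pos_b = 3e5)[1, ], gene)
  expect_equal(utr$relation_a, "in_utr3")

  oracle_rel <- function(chrom, pos, g) {
    if (chrom != g$chrom) return("none")
    if (!is.na(g$utr3_start) && pos >= g$utr3_start && pos < g$utr3_end)
      return("in_utr3")
    if (pos >= g$start && pos < g$end) return("breakpoint_in_gene")
    before <- pos < g$start
    if (before == (g$strand == "+")) "upstream" else "downstream"
  }
  inst <- random_instance(25, 10, 400, seed = 23)
  set.seed(24)
  for (k in sample(nrow(inst$cohort), 200)) {
    g <- inst$genes[sample(nrow(inst$genes), 1), ]
    sv <- inst$cohort[k, ]
    got <- classify_sv_gene_relation(sv, g)
    expect_equal(got$relation_a, oracle_rel(sv$chrom_a, sv$pos_a, g))
    expect_equal(got$relation_b, oracle_rel(sv$chrom_b, sv$pos_b, g))
    expect_equal(got$spans_gene,
                 sv$chrom_a == sv$chrom_b && sv$chrom_a == g$chrom &&
                   sv$pos_a <= g$start && sv$pos_b >= g$end)
  }
})
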