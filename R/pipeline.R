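# End-to-end driver: simulate -> merge -> matrices -> associate -> enrich ->
# signature -> survival, writing plain-text outputs along the way.

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- data.frame(setNames(list(rownames(df)), rownames_as),
                     as.data.frame(df), check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-by-sample numeric matrix from TSV
#'
#' First column = gene identifiers, remaining columns = samples.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a simulated cohort to disk
#'
#' Emits the same formats the pipeline reads: BEDPE-like SV tables, BED
#' (enhancers, cytobands), a gene table with strand and 3' UTR, expression /
#' copy-number matrices, covariates and survival TSVs.
#'
#' @param genome A `genome_annotation`.
#' @param cohort An `sv_cohort`.
#' @param expr Result of [simulate_expression()].
#' @param surv Result of [simulate_survival()], or NULL.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(genome, cohort, expr, surv = NULL, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_sv_table(cohort$germline_a, p("germline_caller_a.bedpe"))
  write_sv_table(cohort$germline_b, p("germline_caller_b.bedpe"))
  if (!is.null(cohort$somatic)) write_sv_table(cohort$somatic, p("somatic.bedpe"))
  write_tsv(genome$genes, p("genes.tsv"))
  write_tsv(genome$enhancers[, c("chrom", "start", "end", "enh_id")],
            p("enhancers.bed"))
  write_tsv(genome$cytobands[, c("chrom", "start", "end", "band")],
            p("cytobands.bed"))
  write_tsv(expr$expression, p("expression.tsv"), rownames_as = "gene_id")
  write_tsv(expr$copy_number, p("copy_number.tsv"), rownames_as = "gene_id")
  write_tsv(expr$covariates, p("covariates.tsv"))
  if (!is.null(surv)) write_tsv(surv, p("survival.tsv"))
  invisible(outdir)
}

#' Default pipeline parameters
#'
#' Study-scale defaults for the synthetic cohort: 4 chromosomes of 50 Mb,
#' 1,000 genes, 300 enhancers, 400 patients across 4 tissues, a 400-SV
#' germline population panel (78% deletions, 2.1 kb median size, carrier
#' frequencies 0.05-0.5) plus 30 planted gene-body cis-effects of +1 log2 at
#' panel-SV carriers, 8 enhancer-duplication effects, private somatic SVs
#' (24% translocations, 175 kb median), residual noise SD 0.5, and planted
#' hazards on the first three effect genes' carrier patterns.
#'
#' @return Named list of parameters accepted by [run_pipeline()].
#' @export
default_pipeline_params <- function() {
  list(n_chroms = 4L, chrom_length = 5e7, n_genes = 1000L,
       n_enhancers = 300L, bands_per_chrom = 10L,
       n_patients = 400L, tissues = paste0("T", 1:4),
       n_effect_genes = 30L, effect_size = 1.0,
       effect_freq_range = c(0.05, 0.5),
       n_enhancer_dup_genes = 8L,
       n_dual_genes = 5L, n_hazard_genes = 10L,
       hotspot_fraction = 0.08,
       noise_sd = 0.5, tissue_sd = 1.0,
       hazard = list(baseline_hazard = 0.02, log_hr_per_carrier = 0.5,
                     censoring_rate = 0.3, max_followup = 120),
       windows = c("gene_body", "up_100kb", "down_100kb", "utr3"),
       min_carriers = 3L, fdr_threshold = 0.10)
}

#' Simulate the default study cohort
#'
#' Runs the simulation phase of [run_pipeline()]: genome, tissue labels,
#' planted gene-body cis-effects, enhancer-duplication effects, dual
#' germline+somatic genes, a recurrent-SV hotspot, expression/copy
#' number/covariates, and survival with hazards on the first
#' `n_hazard_genes` effect genes' carrier patterns.
#'
#' @inheritParams run_pipeline
#' @return List `genome`, `cohort`, `expr`, `surv`, `truth`.
#' @export
simulate_study_cohort <- function(params = list(), seed = 1L) {
  pp <- utils::modifyList(default_pipeline_params(), params)
  genome <- simulate_genome(pp$n_chroms, pp$n_genes, pp$n_enhancers,
                            pp$bands_per_chrom, seed = seed,
                            chrom_length = pp$chrom_length)
  set.seed(seed + 1L)
  tissues <- sample(pp$tissues, pp$n_patients, replace = TRUE)

  # planted cis-effects: gene-body SVs at n_effect_genes random genes, plus
  # enhancer-spanning upstream duplications at eligible genes
  set.seed(seed + 2L)
  effect_genes <- sample(genome$genes$gene_id, pp$n_effect_genes)
  eligible <- find_enhancer_flank_genes(genome, 1e5, side = "up")
  eligible <- eligible[!eligible$gene_id %in% effect_genes, ]
  enh_genes <- head(unique(eligible$gene_id), pp$n_enhancer_dup_genes)
  planted <- rbind(
    data.frame(gene_id = effect_genes, window = "gene_body",
               frequency = runif(pp$n_effect_genes, pp$effect_freq_range[1],
                                 pp$effect_freq_range[2]),
               sv_class = "DEL", span_enhancer = FALSE,
               stringsAsFactors = FALSE),
    if (length(enh_genes))
      data.frame(gene_id = enh_genes, window = "up_100kb",
                 frequency = runif(length(enh_genes), 0.1, 0.4),
                 sv_class = "DUP", span_enhancer = TRUE,
                 stringsAsFactors = FALSE))

  # recurrent-SV hotspot in the second cytoband of the first chromosome
  hotspot <- NULL
  if (pp$hotspot_fraction > 0) {
    hb <- genome$cytobands[min(2, nrow(genome$cytobands)), ]
    hotspot <- list(fraction = pp$hotspot_fraction, chrom = hb$chrom,
                    start = hb$start, end = hb$end)
  }
  # the first n_dual_genes cis-effect genes also acquire somatic SVs within
  # the gene body, so the germline/somatic overlap has a planted truth
  dual_genes <- head(effect_genes, pp$n_dual_genes)
  somatic_planted <- if (length(dual_genes))
    data.frame(gene_id = dual_genes, window = "gene_body",
               frequency = 0.08, sv_class = "DUP", stringsAsFactors = FALSE)

  cohort <- simulate_sv_cohort(genome, pp$n_patients,
                               germline_params = list(planted = planted,
                                                      hotspot = hotspot),
                               somatic_params = list(planted = somatic_planted),
                               seed = seed + 3L, patient_tissues = tissues)
  all_effects <- data.frame(
    gene_id = c(effect_genes, enh_genes),
    effect = rep(pp$effect_size, length(effect_genes) + length(enh_genes)),
    stringsAsFactors = FALSE)
  expr <- simulate_expression(genome, cohort,
                              covariates_params = list(tissues = pp$tissues),
                              effect_spec = list(effect_genes = all_effects,
                                                 noise_sd = pp$noise_sd,
                                                 tissue_sd = pp$tissue_sd),
                              seed = seed + 4L)

  # survival hazards follow the first planted carrier patterns
  hz <- pp$hazard
  hz_genes <- head(effect_genes, pp$n_hazard_genes)
  feat <- sapply(hz_genes, function(g) as.numeric(expr$truth[[g]]))
  colnames(feat) <- hz_genes
  surv <- simulate_survival(feat, expr$covariates,
                            hazard_spec = list(
                              baseline_hazard = hz$baseline_hazard,
                              log_hr = setNames(rep(hz$log_hr_per_carrier,
                                                    length(hz_genes)), hz_genes),
                              censoring_rate = hz$censoring_rate,
                              max_followup = hz$max_followup),
                            seed = seed + 5L)
  list(genome = genome, cohort = cohort, expr = expr, surv = surv,
       truth = list(effect_genes = effect_genes, enh_genes = enh_genes,
                    dual_genes = dual_genes, hazard_genes = hz_genes))
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates a cohort with planted effects, harmonizes the two germline call
#' sets, summarizes the SV landscape, builds the breakpoint matrices, runs
#' covariate-corrected associations for every window, performs mechanism and
#' cytoband enrichment, derives the signed survival signature and tests its
#' score against survival. Deterministic for a fixed seed. When `outdir` is
#' given, all tables are written beneath it as TSV/BEDPE/JSON.
#'
#' @param params List in the shape of [default_pipeline_params()]; partial
#'   lists are merged over the defaults.
#' @param seed Integer seed controlling every random draw.
#' @param outdir Optional output directory.
#' @return List with the main objects: `genome`, `cohort`, `expr`, `surv`,
#'   `merged`, `sv_summary`, `matrices`, `associations` (per window),
#'   `counts` (significant-gene counts per window), `enhancer_dup`,
#'   `class_enrichment`, `cytoband_summary`, `copy_crosstab`,
#'   `somatic_assoc` and `overlap` (germline/somatic intersection),
#'   `surv_scan`, `signature`, `signature_survival`, `truth`.
#' @export
run_pipeline <- function(params = list(), seed = 1L, outdir = NULL) {
  pp <- utils::modifyList(default_pipeline_params(), params)
  sim <- simulate_study_cohort(pp, seed = seed)
  genome <- sim$genome; cohort <- sim$cohort
  expr <- sim$expr; surv <- sim$surv

  merged <- merge_callsets(cohort$germline_a, cohort$germline_b, slop_bp = 200)
  sv_summary <- summarize_svs(merged$records)
  cytoband_summary <- cytoband_cohort_summary(merged$records, genome$cytobands,
                                              min_patients = 20)

  samples <- cohort$patients
  matrices <- lapply(setNames(pp$windows, pp$windows), function(w)
    build_breakpoint_matrix(merged$records, genome$genes, w, samples = samples))
  matrices$flank_1mb_weighted <-
    build_weighted_matrix(merged$records, genome$genes, samples = samples)

  associations <- lapply(matrices, function(M)
    run_associations(M, expr$expression, expr$covariates, model = "full",
                     min_carriers = pp$min_carriers,
                     copy_matrix = expr$copy_number))
  counts <- t(vapply(associations, count_significant,
                     c(n_positive = 0L, n_negative = 0L),
                     q_threshold = pp$fdr_threshold))

  enhancer_dup <- tryCatch(
    enhancer_duplication_enrichment(associations$up_100kb, merged$records,
                                    genome$genes, genome$enhancers,
                                    window = "up_100kb"),
    error = function(e) NULL)
  class_enrichment <- tryCatch(
    sv_class_direction_enrichment(associations$up_100kb, merged$records,
                                  genome$genes, window = "up_100kb"),
    error = function(e) NULL)
  copy_crosstab <- tryCatch(
    copy_category_crosstab(cohort$somatic, genome$genes, expr$copy_number,
                           expr$covariates),
    error = function(e) NULL)

  somatic_gb <- build_breakpoint_matrix(cohort$somatic, genome$genes,
                                        "gene_body", samples = samples)
  somatic_assoc <- run_associations(somatic_gb, expr$expression,
                                    expr$covariates, model = "full",
                                    min_carriers = pp$min_carriers,
                                    copy_matrix = expr$copy_number)
  overlap <- overlap_germline_somatic(associations$gene_body, somatic_assoc)

  surv_windows <- matrices[intersect(names(matrices),
                                     c("gene_body", "up_100kb", "down_100kb",
                                       "flank_1mb_weighted"))]
  surv_scan <- cox_breakpoint_scan(surv_windows, surv,
                                   min_carriers = pp$min_carriers)
  assoc_pool <- do.call(rbind, associations)
  signature <- derive_signature(surv_scan, assoc_pool)
  sig_surv <- NULL
  if (length(signature$genes) >= 4) {
    scores <- score_cohort(signature, expr$expression)
    sig_surv <- tryCatch(signature_survival(scores, surv),
                         error = function(e) NULL)
  }

  result <- list(genome = genome, cohort = cohort, expr = expr, surv = surv,
                 merged = merged, sv_summary = sv_summary,
                 matrices = matrices, associations = associations,
                 counts = counts, enhancer_dup = enhancer_dup,
                 class_enrichment = class_enrichment,
                 cytoband_summary = cytoband_summary,
                 copy_crosstab = copy_crosstab,
                 somatic_assoc = somatic_assoc, overlap = overlap,
                 surv_scan = surv_scan, signature = signature,
                 signature_survival = sig_surv,
                 truth = sim$truth)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(genome, cohort, expr, surv, file.path(outdir, "cohort"))
    write_sv_table(merged$records, file.path(outdir, "germline_merged.bedpe"))
    for (w in names(matrices))
      write_breakpoint_matrix(matrices[[w]],
                              file.path(outdir, paste0("bkpt_", w, ".tsv")))
    for (w in names(associations))
      write_tsv(associations[[w]], file.path(outdir, paste0("assoc_", w, ".tsv")))
    write_tsv(as.data.frame(counts), file.path(outdir, "significant_counts.tsv"),
              rownames_as = "window")
    write_tsv(cytoband_summary, file.path(outdir, "cytoband_summary.tsv"))
    write_tsv(overlap, file.path(outdir, "germline_somatic_overlap.tsv"))
    write_tsv(surv_scan, file.path(outdir, "survival_scan.tsv"))
    jsonlite::write_json(as.list(signature$genes),
                         file.path(outdir, "signature.json"), auto_unbox = TRUE)
    if (!is.null(sig_surv))
      jsonlite::write_json(list(logrank_p = sig_surv$logrank_p,
                                cox_p = sig_surv$cox_p,
                                cox_coef = sig_surv$cox_coef),
                           file.path(outdir, "signature_survival.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  result
}
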