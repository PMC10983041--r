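#!/usr/bin/env Rscript
# Step 1: simulate the synthetic cohort that stands in for a pan-cancer
# WGS + RNA-seq dataset: genome annotation, a recurrent germline SV panel
# called by two "callers" (plus a positional hotspot), private somatic SVs,
# expression with planted cis-effects (gene-body deletions, upstream
# enhancer duplications, five dual germline+somatic genes), covariates, and
# survival with planted hazards on the first ten effect genes.

suppressPackageStartupMessages(library(svimpact))
seed <- as.integer(Sys.getenv("SEED", "1"))
pp <- default_pipeline_params()
outdir <- file.path("results", "cohort")

sim <- simulate_study_cohort(pp, seed = seed)
write_cohort(sim$genome, sim$cohort, sim$expr, sim$surv, outdir)

roles <- with(sim$truth, data.frame(
  gene_id = c(effect_genes, enh_genes, dual_genes, hazard_genes),
  role = c(rep("cis_effect", length(effect_genes)),
           rep("enhancer_dup", length(enh_genes)),
           rep("dual_germline_somatic", length(dual_genes)),
           rep("hazard", length(hazard_genes)))))
write.table(roles, file.path(outdir, "planted_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$cohort$panel, file.path(outdir, "germline_panel.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d patients (%d tissues), %d genes, %d panel SVs\n",
            pp$n_patients, length(pp$tissues), pp$n_genes,
            nrow(sim$cohort$panel)))
cat(sprintf("germline calls: caller A %d, caller B %d; somatic %d\n",
            nrow(sim$cohort$germline_a), nrow(sim$cohort$germline_b),
            nrow(sim$cohort$somatic)))
cat(sprintf("planted: %d cis-effects (+%g log2), %d enhancer dups, %d dual, %d hazard genes\n",
            length(sim$truth$effect_genes), pp$effect_size,
            length(sim$truth$enh_genes), length(sim$truth$dual_genes),
            length(sim$truth$hazard_genes)))
cat("wrote cohort files under", outdir, "\n")
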