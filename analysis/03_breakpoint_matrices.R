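#!/usr/bin/env Rscript
# Step 3: build the gene x sample breakpoint matrices for each genomic
# region window from the merged germline call set (and gene-body matrices
# for the somatic calls, used later for the germline/somatic overlap).

suppressPackageStartupMessages(library(svimpact))
cdir <- file.path("results", "cohort")
outdir <- file.path("results", "matrices")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

merged <- read_sv_table(file.path("results", "germline_merged.bedpe"))
somatic <- read_sv_table(file.path(cdir, "somatic.bedpe"))
genes <- read.delim(file.path(cdir, "genes.tsv"))
covars <- read.delim(file.path(cdir, "covariates.tsv"))
samples <- covars$patient_id

windows <- c("gene_body", "up_100kb", "down_100kb", "utr3")
for (w in windows) {
  M <- build_breakpoint_matrix(merged, genes, w, samples = samples)
  write_breakpoint_matrix(M, file.path(outdir, paste0("germline_", w, ".tsv")))
  cat(sprintf("germline %-12s: %4d genes with >= 3 carriers\n", w,
              sum(M$carrier_counts >= 3)))
}
W <- build_weighted_matrix(merged, genes, samples = samples)
write_breakpoint_matrix(W, file.path(outdir, "germline_flank_1mb_weighted.tsv"))
cat(sprintf("germline %-12s: %4d genes with >= 3 carriers\n",
            "1mb_weighted", sum(W$carrier_counts >= 3)))

for (w in windows) {
  M <- build_breakpoint_matrix(somatic, genes, w, samples = samples)
  write_breakpoint_matrix(M, file.path(outdir, paste0("somatic_", w, ".tsv")))
}
cat("matrices written under", outdir, "\n")
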