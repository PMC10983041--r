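#!/usr/bin/env Rscript
# Step 2: harmonize the two germline call sets (200 bp slop, caller A
# coordinates kept) and describe the SV landscape: class mix, sizes,
# breakpoint recurrence, cytoband hotspots, and the copy-number footprint of
# gene-spanning somatic DUP/DEL events.

suppressPackageStartupMessages(library(svimpact))
cdir <- file.path("results", "cohort")
outdir <- file.path("results", "sv_landscape")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

germ_a <- read_sv_table(file.path(cdir, "germline_caller_a.bedpe"))
germ_b <- read_sv_table(file.path(cdir, "germline_caller_b.bedpe"))
somatic <- read_sv_table(file.path(cdir, "somatic.bedpe"))
genes <- read.delim(file.path(cdir, "genes.tsv"))
cytobands <- read.delim(file.path(cdir, "cytobands.bed"))
cn <- read_matrix_tsv(file.path(cdir, "copy_number.tsv"))
covars <- read.delim(file.path(cdir, "covariates.tsv"))

merged <- merge_callsets(germ_a, germ_b, slop_bp = 200)
write_sv_table(merged$records, file.path("results", "germline_merged.bedpe"))
cat(sprintf("two-caller merge: %d/%d caller-A calls confirmed (%d caller-B calls unmatched)\n",
            nrow(merged$records), nrow(germ_a), merged$n_unmatched_b))

gsum <- summarize_svs(merged$records)
ssum <- summarize_svs(somatic)
landscape <- data.frame(
  origin = c("germline", "somatic"),
  n = c(nrow(merged$records), nrow(somatic)),
  del_pct = 100 * c(gsum$class_fractions["DEL"], ssum$class_fractions["DEL"]),
  tra_pct = 100 * c(0, ssum$class_fractions["TRA"]),
  median_size_bp = c(gsum$median_intra_size, ssum$median_intra_size),
  recurrence_both_pct = 100 * c(gsum$recurrence_fraction_both,
                                ssum$recurrence_fraction_both))
write.table(landscape, file.path(outdir, "landscape.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("germline: %.1f%% deletions, median size %.0f bp, %.1f%% recurrent (both breakpoints)\n",
            landscape$del_pct[1], landscape$median_size_bp[1],
            landscape$recurrence_both_pct[1]))
cat(sprintf("somatic:  %.1f%% translocations, median size %.0f bp, %.2f%% recurrent\n",
            landscape$tra_pct[2], landscape$median_size_bp[2],
            landscape$recurrence_both_pct[2]))

bands <- cytoband_cohort_summary(merged$records, cytobands,
                                 p_threshold = 1e-4, min_patients = 20)
write.table(bands, file.path(outdir, "cytoband_hotspots.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("cytoband hotspots (p < 1e-4 in >= 20 patients): %d bands\n",
            nrow(bands)))

ct <- copy_category_crosstab(somatic, genes, cn, covars)
write.table(as.data.frame(ct$crosstab), file.path(outdir, "copy_crosstab.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("somatic gene-spanning events: DUP-gain chi2 p = %.3g, DEL-loss chi2 p = %.3g\n",
            ct$dup_gain$p, ct$del_loss$p))
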