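# Mechanism and descriptive enrichment layers: enhancer-duplication
# classification, chi-squared enrichments, per-patient cytoband density,
# ploidy-corrected copy categories, and essentiality crossing.

#' Pearson chi-squared enrichment on two boolean vectors
#'
#' Cross-tabulates `member_flags` against `outcome_flags` and applies the
#' Pearson chi-squared test without continuity correction. A degenerate
#' margin (all items on one side) yields `p = NA` with `degenerate = TRUE`;
#' an expected cell below 5 sets `low_expected = TRUE`.
#'
#' @param member_flags,outcome_flags Logical vectors of equal length >= 1.
#' @return An `enrichment_result` list: `counts` (2x2, member x outcome),
#'   `chi2`, `p`, `enriched` (TRUE when the member/outcome cell exceeds its
#'   expectation), `degenerate`, `low_expected`.
#' @export
enrichment_chisq <- function(member_flags, outcome_flags) {
  stopifnot(length(member_flags) == length(outcome_flags),
            length(member_flags) >= 1)
  counts <- matrix(c(sum(member_flags & outcome_flags),
                     sum(member_flags & !outcome_flags),
                     sum(!member_flags & outcome_flags),
                     sum(!member_flags & !outcome_flags)),
                   2, 2, byrow = TRUE,
                   dimnames = list(member = c("TRUE", "FALSE"),
                                   outcome = c("TRUE", "FALSE")))
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) {
    return(structure(list(counts = counts, chi2 = NA_real_, p = NA_real_,
                          enriched = NA, degenerate = TRUE,
                          low_expected = NA),
                     class = "enrichment_result"))
  }
  expected <- outer(rs, cs) / n
  chi2 <- sum((counts - expected)^2 / expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(counts = counts, chi2 = chi2, p = p,
                 enriched = counts[1, 1] > expected[1, 1],
                 degenerate = FALSE,
                 low_expected = any(expected < 5)),
            class = "enrichment_result")
}

#' Classify an SV as a flanking enhancer duplication for a gene
#'
#' TRUE iff the SV is a duplication, both breakpoints lie within the flank
#' window of the gene (`flank_bp` upstream or downstream, strand-aware),
#' neither breakpoint falls inside the gene, the SV does not span the gene,
#' and the SV interval `[pos_a, pos_b)` contains at least one whole enhancer
#' interval (`partial = TRUE` relaxes containment to overlap).
#'
#' @param sv One intrachromosomal SV record.
#' @param gene One gene model row.
#' @param enhancers Enhancer data frame (`chrom`, `start`, `end`).
#' @param flank_bp Flank extent (default 100 kb).
#' @param partial Accept partial enhancer overlap (default FALSE).
#' @return Logical scalar.
#' @export
classify_enhancer_duplication <- function(sv, gene, enhancers,
                                          flank_bp = 1e5, partial = FALSE) {
  stopifnot(sv$chrom_a == sv$chrom_b)
  if (sv$sv_class != "DUP") return(FALSE)
  if (sv$chrom_a != gene$chrom) return(FALSE)
  in_gene <- function(p) p >= gene$start && p < gene$end
  if (in_gene(sv$pos_a) || in_gene(sv$pos_b)) return(FALSE)
  if (sv$pos_a <= gene$start && sv$pos_b >= gene$end) return(FALSE)  # spans
  in_flank <- function(p)
    (p >= gene$start - flank_bp && p < gene$start) ||
    (p >= gene$end && p < gene$end + flank_bp)
  if (!in_flank(sv$pos_a) || !in_flank(sv$pos_b)) return(FALSE)
  e <- enhancers[enhancers$chrom == sv$chrom_a, , drop = FALSE]
  if (!nrow(e)) return(FALSE)
  if (partial) any(e$start < sv$pos_b & e$end > sv$pos_a)
  else any(e$start >= sv$pos_a & e$end <= sv$pos_b)
}

#' Enhancer-duplication enrichment among up-regulated associations
#'
#' Tabulates (gene, SV) pairs in which the SV has a breakpoint within the
#' flank window of the gene, flags each pair as an enhancer duplication
#' ([classify_enhancer_duplication()]) and as belonging to a significantly
#' up-regulated gene (`p < p_threshold`, positive direction), and tests
#' enrichment by [enrichment_chisq()].
#'
#' @param assoc Association records for the flank window.
#' @param cohort SV record data frame used for the associations.
#' @param genes Gene model data frame.
#' @param enhancers Enhancer data frame.
#' @param window Flank window label (`up_100kb` or `down_100kb`).
#' @param p_threshold Significance cutoff on the association p (default 0.01).
#' @return An `enrichment_result` with an `items` data frame attached.
#' @export
enhancer_duplication_enrichment <- function(assoc, cohort, genes, enhancers,
                                            window = "up_100kb",
                                            p_threshold = 0.01) {
  spec <- window_spec(window)
  g <- genes[genes$gene_id %in% assoc$gene_id, , drop = FALSE]
  iv <- window_interval(g, spec)
  sig_up <- assoc$gene_id[!is.na(assoc$p) & assoc$p < p_threshold &
                            !is.na(assoc$direction) &
                            assoc$direction == "positive"]
  intra <- cohort[cohort$chrom_a == cohort$chrom_b, ]
  items <- list()
  for (i in seq_len(nrow(g))) {
    sub <- intra[intra$chrom_a == g$chrom[i], ]
    if (!nrow(sub)) next
    hit <- (sub$pos_a >= iv$lo[i] & sub$pos_a < iv$hi[i]) |
           (sub$pos_b >= iv$lo[i] & sub$pos_b < iv$hi[i])
    if (!any(hit)) next
    sub <- sub[hit, ]
    member <- vapply(seq_len(nrow(sub)), function(k)
      classify_enhancer_duplication(sub[k, ], g[i, ], enhancers,
                                    flank_bp = spec$extent), logical(1))
    items[[g$gene_id[i]]] <- data.frame(
      gene_id = g$gene_id[i], sv_id = sub$sv_id,
      enhancer_dup = member, sig_up = g$gene_id[i] %in% sig_up,
      stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, c(items, make.row.names = FALSE))
  if (is.null(items) || !nrow(items))
    stop("no (gene, SV) pairs in the ", window, " window")
  res <- enrichment_chisq(items$enhancer_dup, items$sig_up)
  res$items <- items
  res
}

#' SV-class enrichment by association direction
#'
#' For genes significant at `p < p_threshold`, each (gene, sample) carrier is
#' attributed to every SV class with a breakpoint in the gene's window for
#' that sample. Per class, a 2x2 of (class vs other classes) x (increased vs
#' decreased expression association) is tested with [enrichment_chisq()].
#'
#' @param assoc Association records for the window.
#' @param cohort SV record data frame.
#' @param genes Gene model data frame.
#' @param window Window label.
#' @param p_threshold Significance cutoff (default 0.01).
#' @return Named list of `enrichment_result`, one per SV class observed.
#' @export
sv_class_direction_enrichment <- function(assoc, cohort, genes,
                                          window = "up_100kb",
                                          p_threshold = 0.01) {
  spec <- window_spec(window)
  sig <- assoc[!is.na(assoc$p) & assoc$p < p_threshold &
                 !is.na(assoc$direction), ]
  if (!nrow(sig)) stop("no significant associations at p < ", p_threshold)
  g <- genes[match(sig$gene_id, genes$gene_id), ]
  iv <- window_interval(g, spec)
  bp <- breakpoint_table(cohort)
  items <- list()
  for (i in seq_len(nrow(sig))) {
    sub <- bp[bp$chrom == g$chrom[i] & bp$pos >= iv$lo[i] & bp$pos < iv$hi[i], ]
    if (!nrow(sub)) next
    cls <- tapply(sub$sv_class, sub$patient_id, function(x) unique(x),
                  simplify = FALSE)
    items[[sig$gene_id[i]]] <- data.frame(
      gene_id = sig$gene_id[i],
      patient_id = rep(names(cls), lengths(cls)),
      sv_class = unlist(cls, use.names = FALSE),
      increased = sig$direction[i] == "positive",
      stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, c(items, make.row.names = FALSE))
  out <- lapply(intersect(SV_CLASSES, unique(items$sv_class)), function(cl)
    enrichment_chisq(items$sv_class == cl, items$increased))
  names(out) <- intersect(SV_CLASSES, unique(items$sv_class))
  out
}

#' Per-patient cytoband enrichment of SV breakpoints
#'
#' For one patient, tests each cytoband for an excess of SV breakpoints
#' relative to the expectation proportional to the band's share of the
#' genome length: a chi-squared test (1 df) on the in-band/out-of-band
#' breakpoint counts against expected proportions.
#'
#' @param patient_svs SV records of one patient.
#' @param cytobands Cytoband data frame (`band`, `chrom`, `start`, `end`)
#'   tiling the genome.
#' @return Data frame per band: `band`, `n_in`, `n_total`, `expected`,
#'   `chi2`, `p`, `enriched`; zero rows when the patient has no SVs.
#' @export
cytoband_enrichment <- function(patient_svs, cytobands) {
  bp <- breakpoint_table(patient_svs)
  n <- nrow(bp)
  if (!n)
    return(data.frame(band = character(), n_in = integer(),
                      n_total = integer(), expected = numeric(),
                      chi2 = numeric(), p = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  total_len <- sum(cytobands$end - cytobands$start)
  counts <- integer(nrow(cytobands))
  for (ch in unique(cytobands$chrom)) {
    bi <- which(cytobands$chrom == ch)
    pos <- bp$pos[bp$chrom == ch]
    if (!length(pos)) next
    # bands tile the chromosome; bin by start boundaries
    brk <- c(cytobands$start[bi], cytobands$end[bi[length(bi)]])
    counts[bi] <- counts[bi] +
      tabulate(findInterval(pos, brk, left.open = FALSE,
                            rightmost.closed = FALSE),
               nbins = length(bi))
  }
  f <- (cytobands$end - cytobands$start) / total_len
  expected <- n * f
  chi2 <- (counts - expected)^2 / expected +
    ((n - counts) - (n - expected))^2 / (n - expected)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  data.frame(band = cytobands$band, n_in = counts, n_total = n,
             expected = expected, chi2 = chi2, p = p,
             enriched = counts > expected, stringsAsFactors = FALSE)
}

#' Cohort-level cytoband summary
#'
#' Runs [cytoband_enrichment()] per patient and returns the bands enriched
#' with `p < p_threshold` for at least `min_patients` patients.
#'
#' @param cohort SV record data frame across patients.
#' @param cytobands Cytoband data frame.
#' @param p_threshold Per-patient significance cutoff (default 1e-4).
#' @param min_patients Minimum number of significant patients (default 20).
#' @return Data frame `band`, `n_significant_patients`, sorted decreasing.
#' @export
cytoband_cohort_summary <- function(cohort, cytobands, p_threshold = 1e-4,
                                    min_patients = 20) {
  patients <- unique(cohort$patient_id)
  hits <- lapply(patients, function(p) {
    res <- cytoband_enrichment(cohort[cohort$patient_id == p, ], cytobands)
    res$band[!is.na(res$p) & res$p < p_threshold & res$enriched]
  })
  tab <- table(unlist(hits))
  tab <- tab[tab >= min_patients]
  out <- data.frame(band = names(tab),
                    n_significant_patients = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n_significant_patients, out$band), , drop = FALSE]
}

#' Ploidy-corrected copy-number category
#'
#' Diploid-equivalent copies are `copies * 2 / ploidy`. Categories:
#' amplification (> 5), copy gain (3 to 5, inclusive), copy loss (0 to 1,
#' inclusive), neutral otherwise.
#'
#' @param copies Numeric copy values.
#' @param ploidy Matching tumor ploidy values (default 2: no correction).
#' @return Character vector of categories.
#' @export
copy_category <- function(copies, ploidy = 2) {
  corrected <- copies * 2 / ploidy
  ifelse(corrected > 5, "amplification",
         ifelse(corrected >= 3, "copy_gain",
                ifelse(corrected <= 1, "copy_loss", "neutral")))
}

#' Crosstab of gene-spanning DUP/DEL events by copy category
#'
#' Finds intrachromosomal duplication and deletion SVs whose interval spans a
#' whole gene, looks up the gene's ploidy-corrected copy number in that
#' sample, and cross-tabulates SV class against copy category. Chi-squared
#' enrichments for duplication with copy gain/amplification and deletion
#' with copy loss are attached.
#'
#' @param cohort SV record data frame.
#' @param genes Gene model data frame.
#' @param copy_matrix Gene x sample copy-number matrix (raw copies).
#' @param covars Covariates with `patient_id` and `ploidy`.
#' @return List `crosstab` (class x category counts), `dup_gain`
#'   (`enrichment_result`), `del_loss` (`enrichment_result`), `events`.
#' @export
copy_category_crosstab <- function(cohort, genes, copy_matrix, covars) {
  sv <- cohort[cohort$chrom_a == cohort$chrom_b &
                 cohort$sv_class %in% c("DUP", "DEL"), ]
  events <- list()
  for (k in seq_len(nrow(sv))) {
    hit <- genes$chrom == sv$chrom_a[k] & genes$start >= sv$pos_a[k] &
      genes$end <= sv$pos_b[k]
    if (!any(hit)) next
    gid <- genes$gene_id[hit]
    gid <- gid[gid %in% rownames(copy_matrix)]
    if (!length(gid)) next
    events[[k]] <- data.frame(gene_id = gid, patient_id = sv$patient_id[k],
                              sv_class = sv$sv_class[k],
                              stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, c(events, make.row.names = FALSE))
  if (is.null(events) || !nrow(events))
    stop("no gene-spanning DUP/DEL events in the cohort")
  missing <- setdiff(events$patient_id, colnames(copy_matrix))
  if (length(missing))
    stop("samples without copy data: ", paste(head(missing, 5), collapse = ", "))
  copies <- copy_matrix[cbind(events$gene_id, events$patient_id)]
  ploidy <- covars$ploidy[match(events$patient_id, covars$patient_id)]
  events$category <- copy_category(copies, ploidy)
  crosstab <- table(sv_class = events$sv_class,
                    category = factor(events$category,
                                      levels = c("copy_loss", "neutral",
                                                 "copy_gain", "amplification")))
  list(crosstab = crosstab,
       dup_gain = enrichment_chisq(events$sv_class == "DUP",
                                   events$category %in% c("copy_gain",
                                                          "amplification")),
       del_loss = enrichment_chisq(events$sv_class == "DEL",
                                   events$category == "copy_loss"),
       events = events)
}

#' Cross up-regulated SV-associated genes with essentiality screens
#'
#' @param genes_up Character vector of genes with positive SV-expression
#'   association (e.g. p < 0.01 and >= 3 carriers).
#' @param ess Gene x cell-line matrix of gene-effect scores (more negative =
#'   more essential).
#' @param score_threshold Essentiality cutoff on the score (default -0.75).
#' @param frac_threshold Minimum fraction of cell lines below the cutoff
#'   (default 0.05, strict inequality).
#' @return Data frame `gene_id`, `essential_fraction` for the qualifying
#'   genes; genes absent from `ess` are excluded with a message.
#' @export
cross_essentiality <- function(genes_up, ess, score_threshold = -0.75,
                               frac_threshold = 0.05) {
  absent <- setdiff(genes_up, rownames(ess))
  if (length(absent))
    message(length(absent), " genes absent from the essentiality matrix")
  present <- intersect(genes_up, rownames(ess))
  frac <- rowMeans(ess[present, , drop = FALSE] < score_threshold)
  keep <- frac > frac_threshold
  data.frame(gene_id = present[keep],
             essential_fraction = unname(frac[keep]),
             stringsAsFactors = FALSE)
}
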