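# Synthetic cohort generator: genome annotation, two-caller SV call sets with
# a recurrent germline population panel, expression/copy-number/covariates
# with planted cis-effects, and survival times with planted hazards.

SV_CLASSES <- c("DEL", "DUP", "INV", "TRA")

#' Simulate a genome annotation
#'
#' Builds a small genome: chromosomes of equal length, non-overlapping genes
#' with random strands (about half carrying a 3' UTR at the strand-appropriate
#' end), enhancer intervals, and cytobands that tile each chromosome exactly.
#'
#' @param n_chroms Number of chromosomes.
#' @param n_genes Total number of genes, distributed across chromosomes.
#' @param n_enhancers Total number of enhancer intervals.
#' @param bands_per_chrom Cytobands per chromosome (equal-width tiling).
#' @param seed Integer seed; identical seeds give identical annotations.
#' @param chrom_length Length of every chromosome in bp.
#' @param gene_length_range Min/max gene length (bp).
#' @param utr3_fraction Fraction of genes assigned a 3' UTR.
#' @param utr3_length_range Min/max 3' UTR length (bp); truncated to fit.
#' @param enhancer_length_range Min/max enhancer length (bp).
#' @return A `genome_annotation` list with `genes` (gene_id, chrom, start,
#'   end, strand, utr3_start, utr3_end), `enhancers`, `cytobands` and
#'   `chrom_lengths`. Coordinates are 0-based half-open.
#' @export
simulate_genome <- function(n_chroms, n_genes, n_enhancers, bands_per_chrom,
                            seed = 1L,
                            chrom_length = 5e7,
                            gene_length_range = c(5e3, 1e5),
                            utr3_fraction = 0.5,
                            utr3_length_range = c(200, 2000),
                            enhancer_length_range = c(500, 2000)) {
  stopifnot(n_chroms >= 1, n_genes >= 1, n_enhancers >= 0, bands_per_chrom >= 1)
  set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chroms))
  chrom_lengths <- setNames(rep(chrom_length, n_chroms), chroms)

  # genes round-robin across chromosomes, packed left to right with random gaps
  gene_chrom <- chroms[((seq_len(n_genes) - 1L) %% n_chroms) + 1L]
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    idx <- which(gene_chrom == ch)
    if (!length(idx)) return(NULL)
    k <- length(idx)
    len <- floor(runif(k, gene_length_range[1], gene_length_range[2]))
    free <- chrom_length - sum(len)
    if (free < 0)
      stop("infeasible gene packing: ", k, " genes do not fit on ", ch)
    gaps <- diff(c(0, sort(runif(k, 0, free))))
    start <- floor(cumsum(gaps) + cumsum(c(0, len[-k])))
    data.frame(gene_id = sprintf("gene%05d", idx), chrom = ch,
               start = start, end = start + len,
               strand = sample(c("+", "-"), k, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  genes <- genes[order(as.integer(sub("gene", "", genes$gene_id))), ]
  rownames(genes) <- NULL

  has_utr <- runif(n_genes) < utr3_fraction
  ulen <- floor(runif(n_genes, utr3_length_range[1], utr3_length_range[2]))
  ulen <- pmin(ulen, genes$end - genes$start - 1L)
  genes$utr3_start <- ifelse(has_utr,
                             ifelse(genes$strand == "+", genes$end - ulen, genes$start),
                             NA_real_)
  genes$utr3_end <- ifelse(has_utr,
                           ifelse(genes$strand == "+", genes$end, genes$start + ulen),
                           NA_real_)

  enhancers <- NULL
  if (n_enhancers > 0) {
    elen <- floor(runif(n_enhancers, enhancer_length_range[1], enhancer_length_range[2]))
    echrom <- sample(chroms, n_enhancers, replace = TRUE)
    estart <- floor(runif(n_enhancers, 0, chrom_length - elen))
    enhancers <- data.frame(enh_id = sprintf("enh%05d", seq_len(n_enhancers)),
                            chrom = echrom, start = estart, end = estart + elen,
                            stringsAsFactors = FALSE)
  } else {
    enhancers <- data.frame(enh_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            stringsAsFactors = FALSE)
  }

  cytobands <- do.call(rbind, lapply(chroms, function(ch) {
    b <- round(seq(0, chrom_length, length.out = bands_per_chrom + 1L))
    data.frame(band = sprintf("%s:b%02d", ch, seq_len(bands_per_chrom)),
               chrom = ch, start = b[-length(b)], end = b[-1],
               stringsAsFactors = FALSE)
  }))

  out <- list(genes = genes, enhancers = enhancers, cytobands = cytobands,
              chrom_lengths = chrom_lengths)
  class(out) <- "genome_annotation"
  out
}

default_germline_params <- function() {
  list(n_panel = 1000L,
       class_fractions = c(DEL = 0.78, INV = 0.125, DUP = 0.093) /
         sum(c(0.78, 0.125, 0.093)),
       size_meanlog = log(2100), size_sdlog = 1.0,
       freq_range = c(0.05, 0.5),
       dropout = 0.05,
       tissue_bias = NULL,
       hotspot = NULL,
       planted = NULL)
}

default_somatic_params <- function() {
  list(mean_per_patient = 20,
       class_fractions = c(DEL = 0.30, DUP = 0.25, INV = 0.21, TRA = 0.24),
       size_meanlog = log(175000), size_sdlog = 1.2,
       planted = NULL)
}

# place one planted SV relative to a gene; returns c(pos_a, pos_b)
place_planted_sv <- function(gene, window, genome, extent = 1e5,
                             span_enhancer = FALSE) {
  tss <- if (gene$strand == "+") gene$start else gene$end
  tes <- if (gene$strand == "+") gene$end else gene$start
  flank <- switch(window,
    gene_body = c(gene$start, gene$end),
    up_100kb = if (gene$strand == "+") c(max(0, gene$start - extent), gene$start)
               else c(gene$end, gene$end + extent),
    down_100kb = if (gene$strand == "+") c(gene$end, gene$end + extent)
                 else c(max(0, gene$start - extent), gene$start),
    utr3 = c(gene$utr3_start, gene$utr3_end),
    stop("unsupported planted window: ", window))
  if (any(is.na(flank))) stop("gene ", gene$gene_id, " lacks the ", window, " region")
  if (span_enhancer) {
    enh <- genome$enhancers
    enh <- enh[enh$chrom == gene$chrom & enh$start >= flank[1] & enh$end <= flank[2], ]
    if (!nrow(enh)) stop("no enhancer inside the ", window, " flank of ", gene$gene_id)
    e <- enh[1, ]
    margin_lo <- floor((e$start - flank[1]) / 2)
    margin_hi <- floor((flank[2] - e$end) / 2)
    return(c(e$start - max(1, margin_lo), e$end + max(1, margin_hi)))
  }
  sort(floor(runif(2, flank[1], flank[2])))
}

#' Simulate a cohort of SV call sets
#'
#' Germline SVs are drawn from a shared population panel: each panel SV has
#' fixed breakpoints and a carrier frequency, and carriers are Bernoulli draws
#' per patient, which makes germline calls highly recurrent across patients.
#' Panel SVs are mostly small deletions (kb scale) by default. Somatic SVs are
#' patient-private, larger, and include inter-chromosomal translocations. Two
#' germline call sets are emitted: caller A at the true coordinates and
#' caller B with per-breakpoint uniform jitter and per-call dropout, emulating
#' a second caller to be harmonized by [merge_callsets()].
#'
#' `germline_params$planted` may name genes at which panel SVs are placed
#' inside a specific window (`gene_body`, `up_100kb`, `down_100kb`, `utr3`),
#' optionally spanning an enhancer (`span_enhancer = TRUE`, for duplication
#' SVs); these anchor planted expression effects downstream.
#' `germline_params$tissue_bias = list(fraction, hi, lo)` makes that fraction
#' of background panel SVs tissue-restricted: carrier frequency `hi` in the
#' SV's home tissue and `lo` elsewhere (requires `patient_tissues`).
#'
#' @param genome A `genome_annotation`.
#' @param n_patients Cohort size.
#' @param germline_params,somatic_params Named lists overriding the defaults
#'   (see Details); partial lists are merged.
#' @param caller_jitter_bp Max absolute per-breakpoint jitter for caller B.
#' @param seed Integer seed.
#' @param patient_tissues Optional character vector (length `n_patients`) of
#'   tissue labels, used by tissue-biased panels and stored on the cohort.
#' @return An `sv_cohort` list: `germline_a`, `germline_b`, `somatic` (SV
#'   record data frames), `panel` (panel SV table with `frequency` and any
#'   planted `gene_id`/`window`), `carriers` (panel x patient logical truth
#'   matrix), `patients`, `patient_tissues`.
#' @export
simulate_sv_cohort <- function(genome, n_patients,
                               germline_params = list(),
                               somatic_params = list(),
                               caller_jitter_bp = 50L,
                               seed = 1L,
                               patient_tissues = NULL) {
  gp <- utils::modifyList(default_germline_params(), germline_params)
  sp <- utils::modifyList(default_somatic_params(), somatic_params)
  stopifnot(caller_jitter_bp >= 0, n_patients >= 1)
  if (abs(sum(gp$class_fractions) - 1) > 1e-6)
    stop("germline class fractions must sum to 1")
  if (abs(sum(sp$class_fractions) - 1) > 1e-6)
    stop("somatic class fractions must sum to 1")
  set.seed(seed)
  patients <- sprintf("P%04d", seq_len(n_patients))
  chroms <- names(genome$chrom_lengths)

  # --- germline population panel ---
  n_bg <- gp$n_panel
  n_planted <- if (is.null(gp$planted)) 0L else nrow(gp$planted)
  if (n_bg + n_planted == 0L && n_patients > 0L)
    stop("empty germline panel with n_patients > 0")

  panel <- NULL
  if (n_bg > 0) {
    cls <- sample(names(gp$class_fractions), n_bg, replace = TRUE,
                  prob = gp$class_fractions)
    size <- pmax(50, floor(rlnorm(n_bg, gp$size_meanlog, gp$size_sdlog)))
    ch <- sample(chroms, n_bg, replace = TRUE)
    maxpos <- genome$chrom_lengths[ch] - size
    pos_a <- floor(runif(n_bg, 0, pmax(1, maxpos)))
    if (!is.null(gp$hotspot)) {
      # a fraction of the panel concentrates in one genomic region, emulating
      # recurrent SV hotspots at specific cytobands
      hs <- gp$hotspot
      in_hs <- runif(n_bg) < hs$fraction
      ch[in_hs] <- hs$chrom
      pos_a[in_hs] <- floor(runif(sum(in_hs), hs$start,
                                  pmax(hs$start + 1, hs$end - size[in_hs])))
    }
    panel <- data.frame(panel_id = sprintf("pnl%04d", seq_len(n_bg)),
                        chrom = ch, pos_a = pos_a, pos_b = pos_a + size,
                        sv_class = cls,
                        frequency = runif(n_bg, gp$freq_range[1], gp$freq_range[2]),
                        gene_id = NA_character_, window = NA_character_,
                        home_tissue = NA_character_,
                        stringsAsFactors = FALSE)
    if (!is.null(gp$tissue_bias) && gp$tissue_bias$fraction > 0) {
      if (is.null(patient_tissues))
        stop("tissue_bias requires patient_tissues")
      biased <- runif(n_bg) < gp$tissue_bias$fraction
      panel$home_tissue[biased] <- sample(unique(patient_tissues),
                                          sum(biased), replace = TRUE)
    }
  }
  if (n_planted > 0) {
    pl <- gp$planted
    if (is.null(pl$sv_class)) pl$sv_class <- "DEL"
    if (is.null(pl$span_enhancer)) pl$span_enhancer <- FALSE
    rows <- lapply(seq_len(n_planted), function(i) {
      g <- genome$genes[genome$genes$gene_id == pl$gene_id[i], ]
      if (!nrow(g)) stop("planted gene not in annotation: ", pl$gene_id[i])
      pos <- place_planted_sv(g[1, ], pl$window[i], genome,
                              span_enhancer = isTRUE(pl$span_enhancer[i]))
      data.frame(panel_id = sprintf("pltd%04d", i),
                 chrom = g$chrom[1], pos_a = pos[1], pos_b = pos[2],
                 sv_class = pl$sv_class[i], frequency = pl$frequency[i],
                 gene_id = pl$gene_id[i], window = pl$window[i],
                 home_tissue = NA_character_, stringsAsFactors = FALSE)
    })
    panel <- rbind(panel, do.call(rbind, rows))
  }
  rownames(panel) <- NULL
  n_panel <- nrow(panel)

  # carrier truth: Bernoulli per (panel SV, patient)
  freq <- matrix(panel$frequency, n_panel, n_patients)
  if (any(!is.na(panel$home_tissue))) {
    tb <- gp$tissue_bias
    for (i in which(!is.na(panel$home_tissue)))
      freq[i, ] <- ifelse(patient_tissues == panel$home_tissue[i], tb$hi, tb$lo)
  }
  carriers <- matrix(runif(n_panel * n_patients), n_panel, n_patients) < freq
  dimnames(carriers) <- list(panel$panel_id, patients)

  idx <- which(carriers, arr.ind = TRUE)
  if (!nrow(idx)) {
    germline_a <- data.frame(sv_id = character(), patient_id = character(),
                             chrom_a = character(), pos_a = numeric(),
                             chrom_b = character(), pos_b = numeric(),
                             sv_class = character(), origin = character(),
                             stringsAsFactors = FALSE)
  } else
  germline_a <- data.frame(
    sv_id = paste0(panel$panel_id[idx[, 1]], ".", patients[idx[, 2]]),
    patient_id = patients[idx[, 2]],
    chrom_a = panel$chrom[idx[, 1]], pos_a = panel$pos_a[idx[, 1]],
    chrom_b = panel$chrom[idx[, 1]], pos_b = panel$pos_b[idx[, 1]],
    sv_class = panel$sv_class[idx[, 1]], origin = "germline",
    stringsAsFactors = FALSE)
  germline_a <- germline_a[order(germline_a$patient_id, germline_a$sv_id), ]
  rownames(germline_a) <- NULL

  # caller B replicate: jitter within +/- caller_jitter_bp, then dropout
  nb <- nrow(germline_a)
  germline_b <- germline_a
  if (nb > 0) {
    j <- function(n) floor(runif(n, -caller_jitter_bp, caller_jitter_bp + 1))
    germline_b$pos_a <- pmax(0, germline_a$pos_a + j(nb))
    germline_b$pos_b <- pmax(0, germline_a$pos_b + j(nb))
    swap <- germline_b$pos_a > germline_b$pos_b
    tmp <- germline_b$pos_a[swap]
    germline_b$pos_a[swap] <- germline_b$pos_b[swap]
    germline_b$pos_b[swap] <- tmp
    germline_b$sv_id <- sub("^pnl", "b.pnl", sub("^pltd", "b.pltd", germline_b$sv_id))
    keep <- runif(nb) >= gp$dropout
    germline_b <- germline_b[keep, ]
    rownames(germline_b) <- NULL
  }

  # --- somatic: private per patient ---
  n_som <- rpois(n_patients, sp$mean_per_patient)
  som <- NULL
  tot <- sum(n_som)
  if (tot > 0) {
    pat <- rep(patients, n_som)
    cls <- sample(names(sp$class_fractions), tot, replace = TRUE,
                  prob = sp$class_fractions)
    ch_a <- sample(chroms, tot, replace = TRUE)
    size <- pmax(50, floor(rlnorm(tot, sp$size_meanlog, sp$size_sdlog)))
    is_tra <- cls == "TRA"
    ch_b <- ch_a
    if (any(is_tra) && length(chroms) > 1) {
      ch_b[is_tra] <- vapply(ch_a[is_tra], function(c0)
        sample(setdiff(chroms, c0), 1L), character(1))
    } else if (any(is_tra)) {
      cls[is_tra] <- "INV"  # single-chromosome genome cannot host TRA
      is_tra[] <- FALSE
    }
    size[is_tra] <- NA
    maxa <- genome$chrom_lengths[ch_a] - ifelse(is_tra, 1, size)
    pos_a <- floor(runif(tot, 0, pmax(1, maxa)))
    pos_b <- ifelse(is_tra,
                    floor(runif(tot, 0, genome$chrom_lengths[ch_b])),
                    pos_a + size)
    som <- data.frame(sv_id = sprintf("som%06d", seq_len(tot)),
                      patient_id = pat, chrom_a = ch_a, pos_a = pos_a,
                      chrom_b = ch_b, pos_b = pos_b, sv_class = cls,
                      origin = "somatic", stringsAsFactors = FALSE)
  }
  somatic_planted <- NULL
  if (!is.null(sp$planted)) {
    # somatic planted SVs use the same placement machinery, one event per
    # listed (gene, patient) frequency draw; carriers are returned as truth
    pls <- sp$planted
    extra <- lapply(seq_len(nrow(pls)), function(i) {
      g <- genome$genes[genome$genes$gene_id == pls$gene_id[i], ]
      if (!nrow(g)) stop("planted gene not in annotation: ", pls$gene_id[i])
      carr <- patients[runif(n_patients) < pls$frequency[i]]
      if (!length(carr)) return(NULL)
      pos <- place_planted_sv(g[1, ], pls$window[i], genome)
      data.frame(sv_id = sprintf("somp%03d.%s", i, carr), patient_id = carr,
                 chrom_a = g$chrom[1], pos_a = pos[1],
                 chrom_b = g$chrom[1], pos_b = pos[2],
                 sv_class = if (is.null(pls$sv_class)) "DUP" else pls$sv_class[i],
                 origin = "somatic",
                 gene_id = pls$gene_id[i], stringsAsFactors = FALSE)
    })
    extra <- do.call(rbind, extra)
    if (!is.null(extra)) {
      somatic_planted <- extra[, c("gene_id", "patient_id")]
      som <- rbind(som, extra[, setdiff(names(extra), "gene_id")])
    }
  }
  if (!is.null(som)) rownames(som) <- NULL

  out <- list(germline_a = germline_a, germline_b = germline_b, somatic = som,
              panel = panel, carriers = carriers, patients = patients,
              somatic_planted = somatic_planted,
              patient_tissues = patient_tissues)
  class(out) <- "sv_cohort"
  out
}

#' Find genes with an enhancer wholly inside a flank window
#'
#' Convenience lookup used when planting enhancer-duplication SVs: returns
#' (gene, enhancer) pairs where the enhancer lies entirely within the gene's
#' upstream or downstream flank of the given extent and outside the gene body.
#'
#' @param genome A `genome_annotation`.
#' @param extent_bp Flank extent in bp.
#' @param side `"up"` or `"down"` (strand-aware).
#' @return Data frame with `gene_id`, `enh_id`, `window`.
#' @export
find_enhancer_flank_genes <- function(genome, extent_bp = 1e5, side = "up") {
  g <- genome$genes
  lo <- ifelse((g$strand == "+") == (side == "up"),
               pmax(0, g$start - extent_bp), g$end)
  hi <- ifelse((g$strand == "+") == (side == "up"), g$start, g$end + extent_bp)
  e <- genome$enhancers
  hits <- lapply(seq_len(nrow(g)), function(i) {
    sel <- e$chrom == g$chrom[i] & e$start >= lo[i] & e$end <= hi[i]
    if (!any(sel)) return(NULL)
    data.frame(gene_id = g$gene_id[i], enh_id = e$enh_id[sel],
               window = if (side == "up") "up_100kb" else "down_100kb",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(gene_id = character(), enh_id = character(),
                               window = character(), stringsAsFactors = FALSE)
  else out
}

#' Simulate expression, copy number and sample covariates
#'
#' Log2 expression for gene g in sample s is
#' `baseline(g) + tissue_offset(g, tissue(s)) + effect(g) * carrier(g, s)
#'  + cn_coef * (copies - 2) + N(0, noise_sd)`,
#' and the emitted matrix is on the linear scale, `2^y - 1`, so that the
#' downstream `log2(x + 1)` transform recovers y. Carrier status for an
#' effect gene is the union of carriers of the panel SVs planted at that gene
#' (`cohort$panel$gene_id`). Ploidy and purity are uniform draws; gene-level
#' copy number fluctuates around ploidy and, when `cn_somatic_effect` is on,
#' is shifted for genes spanned by somatic duplication (+2) or deletion
#' (-1.5) SVs of the sample.
#'
#' @param genome A `genome_annotation`.
#' @param cohort An `sv_cohort`.
#' @param covariates_params List: `tissues` (labels), `tissue_probs`,
#'   `ploidy_range` (default 1.5-4.5), `purity_range` (default 0.3-1),
#'   `cn_sd`, `cn_somatic_effect`.
#' @param effect_spec List: `effect_genes` (data frame `gene_id`, `effect` in
#'   log2 units), `noise_sd` (default 0.5), `tissue_sd` (default 1, SD of
#'   per-gene tissue baseline offsets), `baseline_range`, `cn_coef`.
#' @param seed Integer seed.
#' @return List with `expression` (linear-scale gene x sample matrix),
#'   `copy_number` (gene x sample), `covariates` (patient_id, tissue, ploidy,
#'   purity), and `truth` (per effect gene: carrier vector used).
#' @export
simulate_expression <- function(genome, cohort,
                                covariates_params = list(),
                                effect_spec = list(),
                                seed = 1L) {
  cp <- utils::modifyList(
    list(tissues = paste0("T", 1:4), tissue_probs = NULL,
         ploidy_range = c(1.5, 4.5), purity_range = c(0.3, 1.0),
         cn_sd = 0.3, cn_somatic_effect = TRUE),
    covariates_params)
  es <- utils::modifyList(
    list(effect_genes = NULL, noise_sd = 0.5, tissue_sd = 1.0,
         baseline_range = c(4, 8), cn_coef = 0),
    effect_spec)
  stopifnot(es$noise_sd >= 0, es$tissue_sd >= 0)
  set.seed(seed)

  patients <- cohort$patients
  n <- length(patients)
  genes <- genome$genes$gene_id
  ng <- length(genes)

  tissue <- cohort$patient_tissues
  if (is.null(tissue))
    tissue <- sample(cp$tissues, n, replace = TRUE, prob = cp$tissue_probs)
  ploidy <- runif(n, cp$ploidy_range[1], cp$ploidy_range[2])
  purity <- runif(n, cp$purity_range[1], cp$purity_range[2])
  covariates <- data.frame(patient_id = patients, tissue = tissue,
                           ploidy = ploidy, purity = purity,
                           stringsAsFactors = FALSE)

  baseline <- runif(ng, es$baseline_range[1], es$baseline_range[2])
  utissues <- sort(unique(tissue))
  toff <- matrix(rnorm(ng * length(utissues), 0, es$tissue_sd),
                 ng, length(utissues), dimnames = list(genes, utissues))

  y <- baseline + toff[, match(tissue, utissues), drop = FALSE]
  dimnames(y) <- list(genes, patients)

  # copy number around ploidy, optionally dented by spanning somatic SVs
  cn <- matrix(rep(ploidy, each = ng), ng, n, dimnames = list(genes, patients)) +
    matrix(rnorm(ng * n, 0, cp$cn_sd), ng, n)
  if (isTRUE(cp$cn_somatic_effect) && !is.null(cohort$somatic) &&
      nrow(cohort$somatic) > 0) {
    sv <- cohort$somatic
    sv <- sv[sv$chrom_a == sv$chrom_b & sv$sv_class %in% c("DUP", "DEL"), ]
    gt <- genome$genes
    for (k in seq_len(nrow(sv))) {
      hit <- gt$chrom == sv$chrom_a[k] & gt$start >= sv$pos_a[k] &
        gt$end <= sv$pos_b[k]
      if (!any(hit)) next
      d <- if (sv$sv_class[k] == "DUP") 2 else -1.5
      cn[hit, sv$patient_id[k]] <- cn[hit, sv$patient_id[k]] + d
    }
  }
  cn <- pmax(cn, 0)

  truth <- list()
  if (!is.null(es$effect_genes) && nrow(es$effect_genes) > 0) {
    eg <- es$effect_genes
    missing <- setdiff(eg$gene_id, genes)
    if (length(missing)) stop("effect genes not in annotation: ",
                              paste(missing, collapse = ", "))
    for (i in seq_len(nrow(eg))) {
      gid <- eg$gene_id[i]
      pids <- cohort$panel$panel_id[!is.na(cohort$panel$gene_id) &
                                      cohort$panel$gene_id == gid]
      som_carr <- if (is.null(cohort$somatic_planted)) character(0)
                  else cohort$somatic_planted$patient_id[
                    cohort$somatic_planted$gene_id == gid]
      if (!length(pids) && !length(som_carr)) {
        warning("effect gene ", gid, " has no planted SV; zero carriers")
        carrier <- rep(FALSE, n)
      } else {
        carrier <- rep(FALSE, n)
        if (length(pids))
          carrier <- colSums(cohort$carriers[pids, , drop = FALSE]) > 0
        carrier <- carrier | patients %in% som_carr
      }
      if (!any(carrier))
        warning("effect gene ", gid, " has zero carriers in this cohort")
      y[gid, ] <- y[gid, ] + eg$effect[i] * carrier
      truth[[gid]] <- carrier
    }
  }

  if (es$cn_coef != 0) y <- y + es$cn_coef * (cn - 2)
  if (es$noise_sd > 0)
    y <- y + matrix(rnorm(ng * n, 0, es$noise_sd), ng, n)

  expression <- pmax(2^y - 1, 0)
  list(expression = expression, copy_number = cn, covariates = covariates,
       truth = truth)
}

#' Simulate survival times with planted hazards
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(sum(log_hr * feature))` per patient; censoring times
#' are independent exponentials calibrated so that roughly `censoring_rate`
#' of baseline patients are censored before their event; follow-up is capped
#' at `max_followup` months (event set to 0 at the cap).
#'
#' @param features Data frame or matrix of per-patient features (rows =
#'   patients, in the order of `covariates`); may be NULL when all log-HRs
#'   are zero.
#' @param covariates Data frame with `patient_id` and `tissue` (used as the
#'   stratum label).
#' @param hazard_spec List: `baseline_hazard` (events/month, default 0.02),
#'   `log_hr` (named by feature column, default none), `censoring_rate`
#'   (default 0.3), `max_followup` (months, default 120; may be `Inf`).
#' @param seed Integer seed.
#' @return Data frame `patient_id`, `time` (months), `event` (0/1),
#'   `stratum`.
#' @export
simulate_survival <- function(features, covariates, hazard_spec = list(),
                              seed = 1L) {
  hs <- utils::modifyList(
    list(baseline_hazard = 0.02, log_hr = numeric(0),
         censoring_rate = 0.3, max_followup = 120),
    hazard_spec)
  stopifnot(hs$baseline_hazard > 0,
            hs$censoring_rate >= 0, hs$censoring_rate < 1)
  set.seed(seed)
  n <- nrow(covariates)
  lp <- rep(0, n)
  if (length(hs$log_hr)) {
    f <- as.matrix(as.data.frame(features)[, names(hs$log_hr), drop = FALSE])
    lp <- as.vector(f %*% hs$log_hr)
  }
  t_event <- rexp(n, rate = hs$baseline_hazard * exp(lp))
  if (hs$censoring_rate > 0) {
    c_rate <- hs$baseline_hazard * hs$censoring_rate / (1 - hs$censoring_rate)
    t_cens <- rexp(n, rate = c_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  event <- as.integer(t_event <= t_cens)
  time <- pmin(t_event, t_cens)
  over <- time > hs$max_followup
  time[over] <- hs$max_followup
  event[over] <- 0L
  data.frame(patient_id = covariates$patient_id, time = time, event = event,
             stratum = covariates$tissue, stringsAsFactors = FALSE)
}
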