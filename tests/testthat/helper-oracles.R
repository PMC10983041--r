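# Fixtures and independent brute-force oracles used across the suite.

make_records <- function(chrom_a, pos_a, chrom_b = chrom_a, pos_b,
                         sv_class = "DEL", patient_id = "P1",
                         origin = "germline", sv_id = NULL) {
  n <- max(length(pos_a), length(pos_b))
  data.frame(
    sv_id = if (is.null(sv_id)) sprintf("sv%03d", seq_len(n)) else sv_id,
    patient_id = rep_len(patient_id, n),
    chrom_a = rep_len(chrom_a, n), pos_a = rep_len(pos_a, n),
    chrom_b = rep_len(chrom_b, n), pos_b = rep_len(pos_b, n),
    sv_class = rep_len(sv_class, n), origin = rep_len(origin, n),
    stringsAsFactors = FALSE)
}

make_genes <- function(chrom, start, end, strand = "+", gene_id = NULL,
                       utr3_start = NA_real_, utr3_end = NA_real_) {
  n <- length(start)
  data.frame(
    gene_id = if (is.null(gene_id)) sprintf("g%03d", seq_len(n)) else gene_id,
    chrom = rep_len(chrom, n), start = start, end = end,
    strand = rep_len(strand, n),
    utr3_start = rep_len(utr3_start, n), utr3_end = rep_len(utr3_end, n),
    stringsAsFactors = FALSE)
}

# random SV cohort + genes on a small genome, for oracle comparisons
random_instance <- function(n_genes, n_samples, n_svs, seed,
                            chrom_names = c("chr1", "chr2"), L = 2e6) {
  set.seed(seed)
  gstart <- floor(runif(n_genes, 0, L - 6e4))
  genes <- make_genes(sample(chrom_names, n_genes, replace = TRUE),
                      gstart, gstart + floor(runif(n_genes, 1e3, 5e4)),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE))
  has_utr <- runif(n_genes) < 0.5
  ul <- floor(runif(n_genes, 100, 900))
  genes$utr3_start[has_utr] <- ifelse(genes$strand[has_utr] == "+",
                                      genes$end[has_utr] - ul[has_utr],
                                      genes$start[has_utr])
  genes$utr3_end[has_utr] <- ifelse(genes$strand[has_utr] == "+",
                                    genes$end[has_utr],
                                    genes$start[has_utr] + ul[has_utr])
  samples <- sprintf("S%03d", seq_len(n_samples))
  cls <- sample(c("DEL", "DUP", "INV", "TRA"), n_svs, replace = TRUE,
                prob = c(0.4, 0.2, 0.2, 0.2))
  ch_a <- sample(chrom_names, n_svs, replace = TRUE)
  ch_b <- ifelse(cls == "TRA",
                 vapply(ch_a, function(c0) sample(setdiff(chrom_names, c0), 1),
                        character(1)),
                 ch_a)
  pa <- floor(runif(n_svs, 0, L - 1e5))
  pb <- ifelse(cls == "TRA", floor(runif(n_svs, 0, L)),
               pa + floor(runif(n_svs, 50, 1e5)))
  cohort <- data.frame(sv_id = sprintf("sv%04d", seq_len(n_svs)),
                       patient_id = sample(samples, n_svs, replace = TRUE),
                       chrom_a = ch_a, pos_a = pa, chrom_b = ch_b, pos_b = pb,
                       sv_class = cls, origin = "germline",
                       stringsAsFactors = FALSE)
  list(genes = genes, cohort = cohort, samples = samples)
}

# literal per-gene window interval (independent of the package's helper)
oracle_window <- function(g, label, extent) {
  plus <- g$strand == "+"
  if (label == "gene_body") return(c(g$start, g$end))
  if (label == "utr3") return(c(g$utr3_start, g$utr3_end))
  if (label %in% c("up_100kb", "up_2kb")) {
    if (plus) return(c(max(0, g$start - extent), g$start))
    return(c(g$end, g$end + extent))
  }
  if (label == "down_100kb") {
    if (plus) return(c(g$end, g$end + extent))
    return(c(max(0, g$start - extent), g$start))
  }
  stop("bad label")
}

# nested-loop brute-force breakpoint matrix over (gene, SV, breakpoint);
# columns are hoisted into plain vectors so the loops stay affordable
oracle_matrix <- function(cohort, genes, label, samples,
                          extent = switch(label, up_100kb = 1e5,
                                          down_100kb = 1e5, up_2kb = 2e3, NA)) {
  if (label == "utr3") genes <- genes[!is.na(genes$utr3_start), ]
  M <- matrix(0, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  ch_a <- cohort$chrom_a; ch_b <- cohort$chrom_b
  p_a <- cohort$pos_a; p_b <- cohort$pos_b
  pat <- cohort$patient_id
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    iv <- oracle_window(g, label, extent)
    for (si in seq_along(p_a)) {
      if (ch_a[si] == g$chrom && p_a[si] >= iv[1] && p_a[si] < iv[2])
        M[gi, pat[si]] <- 1
      if (ch_b[si] == g$chrom && p_b[si] >= iv[1] && p_b[si] < iv[2])
        M[gi, pat[si]] <- 1
    }
  }
  M
}

oracle_weighted <- function(cohort, genes, samples, extent = 1e6) {
  M <- matrix(0, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    tss <- if (g$strand == "+") g$start else g$end
    for (s in samples) {
      sel <- cohort$patient_id == s
      if (!any(sel)) next
      d <- Inf
      da <- abs(cohort$pos_a[sel] - tss)[cohort$chrom_a[sel] == g$chrom]
      db <- abs(cohort$pos_b[sel] - tss)[cohort$chrom_b[sel] == g$chrom]
      d <- min(Inf, da, db)
      if (d <= extent) M[gi, s] <- 1 - d / extent
    }
  }
  M
}

# quadratic all-pairs recurrence oracle
oracle_recurrence <- function(cohort, slop) {
  n <- nrow(cohort)
  both <- logical(n); either <- logical(n)
  ch_a <- cohort$chrom_a; ch_b <- cohort$chrom_b
  p_a <- cohort$pos_a; p_b <- cohort$pos_b
  pat <- cohort$patient_id
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (pat[i] == pat[j]) next
    if (ch_a[i] != ch_a[j] || ch_b[i] != ch_b[j]) next
    ma <- abs(p_a[i] - p_a[j]) <= slop
    mb <- abs(p_b[i] - p_b[j]) <= slop
    if (ma && mb) both[i] <- TRUE
    if (ma || mb) either[i] <- TRUE
  }
  data.frame(both_shared = both, either_shared = either)
}

# exhaustive-search one-to-one merge oracle (greedy by total distance)
oracle_merge_ids <- function(a, b, slop) {
  cand <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$patient_id[i] != b$patient_id[j]) next
    if (a$chrom_a[i] != b$chrom_a[j] || a$chrom_b[i] != b$chrom_b[j]) next
    da <- abs(a$pos_a[i] - b$pos_a[j]); db <- abs(a$pos_b[i] - b$pos_b[j])
    if (da <= slop && db <= slop) cand <- rbind(cand, c(i, j, da + db))
  }
  if (is.null(cand)) return(character(0))
  cand <- cand[order(cand[, 3], cand[, 1], cand[, 2]), , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b)); keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE; keep <- c(keep, i)
  }
  sort(a$sv_id[keep])
}

# literal re-implementation of the five enhancer-duplication conditions
oracle_enh_dup <- function(sv, gene, enhancers, flank = 1e5) {
  if (sv$sv_class != "DUP") return(FALSE)
  if (sv$chrom_a != sv$chrom_b || sv$chrom_a != gene$chrom) return(FALSE)
  inside <- function(p) p >= gene$start && p < gene$end
  if (inside(sv$pos_a) || inside(sv$pos_b)) return(FALSE)
  if (sv$pos_a <= gene$start && sv$pos_b >= gene$end) return(FALSE)
  fl <- function(p) (p >= gene$start - flank && p < gene$start) ||
    (p >= gene$end && p < gene$end + flank)
  if (!fl(sv$pos_a) || !fl(sv$pos_b)) return(FALSE)
  found <- FALSE
  for (k in seq_len(nrow(enhancers)))
    if (enhancers$chrom[k] == sv$chrom_a &&
        enhancers$start[k] >= sv$pos_a && enhancers$end[k] <= sv$pos_b)
      found <- TRUE
  found
}

# hand BH implementation for q-value cross-checks
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * n / seq_len(n))))
  pmin(1, q)[order(o)]
}
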