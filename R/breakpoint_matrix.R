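# Gene x sample breakpoint matrices for genomic region windows, and SV/gene
# geometric relation classification.
#
# Window semantics (0-based half-open intervals, strand-aware flanks):
#   gene_body        breakpoint in [start, end)
#   up_100kb/up_2kb  breakpoint in the flank 5' of the gene start, excluding
#                    the gene body
#   down_100kb       flank 3' of the gene end, excluding the gene body
#   utr3             breakpoint within the annotated 3' UTR (genes lacking a
#                    3' UTR are skipped)
#   flank_1mb_weighted  weight 1 - d/extent for the breakpoint nearest the
#                    gene start (transcription start site), d <= extent

WINDOW_LABELS <- c("gene_body", "up_100kb", "down_100kb", "up_2kb", "utr3",
                   "flank_1mb_weighted")

#' Construct a window specification
#'
#' @param label One of `gene_body`, `up_100kb`, `down_100kb`, `up_2kb`,
#'   `utr3`, `flank_1mb_weighted`.
#' @param extent_bp Flank extent; defaults to 100 kb for the 100 kb flanks,
#'   2 kb for `up_2kb` and 1 Mb for the weighted window.
#' @return A `window_spec` list with `label`, `extent`, `weighted`.
#' @export
window_spec <- function(label, extent_bp = NULL) {
  label <- match.arg(label, WINDOW_LABELS)
  if (is.null(extent_bp))
    extent_bp <- switch(label, up_100kb = 1e5, down_100kb = 1e5,
                        up_2kb = 2e3, flank_1mb_weighted = 1e6, NA_real_)
  weighted <- label == "flank_1mb_weighted"
  if (!is.na(extent_bp) && extent_bp <= 0) stop("extent_bp must be positive")
  structure(list(label = label, extent = extent_bp, weighted = weighted),
            class = "window_spec")
}

# per-gene target interval [lo, hi) for an unweighted window; NA row = skip
window_interval <- function(genes, spec) {
  plus <- genes$strand == "+"
  switch(spec$label,
    gene_body = data.frame(lo = genes$start, hi = genes$end),
    utr3 = data.frame(lo = genes$utr3_start, hi = genes$utr3_end),
    up_100kb = ,
    up_2kb = data.frame(lo = ifelse(plus, pmax(0, genes$start - spec$extent),
                                    genes$end),
                        hi = ifelse(plus, genes$start, genes$end + spec$extent)),
    down_100kb = data.frame(lo = ifelse(plus, genes$end,
                                        pmax(0, genes$start - spec$extent)),
                            hi = ifelse(plus, genes$end + spec$extent,
                                        genes$start)),
    stop("window_interval undefined for ", spec$label))
}

# long table of single breakpoints: both mates of every SV, each on its own
# chromosome (translocation mates land separately)
breakpoint_table <- function(cohort) {
  data.frame(chrom = c(cohort$chrom_a, cohort$chrom_b),
             pos = c(cohort$pos_a, cohort$pos_b),
             patient_id = rep(cohort$patient_id, 2),
             sv_class = rep(cohort$sv_class, 2),
             sv_id = rep(cohort$sv_id, 2),
             stringsAsFactors = FALSE)
}

#' Build a binary gene-by-sample breakpoint matrix
#'
#' Entry (g, s) is 1 iff any breakpoint of any SV of sample s lies in the
#' window of gene g; both breakpoints of every SV contribute independently,
#' and SV class plays no role. For the `utr3` window, genes without an
#' annotated 3' UTR are dropped from the matrix.
#'
#' @param cohort SV record data frame.
#' @param genes Gene model data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, optional `utr3_start`/`utr3_end`).
#' @param window A `window_spec` (unweighted), or a label passed to
#'   [window_spec()].
#' @param samples Sample (patient) IDs forming the columns; defaults to the
#'   patients present in `cohort`.
#' @return A `breakpoint_matrix` list: `window`, `values` (gene x sample 0/1
#'   matrix), `carrier_counts`.
#' @export
build_breakpoint_matrix <- function(cohort, genes, window,
                                    samples = NULL) {
  if (is.character(window)) window <- window_spec(window)
  if (window$weighted)
    stop("use build_weighted_matrix() for the weighted window")
  if (is.null(samples)) samples <- sort(unique(cohort$patient_id))
  if (window$label == "utr3") genes <- genes[!is.na(genes$utr3_start), ]
  iv <- window_interval(genes, window)
  values <- matrix(0, nrow(genes), length(samples),
                   dimnames = list(genes$gene_id, samples))
  bp <- breakpoint_table(cohort)
  bp <- bp[bp$patient_id %in% samples, ]
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    sub <- bp[bp$chrom == ch, ]
    if (!nrow(sub)) next
    ord <- order(sub$pos)
    pos <- sub$pos[ord]
    pat <- sub$patient_id[ord]
    for (g in gi) {
      lo <- findInterval(iv$lo[g], pos, left.open = TRUE) + 1L
      hi <- findInterval(iv$hi[g], pos, left.open = TRUE)  # pos < hi (half-open)
      if (lo > hi) next
      values[g, unique(pat[lo:hi])] <- 1
    }
  }
  structure(list(window = window, values = values,
                 carrier_counts = rowSums(values > 0)),
            class = "breakpoint_matrix")
}

#' Build the distance-weighted 1 Mb flank matrix
#'
#' For each (gene, sample), let d be the smallest distance between the gene
#' start (transcription start site, strand-aware) and any breakpoint of the
#' sample on the gene's chromosome with d <= `extent_bp`. The entry is
#' `1 - d / extent_bp` when such a breakpoint exists and 0 otherwise, so
#' breakpoints at the gene start weigh 1 and weight decays linearly to 0 at
#' the extent. Moving the nearest breakpoint closer never decreases the
#' entry.
#'
#' @inheritParams build_breakpoint_matrix
#' @param extent_bp Flank extent in bp (default 1 Mb).
#' @return A `breakpoint_matrix` with entries in `[0, 1]`.
#' @export
build_weighted_matrix <- function(cohort, genes, extent_bp = 1e6,
                                  samples = NULL) {
  stopifnot(extent_bp > 0)
  if (is.null(samples)) samples <- sort(unique(cohort$patient_id))
  spec <- window_spec("flank_1mb_weighted", extent_bp)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  values <- matrix(0, nrow(genes), length(samples),
                   dimnames = list(genes$gene_id, samples))
  bp <- breakpoint_table(cohort)
  bp <- bp[bp$patient_id %in% samples, ]
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    sub <- bp[bp$chrom == ch, ]
    if (!nrow(sub)) next
    # per sample, nearest-breakpoint distance via sorted positions
    for (s in unique(sub$patient_id)) {
      pos <- sort(sub$pos[sub$patient_id == s])
      j <- findInterval(tss[gi], pos)
      d_left <- ifelse(j >= 1, tss[gi] - pos[pmax(j, 1)], Inf)
      d_right <- ifelse(j < length(pos), pos[pmin(j + 1L, length(pos))] - tss[gi],
                        Inf)
      d <- pmin(d_left, d_right)
      w <- ifelse(d <= extent_bp, 1 - d / extent_bp, 0)
      values[gi, s] <- w
    }
  }
  structure(list(window = spec, values = values,
                 carrier_counts = rowSums(values > 0)),
            class = "breakpoint_matrix")
}

#' Classify the geometric relation between one SV and one gene
#'
#' Each breakpoint is classified independently: `in_utr3` when it falls in
#' the annotated 3' UTR, else `breakpoint_in_gene` when inside
#' `[start, end)`, else `upstream`/`downstream` (strand-aware: upstream is 5'
#' of the gene on the gene's strand) with the distance to the nearer gene
#' boundary, or `none` on a different chromosome. `spans_gene` is TRUE for
#' intrachromosomal SVs whose `[pos_a, pos_b]` contains the whole gene.
#'
#' @param sv One SV record (1-row data frame or list).
#' @param gene One gene model row.
#' @return List `relation_a`, `relation_b`, `distance_a`, `distance_b`
#'   (bp to the nearer gene boundary, NA inside the gene or off-chromosome),
#'   `spans_gene`.
#' @export
classify_sv_gene_relation <- function(sv, gene) {
  classify_bp <- function(chrom, pos) {
    if (chrom != gene$chrom)
      return(list(relation = "none", distance = NA_real_))
    if (!is.na(gene$utr3_start) && pos >= gene$utr3_start && pos < gene$utr3_end)
      return(list(relation = "in_utr3", distance = NA_real_))
    if (pos >= gene$start && pos < gene$end)
      return(list(relation = "breakpoint_in_gene", distance = NA_real_))
    before <- pos < gene$start
    dist <- if (before) gene$start - pos else pos - gene$end + 1
    rel <- if (before == (gene$strand == "+")) "upstream" else "downstream"
    list(relation = rel, distance = dist)
  }
  a <- classify_bp(sv$chrom_a, sv$pos_a)
  b <- classify_bp(sv$chrom_b, sv$pos_b)
  spans <- sv$chrom_a == sv$chrom_b && sv$chrom_a == gene$chrom &&
    sv$pos_a <= gene$start && sv$pos_b >= gene$end
  list(relation_a = a$relation, relation_b = b$relation,
       distance_a = a$distance, distance_b = b$distance,
       spans_gene = spans)
}

#' Assemble a breakpoint matrix from a plain values matrix
#'
#' Useful when a matrix written by [write_breakpoint_matrix()] is read back
#' from disk (see [read_matrix_tsv()]).
#'
#' @param values Gene x sample numeric matrix.
#' @param window A `window_spec` or window label.
#' @return A `breakpoint_matrix`.
#' @export
as_breakpoint_matrix <- function(values, window) {
  if (is.character(window)) window <- window_spec(window)
  structure(list(window = window, values = values,
                 carrier_counts = rowSums(values > 0)),
            class = "breakpoint_matrix")
}

#' Write a breakpoint matrix with its window sidecar
#'
#' The matrix goes to `path` as a TSV (genes x samples) and the window
#' specification to `paste0(path, ".json")`.
#'
#' @param m A `breakpoint_matrix`.
#' @param path Output TSV path.
#' @export
write_breakpoint_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(label = m$window$label, extent = m$window$extent,
                            weighted = m$window$weighted),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
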