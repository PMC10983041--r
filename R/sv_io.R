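# SV call-set I/O, two-caller harmonization with positional slop, breakpoint
# recurrence, known-catalog overlap and descriptive statistics.

validate_sv_records <- function(records, context = "SV table") {
  required <- c("sv_id", "patient_id", "chrom_a", "pos_a", "chrom_b", "pos_b",
                "sv_class", "origin")
  missing <- setdiff(required, names(records))
  if (length(missing))
    stop(context, ": missing columns: ", paste(missing, collapse = ", "))
  bad <- list()
  unknown <- !(records$sv_class %in% SV_CLASSES)
  if (any(unknown))
    stop(context, ": unknown sv_class token(s) ",
         paste(unique(records$sv_class[unknown]), collapse = ", "),
         " at row(s) ", paste(head(which(unknown), 10), collapse = ", "))
  if (any(records$pos_a < 0 | records$pos_b < 0))
    stop(context, ": negative coordinate at row(s) ",
         paste(head(which(records$pos_a < 0 | records$pos_b < 0), 10),
               collapse = ", "))
  inter <- records$chrom_a != records$chrom_b
  geom_bad <- (records$sv_class == "TRA") != inter
  if (any(geom_bad))
    stop(context, ": sv_class/geometry mismatch (TRA iff chrom_a != chrom_b) ",
         "at row(s) ", paste(head(which(geom_bad), 10), collapse = ", "))
  # canonical breakpoint order for intrachromosomal records
  swap <- !inter & records$pos_a > records$pos_b
  if (any(swap)) {
    tmp <- records$pos_a[swap]
    records$pos_a[swap] <- records$pos_b[swap]
    records$pos_b[swap] <- tmp
  }
  records
}

#' Read an SV call set from a BEDPE-like table
#'
#' Expects a tab-separated table with header columns `chrom_a, start_a,
#' end_a, chrom_b, start_b, end_b, sv_id, sv_class, patient_id, origin`
#' (the format written by [write_sv_table()]). Breakpoint positions are the
#' `start_*` values; `one_based = TRUE` converts 1-based inputs. Records are
#' validated (class tokens, non-negative coordinates, translocation geometry)
#' and intrachromosomal breakpoints are reordered so `pos_a <= pos_b`.
#'
#' @param path File path.
#' @param origin Overrides the table's `origin` column when given
#'   (`"germline"` or `"somatic"`).
#' @param one_based Set TRUE when the file uses 1-based coordinates.
#' @return Data frame of SV records.
#' @export
read_sv_table <- function(path, origin = NULL, one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) {
    return(data.frame(sv_id = character(), patient_id = character(),
                      chrom_a = character(), pos_a = numeric(),
                      chrom_b = character(), pos_b = numeric(),
                      sv_class = character(), origin = character(),
                      stringsAsFactors = FALSE))
  }
  rec <- data.frame(sv_id = as.character(d$sv_id),
                    patient_id = as.character(d$patient_id),
                    chrom_a = as.character(d$chrom_a),
                    pos_a = as.numeric(d$start_a) - as.integer(one_based),
                    chrom_b = as.character(d$chrom_b),
                    pos_b = as.numeric(d$start_b) - as.integer(one_based),
                    sv_class = as.character(d$sv_class),
                    origin = if (is.null(origin)) as.character(d$origin)
                             else origin,
                    stringsAsFactors = FALSE)
  validate_sv_records(rec, context = path)
}

#' Write SV records as a BEDPE-like table
#'
#' Each breakpoint is written as a 1 bp half-open interval
#' (`start = pos`, `end = pos + 1`), 0-based.
#'
#' @param records SV record data frame.
#' @param path Output path.
#' @export
write_sv_table <- function(records, path) {
  out <- data.frame(chrom_a = records$chrom_a, start_a = records$pos_a,
                    end_a = records$pos_a + 1,
                    chrom_b = records$chrom_b, start_b = records$pos_b,
                    end_b = records$pos_b + 1,
                    sv_id = records$sv_id, sv_class = records$sv_class,
                    patient_id = records$patient_id, origin = records$origin,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# greedy one-to-one matching of two record sets for a single patient;
# returns data frame of (ia, ib) row indices
match_greedy <- function(a, b, slop_bp) {
  if (!nrow(a) || !nrow(b)) return(NULL)
  key_a <- paste(a$chrom_a, a$chrom_b)
  key_b <- paste(b$chrom_a, b$chrom_b)
  pairs <- NULL
  for (k in unique(key_a)) {
    ia <- which(key_a == k)
    ib <- which(key_b == k)
    if (!length(ib)) next
    da <- abs(outer(a$pos_a[ia], b$pos_a[ib], "-"))
    db <- abs(outer(a$pos_b[ia], b$pos_b[ib], "-"))
    ok <- da <= slop_bp & db <= slop_bp
    if (!any(ok)) next
    cand <- which(ok, arr.ind = TRUE)
    tot <- da[cand] + db[cand]
    ord <- order(tot, cand[, 1], cand[, 2])
    used_a <- logical(length(ia)); used_b <- logical(length(ib))
    for (r in ord) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs <- rbind(pairs, c(ia[i], ib[j]))
    }
  }
  pairs
}

#' Harmonize two SV call sets with positional slop
#'
#' Pairwise-joins call set `a` (the coordinate source) with call set `b`:
#' a record of `a` is kept iff some record of `b` shares its chromosome pair
#' and has both breakpoints within `slop_bp` (inclusive). Matching is
#' one-to-one, greedy by ascending total breakpoint distance with ties broken
#' by input order, so no source record supports more than one emission.
#' Records are matched within patients. Emitted coordinates are those of `a`.
#'
#' @param a,b SV record data frames for the same origin (and cohort).
#' @param slop_bp Inclusive breakpoint tolerance in bp (default 200).
#' @return List `records` (matched subset of `a`), `provenance` (data frame
#'   `id_a`, `id_b`), `n_unmatched_a`, `n_unmatched_b`.
#' @export
merge_callsets <- function(a, b, slop_bp = 200) {
  stopifnot(slop_bp >= 0)
  a <- validate_sv_records(a, "callset a")
  b <- validate_sv_records(b, "callset b")
  keep <- integer(0)
  prov <- list()
  for (p in unique(a$patient_id)) {
    ia <- which(a$patient_id == p)
    ib <- which(b$patient_id == p)
    m <- match_greedy(a[ia, ], b[ib, ], slop_bp)
    if (is.null(m)) next
    keep <- c(keep, ia[m[, 1]])
    prov[[p]] <- data.frame(id_a = a$sv_id[ia[m[, 1]]],
                            id_b = b$sv_id[ib[m[, 2]]],
                            stringsAsFactors = FALSE)
  }
  keep <- sort(keep)
  records <- a[keep, ]
  rownames(records) <- NULL
  prov <- if (length(prov)) do.call(rbind, c(prov, make.row.names = FALSE))
          else data.frame(id_a = character(), id_b = character())
  list(records = records,
       provenance = prov,
       n_unmatched_a = nrow(a) - nrow(records),
       n_unmatched_b = nrow(b) - nrow(records))
}

# for each record, does any record of another patient (or any catalog entry)
# match breakpoint A, breakpoint B, or both within slop? Breakpoints
# correspond A-to-A and B-to-B after canonical ordering. Candidates are
# located by binary search on position-sorted copies of each chromosome-pair
# group, so runtime is n log n plus the (small) candidate neighborhoods.
match_flags <- function(records, against, slop_bp, exclude_same_patient) {
  n <- nrow(records)
  both <- logical(n); either <- logical(n)
  if (!n || !nrow(against))
    return(data.frame(both_shared = both, either_shared = either))
  key_r <- paste(records$chrom_a, records$chrom_b)
  key_g <- paste(against$chrom_a, against$chrom_b)
  for (k in unique(key_r)) {
    ir <- which(key_r == k)
    ig <- which(key_g == k)
    if (!length(ig)) next
    oa <- ig[order(against$pos_a[ig])]
    sa_a <- against$pos_a[oa]; sa_b <- against$pos_b[oa]
    sa_p <- against$patient_id[oa]
    ob <- ig[order(against$pos_b[ig])]
    sb_b <- against$pos_b[ob]; sb_p <- against$patient_id[ob]
    for (i in ir) {
      pa <- records$pos_a[i]; pb <- records$pos_b[i]
      pat <- records$patient_id[i]
      lo <- findInterval(pa - slop_bp, sa_a, left.open = TRUE) + 1L
      hi <- findInterval(pa + slop_bp, sa_a)
      b_hit <- FALSE; a_hit <- FALSE
      if (lo <= hi) {
        sel <- lo:hi
        ok <- if (exclude_same_patient) sa_p[sel] != pat else rep(TRUE, length(sel))
        a_hit <- any(ok)
        b_hit <- any(ok & abs(sa_b[sel] - pb) <= slop_bp)
      }
      e_hit <- a_hit
      if (!e_hit) {
        lo2 <- findInterval(pb - slop_bp, sb_b, left.open = TRUE) + 1L
        hi2 <- findInterval(pb + slop_bp, sb_b)
        if (lo2 <= hi2) {
          sel2 <- lo2:hi2
          e_hit <- if (exclude_same_patient) any(sb_p[sel2] != pat) else TRUE
        }
      }
      both[i] <- b_hit
      either[i] <- e_hit
    }
  }
  data.frame(both_shared = both, either_shared = either)
}

#' Breakpoint recurrence across patients
#'
#' For every record, `both_shared` is TRUE iff some SV of a *different*
#' patient has the same chromosome pair with both corresponding breakpoints
#' within `slop_bp` (inclusive); `either_shared` requires at least one
#' breakpoint to be shared. Breakpoints correspond positionally (A to A, B to
#' B) after canonical `pos_a <= pos_b` ordering; a patient's own other SVs
#' never count.
#'
#' @param cohort SV record data frame across patients.
#' @param slop_bp Inclusive tolerance in bp (default 10).
#' @return `cohort` with logical columns `both_shared`, `either_shared`.
#' @export
compute_recurrence <- function(cohort, slop_bp = 10) {
  cohort <- validate_sv_records(cohort, "cohort")
  flags <- match_flags(cohort, cohort, slop_bp, exclude_same_patient = TRUE)
  cbind(cohort, flags)
}

#' Flag SVs present in a known-variant catalog
#'
#' Same matching rule as [compute_recurrence()] but against a catalog of
#' SV-like breakpoint pairs: both breakpoints must lie within `slop_bp` of a
#' single catalog entry's corresponding breakpoints.
#'
#' @param records SV record data frame.
#' @param catalog Data frame with at least `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b`.
#' @param slop_bp Inclusive tolerance in bp.
#' @return Logical vector `in_catalog`, one per record.
#' @export
annotate_known <- function(records, catalog, slop_bp = 10) {
  if (is.null(catalog) || nrow(catalog) == 0)
    stop("catalog must be non-empty")
  flags <- match_flags(records, catalog, slop_bp, exclude_same_patient = FALSE)
  flags$both_shared
}

#' Descriptive summary of an SV call set
#'
#' Class fractions over all records, the median breakpoint distance over
#' intrachromosomal records (absent when there are none), per-patient record
#' counts, and breakpoint recurrence fractions at `recurrence_slop_bp`.
#'
#' @param records SV record data frame.
#' @param recurrence_slop_bp Slop used for the recurrence fractions.
#' @return List `class_fractions`, `median_intra_size`,
#'   `recurrence_fraction_both`, `recurrence_fraction_either`,
#'   `per_patient_counts`.
#' @export
summarize_svs <- function(records, recurrence_slop_bp = 10) {
  records <- validate_sv_records(records, "records")
  n <- nrow(records)
  if (!n)
    return(list(class_fractions = setNames(numeric(0), character(0)),
                median_intra_size = NA_real_,
                recurrence_fraction_both = NA_real_,
                recurrence_fraction_either = NA_real_,
                per_patient_counts = integer(0)))
  cf <- table(records$sv_class) / n
  intra <- records$chrom_a == records$chrom_b
  med <- if (any(intra)) median(records$pos_b[intra] - records$pos_a[intra])
         else NA_real_
  rec <- compute_recurrence(records, slop_bp = recurrence_slop_bp)
  list(class_fractions = setNames(as.numeric(cf), names(cf)),
       median_intra_size = med,
       recurrence_fraction_both = mean(rec$both_shared),
       recurrence_fraction_either = mean(rec$either_shared),
       per_patient_counts = table(records$patient_id))
}
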