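# mismatch distance between comparator strings: positional (Hamming) when the
# lengths agree -- which they do by construction for pure-M alignments -- and
# Levenshtein otherwise (internal indels make the reference windows differ in
# length from the merged read).
mismatch_distance <- function(x, y) {
  if (nchar(x) == nchar(y)) hamming(x, y) else as.integer(utils::adist(x, y))
}

#' Build the merged read and its reference comparators
#'
#' Merging the MS read with the SM read at their common string yields a
#' longer read, `MERGE`, that should be a piece of the variant allele
#' spanning the junction. Three same-length reference strings are cut for
#' comparison: `REFa`, the reference starting at the MS read's POS (what the
#' merged read would look like if the region were plain reference on the 5'
#' side); `REFb`, the reference ending at the SM read's last matched base;
#' and `REFab`, the junction reconstruction
#' `RNAME[p1, a] . RNAME[b, p2 + ref_span2 - 1]` using the refined
#' breakpoints.
#'
#' @param call A draft `cnv_call`.
#' @param ref A [reference_store].
#' @return List of class `filter_strings` with fields `merge`, `ref_a`,
#'   `ref_b`, `ref_ab`, or `NULL` when a reference window falls outside the
#'   contig (the draft is then discarded).
#' @export
build_filter_strings <- function(call, ref) {
  m <- call$match
  cl <- m$common_len
  L2 <- m$read_sm$length
  merge <- paste0(m$read_ms$seq, substr(m$read_sm$seq, cl + 1L, L2))
  w <- nchar(merge)
  rname <- call$rname
  len <- contig_lengths(ref)[[rname]]
  sm_end <- call$p2 + call$ref_span2 - 1L
  if (call$p1 < 1L || call$p1 + w - 1L > len) return(NULL)
  if (sm_end - w + 1L < 1L || sm_end > len) return(NULL)
  if (call$a > len || call$b < 1L || call$p1 > call$a || call$b > sm_end) return(NULL)
  fs <- list(
    merge = merge,
    ref_a = ref_slice(ref, rname, call$p1, call$p1 + w - 1L),
    ref_b = ref_slice(ref, rname, sm_end - w + 1L, sm_end),
    ref_ab = paste0(
      ref_slice(ref, rname, call$p1, call$a),
      ref_slice(ref, rname, call$b, sm_end)
    )
  )
  class(fs) <- "filter_strings"
  fs
}

#' Accept or reject a draft call on its reference comparators
#'
#' A draft is rejected when the merged read is explainable by a single
#' reference location (`dist(MERGE, REFa) < t` or `dist(MERGE, REFb) < t`),
#' or when it does *not* match the junction reconstruction
#' (`dist(MERGE, REFab) > t`), with `t = threshold_frac * |MERGE|`. The
#' inequalities are strict, so a distance exactly at the threshold is
#' accepted.
#'
#' @param fs `filter_strings` from [build_filter_strings()].
#' @param threshold_frac Distance threshold as a fraction of the merged-read
#'   length (default 0.08).
#' @return List with `accept` (logical), `reason` (`NA` or one of
#'   `"merge_matches_ref_a"`, `"merge_matches_ref_b"`,
#'   `"merge_mismatches_ref_ab"`), `ed_merge_refab`, and `threshold`.
#' @export
apply_reference_filters <- function(fs, threshold_frac = 0.08) {
  stopifnot(inherits(fs, "filter_strings"))
  tau <- threshold_frac * nchar(fs$merge)
  ed_a <- mismatch_distance(fs$merge, fs$ref_a)
  ed_b <- mismatch_distance(fs$merge, fs$ref_b)
  ed_ab <- mismatch_distance(fs$merge, fs$ref_ab)
  reason <- NA_character_
  if (ed_a < tau) {
    reason <- "merge_matches_ref_a"
  } else if (ed_b < tau) {
    reason <- "merge_matches_ref_b"
  } else if (ed_ab > tau) {
    reason <- "merge_mismatches_ref_ab"
  }
  list(
    accept = is.na(reason),
    reason = reason,
    ed_merge_refab = ed_ab,
    threshold = tau
  )
}

#' 50-base identifier of a CNV call
#'
#' The 25 reference bases ending at the 5' breakpoint concatenated with the
#' 25 reference bases starting at the 3' breakpoint. Two calls of the same
#' CNV — including calls whose breakpoints differ by a shift inside a
#' repeat — share this identifier. Windows truncated by a contig edge are
#' `N`-padded to keep near-telomeric calls comparable.
#'
#' @param call A `cnv_call`.
#' @param ref A [reference_store].
#' @return Character scalar of length 50.
#' @export
make_identifier <- function(call, ref) {
  paste0(
    ref_slice(ref, call$rname, call$a - 24L, call$a, pad = TRUE),
    ref_slice(ref, call$rname, call$b, call$b + 24L, pad = TRUE)
  )
}

#' Collapse duplicate calls sharing an identifier
#'
#' Among calls with the same identifier the one with the smallest
#' `ed_merge_refab` is kept (ties broken by smaller `a`, then smaller `b`)
#' and the supporting read pairs of the whole group are merged onto it.
#' Idempotent.
#'
#' @param calls List of `cnv_call` with identifiers computed.
#' @return List of `cnv_call`.
#' @export
dedup_calls <- function(calls) {
  if (length(calls) <= 1L) return(calls)
  ids <- vapply(calls, function(x) x$identifier, character(1))
  out <- list()
  for (id in unique(ids)) {
    grp <- calls[ids == id]
    eds <- vapply(grp, function(x) as.integer(x$ed_merge_refab), integer(1))
    as <- vapply(grp, function(x) x$a, integer(1))
    bs <- vapply(grp, function(x) x$b, integer(1))
    best <- order(eds, as, bs)[1]
    keep <- grp[[best]]
    keep$support <- unique(unlist(lapply(grp, function(x) x$support)))
    out[[length(out) + 1L]] <- keep
  }
  out
}

#' Drop calls with insufficient supporting read pairs
#'
#' A real CNV junction at working coverage is spanned by several reads, so a
#' call backed by a single (MS, SM) pair is discarded: more than one distinct
#' supporting pair is required by default.
#'
#' @param calls List of `cnv_call`.
#' @param min_pairs Minimum number of distinct supporting read-name pairs
#'   (default 2).
#' @return Filtered list.
#' @export
enforce_min_support <- function(calls, min_pairs = 2L) {
  Filter(function(x) length(unique(x$support)) >= min_pairs, calls)
}

# per-base coverage Rle for one contig from an alignment table
coverage_rle <- function(alignments, rname, contig_len) {
  rows <- alignments$rname == rname
  if (!any(rows)) return(IRanges::coverage(IRanges::IRanges(), width = contig_len))
  pos <- alignments$pos[rows]
  spans <- vapply(
    alignments$cigar[rows],
    function(cg) {
      if (grepl("^[0-9]+M$", cg)) as.integer(sub("M$", "", cg)) else cigar_ref_span(parse_cigar(cg))
    },
    integer(1),
    USE.NAMES = FALSE
  )
  ir <- IRanges::IRanges(start = pos, width = spans)
  ir <- IRanges::restrict(ir, start = 1L, end = contig_len)
  IRanges::coverage(ir, width = contig_len)
}

depth_sum <- function(cov, lo, hi, contig_len) {
  lo <- max(lo, 1L)
  hi <- min(hi, contig_len)
  if (lo > hi) return(c(total = 0, width = 0))
  v <- as.numeric(IRanges::Views(cov, lo, hi)[[1]])
  c(total = sum(v), width = length(v))
}

#' Read-depth ratio of a CNV call
#'
#' Mean per-base depth inside the CNV region (`[a, b]` for a deletion,
#' `[b, a]` for a duplication) divided by the mean depth in the two flanking
#' windows just outside it. Expected below 1 for deletions and above 1 for
#' duplications; a hemizygous deletion at uniform coverage sits near 0.5.
#'
#' @param call A `cnv_call`, or a list with fields `rname`, `a`, `b`.
#' @param alignments Alignment table (columns `rname`, `pos`, `cigar`).
#' @param ref A [reference_store] (for contig lengths).
#' @param flank Flank width in bases (default 1000).
#' @return Ratio (dimensionless); `NA` when the flanks carry no coverage.
#' @export
read_depth_ratio <- function(call, alignments, ref, flank = 1000L) {
  contig_len <- contig_lengths(ref)[[call$rname]]
  cov <- coverage_rle(alignments, call$rname, contig_len)
  lo <- min(call$a, call$b)
  hi <- max(call$a, call$b)
  inner <- depth_sum(cov, lo, hi, contig_len)
  left <- depth_sum(cov, lo - flank, lo, contig_len)
  right <- depth_sum(cov, hi, hi + flank, contig_len)
  outer_width <- left[["width"]] + right[["width"]]
  if (inner[["width"]] == 0 || outer_width == 0) return(NA_real_)
  outer_mean <- (left[["total"]] + right[["total"]]) / outer_width
  if (outer_mean == 0) return(NA_real_)
  (inner[["total"]] / inner[["width"]]) / outer_mean
}
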