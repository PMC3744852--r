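# count positional mismatches between two equal-length strings
hamming <- function(x, y) {
  if (nchar(x) != nchar(y)) {
    stop("hamming: strings differ in length (", nchar(x), " vs ", nchar(y), ")")
  }
  sum(utf8ToInt(x) != utf8ToInt(y))
}

#' Find the polarized overlap between an MS and an SM read
#'
#' Tests whether the 3'-clipped (`MS`) read and the 5'-clipped (`SM`) read
#' share a common string in the MS-before-SM orientation. The common string
#' must contain both soft-clipped parts, so candidate overlap lengths run
#' from `max(min_overlap, s1 + s2)` to the shorter read length. For each
#' candidate length the suffix of the MS read is compared base by base with
#' the prefix of the SM read; a candidate qualifies when its mismatch count
#' is at most `floor(max_mismatch_frac * CL)`. Among qualifying candidates
#' the one with fewest mismatches wins, ties broken toward the longest
#' overlap.
#'
#' The stored common string takes the SM read's bases for the first `s2`
#' positions (its soft clip), and the MS read's bases for the remainder (the
#' repeat segment and the MS soft clip); disagreements are counted in
#' `mismatches`.
#'
#' @param read_ms,read_sm `aligned_read` objects of class `MS` / `SM`.
#' @param min_overlap Minimum common-string length (default 28).
#' @param max_mismatch_frac Mismatch tolerance as a fraction of the
#'   common-string length (default 0.08, applied with `floor`).
#' @return An `overlap_match` (fields `read_ms`, `read_sm`, `common_len`,
#'   `mismatches`, `common_string`) or `NULL` when no candidate qualifies.
#' @export
find_overlap <- function(read_ms, read_sm, min_overlap = 28L,
                         max_mismatch_frac = 0.08) {
  stopifnot(read_ms$clip_class == "MS", read_sm$clip_class == "SM")
  s1 <- read_ms$clip_len
  s2 <- read_sm$clip_len
  L1 <- read_ms$length
  L2 <- read_sm$length
  lo <- max(min_overlap, s1 + s2)
  hi <- min(L1, L2)
  if (lo > hi) return(NULL)
  mi <- utf8ToInt(read_ms$seq)
  si <- utf8ToInt(read_sm$seq)
  best_cl <- NA_integer_
  best_mm <- NA_integer_
  for (cl in lo:hi) {
    mm <- sum(mi[(L1 - cl + 1L):L1] != si[seq_len(cl)])
    if (mm > floor(max_mismatch_frac * cl)) next
    if (is.na(best_mm) || mm < best_mm || (mm == best_mm && cl > best_cl)) {
      best_mm <- mm
      best_cl <- cl
    }
  }
  if (is.na(best_cl)) return(NULL)
  ms_suffix <- substr(read_ms$seq, L1 - best_cl + 1L, L1)
  cs <- paste0(
    substr(read_sm$seq, 1L, s2),
    substr(ms_suffix, s2 + 1L, best_cl)
  )
  structure(
    list(
      read_ms = read_ms,
      read_sm = read_sm,
      common_len = best_cl,
      mismatches = best_mm,
      common_string = cs
    ),
    class = "overlap_match"
  )
}

#' Breakpoints and uncertainty of an accepted read pair
#'
#' The 5' breakpoint `a` is the last reference base covered by the MS read's
#' aligned part (`pos + ref_span - 1`, which reduces to `p1 + (L - s1) - 1`
#' for pure-M alignments); the 3' breakpoint `b` is the SM read's POS. The
#' uncertainty `dx = CL - s1 - s2` is the length of the repeat segment inside
#' the common string.
#'
#' @param match An `overlap_match` from [find_overlap()].
#' @return List with integer fields `a`, `b`, `dx`.
#' @export
compute_breakpoints <- function(match) {
  stopifnot(inherits(match, "overlap_match"))
  a <- match$read_ms$pos + match$read_ms$ref_span - 1L
  b <- match$read_sm$pos
  dx <- match$common_len - match$read_ms$clip_len - match$read_sm$clip_len
  if (dx < 0L) stop("internal error: negative breakpoint uncertainty")
  list(a = a, b = b, dx = dx)
}

#' Refine breakpoints against the reference inside a repeat
#'
#' When the junction lies in a short repeat the raw breakpoint pair can slide
#' by up to `dx` bases. For each shift `i` in `0..dx` the reference
#' reconstruction of the common string,
#' `CSREF(i) = RNAME[a0 - s2 + 1, a0 + i] . RNAME[b + i, b + CL - s2 - 1]`
#' with `a0 = a - dx` the junction-anchored 5' position, is compared base by
#' base with the observed common string. The set `{d}` of shifts attaining
#' the minimum mismatch count defines the refined call: breakpoints
#' `(a0 + min d, b + min d)` — the left-most equivalent pair — with residual
#' uncertainty `max d - min d`.
#'
#' The raw `a` from [compute_breakpoints()] anchors the *end of the MS match*,
#' which overshoots the left-most junction by exactly `dx` when the aligner
#' has extended the match through the repeat; anchoring the scan at `a - dx`
#' is what makes the reconstruction agree with the common string at `i = 0`
#' (for `dx = 0` the two anchors coincide).
#'
#' @param a,b,dx Raw breakpoints and uncertainty from [compute_breakpoints()].
#' @param match The supporting `overlap_match`.
#' @param ref A [reference_store].
#' @return List with `a`, `b`, `dx` (refined), `d_set` (the full argmin set)
#'   and `mismatches` (the minimum count) — or `NULL` when the reference
#'   window falls outside the contig.
#' @export
refine_breakpoints <- function(a, b, dx, match, ref) {
  s2 <- match$read_sm$clip_len
  cl <- match$common_len
  cs <- match$common_string
  rname <- match$read_ms$rname
  a0 <- a - dx
  len <- contig_lengths(ref)[[rname]]
  if (a0 - s2 + 1L < 1L || b + cl - s2 - 1L > len || a0 + dx > len || b < 1L) {
    return(NULL)
  }
  mm <- integer(dx + 1L)
  for (i in 0:dx) {
    left <- ref_slice(ref, rname, a0 - s2 + 1L, a0 + i)
    right <- ref_slice(ref, rname, b + i, b + cl - s2 - 1L)
    mm[i + 1L] <- hamming(cs, paste0(left, right))
  }
  d_set <- which(mm == min(mm)) - 1L
  list(
    a = a0 + min(d_set),
    b = b + min(d_set),
    dx = max(d_set) - min(d_set),
    d_set = d_set,
    mismatches = min(mm)
  )
}

new_cnv_call <- function(match, refined, raw_dx) {
  ms <- match$read_ms
  sm <- match$read_sm
  structure(
    list(
      rname = ms$rname,
      a = refined$a,
      b = refined$b,
      dx = refined$dx,
      cnv_type = if (refined$a < refined$b) "DEL" else "DUP",
      match = match,
      p1 = ms$pos,
      ref_span1 = ms$ref_span,
      p2 = sm$pos,
      ref_span2 = sm$ref_span,
      raw_dx = raw_dx,
      d_set = refined$d_set,
      support = paste(ms$name, sm$name, sep = "|"),
      ed_merge_refab = NA_integer_,
      identifier = NA_character_
    ),
    class = "cnv_call"
  )
}

#' Pair MS and SM reads into draft CNV calls
#'
#' Every (MS, SM) pair on the same contig whose positions lie within
#' `search_window` of each other (in either order — for a tandem duplication
#' the SM read maps left of the MS read) is tested with [find_overlap()];
#' qualifying pairs flow through [compute_breakpoints()] and
#' [refine_breakpoints()] into one draft call each.
#'
#' @param ms_batch,sm_batch Lists of `aligned_read` objects of the respective
#'   class, all on one contig.
#' @param ref A [reference_store].
#' @param config A [caller_config()].
#' @return List with `drafts` (list of `cnv_call`) and `counters`
#'   (`pairs_tested`, `overlaps_found`, `refine_oob`).
#' @export
pair_reads <- function(ms_batch, sm_batch, ref, config = caller_config()) {
  drafts <- list()
  pairs_tested <- 0L
  overlaps_found <- 0L
  refine_oob <- 0L
  if (length(ms_batch) == 0L || length(sm_batch) == 0L) {
    return(list(
      drafts = drafts,
      counters = c(pairs_tested = 0L, overlaps_found = 0L, refine_oob = 0L)
    ))
  }
  sm_pos <- vapply(sm_batch, function(r) r$pos, integer(1))
  ord <- order(sm_pos)
  sm_batch <- sm_batch[ord]
  sm_pos <- sm_pos[ord]
  for (ms in ms_batch) {
    lo <- ms$pos - config$search_window
    hi <- ms$pos + config$search_window
    for (j in which(sm_pos >= lo & sm_pos <= hi)) {
      sm <- sm_batch[[j]]
      pairs_tested <- pairs_tested + 1L
      m <- find_overlap(ms, sm, config$min_overlap, config$max_mismatch_frac)
      if (is.null(m)) next
      overlaps_found <- overlaps_found + 1L
      bp <- compute_breakpoints(m)
      refined <- refine_breakpoints(bp$a, bp$b, bp$dx, m, ref)
      if (is.null(refined)) {
        refine_oob <- refine_oob + 1L
        next
      }
      drafts[[length(drafts) + 1L]] <- new_cnv_call(m, refined, bp$dx)
    }
  }
  list(
    drafts = drafts,
    counters = c(
      pairs_tested = pairs_tested,
      overlaps_found = overlaps_found,
      refine_oob = refine_oob
    )
  )
}

#' @export
print.cnv_call <- function(x, ...) {
  cat(
    "cnv_call ", x$cnv_type, " ", x$rname, ":", x$a, "-", x$b,
    " dx=", x$dx, " support=", length(unique(x$support)), "\n",
    sep = ""
  )
  invisible(x)
}
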