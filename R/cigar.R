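#' Parse a CIGAR string
#'
#' Splits a SAM CIGAR string into its (length, operator) pairs. Valid
#' operators are `M I D N S H P = X`; every length must be a positive
#' integer. The parse is exact: the concatenation of the parsed operations
#' reproduces the input string.
#'
#' @param cigar_string A single non-empty CIGAR string, e.g. `"70M30S"`.
#' @return A data frame with integer column `len` and character column `op`,
#'   one row per operation, in order.
#' @export
#' @examples
#' parse_cigar("70M30S")
parse_cigar <- function(cigar_string) {
  if (!is.character(cigar_string) || length(cigar_string) != 1L ||
      is.na(cigar_string) || !nzchar(cigar_string)) {
    stop("CIGAR must be a single non-empty string")
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar_string)[[1]]
  tokens <- regmatches(cigar_string, list(m))[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar_string)) {
    # locate the first offending character for the error message
    consumed <- if (m[1] == -1L) 0L else {
      ends <- m + attr(m, "match.length") - 1L
      gap <- which(c(m, nchar(cigar_string) + 1L) != c(1L, ends + 1L))[1]
      if (is.na(gap)) nchar(cigar_string) else c(1L, ends + 1L)[gap] - 1L
    }
    stop(
      "malformed CIGAR '", cigar_string, "': cannot parse at position ",
      consumed + 1L, " ('", substr(cigar_string, consumed + 1L, consumed + 1L), "')"
    )
  }
  len <- as.integer(sub("[MIDNSHP=X]$", "", tokens))
  op <- substr(tokens, nchar(tokens), nchar(tokens))
  if (any(len < 1L)) stop("malformed CIGAR '", cigar_string, "': zero-length operation")
  data.frame(len = len, op = op, stringsAsFactors = FALSE)
}

#' Render parsed CIGAR operations back to a string
#'
#' Inverse of [parse_cigar()].
#'
#' @param ops Data frame with columns `len` and `op`.
#' @return CIGAR string.
#' @export
cigar_string <- function(ops) {
  paste0(ops$len, ops$op, collapse = "")
}

# query bases consumed by the CIGAR (SEQ length)
cigar_query_len <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
}

# reference bases consumed by the CIGAR
cigar_ref_span <- function(ops) {
  sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
}

reject_read <- function(reason, name = NA_character_) {
  structure(list(reason = reason, name = name), class = "read_rejection")
}

#' Test for a rejected read
#'
#' @param x Result of [classify_read()].
#' @return `TRUE` if `x` is a rejection marker.
#' @export
is_rejected <- function(x) inherits(x, "read_rejection")

#' Classify an alignment record by soft-clip orientation
#'
#' A mapped read whose dominant soft clip sits at the 3' end is of class
#' `MS` (matched part first) and anchors the 5' breakpoint of a CNV; a read
#' whose dominant clip sits at the 5' end is of class `SM` and anchors the
#' 3' breakpoint. Reads are rejected when they carry no usable clip, when
#' the clip is shorter than `min_clip`, when the clip is *longer* than the
#' matched part (a sporadic paired-end aligner artifact that cannot be
#' checked for accuracy), when both end clips are equal (orientation is
#' ambiguous), or when the dominant clipped sequence is absent (hard clip,
#' missing SEQ).
#'
#' When a read is clipped at both ends the larger clip decides the
#' orientation and the smaller ("minor") clip is trimmed from the stored
#' sequence, so that downstream string arithmetic sees a read that is exactly
#' matched part plus one clip.
#'
#' @param record A list or one-row data frame with fields `qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar`, `seq`.
#' @param min_clip Minimum dominant soft-clip length to keep a read
#'   (default 11, i.e. clips of more than 10 bases).
#' @param min_mapq Minimum mapping quality; 0 disables the filter.
#' @return An object of class `aligned_read` with fields `name`, `rname`,
#'   `pos`, `cigar`, `seq`, `length`, `clip_class` (`"MS"` or `"SM"`),
#'   `clip_len`, `match_len`, `ref_span` — or a `read_rejection` carrying the
#'   reason. Use [is_rejected()] to discriminate.
#' @export
#' @examples
#' rec <- list(qname = "r1", flag = 0L, rname = "chr1", pos = 101L,
#'             mapq = 60L, cigar = "70M30S", seq = strrep("A", 100))
#' classify_read(rec)
classify_read <- function(record, min_clip = 11L, min_mapq = 0L) {
  name <- as.character(record$qname)
  flag <- as.integer(record$flag)
  if (bitwAnd(flag, 0x4L) != 0L) return(reject_read("unmapped", name))
  if (bitwAnd(flag, 0x100L) != 0L) return(reject_read("secondary", name))
  if (bitwAnd(flag, 0x800L) != 0L) return(reject_read("supplementary", name))
  if (bitwAnd(flag, 0x400L) != 0L) return(reject_read("duplicate", name))
  if (is.na(record$rname) || is.na(record$pos)) return(reject_read("unplaced", name))
  if (min_mapq > 0L && !is.na(record$mapq) && record$mapq < min_mapq) {
    return(reject_read("low_mapq", name))
  }
  seq <- as.character(record$seq)
  if (is.na(seq) || seq == "*" || !nzchar(seq)) return(reject_read("missing_seq", name))

  ops <- parse_cigar(as.character(record$cigar))
  if (cigar_query_len(ops) != nchar(seq)) {
    return(reject_read("seq_cigar_mismatch", name))
  }

  n <- nrow(ops)
  # end clips: S and H may only appear at the ends (H outermost)
  lead_h <- if (ops$op[1] == "H") ops$len[1] else 0L
  tail_h <- if (ops$op[n] == "H") ops$len[n] else 0L
  core <- ops[ops$op != "H", , drop = FALSE]
  nc <- nrow(core)
  if (nc == 0L) return(reject_read("hard_clip_only", name))
  lead_s <- if (core$op[1] == "S") core$len[1] else 0L
  tail_s <- if (core$op[nc] == "S" && nc > 1L) core$len[nc] else 0L

  lead_clip <- lead_h + lead_s
  tail_clip <- tail_h + tail_s
  if (lead_clip == 0L && tail_clip == 0L) return(reject_read("no_clip", name))
  if (lead_clip == tail_clip) return(reject_read("ambiguous_clips", name))
  dominant_at_3p <- tail_clip > lead_clip
  dom_h <- if (dominant_at_3p) tail_h else lead_h
  dom_s <- if (dominant_at_3p) tail_s else lead_s
  if (dom_h > 0L) return(reject_read("hard_clip", name))
  if (dom_s < min_clip) return(reject_read("clip_below_min", name))

  aligned <- core[core$op != "S", , drop = FALSE]
  match_len <- sum(aligned$len[aligned$op %in% c("M", "I", "=", "X")])
  if (match_len == 0L) return(reject_read("no_match", name))
  if (dom_s > match_len) return(reject_read("clip_exceeds_match", name))
  ref_span <- cigar_ref_span(ops)

  # trim the minor clip so seq == matched part + dominant clip
  minor_s <- if (dominant_at_3p) lead_s else tail_s
  if (minor_s > 0L) {
    seq <- if (dominant_at_3p) {
      substr(seq, minor_s + 1L, nchar(seq))
    } else {
      substr(seq, 1L, nchar(seq) - minor_s)
    }
  }

  structure(
    list(
      name = name,
      rname = as.character(record$rname),
      pos = as.integer(record$pos),
      cigar = ops,
      seq = seq,
      length = nchar(seq),
      clip_class = if (dominant_at_3p) "MS" else "SM",
      clip_len = dom_s,
      match_len = match_len,
      ref_span = ref_span
    ),
    class = "aligned_read"
  )
}

#' Collect clip-classified reads from an alignment table
#'
#' Vectorised front end to [classify_read()]: records whose CIGAR contains no
#' `S` operation are counted as unclipped in bulk, the rest are classified
#' one by one.
#'
#' @param alignments Data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq` (as returned by [read_alignments()] or the
#'   simulator).
#' @param min_clip,min_mapq See [classify_read()].
#' @return List with `reads` (list of `aligned_read`, original order) and
#'   `reject_counts` (named integer vector of rejection reasons).
#' @export
collect_clipped_reads <- function(alignments, min_clip = 11L, min_mapq = 0L) {
  has_s <- grepl("S", alignments$cigar, fixed = TRUE)
  reasons <- character(0)
  reads <- list()
  idx <- which(has_s)
  for (i in idx) {
    r <- classify_read(
      list(
        qname = alignments$qname[i], flag = alignments$flag[i],
        rname = alignments$rname[i], pos = alignments$pos[i],
        mapq = alignments$mapq[i], cigar = alignments$cigar[i],
        seq = alignments$seq[i]
      ),
      min_clip = min_clip, min_mapq = min_mapq
    )
    if (is_rejected(r)) reasons <- c(reasons, r$reason) else reads[[length(reads) + 1L]] <- r
  }
  tab <- table(reasons)
  counts <- stats::setNames(as.integer(tab), as.character(names(tab)))
  if (is.null(names(counts))) names(counts) <- character(0)
  n_noclip <- sum(!has_s)
  if (n_noclip > 0L) {
    prev <- if ("no_clip" %in% names(counts)) counts[["no_clip"]] else 0L
    counts["no_clip"] <- n_noclip + prev
  }
  list(reads = reads, reject_counts = counts[order(names(counts))])
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(
    "aligned_read ", x$name, " ", x$rname, ":", x$pos, " ",
    cigar_string(x$cigar), " class=", x$clip_class,
    " clip=", x$clip_len, " match=", x$match_len,
    " ref_span=", x$ref_span, "\n",
    sep = ""
  )
  invisible(x)
}
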