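#' Caller configuration
#'
#' Central knobs of the breakpoint caller, with the defaults used throughout:
#' soft clips shorter than 11 bases are ignored (`min_clip`), a read pair
#' must share a common string of at least 28 bases (`min_overlap`) with at
#' most 8% mismatches (`max_mismatch_frac`), candidate mates are searched
#' within 2,000,000 bases (`search_window`; reduce to ~20,000 for exome
#' data), a call needs more than one supporting read pair (`min_support`),
#' and the read-depth ratio uses 1,000-base flanks (`flank`).
#'
#' @param min_clip Minimum dominant soft-clip length (bases).
#' @param min_overlap Minimum common-string length (bases).
#' @param max_mismatch_frac Mismatch tolerance for overlap and reference
#'   filters, as a fraction in (0, 1).
#' @param search_window Maximum POS distance between paired reads (bases).
#' @param min_support Minimum distinct supporting read pairs per call.
#' @param flank Flank width for the read-depth ratio (bases).
#' @param min_mapq Minimum mapping quality (0 disables).
#' @return List of class `caller_config`.
#' @export
caller_config <- function(min_clip = 11L, min_overlap = 28L,
                          max_mismatch_frac = 0.08,
                          search_window = 2000000L, min_support = 2L,
                          flank = 1000L, min_mapq = 0L) {
  stopifnot(
    min_clip >= 1L, min_overlap >= 1L, search_window >= 1L,
    min_support >= 1L, flank >= 1L, min_mapq >= 0L,
    max_mismatch_frac > 0, max_mismatch_frac < 1
  )
  structure(
    list(
      min_clip = as.integer(min_clip),
      min_overlap = as.integer(min_overlap),
      max_mismatch_frac = max_mismatch_frac,
      search_window = as.integer(search_window),
      min_support = as.integer(min_support),
      flank = as.integer(flank),
      min_mapq = as.integer(min_mapq)
    ),
    class = "caller_config"
  )
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted to BAM via samtools (Rsamtools) first, which also
#' validates the records.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return Data frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(
      path, tempfile(fileext = ""),
      overwrite = TRUE, indexDestination = FALSE
    )
  }
  res <- Rsamtools::scanBam(
    path,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
    )
  )[[1]]
  data.frame(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    stringsAsFactors = FALSE
  )
}

#' Call CNV breakpoints from an in-memory alignment table
#'
#' The core engine behind [run_caller()]: classifies reads by clip
#' orientation, pairs MS with SM reads per contig, computes and refines
#' breakpoints, applies the reference filters, collapses duplicate calls and
#' enforces minimum support. Results are deterministic and independent of
#' input record order.
#'
#' @param alignments Data frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`.
#' @param ref A [reference_store].
#' @param config A [caller_config()].
#' @return Object of class `cnv_callset`: list with `calls` (data frame, one
#'   row per final call, sorted by contig and `a`), `call_objects` (the
#'   underlying `cnv_call` list), `report` (per-stage counters) and `config`.
#' @export
call_cnvs <- function(alignments, ref, config = caller_config()) {
  stopifnot(inherits(ref, "reference_store"))
  needed <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")
  if (!all(needed %in% names(alignments))) {
    stop("alignments must have columns: ", paste(needed, collapse = ", "))
  }
  used <- unique(alignments$rname[!is.na(alignments$rname)])
  missing_contigs <- setdiff(used, names(ref$seq))
  if (length(missing_contigs)) {
    stop(
      "alignment contigs absent from the reference: ",
      paste(missing_contigs, collapse = ", ")
    )
  }
  alignments <- alignments[order(alignments$rname, alignments$pos), , drop = FALSE]

  collected <- collect_clipped_reads(alignments, config$min_clip, config$min_mapq)
  reads <- collected$reads
  classes <- vapply(reads, function(r) r$clip_class, character(1))
  rnames <- vapply(reads, function(r) r$rname, character(1))

  drafts <- list()
  counters <- c(pairs_tested = 0L, overlaps_found = 0L, refine_oob = 0L)
  for (chrom in unique(rnames)) {
    ms <- reads[classes == "MS" & rnames == chrom]
    sm <- reads[classes == "SM" & rnames == chrom]
    res <- pair_reads(ms, sm, ref, config)
    drafts <- c(drafts, res$drafts)
    counters <- counters + res$counters
  }

  accepted <- list()
  reject_reasons <- character(0)
  filter_oob <- 0L
  for (call in drafts) {
    fs <- build_filter_strings(call, ref)
    if (is.null(fs)) {
      filter_oob <- filter_oob + 1L
      next
    }
    verdict <- apply_reference_filters(fs, config$max_mismatch_frac)
    if (!verdict$accept) {
      reject_reasons <- c(reject_reasons, verdict$reason)
      next
    }
    call$ed_merge_refab <- verdict$ed_merge_refab
    call$identifier <- make_identifier(call, ref)
    accepted[[length(accepted) + 1L]] <- call
  }

  deduped <- dedup_calls(accepted)
  final <- enforce_min_support(deduped, config$min_support)

  # stable output order
  if (length(final)) {
    ord <- order(
      vapply(final, function(x) x$rname, character(1)),
      vapply(final, function(x) x$a, integer(1)),
      vapply(final, function(x) x$b, integer(1))
    )
    final <- final[ord]
  }

  rej_tab <- table(reject_reasons)
  report <- list(
    records = nrow(alignments),
    collected_ms = sum(classes == "MS"),
    collected_sm = sum(classes == "SM"),
    read_rejections = collected$reject_counts,
    pairs_tested = unname(counters[["pairs_tested"]]),
    drafts = length(drafts),
    refine_oob = unname(counters[["refine_oob"]]),
    filter_window_oob = filter_oob,
    filter_rejected = stats::setNames(as.integer(rej_tab), names(rej_tab)),
    accepted = length(accepted),
    deduped_away = length(accepted) - length(deduped),
    below_min_support = length(deduped) - length(final),
    final = length(final)
  )

  structure(
    list(
      calls = calls_to_df(final),
      call_objects = final,
      report = report,
      config = config
    ),
    class = "cnv_callset"
  )
}

calls_to_df <- function(calls) {
  if (!length(calls)) {
    return(data.frame(
      chrom = character(0), type = character(0), a = integer(0),
      b = integer(0), dx = integer(0), length = integer(0),
      n_support = integer(0), ed_merge_refab = integer(0),
      identifier = character(0), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    chrom = vapply(calls, function(x) x$rname, character(1)),
    type = vapply(calls, function(x) x$cnv_type, character(1)),
    a = vapply(calls, function(x) x$a, integer(1)),
    b = vapply(calls, function(x) x$b, integer(1)),
    dx = vapply(calls, function(x) x$dx, integer(1)),
    length = vapply(
      calls,
      function(x) if (x$cnv_type == "DEL") x$b - x$a - 1L else x$a - x$b + 1L,
      integer(1)
    ),
    n_support = vapply(calls, function(x) length(unique(x$support)), integer(1)),
    ed_merge_refab = vapply(calls, function(x) as.integer(x$ed_merge_refab), integer(1)),
    identifier = vapply(calls, function(x) x$identifier, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Run the caller on alignment and reference files
#'
#' @param alignments Path to a coordinate-sorted SAM/BAM file, or an
#'   alignment table (data frame).
#' @param reference Path to a FASTA file, or a [reference_store].
#' @param config A [caller_config()].
#' @return A `cnv_callset` (see [call_cnvs()]).
#' @export
run_caller <- function(alignments, reference, config = caller_config()) {
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  if (is.character(reference)) reference <- read_reference(reference)
  call_cnvs(alignments, reference, config)
}

#' @export
print.cnv_callset <- function(x, ...) {
  r <- x$report
  cat("cnv_callset:", r$final, "call(s)\n")
  cat(
    "  records:", r$records,
    " MS:", r$collected_ms, " SM:", r$collected_sm,
    " pairs tested:", r$pairs_tested,
    " drafts:", r$drafts, "\n"
  )
  cat(
    "  filter-rejected:", sum(r$filter_rejected),
    " dedup-merged:", r$deduped_away,
    " below min support:", r$below_min_support, "\n"
  )
  if (nrow(x$calls)) print(x$calls[, c("chrom", "type", "a", "b", "dx", "length", "n_support")])
  invisible(x)
}

#' Write calls as TSV
#'
#' Columns `chrom`, `type`, `a`, `b`, `dx`, `length`, `n_support`,
#' `ed_merge_refab`, `identifier`; coordinates are 1-based inclusive and
#' `length` is `b - a - 1` for deletions and `a - b + 1` for duplications.
#'
#' @param calls A `cnv_callset` or a calls data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  df <- if (inherits(calls, "cnv_callset")) calls$calls else calls
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive breakpoints (a, b)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calls as VCF 4.2 symbolic structural variants
#'
#' Deletions are anchored at `POS = a` (`REF` = base at `a`, `ALT = <DEL>`,
#' `END = b - 1`, `SVLEN = -(b - a - 1)`); tandem duplications at
#' `POS = b - 1` (`ALT = <DUP:TANDEM>`, `END = a`, `SVLEN = a - b + 1`).
#' `HOMLEN` carries the breakpoint uncertainty `dx`, `SUPPORT` the number of
#' supporting read pairs. Calls whose anchor base falls outside the contig
#' are skipped with a warning.
#'
#' @param calls A `cnv_callset` or calls data frame.
#' @param ref A [reference_store].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, ref, path) {
  df <- if (inherits(calls, "cnv_callset")) calls$calls else calls
  lens <- contig_lengths(ref)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=clipcnv",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP:TANDEM,Description=\"Tandem duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed SV length\">",
    "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Breakpoint microhomology length\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  rows <- character(0)
  for (i in seq_len(nrow(df))) {
    del <- df$type[i] == "DEL"
    pos <- if (del) df$a[i] else df$b[i] - 1L
    if (pos < 1L || pos > lens[[df$chrom[i]]]) {
      warning("skipping call with out-of-bounds VCF anchor at row ", i)
      next
    }
    info <- sprintf(
      "SVTYPE=%s;END=%d;SVLEN=%d;HOMLEN=%d;SUPPORT=%d",
      if (del) "DEL" else "DUP",
      if (del) df$b[i] - 1L else df$a[i],
      if (del) -(df$b[i] - df$a[i] - 1L) else df$a[i] - df$b[i] + 1L,
      df$dx[i], df$n_support[i]
    )
    rows <- c(rows, sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
      df$chrom[i], pos, sprintf("cnv%04d", i),
      ref_slice(ref, df$chrom[i], pos, pos),
      if (del) "<DEL>" else "<DUP:TANDEM>", info
    ))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
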