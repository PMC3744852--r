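#' Generate a random reference contig
#'
#' @param length Contig length in bases (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   sequence.
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param rname Contig name (default `"chr1"`).
#' @return A [reference_store] with one contig.
#' @export
generate_reference <- function(length, seed = NULL, gc = 0.5, rname = "chr1") {
  stopifnot(length >= 1L, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  reference_store(stats::setNames(paste(bases, collapse = ""), rname))
}

# overwrite single bases of a contig in place
set_base <- function(ref, rname, pos, base) {
  substr(ref$seq[[rname]], pos, pos) <- base
  ref
}

other_base <- function(not) {
  setdiff(c("A", "C", "G", "T"), not)[1]
}

#' Engineer a CNV site into a reference
#'
#' Rewrites the reference locally so that the requested breakpoint pair is
#' exactly the left-most representative of its equivalence class: the
#' homology block `RNAME[a+1, a+h] == RNAME[b, b+h-1]` is copied into place,
#' and the junction boundaries are pinned (`RNAME[a] != RNAME[b-1]` and
#' `RNAME[a+h+1] != RNAME[b+h]`) so no accidental shorter or longer homology
#' survives. With `homology_len = 0` only the boundary pinning applies.
#'
#' @param ref A [reference_store].
#' @param cnv List with fields `rname`, `a`, `b`, `type` (`"DEL"`/`"DUP"`)
#'   and `homology_len`.
#' @return The modified [reference_store].
#' @export
prepare_cnv_site <- function(ref, cnv) {
  rname <- cnv$rname
  a <- cnv$a
  b <- cnv$b
  h <- if (is.null(cnv$homology_len)) 0L else as.integer(cnv$homology_len)
  stopifnot(h >= 0L)
  size <- abs(b - a)
  if (size <= h + 1L) stop("CNV too short to engineer a homology of ", h, " bases")
  if (h > 0L) {
    block <- ref_slice(ref, rname, b, b + h - 1L)
    for (k in seq_len(h)) {
      ref <- set_base(ref, rname, a + k, substr(block, k, k))
    }
  }
  # pin the boundaries of the equivalence class
  if (ref_slice(ref, rname, a, a) == ref_slice(ref, rname, b - 1L, b - 1L)) {
    ref <- set_base(ref, rname, a, other_base(ref_slice(ref, rname, b - 1L, b - 1L)))
  }
  if (ref_slice(ref, rname, a + h + 1L, a + h + 1L) ==
      ref_slice(ref, rname, b + h, b + h)) {
    ref <- set_base(
      ref, rname, a + h + 1L,
      other_base(ref_slice(ref, rname, b + h, b + h))
    )
  }
  ref
}

#' Construct the variant allele sequence of a CNV
#'
#' Both CNV types share one junction formula: the variant allele is the
#' reference up to `a` concatenated with the reference from `b` onward. For a
#' deletion (`a < b`) that removes bases `a+1 .. b-1`; for a tandem
#' duplication (`a >= b`) it repeats bases `b .. a`.
#'
#' @param ref A [reference_store].
#' @param cnv List with fields `rname`, `a`, `b`.
#' @return The variant contig as a character scalar.
#' @export
implant_cnv <- function(ref, cnv) {
  len <- contig_lengths(ref)[[cnv$rname]]
  stopifnot(cnv$a >= 1L, cnv$a <= len, cnv$b >= 1L, cnv$b <= len)
  paste0(
    ref_slice(ref, cnv$rname, 1L, cnv$a),
    ref_slice(ref, cnv$rname, cnv$b, len)
  )
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hit) ch[i] <- other_base(ch[i])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

make_sam_records <- function(qname, rname, pos, cigar, seq, flag = 0L, mapq = 60L) {
  data.frame(
    qname = qname,
    flag = as.integer(flag),
    rname = rname,
    pos = as.integer(pos),
    mapq = as.integer(mapq),
    cigar = cigar,
    seq = seq,
    stringsAsFactors = FALSE
  )
}

#' Simulate junction-spanning reads over a CNV
#'
#' Emits aligner-faithful single-end records for reads sampled across the
#' variant junction. Each read's sequence is the variant-allele substring
#' `RNAME[ar-x+1, ar] . RNAME[br, br+L-x-1]`, where `x` is the breakpoint
#' offset within the read and `(ar, br) = (a+h, b+h)` is the right-most
#' equivalent breakpoint pair — the representation in which a
#' maximal-extension local aligner places these reads. Reads with `x > L/2`
#' are emitted 3'-clipped (`POS = ar-x+1`, CIGAR `xM(L-x)S`); reads with
#' `x < L/2` are emitted 5'-clipped (`POS = b`, CIGAR `(x-h)S(L-x+h)M`: the
#' aligner extends the match leftward through the homology block, so the clip
#' shrinks by `h` and POS lands on the left-most 3' breakpoint). Offsets
#' `x <= h` leave the read entirely inside the right segment and are emitted
#' as plain fully-matched records; `x == L/2` is redrawn.
#'
#' @param ref A [reference_store] already processed by [prepare_cnv_site()].
#' @param cnv List with `rname`, `a`, `b` (left-most pair), `homology_len`.
#' @param n Number of junction reads.
#' @param read_length Read length `L` (default 100).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Optional seed.
#' @param x Optional integer vector of breakpoint offsets (recycled to `n`);
#'   when `NULL`, offsets are uniform on `1..L-1` excluding `L/2`.
#' @param misassign_frac Fraction of reads emitted with the sporadic
#'   swapped-orientation alignment some paired-end aligners produce (soft
#'   clip longer than the match); used to exercise the corresponding read
#'   filter. Default 0.
#' @return Data frame of SAM-like records (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`).
#' @export
simulate_junction_reads <- function(ref, cnv, n, read_length = 100L,
                                    error_rate = 0, seed = NULL, x = NULL,
                                    misassign_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(read_length)
  h <- if (is.null(cnv$homology_len)) 0L else as.integer(cnv$homology_len)
  ar <- cnv$a + h
  br <- cnv$b + h
  len <- contig_lengths(ref)[[cnv$rname]]
  if (ar < L || br + L - 1L > len) {
    stop("CNV too close to a contig edge for reads of length ", L)
  }
  if (is.null(x)) {
    x <- sample(setdiff(1:(L - 1L), L %/% 2L), n, replace = TRUE)
  } else {
    x <- as.integer(rep_len(x, n))
    if (any(x < 1L | x > L - 1L | x == L / 2)) {
      stop("breakpoint offsets must lie in 1..L-1 and avoid L/2")
    }
  }
  misassigned <- stats::runif(n) < misassign_frac
  pos <- integer(n)
  cig <- character(n)
  seqs <- character(n)
  for (k in seq_len(n)) {
    xk <- x[k]
    seqs[k] <- paste0(
      ref_slice(ref, cnv$rname, ar - xk + 1L, ar),
      ref_slice(ref, cnv$rname, br, br + L - xk - 1L)
    )
    if (misassigned[k]) {
      if (xk > L / 2) { # long 5' clip, short match: Eq-3 style
        pos[k] <- br
        cig[k] <- paste0(xk, "S", L - xk, "M")
      } else {
        pos[k] <- ar - xk + 1L
        cig[k] <- paste0(xk, "M", L - xk, "S")
      }
    } else if (xk > L / 2) {
      pos[k] <- ar - xk + 1L
      cig[k] <- paste0(xk, "M", L - xk, "S")
    } else if (xk > h) {
      pos[k] <- cnv$b
      cig[k] <- paste0(xk - h, "S", L - xk + h, "M")
    } else { # read lies entirely in the right segment
      pos[k] <- br - xk
      cig[k] <- paste0(L, "M")
    }
  }
  seqs <- inject_errors(seqs, error_rate)
  make_sam_records(
    qname = sprintf("%s_%d_%d_j%04d", cnv$rname, cnv$a, cnv$b, seq_len(n)),
    rname = cnv$rname, pos = pos, cigar = cig, seq = seqs
  )
}

#' Simulate fully-matched background reads
#'
#' Uniformly placed reads copied from the reference with CIGAR `LM`. The
#' number of reads is Poisson with mean `depth * contig_length / L`, so the
#' expected per-base depth equals `depth`.
#'
#' @param ref A [reference_store].
#' @param depth Target mean coverage (> 0).
#' @param read_length Read length (default 100).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Optional seed.
#' @param rname Contig to draw from (default: first contig).
#' @param exclude Optional `c(start, end)` interval; reads overlapping it are
#'   not emitted (models the missing coverage of a homozygously deleted
#'   segment).
#' @return Data frame of SAM-like records.
#' @export
simulate_background_reads <- function(ref, depth, read_length = 100L,
                                      error_rate = 0, seed = NULL,
                                      rname = NULL, exclude = NULL) {
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rname)) rname <- names(ref$seq)[1]
  L <- as.integer(read_length)
  len <- contig_lengths(ref)[[rname]]
  stopifnot(len >= L)
  n <- stats::rpois(1L, depth * len / L)
  starts <- seq_len(len - L + 1L)
  if (!is.null(exclude)) {
    # drop starts whose read [s, s+L-1] overlaps [exclude[1], exclude[2]]
    starts <- starts[starts + L - 1L < exclude[1] | starts > exclude[2]]
    if (!length(starts)) stop("exclusion interval leaves no room for reads")
  }
  pos <- sample(starts, n, replace = TRUE)
  seqs <- vapply(
    pos, function(p) ref_slice(ref, rname, p, p + L - 1L),
    character(1)
  )
  seqs <- inject_errors(seqs, error_rate)
  make_sam_records(
    qname = sprintf("%s_bg%06d", rname, seq_len(n)),
    rname = rname, pos = pos, cigar = paste0(L, "M"), seq = seqs
  )
}

#' Simulate a complete dataset: reference, CNVs, reads, truth table
#'
#' Generates a random reference, engineers each requested CNV site
#' ([prepare_cnv_site()]), emits `n_junction` junction reads per CNV and
#' optional fully-matched background coverage, and returns everything needed
#' for a round-trip test of the caller.
#'
#' @param ref_length Reference length in bases.
#' @param cnvs Data frame with columns `a`, `b`, `type` (`"DEL"`/`"DUP"`) and
#'   optionally `homology_len` (default 0). Breakpoints are 1-based inclusive,
#'   left-most representatives; CNV windows must not overlap.
#' @param n_junction Junction reads per CNV (default 6).
#' @param background_depth Mean background coverage (default 0 = none).
#' @param read_length,error_rate,gc,seed,misassign_frac Passed through to the
#'   generators.
#' @param x Optional list of offset vectors, one per CNV (see
#'   [simulate_junction_reads()]).
#' @param rname Contig name.
#' @return List with `ref` (engineered [reference_store]), `truth` (data
#'   frame `rname`, `a`, `b`, `type`, `homology_len`), and `records`
#'   (coordinate-sorted alignment table).
#' @export
simulate_cnv_dataset <- function(ref_length, cnvs, n_junction = 6L,
                                 background_depth = 0, read_length = 100L,
                                 error_rate = 0, gc = 0.5, seed = NULL,
                                 x = NULL, rname = "chr1",
                                 misassign_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cnvs$homology_len)) cnvs$homology_len <- 0L
  L <- as.integer(read_length)
  # reject overlapping CNV windows (junction neighbourhoods must be disjoint)
  win <- cbind(pmin(cnvs$a, cnvs$b) - L, pmax(cnvs$a, cnvs$b) + L)
  if (nrow(cnvs) > 1L) {
    o <- order(win[, 1])
    if (any(win[o, 1][-1] <= win[o, 2][-nrow(win)])) {
      stop("overlapping CNV requests")
    }
  }
  ref <- generate_reference(ref_length, gc = gc, rname = rname)
  for (i in seq_len(nrow(cnvs))) {
    ref <- prepare_cnv_site(ref, list(
      rname = rname, a = cnvs$a[i], b = cnvs$b[i],
      type = cnvs$type[i], homology_len = cnvs$homology_len[i]
    ))
  }
  records <- list()
  for (i in seq_len(nrow(cnvs))) {
    records[[i]] <- simulate_junction_reads(
      ref,
      list(
        rname = rname, a = cnvs$a[i], b = cnvs$b[i],
        homology_len = cnvs$homology_len[i]
      ),
      n = n_junction, read_length = L, error_rate = error_rate,
      x = if (is.null(x)) NULL else x[[i]],
      misassign_frac = misassign_frac
    )
  }
  if (background_depth > 0) {
    records[[length(records) + 1L]] <- simulate_background_reads(
      ref, background_depth, read_length = L, error_rate = error_rate,
      rname = rname
    )
  }
  records <- do.call(rbind, records)
  records <- records[order(records$rname, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  truth <- data.frame(
    rname = rname, a = cnvs$a, b = cnvs$b, type = cnvs$type,
    homology_len = cnvs$homology_len, stringsAsFactors = FALSE
  )
  list(ref = ref, truth = truth, records = records)
}

#' Write alignment records as SAM
#'
#' Minimal valid single-end SAM: `@HD`/`@SQ` header, records sorted by
#' coordinate, `RNEXT/PNEXT/TLEN` unset, base qualities constant `I`.
#'
#' @param records Alignment table as produced by the simulators.
#' @param ref A [reference_store] (for the `@SQ` lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, ref, path) {
  lens <- contig_lengths(ref)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens)
  )
  records <- records[order(records$rname, records$pos), , drop = FALSE]
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
    records$qname, records$flag, records$rname, records$pos,
    records$mapq, records$cigar, records$seq,
    strrep("I", nchar(records$seq))
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a CNV truth table as TSV
#'
#' @param truth Data frame as returned by [simulate_cnv_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(
    "# breakpoints a, b are 1-based inclusive, left-most representatives",
    con
  )
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
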