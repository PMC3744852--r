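# Exhaustive brute-force oracle for error-free data, written independently of
# the package internals: naive CIGAR handling, all-pairs overlap search over
# every candidate length, breakpoints by enumerating every exact split of the
# merged read against the reference, then the same filter rules computed with
# plain string operations. Used to cross-check the pipeline on small contigs.

oracle_parse_cigar <- function(cg) {
  toks <- regmatches(cg, gregexpr("[0-9]+[A-Z=]", cg))[[1]]
  list(len = as.integer(sub(".$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

oracle_classify <- function(rec, min_clip) {
  ops <- oracle_parse_cigar(rec$cigar)
  n <- length(ops$op)
  if (any(ops$op == "H")) return(NULL)
  lead <- if (ops$op[1] == "S") ops$len[1] else 0L
  tail <- if (n > 1 && ops$op[n] == "S") ops$len[n] else 0L
  if (lead == 0L && tail == 0L) return(NULL)
  if (lead == tail) return(NULL)
  cls <- if (tail > lead) "MS" else "SM"
  clip <- max(lead, tail)
  match_len <- sum(ops$len[ops$op %in% c("M", "I", "=", "X")])
  if (clip < min_clip || clip > match_len) return(NULL)
  seq <- rec$seq
  minor <- min(lead, tail)
  if (minor > 0L) {
    seq <- if (cls == "MS") substr(seq, minor + 1, nchar(seq)) else substr(seq, 1, nchar(seq) - minor)
  }
  list(name = rec$qname, rname = rec$rname, pos = rec$pos, seq = seq,
       clip = clip, class = cls,
       ref_span = sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")]))
}

oracle_mm <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])

# returns data.frame(chrom, type, a, b, dx, n_support) of final oracle calls
oracle_call <- function(records, ref, min_clip = 11, min_overlap = 28,
                        frac = 0.08, window = 2e6, min_support = 2) {
  reads <- list()
  for (i in seq_len(nrow(records))) {
    r <- oracle_classify(as.list(records[i, ]), min_clip)
    if (!is.null(r)) reads[[length(reads) + 1]] <- r
  }
  ms <- Filter(function(r) r$class == "MS", reads)
  sm <- Filter(function(r) r$class == "SM", reads)
  raw <- list()
  for (m in ms) {
    for (s in sm) {
      if (m$rname != s$rname || abs(m$pos - s$pos) > window) next
      contig <- ref$seq[[m$rname]]
      L1 <- nchar(m$seq); L2 <- nchar(s$seq)
      best_cl <- NA; best_mm <- NA
      for (cl in max(min_overlap, m$clip + s$clip):min(L1, L2)) {
        if (cl > min(L1, L2)) break
        mm <- oracle_mm(substr(m$seq, L1 - cl + 1, L1), substr(s$seq, 1, cl))
        if (mm > floor(frac * cl)) next
        if (is.na(best_mm) || mm < best_mm || (mm == best_mm && cl > best_cl)) {
          best_mm <- mm; best_cl <- cl
        }
      }
      if (is.na(best_cl)) next
      merge <- paste0(m$seq, substr(s$seq, best_cl + 1, L2))
      W <- nchar(merge)
      p1 <- m$pos
      endb <- s$pos + s$ref_span - 1
      if (p1 + W - 1 > nchar(contig) || endb - W + 1 < 1) next
      ks <- integer(0)
      for (k in 1:(W - 1)) {
        aa <- p1 + k - 1
        bb <- endb - (W - k) + 1
        if (aa < 1 || aa > nchar(contig) || bb < 1 || bb > nchar(contig)) next
        if (paste0(substr(contig, p1, aa), substr(contig, bb, endb)) == merge) {
          ks <- c(ks, k)
        }
      }
      if (!length(ks)) next
      a <- p1 + min(ks) - 1
      b <- endb - (W - min(ks)) + 1
      tau <- frac * W
      ed_a <- oracle_mm(merge, substr(contig, p1, p1 + W - 1))
      ed_b <- oracle_mm(merge, substr(contig, endb - W + 1, endb))
      ed_ab <- 0 # exact split found above
      if (ed_a < tau || ed_b < tau || ed_ab > tau) next
      if (a - 24 < 1 || b + 24 > nchar(contig)) next
      raw[[length(raw) + 1]] <- list(
        chrom = m$rname, a = a, b = b, dx = max(ks) - min(ks),
        type = if (a < b) "DEL" else "DUP",
        id = paste0(substr(contig, a - 24, a), substr(contig, b, b + 24)),
        pair = paste(m$name, s$name, sep = "|")
      )
    }
  }
  if (!length(raw)) {
    return(data.frame(chrom = character(0), type = character(0), a = integer(0),
                      b = integer(0), dx = integer(0), n_support = integer(0)))
  }
  ids <- vapply(raw, function(x) x$id, character(1))
  out <- lapply(unique(ids), function(id) {
    grp <- raw[ids == id]
    g <- grp[[order(vapply(grp, function(x) x$a, numeric(1)),
                    vapply(grp, function(x) x$b, numeric(1)))[1]]]
    data.frame(chrom = g$chrom, type = g$type, a = g$a, b = g$b, dx = g$dx,
               n_support = length(unique(vapply(grp, function(x) x$pair, character(1)))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$n_support >= min_support, , drop = FALSE]
  out <- out[order(out$chrom, out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
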