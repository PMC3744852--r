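# shared builders for constructed fixtures (everything generated in code)

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

mk_ref <- function(seq, rname = "chr1") reference_store(stats::setNames(seq, rname))

mk_record <- function(pos, cigar, seq, qname = "r1", rname = "chr1",
                      flag = 0L, mapq = 60L) {
  list(qname = qname, flag = flag, rname = rname, pos = as.integer(pos),
       mapq = mapq, cigar = cigar, seq = seq)
}

records_df <- function(...) {
  recs <- list(...)
  do.call(rbind, lapply(recs, function(r) {
    data.frame(qname = r$qname, flag = r$flag, rname = r$rname, pos = r$pos,
               mapq = r$mapq, cigar = r$cigar, seq = r$seq,
               stringsAsFactors = FALSE)
  }))
}

# junction-read records cut directly from a reference with an implanted
# CNV (a, b): independent of the package's simulator. x = bases left of the
# junction; the pair is emitted with maximal-extension CIGARs for h = 0.
mk_junction_ms <- function(ref, a, b, x, L = 100, qname = "ms1", rname = "chr1") {
  seq <- paste0(ref_slice(ref, rname, a - x + 1, a),
                ref_slice(ref, rname, b, b + L - x - 1))
  mk_record(a - x + 1, paste0(x, "M", L - x, "S"), seq, qname = qname, rname = rname)
}

mk_junction_sm <- function(ref, a, b, x, L = 100, qname = "sm1", rname = "chr1") {
  seq <- paste0(ref_slice(ref, rname, a - x + 1, a),
                ref_slice(ref, rname, b, b + L - x - 1))
  mk_record(b, paste0(x, "S", L - x, "M"), seq, qname = qname, rname = rname)
}

# x offsets guaranteeing usable clips and pairwise overlaps >= 28 at L = 100
usable_x <- function(n_ms = 4, n_sm = 4, h = 0, L = 100) {
  c(sample((L / 2 + 10):(L - 14), n_ms, replace = TRUE),
    sample((h + 14):(L / 2 - 5), n_sm, replace = TRUE))
}

# one detection trial at the FNR model's study conditions: n junction reads,
# uniform offsets, error-free; returns TRUE when the caller misses the CNV
detect_failure <- function(n = 6, L = 100, h = 0) {
  a <- 1000L
  b <- a + 151L
  ds <- simulate_cnv_dataset(
    2600, data.frame(a = a, b = b, type = "DEL", homology_len = h),
    n_junction = n, read_length = L
  )
  cs <- call_cnvs(ds$records, ds$ref)
  !any(cs$calls$type == "DEL" & cs$calls$a == a & cs$calls$b == b)
}
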