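#' Random-access reference store
#'
#' A `reference_store` holds one or more contigs as in-memory strings and
#' serves 1-based inclusive substrings, the coordinate convention used by
#' every formula in this package (it matches SAM POS).
#'
#' @param x Named character vector of contig sequences, or a
#'   [Biostrings::DNAStringSet]. Names are truncated at the first whitespace,
#'   as FASTA readers do.
#' @return An object of class `reference_store`.
#' @export
#' @examples
#' ref <- reference_store(c(chr1 = "ACGTACGTACGT"))
#' ref_slice(ref, "chr1", 2, 5)
reference_store <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (!is.character(x) || length(x) < 1L) {
    stop("reference must be a non-empty named character vector or DNAStringSet")
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("every contig needs a name")
  }
  names(x) <- sub("\\s.*$", "", names(x))
  x <- toupper(x)
  structure(list(seq = x), class = "reference_store")
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [reference_store].
#' @export
read_reference <- function(path) {
  reference_store(Biostrings::readDNAStringSet(path))
}

#' Write a reference store to FASTA
#'
#' @param ref A [reference_store].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_store"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$seq), path)
  invisible(path)
}

#' Contig lengths of a reference store
#'
#' @param ref A [reference_store].
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(ref) {
  vapply(ref$seq, nchar, integer(1))
}

#' Extract a 1-based inclusive reference substring
#'
#' @param ref A [reference_store].
#' @param rname Contig name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param pad If `TRUE`, out-of-bounds positions are returned as `N` instead
#'   of raising an error (used for identifier windows near contig edges).
#' @return Character scalar of length `end - start + 1`.
#' @export
ref_slice <- function(ref, rname, start, end, pad = FALSE) {
  stopifnot(inherits(ref, "reference_store"))
  if (!rname %in% names(ref$seq)) stop("unknown contig: ", rname)
  contig <- ref$seq[[rname]]
  len <- nchar(contig)
  if (start > end) stop("ref_slice: start > end (", start, " > ", end, ")")
  if (start >= 1L && end <= len) {
    return(substr(contig, start, end))
  }
  if (!pad) {
    stop(
      "ref_slice: window [", start, ", ", end, "] out of bounds for ",
      rname, " (length ", len, ")"
    )
  }
  lo <- max(start, 1L)
  hi <- min(end, len)
  core <- if (lo <= hi) substr(contig, lo, hi) else ""
  paste0(
    strrep("N", max(0L, lo - start)),
    core,
    strrep("N", max(0L, end - hi))
  )
}

#' @export
print.reference_store <- function(x, ...) {
  lens <- contig_lengths(x)
  cat("reference_store with", length(lens), "contig(s):\n")
  for (nm in names(lens)) cat("  ", nm, ": ", lens[[nm]], " bp\n", sep = "")
  invisible(x)
}
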