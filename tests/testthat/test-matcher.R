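# independent brute-force overlap search used to cross-check find_overlap
brute_overlap <- function(ms, sm, min_overlap = 28, frac = 0.08) {
  L1 <- nchar(ms$seq); L2 <- nchar(sm$seq)
  best <- NULL
  for (cl in max(min_overlap, ms$clip_len + sm$clip_len):min(L1, L2)) {
    if (cl > min(L1, L2)) break
    mm <- oracle_mm(substr(ms$seq, L1 - cl + 1, L1), substr(sm$seq, 1, cl))
    if (mm <= floor(frac * cl) &&
        (is.null(best) || mm < best$mm || (mm == best$mm && cl > best$cl))) {
      best <- list(cl = cl, mm = mm)
    }
  }
  best
}

test_that("find_overlap locates the exact suffix/prefix common string", {
  set.seed(21)
  ms_seq <- rand_dna(100)
  sm_seq <- paste0(substr(ms_seq, 51, 100), rand_dna(50))
  ms <- classify_read(mk_record(1000, "80M20S", ms_seq, qname = "ms"))
  sm <- classify_read(mk_record(1500, "20S80M", sm_seq, qname = "sm"))
  m <- find_overlap(ms, sm)
  ref_best <- brute_overlap(ms, sm)
  expect_equal(m$common_len, ref_best$cl)
  expect_equal(m$mismatches, ref_best$mm)
  expect_equal(m$common_len, 50L)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$common_string, substr(ms_seq, 51, 100))
  # common string contains both soft-clipped parts
  expect_gte(m$common_len, ms$clip_len + sm$clip_len)
})

test_that("overlaps shorter than the minimum are not reported", {
  set.seed(22)
  ref <- mk_ref(rand_dna(200))
  # deletion (100, 111); reads overlap by s1 + s2 = 13 + 14 = 27 < 28
  ms <- classify_read(
    mk_junction_ms(ref, 100, 111, x = 47, L = 60, qname = "ms"), min_clip = 5
  )
  sm <- classify_read(
    mk_junction_sm(ref, 100, 111, x = 14, L = 60, qname = "sm"), min_clip = 5
  )
  expect_equal(ms$clip_len + sm$clip_len, 27L)
  expect_null(find_overlap(ms, sm))
})

test_that("the mismatch tolerance is floor(8% of the common string)", {
  set.seed(23)
  ms_seq <- rand_dna(100)
  sm_base <- substr(ms_seq, 51, 100)
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    for (i in sample(nchar(s), k)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    paste(ch, collapse = "")
  }
  ms <- classify_read(mk_record(1000, "80M20S", ms_seq, qname = "ms"))
  # 5 mismatches at CL = 50: 5 > floor(0.08 * 50) = 4, no other CL qualifies
  sm5 <- classify_read(
    mk_record(1500, "20S80M", paste0(mutate_at(sm_base, 5), rand_dna(50)), qname = "s5")
  )
  expect_null(find_overlap(ms, sm5))
  # 4 mismatches qualify
  sm4 <- classify_read(
    mk_record(1500, "20S80M", paste0(mutate_at(sm_base, 4), rand_dna(50)), qname = "s4")
  )
  m <- find_overlap(ms, sm4)
  expect_equal(m$common_len, 50L)
  expect_equal(m$mismatches, 4L)
})

test_that("breakpoint arithmetic follows the position/clip geometry", {
  mk_match <- function(p1, cg1, p2, cg2, cl) {
    ms <- classify_read(mk_record(p1, cg1, rand_dna(100), qname = "m"))
    sm <- classify_read(mk_record(p2, cg2, rand_dna(100), qname = "s"))
    structure(
      list(read_ms = ms, read_sm = sm, common_len = cl, mismatches = 0L,
           common_string = rand_dna(cl)),
      class = "overlap_match"
    )
  }
  set.seed(24)
  bp <- compute_breakpoints(mk_match(101, "70M30S", 500, "35S65M", 70L))
  expect_equal(bp, list(a = 170L, b = 500L, dx = 5L))
  bp2 <- compute_breakpoints(mk_match(201, "60M40S", 90, "48S52M", 88L))
  expect_equal(bp2, list(a = 260L, b = 90L, dx = 0L))
  expect_true(bp2$a >= bp2$b) # duplication by the sign rule
})

test_that("a toy deletion round-trips through overlap and breakpoint arithmetic", {
  set.seed(25)
  ref <- mk_ref(rand_dna(60))
  ref <- prepare_cnv_site(ref, list(rname = "chr1", a = 20, b = 31, homology_len = 0L))
  variant <- implant_cnv(ref, list(rname = "chr1", a = 20, b = 31))
  expect_equal(nchar(variant), 50L)
  ms <- classify_read(mk_junction_ms(ref, 20, 31, x = 10, L = 16, qname = "ms"), min_clip = 3)
  sm <- classify_read(mk_junction_sm(ref, 20, 31, x = 6, L = 16, qname = "sm"), min_clip = 3)
  # both reads are exact substrings of the variant allele
  expect_true(grepl(ms$seq, variant, fixed = TRUE))
  expect_true(grepl(sm$seq, variant, fixed = TRUE))
  m <- find_overlap(ms, sm, min_overlap = 10)
  bp <- compute_breakpoints(m)
  expect_equal(bp$a, 20L)
  expect_equal(bp$b, 31L)
  expect_equal(bp$dx, 0L)
})

homology_fixture <- function(seed, h, a = 100L, b = 201L, L = 100L) {
  set.seed(seed)
  ref <- mk_ref(rand_dna(400))
  ref <- prepare_cnv_site(ref, list(rname = "chr1", a = a, b = b, homology_len = h))
  ar <- a + h
  br <- b + h
  x_ms <- 60L
  x_sm <- 30L
  ms_seq <- paste0(ref_slice(ref, "chr1", ar - x_ms + 1, ar),
                   ref_slice(ref, "chr1", br, br + L - x_ms - 1))
  sm_seq <- paste0(ref_slice(ref, "chr1", ar - x_sm + 1, ar),
                   ref_slice(ref, "chr1", br, br + L - x_sm - 1))
  ms <- classify_read(mk_record(ar - x_ms + 1, paste0(x_ms, "M", L - x_ms, "S"),
                                ms_seq, qname = "ms"))
  sm <- classify_read(mk_record(b, paste0(x_sm - h, "S", L - x_sm + h, "M"),
                                sm_seq, qname = "sm"))
  list(ref = ref, ms = ms, sm = sm, a = a, b = b, h = h)
}

test_that("refinement reports the left-most breakpoints and the repeat width", {
  fx <- homology_fixture(26, h = 3L)
  m <- find_overlap(fx$ms, fx$sm)
  expect_equal(m$mismatches, 0L)
  bp <- compute_breakpoints(m)
  expect_equal(bp$dx, 3L) # common string carries the repeat
  r <- refine_breakpoints(bp$a, bp$b, bp$dx, m, fx$ref)
  expect_equal(r$d_set, 0:3)
  expect_equal(r$a, fx$a)
  expect_equal(r$b, fx$b)
  expect_equal(r$dx, 3L)

  # without homology the minimum is unique at d = 0
  fx0 <- homology_fixture(27, h = 0L)
  m0 <- find_overlap(fx0$ms, fx0$sm)
  bp0 <- compute_breakpoints(m0)
  expect_equal(bp0$dx, 0L)
  r0 <- refine_breakpoints(bp0$a, bp0$b, bp0$dx, m0, fx0$ref)
  expect_equal(r0$d_set, 0L)
  expect_equal(c(r0$a, r0$b), c(fx0$a, fx0$b))
})

test_that("refinement with a read error matches exhaustive enumeration", {
  fx <- homology_fixture(28, h = 5L)
  m <- find_overlap(fx$ms, fx$sm)
  bp <- compute_breakpoints(m)
  # plant one error inside the repeat segment of the common string by
  # mutating the MS read (which contributes that segment)
  s2 <- fx$sm$clip_len
  repeat_pos_in_ms <- fx$ms$length - m$common_len + s2 + 2L
  seq <- fx$ms$seq
  substr(seq, repeat_pos_in_ms, repeat_pos_in_ms) <-
    setdiff(c("A", "C", "G", "T"), substr(seq, repeat_pos_in_ms, repeat_pos_in_ms))[1]
  ms_err <- fx$ms
  ms_err$seq <- seq
  m2 <- find_overlap(ms_err, fx$sm)
  bp2 <- compute_breakpoints(m2)
  r <- refine_breakpoints(bp2$a, bp2$b, bp2$dx, m2, fx$ref)

  # independent enumeration oracle over every shift
  a0 <- bp2$a - bp2$dx
  contig <- fx$ref$seq[["chr1"]]
  mm <- vapply(0:bp2$dx, function(i) {
    csref <- paste0(substr(contig, a0 - s2 + 1, a0 + i),
                    substr(contig, bp2$b + i, bp2$b + m2$common_len - s2 - 1))
    oracle_mm(m2$common_string, csref)
  }, integer(1))
  dset <- which(mm == min(mm)) - 1L
  expect_equal(r$d_set, dset)
  expect_equal(r$a, a0 + min(dset))
  expect_equal(r$b, bp2$b + min(dset))
  expect_equal(r$dx, max(dset) - min(dset))
})

test_that("pairing respects the search window and empty batches", {
  set.seed(29)
  ref <- mk_ref(rand_dna(2e5))
  ms <- classify_read(mk_record(100, "60M40S", rand_dna(100), qname = "m"))
  sm_far <- classify_read(mk_record(3000100L, "40S60M", rand_dna(100), qname = "s"))
  sm_far$rname <- "chr1"
  res <- pair_reads(list(ms), list(sm_far), ref, caller_config())
  expect_equal(unname(res$counters["pairs_tested"]), 0L)
  expect_length(res$drafts, 0L)

  res2 <- pair_reads(list(ms), list(), ref, caller_config())
  expect_length(res2$drafts, 0L)
})

test_that("one MS/SM pair across a simulated deletion yields one draft", {
  set.seed(30)
  ref <- generate_reference(2000, seed = 30)
  ref <- prepare_cnv_site(ref, list(rname = "chr1", a = 800L, b = 1001L, homology_len = 0L))
  ms <- classify_read(mk_junction_ms(ref, 800, 1001, x = 65, qname = "m"))
  sm <- classify_read(mk_junction_sm(ref, 800, 1001, x = 30, qname = "s"))
  res <- pair_reads(list(ms), list(sm), ref, caller_config())
  expect_length(res$drafts, 1L)
  d <- res$drafts[[1]]
  expect_equal(d$a, 800L)
  expect_equal(d$b, 1001L)
  expect_equal(d$cnv_type, "DEL")
})

test_that("accepted calls reconstruct one variant junction for every shift", {
  set.seed(31)
  for (rep in 1:5) {
    h <- sample(c(0L, 2L, 4L), 1)
    type <- sample(c("DEL", "DUP"), 1)
    if (type == "DEL") {
      a <- 900L; b <- a + sample(80:300, 1)
    } else {
      b <- 900L; a <- b + sample(80:300, 1)
    }
    ds <- simulate_cnv_dataset(
      3000, data.frame(a = a, b = b, type = type, homology_len = h),
      n_junction = 8, x = list(usable_x(h = h))
    )
    cs <- call_cnvs(ds$records, ds$ref)
    expect_equal(nrow(cs$calls), 1L)
    call <- cs$calls
    # every shift in [0, dx] reconstructs the identical variant allele
    variants <- vapply(0:call$dx, function(d) {
      implant_cnv(ds$ref, list(rname = "chr1", a = call$a + d, b = call$b + d))
    }, character(1))
    expect_length(unique(variants), 1L)
    expect_equal(call$dx, h)
    # left-most property: shifting one base further left changes the variant
    expect_false(
      ref_slice(ds$ref, "chr1", call$a, call$a) ==
        ref_slice(ds$ref, "chr1", call$b - 1, call$b - 1)
    )
  }
})
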