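---
title: "Locating CNV breakpoints by matching soft-clipped reads"
author: "clipcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating CNV breakpoints by matching soft-clipped reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipcnv)
```

## The model

A deletion or tandem duplication replaces the sample's chromosome by the
reference up to position `a` concatenated with the reference from position
`b` onward (all coordinates 1-based inclusive). For a deletion `a < b` and
bases `a+1 .. b-1` are lost; for a tandem duplication `a >= b` and bases
`b .. a` appear twice in a row. Insertions of novel sequence are out of
scope: they need assembly, not split-read arithmetic.

A read of length `L` that straddles the junction cannot be aligned
contiguously. A local aligner matches its longer side and soft-clips the
rest, so junction reads surface in a BAM file in two flavours:

* **MS reads** — matched part first, long `S` at the 3' end. The last
  reference base consumed by the aligned part (`POS + ref_span - 1`) pins
  the 5' breakpoint `a`.
* **SM reads** — long `S` at the 5' end, matched part second. `POS` pins the
  3' breakpoint `b`.

One read of each flavour determines both breakpoints, but only if the two
reads really cover the *same* junction. The certificate is a polarized
overlap: a suffix of the MS read must align, base by base, with a prefix of
the SM read, and this common string must contain both soft-clipped parts.
When it does, with the MS read's CIGAR `m1 M s1 S` at `p1` and the SM read's
`s2 S m2 M` at `p2`:

```
a  = p1 + ref_span1 - 1        (p1 + (L - s1) - 1 for pure-M alignments)
b  = p2
dx = CL - s1 - s2
```

where `CL` is the common-string length. `dx > 0` appears exactly when the
junction sits inside a short repeat (microhomology): the same variant allele
can then be written with any of the breakpoint pairs `(a+d, b+d)`,
`d = 0..dx`, and the common string carries the repeat between the two
clipped parts.

## Repeat refinement and the left-most convention

Aligner CIGARs near a repeat are not always optimal, so the raw pair is
refined against the reference: for each shift `i` in `0..dx` the package
rebuilds what the common string should look like if the junction were at
shift `i` and counts mismatches; the set `{d}` of shifts attaining the
minimum gives the reported call `(a0 + min d, b + min d)` with residual
uncertainty `max d - min d`.

One anchoring subtlety is worth recording. A maximal-extension aligner runs
the MS read's match *through* the homology block, so the raw
`a = p1 + ref_span - 1` lands on the right-most equivalent 5' breakpoint,
while the SM read's `POS` lands on the left-most 3' breakpoint. The
refinement window is therefore anchored at `a0 = a - dx`, the junction
position consistent with `b`; with that anchor the reconstruction agrees
with the observed common string at `i = 0`, the error-free argmin set is
exactly `{0..dx}`, and the reported pair is the left-most representative —
the package's output convention everywhere, including `HOMLEN` in the VCF.
For `dx = 0` the anchor coincides with the raw `a` and the refinement is a
no-op. Decrementing a reported pair by one base always changes the variant
allele (the tests assert this), so "left-most" is well defined. The argmin
set can in principle be non-contiguous under pathological repeats plus read
errors; `min`/`max` are reported regardless, and the full set is kept on the
call object.

## False-positive filters

Two failure modes dominate: a normal region with scattered mismatches that
provoke a clip (the pair is then explainable by one reference locus), and a
variant read pair whose clip was mapped to the wrong place. Both are caught
by comparing the merged read `MERGE = READ1 . READ2[CL+1 ..]` (length
`2L - CL`) against three equal-length reference strings: `REFa` (reference
from `p1`), `REFb` (reference ending at the SM read's last matched base) and
`REFab` (the junction reconstruction `RNAME[p1, a] . RNAME[b, p2 + m2 - 1]`).
A draft is rejected when

```
dist(MERGE, REFa)  < 0.08 (2L - CL)   or
dist(MERGE, REFb)  < 0.08 (2L - CL)   or
dist(MERGE, REFab) > 0.08 (2L - CL)
```

with strict inequalities, so a distance exactly at the threshold passes. The
distance is a positional mismatch count (Hamming): all compared strings have
equal length by construction, and for substitution-only differences this
coincides with edit distance while staying exactly consistent with the
mismatch counting used in the refinement step. For alignments with internal
indels, where window lengths can diverge, the comparison falls back to
Levenshtein distance (`utils::adist`).

Every surviving call gets a 50-base identifier — 25 reference bases ending
at `a` plus 25 starting at `b` — used to recognise duplicate detections of
one CNV; among calls sharing an identifier the smallest
`dist(MERGE, REFab)` wins and support is pooled. Identifier windows
truncated by a contig edge are N-padded rather than dropped, keeping
near-telomeric calls comparable. Finally, a call must be backed by more
than one distinct supporting read pair (`min_support = 2`); two SM mates of
one MS read count as two pairs.

As an orthogonal sanity statistic, `read_depth_ratio()` divides the mean
coverage inside the called region by the mean coverage in 1 kb flanks:
deletions should sit below 1 (about 0.5 for hemizygous events), tandem
duplications above 1.

## The false-negative-rate model

Even with perfect mapping the caller fails when no usable MS read or no
usable SM read covers the junction. With `n` junction reads of length `L`,
each flavour is equally likely, an MS read is unusable when its clip falls
below the threshold `nS` (probability `q1 = (nS-1)/(L/2)`), and an SM read
when its clip minus the homology does (probability
`q2 = (nS+dx-1)/(L/2)`). Summing over the split between flavours:

```{r}
fnr_analytic(n = 20, read_length = 100, min_clip = 11, dx = 10)
```

At 40x coverage (`n = 20`) the failure rate is below 0.05 even with a
10-base homology. `fnr_monte_carlo()` verifies the closed form by direct
simulation of the same usability model; the test suite also checks the
binomial-theorem collapse of the sum and the monotonicities (non-increasing
in `n`, non-decreasing in `nS` and `dx`). The model deliberately excludes
mapping failure of junction reads — the practical ceiling for any split-read
method — so measured detection rates are compared against it as a bound,
not an equality.

## The simulator

`simulate_cnv_dataset()` builds the study conditions end to end: a uniform
random reference (GC fraction configurable), engineered CNV sites, junction
reads with aligner-faithful POS/CIGAR, optional fully-matched background
coverage, and writers for standard FASTA/SAM plus a truth TSV.

Design choices that matter for interpreting results:

* **Truth is stored left-most.** `prepare_cnv_site()` copies the homology
  block `RNAME[a+1, a+h] = RNAME[b, b+h-1]` into place and then pins both
  boundaries (`RNAME[a] != RNAME[b-1]`, `RNAME[a+h+1] != RNAME[b+h]`),
  rewriting single bases where needed. Without pinning, about a quarter of
  random references would make the stored pair non-left-most and "exact
  recovery" ill-posed.
* **Reads are emitted in the right-most representation.** A junction read
  with offset `x` (bases left of the junction, measured against the
  right-most pair `(a+h, b+h)`) is the variant substring
  `RNAME[a+h-x+1, a+h] . RNAME[b+h, b+h+L-x-1]`. Offsets above `L/2` become
  MS records (`POS = a+h-x+1`, CIGAR `xM(L-x)S`); offsets below become SM
  records (`POS = b`, CIGAR `(x-h)S(L-x+h)M`) — the match extended leftward
  through the homology, exactly what a maximal local aligner reports.
  `x = L/2` is redrawn (orientation would be arbitrary); `x <= h` leaves the
  read entirely inside the right segment and is emitted as a plain `LM`
  record. An optional `misassign_frac` emits the sporadic swapped-orientation
  records (clip longer than match) some paired-end aligners produce, to
  exercise the corresponding filter.
* **Background reads** are uniform `LM` copies of the reference, Poisson in
  number with mean `depth * contig_length / L`. An `exclude` interval lets a
  test model the missing coverage of a homozygously deleted segment; the
  default background does *not* subtract coverage inside implanted CNVs, so
  depth ratios on default datasets reflect junction-read pile-up, not allele
  dosage.

What the simulator does **not** emulate: realistic error profiles or quality
scores (substitutions are iid; no indel errors), paired-end inserts, mapping
ambiguity in genomic repeats, and real aligner heuristics. Passing the
round-trip tests therefore demonstrates the correctness of the breakpoint
arithmetic, refinement, filters and bookkeeping — not robustness to the
mapping difficulties of real genomes, which the source data for any real
analysis brings along.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `min_clip` | 11 | bases | dominant soft clip must exceed 10 bases; balances sensitivity against sporadic clips from scattered mismatches |
| `min_overlap` | 28 | bases | minimum common-string length; the overlap is what certifies that two reads share a junction, so lowering it weakens the certificate |
| `max_mismatch_frac` | 0.08 | fraction | tolerance for overlap mismatches and all reference-filter comparisons, applied as `floor(0.08 * CL)` for the overlap |
| `search_window` | 2,000,000 | bases | maximum POS distance between paired reads; symmetric, both orders searched; ~20,000 suits exome data |
| `min_support` | 2 | pairs | distinct supporting read pairs required per call |
| `flank` | 1000 | bases | flank width for the read-depth ratio |
| `min_mapq` | 0 | — | mapping-quality floor, disabled by default |

## Numerical and degenerate-input choices

* The 8% mismatch budget uses `floor` (the stricter reading) for the overlap
  search; the reference filters compare raw distances against
  `0.08 * (2L - CL)` with strict inequalities.
* Overlap tie-break: fewest mismatches first, then the longest common
  string — maximising evidence when several lengths qualify.
* Reads clipped equally at both ends are orientation-ambiguous and dropped;
  a dominant hard clip makes the read unusable (its sequence is absent).
* Reads with a minor second clip are trimmed to matched-part-plus-one-clip
  before any string arithmetic; their `POS` is unaffected.
* A clip longer than the matched part marks the sporadic swapped-orientation
  alignment; such reads are rejected unconditionally (no rescue via mate
  information is attempted).
* Out-of-bounds reference windows discard the affected draft (refinement,
  filter strings) except for identifiers, which are N-padded.
* `fnr_analytic` accumulates the sum with `lchoose` to stay stable at large
  `n`; `0^0` is taken as 1 so `n = 0` returns exactly 1.
* The search window is measured between POS values, not between putative
  breakpoints.

## Problem sizes used by the test suite

The suite exercises the caller on simulated contigs of 2–5 kb (50 exactness
datasets, 20 homology datasets with `h` in {1, 3, 5, 10}, 20 brute-force
oracle comparisons against an independent all-pairs implementation), checks
the analytic FNR against Monte Carlo at 10^6 replicates on a 12-point grid,
bounds the empirical detection failure over 500 simulator-plus-caller
replicates at `n = 6`, and confirms zero calls on 10^4 background-only reads
over 100 kb. These sizes keep a full run in well under a minute of CPU while
leaving every code path covered; all randomness is seeded.

## Limitations

* Inter-chromosomal events and novel insertions are not called.
* Single-end evidence only: insert sizes, mate positions and genotype
  likelihoods are out of scope, as is multi-sample joint calling.
* Junctions whose reads fail to map (long repeats at both breakpoints)
  are invisible to any split-read method; the FNR model quantifies only the
  clip-threshold and orientation components of that loss.
* Alignments are trusted as given: no realignment or base-quality
  recalibration is performed.
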