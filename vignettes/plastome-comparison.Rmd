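---
title: "Comparing near-identical plastomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing near-identical plastomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeDiff)
```

# Scope

plastomeDiff compares complete chloroplast genomes of very closely related
plants — congeneric species or even conspecific accessions, where divergence
is on the order of a few dozen mutations across ~150 kb. At that divergence
the interesting quantities are not phylogenetic models but an exact census:
the quadripartite architecture (LSC, SSC and the two inverted repeats), the
microsatellite (SSR) complement, every substitution with its
transition/transversion class, every indel with its slippage
(homopolymeric) or non-slippage origin and its polarity against a designated
standard genome, the short inversions that would otherwise masquerade as SNP
clusters, and the positions of the IR junctions relative to their border
genes. The motivating system is a pair of *Haloxylon* (saxaul) plastomes
that differ by 44 substitutions, 23 indels and two micro-inversions; the
package ships transcriptions of that study's tables as fixtures so all of
its headline statistics can be recomputed with no sequence downloads.

# Quadripartite structure detection

The IR pair is found as the maximal-length pair of disjoint segments of the
circular sequence such that one is the exact reverse complement of the other
(`detect_inverted_repeats()`). The search is seed-and-extend: all shared
21-mers between the doubled sequence and its reverse complement are grouped
by anti-diagonal into maximal runs; with the default mismatch budget of 0 a
maximal run *is* a maximal common substring, so no further extension is
needed. Doubling handles circularity; coordinates are mapped back to
`[1, L]` and duplicate representations of the same physical pair are
collapsed. The two arcs between the chosen pair become LSC (longer) and SSC
(shorter).

Choices worth knowing about:

* **Defaults.** `min_ir_length = 1000`, `max_mismatches = 0`, `k = 21`.
  Plastome IRs are tens of kilobases and internally exact, so the defaults
  are conservative rather than tight. A nonzero mismatch budget extends
  seeds greedily and trims flanking mismatches, but 0 is both the default
  and the only setting under which `IRa == revcomp(IRb)` is guaranteed
  exactly.
* **Ties are errors.** Two non-equivalent maximal pairs of equal length (or
  two equal-length arcs, which would make LSC/SSC labels arbitrary) raise an
  error instead of picking silently; lower `min_ir_length` and inspect if
  this ever happens on real data.
* **Canonical rotation.** The conventional layout starts the sequence at the
  first LSC base (LSC, IRb, SSC, IRa). That fixes the rotation but not the
  strand: both the genome and its reverse complement admit an LSC-first
  layout. `canonical_rotation()` resolves the strand by taking the
  lexicographically smaller of the two candidate strings, making the result
  a pure function of the circular molecule — any rotation or
  reverse-complement of the same molecule canonicalizes identically. The
  synthetic generator pins the first and last LSC base to `A` (versus the
  `T` that the flipped layout would start with), so generated genomes are
  canonical by construction and the planted coordinates never need
  remapping.

GC content is reported as (G+C)/(A+C+G+T) with `N` excluded from both
numerator and denominator; per-region GC is computed per region and
total GC over the full circle, with both IR copies counted. Reports print
percents with one decimal, the convention of published genome-feature
tables.

# SSR scanning

`find_ssrs()` reports every maximal perfect tandem repeat of a 1–6 bp motif
meeting the class thresholds (defaults ≥10 mono, ≥5 di, ≥4 tri, ≥3
tetra/penta/hexa repeats — the conventional plastome SSR settings). The
implementation compares the sequence against itself at lag *p*: a maximal
run of equalities of length *r* is a periodic region of length *r + p*, of
which `floor((r + p) / p)` complete units anchored at the run start are
reported. Consequences of that definition:

* a locus satisfies `end - start + 1 == unit_length * n_repeats` exactly
  (partial trailing units are not part of the reported interval, and no
  additional complete unit exists on either flank);
* a run is reported under its primitive, smallest period only — 12 `A`s is
  one mono locus, never an `AA` di locus, because non-primitive motifs are
  discarded;
* motifs are kept as they read on the forward strand (`A` runs and `T` runs
  are distinct classes, as in published repeat tables).

Circularity is again handled by doubling; a run crossing the origin is
reported once, with a wrapped end coordinate and a `wraps` flag, and a
degenerate fully-periodic circle reports nothing (every rotation is
equivalent, so no locus is maximal). The scanner is property-tested against
two independent oracles: a PCRE backreference enumerator and a
position-by-position counter.

# Aligning two near-identical genomes

`align_pair()` is an anchor-based collinear aligner, not a general aligner:
it assumes both genomes are canonically rotated and collinear, which is the
plastome regime it is built for. K-mers (21 by default) that occur exactly
once in each genome are matched, collapsed into co-diagonal runs, and
chained by a weighted longest-increasing-subsequence; gaps between anchors
are closed by optimal global alignment (match +1, mismatch −1, gap open −5,
gap extend −1) via `Biostrings::pairwiseAlignment()`.

The non-collinearity guard deserves a note. The IR copies can contribute no
unique k-mers, so a plastome's anchor chain inevitably has two large anchor
deserts. Coverage is therefore credited as: chained anchor length plus, for
each inter-anchor gap, the *shorter* of its two sides. For a collinear pair
the gaps are nearly symmetric and coverage approaches 100%; for a rotated or
rearranged input the leftover sequence piles up on one side of a break and
the check fails (default threshold 90%).

# Event calling and classification

Calling order matters: micro-inversions are detected first, and their
columns are masked from substitution calling, so a 14 bp inversion is one
event rather than a cluster of spurious SNPs.

**Substitutions.** One event per mismatched non-gap column; transition iff
both bases are purines or both pyrimidines. Adjacent mismatch columns stay
separate single-base events (published substitution tables list single
sites; no MNP merging). The six-type spectrum pools strand-symmetric pairs
(e.g. `A>C` with `T>G`).

**Indels.** Each maximal gap run is one event, left-normalized by the
standard single-step rule (shift left while the base before the event equals
its last base), which makes equivalent placements canonical and
re-normalization a no-op. Polarity follows the standard genome: `Insertion`
when the standard carries the bases, `Deletion` when it lacks them. An
event is `homopolymeric` — the slippage class — iff its sequence is a run of
one base *and* the standard's run of that base adjacent to the normalized
position is at least `homopolymer_min_run` (default 3) long. Three is the
smallest value that keeps all published slippage rows in class (including a
two-base `AA` event inside an A run) while excluding an isolated single-base
deletion with no adjacent run.

**Micro-inversions.** A true inverted segment shows up as a dense mismatch
run whose other-genome segment is the reverse complement of the standard's.
Interior positions can match by coincidence (any base that happens to equal
the complement of its mirror partner), so the detector searches, per
anti-diagonal, for the shortest gap-free window containing each maximal
mismatch run that satisfies the reverse-complement test, and reports that
minimal window. `min_len` defaults to 3: a 2 bp segment whose reverse
complement also differs at both positions is formally indistinguishable from
two substitutions, and is left to the SNP caller. Perfect palindromes are
undetectable by definition and never emitted. Hairpin stem arms
(`find_stem_arms()`) are measured strictly *outside* the inverted interval —
the longest flanking stretch where the 5′ side base-pairs with the 3′ side —
with a 0-mismatch default, since published hairpin stems are drawn perfect.
No free-energy folding is attempted; complementarity length is the only
stem statistic.

**p-distance.** Mismatched over comparable (non-gap) columns, pairwise
deletion, rounded to 5 decimals. The operation accepts an exclusion list of
intervals; the pipeline passes the detected inversions so that the distance
counts substitutions only and equals `n_substitutions / comparable columns`
by construction. Ts/Tv ratios print with 2 decimals.

# IR junction analysis

`junction_positions()` reports each junction as the last base of the
upstream region on the canonical rotation; `junction_gene_distance()` counts
the bases strictly between a junction and the nearest gene boundary on the
single-copy side — so a touching gene is at distance 0 and one intervening
base gives 1, reproducing the 0/1/2 bp phrasing used when comparing border
genes across related genomes — and lists genes whose span crosses a junction
together with how many of their bases lie inside the IR. Origin-wrapping
genes are not modeled; the classic border configuration (a tRNA gene a base
or two into the LSC, a ycf1-like gene running hundreds of bases into the
IR) is representable without them.

# The synthetic generator and what a green test means

`generate_plastome()` builds `LSC + IRb + SSC + revcomp(IRb)` from
per-region base compositions and plants genes (some with introns), SSR loci
of each motif class, and hairpin sites — a short core flanked by perfect
inverted-repeat arms — recording everything in a truth set. Defaults are the
observed saxaul-plastome values: region lengths 84,214 / 24,171 / 19,014 bp,
GC 34.4/43.0/29.7%, and hairpin cores of 3–14 bp with 19–27 bp arms.
`mutate_genome()` plants substitutions (transition count drawn
`Binomial(n, ts_fraction)`, default 44 events at 19/44), slippage indels at
existing single-base runs, heterogeneous indels of 5–6 bp, and inversions at
the planted hairpin sites, then rebuilds the mutated copy through the same
event-application routine the callers are tested against.

Deliberate simplifications, so green tests are read correctly:

* **Events live in single-copy regions only.** A real IR mutation appears
  in both copies (published indel tables list such events twice) and would
  break the mutated genome's exact IR unless mirrored; rather than model
  mirrored events the generator leaves the IR untouched, which also matches
  the empirical conservation of the IR.
* **Events are planted ≥50 bp apart and ≥100 bp from junctions**, so no
  call is ambiguous and truth recovery can be asserted event-for-event,
  class-for-class. Real mutational hotspots violate this; the package's
  callers still run on such data, but the *tests* only certify the
  well-separated regime.
* **Hairpin cores are drawn from a two-letter alphabet** ({A,C} or {T,G}),
  which guarantees every position of an inverted core mismatches its
  reverse complement — the detector's minimal window is then exactly the
  planted core. Real inversions can have coincidentally matching interior
  positions; the detector's window search handles them, but planted truth
  stays unambiguous.
* **No codon structure or selection**: synonymous/nonsynonymous
  classification is out of scope, and the packaged per-gene table's S/N
  columns are carried as data only.
* The generator cannot emulate mutational clustering, heteroplasmy,
  assembly error, or IR boundary shifts between the two genomes (both
  genomes share one architecture by construction).

Scaled-down genomes (tens of kb) are used throughout the test suite for
speed; the generator's defaults remain full scale, and the acceptance
script runs one full-default-scale pair end to end.

# Numerical and formatting conventions

Coordinates are 1-based inclusive everywhere; region and locus ends may wrap
the origin (flagged, with `end < start`). TSV reports are tab-separated,
unquoted, UTF-8, with a header row. GC percents print with one decimal,
Ts/Tv with two, p-distances with five. JSON is written without rounding.
Seeds make every simulation and report byte-reproducible.

# Fixture transcription notes

The packaged tables carry printed values as-is, with a `flag` column where
the print is internally inconsistent rather than a silent correction: one
repeat-table row prints a comma-shifted coordinate (read as 112,371); one
prints its motif with interior spaces (read as `CTAC`); two indel rows print
six bases against a stated length of 5 (the printed length is kept). One
arithmetic inconsistency is inherited from the source abstract: it reports
67 mutations while enumerating 44 substitutions, 23 indels and two
micro-inversions (69 events); only substitutions + indels reproduce the
printed 67, and that is the identity the acceptance suite asserts, with the
two inversions counted separately.

# Limitations

Plastomes that have lost an IR are rejected with a clean error, not
analyzed. Comparisons are strictly pairwise against a standard;
multi-genome joint calling is out of scope. The aligner assumes
collinearity and will refuse rearranged genomes rather than align through
them. GenBank reading is a minimal feature-table parser sufficient for
plastome annotations (`join`/`complement` locations, `/pseudo`), not a
general GenBank implementation; GFF3 is the native dialect.
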