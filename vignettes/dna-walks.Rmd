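---
title: "DNA walks: methods, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA walks: methods, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnawalkr)
```

## The problem

A raw DNA sequence is close to unreadable for a human, and most sequences of
interest are far too long to display base by base. One family of remedies
maps each nucleotide to one or more points in the plane and draws the
sequence as a *walk* — a polyline whose shape exposes composition bias,
repeats, and local structure at a glance, without any annotation. dnawalkr
implements five such transforms, restricted deliberately to *non-degenerate*
methods: each walk can be decoded back into the exact sequence it came from.
That invertibility is not just a theoretical nicety — it is the package's
built-in correctness oracle, exercised throughout the test suite.

## The five transforms

All transforms operate on normalized sequences over `{A, C, G, T}`
(lowercase is folded, RNA `U` becomes `T`; anything else either aborts or is
stripped, under an explicit policy). The conventions below are fixed
**format contracts**: stored walks are only decodable because every run uses
the same tables.

**Gates** — cumulative walk from the origin; T = (0, +1), A = (0, −1),
C = (−1, 0), G = (+1, 0). `n` bases give `n + 1` points. The endpoint
satisfies the identity (#G − #C, #T − #A), which the tests verify against
direct base counting. The x-coordinate may revisit values, so this is the
one method whose walk can cross itself.

**Yau** — cumulative walk with unit vectors: A = (1/2, −√3/2),
G = (√3/2, −1/2), C = (√3/2, 1/2), T = (1/2, √3/2). The source method is
specified only as "vectors along a unit circle", so the exact assignment was
an open choice; we fixed purines below the axis, pyrimidines above, and all
x-components positive so x is strictly increasing and the walk never doubles
back — preserving the property that motivates the method. `n` bases give
`n + 1` points.

**Squiggle** — each base becomes two bits (A = 10, T = 01, G = 11, C = 00)
and each bit a half-step of Δx = 0.5, Δy = ±0.5. The bit table was likewise
an open choice; ours makes complementary bases bit-complements and returns
y to an integer after every A or T. `n` bases give `2n + 1` points. All
coordinates are exact multiples of 0.5, which doubles are guaranteed to
represent exactly, so squiggle decoding is exact arithmetic, not tolerance
matching.

**Randic tablature** — point `i` is `(i, level(base_i))` with fixed levels
A = 3, T = 2, G = 1, C = 0. Any bijection onto four levels would decode; the
table is fixed for cross-run stability. `n` bases give `n` points.

**Qi dinucleotide tablature** — point `i` is the alphabetical rank
(AA = 0 … TT = 15) of the overlapping dinucleotide starting at base `i`.
`n` bases give `max(n − 1, 0)` points. The literature describes the
originating method ambiguously (one line suggests a binary-representation
variant); this package implements the dinucleotide tablature under the name
`qi` and notes the attribution ambiguity here rather than in the API.

```{r}
qi_walk("ATG") # AT has rank 3, TG rank 14
```

## Decoding and its one blind spot

`decode_walk()` inverts each transform: cumulative walks by matching step
vectors (yau steps are matched to the nearest candidate vector with a 1e-6
tolerance; gates and squiggle steps are integer/half-integer and matched
exactly), tablature walks by inverting the level tables, with qi
additionally checking that consecutive dinucleotides overlap in one base.
Corrupt input — a step matching no base, an even squiggle point count, an
impossible dinucleotide chain — raises an error naming the first bad point.

One input is provably unrecoverable: a **single-base qi walk** has zero
points (`max(n − 1, 0) = 0` for both `n = 0` and `n = 1`), so the base
identity is simply not in the data. `decode_walk()` raises an explicit
error for a zero-point qi walk recorded as one base rather than guessing.
Every other (method, sequence) combination round-trips exactly, which the
suite checks property-style over random sequences up to 10,000 bases.

## Storage and query-in-place

Walks are persisted one Parquet table per key `(source_file, seq_id,
method)`, columns `idx`, `x`, `y`, Snappy-compressed, with a JSON manifest
recording path, creation time and point count. Range queries are executed by
the Arrow engine against the compressed table — a local analogue of
submitting a SQL predicate to remote columnar storage — and return points in
the **closed** interval `[xmin, xmax]` (the semantics of SQL `BETWEEN`),
ordered by `idx`. Walk order, not x order, is what a polyline redraw needs:
a gates walk can revisit the same x many times.

Re-putting an existing key overwrites it and refreshes `created_at` — the
cache-refresh contract. `expire_walks()` removes entries strictly older than
the TTL (default 24 hours); an entry exactly at the boundary is retained.
Expiry only runs when invoked (or wired into store opening by the caller),
because there is no resident server process to run it in the background.

## Downsampling

Rendering budgets are enforced by min-max decimation: over-budget series are
split into `max_points / 2` equal contiguous buckets and each bucket
contributes its minimum-y and maximum-y points. Choices worth recording:

* **Bucketing is by point position, not by x.** Gates walks revisit x, so
  position buckets are the only rule that works uniformly across methods;
  for the monotone-x methods the two coincide up to bucket boundaries.
* **Min-max rather than uniform stride**, because the zoom view depends on
  the visual envelope: the global extrema are always retained, a stride
  would miss spikes.
* **Ties**: the first occurrence of the bucket minimum and the last
  occurrence of the maximum are kept; a degenerate one-point bucket
  contributes its only point.
* **Emission order**: selected points are emitted in walk order, making the
  output a strict subsequence of the input — required both for redrawing
  the polyline and for downsampling to be idempotent. (Emitting min before
  max regardless of position would violate the subsequence property
  whenever a bucket's maximum precedes its minimum.)

With the default budget of 1000 and any input of more than 1000 points, every
bucket holds at least two points, so the output is exactly 1000 points.

## Visualization semantics

The initial view autoscales to the union bounding box of the *visible* walks
plus a 2% margin per side (the margin keeps endpoint strokes visible; the
exact padding was an open choice). Toggling a sequence off recomputes bounds
from the remainder. Legends color either each sequence or each file
(first-appearance order), from a fixed 36-color categorical palette that
cycles — determinism across runs is preferred over aesthetics, and hidden
sequences keep their assignment so re-showing one never recolors others.
Rendered data always flows through the store's range query and the point
budget: the plot never draws a raw over-budget series. Export formats are
svg, pdf, png and jpg; anything else is rejected with the list of the four.

Zooming re-queries the store for the closed region per visible key. A key
with nothing in the region returns an empty table but keeps its row, so it
stays in the legend. Since tablature methods place at most one point per
base and squiggle at most two, a zoom region narrower than half the point
budget in bases returns stored points exactly — base-pair resolution.

## Capacity limits

Batch validation enforces at most 30 sequences, 4.5 Mb per sequence and
135 Mb in total — the capacities the transform-and-store pipeline is sized
for, framed as configuration (a `walk_limits()` object) rather than
constants, since they are operational rather than fundamental. Validation
runs before any write, so an over-limit batch stores nothing.

## The synthetic generator

`synth_sequences()` draws iid bases with `P(G) = P(C) = gc/2`,
`P(A) = P(T) = (1 − gc)/2`, fully determined by an integer seed. The default
`gc = 0.5` (uniform base composition) is the neutral null for testing
transform and storage machinery, whose correctness properties are
composition-free. What the generator deliberately does **not** emulate:
long-range composition structure (isochores, CpG islands), repeats, or
realistic length distributions. Passing tests therefore certify the
*machinery* — exact transforms, exact inversion, exact query semantics —
on any composition, but say nothing about the biological interpretability
of a given walk's shape on real genomes.

## Numerical choices and degenerate inputs

* x-steps are multiples of 0.5 everywhere except yau; yau y-values are
  irrational and matched on decode within 1e-6 per component.
* Cumulative walks of the empty sequence are the single origin point;
  tablature walks of the empty sequence have no points.
* Cumulative walks are additive under concatenation (bit-exactly, since
  summation order is identical), which the suite checks.
* Region queries reject `xmin > xmax`; budgets must be even and at least 2
  (a bucket needs room for a min and a max).

## Problem sizes used in testing

The suite exercises round trips on ~1000 random sequences of lengths 0 to
10,000 across all five methods, 500 random (walk, region) query pairs
against a naive linear-scan oracle, dense-walk downsampling at 120,001
points, and a 30-sequence batch transformed serially and in parallel and
compared byte-for-byte. These sizes exercise every contract boundary
(including the printed capacity limits, checked exactly) while keeping a
full run in the order of a minute.

## Known limitations

* The five conventions (yau vectors, squiggle bits, randic levels, qi
  ranking) are this package's fixed contracts; other implementations of the
  same methods may differ by rotation, reflection or relabeling, so walks
  are comparable within dnawalkr, not necessarily across tools.
* Single-base sequences are invisible to qi (see above).
* The store is a local directory with a JSON manifest; concurrent writers
  are serialized only by the filesystem and the manifest is not locked.
* Interactivity (click-drag zoom, legend toggling) is modeled as function
  calls — `zoom_walks()`, visibility subsets in `plot_spec()` — not as an
  event loop.
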