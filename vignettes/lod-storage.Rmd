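---
title: "Level-of-detail storage for huge time series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-of-detail storage for huge time series: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `tslod`, the parameters that
matter, and the design decisions taken where more than one faithful
implementation was possible. It is the companion to the package
documentation; the README shows the user-facing workflow.

## The proxy model and its assumptions

The package rests on one observation: a plot is a raster. All samples
falling into one pixel column are indistinguishable from a vertical line
spanning their minimum and maximum, so a column's `(min, max)` pair is a
*lossless proxy for rendering purposes* (not for analysis — the proxy
discards everything but the envelope). Three structures exploit this:

* **Static pyramid** (`build_pyramid()`): level `l` holds one pair per
  `T^l` samples, where the thinning factor `T` is a power of two. Levels
  are built while the level below has at least `T` elements, so the top
  level always has between 1 and `T − 1` pairs and can satisfy any element
  budget. A trailing block shorter than `T` produces a pair over the
  remaining elements, which keeps every stored pair equal to the exact
  min/max of the raw samples it covers — the invariant the test suite
  checks against brute-force scans.
* **Event tree** (`event_store()`): positions are 64-bit integers; the high
  `64 − B` bits, split most-significant-first into `r`-bit chunks, name a
  directory path and block file. Node files summarize directories with the
  low `n·r` bits of every entry zeroed (level `n` counts from the blocks
  upward) and duplicates removed. Zeroing `n·r` *value* bits per level is
  the reduction rule implemented and tested; it gives every node file the
  same maximal entry count `2^B` as a block file.
* **Interval tree** (`interval_store()`): same scheme with `(begin, end)`
  pairs, plus high-level block files at interior nodes for intervals whose
  endpoints do not share a leaf block span. The home node is found by
  trimming the common most-significant bit prefix of `begin` and `end`
  (within the path bits) down to a whole number of chunks.

Queries are constant-time because the static level just below the requested
reduction factor `R` bounds the dynamic work by a factor of `T` per emitted
element, regardless of how long the series is. The interval query is the
one exception in the worst case: long-range intervals collected along the
descent are kept on a stack, and with adversarially overlapping intervals
that stack can grow to the store size. Traversal stays streaming (one pass,
memory linear in the stack), which is the graceful-degradation behaviour
the tests exercise with hundreds of mutually overlapping intervals;
electrophysiology annotations are in practice sparse and mostly
non-overlapping, which restores constant cost.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `thinning_factor` (T) | 64 | samples/pair ratio per level | Storage overhead is between `2/T` and `2/(T−1)` (3.2 % at 64 for the 2^24 benchmark series); per-query work grows with `T`, the number of levels shrinks with it. 64 is the established sweet spot. |
| `budget` | 8192 | display elements | Viewport width in drawable columns. With the default budget, ranges up to 8192 samples are returned as raw points; reduction activates above that. |
| `blockfactor` (B) | 20 | bits | A block file spans `2^B = 1,048,576` samples. Larger blocks favour query speed, smaller blocks favour edit speed. |
| `branchfactor` (r) | 4 | bits | Directory fan-out `2^r = 16`; tree depth is `(64 − B)/r = 11`. `64 − B` must be divisible by `r` (validated). |
| `width_margin` | 4 | × visible width | Prefetch window width for `query_window()`. |
| `resolution_margin` | 2 | × visible resolution | Extra cached detail; also the zoom drift tolerated before the cache regenerates. |

The margins implement the double-buffer contract: panning inside the cached
range at a similar zoom costs nothing; crossing the range edge or zooming
beyond the resolution margin regenerates the cache, recentred on the new
viewport. Regeneration here is synchronous — the original design hands it
to a background thread, and `tslod` models the swap as cache invalidation
(`$regenerated`) rather than reproducing the threading.

## Numerical and format decisions

* **Positions are doubles.** R has no native 64-bit integers, so sample
  positions are exact only on `[0, 2^53)`. That is ~28,500 years at 10 kHz,
  far beyond any recording, but it is an address-space cap: the on-disk
  format stays 64-bit little-endian unsigned (top bytes zero), and all bit
  operations are implemented as exact integer arithmetic on doubles. One
  visible consequence: the top path chunk always contains bit 63, so the
  depth-0 (store root) high-level interval block can never be the computed
  home of a representable interval; the code path and the query probe for
  it exist regardless.
* **Byte order** is little-endian everywhere (raw samples, min/max pairs,
  annotation entries), recorded in the JSON configs.
* **NaN policy**: `build_pyramid()` rejects NaN input, naming the first
  offending position; min/max semantics would otherwise be ambiguous.
* **Bucket snapping**: reduced series queries snap bucket edges to static
  level element boundaries so stored pairs are never split; the first and
  last bucket may cover samples outside the requested range, and their
  reported `pos_lo`/`pos_hi` state the actual coverage. This keeps every
  emitted `(min, max)` exactly equal to a raw-range min/max (exactness over
  pixel-edge fidelity). At most `budget + 1` primitives are emitted.
* **Dynamic reduction grid**: the requested factor `R` may be any integer;
  masking uses the largest power of two `≤ R` (`2^⌊log2 R⌋`), and the
  traversal level is `⌊log2(R)/r⌋` clamped to the available depths.
* **Edge semantics of reduced annotation queries**: a query returns the
  *reduced representatives* inside the viewport — positions are masked and
  then clipped to `[begin, end)`; reduced intervals are kept when their
  masked extent intersects the range. When the viewport bounds are aligned
  to the reduction grid (which a renderer's columns are), this is
  indistinguishable from filtering first and masking second; at unaligned
  bounds the grid semantics is the one that node files can answer exactly,
  and it is the semantics both the implementation and the test oracles use.
* **Interval endpoints are inclusive**, and reduction masks both endpoints
  down (pure bit-chop). A reduced interval whose endpoints collapse becomes
  a line proxy. Sub-element under-coverage at the right edge is accepted.
* **Node maintenance** is eager: every insert/delete recomputes the node
  chain from the edited directory to the root, stopping early when a
  recomputed node equals the stored one (ancestors then cannot change).
  Empty files and directories are pruned immediately. `verify_store()`
  recomputes every node bottom-up from block files only — deliberately
  independent of the incremental path — and additionally checks record
  placement, sortedness and `begin ≤ end`.
* **Set semantics**: at most one event per position, at most one copy of a
  `(begin, end)` record; duplicate inserts are idempotent, deleting a
  missing interval warns and does nothing.
* **Config formats** (`pyramid.json`, `store.json`) are this package's own
  small JSON descriptions; no authoritative format existed to follow.

## What the fixtures emulate — and what they do not

`gen_alternating()` (±1 samples) and `gen_dense_events()` (an event at
every position) are worst-case *density* fixtures: every proxy is saturated,
so read-count bounds measured on them are upper bounds for real data.
`gen_stipple_intervals()` produces 50 %-duty interval/gap patterns whose
closed form (interval `k` is `[k·2^(p+1), k·2^(p+1) + 2^p − 1]`) makes
reduction outcomes predictable in tests. `gen_spiketrain()` reproduces a
14-day, 10 kHz continuous firing pattern (a spike every 300 samples,
30-sample bursts at the same period); tests use `max_samples` to take a
desk-scale prefix with identical spacing. None of these fixtures exhibit
realistic amplitude structure, drift, or irregular annotation clustering,
so passing tests demonstrate correctness of storage and query semantics and
boundedness of work — not rendering quality on physiological signals, nor
file-system-dependent properties (directory fragmentation, block-allocation
overhead of sparse annotation trees), which are explicitly out of scope.

## Problem sizes used by the test suite

The structural scales are the package's choices for routine runs: oracle
equivalence is property-tested with ~10^3 randomized queries against
brute-force scans over a 10^5-sample random walk, a 10^5-entry event store
and a 10^4-record interval store; work-boundedness compares read counts for
identical ranges across series of 2^16–2^26 samples; store consistency is
re-verified after 10^4 interleaved random edits; and the storage-overhead
table is measured on the 2^24-sample alternating series at thinning factors
32–256. The read-cost sweeps report deterministic counters (elements read,
files opened, traversal depth) rather than wall-clock times, so their
three-phase shape — constant floor, linear rise, bounded plateau with
saw-teeth (series) or stepwise depth decrease (annotations) — is
machine-independent.

## Known limitations

* No concurrency: stores assume a single writer, and there is no
  transactional safety across the block-file/node-chain update.
* No on-the-fly reduction during acquisition; pyramids are batch-built.
* The interval stack is unbounded under adversarial overlap (see above).
* Multi-channel containers, compression, and rasterization/rendering are
  out of scope; the display list is the interface to a renderer.
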