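# tslod — level-of-detail storage and constant-complexity queries for huge time series

Long electrophysiology recordings (days of multi-kHz sampling) produce far
more samples than any screen can show and any plotting tool can redraw
interactively: a viewport is a few thousand pixel columns wide, while the
recording behind it may hold billions of samples. `tslod` implements the
out-of-core storage layout and query engine that makes panning and zooming
over such recordings — and over their event and interval annotations — a
constant-time operation, independent of the recording length. It is aimed at
anyone building or scripting visual inspection pipelines for long
single-channel signals: the package prepares the on-disk structures, answers
viewport queries with render-ready primitives, and verifies the structures'
integrity.

## The method

**Min/max proxy reduction.** All samples that project into one pixel column
can be replaced by a single vertical line from their minimum to their
maximum — the plot is pixel-identical. For a column covering samples
`[a, b)` the proxy is `(min x[a:b), max x[a:b))`.

**Static reduction pyramid.** To support every zoom level, proxies are
precomputed hierarchically with a power-of-two *thinning factor* `T`: level
`l` stores one `(min, max)` pair per `T^l` raw samples, level `l+1` takes
min-of-mins/max-of-maxes over `T` pairs of level `l`, until fewer than `T`
pairs remain. The extra disk space is a geometric series bounded by
`2/(T−1)` of the raw file — 3.2 % at the default `T = 64`.

**Viewport queries.** A query for range `[s, e)` with an element budget `m`
(≈ pixel columns) needs reduction factor `R = ⌈(e−s)/m⌉`. The engine picks
static level `l = ⌊log_T R⌋` (the level just *below* `R`, which still has
more detail than requested) and dynamically aggregates at most `T` level-`l`
pairs per emitted column. Work per query is therefore `O(m·T)` — constant in
the series length. Emitted min/max values are exact, never approximated.

**Annotation trees.** Events (64-bit sample positions) and intervals
(`begin ≤ end` pairs) are editable, so they live in a sparse directory tree
instead of flat files: the high `64 − B` bits of a position, cut into
`r`-bit chunks, form the hex path of a *block file* spanning `2^B` samples
(`B = 20`, `r = 4` by default, tree depth `(64−B)/r = 11`). Every directory
is summarized by a *node file* one level up: all entries below with the low
`n·r` bits zeroed and duplicates removed, giving proxies with the same
maximal density as a block file at every scale. Intervals too long for one
block span live in *high-level block files* at the interior node addressed
by the chunk-aligned common prefix of `begin` and `end`; range queries push
them onto a stack while descending. Queries read only the files at the
traversal level matching `R`, so annotation panning/zooming is constant-time
as well.

## Worked example

```r
library(tslod)

raw <- gen_alternating(2^20, "alt.f64")     # benchmark fixture: ±1 samples
pyr <- build_pyramid(raw, 64, "alt-pyr")
glance(pyr)
#> # A tibble: 1 × 4
#>   n_samples thinning_factor n_levels overhead_pct
#> 1   1048576              64        3         3.17

query_series(pyr, 0, 2^20, budget = 512)
#> <tslod_display> 512 primitives, range [0, 1048576), factor 2048, level 1
#> # A tibble: 512 × 6
#>   kind  pos_lo pos_hi     x   min   max
#> 1 vline      0   2048  1024    -1     1
#> 2 vline   2048   4096  3072    -1     1
#> ...
```

One million samples become 512 vertical lines; each line's `(min, max)` is
the exact range of the 2048 samples it covers (for the alternating fixture,
always `(−1, 1)`), built from static level 1 (factor 64) with a dynamic
residual of 32. `overhead_pct` is the level files' size relative to the raw
file. Annotations work the same way:

```r
es <- event_store("spikes")                 # B = 20, r = 4
insert_events(es, gen_spiketrain(max_samples = 2^20)$events)
query_events(es, 0, 2^20, factor = 4096)
#> <tslod_display> 256 primitives, range [0, 1048576), factor 4096, level 3
#> # A tibble: 256 × 5  (marks on the 4096-sample grid)
```

A shell interface mirroring the library (`prep`, `query`, `events …`,
`intervals …`, `fixtures …`, `bench`, `verify`) is installed as `exec/tslod`.

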