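## Synthetic benchmark fixtures.  All generators are deterministic; only the
## random-walk test helper takes a seed.  The alternating series and the
## dense event set are worst-case-density fixtures; the stipple pattern and
## the spike train mimic typical electrophysiology annotation layouts.

#' Generate an alternating +1/-1 raw series
#'
#' Sample `i` is `+1` for even `i` and `-1` for odd `i`, so any reduced
#' query sees exactly `(-1, +1)` in every column — the worst-case dense
#' series used for read-cost benchmarking.
#'
#' @param n number of samples.
#' @param path output raw file (`8 * n` bytes).
#' @param chunk_samples samples per write chunk.
#' @return A [raw_series()] handle.
#' @export
gen_alternating <- function(n, path, chunk_samples = 2^22) {
  stopifnot(n >= 1)
  con <- file(path, "wb")
  on.exit(close(con))
  done <- 0
  while (done < n) {
    take <- min(chunk_samples, n - done)
    idx <- seq(done, done + take - 1)
    writeBin(ifelse(idx %% 2 == 0, 1, -1), con, size = 8L,
             endian = "little")
    done <- done + take
  }
  close(con)
  on.exit()
  raw_series(path)
}

#' Generate a seeded random-walk raw series (test helper)
#'
#' Cumulative sum of standard normal steps; reproducible by seed and
#' independent of the caller's RNG state.
#'
#' @param n number of samples.
#' @param path output raw file.
#' @param seed RNG seed.
#' @return A [raw_series()] handle.
#' @export
gen_randomwalk <- function(n, path, seed = 1L) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  write_raw_series(cumsum(stats::rnorm(n)), path)
  raw_series(path)
}

#' Dense event positions
#'
#' Events at every possible sample position `0, 1, ..., n - 1`: the
#' worst-case-density event fixture.
#'
#' @param n number of events.
#' @return Numeric vector of positions.
#' @export
gen_dense_events <- function(n) {
  stopifnot(n >= 1)
  seq(0, n - 1)
}

#' Stipple interval pattern (50% interval, 50% gap)
#'
#' Interval `k` (for `k = 0, ..., count - 1`) is
#' `[k * 2^(scale + 1), k * 2^(scale + 1) + 2^scale - 1]`: intervals of
#' length `2^scale` separated by gaps of the same length, a 50% duty cycle
#' at scale `scale`.
#'
#' @param scale log2 of the interval (and gap) length.
#' @param count number of intervals.
#' @return A tibble with columns `begin`, `end`.
#' @export
gen_stipple_intervals <- function(scale, count) {
  stopifnot(scale >= 0, count >= 1)
  k <- seq(0, count - 1)
  tibble::tibble(begin = k * 2^(scale + 1),
                 end = k * 2^(scale + 1) + 2^scale - 1)
}

#' Spike-train annotation fixture
#'
#' Emulates a neuron firing continuously: one detected spike (event) every
#' `spike_period` samples and one burst interval of `interval_length`
#' samples every `spike_period` samples. Defaults model 14 days of
#' continuous firing at a 10 kHz sampling rate with a spike every 300
#' samples (about 33 Hz) and 30-sample intervals; `max_samples` caps the
#' span for desk-scale variants with identical spacing.
#'
#' @param days recording duration in days.
#' @param sample_rate sampling rate in Hz.
#' @param spike_period samples between consecutive spikes.
#' @param interval_length samples per burst interval.
#' @param max_samples optional cap on the spanned sample count.
#' @return A list with `events` (numeric positions) and `intervals` (tibble
#'   with `begin`, `end`), plus `n_samples`.
#' @export
gen_spiketrain <- function(days = 14, sample_rate = 10000,
                           spike_period = 300, interval_length = 30,
                           max_samples = Inf) {
  n <- min(days * 86400 * sample_rate, max_samples)
  stopifnot(n >= spike_period)
  ev <- seq(0, n - 1, by = spike_period)
  list(events = ev,
       intervals = tibble::tibble(begin = ev,
                                  end = ev + interval_length - 1),
       n_samples = n)
}

#' Read-cost sweep over power-of-two range lengths
#'
#' Queries `[0, 2^i)` for increasing `i` until `max_range` is covered,
#' recording deterministic work counters instead of wall-clock time. For a
#' pyramid the sweep shows three phases: a raw-point floor, a linear rise up
#' to the element budget, and a bounded plateau with a saw-tooth
#' `entries_read` profile whose drops mark static-level switches. For
#' annotation stores the traversal `path_depth` decreases stepwise as
#' coarser node files take over.
#'
#' @param x a `tslod_pyramid`, `tslod_events` or `tslod_intervals` object.
#' @param max_range largest range length to query (capped at the series
#'   length for pyramids).
#' @param budget element budget per query; the requested reduction factor is
#'   `ceiling(range / budget)`.
#' @param min_range smallest range length.
#' @return A tibble with one row per range length: `range`, `factor`,
#'   `level`, `elements_read` (or `entries_read`), `files_opened`,
#'   `primitives`, `path_depth` (annotation stores).
#' @export
benchmark_sweep <- function(x, max_range, budget = 8192, min_range = 4) {
  UseMethod("benchmark_sweep")
}

sweep_ranges <- function(min_range, max_range) {
  2^seq(ceiling(log2(min_range)), floor(log2(max_range)))
}

#' @export
benchmark_sweep.tslod_pyramid <- function(x, max_range = x$raw$n_samples,
                                          budget = 8192, min_range = 4) {
  rows <- lapply(sweep_ranges(min_range, min(max_range, x$raw$n_samples)),
                 function(len) {
    dl <- query_series(x, 0, len, budget)
    st <- attr(dl, "stats")
    tibble::tibble(range = len, factor = st$requested_factor,
                   level = st$level, elements_read = st$elements_read,
                   files_opened = st$files_opened, primitives = nrow(dl))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tslod_sweep", class(out))
  out
}

sweep_store <- function(x, max_range, budget, min_range, query) {
  rows <- lapply(sweep_ranges(min_range, max_range), function(len) {
    dl <- query(x, 0, len, max(1, ceiling(len / budget)))
    st <- attr(dl, "stats")
    tibble::tibble(range = len, factor = st$requested_factor,
                   level = st$level, entries_read = st$entries_read,
                   files_opened = st$files_opened, primitives = nrow(dl),
                   path_depth = st$path_depth)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tslod_sweep", class(out))
  out
}

#' @export
benchmark_sweep.tslod_events <- function(x, max_range, budget = 8192,
                                         min_range = 4) {
  sweep_store(x, max_range, budget, min_range, query_events)
}

#' @export
benchmark_sweep.tslod_intervals <- function(x, max_range, budget = 8192,
                                            min_range = 4) {
  sweep_store(x, max_range, budget, min_range, query_intervals)
}

#' Plot a read-cost sweep
#'
#' @param object a `tslod_sweep` tibble from [benchmark_sweep()].
#' @param ... unused.
#' @return A ggplot object (log2 range versus elements/entries read).
#' @export
autoplot.tslod_sweep <- function(object, ...) {
  ycol <- if ("elements_read" %in% names(object)) "elements_read" else
    "entries_read"
  ggplot2::ggplot(object, ggplot2::aes(
    x = log2(.data$range), y = .data[[ycol]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$level))) +
    ggplot2::labs(x = "log2 range length (samples)", y = ycol,
                  colour = "static level")
}
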