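# Brute-force reference implementations, independent of the storage layer:
# they operate on plain in-memory vectors/data frames.

# exact min/max of raw samples over [lo, hi) for a display-list row
oracle_minmax <- function(values, lo, hi) {
  x <- values[(lo + 1):hi]
  c(min(x), max(x))
}

# event query semantics: representatives on the 2^floor(log2(R)) grid that
# fall inside [begin, end)
oracle_events <- function(all_pos, begin, end, factor) {
  zb <- floor(log2(factor))
  m <- sort(unique(mask_low_bits(all_pos, zb)))
  m[m >= begin & m < end]
}

# interval query semantics: reduce onto the grid, keep reduced records
# intersecting [begin, end), deduplicated
oracle_intervals <- function(df, begin, end, factor) {
  zb <- floor(log2(factor))
  red <- reduce_intervals(df, zb)
  red[red$begin < end & red$end >= begin, ]
}

# pyramid oracle: per-block min/max with a partial trailing block
oracle_level_pairs <- function(values, block) {
  n <- length(values)
  nb <- ceiling(n / block)
  grp <- factor(rep(seq_len(nb), each = block, length.out = n),
                levels = seq_len(nb))
  list(mins = as.numeric(tapply(values, grp, min)),
       maxs = as.numeric(tapply(values, grp, max)))
}

tmp_raw <- function(values, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".f64", .local_envir = env)
  write_raw_series(values, path)
  raw_series(path)
}

tmp_pyramid <- function(values, thinning, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  build_pyramid(tmp_raw(values, env = env), thinning, dir)
}

tmp_event_store <- function(env = parent.frame(), ...) {
  event_store(withr::local_tempdir(.local_envir = env), ...)
}

tmp_interval_store <- function(env = parent.frame(), ...) {
  interval_store(withr::local_tempdir(.local_envir = env), ...)
}

read_pairs_mat <- function(pyr, level) {
  n <- pyr$levels$pairs[pyr$levels$level == level]
  m <- matrix(readBin(pyr$levels$path[pyr$levels$level == level], "numeric",
                      n = 2 * n, size = 8L, endian = "little"), nrow = 2L)
  list(mins = m[1, ], maxs = m[2, ])
}
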