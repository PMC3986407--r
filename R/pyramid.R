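## Static min/max data-reduction pyramid.
##
## Level 1 stores one (min, max) pair per block of T consecutive raw samples;
## level l+1 stores one pair per block of T pairs of level l (min of mins,
## max of maxes).  Levels are built while the level below has at least T
## elements, so the top level always has fewer than T pairs.  Level files are
## headerless little-endian binaries of interleaved (min, max) doubles.

PYRAMID_FORMAT <- "tslod-pyramid-1"

## One pairwise pmin/pmax halving pass per factor-of-two; padding with
## +Inf/-Inf only ever extends the trailing partial block, so the result is
## exactly the per-block min/max with a partial last block.
reduce_pairs <- function(mins, maxs, factor) {
  steps <- round(log2(factor))
  for (s in seq_len(steps)) {
    n <- length(mins)
    if (n %% 2 == 1L) {
      mins <- c(mins, Inf)
      maxs <- c(maxs, -Inf)
      n <- n + 1L
    }
    odd <- seq.int(1L, n, by = 2L)
    mins <- pmin(mins[odd], mins[odd + 1L])
    maxs <- pmax(maxs[odd], maxs[odd + 1L])
  }
  list(mins = mins, maxs = maxs)
}

level_file_name <- function(level) sprintf("level_%02d.minmax", level)

#' Build a static min/max reduction pyramid over a raw series
#'
#' Scans the raw file once per level and writes one `(min, max)` pair per
#' block of `thinning_factor` elements of the level below, until a level has
#' fewer than `thinning_factor` pairs. A trailing partial block yields a pair
#' over the remaining elements. A JSON config describing the pyramid is
#' written to `out_dir/pyramid.json`.
#'
#' @param raw a [raw_series()] handle or a path to a raw `.f64` file.
#' @param thinning_factor reduction ratio between adjacent levels; must be a
#'   power of two `>= 2`.
#' @param out_dir output directory for the level files and config (created if
#'   missing).
#' @param chunk_samples samples per read chunk during the level-1 pass
#'   (rounded down to a multiple of `thinning_factor`); bounds memory use.
#' @return A `tslod_pyramid` object (see [load_pyramid()]).
#' @seealso [storage_overhead()], [verify_pyramid()], [query_series()]
#' @export
build_pyramid <- function(raw, thinning_factor, out_dir,
                          chunk_samples = 2^22) {
  if (is.character(raw)) raw <- raw_series(raw)
  stopifnot(inherits(raw, "tslod_raw"))
  if (!is_power_of_two(thinning_factor) || thinning_factor < 2) {
    stop("thinning_factor must be a power of two >= 2", call. = FALSE)
  }
  if (raw$n_samples < 1) stop("raw series is empty", call. = FALSE)
  t_fac <- as.numeric(thinning_factor)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ## level 1: chunked pass over the raw file
  chunk <- max(t_fac, floor(chunk_samples / t_fac) * t_fac)
  in_con <- file(raw$path, "rb")
  on.exit(close(in_con), add = TRUE)
  lvl_path <- file.path(out_dir, level_file_name(1))
  out_con <- file(lvl_path, "wb")
  done <- 0
  pair_counts <- numeric(0)
  n_pairs1 <- 0
  while (done < raw$n_samples) {
    take <- min(chunk, raw$n_samples - done)
    x <- readBin(in_con, "numeric", n = take, size = 8L, endian = "little")
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      close(out_con)
      stop(sprintf("NaN sample at position %.0f", done + bad - 1),
           call. = FALSE)
    }
    red <- reduce_pairs(x, x, t_fac)
    writeBin(as.numeric(rbind(red$mins, red$maxs)), out_con,
             size = 8L, endian = "little")
    n_pairs1 <- n_pairs1 + length(red$mins)
    done <- done + take
  }
  close(out_con)
  pair_counts <- n_pairs1
  level_files <- lvl_path

  ## higher levels from the level below, whole-file (level files are small)
  l <- 1L
  while (pair_counts[l] >= t_fac) {
    below <- readBin(level_files[l], "numeric",
                     n = 2 * pair_counts[l], size = 8L, endian = "little")
    m <- matrix(below, nrow = 2L)
    red <- reduce_pairs(m[1L, ], m[2L, ], t_fac)
    l <- l + 1L
    lvl_path <- file.path(out_dir, level_file_name(l))
    writeBin(as.numeric(rbind(red$mins, red$maxs)), lvl_path,
             size = 8L, endian = "little")
    level_files <- c(level_files, lvl_path)
    pair_counts <- c(pair_counts, length(red$mins))
  }

  cfg <- list(
    format = PYRAMID_FORMAT,
    byte_order = "little",
    raw_path = raw$path,
    n_samples = raw$n_samples,
    thinning_factor = t_fac,
    levels = lapply(seq_along(level_files), function(i) {
      list(level = i, pairs = pair_counts[i], file = level_file_name(i))
    })
  )
  config_path <- file.path(out_dir, "pyramid.json")
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  load_pyramid(config_path)
}

#' Load and validate a pyramid from its config file
#'
#' Reconstructs the pyramid object and checks the structural invariants: the
#' thinning factor is a power of two, levels are consecutive from 1, each
#' level's pair count equals the ceil-division of the count below, every
#' level file has exactly 16 bytes per pair, and the raw file size matches
#' the recorded sample count.
#'
#' @param config_path path to a `pyramid.json` written by [build_pyramid()].
#' @return A `tslod_pyramid` object: a list with `raw` ([raw_series()]
#'   handle), `thinning_factor`, `config_path`, `dir`, and `levels` (a tibble
#'   with columns `level`, `reduction_factor`, `pairs`, `path`).
#' @export
load_pyramid <- function(config_path) {
  if (!file.exists(config_path)) {
    stop("pyramid config not found: ", config_path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(config_path)
  if (!identical(cfg$format, PYRAMID_FORMAT)) {
    stop("not a pyramid config: ", config_path, call. = FALSE)
  }
  dir <- dirname(normalizePath(config_path))
  raw <- raw_series(cfg$raw_path)
  if (raw$n_samples != cfg$n_samples) {
    stop("raw file size does not match config n_samples", call. = FALSE)
  }
  t_fac <- as.numeric(cfg$thinning_factor)
  if (!is_power_of_two(t_fac) || t_fac < 2) {
    stop("config thinning_factor is not a power of two >= 2", call. = FALSE)
  }
  lv <- cfg$levels
  expected <- raw$n_samples
  levels <- tibble::tibble(
    level = vapply(lv, function(e) as.numeric(e$level), numeric(1)),
    pairs = vapply(lv, function(e) as.numeric(e$pairs), numeric(1)),
    path = vapply(lv, function(e) file.path(dir, e$file), character(1))
  )
  if (!identical(levels$level, as.numeric(seq_len(nrow(levels))))) {
    stop("pyramid levels are not consecutive from 1", call. = FALSE)
  }
  for (i in seq_len(nrow(levels))) {
    expected <- ceiling(expected / t_fac)
    if (levels$pairs[i] != expected) {
      stop(sprintf("level %d pair count %.0f != expected %.0f",
                   i, levels$pairs[i], expected), call. = FALSE)
    }
    sz <- file.size(levels$path[i])
    if (is.na(sz)) stop("missing level file: ", levels$path[i], call. = FALSE)
    if (sz != 16 * levels$pairs[i]) {
      stop(sprintf("level file %s has %.0f bytes, expected %.0f",
                   levels$path[i], sz, 16 * levels$pairs[i]), call. = FALSE)
    }
  }
  if (nrow(levels) == 0 || levels$pairs[nrow(levels)] >= t_fac) {
    stop("pyramid is not reduced to fewer than thinning_factor pairs",
         call. = FALSE)
  }
  levels$reduction_factor <- t_fac^levels$level
  structure(
    list(config_path = normalizePath(config_path), dir = dir, raw = raw,
         thinning_factor = t_fac,
         levels = levels[, c("level", "reduction_factor", "pairs", "path")]),
    class = "tslod_pyramid"
  )
}

#' @export
print.tslod_pyramid <- function(x, ...) {
  cat(sprintf(
    "<tslod_pyramid> %s samples, thinning factor %d, %d levels (%.2f%% overhead)\n",
    format(x$raw$n_samples, big.mark = ","), x$thinning_factor,
    nrow(x$levels), storage_overhead(x)))
  invisible(x)
}

## read pairs k0..k1 (0-based, inclusive) of one level; rows: mins, maxs
read_level_pairs <- function(pyr, level, k0, k1) {
  row <- pyr$levels[pyr$levels$level == level, ]
  stopifnot(nrow(row) == 1L, k0 >= 0, k1 < row$pairs, k0 <= k1)
  con <- file(row$path, "rb")
  on.exit(close(con))
  seek(con, where = 16 * k0)
  x <- readBin(con, "numeric", n = 2 * (k1 - k0 + 1), size = 8L,
               endian = "little")
  matrix(x, nrow = 2L)
}

#' Relative storage overhead of a pyramid
#'
#' Total size of all level files as a percentage of the raw file size
#' (measured from the files on disk; each pair occupies two 8-byte floats).
#' For a thinning factor T the geometric series of level sizes bounds the
#' overhead by `2/(T-1)` from above and `2/T` from below.
#'
#' @param pyr a `tslod_pyramid`.
#' @return Overhead in percent (a bare number, e.g. `3.17`).
#' @export
storage_overhead <- function(pyr) {
  stopifnot(inherits(pyr, "tslod_pyramid"))
  sizes <- file.size(pyr$levels$path)
  if (anyNA(sizes)) {
    stop("missing level file: ",
         paste(pyr$levels$path[is.na(sizes)], collapse = ", "), call. = FALSE)
  }
  raw_sz <- file.size(pyr$raw$path)
  100 * sum(sizes) / raw_sz
}

#' Verify stored pyramid pairs against the level below
#'
#' Recomputes a subset of stored `(min, max)` pairs from the level below
#' (level 1 from the raw samples) and reports every mismatch, including
#' pairs violating `min <= max`. When a level has at most `max_checks` pairs
#' all of them are checked; otherwise an evenly spaced deterministic subset
#' is used.
#'
#' @param pyr a `tslod_pyramid`.
#' @param max_checks per-level cap on the number of recomputed pairs.
#' @return A tibble of mismatches (zero rows if the pyramid is intact) with
#'   columns `level`, `index`, `stored_min`, `stored_max`, `expected_min`,
#'   `expected_max`; the number of pairs checked is in attribute `checked`.
#' @export
verify_pyramid <- function(pyr, max_checks = 4096) {
  stopifnot(inherits(pyr, "tslod_pyramid"))
  t_fac <- pyr$thinning_factor
  bad <- list()
  checked <- 0
  for (i in seq_len(nrow(pyr$levels))) {
    n_pairs <- pyr$levels$pairs[i]
    idx <- if (n_pairs <= max_checks) {
      seq_len(n_pairs) - 1
    } else {
      unique(floor(seq(0, n_pairs - 1, length.out = max_checks)))
    }
    below_n <- if (i == 1L) pyr$raw$n_samples else pyr$levels$pairs[i - 1L]
    for (k in idx) {
      c0 <- k * t_fac
      c1 <- min((k + 1) * t_fac, below_n) - 1
      if (i == 1L) {
        x <- read_samples(pyr$raw, c0, c1 + 1)
        exp_min <- min(x); exp_max <- max(x)
      } else {
        m <- read_level_pairs(pyr, i - 1L, c0, c1)
        exp_min <- min(m[1L, ]); exp_max <- max(m[2L, ])
      }
      st <- read_level_pairs(pyr, i, k, k)
      checked <- checked + 1
      ok <- identical(st[1L], exp_min) && identical(st[2L], exp_max) &&
        isTRUE(st[1L] <= st[2L])
      if (!ok) {
        bad[[length(bad) + 1L]] <- tibble::tibble(
          level = i, index = k,
          stored_min = st[1L], stored_max = st[2L],
          expected_min = exp_min, expected_max = exp_max)
      }
    }
  }
  out <- if (length(bad)) dplyr::bind_rows(bad) else tibble::tibble(
    level = numeric(0), index = numeric(0),
    stored_min = numeric(0), stored_max = numeric(0),
    expected_min = numeric(0), expected_max = numeric(0))
  attr(out, "checked") <- checked
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-level summary of a pyramid
#'
#' @param x a `tslod_pyramid`.
#' @param ... unused.
#' @return A tibble with one row per level: `level`, `reduction_factor`,
#'   `pairs`, `bytes`.
#' @export
tidy.tslod_pyramid <- function(x, ...) {
  dplyr::mutate(
    x$levels[, c("level", "reduction_factor", "pairs")],
    bytes = 16 * .data$pairs)
}

#' One-row summary of a pyramid
#'
#' @param x a `tslod_pyramid`.
#' @param ... unused.
#' @return A tibble with `n_samples`, `thinning_factor`, `n_levels`,
#'   `overhead_pct`.
#' @export
glance.tslod_pyramid <- function(x, ...) {
  tibble::tibble(
    n_samples = x$raw$n_samples,
    thinning_factor = x$thinning_factor,
    n_levels = nrow(x$levels),
    overhead_pct = storage_overhead(x))
}
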