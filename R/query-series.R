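## Viewport queries over a pyramid.
##
## A query asks for a half-open sample range and an element budget (roughly
## the pixel-column count of the viewport).  The requested reduction factor
## R = ceil(range / budget) is split into a static part (the pyramid level
## just below R) and a dynamic residual (< thinning factor), so the number of
## level elements touched is bounded by budget * thinning_factor + O(1)
## regardless of the series length.

#' Choose the static pyramid level for a requested reduction factor
#'
#' Picks the deepest static level whose reduction factor does not exceed the
#' requested one, i.e. the level that still contains more detail than
#' requested; the remaining (dynamic) reduction is returned as the residual
#' factor. The residual is below the thinning factor whenever a deeper level
#' exists.
#'
#' @param requested_factor requested samples-per-element ratio, `>= 1`.
#' @param thinning_factor the pyramid's thinning factor (power of two).
#' @param max_level number of static levels available (`>= 0`).
#' @return A list with `level` (0 means raw data) and `residual`
#'   (`requested_factor / thinning_factor^level`).
#' @export
select_level <- function(requested_factor, thinning_factor, max_level) {
  stopifnot(requested_factor >= 1, max_level >= 0)
  level <- 0L
  f <- 1
  while (level < max_level && f * thinning_factor <= requested_factor) {
    f <- f * thinning_factor
    level <- level + 1L
  }
  list(level = level, residual = requested_factor / f)
}

new_display_list <- function(df, start, end, factor, stats) {
  out <- tibble::as_tibble(df)
  attr(out, "range") <- c(start, end)
  attr(out, "reduction_factor") <- factor
  attr(out, "stats") <- stats
  class(out) <- c("tslod_display", class(out))
  out
}

#' Query a pyramid for render-ready display primitives
#'
#' Computes the requested reduction factor `R = max(1, ceiling((end - start) /
#' budget))`. When `R == 1` every raw sample in range is emitted as a point.
#' Otherwise the static level below `R` is selected and the range is cut into
#' buckets whose edges snap to level element boundaries (static pairs are
#' never split); each bucket becomes one vertical min/max line whose values
#' are the exact min/max of all raw samples the bucket covers. At most
#' `budget + 1` primitives are emitted.
#'
#' @param pyr a `tslod_pyramid`.
#' @param start,end half-open 0-based sample range, `0 <= start < end <=
#'   n_samples`.
#' @param budget maximum number of display elements (`>= 2`), e.g. the
#'   viewport width in pixels.
#' @return A `tslod_display` tibble with columns `kind` (`"point"` or
#'   `"vline"`), `pos_lo`, `pos_hi` (covered sample range, half-open), `x`
#'   (representative position: the midpoint), `min`, `max`. Attribute
#'   `stats` records `elements_read`, `files_opened`, `level`,
#'   `requested_factor` and `residual`.
#' @export
query_series <- function(pyr, start, end, budget) {
  stopifnot(inherits(pyr, "tslod_pyramid"))
  if (!(budget >= 2)) stop("budget must be >= 2", call. = FALSE)
  n <- pyr$raw$n_samples
  if (!(start >= 0 && start < end && end <= n)) {
    stop("query range must satisfy 0 <= start < end <= n_samples",
         call. = FALSE)
  }
  len <- end - start
  r_req <- max(1, ceiling(len / budget))

  if (r_req == 1) {
    vals <- read_samples(pyr$raw, start, end)
    pos <- seq(start, end - 1)
    return(new_display_list(
      tibble::tibble(kind = "point", pos_lo = pos, pos_hi = pos + 1,
                     x = pos, min = vals, max = vals),
      start, end, 1,
      list(elements_read = len, files_opened = 1L, level = 0L,
           requested_factor = 1, residual = 1)))
  }

  sel <- select_level(r_req, pyr$thinning_factor, nrow(pyr$levels))
  esize <- pyr$thinning_factor^sel$level
  n_elem_level <- if (sel$level == 0L) n else
    pyr$levels$pairs[pyr$levels$level == sel$level]
  k0 <- floor(start / esize)
  k1 <- min(ceiling(end / esize), n_elem_level) - 1
  m <- k1 - k0 + 1
  if (sel$level == 0L) {
    x <- read_samples(pyr$raw, k0, k1 + 1)
    mins <- x
    maxs <- x
  } else {
    pm <- read_level_pairs(pyr, sel$level, k0, k1)
    mins <- pm[1L, ]
    maxs <- pm[2L, ]
  }
  g <- max(1, ceiling(sel$residual))     # level elements per bucket
  nb <- ceiling(m / g)
  grp <- factor(rep(seq_len(nb), each = g, length.out = m),
                levels = seq_len(nb))
  bmin <- as.numeric(tapply(mins, grp, min))
  bmax <- as.numeric(tapply(maxs, grp, max))
  e_lo <- k0 + (seq_len(nb) - 1) * g
  e_hi <- pmin(e_lo + g, k1 + 1)      # last bucket may hold fewer elements
  pos_lo <- e_lo * esize
  pos_hi <- pmin(e_hi * esize, n)
  new_display_list(
    tibble::tibble(kind = "vline", pos_lo = pos_lo, pos_hi = pos_hi,
                   x = (pos_lo + pos_hi) / 2, min = bmin, max = bmax),
    start, end, r_req,
    list(elements_read = m, files_opened = 1L, level = sel$level,
         requested_factor = r_req, residual = sel$residual))
}

#' @export
print.tslod_display <- function(x, ...) {
  st <- attr(x, "stats")
  rg <- attr(x, "range")
  cat(sprintf(
    "<tslod_display> %d primitives, range [%.0f, %.0f), factor %.0f, level %d\n",
    nrow(x), rg[1], rg[2], attr(x, "reduction_factor"), st$level))
  NextMethod()
}

#' Write a display list as TSV
#'
#' One primitive per line: `kind`, `pos_lo`, `pos_hi`, `min`, `max` (events
#' and interval primitives use their own kinds with `min`/`max` empty).
#'
#' @param dl a display list tibble ([query_series()], [query_events()],
#'   [query_intervals()]).
#' @param path output file or connection (`stdout()` works).
#' @return `dl`, invisibly.
#' @export
export_display_list <- function(dl, path) {
  cols <- intersect(c("kind", "pos_lo", "pos_hi", "min", "max"), names(dl))
  df <- as.data.frame(dl)[, cols]
  for (col in intersect(c("pos_lo", "pos_hi"), cols)) {
    df[[col]] <- sprintf("%.0f", df[[col]])   # never scientific notation
  }
  readr::write_tsv(df, path, progress = FALSE)
  invisible(dl)
}

#' Plot a series display list
#'
#' Raw points are drawn as a connected line, vertical min/max lines as
#' segments — the proxy representation that is pixel-identical to plotting
#' every covered sample in one column.
#'
#' @param object a `tslod_display` from [query_series()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tslod_display <- function(object, ...) {
  if (all(object$kind == "point")) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$min)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "sample position", y = "value")
  } else {
    ggplot2::ggplot(object) +
      ggplot2::geom_segment(ggplot2::aes(
        x = .data$x, xend = .data$x, y = .data$min, yend = .data$max)) +
      ggplot2::labs(x = "sample position", y = "value")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
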