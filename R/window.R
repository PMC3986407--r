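## Prefetch-window cache.
##
## To hide storage latency while panning and zooming, the cached display list
## covers a range width_margin times wider than the visible section and holds
## resolution_margin times more elements than the viewport needs.  A refresh
## only regenerates the cache when the visible range leaves the cached range
## or the required reduction factor drifts beyond the resolution margin; the
## original renderer swaps two display-list buffers in a background thread,
## which is modelled here as synchronous cache invalidation.

window_build <- function(pyr, start, end, budget, width_margin,
                         resolution_margin) {
  n <- pyr$raw$n_samples
  width <- end - start
  half_extra <- (width_margin - 1) * width / 2
  c_start <- max(0, floor(start - half_extra))
  c_end <- min(n, ceiling(end + half_extra))
  c_budget <- ceiling(budget * resolution_margin * (c_end - c_start) / width)
  dl <- query_series(pyr, c_start, c_end, c_budget)
  list(cached_range = c(c_start, c_end),
       base_factor = max(1, ceiling(width / budget)),
       display = dl)
}

#' Create a prefetch query window over a pyramid
#'
#' @param pyr a `tslod_pyramid`.
#' @param start,end visible half-open sample range.
#' @param budget visible element budget (e.g. viewport width in pixels).
#' @param width_margin cached range width as a multiple of the visible width.
#' @param resolution_margin cached resolution as a multiple of the visible
#'   resolution; also the tolerated zoom drift before regeneration.
#' @return A `tslod_window` object; the cached display list is in
#'   `$display`.
#' @export
query_window <- function(pyr, start, end, budget,
                         width_margin = 4, resolution_margin = 2) {
  stopifnot(inherits(pyr, "tslod_pyramid"),
            width_margin >= 1, resolution_margin >= 1, budget >= 2)
  built <- window_build(pyr, start, end, budget, width_margin,
                        resolution_margin)
  structure(
    list(pyramid = pyr, visible = c(start, end), budget = budget,
         width_margin = width_margin, resolution_margin = resolution_margin,
         cached_range = built$cached_range, base_factor = built$base_factor,
         display = built$display),
    class = "tslod_window")
}

#' Pan or zoom a query window
#'
#' Moves the visible range. The cached display list is regenerated (recentred
#' on the new visible range) only if the new visible range leaves the cached
#' range or its required reduction factor differs from the factor at
#' generation time by more than the resolution margin.
#'
#' @param win a `tslod_window`.
#' @param start,end new visible half-open sample range.
#' @return The updated `tslod_window`; whether the cache was rebuilt is in
#'   field `$regenerated`.
#' @export
window_refresh <- function(win, start, end) {
  stopifnot(inherits(win, "tslod_window"), start >= 0, end > start,
            end <= win$pyramid$raw$n_samples)
  new_factor <- max(1, ceiling((end - start) / win$budget))
  inside <- start >= win$cached_range[1] && end <= win$cached_range[2]
  ratio <- new_factor / win$base_factor
  ok_res <- ratio <= win$resolution_margin && ratio >= 1 / win$resolution_margin
  win$visible <- c(start, end)
  if (inside && ok_res) {
    win$regenerated <- FALSE
    return(win)
  }
  built <- window_build(win$pyramid, start, end, win$budget,
                        win$width_margin, win$resolution_margin)
  win$cached_range <- built$cached_range
  win$base_factor <- built$base_factor
  win$display <- built$display
  win$regenerated <- TRUE
  win
}

#' @export
print.tslod_window <- function(x, ...) {
  cat(sprintf(
    "<tslod_window> visible [%.0f, %.0f), cached [%.0f, %.0f), base factor %.0f\n",
    x$visible[1], x$visible[2], x$cached_range[1], x$cached_range[2],
    x$base_factor))
  invisible(x)
}
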