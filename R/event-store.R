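## Event annotation store: one 64-bit sample position per event, at most one
## event per position, stored sorted in sparse block files with reduced
## node-file proxies along the directory tree.

#' Open or create an event store
#'
#' @param root store directory (created on first use).
#' @param blockfactor,branchfactor tree geometry for a new store (see
#'   [tree_config()]); existing stores keep their recorded geometry.
#' @return A `tslod_events` store handle.
#' @export
event_store <- function(root, blockfactor = 20, branchfactor = 4) {
  open_store(root, "events", blockfactor, branchfactor)
}

#' Reduce event positions onto a coarser grid
#'
#' Zeroes the low `zero_bits` bits of every position and removes the
#' duplicates this creates; the result is sorted. This is the data-reduction
#' step applied when node files are built and again (dynamically) at query
#' time.
#'
#' @param pos numeric vector of sample positions.
#' @param zero_bits number of low bits to clear.
#' @return Sorted vector of unique reduced positions.
#' @export
reduce_events <- function(pos, zero_bits) {
  sort(unique(mask_low_bits(pos, zero_bits)))
}

## group positions by leaf block and hand each group to `edit`; afterwards
## refresh the node chain once per affected leaf directory
edit_blocks <- function(store, pos, edit) {
  pos <- sort(unique(assert_position(pos, "pos")))
  if (length(pos) == 0L) return(invisible(store))
  block <- floor(pos / 2^store$blockfactor)
  chains <- list()
  for (grp in split(pos, format(block, scientific = FALSE))) {
    chunks <- path_chunks(store, grp[1])
    dirs <- chunks[-length(chunks)]
    dir <- chunk_dir(store, dirs)
    path <- file.path(dir, paste0(
      chunk_hex(chunks[length(chunks)], store$branchfactor), ".block"))
    edit(dir, path, grp)
    chains[[paste(dirs, collapse = "/")]] <- dirs
  }
  for (dirs in chains) update_node_chain(store, dirs)
  invisible(store)
}

#' Insert events into a store
#'
#' Places each position in its block file (sorted, deduplicated), creating
#' directories on demand, and refreshes the node-file chain up to the root.
#' Inserting an existing position is a no-op (idempotent).
#'
#' @param store a `tslod_events` store.
#' @param pos positions to insert (vectorized).
#' @return The store, invisibly.
#' @export
insert_events <- function(store, pos) {
  stopifnot(inherits(store, "tslod_events"))
  edit_blocks(store, pos, function(dir, path, grp) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    old <- if (file.exists(path)) read_u64(path) else numeric(0)
    merged <- sort(unique(c(old, grp)))
    if (!identical(merged, old)) write_u64(merged, path)
  })
}

#' Delete events from a store
#'
#' Removes positions from their block files, deletes block files, node files
#' and directories that become empty, and refreshes the node chain. Deleting
#' an absent position is a no-op (idempotent).
#'
#' @inheritParams insert_events
#' @return The store, invisibly.
#' @export
delete_events <- function(store, pos) {
  stopifnot(inherits(store, "tslod_events"))
  edit_blocks(store, pos, function(dir, path, grp) {
    if (!file.exists(path)) return()
    old <- read_u64(path)
    kept <- old[!(old %in% grp)]
    if (length(kept) == 0L) {
      unlink(path)
    } else if (length(kept) != length(old)) {
      write_u64(kept, path)
    }
  })
}

#' Export all events of a store
#'
#' @param store a `tslod_events` store.
#' @return Sorted numeric vector of all stored positions.
#' @export
export_events <- function(store) {
  stopifnot(inherits(store, "tslod_events"))
  blocks <- list.files(store$root, pattern = "\\.block$",
                       recursive = TRUE, full.names = TRUE)
  out <- unlist(lapply(blocks, read_u64), use.names = FALSE)
  if (is.null(out)) numeric(0) else sort(out)
}

#' Query events in a range at a reduction factor
#'
#' Walks the directory tree at the level whose node files are just below the
#' requested reduction factor (`n = clamp(floor(log2(R) / r), 0, treedepth -
#' 1)`; level 0 reads the block files), reading only the files whose span
#' intersects the range, then applies the dynamic reduction: positions are
#' masked to the `2^floor(log2(R))` grid, deduplicated, and clipped to
#' `[begin, end)`.
#'
#' @param store a `tslod_events` store.
#' @param begin,end half-open query range.
#' @param factor requested reduction factor R (samples per display element),
#'   `>= 1`; `R = 1` returns the stored events unreduced.
#' @return A `tslod_display` tibble of event marks with columns `kind`
#'   (`"event"`), `pos`, `pos_lo`, `pos_hi`, `x`; attribute `stats` records
#'   `files_opened`, `entries_read` and the traversal `level`.
#' @export
query_events <- function(store, begin, end, factor = 1) {
  stopifnot(inherits(store, "tslod_events"), begin < end, factor >= 1)
  assert_position(begin, "begin")
  zb <- floor(log2(factor))
  r <- store$branchfactor
  n_lvl <- min(max(floor(zb / r), 0), store$treedepth - 1)
  span <- 2^(store$blockfactor + n_lvl * r)
  ## when the dynamic grid is coarser than the file span, a mark's source
  ## entries can sit one grid cell beyond the range
  scan_end <- if (2^zb > span) end + 2^zb else end
  s0 <- floor(begin / span)
  s1 <- floor((scan_end - 1) / span)
  opened <- 0L
  read <- 0
  hits <- list()
  for (s in seq(s0, s1)) {
    base <- s * span
    chunks <- path_chunks(store, base)
    if (n_lvl == 0L) {
      dir <- chunk_dir(store, chunks[-length(chunks)])
      path <- file.path(dir, paste0(
        chunk_hex(chunks[length(chunks)], r), ".block"))
    } else {
      d <- store$treedepth - n_lvl
      dir <- chunk_dir(store, chunks[seq_len(d - 1L)])
      path <- file.path(dir, paste0(chunk_hex(chunks[d], r), ".node"))
    }
    if (file.exists(path)) {
      e <- read_u64(path)
      opened <- opened + 1L
      read <- read + length(e)
      hits[[length(hits) + 1L]] <- e
    }
  }
  pos <- reduce_events(unlist(hits, use.names = FALSE), zb)
  pos <- pos[pos >= begin & pos < end]
  out <- new_display_list(
    tibble::tibble(kind = "event", pos = pos, pos_lo = pos,
                   pos_hi = pos, x = pos),
    begin, end, factor,
    list(files_opened = opened, entries_read = read, level = n_lvl,
         requested_factor = factor, path_depth = store$treedepth - n_lvl))
  out
}
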