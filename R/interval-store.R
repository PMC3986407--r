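## Interval annotation store: (begin, end) pairs of 64-bit sample positions,
## begin <= end, overlap allowed.  Intervals contained in one leaf block span
## live in that leaf block file; longer intervals live in a high-level block
## file located by the chunk-aligned common bit prefix of begin and end, and
## are combined with the node files at their level when node files above are
## built.  Duplicate (begin, end) pairs are stored once (set semantics).

#' Open or create an interval store
#'
#' @inheritParams event_store
#' @return A `tslod_intervals` store handle.
#' @export
interval_store <- function(root, blockfactor = 20, branchfactor = 4) {
  open_store(root, "intervals", blockfactor, branchfactor)
}

#' Home file of an interval
#'
#' An interval whose begin and end fall in the same leaf block span lives in
#' that leaf block file. Otherwise the common most-significant bit prefix of
#' begin and end (within the `64 - B` path bits) is trimmed down to a whole
#' number of `r`-bit chunks, `d = floor(p / r)`, and the interval lives in
#' the high-level block file of the depth-`d` node (named
#' `"<chunk_d>.block"` beside that node's `"<chunk_d>.node"`; at depth 0 the
#' file `"root.block"` in the store root).
#'
#' @param store a `tslod_intervals` store (or [tree_config()]-like list).
#' @param begin,end interval endpoints, `begin <= end` (inclusive).
#' @return A list with `depth` (`treedepth` for a leaf block), `dirs`
#'   (character vector of directory components) and `file` (block file
#'   name).
#' @export
home_for_interval <- function(store, begin, end) {
  assert_position(begin, "begin")
  assert_position(end, "end")
  if (begin > end) stop("interval must satisfy begin <= end", call. = FALSE)
  r <- store$branchfactor
  if (floor(begin / 2^store$blockfactor) ==
      floor(end / 2^store$blockfactor)) {
    chunks <- path_chunks(store, begin)
    d <- store$treedepth
  } else {
    cb <- path_chunks(store, begin)
    ce <- path_chunks(store, end)
    d <- 0L
    while (d < store$treedepth && cb[d + 1L] == ce[d + 1L]) d <- d + 1L
    chunks <- cb
  }
  if (d == 0L) {
    list(depth = 0L, dirs = character(0), file = "root.block")
  } else {
    list(depth = d,
         dirs = if (d > 1L) chunk_hex(chunks[seq_len(d - 1L)], r)
                else character(0),
         file = paste0(chunk_hex(chunks[d], r), ".block"),
         chunks = chunks[seq_len(d - 1L)])
  }
}

## group records by home file; `edit(dir, path, begin, end)` performs the
## file update, then the node chain above each touched home is refreshed
edit_interval_homes <- function(store, begin, end, edit) {
  stopifnot(length(begin) == length(end))
  keys <- character(length(begin))
  homes <- vector("list", length(begin))
  for (i in seq_along(begin)) {
    h <- home_for_interval(store, begin[i], end[i])
    homes[[i]] <- h
    keys[i] <- paste(c(h$dirs, h$file), collapse = "/")
  }
  for (key in unique(keys)) {
    sel <- which(keys == key)
    h <- homes[[sel[1]]]
    dir <- chunk_dir_hex(store, h$dirs)
    edit(dir, file.path(dir, h$file), begin[sel], end[sel])
    if (h$depth > 0L) {
      update_node_chain(store,
                        path_chunks(store, begin[sel[1]])[
                          seq_len(h$depth - 1L)])
    }
  }
  invisible(store)
}

chunk_dir_hex <- function(store, hex_dirs) {
  if (length(hex_dirs) == 0L) return(store$root)
  do.call(file.path, as.list(c(store$root, hex_dirs)))
}

#' Insert intervals into a store
#'
#' Appends each `(begin, end)` record to its home file (kept sorted by
#' `(begin, end)` with set semantics), creating directories on demand, and
#' refreshes the node chain above. Re-inserting an existing record is a
#' no-op.
#'
#' @param store a `tslod_intervals` store.
#' @param begin,end numeric vectors of interval endpoints (inclusive,
#'   `begin <= end`).
#' @return The store, invisibly.
#' @export
insert_intervals <- function(store, begin, end) {
  stopifnot(inherits(store, "tslod_intervals"))
  if (any(begin > end)) stop("interval must satisfy begin <= end",
                             call. = FALSE)
  edit_interval_homes(store, begin, end, function(dir, path, b, e) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    old <- if (file.exists(path)) read_entry_file(store, path) else
      entries_empty(store)
    merged <- entries_reduce(
      store, list(begin = c(old$begin, b), end = c(old$end, e)), 0)
    if (!entries_identical(store, merged, old)) {
      write_entry_file(store, merged, path)
    }
  })
}

#' Delete intervals from a store
#'
#' Removes records from their home files, pruning files and directories that
#' become empty and refreshing the node chain. Deleting a record that is not
#' stored is a no-op with a warning.
#'
#' @inheritParams insert_intervals
#' @return The store, invisibly.
#' @export
delete_intervals <- function(store, begin, end) {
  stopifnot(inherits(store, "tslod_intervals"))
  if (any(begin > end)) stop("interval must satisfy begin <= end",
                             call. = FALSE)
  edit_interval_homes(store, begin, end, function(dir, path, b, e) {
    old <- if (file.exists(path)) read_entry_file(store, path) else
      entries_empty(store)
    drop <- paste(old$begin, old$end) %in% paste(b, e)
    missing <- !(paste(b, e) %in% paste(old$begin, old$end))
    if (any(missing)) {
      warning(sprintf("%d interval(s) not found in store", sum(missing)),
              call. = FALSE)
    }
    kept <- list(begin = old$begin[!drop], end = old$end[!drop])
    if (length(kept$begin) == 0L) {
      if (file.exists(path)) unlink(path)
    } else if (any(drop)) {
      write_entry_file(store, kept, path)
    }
  })
}

#' Export all intervals of a store
#'
#' @param store a `tslod_intervals` store.
#' @return A tibble with columns `begin`, `end`, sorted by `(begin, end)`.
#' @export
export_intervals <- function(store) {
  stopifnot(inherits(store, "tslod_intervals"))
  blocks <- list.files(store$root, pattern = "\\.block$",
                       recursive = TRUE, full.names = TRUE)
  e <- entries_reduce(
    store,
    entries_concat(store, lapply(blocks, read_entry_file, store = store)),
    0)
  tibble::tibble(begin = e$begin, end = e$end)
}

#' Reduce intervals onto a coarser grid
#'
#' Masks the low `zero_bits` bits of both endpoints (pure bit-chop, rounding
#' down); an interval whose endpoints collapse onto the same value becomes a
#' line proxy. Duplicates created by the reduction are removed.
#'
#' @param intervals data frame with columns `begin` and `end`.
#' @param zero_bits number of low bits to clear.
#' @return A tibble with columns `kind` (`"box"` or `"line"`), `begin`,
#'   `end`, sorted by `(begin, end)`.
#' @export
reduce_intervals <- function(intervals, zero_bits) {
  e <- entries_reduce(
    list(kind = "intervals"),
    list(begin = intervals$begin, end = intervals$end), zero_bits)
  tibble::tibble(kind = as.character(ifelse(e$begin == e$end,
                                            "line", "box")),
                 begin = e$begin, end = e$end)
}

#' Query intervals intersecting a range at a reduction factor
#'
#' Descends the directory tree toward the range, pushing the intervals of
#' every high-level block file along the way onto a stack, then reads the
#' node or block files at the traversal level matching `factor`
#' (`n = clamp(floor(log2(R) / r), 0, treedepth - 1)`). All collected
#' records are dynamically reduced onto the `2^floor(log2(R))` grid
#' ([reduce_intervals()]); records whose reduced form intersects
#' `[begin, end)` are returned deduplicated. The stack grows with the number
#' of overlapping long-range intervals on the path (worst case: all of
#' them), but traversal remains streaming — no quadratic blow-up beyond the
#' stack itself.
#'
#' @param store a `tslod_intervals` store.
#' @param begin,end half-open query range.
#' @param factor requested reduction factor R, `>= 1`.
#' @return A `tslod_display` tibble with columns `kind` (`"box"` or
#'   `"line"`), `begin`, `end`, `pos_lo`, `pos_hi`, `x`; attribute `stats`
#'   records `files_opened`, `entries_read`, traversal `level` and
#'   `stack_size` (records collected from high-level blocks above the
#'   traversal level).
#' @export
query_intervals <- function(store, begin, end, factor = 1) {
  stopifnot(inherits(store, "tslod_intervals"), begin < end, factor >= 1)
  assert_position(begin, "begin")
  zb <- floor(log2(factor))
  r <- store$branchfactor
  n_lvl <- min(max(floor(zb / r), 0), store$treedepth - 1)
  d_target <- store$treedepth - n_lvl
  scan_end <- end + 2^zb            # masked coordinates can trail the raw ones
  opened <- 0L
  read <- 0
  stack <- 0
  acc <- list()
  grab <- function(path, stacked = FALSE) {
    if (!file.exists(path)) return()
    e <- read_entry_file(store, path)
    opened <<- opened + 1L
    read <<- read + length(e$begin)
    if (stacked) stack <<- stack + length(e$begin)
    acc[[length(acc) + 1L]] <<- e
  }
  grab(file.path(store$root, "root.block"), stacked = d_target > 0L)

  descend <- function(dir, depth, base) {
    child_span <- 2^(64 - (depth + 1L) * r)
    c_lo <- max(0, floor((begin - base) / child_span))
    c_hi <- min(2^r - 1, floor((scan_end - 1 - base) / child_span))
    if (c_hi < c_lo) return()
    for (ch in seq(c_lo, c_hi)) {
      hx <- chunk_hex(ch, r)
      if (depth + 1L == d_target) {
        grab(file.path(dir, paste0(hx, ".block")))
        if (n_lvl > 0L) grab(file.path(dir, paste0(hx, ".node")))
      } else {
        grab(file.path(dir, paste0(hx, ".block")), stacked = TRUE)
        sub <- file.path(dir, hx)
        if (dir.exists(sub)) {
          descend(sub, depth + 1L, base + ch * child_span)
        }
      }
    }
  }
  descend(store$root, 0L, 0)

  e <- entries_reduce(store, entries_concat(store, acc), zb)
  keep <- e$begin < end & e$end >= begin
  b <- e$begin[keep]
  nd <- e$end[keep]
  new_display_list(
    tibble::tibble(kind = as.character(ifelse(b == nd, "line", "box")),
                   begin = b, end = nd,
                   pos_lo = b, pos_hi = nd, x = (b + nd) / 2),
    begin, end, factor,
    list(files_opened = opened, entries_read = read, level = n_lvl,
         stack_size = stack, requested_factor = factor,
         path_depth = d_target))
}

## every stored record must live in exactly the home file its endpoints
## dictate; events analogously must live in the block file of their position
verify_placement <- function(store) {
  issues <- list()
  blocks <- list.files(store$root, pattern = "\\.block$",
                       recursive = TRUE, full.names = FALSE)
  for (rel in blocks) {
    path <- file.path(store$root, rel)
    e <- read_entry_file(store, path)
    if (store$kind == "events") {
      comp <- strsplit(rel, "/", fixed = TRUE)[[1]]
      comp[length(comp)] <- sub("\\.block$", "", comp[length(comp)])
      chunks <- strtoi(comp, 16L)
      if (length(comp) != store$treedepth || anyNA(chunks)) {
        issues[[length(issues) + 1L]] <- tibble::tibble(
          issue = "event block file at wrong tree depth", path = path)
        next
      }
      base_block <- sum(chunks *
                          2^(64 - seq_along(chunks) * store$branchfactor)) /
        2^store$blockfactor
      bad <- floor(e / 2^store$blockfactor) != base_block
      if (any(bad)) {
        issues[[length(issues) + 1L]] <- tibble::tibble(
          issue = sprintf("%d event(s) outside the block file span",
                          sum(bad)),
          path = path)
      }
    } else {
      if (any(e$begin > e$end)) {
        issues[[length(issues) + 1L]] <- tibble::tibble(
          issue = "interval with begin > end", path = path)
      }
      for (i in seq_along(e$begin)) {
        h <- home_for_interval(store, e$begin[i], e$end[i])
        want <- paste(c(h$dirs, h$file), collapse = "/")
        if (want != rel) {
          issues[[length(issues) + 1L]] <- tibble::tibble(
            issue = sprintf("interval (%.0f, %.0f) misplaced (expected %s)",
                            e$begin[i], e$end[i], want),
            path = path)
        }
      }
    }
  }
  issues
}
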