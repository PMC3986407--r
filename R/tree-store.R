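## Sparse directory-tree stores for annotations.
##
## A 64-bit sample position splits into a path section (the high 64 - B bits,
## cut most-significant-first into chunks of r bits, each printed as
## lower-case hex) and a block section (the low B bits).  The first
## treedepth - 1 chunks name nested directories, the last chunk names the
## block file, so treedepth = (64 - B) / r path components address a leaf
## block spanning 2^B sample positions.  Every directory is summarised by a
## node file in its parent: the union of all entries below with the low
## (treedepth - depth) * r bits zeroed and duplicates removed, giving a
## level-n node file (span 2^(B + n*r)) the same maximal entry count as a
## block file.  Directories, block files and node files exist only on
## demand.

TREE_FORMAT <- "tslod-tree-1"

#' Directory-tree geometry for annotation stores
#'
#' @param blockfactor B, number of low position bits spanned by one block
#'   file; a block file covers `2^B` sample positions.
#' @param branchfactor r, bits per directory path chunk; a directory has at
#'   most `2^r` subdirectories.
#' @return A list with `blockfactor`, `branchfactor` and the derived
#'   `treedepth = (64 - B) / r` (total path components). `64 - B` must be a
#'   positive multiple of `r`.
#' @export
tree_config <- function(blockfactor = 20, branchfactor = 4) {
  b <- as.numeric(blockfactor)
  r <- as.numeric(branchfactor)
  if (!(b == floor(b) && b >= 1 && b <= 62)) {
    stop("blockfactor must be an integer in [1, 62]", call. = FALSE)
  }
  if (!(r == floor(r) && r >= 1 && r <= 24)) {
    stop("branchfactor must be an integer in [1, 24]", call. = FALSE)
  }
  if ((64 - b) %% r != 0) {
    stop("64 - blockfactor must be a multiple of branchfactor", call. = FALSE)
  }
  list(blockfactor = b, branchfactor = r, treedepth = (64 - b) / r)
}

open_store <- function(root, kind, blockfactor, branchfactor) {
  meta_path <- file.path(root, "store.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!identical(meta$format, TREE_FORMAT) || !identical(meta$kind, kind)) {
      stop(sprintf("%s is not a %s store", root, kind), call. = FALSE)
    }
    cfg <- tree_config(meta$blockfactor, meta$branchfactor)
  } else {
    cfg <- tree_config(blockfactor, branchfactor)
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(format = TREE_FORMAT, kind = kind,
           blockfactor = cfg$blockfactor, branchfactor = cfg$branchfactor),
      meta_path, auto_unbox = TRUE)
  }
  structure(
    c(list(root = normalizePath(root), kind = kind), cfg),
    class = c(paste0("tslod_", kind), "tslod_store"))
}

#' @export
print.tslod_store <- function(x, ...) {
  cat(sprintf("<tslod_%s> B=%d r=%d treedepth=%d root=%s\n",
              x$kind, x$blockfactor, x$branchfactor, x$treedepth, x$root))
  invisible(x)
}

## all treedepth path chunks of one position
path_chunks <- function(store, pos) {
  vapply(seq_len(store$treedepth),
         function(i) pos_chunk(pos, i, store$branchfactor), numeric(1))
}

## directory of the store addressed by a chunk prefix (possibly empty)
chunk_dir <- function(store, chunks) {
  if (length(chunks) == 0L) return(store$root)
  do.call(file.path,
          as.list(c(store$root, chunk_hex(chunks, store$branchfactor))))
}

#' Path components of the block file holding an event position
#'
#' Splits the high `64 - B` bits of `pos` most-significant-first into
#' `treedepth` chunks of `r` bits: the first `treedepth - 1` chunks name
#' nested directories (lower-case hex), the last names the block file.
#'
#' @param store an annotation store or a [tree_config()] list.
#' @param pos sample position.
#' @return Character vector of `treedepth` components; the last one is
#'   `"<hex>.block"`.
#' @export
path_for_event <- function(store, pos) {
  assert_position(pos, "pos")
  chunks <- vapply(seq_len(store$treedepth),
                   function(i) pos_chunk(pos, i, store$branchfactor),
                   numeric(1))
  hx <- chunk_hex(chunks, store$branchfactor)
  c(hx[-length(hx)], paste0(hx[length(hx)], ".block"))
}

## ---- entry file I/O (dispatch on store kind) ----------------------------

read_entry_file <- function(store, path) {
  x <- read_u64(path)
  if (store$kind == "events") return(x)
  if (length(x) %% 2 != 0) stop("corrupt interval file: ", path, call. = FALSE)
  list(begin = x[c(TRUE, FALSE)], end = x[c(FALSE, TRUE)])
}

write_entry_file <- function(store, entries, path) {
  if (store$kind == "events") {
    write_u64(entries, path)
  } else {
    write_u64(as.numeric(rbind(entries$begin, entries$end)), path)
  }
}

entries_empty <- function(store) {
  if (store$kind == "events") numeric(0) else
    list(begin = numeric(0), end = numeric(0))
}

entries_concat <- function(store, lst) {
  if (store$kind == "events") {
    if (length(lst) == 0L) numeric(0) else unlist(lst, use.names = FALSE)
  } else {
    b <- unlist(lapply(lst, `[[`, "begin"), use.names = FALSE)
    e <- unlist(lapply(lst, `[[`, "end"), use.names = FALSE)
    list(begin = if (is.null(b)) numeric(0) else b,
         end = if (is.null(e)) numeric(0) else e)
  }
}

entries_n <- function(store, e) {
  if (store$kind == "events") length(e) else length(e$begin)
}

## absolute reduction to a zero_bits grid, deduplicated and sorted
entries_reduce <- function(store, e, zero_bits) {
  if (store$kind == "events") {
    reduce_events(e, zero_bits)
  } else {
    if (length(e$begin) == 0L) {
      return(list(begin = numeric(0), end = numeric(0)))
    }
    b <- mask_low_bits(e$begin, zero_bits)
    nd <- mask_low_bits(e$end, zero_bits)
    o <- order(b, nd)
    b <- b[o]; nd <- nd[o]
    keep <- c(TRUE, b[-1] != b[-length(b)] | nd[-1] != nd[-length(nd)])
    if (length(b) == 0L) keep <- logical(0)
    list(begin = b[keep], end = nd[keep])
  }
}

entries_identical <- function(store, a, b) {
  if (store$kind == "events") identical(a, b) else
    identical(a$begin, b$begin) && identical(a$end, b$end)
}

## content files of one directory: every *.block and *.node directly inside
dir_entry_files <- function(dir) {
  list.files(dir, pattern = "\\.(block|node)$", full.names = TRUE)
}

dir_is_empty <- function(dir) {
  length(list.files(dir, all.files = TRUE, no.. = TRUE)) == 0L
}

## Recompute the node-file chain along one chunk path after an edit at its
## bottom.  dir_chunks addresses the deepest affected directory; node files
## are refreshed from that directory up to the root, stopping early when a
## recomputed node is identical to the stored one (ancestors then cannot
## change).  Empty directories and node files are pruned on the way up.
update_node_chain <- function(store, dir_chunks) {
  for (d in rev(seq_along(dir_chunks))) {
    dir <- chunk_dir(store, dir_chunks[seq_len(d)])
    parent <- chunk_dir(store, dir_chunks[seq_len(d - 1L)])
    node_path <- file.path(parent, paste0(
      chunk_hex(dir_chunks[d], store$branchfactor), ".node"))
    zero_bits <- (store$treedepth - d) * store$branchfactor
    content <- entries_empty(store)
    if (dir.exists(dir)) {
      files <- dir_entry_files(dir)
      if (length(files)) {
        content <- entries_reduce(
          store,
          entries_concat(store, lapply(files, read_entry_file,
                                       store = store)),
          zero_bits)
      }
    }
    changed <- FALSE
    if (entries_n(store, content) == 0L) {
      if (file.exists(node_path)) {
        unlink(node_path)
        changed <- TRUE
      }
      if (dir.exists(dir) && dir_is_empty(dir)) {
        unlink(dir, recursive = TRUE)
        changed <- TRUE
      }
    } else {
      old <- if (file.exists(node_path)) {
        read_entry_file(store, node_path)
      } else NULL
      if (is.null(old) || !entries_identical(store, old, content)) {
        write_entry_file(store, content, node_path)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  invisible(store)
}

## Bottom-up verification: recompute every node file from the block files
## only, independent of the incremental maintenance path.
verify_walk <- function(store, dir, depth, issues) {
  subdirs <- list.dirs(dir, full.names = FALSE, recursive = FALSE)
  files <- list.files(dir, full.names = FALSE)
  blocks <- files[grepl("\\.block$", files)]
  nodes <- files[grepl("\\.node$", files)]
  acc <- list()
  for (bf in blocks) {
    e <- read_entry_file(store, file.path(dir, bf))
    if (entries_n(store, e) == 0L) {
      issues[[length(issues) + 1L]] <-
        tibble::tibble(issue = "empty block file",
                       path = file.path(dir, bf))
    }
    red <- entries_reduce(store, e, 0)
    if (!entries_identical(store, red, e)) {
      issues[[length(issues) + 1L]] <-
        tibble::tibble(issue = "block file not sorted/deduplicated",
                       path = file.path(dir, bf))
    }
    acc[[length(acc) + 1L]] <- e
  }
  for (sd in subdirs) {
    res <- verify_walk(store, file.path(dir, sd), depth + 1L, issues)
    issues <- res$issues
    node_path <- file.path(dir, paste0(sd, ".node"))
    if (!file.exists(node_path)) {
      issues[[length(issues) + 1L]] <-
        tibble::tibble(issue = "missing node file", path = node_path)
    } else {
      stored <- read_entry_file(store, node_path)
      if (!entries_identical(store, stored, res$expected)) {
        issues[[length(issues) + 1L]] <-
          tibble::tibble(issue = "node file does not match subtree",
                         path = node_path)
      }
    }
    acc[[length(acc) + 1L]] <- res$expected
  }
  for (nf in nodes) {
    if (!(sub("\\.node$", "", nf) %in% subdirs)) {
      issues[[length(issues) + 1L]] <-
        tibble::tibble(issue = "orphan node file (no such subdirectory)",
                       path = file.path(dir, nf))
    }
  }
  zero_bits <- (store$treedepth - depth) * store$branchfactor
  expected <- entries_reduce(store, entries_concat(store, acc), zero_bits)
  list(expected = expected, issues = issues)
}

#' Verify the internal consistency of an annotation store
#'
#' Recomputes every node file bottom-up from the block files alone and
#' reports node files that disagree with their subtree, orphan node files,
#' empty block files, and unsorted or duplicated entries. For interval
#' stores, record placement (leaf versus high-level block) and `begin <=
#' end` are also checked.
#'
#' @param store an event or interval store.
#' @return A tibble of issues with columns `issue` and `path`; zero rows
#'   means the store is consistent.
#' @export
verify_store <- function(store) {
  stopifnot(inherits(store, "tslod_store"))
  issues <- verify_placement(store)
  res <- verify_walk(store, store$root, 0L, issues)
  if (length(res$issues) == 0L) {
    return(tibble::tibble(issue = character(0), path = character(0)))
  }
  dplyr::bind_rows(res$issues)
}
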