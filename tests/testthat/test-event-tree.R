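test_that("tree geometry follows (64 - B) / r and validates divisibility", {
  cfg <- tree_config(20, 4)
  expect_equal(cfg$treedepth, 11)
  expect_equal(tree_config(16, 8)$treedepth, 6)
  expect_error(tree_config(20, 7), "multiple")
  expect_error(tree_config(0, 4), "blockfactor")
  # a block file spans 2^B positions; a directory fans out to 2^r children
  expect_equal(2^cfg$blockfactor, 1048576)
  expect_equal(2^cfg$branchfactor, 16)
})

test_that("event paths decompose the high bits most-significant-first", {
  st <- tmp_event_store(blockfactor = 20, branchfactor = 4)
  expect_equal(path_for_event(st, 0),
               c(rep("0", 10), "0.block"))
  # 0x123456789: high 44 bits are 0x00000001234
  expect_equal(path_for_event(st, 0x123456789),
               c("0", "0", "0", "0", "0", "0", "0", "1", "2", "3",
                 "4.block"))
  expect_length(path_for_event(st, 0x123456789), 11)
  # oracle: rebuild the position's high bits from the path components
  for (pos in c(7, 2^20, 2^20 + 5, 0xabcdef01234, 2^52 + 12345)) {
    comp <- path_for_event(st, pos)
    comp[11] <- sub("\\.block$", "", comp[11])
    chunks <- strtoi(comp, 16L)
    expect_equal(sum(chunks * 2^(64 - (1:11) * 4)),
                 mask_low_bits(pos, 20))
  }
})

test_that("reduce_events zeroes low bits, deduplicates, sorts", {
  expect_equal(reduce_events(c(0x12345, 0x12346, 0x22222), 4),
               c(0x12340, 0x22220))
  x <- c(99, 5, 5, 7)
  expect_equal(reduce_events(x, 0), c(5, 7, 99))
  # all positions of one block span reduced by r bits leave 2^(B-r) values
  st <- tree_config(8, 2)
  expect_length(reduce_events(0:(2^8 - 1), 2), 2^(8 - 2))
})

test_that("insert/delete round-trips leave an empty store", {
  st <- tmp_event_store()
  insert_events(st, 123456789)
  expect_equal(export_events(st), 123456789)
  delete_events(st, 123456789)
  expect_equal(export_events(st), numeric(0))
  expect_equal(list.files(st$root, recursive = TRUE), "store.json")
  # deleting again is a silent no-op
  expect_silent(delete_events(st, 123456789))
})

test_that("neighbouring events share one block and its node chain", {
  st <- tmp_event_store(blockfactor = 20, branchfactor = 4)
  insert_events(st, c(0, 1))
  files <- list.files(st$root, recursive = TRUE)
  blocks <- files[grepl("\\.block$", files)]
  expect_equal(blocks, paste(c(rep("0", 10), "0.block"), collapse = "/"))
  # every node file on the path holds the single reduced value 0
  nodes <- files[grepl("\\.node$", files)]
  expect_length(nodes, 10)
  for (nf in nodes) {
    expect_equal(tslod:::read_u64(file.path(st$root, nf)), 0)
  }
  # duplicate insert leaves the block byte-identical
  block_path <- file.path(st$root, blocks)
  before <- readBin(block_path, "raw", 1e3)
  insert_events(st, 1)
  expect_identical(readBin(block_path, "raw", 1e3), before)
  expect_equal(nrow(verify_store(st)), 0)
})

test_that("node files mask exactly n*r bits per level", {
  st <- tmp_event_store(blockfactor = 8, branchfactor = 2)
  # two events in one block that coincide at level 2 but not at level 1:
  # they differ only within bits [r, 2r) = [2, 4)
  a <- 4
  b <- 8
  insert_events(st, c(a, b))
  nodes <- list.files(st$root, pattern = "\\.node$", recursive = TRUE,
                      full.names = TRUE)
  depth <- lengths(strsplit(sub(st$root, "", nodes, fixed = TRUE), "/"))
  expect_length(nodes, st$treedepth - 1)
  # level-1 node (masks r bits): both values survive
  expect_equal(tslod:::read_u64(nodes[which.max(depth)]), c(4, 8))
  # level-2 node (masks 2r bits): they collapse onto one representative
  expect_equal(tslod:::read_u64(nodes[order(depth, decreasing = TRUE)[2]]),
               0)
  # a single event leaves exactly one (masked) value in every path node
  st2 <- tmp_event_store(blockfactor = 8, branchfactor = 2)
  insert_events(st2, 0xabcdef)
  nodes2 <- list.files(st2$root, pattern = "\\.node$", recursive = TRUE,
                       full.names = TRUE)
  expect_length(nodes2, st2$treedepth - 1)
  for (nf in nodes2) expect_length(tslod:::read_u64(nf), 1)
  expect_equal(nrow(verify_store(st2)), 0)
})

test_that("dense events give the masked-grid counts and query marks", {
  n <- 2^12
  st <- tmp_event_store(blockfactor = 8, branchfactor = 2)
  insert_events(st, gen_dense_events(n))
  expect_equal(export_events(st), seq(0, n - 1))
  # query at R = 2^k returns marks on every 2^k-aligned position
  for (k in c(0, 1, 3, 5)) {
    q <- query_events(st, 0, n, 2^k)
    expect_equal(q$pos, seq(0, n - 1, by = 2^k))
  }
  # fully dense data saturates every level-1 node at 2^B entries — the same
  # maximal density as a block file
  nodes <- list.files(st$root, pattern = "\\.node$", recursive = TRUE,
                      full.names = TRUE)
  depth <- lengths(strsplit(sub(st$root, "", nodes, fixed = TRUE), "/"))
  l1 <- nodes[depth == max(depth)]
  expect_true(all(vapply(l1, function(f) length(tslod:::read_u64(f)),
                         numeric(1)) == 2^8))
  # density confined to a single block span: its level-1 node reduces the
  # 2^B events to 2^(B-r) masked values
  st1 <- tmp_event_store(blockfactor = 8, branchfactor = 2)
  insert_events(st1, gen_dense_events(2^8))
  nodes1 <- list.files(st1$root, pattern = "\\.node$", recursive = TRUE,
                       full.names = TRUE)
  depth1 <- lengths(strsplit(sub(st1$root, "", nodes1, fixed = TRUE), "/"))
  expect_equal(length(tslod:::read_u64(nodes1[which.max(depth1)])),
               2^(8 - 2))
})

test_that("random stores match the flat-list oracle at any factor", {
  set.seed(77)
  st <- tmp_event_store(blockfactor = 12, branchfactor = 4)
  all_pos <- sort(unique(floor(stats::runif(2000, 0, 2^26))))
  insert_events(st, all_pos)
  expect_equal(export_events(st), all_pos)
  for (case in seq_len(80)) {
    begin <- floor(stats::runif(1, 0, 2^26 - 2))
    end <- begin + max(1, floor(stats::runif(1, 1, 2^26 - begin)))
    r_req <- sample(c(1, 2, 7, 64, 1000, 2^13, 2^20), 1)
    q <- query_events(st, begin, end, r_req)
    expect_equal(q$pos, oracle_events(all_pos, begin, end, r_req))
  }
})

test_that("interleaved edits keep every node consistent with its subtree", {
  set.seed(88)
  st <- tmp_event_store(blockfactor = 12, branchfactor = 4)
  live <- numeric(0)
  for (op in seq_len(300)) {
    if (length(live) > 0 && stats::runif(1) < 0.4) {
      p <- sample(live, 1)
      delete_events(st, p)
      live <- setdiff(live, p)
    } else {
      p <- floor(stats::runif(1, 0, 2^24))
      insert_events(st, p)
      live <- union(live, p)
    }
  }
  expect_equal(export_events(st), sort(unique(live)))
  expect_equal(nrow(verify_store(st)), 0)
})

test_that("verify flags a corrupted node file", {
  st <- tmp_event_store(blockfactor = 12, branchfactor = 4)
  insert_events(st, c(100, 2^20))
  nodes <- list.files(st$root, pattern = "\\.node$", recursive = TRUE,
                      full.names = TRUE)
  tslod:::write_u64(c(1, 2, 3), nodes[1])
  issues <- verify_store(st)
  expect_gt(nrow(issues), 0)
  expect_true(any(grepl("node file", issues$issue)))
})

test_that("queries open few files regardless of store size", {
  st <- tmp_event_store(blockfactor = 8, branchfactor = 2)
  insert_events(st, gen_dense_events(2^13))
  for (r_req in c(2, 2^4, 2^8)) {
    q <- query_events(st, 0, 2^12, r_req)
    stats <- attr(q, "stats")
    spans <- 2^12 / 2^(8 + stats$level * 2)
    expect_lte(stats$files_opened, max(1, spans) + st$treedepth)
  }
})
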