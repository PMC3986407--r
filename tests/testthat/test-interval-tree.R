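test_that("home_for_interval follows the chunk-aligned common prefix", {
  st <- tmp_interval_store(blockfactor = 20, branchfactor = 4)
  # degenerate and block-local intervals live in the leaf block
  h <- home_for_interval(st, 5, 5)
  expect_equal(h$depth, st$treedepth)
  expect_equal(h$file, "0.block")
  h2 <- home_for_interval(st, 2^20, 2^20 + 100)
  expect_equal(h2$depth, st$treedepth)
  # crossing a block boundary moves the record to a high-level block
  h3 <- home_for_interval(st, 2^20, 2^21)
  expect_lt(h3$depth, st$treedepth)
  expect_equal(h3$depth, 10)
  expect_equal(h3$file, "0.block")
  expect_length(h3$dirs, 9)
  # bit-prefix oracle: depth equals the number of leading equal r-bit
  # chunks within the 64 - B path bits
  set.seed(5)
  for (i in 1:50) {
    b <- floor(stats::runif(1, 0, 2^40))
    e <- b + floor(stats::runif(1, 0, 2^36))
    h <- home_for_interval(st, b, e)
    cb <- sapply(1:11, function(i) floor(b / 2^(64 - 4 * i)) %% 16)
    ce <- sapply(1:11, function(i) floor(e / 2^(64 - 4 * i)) %% 16)
    same_block <- floor(b / 2^20) == floor(e / 2^20)
    want <- if (same_block) 11 else {
      d <- 0
      while (cb[d + 1] == ce[d + 1]) d <- d + 1
      d
    }
    expect_equal(h$depth, want)
  }
  expect_error(home_for_interval(st, 10, 5), "begin <= end")
})

test_that("reduce_intervals collapses short intervals to lines", {
  out <- reduce_intervals(
    tibble::tibble(begin = c(0x100, 0x100), end = c(0x10F, 0x230)), 4)
  expect_equal(out$kind, c("line", "box"))
  expect_equal(out$begin, c(0x100, 0x100))
  expect_equal(out$end, c(0x100, 0x230))
  # zero bits: identity apart from set semantics
  df <- tibble::tibble(begin = c(7, 3, 3), end = c(9, 4, 4))
  out0 <- reduce_intervals(df, 0)
  expect_equal(out0$begin, c(3, 7))
  expect_equal(out0$end, c(4, 9))
  expect_true(all(out0$kind == "box"))
})

test_that("insert/delete round-trip leaves an empty store", {
  st <- tmp_interval_store()
  insert_intervals(st, 100, 5000)
  insert_intervals(st, 2^21, 2^23)      # high-level home
  expect_equal(nrow(export_intervals(st)), 2)
  delete_intervals(st, 100, 5000)
  delete_intervals(st, 2^21, 2^23)
  expect_equal(nrow(export_intervals(st)), 0)
  expect_equal(list.files(st$root, recursive = TRUE), "store.json")
  # duplicate insert is idempotent; deleting a missing record warns
  insert_intervals(st, 7, 9)
  insert_intervals(st, 7, 9)
  expect_equal(nrow(export_intervals(st)), 1)
  expect_warning(delete_intervals(st, 7, 8), "not found")
  expect_equal(nrow(export_intervals(st)), 1)
  expect_equal(nrow(verify_store(st)), 0)
})

test_that("lengthening an interval past the block span relocates its home", {
  st <- tmp_interval_store(blockfactor = 12, branchfactor = 4)
  b <- 5 * 2^12 + 17
  short_end <- 5 * 2^12 + 100
  long_end <- 9 * 2^12
  h_short <- home_for_interval(st, b, short_end)
  h_long <- home_for_interval(st, b, long_end)
  expect_equal(h_short$depth, st$treedepth)
  expect_lt(h_long$depth, st$treedepth)
  insert_intervals(st, b, short_end)
  path_short <- file.path(st$root,
                          paste(c(h_short$dirs, h_short$file), collapse = "/"))
  expect_true(file.exists(path_short))
  # editing = delete + insert with the new end; no stale copy remains
  delete_intervals(st, b, short_end)
  insert_intervals(st, b, long_end)
  expect_false(file.exists(path_short))
  path_long <- file.path(st$root,
                         paste(c(h_long$dirs, h_long$file), collapse = "/"))
  expect_true(file.exists(path_long))
  expect_equal(nrow(verify_store(st)), 0)
})

test_that("a covering interval is returned as exactly one box at any factor", {
  st <- tmp_interval_store(blockfactor = 12, branchfactor = 4)
  insert_intervals(st, 0, 2^30)
  for (r_req in c(1, 2^6, 2^13, 2^24)) {
    q <- query_intervals(st, 2^16, 2^20, r_req)
    expect_equal(nrow(q), 1)
    expect_equal(q$kind, "box")
    expect_lte(q$begin, 2^16)
    expect_gte(q$end, 2^20)
  }
})

test_that("stipple patterns collapse to grid lines at coarse factors", {
  st <- tmp_interval_store(blockfactor = 12, branchfactor = 4)
  iv <- gen_stipple_intervals(4, 64)      # length-16 intervals, period 32
  insert_intervals(st, iv$begin, iv$end)
  # coarser than the stipple period: every interval collapses to a line on
  # the masked grid, exactly as the closed-form mask predicts
  q <- query_intervals(st, 0, 64 * 32, 2^6)
  expect_true(all(q$kind == "line"))
  expect_equal(q$begin, sort(unique(mask_low_bits(iv$begin, 6))))
  # finer than one interval: boxes survive
  q2 <- query_intervals(st, 0, 64 * 32, 2)
  expect_true(all(q2$kind == "box"))
  expect_equal(nrow(q2), 64)
})

test_that("random stores match the flat-list oracle at any factor", {
  set.seed(99)
  st <- tmp_interval_store(blockfactor = 12, branchfactor = 4)
  n <- 400
  b <- floor(stats::runif(n, 0, 2^26))
  len <- floor(stats::rexp(n, rate = 1 / 2^12))
  df <- dplyr::distinct(tibble::tibble(begin = b, end = b + len))
  insert_intervals(st, df$begin, df$end)
  expect_equal(nrow(verify_store(st)), 0)
  for (case in seq_len(60)) {
    begin <- floor(stats::runif(1, 0, 2^26 - 2))
    end <- begin + max(1, floor(stats::runif(1, 1, 2^25)))
    r_req <- sample(c(1, 2, 7, 64, 1000, 2^13, 2^20), 1)
    q <- query_intervals(st, begin, end, r_req)
    want <- oracle_intervals(df, begin, end, r_req)
    expect_equal(q$kind, want$kind)
    expect_equal(q$begin, want$begin)
    expect_equal(q$end, want$end)
  }
})

test_that("interleaved edits keep homes and nodes consistent", {
  set.seed(101)
  st <- tmp_interval_store(blockfactor = 12, branchfactor = 4)
  live <- tibble::tibble(begin = numeric(0), end = numeric(0))
  for (op in seq_len(200)) {
    if (nrow(live) > 0 && stats::runif(1) < 0.4) {
      i <- sample(nrow(live), 1)
      delete_intervals(st, live$begin[i], live$end[i])
      live <- live[-i, ]
    } else {
      b <- floor(stats::runif(1, 0, 2^24))
      e <- b + floor(stats::rexp(1, rate = 1 / 2^14))
      if (!any(live$begin == b & live$end == e)) {
        insert_intervals(st, b, e)
        live <- dplyr::bind_rows(live, tibble::tibble(begin = b, end = e))
      }
    }
  }
  got <- export_intervals(st)
  live <- dplyr::arrange(live, begin, end)
  expect_equal(got$begin, live$begin)
  expect_equal(got$end, live$end)
  expect_equal(nrow(verify_store(st)), 0)
})

test_that("heavily overlapping intervals stream through the stack", {
  # adversarial case: many long intervals overlapping the same point; the
  # query must return them all (completeness) without losing records
  st <- tmp_interval_store(blockfactor = 12, branchfactor = 4)
  n <- 300
  b <- seq(0, n - 1) * 2^12
  e <- 2^26 + seq(0, n - 1) * 2^12
  insert_intervals(st, b, e)
  q <- query_intervals(st, 2^25, 2^25 + 10, 1)
  expect_equal(nrow(q), n)
  stats <- attr(q, "stats")
  expect_gte(stats$stack_size, 0)
  expect_equal(nrow(verify_store(st)), 0)
})
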