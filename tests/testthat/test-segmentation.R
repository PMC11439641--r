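test_that("overlapping segmentation yields exactly K in-range windows", {
  cfg <- window_config(window_length = 64L, k_fragments = 64L)
  set.seed(1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (L in c(1L, 2L, 63L, 64L, 65L, 127L, 128L, 640L, 2000L)) {
    s <- paste(sample(aa, L, replace = TRUE), collapse = "")
    fs <- segment_overlapping(s, cfg)
    expect_length(fs$fragments, 64L)
    tab <- fragment_table(fs)
    real <- tab[!tab$is_padding, ]
    # every real window lies inside [0, L) and has the right length
    expect_true(all(real$start >= 0L & real$end <= L))
    expect_true(all(real$end - real$start == pmin(64L, L)))
    # starts are non-decreasing and the last real window touches the end
    expect_true(all(diff(real$start) >= 0L))
    if (L > 64L) expect_identical(real$end[nrow(real)], L)
  }
})

test_that("overlapping stride follows the documented worked examples", {
  fs <- segment_overlapping(strrep("A", 10L),
                            window_config(window_length = 4L,
                                          k_fragments = 4L))
  tab <- fragment_table(fs)
  expect_identical(tab$start, c(0L, 2L, 4L, 6L))
  expect_identical(tab$end, c(4L, 6L, 8L, 10L))
  expect_false(any(tab$is_padding))

  # L = 640, l = 64, K = 64: stride ceil((640-64)/63) = 10, last start 576
  tab2 <- fragment_table(segment_overlapping(strrep("K", 640L),
                                             window_config()))
  expect_identical(tab2$start, pmin((0:63) * 10L, 576L))
  expect_identical(tab2$end[64L], 640L)
})

test_that("short sequences pad up to K fragments", {
  cfg <- window_config()
  fs <- segment_overlapping(strrep("A", 10L), cfg)   # L <= window length
  tab <- fragment_table(fs)
  expect_identical(sum(!tab$is_padding), 1L)
  expect_identical(sum(tab$is_padding), 63L)
  expect_identical(tab$start[1L], 0L)
  expect_identical(tab$end[1L], 10L)
})

test_that("non-overlapping windows are disjoint, ordered and tail-trimmed", {
  cfg <- window_config()
  fs <- segment_nonoverlapping(strrep("M", 200L), cfg)
  tab <- fragment_table(fs)
  # 200 = 3 * 64 + 8: the 8-residue tail meets min_fragment_length
  expect_identical(tab$start, c(0L, 64L, 128L, 192L))
  expect_identical(tab$end, c(64L, 128L, 192L, 200L))
  expect_true(all(tab$end[-nrow(tab)] == tab$start[-1L]))  # disjoint, ordered

  # a 7-residue tail is dropped
  tab2 <- fragment_table(segment_nonoverlapping(strrep("M", 199L), cfg))
  expect_identical(nrow(tab2), 3L)
  expect_identical(tab2$end[3L], 192L)
})

test_that("fragment offsets are 0-based half-open and recover the window", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  fs <- segment_overlapping(s, window_config(window_length = 8L,
                                             k_fragments = 3L))
  for (f in fs$fragments) {
    expect_identical(f$sequence, substr(s, f$start + 1L, f$end))
    expect_identical(nchar(f$sequence), f$end - f$start)
  }
})
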