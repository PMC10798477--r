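# CTM/BDM measures, normalization, and the rolling/overall profiles

test_that("bdm reduces to ctm for single-block strings", {
  tb <- tab()
  set.seed(21)
  for (L in 1:12) {
    bits <- random_bits(L)
    expect_identical(bdm(bits, 12, tb), ctm(bits, tb))
  }
})

test_that("bdm partitions, counts multiplicities, discards the remainder", {
  tb <- tab()
  # two identical blocks of 12: one distinct block with multiplicity 2
  s <- strrep("01", 12)
  expect_equal(bdm(s, 12, tb), ctm(substr(s, 1, 12), tb) + 1)
  # trailing remainder shorter than the block is ignored
  s13 <- paste0(strrep("0", 12), "1")
  expect_equal(bdm(s13, 12, tb), ctm(strrep("0", 12), tb))
  # distinct blocks add their own values
  s24 <- paste0(strrep("0", 12), strrep("01", 6))
  expect_equal(bdm(s24, 12, tb),
               ctm(strrep("0", 12), tb) + ctm(strrep("01", 6), tb))
  expect_error(bdm(integer(0), 12, tb), class = "randser_validation_error")
})

test_that("normalization maps constants to 0 and everything into [0,1]", {
  tb <- tab()
  # lengths 1-2 are degenerate in the packaged table (every output equally
  # frequent), and normalization refuses them; from length 3 on the
  # constant string anchors the scale at exactly 0
  expect_error(normalize_complexity(ctm(rep(0L, 2), tb), 2, table = tb),
               class = "randser_validation_error")
  for (L in 3:12) {
    expect_identical(normalize_complexity(ctm(rep(0L, L), tb), L, table = tb), 0)
    expect_identical(normalize_complexity(ctm(rep(1L, L), tb), L, table = tb), 0)
  }
  set.seed(22)
  for (i in 1:1000) {
    L <- sample(5:12, 1)
    v <- normalize_complexity(ctm(random_bits(L), tb), L, table = tb)
    expect_true(v >= 0 && v <= 1)
  }
  expect_error(normalize_complexity(1, 1, table = tb),
               class = "randser_validation_error")
})

test_that("overall complexity matches an independent re-implementation", {
  tb <- tab()
  expect_identical(overall_complexity(strrep("0", 120), tb), 0)
  set.seed(23)
  for (i in 1:20) {
    s <- bits_string(random_bits(120))
    expect_equal(overall_complexity(s, tb), naive_overall(s, tb),
                 tolerance = 1e-9)
  }
  expect_error(overall_complexity(strrep("01", 5), tb),
               class = "randser_validation_error")
})

test_that("disjoint chunk dialect averages floor(n/11) chunks", {
  tb <- tab()
  s <- bits_string(random_bits(40))                  # 3 disjoint chunks
  chunks <- vapply(0:2, function(i) substr(s, 11 * i + 1, 11 * i + 11),
                   character(1))
  manual <- mean(vapply(chunks, function(ch)
    naive_normalize(naive_ctm(ch, tb), 11, tb), numeric(1)))
  expect_equal(overall_complexity(s, tb, chunks = "disjoint"), manual,
               tolerance = 1e-12)
})

test_that("rolling profiles have the right geometry and invariances", {
  tb <- tab()
  ser <- binary_series(random_bits(120), "p1", "visible")
  prof <- rolling_complexity(ser, 7, tb)
  expect_length(prof$values, 114)
  expect_identical(prof$positions, 6:119)
  expect_true(all(prof$values >= 0 & prof$values <= 1))
  expect_identical(prof$condition, "visible")
  expect_false(is.na(prof$overall))
  # alternating series: every window is 0101... or 1010..., which the
  # table values cannot distinguish (complement symmetry)
  alt <- rolling_complexity(binary_series(strrep("01", 30)), 7, tb)
  expect_equal(diff(range(alt$values)), 0)
  # global complement leaves the whole profile unchanged
  bits <- random_bits(60)
  p1 <- rolling_complexity(binary_series(bits), 7, tb)
  p2 <- rolling_complexity(binary_series(1L - bits), 7, tb)
  expect_identical(p1$values, p2$values)
  expect_error(rolling_complexity(ser, 4, tb),
               class = "randser_validation_error")
  expect_error(rolling_complexity(ser, 10, tb),
               class = "randser_validation_error")
  short <- rolling_complexity(binary_series(random_bits(9)), 5, tb)
  expect_true(is.na(short$overall))
})

test_that("O/R letters transcode at the boundary", {
  expect_identical(as_binary_symbols("ORRRROR"),
                   c(0L, 1L, 1L, 1L, 1L, 0L, 1L))
  expect_identical(as_binary_symbols("ORRRROO"),
                   c(0L, 1L, 1L, 1L, 1L, 0L, 0L))
  expect_error(as_binary_symbols("01X"))
})

test_that("series and profile CSVs round-trip", {
  dir <- withr::local_tempdir()
  sl <- list(binary_series(random_bits(15), "a", "visible"),
             binary_series(random_bits(20), "b", "invisible"))
  f <- file.path(dir, "series.csv")
  write_series_csv(sl, f)
  back <- read_series_csv(f)
  expect_identical(back[["a"]]$symbols, sl[[1]]$symbols)
  expect_identical(back[["b"]]$symbols, sl[[2]]$symbols)
  expect_identical(back[["b"]]$condition, "invisible")
  profs <- lapply(sl, rolling_complexity, window_w = 5, table = tab())
  pf <- file.path(dir, "profiles.csv")
  write_profiles_csv(profs, pf)
  df <- read.csv(pf)
  expect_identical(nrow(df), 11L + 16L)
  expect_identical(df$position[1], 4L)      # 0-based window END index
})
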