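test_that("series constructors enforce their invariants", {
  expect_error(accel_series(numeric(0), numeric(0), numeric(0), numeric(0)),
               "empty-input")
  expect_error(accel_series(c(0, 1), 0, 0, 0), "lengths differ")
  expect_error(accel_series(c(1, 0), c(0, 0), c(0, 0), c(0, 0)), "ordering")
  expect_error(accel_series(c(0, 1), c(0, 9), c(0, 0), c(0, 0)), "8 g")
  # timestamps inside the +/- 30 min clock-drift slack are accepted
  ok <- accel_series(c(0, 86400 + 1700), c(1, 1), c(0, 0), c(0, 0))
  expect_s3_class(ok, "accel_series")
  expect_error(accel_series(c(0, 86400 + 1900), c(1, 1), c(0, 0), c(0, 0)),
               "slack")
  expect_error(baro_series(c(0, 1), c(1000, 700), c(290, 290)), "plausible")
})

test_that("write_day then read_day reproduces a recording to round-off", {
  set.seed(42)
  n <- 500
  acc <- accel_series((0:(n - 1)) / 50, rnorm(n, 1, 0.1), rnorm(n, 0, 0.1),
                      rnorm(n, 0, 0.1))
  bar <- make_baro(10, p = 1000 + cumsum(rnorm(50, 0, 0.01)))
  rec <- day_recording("S1", "2020-06-01", acc, bar, weight_kg = 63)
  dir <- withr::local_tempdir()
  paths <- day_paths(dir, "S1", "2020-06-01")
  write_day(rec, paths["acc"], paths["baro"])
  back <- suppressWarnings(read_day(paths["acc"], paths["baro"],
                                    subject_id = "S1", date = "2020-06-01",
                                    weight_kg = 63))
  for (f in c("t", "ax", "ay", "az"))
    expect_equal(back$accel[[f]], rec$accel[[f]], tolerance = 1e-9)
  for (f in c("t", "p", "temp"))
    expect_equal(back$baro[[f]], rec$baro[[f]], tolerance = 1e-9)
  expect_equal(attr(back, "dropped_rows"), 0)
})

test_that("read_day rejects malformed input and counts dropped rows", {
  dir <- withr::local_tempdir()
  acc_path <- file.path(dir, "a.csv"); baro_path <- file.path(dir, "b.csv")
  writeLines(c("t,ax,ay,az", "0,1,0,0", "0.02,NA,0,0", "0.04,1,0,0"), acc_path)
  writeLines(c("t,p,temp", "0,1000,290", "0.2,1000,290"), baro_path)
  rec <- suppressWarnings(read_day(acc_path, baro_path))
  expect_equal(attr(rec, "dropped_rows"), 1)

  writeLines(c("time,ax,ay,az", "0,1,0,0"), acc_path)
  expect_error(read_day(acc_path, baro_path), "format error")
  writeLines("t,ax,ay,az", acc_path)
  expect_error(read_day(acc_path, baro_path), "empty-input")
  writeLines(c("t,ax,ay,az", "1,1,0,0", "0.5,1,0,0"), acc_path)
  expect_error(read_day(acc_path, baro_path), "ordering")
})

test_that("write_day refuses empty series and warns on short coverage", {
  dir <- withr::local_tempdir()
  acc <- make_accel(60)                    # 1 min of data
  bar <- make_baro(60)
  rec <- day_recording("S1", "2020-06-01", acc, bar)
  paths <- day_paths(dir, "S1", "2020-06-01")
  write_day(rec, paths["acc"], paths["baro"])
  expect_warning(read_day(paths["acc"], paths["baro"]), "under 4 h")
})

test_that("partition_windows tiles as specified", {
  expect_equal(nrow(partition_windows(3000, 50, 30)), 2)           # 3000/1500
  w <- partition_windows(250, 50, 5, overlap_fraction = 0.8)
  expect_equal(nrow(w), 1)          # hop 1 s; only start 0 fits 250 samples
  expect_equal(w$start_s, 0)
  expect_equal(nrow(partition_windows(100, 50, 30)), 0)  # partial discarded
  expect_error(partition_windows(100, 50, 5, overlap_fraction = 1),
               "parameter error")
  # disjoint tiling at overlap 0: total coverage never exceeds the series
  w0 <- partition_windows(3700, 50, 30)
  expect_true(sum(w0$length_s) * 50 <= 3700)
  expect_true(all(diff(w0$start_idx) == 1500))
})

test_that("feature CSV round-trips with missing cells", {
  df <- feature_row("S1", "2020-06-01", G1 = 0.2, G3 = 100, label = "frail")
  path <- withr::local_tempfile(fileext = ".csv")
  write_features(df, path)
  back <- read_features(path)
  expect_equal(back$G3, 100)
  expect_true(is.na(back$G5))
  expect_equal(back$label, "frail")
})
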