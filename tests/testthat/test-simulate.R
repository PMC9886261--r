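test_that("a silent profile yields a silent day end to end", {
  prof <- frail_profile(steps_per_day = 0, periodic_windows_per_day = 0,
                        activity_rate = 0, stairs_per_day = 0,
                        lifts_per_day = 0, agitations_per_night = 0,
                        pressure_spikes_per_day = 0)
  g <- generate_day(prof, seed = 5)
  expect_equal(g$truth$features$G1, 0)
  expect_equal(g$truth$features$G3, 0)
  expect_equal(g$truth$features$G2, 100)
  ex <- extract_day(g$recording)
  expect_equal(ex$features$G1, 0)
  expect_equal(ex$features$G3, 0)
  expect_equal(ex$features$G2, 100)
  expect_equal(ex$features$G6, 0)
  expect_equal(ex$features$G7, 0)
  expect_equal(ex$features$G8, 0)
  expect_equal(ex$features$G9, 24, tolerance = 1e-6)  # MET 1 for 24 h
  expect_true(is.na(ex$features$G5))
})

test_that("the generator is deterministic under a fixed seed", {
  prof <- frail_profile()
  g1 <- generate_day(prof, seed = 77)
  g2 <- generate_day(prof, seed = 77)
  expect_identical(g1$recording$accel$ax, g2$recording$accel$ax)
  expect_identical(g1$recording$baro$p, g2$recording$baro$p)
  expect_identical(g1$truth$features, g2$truth$features)
  g3 <- generate_day(prof, seed = 78)
  expect_false(identical(g1$truth$features$G3, g3$truth$features$G3))
})

test_that("injected vertical speed is recovered from the pressure channel", {
  prof <- robust_profile(steps_per_day = 0, periodic_windows_per_day = 0,
                         activity_rate = 0, stairs_per_day = 0,
                         lifts_per_day = 3, agitations_per_night = 0,
                         pressure_spikes_per_day = 0)
  g <- generate_day(prof, seed = 9)
  ev <- g$truth$episodes[g$truth$episodes$kind == "lift", ]
  alt <- altitude(slope_limit_filter(g$recording$baro))
  for (r in seq_len(nrow(ev))) {
    i0 <- which(alt$t == round(ev$start_s[r]))
    i1 <- which(alt$t == round(ev$end_s[r]))
    slope <- (alt$h[i1] - alt$h[i0]) / (alt$t[i1] - alt$t[i0])
    expect_equal(slope, ev$value[r] / (ev$end_s[r] - ev$start_s[r]),
                 tolerance = 0.05)
  }
})

test_that("weightless intervals are injected and recovered", {
  prof <- frail_profile(steps_per_day = 0, periodic_windows_per_day = 0,
                        activity_rate = 0, stairs_per_day = 0,
                        lifts_per_day = 0, agitations_per_night = 0,
                        jumps = list(count = 10, len_s = 0.24))
  g <- generate_day(prof, seed = 3)
  expect_equal(g$truth$features$G6, 2.4, tolerance = 1e-9)
  mag <- magnitude(g$recording$accel)
  w <- weightlessness(mag)
  expect_equal(w$G6, g$truth$features$G6, tolerance = 0.05)
})

test_that("feature-mode cohorts have the requested shape and balance", {
  co <- generate_cohort(n_frail = 9, n_robust = 9, days_per_subject = 32,
                        seed = 1)
  expect_equal(nrow(co$features), 18 * 32)
  expect_equal(sum(co$subjects$label == "frail"), 9)
  expect_true(all(paste0("G", 1:9) %in% names(co$features)))
  # weightlessness is identically zero in both groups
  expect_true(all(co$features$G6 == 0))
  # deterministic under the seed
  co2 <- generate_cohort(n_frail = 9, n_robust = 9, days_per_subject = 32,
                         seed = 1)
  expect_identical(co$features, co2$features)
})

test_that("cohort feature means sit within one between-subject SD of target", {
  set.seed(14)
  mono <- list(G3 = c(1019, 939, 4663, 2036), G9 = c(19.7, 2, 26.6, 2.3),
               G5 = c(1.9, 0.63, 1.18, 0.04))
  agg <- replicate(20, {
    co <- generate_cohort(seed = sample.int(1e6, 1))
    sm <- suppressWarnings(subject_means(co$features))
    # a deeply frail subject can have G5 missing on every day
    c(mean(sm$G3[sm$label == "frail"]), mean(sm$G3[sm$label == "robust"]),
      mean(sm$G9[sm$label == "frail"]), mean(sm$G9[sm$label == "robust"]),
      mean(sm$G5[sm$label == "frail"], na.rm = TRUE),
      mean(sm$G5[sm$label == "robust"], na.rm = TRUE))
  })
  m <- rowMeans(agg)
  expect_lt(abs(m[1] - 1019), 939)
  expect_lt(abs(m[2] - 4663), 2036)
  expect_lt(abs(m[3] - 19.7), 2)
  expect_lt(abs(m[4] - 26.6), 2.3)
  expect_lt(abs(m[5] - 1.9), 0.63)
  expect_lt(abs(m[6] - 1.18), 0.1)
})

test_that("signal-mode cohorts write day file pairs and a truth table", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(n_frail = 1, n_robust = 1, days_per_subject = 1,
                        seed = 2, mode = "signals", out_dir = dir)
  expect_length(co$recordings, 2)
  files <- list.files(dir)
  expect_equal(sum(grepl("_acc.csv$", files)), 2)
  expect_equal(sum(grepl("_baro.csv$", files)), 2)
  expect_true("truth.csv" %in% files)
  truth <- read_features(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), 2)
  expect_setequal(truth$label, c("frail", "robust"))
})

test_that("burst and fidget windows never register as periodic movement", {
  # the step-supplying bursts and the tilted fidget windows are built to
  # stay below the autocorrelation peak threshold
  prof <- robust_profile(periodic_windows_per_day = 0, stairs_per_day = 0,
                         lifts_per_day = 0)
  g <- generate_day(prof, seed = 21)
  ex <- extract_day(g$recording)
  expect_equal(ex$features$G4, 0)
})
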