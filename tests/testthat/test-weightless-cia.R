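test_that("weightlessness sums airborne intervals and ignores rest", {
  # resting magnitude near 1 g: no weightlessness
  expect_equal(weightlessness(make_mag(rep(1, 1000)))$G6, 0)
  # jump train at 40 Hz: 10 intervals of exactly 0.25 s at 0.1 g
  x <- rep(1, 40 * 60)
  for (j in 0:9) x[j * 100 + 1:10] <- 0.1
  w <- weightlessness(make_mag(x, fs = 40))
  expect_equal(w$G6, 2.5)
  expect_equal(nrow(w$episodes), 10)
})

test_that("raising the weightlessness threshold never decreases G6", {
  set.seed(4)
  x <- pmax(0, 1 + rnorm(5000, 0, 0.6))
  g6 <- sapply(c(0.2, 0.3, 0.5), function(th)
    weightlessness(make_mag(x), threshold_g = th)$G6)
  expect_true(all(diff(g6) >= 0))
})

cia_fixture <- function(rise_m, dur_s, active, total_s = 300, start_s = 120) {
  # 1-s altitude grid with one linear ramp; activity via window rms
  h <- rep(10, total_s)
  ramp <- seq_len(dur_s)
  h[start_s + ramp] <- 10 + rise_m * ramp / dur_s
  h[(start_s + dur_s + 1):total_s] <- 10 + rise_m
  alt <- structure(list(t = 0:(total_s - 1), h = h, p_filtered = rep(1000, total_s)),
                   class = "altitude_series")
  x <- if (active) 1 + 0.2 * sin(2 * pi * 1.5 * (0:(50 * total_s - 1)) / 50)
       else rep(1, 50 * total_s)
  aw <- activity_windows(make_mag(x))
  list(alt = alt, windows = aw$windows)
}

test_that("flat altitude gives no lift or stair episodes", {
  fx <- cia_fixture(0, 10, active = FALSE)
  r <- change_in_altitude(fx$alt, fx$windows)
  expect_equal(r$G7, 0)
  expect_equal(r$G8, 0)
})

test_that("a fast rise while inactive is a lift, a moderate one while active is stairs", {
  lift <- cia_fixture(4.2, 6, active = FALSE)     # 0.7 m/s, wearer still
  r1 <- change_in_altitude(lift$alt, lift$windows)
  expect_equal(r1$G7, 1)
  expect_equal(r1$G8, 0)
  expect_equal(r1$episodes$slope_m_per_s, 0.7, tolerance = 0.01)

  st <- cia_fixture(3, 10, active = TRUE)         # 0.3 m/s, wearer active
  r2 <- change_in_altitude(st$alt, st$windows)
  expect_equal(r2$G8, 1)
  expect_equal(r2$G7, 0)

  # descending works symmetrically
  dn <- cia_fixture(-3, 10, active = TRUE)
  expect_equal(change_in_altitude(dn$alt, dn$windows)$G8, 1)
})

test_that("the shared 0.6 m/s boundary resolves by the activity gate", {
  tie_active <- cia_fixture(6, 10, active = TRUE)    # exactly 0.6, active
  r <- change_in_altitude(tie_active$alt, tie_active$windows)
  expect_equal(r$G8, 1)
  expect_equal(r$G7, 0)
  tie_still <- cia_fixture(6, 10, active = FALSE)    # exactly 0.6, still
  r2 <- change_in_altitude(tie_still$alt, tie_still$windows)
  expect_equal(r2$G7, 1)
  expect_equal(r2$G8, 0)
})

test_that("a fast rise while active matches neither band", {
  fx <- cia_fixture(7, 10, active = TRUE)            # 0.7 m/s but moving
  r <- change_in_altitude(fx$alt, fx$windows)
  expect_equal(r$G7 + r$G8, 0)
})

test_that("missing altitude flags both features missing", {
  alt <- structure(list(t = 0:10, h = rep(NA_real_, 11),
                        p_filtered = rep(NA_real_, 11)),
                   class = "altitude_series")
  aw <- activity_windows(make_mag(rep(1, 50 * 60)))
  r <- change_in_altitude(alt, aw$windows)
  expect_true(is.na(r$G7) && is.na(r$G8))
})
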