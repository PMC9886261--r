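# small builders shared across the test files; everything is generated in
# code so the suite carries no binary fixtures

fs_acc <- 50

# accel series from explicit axis vectors (defaults: still, gravity on ax)
make_accel <- function(dur_s, ax = NULL, ay = NULL, az = NULL, t0 = 0,
                       fs = fs_acc) {
  n <- round(dur_s * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  zero <- numeric(n)
  accel_series(t,
               if (is.null(ax)) zero + 1 else rep_len(ax, n),
               if (is.null(ay)) zero else rep_len(ay, n),
               if (is.null(az)) zero else rep_len(az, n),
               fs_nominal = fs)
}

# magnitude series straight from a numeric vector
make_mag <- function(x, fs = fs_acc, t0 = 0) {
  structure(list(t = t0 + (seq_along(x) - 1) / fs, mag = x, fs_nominal = fs),
            class = "magnitude_series")
}

# flat baro series
make_baro <- function(dur_s, p = 1000, temp = 288.15, fs = 5, t0 = 0) {
  n <- round(dur_s * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  baro_series(t, rep_len(p, n), rep_len(temp, n), fs_nominal = fs)
}

# pressure corresponding to altitude h (inverts the barometric formula)
pressure_at <- function(h, temp = 293.15) {
  1013.25 * (1 - 0.0065 * h / temp)^(1 / 0.19)
}
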