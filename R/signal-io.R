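#' Read one subject-day from a pair of CSV files
#'
#' The accelerometer file has header `t,ax,ay,az` (t in seconds since local
#' midnight, axes in g); the barometer file has header `t,p,temp` (mbar,
#' kelvin). Rows containing any non-finite value are dropped and counted; a
#' warning is emitted when total accelerometer coverage is under four hours.
#'
#' @param accel_path,baro_path Paths to the two CSV files.
#' @param subject_id Subject identifier to attach.
#' @param date Calendar date of the recording.
#' @param weight_kg Optional body weight in kg.
#' @return A validated [day_recording()]. The number of dropped rows is
#'   attached as attribute `dropped_rows`.
#' @export
read_day <- function(accel_path, baro_path, subject_id = "unknown",
                     date = Sys.Date(), weight_kg = NA_real_) {
  acc <- read_sensor_csv(accel_path, c("t", "ax", "ay", "az"))
  bar <- read_sensor_csv(baro_path, c("t", "p", "temp"))
  dropped <- attr(acc, "dropped") + attr(bar, "dropped")
  accel <- accel_series(acc$t, acc$ax, acc$ay, acc$az)
  baro  <- baro_series(bar$t, bar$p, bar$temp)
  rec <- day_recording(subject_id, date, accel, baro, weight_kg)
  if (rec$duration_s < 4 * 3600)
    warning(sprintf("coverage %.2f h is under 4 h; features will be unreliable",
                    rec$duration_s / 3600))
  attr(rec, "dropped_rows") <- dropped
  rec
}

read_sensor_csv <- function(path, expected_header) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  if (file.size(path) == 0) stop("empty-input error: ", path, " is empty")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), expected_header))
    stop("format error: header of ", path, " is not `",
         paste(expected_header, collapse = ","), "`")
  df <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(df) == 0L) stop("empty-input error: ", path, " has a header but no rows")
  ok <- Reduce(`&`, lapply(df, is.finite))
  out <- df[ok, , drop = FALSE]
  if (nrow(out) == 0L) stop("empty-input error: ", path, " has no finite rows")
  if (is.unsorted(out$t)) stop("ordering error: timestamps in ", path, " decrease")
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Write one subject-day to a pair of CSV files
#'
#' Inverse of [read_day()]: `read_day(write_day(rec))` reproduces the
#' recording to numeric round-off. Files follow the naming convention
#' `<subject>_<YYYY-MM-DD>_{acc,baro}.csv` when written via [day_paths()].
#'
#' @param rec A [day_recording()].
#' @param accel_path,baro_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_day <- function(rec, accel_path, baro_path) {
  stopifnot(inherits(rec, "day_recording"))
  if (length(rec$accel$t) == 0L || length(rec$baro$t) == 0L)
    stop("empty-input error: refusing to write an empty series")
  acc <- data.frame(t = rec$accel$t, ax = rec$accel$ax,
                    ay = rec$accel$ay, az = rec$accel$az)
  bar <- data.frame(t = rec$baro$t, p = rec$baro$p, temp = rec$baro$temp)
  # full double precision so the round trip is lossless to ~1e-15
  write_numeric_csv(acc, accel_path)
  write_numeric_csv(bar, baro_path)
  invisible(c(accel_path, baro_path))
}

write_numeric_csv <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    lines <- c(paste(names(df), collapse = ","),
               do.call(paste, c(lapply(df, format, digits = 17, scientific = FALSE,
                                       trim = TRUE),
                                sep = ",")))
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
}

#' Conventional file names for a subject-day pair
#'
#' @param dir Directory.
#' @param subject_id Subject identifier.
#' @param date Calendar date.
#' @return Named character vector with elements `acc` and `baro`.
#' @export
day_paths <- function(dir, subject_id, date) {
  stem <- file.path(dir, sprintf("%s_%s", subject_id, format(as.Date(date))))
  c(acc = paste0(stem, "_acc.csv"), baro = paste0(stem, "_baro.csv"))
}

#' Read / write a daily feature table
#'
#' The feature CSV has header
#' `subject,date,G1,G2,G3,G4,G5,G6,G7,G8,G9,label`; empty cells encode
#' missing features (for example G5 on days with no periodic movement).
#'
#' @param path CSV path.
#' @return `read_features()` returns a data frame with that layout.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "date", paste0("G", 1:9), "label")
  if (!all(need %in% names(df)))
    stop("format error: feature CSV must have columns ",
         paste(need, collapse = ","))
  df[need]
}

#' @rdname read_features
#' @param features Data frame in the feature-CSV layout.
#' @export
write_features <- function(features, path) {
  need <- c("subject", "date", paste0("G", 1:9), "label")
  stopifnot(all(need %in% names(features)))
  utils::write.csv(features[need], path, row.names = FALSE, na = "")
  invisible(path)
}
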