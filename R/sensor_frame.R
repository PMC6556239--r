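#' Synchronized PPG + accelerometer record
#'
#' A `sensor_frame` holds one PPG channel and the three accelerometer axes on
#' a common uniform time base. It is the container every pipeline stage
#' consumes. All channels must have equal length and contain only finite
#' values; corrupt input is a hard error rather than silently repaired, since
#' a streaming estimator should fail loudly on bad samples.
#'
#' @param ppg numeric vector, PPG channel (arbitrary ADC units).
#' @param accel_x,accel_y,accel_z numeric vectors, accelerometer axes
#'   (arbitrary units; only relative amplitude and sign matter downstream).
#' @param fs sampling rate in Hz (positive scalar).
#' @param t0 start time in seconds (default 0).
#'
#' @return An object of class `"sensor_frame"`: a list with elements `ppg`,
#'   `accel_x`, `accel_y`, `accel_z`, `fs`, `t0`.
#' @examples
#' fr <- sensor_frame(ppg = sin(2 * pi * 1.2 * (0:249) / 25),
#'                    accel_x = numeric(250), accel_y = numeric(250),
#'                    accel_z = numeric(250), fs = 25)
#' fr
#' @export
sensor_frame <- function(ppg, accel_x, accel_y, accel_z, fs, t0 = 0) {
  frame <- structure(
    list(ppg = as.numeric(ppg),
         accel_x = as.numeric(accel_x),
         accel_y = as.numeric(accel_y),
         accel_z = as.numeric(accel_z),
         fs = as.numeric(fs)[1L],
         t0 = as.numeric(t0)[1L]),
    class = "sensor_frame")
  validate_sensor_frame(frame)
}

validate_sensor_frame <- function(frame) {
  chans <- c("ppg", "accel_x", "accel_y", "accel_z")
  lens <- vapply(frame[chans], length, integer(1))
  if (any(lens < 1L))
    stop("sensor_frame: all channels must have length >= 1", call. = FALSE)
  if (length(unique(lens)) != 1L)
    stop("sensor_frame: channels have unequal lengths (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  if (!is.finite(frame$fs) || frame$fs <= 0)
    stop("sensor_frame: fs must be a positive finite number", call. = FALSE)
  if (!is.finite(frame$t0))
    stop("sensor_frame: t0 must be finite", call. = FALSE)
  for (ch in chans) {
    bad <- which(!is.finite(frame[[ch]]))
    if (length(bad))
      stop("sensor_frame: non-finite value in channel '", ch,
           "' at row ", bad[1L], call. = FALSE)
  }
  frame
}

#' @export
print.sensor_frame <- function(x, ...) {
  n <- length(x$ppg)
  cat(sprintf("<sensor_frame> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              n, x$fs, n / x$fs, x$t0))
  invisible(x)
}

#' @export
as.data.frame.sensor_frame <- function(x, ...) {
  n <- length(x$ppg)
  data.frame(time = x$t0 + (seq_len(n) - 1) / x$fs,
             ppg = x$ppg, ax = x$accel_x, ay = x$accel_y, az = x$accel_z)
}

#' Sample times of a sensor frame
#'
#' @param frame a [sensor_frame()].
#' @return Numeric vector of sample times in seconds.
#' @export
frame_times <- function(frame) {
  frame$t0 + (seq_along(frame$ppg) - 1) / frame$fs
}

#' Read a multichannel sensor CSV into a sensor_frame
#'
#' Reads a header CSV with one row per sample and maps its columns onto the
#' PPG and accelerometer roles. Two simultaneous PPG columns (as in dual-LED
#' wrist sensors) can be combined by arithmetic mean, or only the first kept.
#'
#' @param path path to a CSV file with a header row ('.' decimal separator).
#' @param columns named list mapping roles to column names. Recognised roles:
#'   `ppg` (required), `ppg2` (optional second PPG channel), `ax`, `ay`, `az`
#'   (required), `time` (optional; used for `t0` and, if `fs` is missing, to
#'   infer the sampling rate).
#' @param fs sampling rate in Hz. May be omitted only when a `time` column is
#'   mapped, in which case the rate is inferred from the median time step.
#' @param ppg_combine how to combine two mapped PPG columns: `"mean"`
#'   (elementwise average, the default) or `"first"`.
#' @return A validated [sensor_frame()].
#' @export
read_sensor_csv <- function(path,
                            columns = list(time = "time", ppg = "ppg",
                                           ax = "ax", ay = "ay", az = "az"),
                            fs = NULL,
                            ppg_combine = c("mean", "first")) {
  ppg_combine <- match.arg(ppg_combine)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)

  need <- c("ppg", "ax", "ay", "az")
  for (role in need) {
    if (is.null(columns[[role]]))
      stop("column mapping for role '", role, "' is required", call. = FALSE)
  }
  pick <- function(role) {
    nm <- columns[[role]]
    if (is.null(nm)) return(NULL)
    if (!nm %in% names(df))
      stop("format error: mapped column '", nm, "' (role '", role,
           "') not found in ", path, call. = FALSE)
    as.numeric(df[[nm]])
  }

  ppg <- pick("ppg")
  ppg2 <- pick("ppg2")
  if (!is.null(ppg2) && ppg_combine == "mean") ppg <- (ppg + ppg2) / 2

  t0 <- 0
  tm <- pick("time")
  if (!is.null(tm)) {
    t0 <- tm[1L]
    if (is.null(fs)) {
      if (length(tm) < 2L)
        stop("cannot infer fs from a single-row time column", call. = FALSE)
      fs <- 1 / stats::median(diff(tm))
    }
  }
  if (is.null(fs))
    stop("fs must be given or a 'time' column mapped", call. = FALSE)

  sensor_frame(ppg, pick("ax"), pick("ay"), pick("az"), fs = fs, t0 = t0)
}
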