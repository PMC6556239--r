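#' Decimate a sensor frame to a lower sampling rate
#'
#' All four channels are decimated identically: a zero-phase FIR anti-aliasing
#' low-pass (48-tap Hamming-window design, cutoff at 90% of the target Nyquist
#' frequency, applied forward-backward so no group-delay compensation is
#' needed) followed by keeping every k-th sample starting at the first. Only
#' integer decimation factors are supported; the output length is
#' `ceiling(n / k)` and `t0` is unchanged because the retained grid starts at
#' the first input sample.
#'
#' The standard operating point is 125 Hz raw data decimated to 25 Hz, which
#' keeps the whole physiological heart-rate band while cutting the arithmetic
#' cost of every downstream stage by five.
#'
#' @param frame a [sensor_frame()].
#' @param target_fs target sampling rate in Hz; must divide `frame$fs` to
#'   within rounding. `target_fs == frame$fs` returns the frame unchanged;
#'   upsampling (`target_fs > frame$fs`) is an error.
#' @return A [sensor_frame()] at `target_fs`.
#' @export
resample_frame <- function(frame, target_fs = 25) {
  validate_sensor_frame(frame)
  if (!is.numeric(target_fs) || target_fs <= 0)
    stop("target_fs must be a positive number", call. = FALSE)
  if (target_fs > frame$fs)
    stop("target_fs (", target_fs, ") exceeds frame fs (", frame$fs,
         "): upsampling is out of contract", call. = FALSE)
  if (abs(target_fs - frame$fs) < 1e-9) return(frame)
  k <- frame$fs / target_fs
  if (abs(k - round(k)) > 1e-9)
    stop("only integer decimation factors are supported (fs = ", frame$fs,
         ", target_fs = ", target_fs, ")", call. = FALSE)
  k <- as.integer(round(k))
  b <- as.numeric(signal::fir1(48, 0.9 / k, type = "low"))
  b <- b / sum(b)  # exact unit DC gain
  dec <- function(x) {
    n <- length(x)
    pad <- min(3L * length(b), n - 1L)  # mirror-pad to tame edge transients
    xe <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
    y <- signal::filtfilt(b, 1, xe)[(pad + 1L):(pad + n)]
    y[seq(1L, n, by = k)]
  }
  sensor_frame(dec(frame$ppg), dec(frame$accel_x), dec(frame$accel_y),
               dec(frame$accel_z), fs = target_fs, t0 = frame$t0)
}

#' Band-pass the PPG channel to the physiological heart-rate band
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass to
#' the PPG channel only. The accelerometer channels pass through untouched so
#' that the motion-artifact stage sees the raw (resampled) motion reference.
#' The default band 0.4-4 Hz covers 24-240 BPM while removing baseline wander
#' and high-frequency noise.
#'
#' @param frame a [sensor_frame()].
#' @param low_hz,high_hz band edges in Hz; require `0 < low_hz < high_hz <
#'   fs/2`.
#' @return A [sensor_frame()] with a filtered `ppg` channel.
#' @export
bandpass_prefilter <- function(frame, low_hz = 0.4, high_hz = 4.0) {
  validate_sensor_frame(frame)
  nyq <- frame$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("invalid band edges: need 0 < low_hz < high_hz < fs/2 (fs = ",
         frame$fs, ")", call. = FALSE)
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  frame$ppg <- signal::filtfilt(bf, frame$ppg)
  validate_sensor_frame(frame)
}

#' Preprocess a raw frame for heart-rate estimation
#'
#' Convenience wrapper: decimate to `fs_target`, then band-pass the PPG
#' channel. This is the canonical "preprocessing" stage in front of
#' [estimate_hr()].
#'
#' @param frame a raw [sensor_frame()].
#' @param fs_target target rate in Hz (default 25).
#' @param band_low_hz,band_high_hz PPG band edges in Hz (defaults 0.4, 4).
#' @return A preprocessed [sensor_frame()].
#' @export
preprocess_frame <- function(frame, fs_target = 25,
                             band_low_hz = 0.4, band_high_hz = 4.0) {
  bandpass_prefilter(resample_frame(frame, fs_target),
                     band_low_hz, band_high_hz)
}

#' Band power of a signal via the periodogram
#'
#' Small spectral utility used throughout the tests and examples: the summed
#' periodogram power of `x` within `[f_lo, f_hi]` Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz.
#' @return Scalar band power (arbitrary units, proportional to mean square).
#' @export
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(sp[half & f >= f_lo & f <= f_hi])
}
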