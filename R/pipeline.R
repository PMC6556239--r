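#' Heart-rate series container
#'
#' A data frame with class `"hr_series"`: columns `t` (seconds, strictly
#' increasing), `hr_bpm` (finite, positive), and optionally `warmup`
#' (logical flag for windows overlapping the filter warm-up).
#'
#' @param t timestamps in seconds.
#' @param hr_bpm heart rate in BPM.
#' @param warmup optional logical vector flagging warm-up windows.
#' @return An `"hr_series"` data frame.
#' @export
hr_series <- function(t, hr_bpm, warmup = NULL) {
  t <- as.numeric(t); hr_bpm <- as.numeric(hr_bpm)
  if (length(t) != length(hr_bpm))
    stop("t and hr_bpm must have equal length", call. = FALSE)
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    stop("t must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(hr_bpm)) || any(hr_bpm <= 0))
    stop("hr_bpm must be finite and positive", call. = FALSE)
  df <- data.frame(t = t, hr_bpm = hr_bpm)
  if (!is.null(warmup)) df$warmup <- as.logical(warmup)
  class(df) <- c("hr_series", "data.frame")
  df
}

#' Window a per-sample heart-rate trajectory
#'
#' Aggregates a uniformly sampled per-sample BPM trajectory into overlapping
#' windows (default 8 s advanced by 2 s, matching the reporting cadence of
#' treadmill PPG benchmark recordings). The window statistic is the
#' arithmetic mean by default; timestamps are placed at the window end.
#' Windows that overlap the first `window_s` of data are flagged as warm-up.
#'
#' @param hr an [hr_series()] or data frame with columns `t`, `hr_bpm`
#'   (per-sample trajectory on a uniform grid).
#' @param window_s window length in seconds (default 8); must be >= `step_s`.
#' @param step_s window advance in seconds (default 2); must be > 0.
#' @param stat window statistic, `"mean"` (default) or `"median"`.
#' @return An [hr_series()] with one row per window and a `warmup` column.
#' @export
make_windowed_hr <- function(hr, window_s = 8, step_s = 2,
                             stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!(step_s > 0) || window_s < step_s)
    stop("require window_s >= step_s > 0", call. = FALSE)
  t <- hr$t; v <- hr$hr_bpm
  n <- length(v)
  if (n < 2L) stop("per-sample series too short", call. = FALSE)
  dt <- stats::median(diff(t))
  len <- max(1L, as.integer(round(window_s / dt)))
  stp <- max(1L, as.integer(round(step_s / dt)))
  if (n < len)
    stop("series shorter than one window (", n, " samples < ", len, ")",
         call. = FALSE)
  fun <- if (stat == "mean") mean else stats::median
  starts <- seq.int(1L, n - len + 1L, by = stp)
  vw <- vapply(starts, function(s) fun(v[s:(s + len - 1L)]), numeric(1))
  tw <- t[starts + len - 1L]
  hr_series(tw, vw, warmup = starts < len)
}

#' Pipeline configuration
#'
#' Builds and validates the full parameter set of [estimate_hr()]. Defaults
#' are the standard operating point of the three-stage estimator: sign-sign
#' artifact reduction with M = 21 taps and step size 1e-4; noise-robust
#' tracking with L = 5, beta = 0.95, mu_a = 0.025, initialized at 90 BPM;
#' feedback band-pass with beta_hr = 0.8; 8 s / 2 s mean windowing.
#'
#' @param ma list: `algorithm` ("sign_sign" or "nlms"), `taps`, `mu`,
#'   `enabled` (FALSE bypasses artifact reduction entirely).
#' @param anf list: `variant` ("nr_osc" or "osc"), `L`, `beta`, `mu_a`,
#'   `f_init_bpm`, `feedback` (logical), `beta_hr`.
#' @param window list: `window_s`, `step_s`, `stat`.
#' @return A validated list of class `"hr_config"`.
#' @export
hr_config <- function(ma = list(), anf = list(), window = list()) {
  cfg <- list(
    ma = utils::modifyList(
      list(algorithm = "sign_sign", taps = 21, mu = 1e-4, enabled = TRUE), ma),
    anf = utils::modifyList(
      list(variant = "nr_osc", L = 5, beta = 0.95, mu_a = 0.025,
           f_init_bpm = 90, feedback = TRUE, beta_hr = 0.8), anf),
    window = utils::modifyList(
      list(window_s = 8, step_s = 2, stat = "mean"), window))
  if (!cfg$ma$algorithm %in% c("sign_sign", "nlms"))
    stop("ma$algorithm must be 'sign_sign' or 'nlms'", call. = FALSE)
  if (!cfg$anf$variant %in% c("nr_osc", "osc"))
    stop("anf$variant must be 'nr_osc' or 'osc'", call. = FALSE)
  if (cfg$anf$L < 1) stop("anf$L must be >= 1", call. = FALSE)
  if (!(cfg$window$step_s > 0) || cfg$window$window_s < cfg$window$step_s)
    stop("window: require window_s >= step_s > 0", call. = FALSE)
  class(cfg) <- "hr_config"
  cfg
}

#' Estimate heart rate from a preprocessed sensor frame
#'
#' Runs the three-stage estimator sample by sample over a [sensor_frame()]
#' (already at the target rate; see [preprocess_frame()]). Per sample: (1)
#' the feedback band-pass re-filters the PPG around the tracker's previous
#' frequency estimate (skipped when disabled), (2) the adaptive
#' motion-artifact stage subtracts the accelerometer-correlated component,
#' (3) the adaptive notch tracker converts the residual into a heart-rate
#' sample. The per-sample trajectory is then windowed into the reported
#' series. The whole computation is deterministic given `frame` + `config`.
#'
#' @param frame a preprocessed [sensor_frame()] (25 Hz at the defaults).
#' @param config an [hr_config()].
#' @return An object of class `"hr_fit"` with elements `hr` (windowed
#'   [hr_series()] with warm-up flags), `per_sample` (data frame `t`,
#'   `hr_bpm`, `e`, `d_hr`, `alpha`), `config`, `states` (final stage
#'   states), `stage_calls` (named counts of step calls per stage), `frame_fs`,
#'   `call`.
#' @examples
#' sim <- simulate_ppg(sim_spec(duration_s = 60, seed = 7))
#' fit <- estimate_hr(sim$frame)
#' fit
#' head(fitted(fit))
#' @export
estimate_hr <- function(frame, config = hr_config()) {
  validate_sensor_frame(frame)
  if (!inherits(config, "hr_config")) config <- do.call(hr_config, config)
  n <- length(frame$ppg)
  fs <- frame$fs
  wlen <- as.integer(round(config$window$window_s * fs))
  if (n < wlen)
    stop("frame shorter than one window (", n, " samples < ", wlen, ")",
         call. = FALSE)

  ma_on <- isTRUE(config$ma$enabled)
  fb_on <- isTRUE(config$anf$feedback)
  use_nlms <- config$ma$algorithm == "nlms"
  anf_st <- anf_init(fs = fs, L = config$anf$L, beta = config$anf$beta,
                     mu_a = config$anf$mu_a,
                     f_init_bpm = config$anf$f_init_bpm)
  anf_step <- if (config$anf$variant == "nr_osc") nr_osc_anf_step else osc_anf_step
  fb_st <- feedback_bpf_init(config$anf$beta_hr)
  ma_st <- if (use_nlms) nlms3_init(config$ma$taps, config$ma$mu)
           else ss_init(config$ma$taps, config$ma$mu)
  ma_step <- if (use_nlms) nlms3_step else sign_sign_step

  d <- frame$ppg
  ax <- frame$accel_x; ay <- frame$accel_y; az <- frame$accel_z
  hr <- numeric(n); ev <- numeric(n); dhr <- numeric(n); alv <- numeric(n)
  calls <- c(feedback = 0L, ma = 0L, anf = 0L)

  for (i in seq_len(n)) {
    di <- d[i]
    if (fb_on) {
      r <- feedback_bpf_step(fb_st, di, anf_st$alpha)
      fb_st <- r$state
      di <- r$d_hr
      calls["feedback"] <- calls["feedback"] + 1L
    }
    dhr[i] <- di
    if (ma_on) {
      r <- ma_step(ma_st, ax[i], ay[i], az[i], di)
      ma_st <- r$state
      ei <- r$e
      calls["ma"] <- calls["ma"] + 1L
    } else {
      ei <- di
    }
    ev[i] <- ei
    r <- anf_step(anf_st, ei)
    anf_st <- r$state
    hr[i] <- r$hr_bpm
    alv[i] <- anf_st$alpha
    calls["anf"] <- calls["anf"] + 1L
  }

  t <- frame_times(frame)
  per_sample <- data.frame(t = t, hr_bpm = hr, e = ev, d_hr = dhr, alpha = alv)
  hrw <- make_windowed_hr(per_sample, config$window$window_s,
                          config$window$step_s, config$window$stat)
  structure(list(hr = hrw, per_sample = per_sample, config = config,
                 states = list(ma = ma_st, anf = anf_st, feedback = fb_st),
                 stage_calls = calls, frame_fs = fs,
                 call = match.call()),
            class = "hr_fit")
}

#' @export
print.hr_fit <- function(x, ...) {
  ok <- !x$hr$warmup
  cat(sprintf("Heart-rate fit: %d samples @ %g Hz, %d windows (%g s / %g s)\n",
              nrow(x$per_sample), x$frame_fs, nrow(x$hr),
              x$config$window$window_s, x$config$window$step_s))
  cat(sprintf("  stages: MA = %s%s, tracker = %s (L = %d), feedback %s\n",
              x$config$ma$algorithm,
              if (x$config$ma$enabled) "" else " (bypassed)",
              x$config$anf$variant, x$config$anf$L,
              if (x$config$anf$feedback) "on" else "off"))
  if (any(ok))
    cat(sprintf("  HR after warm-up: mean %.1f BPM, range %.1f-%.1f BPM\n",
                mean(x$hr$hr_bpm[ok]), min(x$hr$hr_bpm[ok]),
                max(x$hr$hr_bpm[ok])))
  invisible(x)
}

#' @export
summary.hr_fit <- function(object, ...) {
  ok <- !object$hr$warmup
  res <- list(
    n_samples = nrow(object$per_sample),
    n_windows = nrow(object$hr),
    n_warmup = sum(object$hr$warmup),
    hr_mean = mean(object$hr$hr_bpm[ok]),
    hr_sd = stats::sd(object$hr$hr_bpm[ok]),
    alpha_final = object$states$anf$alpha,
    residual_power = mean(object$per_sample$e^2),
    stage_calls = object$stage_calls)
  class(res) <- "summary.hr_fit"
  res
}

#' @export
print.summary.hr_fit <- function(x, ...) {
  cat(sprintf("windows: %d (%d warm-up); HR %.1f +/- %.1f BPM\n",
              x$n_windows, x$n_warmup, x$hr_mean, x$hr_sd))
  cat(sprintf("final alpha: %.4f; mean residual power: %.4g\n",
              x$alpha_final, x$residual_power))
  invisible(x)
}

#' @export
coef.hr_fit <- function(object, ...) {
  st <- object$states$ma
  cbind(x = st$w_x, y = st$w_y, z = st$w_z)
}

#' @export
fitted.hr_fit <- function(object, ...) object$hr

#' @export
residuals.hr_fit <- function(object, ...) object$per_sample$e

#' @export
plot.hr_fit <- function(x, truth = NULL, ...) {
  plot(x$per_sample$t, x$per_sample$hr_bpm, type = "l", col = "grey70",
       xlab = "time (s)", ylab = "heart rate (BPM)", ...)
  lines(x$hr$t, x$hr$hr_bpm, col = "black", lwd = 2)
  if (!is.null(truth)) lines(truth$t, truth$hr_bpm, col = "red3", lty = 2)
  legend("topleft", bty = "n",
         legend = c("per-sample", "windowed", if (!is.null(truth)) "truth"),
         col = c("grey70", "black", if (!is.null(truth)) "red3"),
         lty = c(1, 1, if (!is.null(truth)) 2),
         lwd = c(1, 2, if (!is.null(truth)) 1))
  invisible(x)
}
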