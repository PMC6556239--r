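#' Initialize an oscillator-based adaptive notch filter state
#'
#' The tracker is a second-order IIR resonator driven by the sign of its
#' input. Its frequency parameter `alpha = cos(omega)` is adapted each sample
#' by an LMS-style rule normalized by an exponentially weighted power
#' estimate `Px`, and the heart rate in BPM is `acos(alpha) * fs / (2*pi) *
#' 60`. The noise-robust variant anchors the update on the mean of the last
#' `L` values of `alpha`, which damps estimate jitter at low SNR; `L = 1`
#' reproduces the plain tracker exactly.
#'
#' Numerical guards (the recursions themselves do not provide them): `alpha`
#' is clamped to `[-1 + 1e-9, 1 - 1e-9]` so `acos` is always defined, `Px`
#' starts at a small positive value so the first update is defined, and the
#' adaptation gain `mu_a * x1 / (2 Px)` is capped at magnitude 1 for the
#' first `fs` samples to suppress the start-up transient.
#'
#' @param fs sampling rate in Hz (default 25).
#' @param L averaging length of the noise-robust variant (default 5).
#' @param beta notch bandwidth parameter, 0 < beta < 1 (default 0.95).
#' @param mu_a adaptation step size (default 0.025).
#' @param f_init_bpm initial heart-rate guess in BPM (default 90), setting
#'   `alpha = cos(2*pi*f/fs)`.
#' @param px_init initial power estimate (default 1e-6).
#' @return An object of class `"anf_state"`.
#' @export
anf_init <- function(fs = 25, L = 5, beta = 0.95, mu_a = 0.025,
                     f_init_bpm = 90, px_init = 1e-6) {
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  if (!(beta > 0 && beta < 1)) stop("beta must be in (0, 1)", call. = FALSE)
  if (mu_a <= 0) stop("mu_a must be > 0", call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (px_init <= 0) stop("px_init must be > 0", call. = FALSE)
  alpha0 <- cos(2 * pi * (f_init_bpm / 60) / fs)
  structure(list(alpha = alpha0, hist = alpha0, L = as.integer(L),
                 beta = beta, mu_a = mu_a, fs = fs,
                 x1 = 0, x2 = 0, e1 = 0, e2 = 0,
                 Px = px_init, n = 0L),
            class = "anf_state")
}

# Shared recursion of the plain and noise-robust trackers. use_mean selects
# the anchor of the prediction error and update: alpha itself (plain) or the
# mean of the last L alpha values including the current one (noise-robust).
anf_step_core <- function(state, e_in, use_mean) {
  if (!is.finite(e_in)) stop("anf step: non-finite input", call. = FALSE)
  s <- sign(e_in)
  a <- state$alpha
  beta <- state$beta
  mu_a <- state$mu_a
  x <- a * (1 + beta) * state$x1 - beta * state$x2 +
    0.5 * (1 - beta) * (s - state$e2)
  anchor <- if (use_mean) mean(state$hist) else a
  e_a <- x - 2 * anchor * state$x1 + state$x2
  Px <- (1 - mu_a) * state$Px + mu_a * state$x1^2
  g <- mu_a * state$x1 / (2 * Px)
  if (state$n < state$fs) g <- max(min(g, 1), -1)
  a_new <- anchor + g * e_a
  lim <- 1 - 1e-9
  a_new <- max(min(a_new, lim), -lim)
  hist <- c(state$hist, a_new)
  if (length(hist) > state$L) hist <- hist[(length(hist) - state$L + 1):length(hist)]
  state$alpha <- a_new
  state$hist <- hist
  state$x2 <- state$x1; state$x1 <- x
  state$e2 <- state$e1; state$e1 <- s
  state$Px <- Px
  state$n <- state$n + 1L
  hr <- acos(a_new) * state$fs / (2 * pi) * 60
  list(state = state, hr_bpm = hr)
}

#' One step of the plain oscillator-based adaptive notch filter
#'
#' Runs the five-line recursion (oscillator update on `sign(e_in)`,
#' prediction error, power update, `alpha` update, `omega = acos(alpha)`)
#' and returns the heart rate in BPM. The state argument is pure: the caller
#' receives an updated copy.
#'
#' @param state an [anf_init()] state.
#' @param e_in input sample (typically the motion-artifact-reduced residual).
#' @return A list with elements `state` and `hr_bpm`.
#' @export
osc_anf_step <- function(state, e_in) anf_step_core(state, e_in, use_mean = FALSE)

#' One step of the noise-robust adaptive notch filter
#'
#' Identical to [osc_anf_step()] except that the prediction error and the
#' update are anchored on the mean of the last `L` frequency parameters
#' (including the current one); the oscillator recursion itself keeps the
#' instantaneous `alpha`. With `L = 1` the trajectory is bit-identical to the
#' plain tracker.
#'
#' @inheritParams osc_anf_step
#' @return A list with elements `state` and `hr_bpm`.
#' @export
nr_osc_anf_step <- function(state, e_in) anf_step_core(state, e_in, use_mean = TRUE)

#' Batch frequency tracking over a series
#'
#' Streams a numeric series through the selected tracker, one step call per
#' sample.
#'
#' @param x numeric input series.
#' @param state an [anf_init()] state; defaults to `anf_init()` at 25 Hz.
#' @param variant `"nr_osc"` (noise-robust, default) or `"osc"` (plain).
#' @return A list with `hr_bpm` (per-sample BPM trajectory), `alpha`
#'   (per-sample frequency parameter), `state` (final state), `calls`.
#' @export
track_frequency <- function(x, state = anf_init(), variant = c("nr_osc", "osc")) {
  variant <- match.arg(variant)
  step <- if (variant == "nr_osc") nr_osc_anf_step else osc_anf_step
  n <- length(x)
  hr <- numeric(n); al <- numeric(n)
  for (i in seq_len(n)) {
    r <- step(state, x[i])
    state <- r$state
    hr[i] <- r$hr_bpm
    al[i] <- state$alpha
  }
  list(hr_bpm = hr, alpha = al, state = state, calls = n)
}

#' Initialize the heart-rate-centred IIR band-pass feedback state
#'
#' Second-order IIR band-pass whose centre follows the tracker's current
#' `alpha`. Re-filtering the preprocessed PPG around the running heart-rate
#' estimate before artifact reduction suppresses out-of-band artifact energy
#' and closes the feedback loop of the noise-robust pipeline.
#'
#' @param beta_hr bandwidth parameter, 0 < beta_hr < 1 (default 0.8; smaller
#'   values widen the band).
#' @return An object of class `"fbpf_state"`.
#' @export
feedback_bpf_init <- function(beta_hr = 0.8) {
  if (!(beta_hr > 0 && beta_hr < 1))
    stop("beta_hr must be in (0, 1)", call. = FALSE)
  structure(list(beta_hr = beta_hr, d1 = 0, d2 = 0, y1 = 0, y2 = 0),
            class = "fbpf_state")
}

#' One step of the heart-rate-centred IIR band-pass
#'
#' Difference equation
#' `d_hr(n) = alpha*(1+b)*d_hr(n-1) - b*d_hr(n-2) + 0.5*(1-b)*(d(n) - d(n-2))`
#' with `b = beta_hr` and `alpha` the tracker's most recent frequency
#' parameter (the estimate produced at the previous sample, which breaks the
#' algebraic loop between the feedback filter and the adaptive stages). The
#' recursion is the same constrained band-pass structure as the tracker's
#' oscillator; its poles have radius `sqrt(beta_hr) < 1`, so it is stable for
#' any `alpha` in (-1, 1).
#'
#' @param state a [feedback_bpf_init()] state.
#' @param d input sample (preprocessed PPG).
#' @param alpha_hat centre-frequency parameter in (-1, 1).
#' @return A list with elements `state` and `d_hr`.
#' @export
feedback_bpf_step <- function(state, d, alpha_hat) {
  if (!is.finite(d) || !is.finite(alpha_hat))
    stop("feedback_bpf_step: non-finite input", call. = FALSE)
  if (!(alpha_hat > -1 && alpha_hat < 1))
    stop("feedback_bpf_step: alpha_hat must be in (-1, 1)", call. = FALSE)
  b <- state$beta_hr
  y <- alpha_hat * (1 + b) * state$y1 - b * state$y2 +
    0.5 * (1 - b) * (d - state$d2)
  state$d2 <- state$d1; state$d1 <- d
  state$y2 <- state$y1; state$y1 <- y
  list(state = state, d_hr = y)
}

#' Serialize / restore an ANF state as JSON
#'
#' Snapshot of the tracker state for streaming restart. Doubles are written
#' with 17 significant digits, so a round trip restores the trajectory to
#' within floating-point printing precision.
#'
#' @param state an [anf_init()] state.
#' @return `anf_state_json()`: a JSON string; `anf_state_from_json()`: an
#'   `"anf_state"` object.
#' @export
anf_state_json <- function(state) {
  stopifnot(inherits(state, "anf_state"))
  as.character(jsonlite::toJSON(unclass(state), auto_unbox = TRUE,
                                digits = I(17)))
}

#' @rdname anf_state_json
#' @param json a string produced by [anf_state_json()].
#' @export
anf_state_from_json <- function(json) {
  st <- jsonlite::fromJSON(json)
  st$L <- as.integer(st$L)
  st$n <- as.integer(st$n)
  structure(st, class = "anf_state")
}
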