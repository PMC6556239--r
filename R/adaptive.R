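#' Initialize an NLMS adaptive filter state
#'
#' Normalized least-mean-squares baseline for motion-artifact cancellation.
#' The weight update is `w <- w + mu * u * e / (u'u + eps)`; the regularizer
#' `eps` keeps the division defined when the delay line is all zero.
#' Weights and delay line initialize to zero, so the first `taps` samples are
#' a warm-up transient.
#'
#' @param taps filter order M (number of taps), >= 1.
#' @param mu step size, 0 < mu <= 1.
#' @param eps regularizer added to the normalization term (default 1e-8).
#' @return An object of class `"nlms_state"`.
#' @export
nlms_init <- function(taps = 21, mu = 1e-4, eps = 1e-8) {
  if (taps < 1) stop("taps must be >= 1", call. = FALSE)
  if (!(mu > 0 && mu <= 1)) stop("mu must satisfy 0 < mu <= 1", call. = FALSE)
  if (eps < 0) stop("eps must be >= 0", call. = FALSE)
  structure(list(w = numeric(taps), u = numeric(taps),
                 taps = as.integer(taps), mu = mu, eps = eps,
                 n_mult = 0L, n_steps = 0L),
            class = "nlms_state")
}

#' One NLMS update step
#'
#' Pushes `u_new` into the delay line (newest first), computes the filter
#' output `y = u'w` with the pre-update weights, the error `e = d - y`, and
#' applies the normalized weight update. The state also carries `n_mult`, a
#' running count of the multiplications/divisions the update path performs
#' (3M + 2 per step for an order-M filter: M for `y`, M for `u'u`, 2 for the
#' scalar gain, M for scaling `u`).
#'
#' @param state an [nlms_init()] state.
#' @param u_new new reference sample.
#' @param d desired-signal sample.
#' @return A list with elements `state` (updated), `e` (error), `y` (output).
#' @examples
#' st <- nlms_init(taps = 2, mu = 0.5, eps = 0)
#' st$u <- c(1, 0)                      # preload the delay line
#' out <- nlms_step(st, u_new = 1, d = 1)
#' out$e          # 1
#' out$state$w    # c(0.25, 0.25)
#' @export
nlms_step <- function(state, u_new, d) {
  if (!is.finite(u_new) || !is.finite(d))
    stop("nlms_step: non-finite input", call. = FALSE)
  M <- state$taps
  u <- c(u_new, state$u[-M])
  y <- sum(u * state$w)
  e <- d - y
  nrm <- sum(u * u)
  if (nrm + state$eps == 0)
    stop("nlms_step: all-zero delay line with eps = 0 (division by zero)",
         call. = FALSE)
  g <- state$mu * e / (nrm + state$eps)
  state$w <- state$w + g * u
  state$u <- u
  state$n_mult <- state$n_mult + 3L * M + 2L
  state$n_steps <- state$n_steps + 1L
  list(state = state, e = e, y = y)
}

#' Initialize a sign-sign motion-artifact filter state
#'
#' Three per-axis weight vectors driven by the 3-axis accelerometer. The
#' update uses only the signs of the reference delay line and of the shared
#' error, normalized by the count of nonzero sign entries, so every weight
#' increment is exactly one of `-mu/c`, `0`, `+mu/c` where `c` is that count
#' (equal to M when no delay-line entry is zero). Weights and delay lines
#' initialize to zero (warm-up transient of M samples).
#'
#' @param taps filter order M per axis (default 21).
#' @param mu step size (default 1e-4).
#' @return An object of class `"ss_state"`.
#' @export
ss_init <- function(taps = 21, mu = 1e-4) {
  if (taps < 1) stop("taps must be >= 1", call. = FALSE)
  if (!(mu > 0 && mu <= 1)) stop("mu must satisfy 0 < mu <= 1", call. = FALSE)
  z <- numeric(taps)
  structure(list(w_x = z, w_y = z, w_z = z, u_x = z, u_y = z, u_z = z,
                 taps = as.integer(taps), mu = mu,
                 n_mult = 0L, n_steps = 0L),
            class = "ss_state")
}

#' One sign-sign motion-artifact reduction step
#'
#' Pushes the three accelerometer samples into their delay lines, computes
#' the artifact estimate `y` from the *signs* of the delay lines and the
#' pre-update weights, the residual `e = d - y`, and then updates all three
#' axes with the same scalar `sign(e)`. `sign(0) = 0`, so a zero error
#' freezes all weights, and an all-zero delay line (c = 0) skips that axis's
#' update for the sample.
#'
#' Because the reference enters only through its sign, the update path of an
#' order-M filter needs at most M multiplications per sample (here: one
#' `mu / c` division per axis; the sign-gated weight increments and the
#' sign-weighted output sum are additions). `n_mult` in the state counts
#' these multiplicative operations.
#'
#' @param state an [ss_init()] state.
#' @param ax,ay,az new accelerometer samples.
#' @param d desired-signal sample (corrupted PPG, possibly re-filtered by the
#'   feedback band-pass).
#' @return A list with elements `state` (updated), `e` (residual), `y`
#'   (artifact estimate).
#' @export
sign_sign_step <- function(state, ax, ay, az, d) {
  if (!is.finite(ax) || !is.finite(ay) || !is.finite(az) || !is.finite(d))
    stop("sign_sign_step: non-finite input", call. = FALSE)
  M <- state$taps
  state$u_x <- c(ax, state$u_x[-M])
  state$u_y <- c(ay, state$u_y[-M])
  state$u_z <- c(az, state$u_z[-M])
  sx <- sign(state$u_x); sy <- sign(state$u_y); sz <- sign(state$u_z)
  y <- sum(sx * state$w_x) + sum(sy * state$w_y) + sum(sz * state$w_z)
  e <- d - y
  se <- sign(e)
  if (se != 0) {
    nm <- 0L
    upd <- function(w, s) {
      cnt <- sum(s != 0)
      if (cnt == 0L) return(list(w, 0L))
      incr <- state$mu / cnt
      if (se < 0) incr <- -incr
      list(w + incr * s, 1L)
    }
    rx <- upd(state$w_x, sx); state$w_x <- rx[[1]]; nm <- nm + rx[[2]]
    ry <- upd(state$w_y, sy); state$w_y <- ry[[1]]; nm <- nm + ry[[2]]
    rz <- upd(state$w_z, sz); state$w_z <- rz[[1]]; nm <- nm + rz[[2]]
    state$n_mult <- state$n_mult + nm
  }
  state$n_steps <- state$n_steps + 1L
  list(state = state, e = e, y = y)
}

#' Multiplication counts of the artifact-reduction updates
#'
#' Per-sample multiplication budget of an order-M adaptive filter: the
#' sign-sign update needs only M multiplications (and in this implementation
#' at most 3, one normalizing division per axis), whereas NLMS needs 3M + 1.
#' The step functions carry an `n_mult` counter so the claim can be checked
#' against the operations actually executed.
#'
#' @param M filter order (taps), >= 1.
#' @return Named numeric vector `c(proposed = M, nlms = 3 * M + 1)`.
#' @examples
#' count_weight_multiplications(21)  # c(proposed = 21, nlms = 64)
#' @export
count_weight_multiplications <- function(M) {
  if (M < 1) stop("M must be >= 1", call. = FALSE)
  c(proposed = M, nlms = 3 * M + 1)
}

#' Batch motion-artifact reduction over a sensor frame
#'
#' Streams a whole [sensor_frame()] through the selected adaptive filter, one
#' call to the step function per sample, and returns the residual series.
#' With `algorithm = "nlms"` a three-axis normalized LMS with a shared error
#' and joint normalization over the three delay lines is used, mirroring the
#' sign-sign topology.
#'
#' @param frame a [sensor_frame()].
#' @param algorithm `"sign_sign"` (default) or `"nlms"`.
#' @param taps filter order M (default 21).
#' @param mu step size (default 1e-4).
#' @param d optional desired-signal series overriding `frame$ppg` (used by
#'   the pipeline to feed the feedback-filtered PPG).
#' @return A list with `e` (residual series), `y` (artifact estimate series),
#'   `state` (final filter state), `calls` (number of step calls made).
#' @export
ma_reduce <- function(frame, algorithm = c("sign_sign", "nlms"),
                      taps = 21, mu = 1e-4, d = NULL) {
  algorithm <- match.arg(algorithm)
  validate_sensor_frame(frame)
  if (is.null(d)) d <- frame$ppg
  n <- length(d)
  if (n != length(frame$ppg))
    stop("d must have the same length as the frame channels", call. = FALSE)
  e <- numeric(n); y <- numeric(n)
  if (algorithm == "sign_sign") {
    st <- ss_init(taps, mu)
    for (i in seq_len(n)) {
      r <- sign_sign_step(st, frame$accel_x[i], frame$accel_y[i],
                          frame$accel_z[i], d[i])
      st <- r$state; e[i] <- r$e; y[i] <- r$y
    }
  } else {
    st <- nlms3_init(taps, mu)
    for (i in seq_len(n)) {
      r <- nlms3_step(st, frame$accel_x[i], frame$accel_y[i],
                      frame$accel_z[i], d[i])
      st <- r$state; e[i] <- r$e; y[i] <- r$y
    }
  }
  list(e = e, y = y, state = st, calls = n)
}

# Three-axis NLMS with shared error and joint normalization; internal batch
# engine behind ma_reduce(algorithm = "nlms").
nlms3_init <- function(taps, mu, eps = 1e-8) {
  z <- numeric(taps)
  structure(list(w_x = z, w_y = z, w_z = z, u_x = z, u_y = z, u_z = z,
                 taps = as.integer(taps), mu = mu, eps = eps,
                 n_mult = 0L, n_steps = 0L),
            class = "nlms3_state")
}

nlms3_step <- function(state, ax, ay, az, d) {
  if (!is.finite(ax) || !is.finite(ay) || !is.finite(az) || !is.finite(d))
    stop("nlms3_step: non-finite input", call. = FALSE)
  M <- state$taps
  state$u_x <- c(ax, state$u_x[-M])
  state$u_y <- c(ay, state$u_y[-M])
  state$u_z <- c(az, state$u_z[-M])
  y <- sum(state$u_x * state$w_x) + sum(state$u_y * state$w_y) +
    sum(state$u_z * state$w_z)
  e <- d - y
  nrm <- sum(state$u_x^2) + sum(state$u_y^2) + sum(state$u_z^2)
  g <- state$mu * e / (nrm + state$eps)
  state$w_x <- state$w_x + g * state$u_x
  state$w_y <- state$w_y + g * state$u_y
  state$w_z <- state$w_z + g * state$u_z
  # y: 3M, norm: 3M, gain: 2, scaling: 3M  (per-axis order M -> 3M+1 each)
  state$n_mult <- state$n_mult + 9L * M + 2L
  state$n_steps <- state$n_steps + 1L
  list(state = state, e = e, y = y)
}
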