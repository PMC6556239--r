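# Independent line-by-line oracles of the adaptive recursions, coded directly
# from the difference equations (vector algebra organised differently from the
# package implementation), plus small spectral helpers.

# NLMS: w(n) = w(n-1) + mu * u(n) / (u'(n)u(n) + eps) * e(n), newest-first
# delay line. Returns full weight/error trajectories.
oracle_nlms <- function(u_seq, d_seq, M, mu, eps) {
  n <- length(u_seq)
  w <- matrix(0, n + 1, M)
  e <- numeric(n)
  y <- numeric(n)
  buf <- numeric(M)
  for (i in seq_len(n)) {
    buf <- c(u_seq[i], buf)[1:M]
    y[i] <- drop(crossprod(buf, w[i, ]))
    e[i] <- d_seq[i] - y[i]
    w[i + 1, ] <- w[i, ] + mu * buf / (drop(crossprod(buf)) + eps) * e[i]
  }
  list(w = w[-1, , drop = FALSE], e = e, y = y)
}

# Sign-sign three-axis filter: per-axis update
#   w_a(n) = w_a(n-1) + mu * sign(u_a(n)) / (sign(u_a)' sign(u_a)) * sign(e(n))
# with y(n) = sum_a sign(u_a(n))' w_a(n-1), e(n) = d(n) - y(n), sign(0) = 0,
# and an axis skipped when its sign vector is all zero. `order` permutes the
# per-axis update order (immaterial by construction; exercised in tests).
oracle_sign_sign <- function(ax, ay, az, d, M, mu, order = 1:3) {
  n <- length(d)
  W <- list(matrix(0, n + 1, M), matrix(0, n + 1, M), matrix(0, n + 1, M))
  bufs <- list(numeric(M), numeric(M), numeric(M))
  e <- numeric(n); y <- numeric(n)
  axes <- list(ax, ay, az)
  for (i in seq_len(n)) {
    for (a in 1:3) bufs[[a]] <- c(axes[[a]][i], bufs[[a]])[1:M]
    sg <- lapply(bufs, sign)
    y[i] <- sum(vapply(1:3, function(a) drop(crossprod(sg[[a]], W[[a]][i, ])),
                       numeric(1)))
    e[i] <- d[i] - y[i]
    se <- sign(e[i])
    for (a in order) {
      denom <- drop(crossprod(sg[[a]]))
      W[[a]][i + 1, ] <- if (se == 0 || denom == 0) W[[a]][i, ]
                         else W[[a]][i, ] + mu * sg[[a]] / denom * se
    }
  }
  list(w_x = W[[1]][-1, , drop = FALSE], w_y = W[[2]][-1, , drop = FALSE],
       w_z = W[[3]][-1, , drop = FALSE], e = e, y = y)
}

# Second-order recursion y(n) = a(n)(1+b) y(n-1) - b y(n-2)
#                               + 0.5 (1-b)(x(n) - x(n-2)), zero initial state.
oracle_bpf <- function(x, alpha_seq, b) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    y1 <- if (i >= 2) y[i - 1] else 0
    y2 <- if (i >= 3) y[i - 2] else 0
    x2 <- if (i >= 3) x[i - 2] else 0
    y[i] <- alpha_seq[i] * (1 + b) * y1 - b * y2 + 0.5 * (1 - b) * (x[i] - x2)
  }
  y
}

# Amplitude of the spectral component of x nearest to frequency f (Hz).
fft_amp <- function(x, fs, f) {
  n <- length(x)
  sp <- Mod(stats::fft(x)) * 2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sp[half][which.min(abs(freqs[half] - f))]
}

# Frequency (Hz) of the global periodogram peak of x.
fft_peak_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- which(freqs > 0 & freqs <= fs / 2)
  freqs[half][which.max(sp[half])]
}

# Frame with a pure tone on the PPG channel and silent accelerometer.
tone_frame <- function(f, fs = 25, dur = 60, amp = 1) {
  t <- (0:(fs * dur - 1)) / fs
  z <- numeric(length(t))
  sensor_frame(amp * sin(2 * pi * f * t), z, z, z, fs = fs)
}
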