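test_that("frequency parameter converts to BPM via acos", {
  # 1.5 Hz at fs = 25 is 90 BPM; with zero oscillator state the parameter
  # is untouched and the conversion is exact
  st <- anf_init(fs = 25, f_init_bpm = 90)
  expect_equal(osc_anf_step(st, 0)$hr_bpm, 90, tolerance = 1e-9)
  expect_equal(nr_osc_anf_step(st, 0)$hr_bpm, 90, tolerance = 1e-9)
})

test_that("alpha stays clamped inside (-1, 1) under violent updates", {
  st <- anf_init(fs = 25)
  st$alpha <- 1 - 1e-9
  st$hist <- st$alpha
  st$x1 <- 1e6; st$x2 <- 0; st$Px <- 1e-6; st$n <- 1000L
  r <- osc_anf_step(st, 1)
  expect_true(is.finite(r$hr_bpm))
  expect_lte(r$state$alpha, 1 - 1e-9)
  expect_gte(r$state$alpha, -1 + 1e-9)
})

test_that("tracker converges to a clean tone within 30 s", {
  fs <- 25
  t <- (0:(fs * 35 - 1)) / fs
  for (input in list(sin(2 * pi * 1.2 * t), sign(sin(2 * pi * 1.2 * t)))) {
    tr <- track_frequency(input, anf_init(fs = fs))
    late <- tr$hr_bpm[(30 * fs):length(input)]
    expect_true(all(abs(late - 72) < 1))
  }
})

test_that("converged alpha matches cos(2 pi f / fs) on a noiseless sinusoid", {
  fs <- 25
  for (f in c(1.0, 1.5, 2.2)) {
    t <- (0:(fs * 40 - 1)) / fs
    tr <- track_frequency(sin(2 * pi * f * t), anf_init(fs = fs))
    expect_lt(abs(tr$state$alpha - cos(2 * pi * f / fs)), 0.01)
  }
})

test_that("noise-robust tracker with L = 1 is bit-identical to the plain one", {
  set.seed(7)
  x <- rnorm(1e4)
  a <- track_frequency(x, anf_init(L = 1), variant = "nr_osc")
  b <- track_frequency(x, anf_init(L = 1), variant = "osc")
  expect_identical(a$hr_bpm, b$hr_bpm)
  expect_identical(a$alpha, b$alpha)
})

test_that("alpha history averaging behaves like a running mean", {
  # zero input keeps the oscillator silent, so alpha never moves and the
  # history stays constant: the mean anchor equals that constant
  st <- anf_init(fs = 25, L = 5, f_init_bpm = 80)
  a0 <- st$alpha
  for (i in 1:20) st <- nr_osc_anf_step(st, 0)$state
  expect_equal(st$hist, rep(a0, 5))
  expect_equal(st$alpha, a0)
  # history never exceeds L entries and includes the current alpha
  expect_length(st$hist, st$L)
  expect_equal(st$hist[st$L], st$alpha)
})

test_that("averaging the frequency parameter damps jitter at 0 dB SNR", {
  fs <- 25; dur <- 60; n <- fs * dur
  t <- (0:(n - 1)) / fs
  wins <- 0L
  for (s in 1:6) {
    set.seed(500 + s)
    x <- sin(2 * pi * 1.3 * t) + rnorm(n, 0, sqrt(0.5))
    v5 <- var(track_frequency(x, anf_init(fs = fs, L = 5))$hr_bpm[(30 * fs):n])
    v1 <- var(track_frequency(x, anf_init(fs = fs, L = 1))$hr_bpm[(30 * fs):n])
    wins <- wins + (v5 < v1)
  }
  expect_gte(wins, 4L)
})

test_that("power estimate is the exponentially weighted mean of x^2(n-1)", {
  set.seed(8)
  st <- anf_init(fs = 25, L = 1)
  mu_a <- st$mu_a
  px_ref <- st$Px
  x_prev <- st$x1
  for (i in 1:300) {
    r <- osc_anf_step(st, rnorm(1))
    px_ref <- (1 - mu_a) * px_ref + mu_a * x_prev^2
    expect_lt(abs(r$state$Px - px_ref), 1e-14)
    x_prev <- r$state$x1
    st <- r$state
  }
})

test_that("heart-rate output stays inside (0, 60 * fs / 2]", {
  set.seed(9)
  for (fs in c(25, 50)) {
    tr <- track_frequency(rnorm(2000, sd = 10), anf_init(fs = fs))
    expect_true(all(tr$hr_bpm > 0))
    expect_true(all(tr$hr_bpm <= 60 * fs / 2))
  }
})

test_that("step operations are pure in their state argument", {
  st <- anf_init()
  for (i in 1:50) st <- nr_osc_anf_step(st, sin(i / 3))$state
  expect_identical(nr_osc_anf_step(st, 0.3), nr_osc_anf_step(st, 0.3))
  fb <- feedback_bpf_init()
  expect_identical(feedback_bpf_step(fb, 1.1, 0.5),
                   feedback_bpf_step(fb, 1.1, 0.5))
})

test_that("ANF state survives a JSON snapshot round trip", {
  set.seed(10)
  x <- rnorm(500)
  st <- anf_init()
  for (i in 1:250) st <- nr_osc_anf_step(st, x[i])$state
  st2 <- anf_state_from_json(anf_state_json(st))
  a <- track_frequency(x[251:500], st)
  b <- track_frequency(x[251:500], st2)
  expect_equal(a$hr_bpm, b$hr_bpm, tolerance = 1e-12)
})

test_that("feedback band-pass follows its stated difference equation", {
  # zero input gives zero output
  fb <- feedback_bpf_init()
  out <- numeric(50)
  for (i in 1:50) {
    r <- feedback_bpf_step(fb, 0, 0.5)
    fb <- r$state
    out[i] <- r$d_hr
  }
  expect_identical(out, numeric(50))

  # impulse response equals the independent recursion oracle
  set.seed(12)
  n <- 200
  x <- c(1, numeric(n - 1))
  alpha_seq <- rep(cos(2 * pi * 1.5 / 25), n)
  fb <- feedback_bpf_init(0.8)
  y <- numeric(n)
  for (i in seq_len(n)) {
    r <- feedback_bpf_step(fb, x[i], alpha_seq[i])
    fb <- r$state
    y[i] <- r$d_hr
  }
  expect_lt(max(abs(y - oracle_bpf(x, alpha_seq, 0.8))), 1e-12)

  # and with a time-varying centre and arbitrary input
  x2 <- rnorm(n)
  alpha2 <- cos(2 * pi * seq(1.0, 2.0, length.out = n) / 25)
  fb <- feedback_bpf_init(0.8)
  y2 <- numeric(n)
  for (i in seq_len(n)) {
    r <- feedback_bpf_step(fb, x2[i], alpha2[i])
    fb <- r$state
    y2[i] <- r$d_hr
  }
  expect_lt(max(abs(y2 - oracle_bpf(x2, alpha2, 0.8))), 1e-12)
})

test_that("feedback band-pass favours tones at its centre frequency", {
  fs <- 25; n <- fs * 40
  t <- (0:(n - 1)) / fs
  f0 <- 1.5
  alpha <- cos(2 * pi * f0 / fs)
  gain_at <- function(f) {
    fb <- feedback_bpf_init(0.8)
    x <- sin(2 * pi * f * t)
    y <- numeric(n)
    for (i in seq_len(n)) {
      r <- feedback_bpf_step(fb, x[i], alpha)
      fb <- r$state
      y[i] <- r$d_hr
    }
    fft_amp(y[(n / 2):n], fs, f)
  }
  expect_gte(gain_at(f0), gain_at(f0 + 1))
  expect_gte(gain_at(f0), gain_at(f0 - 1))
})
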