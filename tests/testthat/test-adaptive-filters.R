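test_that("NLMS step reproduces the closed-form update", {
  # zero weights: output zero, error equals desired
  st <- nlms_init(taps = 4, mu = 0.1)
  out <- nlms_step(st, u_new = 0.7, d = 2.5)
  expect_equal(out$y, 0)
  expect_equal(out$e, 2.5)

  # forced two-tap case: mu * u / (u'u) * e = 0.5 * (1,1)/2 * 1
  st <- nlms_init(taps = 2, mu = 0.5, eps = 0)
  st$u <- c(1, 0)
  out <- nlms_step(st, u_new = 1, d = 1)
  expect_equal(out$e, 1)
  expect_equal(out$state$w, c(0.25, 0.25))

  # all-zero delay line with eps = 0 is a division-by-zero error
  st <- nlms_init(taps = 2, mu = 0.5, eps = 0)
  expect_error(nlms_step(st, 0, 1), "zero")
  expect_error(nlms_step(nlms_init(4, 0.1), NaN, 1), "non-finite")
})

test_that("NLMS trajectory matches an independent transliteration oracle", {
  set.seed(11)
  n <- 200; M <- 8; mu <- 0.3; eps <- 1e-8
  u <- rnorm(n); d <- rnorm(n)
  ora <- oracle_nlms(u, d, M, mu, eps)
  st <- nlms_init(M, mu, eps)
  e <- numeric(n)
  for (i in seq_len(n)) {
    r <- nlms_step(st, u[i], d[i])
    st <- r$state
    e[i] <- r$e
    expect_lt(max(abs(st$w - ora$w[i, ])), 1e-12)
  }
  expect_lt(max(abs(e - ora$e)), 1e-12)
})

test_that("sign-sign step obeys its exact update structure", {
  M <- 21; mu <- 1e-4
  # zero error freezes all weights
  st <- ss_init(M, mu)
  r <- sign_sign_step(st, 1, -1, 0.5, d = 0)  # y = 0 with zero weights
  expect_equal(r$e, 0)
  expect_equal(r$state$w_x, numeric(M))
  expect_equal(r$state$w_y, numeric(M))
  expect_equal(r$state$w_z, numeric(M))

  # all-positive delay lines, zero weights, d > 0: every weight gains mu/M
  st <- ss_init(M, mu)
  st$u_x <- st$u_y <- st$u_z <- rep(1, M)
  r <- sign_sign_step(st, 1, 1, 1, d = 3)
  expect_equal(r$e, 3)
  expect_equal(r$state$w_x, rep(mu / M, M))
  expect_equal(r$state$w_y, rep(mu / M, M))
  expect_equal(r$state$w_z, rep(mu / M, M))

  # all-zero delay line skips that axis without error
  st <- ss_init(3, mu)
  r <- sign_sign_step(st, 0, 1, 1, d = 1)
  expect_equal(r$state$w_x, numeric(3))
  expect_gt(sum(abs(r$state$w_y)), 0)

  expect_error(sign_sign_step(ss_init(3, mu), Inf, 0, 0, 1), "non-finite")
})

test_that("sign-sign trajectory matches the transliteration oracle, any update order", {
  set.seed(22)
  n <- 500; M <- 21; mu <- 1e-4
  ax <- sample(c(-1, 1), n, replace = TRUE)
  ay <- sample(c(-1, 1), n, replace = TRUE)
  az <- rnorm(n)  # continuous third axis, occasionally near zero
  d <- rnorm(n)
  ora <- oracle_sign_sign(ax, ay, az, d, M, mu)
  ora_rev <- oracle_sign_sign(ax, ay, az, d, M, mu, order = 3:1)
  st <- ss_init(M, mu)
  e <- numeric(n)
  for (i in seq_len(n)) {
    r <- sign_sign_step(st, ax[i], ay[i], az[i], d[i])
    st <- r$state
    e[i] <- r$e
  }
  expect_lt(max(abs(st$w_x - ora$w_x[n, ])), 1e-12)
  expect_lt(max(abs(st$w_y - ora$w_y[n, ])), 1e-12)
  expect_lt(max(abs(st$w_z - ora$w_z[n, ])), 1e-12)
  expect_lt(max(abs(e - ora$e)), 1e-12)
  # shared pre-update error makes the per-axis update order immaterial
  expect_identical(ora$w_x, ora_rev$w_x)
  expect_identical(ora$e, ora_rev$e)
})

test_that("sign-sign updates are quantised and scale-invariant", {
  set.seed(33)
  n <- 300; M <- 7; mu <- 0.01
  ax <- rnorm(n); ay <- rnorm(n); az <- rnorm(n); d <- rnorm(n)

  run <- function(lambda) {
    st <- ss_init(M, mu)
    traj <- matrix(NA_real_, n, 3 * M)
    for (i in seq_len(n)) {
      r <- sign_sign_step(st, lambda * ax[i], lambda * ay[i], lambda * az[i],
                          d[i])
      st <- r$state
      traj[i, ] <- c(st$w_x, st$w_y, st$w_z)
    }
    traj
  }
  t1 <- run(1)

  # every weight increment is in {-mu/c, 0, +mu/c}; here delay lines are
  # dense (no exact zeros beyond warm-up) so c = M after the first M samples
  incr <- diff(t1[M:n, ])
  expect_true(all(abs(incr) < mu / M + 1e-15))
  expect_true(all(abs(incr) < 1e-15 | abs(abs(incr) - mu / M) < 1e-15))

  # positive rescaling of the accelerometer leaves the trajectory bit-identical
  expect_identical(t1, run(3.7))
  expect_identical(t1, run(0.004))
})

test_that("zero accelerometer input makes the filter transparent", {
  set.seed(44)
  d <- rnorm(200)
  z <- numeric(200)
  fr <- sensor_frame(d, z, z, z, fs = 25)
  out <- ma_reduce(fr)
  expect_identical(out$e, d)
  expect_identical(out$y, numeric(200))
  expect_equal(out$state$w_x, numeric(21))
})

test_that("multiplication budget: M for sign-sign, 3M + 1 for NLMS", {
  expect_equal(count_weight_multiplications(21),
               c(proposed = 21, nlms = 64))
  expect_equal(count_weight_multiplications(1), c(proposed = 1, nlms = 4))
  expect_error(count_weight_multiplications(0), ">= 1")

  # instrumented counters: the sign-sign update path performs at most M
  # multiplicative ops per sample; NLMS at least 3M
  set.seed(55)
  n <- 200; M <- 21
  fr <- sensor_frame(rnorm(n), rnorm(n), rnorm(n), rnorm(n), fs = 25)
  ss <- ma_reduce(fr, "sign_sign", taps = M)$state
  expect_lte(ss$n_mult / ss$n_steps, M)
  nl <- ma_reduce(fr, "nlms", taps = M)$state
  expect_gte(nl$n_mult / nl$n_steps, 3 * M)
})

test_that("weights stay bounded over long runs at default settings", {
  set.seed(66)
  n <- 1e5
  fr <- sensor_frame(rnorm(n), rnorm(n), rnorm(n), rnorm(n), fs = 25)
  ss <- ma_reduce(fr, "sign_sign")$state
  w_ss <- c(ss$w_x, ss$w_y, ss$w_z)
  expect_true(all(is.finite(w_ss)))
  expect_lt(max(abs(w_ss)), 0.05)
  nl <- ma_reduce(fr, "nlms")$state
  w_nl <- c(nl$w_x, nl$w_y, nl$w_z)
  expect_true(all(is.finite(w_nl)))
  expect_lt(max(abs(w_nl)), 1)
})

test_that("residual power drops in the artifact band on the mixed fixture", {
  fx <- standard_fixtures("heavy_artifact")$heavy_artifact
  out <- ma_reduce(fx$frame)
  fs <- fx$frame$fs
  n <- length(out$e)
  idx <- (n - 120 * fs + 1):n  # post-convergence stretch
  drop_db <- 10 * log10(band_power(fx$frame$ppg[idx], fs, 1.8, 2.2) /
                          band_power(out$e[idx], fs, 1.8, 2.2))
  expect_gt(drop_db, 3)
})
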