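# Evaluate code under a temporary RNG seed, restoring global state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic PPG + accelerometer recording
#'
#' Parameter set for [simulate_ppg()]. The generator emulates the additive
#' measurement model the adaptive stage assumes: the observed PPG is a clean
#' quasi-periodic pulse train plus a linear FIR mixture of the accelerometer
#' channels plus white Gaussian noise.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (default 25, the pipeline's working rate).
#' @param hr_profile data frame `t`, `bpm`: piecewise-linear heart-rate
#'   trajectory (interpolated; constant-extrapolated at the ends). Must stay
#'   within (30, 240) BPM.
#' @param pulse_harmonics relative amplitudes of the PPG fundamental and
#'   harmonics (default `c(1, 0.5, 0.2)`).
#' @param ppg_amp overall PPG amplitude in sensor units (default 0.05),
#'   scaling both the clean pulse train and the injected artifact. The
#'   absolute scale matters because the sign-sign stage adapts in fixed
#'   quanta of its step size: its convergence time is roughly (artifact
#'   amplitude)/(step size) samples, so the generator's scale is chosen to
#'   sit at the operating point the standard step size (1e-4) implies, with
#'   adaptation time constants of tens of seconds.
#' @param gait_hz cadence frequency in Hz: scalar or data frame `t`, `hz`.
#' @param accel_amp per-axis accelerometer sinusoid amplitudes (default
#'   `c(1, 0.8, 0.6)`; the three axes carry the cadence at irregular phase
#'   offsets so the per-axis artifacts do not cancel in the sum).
#' @param accel_noise_sd SD of white noise added to each accelerometer axis
#'   (default 0.1).
#' @param mixing_fir FIR coefficients mapping accelerometer to artifact: a
#'   matrix with one column per axis (or a vector recycled across axes).
#'   Plays the role of the unknown system the adaptive filter identifies.
#' @param artifact_gain scalar gain on the summed artifact, relative to the
#'   clean pulse amplitude (0 disables; 1 means the FIR-mixed accelerometer
#'   enters at `ppg_amp` scale).
#' @param noise_sd SD of the white measurement noise on the PPG, in sensor
#'   units (default 0.001, i.e. 2% of the default pulse amplitude).
#' @param seed RNG seed; generation is fully reproducible and leaves the
#'   global RNG state untouched.
#' @return A validated list of class `"sim_spec"`.
#' @export
sim_spec <- function(duration_s = 120, fs = 25,
                     hr_profile = data.frame(t = c(0, duration_s),
                                             bpm = c(75, 75)),
                     pulse_harmonics = c(1, 0.5, 0.2),
                     ppg_amp = 0.05,
                     gait_hz = 2.0,
                     accel_amp = c(1, 0.8, 0.6),
                     accel_noise_sd = 0.1,
                     mixing_fir = default_mixing_fir(),
                     artifact_gain = 0,
                     noise_sd = 0.001,
                     seed = 1) {
  if (duration_s * fs < 1) stop("duration_s * fs must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (accel_noise_sd < 0) stop("accel_noise_sd must be >= 0", call. = FALSE)
  if (any(hr_profile$bpm <= 30) || any(hr_profile$bpm >= 240))
    stop("hr_profile must stay within (30, 240) BPM", call. = FALSE)
  if (is.vector(mixing_fir) && is.numeric(mixing_fir))
    mixing_fir <- matrix(mixing_fir, ncol = 3, nrow = length(mixing_fir))
  if (!is.matrix(mixing_fir) || ncol(mixing_fir) != 3L)
    stop("mixing_fir must be a vector or a matrix with 3 columns",
         call. = FALSE)
  if (ppg_amp <= 0) stop("ppg_amp must be > 0", call. = FALSE)
  spec <- list(duration_s = duration_s, fs = fs, hr_profile = hr_profile,
               pulse_harmonics = pulse_harmonics, ppg_amp = ppg_amp,
               gait_hz = gait_hz,
               accel_amp = accel_amp, accel_noise_sd = accel_noise_sd,
               mixing_fir = mixing_fir, artifact_gain = artifact_gain,
               noise_sd = noise_sd, seed = seed)
  class(spec) <- "sim_spec"
  spec
}

#' Default accelerometer-to-artifact mixing FIR
#'
#' A short (5-tap) low-pass-like FIR per axis, distinct across axes so the
#' identification problem is well posed. Column k applies to axis k.
#'
#' @return A 5 x 3 numeric matrix.
#' @export
default_mixing_fir <- function() {
  cbind(c(0.50, 0.30, 0.15, 0.05, 0.00),
        c(0.40, 0.25, 0.10, 0.05, 0.02),
        c(0.30, 0.20, 0.10, 0.03, 0.01))
}

#' Generate a synthetic PPG + accelerometer recording with known truth
#'
#' Builds, at the spec's sampling rate: accelerometer channels as sinusoids
#' at the cadence frequency (axis-specific amplitude and phase) plus white
#' noise; a clean PPG as a harmonic pulse train whose instantaneous
#' frequency follows the heart-rate profile; and the observed PPG as clean
#' plus `artifact_gain` times the per-axis FIR-filtered accelerometer
#' channels plus white measurement noise. The returned truth is the
#' heart-rate profile sampled at every output sample.
#'
#' @param spec a [sim_spec()].
#' @return A list with `frame` (the observed [sensor_frame()]), `truth`
#'   (per-sample [hr_series()]), `clean` (the noise- and artifact-free PPG
#'   component of the observation) and `artifact` (the injected artifact
#'   component, after all gains).
#' @examples
#' sim <- simulate_ppg(sim_spec(duration_s = 30, seed = 42))
#' sim$frame
#' range(sim$truth$hr_bpm)
#' @export
simulate_ppg <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- as.integer(round(spec$duration_s * spec$fs))
  t <- (seq_len(n) - 1) / spec$fs

  f_hr <- stats::approx(spec$hr_profile$t, spec$hr_profile$bpm, t,
                        rule = 2)$y / 60
  phase <- 2 * pi * cumsum(f_hr) / spec$fs
  clean <- numeric(n)
  for (k in seq_along(spec$pulse_harmonics))
    clean <- clean + spec$pulse_harmonics[k] * cos(k * phase)
  clean <- spec$ppg_amp * clean

  if (is.data.frame(spec$gait_hz)) {
    f_g <- stats::approx(spec$gait_hz$t, spec$gait_hz$hz, t, rule = 2)$y
  } else {
    f_g <- rep(spec$gait_hz, n)
  }
  gphase <- 2 * pi * cumsum(f_g) / spec$fs
  offs <- c(0, 1.9, 4.4)  # irregular so the per-axis artifacts do not cancel

  sim <- with_seed(spec$seed, {
    acc <- lapply(1:3, function(k) {
      spec$accel_amp[k] * cos(gphase + offs[k]) +
        stats::rnorm(n, 0, spec$accel_noise_sd)
    })
    artifact <- numeric(n)
    for (k in 1:3) {
      b <- spec$mixing_fir[, k]
      artifact <- artifact + as.numeric(signal::filter(b, 1, acc[[k]]))
    }
    artifact <- spec$artifact_gain * spec$ppg_amp * artifact
    d <- clean + artifact + stats::rnorm(n, 0, spec$noise_sd)
    list(acc = acc, artifact = artifact, d = d)
  })

  frame <- sensor_frame(sim$d, sim$acc[[1]], sim$acc[[2]], sim$acc[[3]],
                        fs = spec$fs)
  truth <- hr_series(t = t, hr_bpm = f_hr * 60)
  list(frame = frame, truth = truth, clean = clean, artifact = sim$artifact)
}

#' Canonical synthetic test fixtures
#'
#' Named, seeded recordings exercising the regimes the estimator must
#' handle:
#'
#' * `clean75` — 120 s at a constant 75 BPM with no motion (accelerometer
#'   identically zero) and light measurement noise; isolates the tracker.
#' * `ramp` — 70 to 150 BPM linear ramp over 120 s with gait-rate
#'   accelerometer content but no injected artifact (treadmill-like cadence
#'   present, coupling absent); isolates tracking speed.
#' * `heavy_artifact` — constant 78 BPM (1.3 Hz) with a 2.0 Hz gait artifact
#'   strong enough that the artifact, not the pulse, dominates the PPG
#'   spectrum; the regime that requires artifact reduction. 300 s long so
#'   the fixed-quantum sign-sign updates have fully converged well before
#'   the end.
#' * `snr_sweep` — 120 s constant 78 BPM, no motion, measurement noise set
#'   for PPG SNRs of 10, 5, 0 and -5 dB.
#'
#' @param names which fixtures to build (default all).
#' @param seed_base optional integer added to each fixture's documented seed
#'   (for replicate families).
#' @return A named list; each element has `frame`, `truth`, `clean`,
#'   `artifact`, and `spec` (`snr_sweep` is itself a named list of such
#'   elements, one per SNR).
#' @export
standard_fixtures <- function(names = c("clean75", "ramp", "heavy_artifact",
                                        "snr_sweep"),
                              seed_base = 0L) {
  names <- match.arg(names, several.ok = TRUE)
  out <- list()
  if ("clean75" %in% names) {
    sp <- sim_spec(duration_s = 120, accel_amp = c(0, 0, 0),
                   accel_noise_sd = 0, artifact_gain = 0,
                   seed = 101 + seed_base)
    out$clean75 <- c(simulate_ppg(sp), list(spec = sp))
  }
  if ("ramp" %in% names) {
    sp <- sim_spec(duration_s = 120,
                   hr_profile = data.frame(t = c(0, 120), bpm = c(70, 150)),
                   artifact_gain = 0,
                   seed = 202 + seed_base)
    out$ramp <- c(simulate_ppg(sp), list(spec = sp))
  }
  if ("heavy_artifact" %in% names) {
    sp <- sim_spec(duration_s = 300,
                   hr_profile = data.frame(t = c(0, 300), bpm = c(78, 78)),
                   gait_hz = 2.0, artifact_gain = 2,
                   seed = 303 + seed_base)
    out$heavy_artifact <- c(simulate_ppg(sp), list(spec = sp))
  }
  if ("snr_sweep" %in% names) {
    snrs <- c(10, 5, 0, -5)
    fam <- list()
    for (i in seq_along(snrs)) {
      base <- sim_spec(duration_s = 120,
                       hr_profile = data.frame(t = c(0, 120), bpm = c(78, 78)),
                       accel_amp = c(0, 0, 0), accel_noise_sd = 0,
                       artifact_gain = 0, noise_sd = 0,
                       seed = 400 + i + seed_base)
      clean_pow <- mean(simulate_ppg(base)$clean^2)
      sp <- base
      sp$noise_sd <- sqrt(clean_pow / 10^(snrs[i] / 10))
      fam[[paste0("snr_", snrs[i], "dB")]] <- c(simulate_ppg(sp),
                                                list(spec = sp))
    }
    out$snr_sweep <- fam
  }
  out
}
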