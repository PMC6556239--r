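---
title: "Heart-rate estimation from motion-corrupted wrist PPG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate estimation from motion-corrupted wrist PPG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppganf)
```

## The problem

Wrist-worn photoplethysmography (PPG) senses blood-volume pulsation
optically; at rest its dominant periodicity is the heart rate. During
exercise, arm swing and ground impact modulate the optical coupling and
inject motion artifact that is often stronger than the pulse itself and is
strongly correlated with the wrist accelerometer. `ppganf` implements a
streaming estimator aimed at the arithmetic budget of a wearable
microcontroller: every stage is a constant-time per-sample recursion, the
artifact canceller needs at most $M$ multiplications per sample, and no
buffering, FFT, or matrix decomposition is required anywhere in the signal
path.

## Signal model

The observed PPG sample is modelled additively,

$$d(n) = u^\top(n)\,w + v(n) + s(n),$$

where $s(n)$ is the pulse component, $u(n)$ stacks recent accelerometer
samples, $w$ is an unknown linear system turning motion into optical
artifact, and $v(n)$ is white measurement noise. The artifact is assumed (i)
linearly related to the accelerometer with short memory, and (ii)
spectrally overlapping the heart rate, so a fixed notch cannot remove it.
The pulse is assumed quasi-periodic with a dominant fundamental — the
estimator tracks a single tone and makes no attempt to resolve harmonics.

## The three stages

### Preprocessing

Raw records (nominally 125 Hz) are decimated to 25 Hz by a zero-phase
48-tap FIR anti-aliasing low-pass (mirror-padded, normalised to exact unit
DC gain, cutoff at 90% of the target Nyquist) followed by keeping every
k-th sample; only integer factors are supported because the one operating
point that matters is 125 → 25 Hz. The PPG channel is then band-passed
0.4–4.0 Hz (24–240 BPM) with a forward–backward 4th-order Butterworth
filter. The band edges are configurable; the defaults bracket the
physiological heart-rate range while removing baseline wander and
high-frequency noise. Accelerometer channels are decimated but **never**
band-passed: the artifact canceller reads only their signs, and filtering
the reference would distort exactly the zero crossings it depends on.

Non-finite input samples are a hard ingest error, deliberately: a streaming
estimator should fail loudly on corrupt input rather than silently
interpolate. Two simultaneous PPG channels, when present, are averaged
(configurable to first-channel-only).

### Sign-sign motion-artifact reduction

Three order-$M$ adaptive filters, one per accelerometer axis, share a
single error. With $s_a(n) = \operatorname{sign}(u_a(n))$ elementwise on
axis $a$'s delay line:

$$y(n) = \sum_a s_a^\top(n)\, \hat w_a(n-1), \qquad e(n) = d(n) - y(n),$$
$$\hat w_a(n) = \hat w_a(n-1) + \mu\,
  \frac{s_a(n)}{s_a^\top(n) s_a(n)}\, \operatorname{sign}(e(n)).$$

Because both the reference and the error enter only through their signs,
every weight update is an add/subtract of the fixed quantum $\mu / c$
(where $c = s_a^\top s_a$ counts the nonzero sign entries, equal to $M$ for
dense data), and the whole update path costs at most $M$ multiplications
per sample versus $3M + 1$ for the NLMS baseline that is also provided.
The step functions carry an `n_mult` counter so this budget is checked
against the operations actually executed, not just asserted.

Conventions the recursion itself does not fix:

* $\operatorname{sign}(0) = 0$ (three-valued sign), which makes "zero error
  → no update" exact and keeps the normaliser meaningful;
* an all-zero delay line ($c = 0$) skips that axis's update for the sample,
  without error — and makes the stage exactly transparent ($e \equiv d$)
  when no motion reference exists;
* weights and delay lines initialise to zero, giving a warm-up transient of
  $M$ samples;
* all three axes update from the *pre-update* weights and the same $e(n)$,
  so the per-axis update order is immaterial (asserted in the tests);
* the NLMS baseline adds a regulariser $\varepsilon = 10^{-8}$ to its
  normalisation term so an all-zero delay line cannot divide by zero.

A consequence worth stating plainly: the update quantum $\mu$ is an
*absolute* amplitude. The canceller's output $y$ grows by at most $3\mu$
per sample, so cancelling an artifact of amplitude $A$ takes at least
$A/3\mu$ samples. The step size and the input scale must therefore be
matched — with the standard $\mu = 10^{-4}$, inputs of amplitude a few
hundredths give adaptation time constants of tens of seconds, which is the
operating point this package (and its synthetic generator) adopts.
Equivalently, users with inputs in raw ADC counts should scale them (or
$\mu$) accordingly.

### Oscillator-based adaptive notch frequency tracking

The residual $e(n)$ drives a second-order IIR resonator through a hard
limiter:

$$x(n) = \hat\alpha(n)(1+\beta)x(n-1) - \beta x(n-2)
       + \tfrac12 (1-\beta)\big(\operatorname{sign} e(n)
       - \operatorname{sign} e(n-2)\big),$$

whose frequency parameter $\hat\alpha = \cos\omega$ is adapted by a
normalised gradient step on the prediction error
$e_\alpha(n) = x(n) - 2\bar\alpha(n) x(n-1) + x(n-2)$:

$$P_x(n) = (1-\mu_a)P_x(n-1) + \mu_a x^2(n-1), \qquad
\hat\alpha(n+1) = \bar\alpha(n) + \mu_a \frac{x(n-1)}{2 P_x(n)} e_\alpha(n),$$

and the heart rate in BPM is $\arccos(\hat\alpha)\, f_s\, 60 / 2\pi$. In
the plain tracker $\bar\alpha(n) = \hat\alpha(n)$; the noise-robust variant
takes $\bar\alpha(n)$ as the mean of the last $L$ values of $\hat\alpha$
*including the current one* (before $L$ samples exist, the mean runs over
what exists). With $L = 1$ the two variants are bit-identical, which the
tests check on $10^4$ random samples. Averaging the frequency parameter
damps estimate jitter markedly at low SNR (roughly 5× lower trajectory
variance at 0 dB in the shipped experiment) at the cost of a small extra
tracking lag.

Numerical guards, all of them package conventions: $\hat\alpha$ is clamped
to $[-1 + 10^{-9},\, 1 - 10^{-9}]$ after every update so the arccosine is
always defined; $P_x$ initialises at $10^{-6}$ so the first update is
defined; the adaptation gain $\mu_a x(n-1) / 2P_x$ is additionally capped
at magnitude 1 for the first $f_s$ samples to suppress the start-up
transient while $P_x$ is still learning the drive level; and the tracker
initialises at $\hat\alpha = \cos(2\pi f_0/f_s)$ with $f_0$ equivalent to
90 BPM, a resting-to-light-exercise prior.

### Heart-rate-centred feedback band-pass

In the noise-robust configuration the *desired* signal of the artifact
canceller is not the preprocessed PPG $d(n)$ but a re-filtered version
$d_{hr}(n)$, produced by a second-order band-pass whose centre follows the
tracker:

$$d_{hr}(n) = \hat\alpha (1+\beta_{hr})\, d_{hr}(n-1) - \beta_{hr}\,
d_{hr}(n-2) + \tfrac12 (1-\beta_{hr})\big(d(n) - d(n-2)\big).$$

Two deliberate choices here. First, the filter is implemented in recursive
form — the delayed terms on the right are past *outputs*. A feed-forward
reading of the same coefficients (past inputs in the recursive slots)
would make the filter FIR and contradict its stated second-order IIR
band-pass structure; the recursive form has poles of radius
$\sqrt{\beta_{hr}} < 1$ and is stable for any $\hat\alpha \in (-1, 1)$.
Second, at sample $n$ the filter uses the $\hat\alpha$ produced at sample
$n-1$, which breaks the algebraic loop between the feedback filter, the
canceller and the tracker; the one-sample-stale centre is immaterial at
these adaptation rates. The feedback stage is active by default and can be
disabled (`anf$feedback = FALSE`) to reproduce the plain
canceller-plus-tracker topology.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `fs_target` | working sampling rate (Hz) | 25 | covers 0–12.5 Hz, 5× cheaper than 125 Hz |
| `band_low_hz`, `band_high_hz` | PPG passband (Hz) | 0.4, 4.0 | 24–240 BPM plus headroom for harmonics |
| `ma$taps` ($M$) | canceller order per axis | 21 | best error in the order sweep; ~0.8 s of reference memory at 25 Hz |
| `ma$mu` ($\mu$) | update quantum | 1e-4 | matched to inputs of amplitude a few hundredths (see above) |
| `anf$beta` ($\beta$) | resonator bandwidth | 0.95 | narrow notch: single-tone selectivity |
| `anf$mu_a` ($\mu_a$) | tracker step | 0.025 | locks on a clean tone in ~2 s at 25 Hz |
| `anf$L` | frequency-averaging length | 5 | jitter reduction with ~0.1 s extra lag |
| `anf$beta_hr` ($\beta_{hr}$) | feedback band-pass bandwidth | 0.8 | ±≈0.4 Hz around the estimate |
| `anf$f_init_bpm` | initial HR prior | 90 | resting-to-light-exercise |
| `window$window_s`, `window$step_s` | reporting windows | 8, 2 | the benchmark reference cadence for treadmill recordings |

## Windowing and evaluation

The tracker emits one BPM value per sample; reported heart rate is the
arithmetic mean (median available) over 8 s windows advanced by 2 s,
stamped at the window end. Windows overlapping the first `window_s` of
data are emitted but flagged `warmup`, and the evaluation helper drops
them by default. How a per-sample trajectory should become a per-window
report is genuinely open; the mean over the reference cadence is the
simplest defensible rule and is therefore the default rather than a claim.

`hr_errors()` inner-joins estimate and reference on timestamps (tolerance
half the reference step), then reports the mean absolute error in BPM, the
mean absolute percentage error *in percent* (the ratio form of this metric
is reported ×100 here: at plausible heart rates the unscaled ratio would
be two orders of magnitude smaller than the BPM error, whereas published
values of the two metrics for this task are of comparable magnitude, which
is only consistent with the percent convention), and Bland–Altman
agreement: bias ± 1.96 sample standard deviations (n−1 denominator) of the
paired differences, plus the least-squares line of estimate on reference.

## The synthetic generator

`simulate_ppg()` produces exactly the structure the model assumes: a
harmonic pulse train (fundamental + 2 harmonics, relative amplitudes
1.0/0.5/0.2) whose instantaneous frequency follows a piecewise-linear BPM
profile; accelerometer axes as cadence-frequency sinusoids at irregular
phase offsets plus white noise; artifact as a per-axis 5-tap FIR of the
accelerometer, scaled by `artifact_gain`; and white measurement noise. The
linear FIR artifact class guarantees the canceller's identifiability —
an ordinary least-squares regression of the observed PPG on lagged
accelerometer samples recovers the mixing coefficients, which the tests
use as a system-identification oracle. A soft-clipping nonlinearity knob
deliberately does not exist: departures from the model class are a
documented non-goal of the generator.

The default amplitude is `ppg_amp = 0.05` sensor units. This is the
scale-matching point discussed above: with the standard $\mu = 10^{-4}$,
artifacts of a few times `ppg_amp` are cancelled with time constants of
tens of seconds. Seeds are explicit everywhere; generation restores the
global RNG state.

What passing tests on this generator do **not** show: real PPG pulse
morphology (dicrotic notch, amplitude modulation), nonlinear or
time-varying motion coupling, accelerometer saturation, sensor drift, skin
tone and contact-pressure effects, or the SNR profile of any particular
recorded dataset. The generator validates the estimator's mechanics under
its own model assumptions, not its field accuracy.

`standard_fixtures()` ships four canonical regimes with fixed documented
seeds: `clean75` (tracker alone), `ramp` (70→150 BPM over 120 s, cadence
present but uncoupled), `heavy_artifact` (300 s at 78 BPM under a
dominant 2 Hz artifact, long enough for full canceller convergence), and
an SNR sweep at 10/5/0/−5 dB.

## Problem sizes used in the shipped checks

Transliteration equivalence runs 500 random steps at $M = 21$;
degeneracy identities run $10^4$ samples; tone recovery uses 35 s at
25 Hz; the ramp and heavy-artifact checks use the fixtures above (3 000
and 7 500 samples); the noise-robustness comparison uses 20 seeded 60 s
runs; weight-boundedness runs $10^5$ steps. These sizes make every
quantity stable to well inside its asserted tolerance.

## Known limitations

* **Harmonic ambiguity.** The tracker follows the strongest tone of a
  hard-limited residual and has no notion of a harmonic stack. When a
  dominant artifact first captures the tracker and is then cancelled, the
  feedback band-pass can hand the tracker to the pulse's *second harmonic*
  rather than its fundamental — from a 2 Hz capture, a 2.6 Hz harmonic is
  spectrally closer than a 1.3 Hz fundamental. On the heavy-artifact
  fixture family this branch is decided by the noise realisation during
  the handover; roughly half of the seeds lock to the fundamental (as the
  canonical fixture does) and the rest to its double. Harmonic
  disambiguation is explicitly out of scope; treat sustained estimates
  near twice a plausible rate with suspicion.
* **Tracking lag.** On a 0.67 BPM/s ramp the windowed estimate trails
  truth by ≈3 BPM (≈4.5 s of loop lag at the default steps). Faster
  profiles will show proportionally larger lag.
* **Absolute scale.** As discussed, $\mu$ fixes an absolute amplitude
  scale; grossly mismatched input amplitudes make the canceller appear
  either frozen or noisy.
* **Integer decimation only**, and the resampler assumes records longer
  than a few filter lengths.
* The estimator reports a value from the very first sample; everything
  before the first full window (and strictly, the first $M$ samples of the
  canceller and the tracker's first seconds) is transient, which is why
  warm-up windows are flagged rather than trusted.
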