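#' Compare an estimated heart-rate series against a reference
#'
#' Aligns the two series by an inner join on timestamps (within half the
#' reference's median step by default) and computes the standard agreement
#' summary for wearable heart-rate validation:
#'
#' * `error1` — mean absolute error in BPM,
#' * `error2` — mean absolute percentage error in percent (the per-window
#'   absolute error divided by the reference, averaged, times 100),
#' * Bland-Altman statistics — mean difference (bias) of estimated minus
#'   reference and limits of agreement at bias +/- 1.96 standard deviations
#'   of the differences (sample SD, n - 1 denominator),
#' * the least-squares line of estimated on reference HR.
#'
#' @param est estimated [hr_series()] (or data frame with `t`, `hr_bpm`).
#' @param ref reference [hr_series()].
#' @param tol timestamp matching tolerance in seconds; default half the
#'   median reference step.
#' @param use_warmup if `FALSE` (default) windows flagged as warm-up in
#'   `est` are dropped before comparison.
#' @return An object of class `"hr_error_report"`: list with `error1`,
#'   `error2`, `n`, `bland_altman` (named vector `bias`, `loa_lower`,
#'   `loa_upper`), `fit` (named vector `slope`, `intercept`).
#' @examples
#' est <- hr_series(t = c(2, 4), hr_bpm = c(101, 99))
#' ref <- hr_series(t = c(2, 4), hr_bpm = c(100, 100))
#' hr_errors(est, ref)
#' @export
hr_errors <- function(est, ref, tol = NULL, use_warmup = FALSE) {
  if (!use_warmup && !is.null(est$warmup)) est <- est[!est$warmup, ]
  if (nrow(est) == 0L || nrow(ref) == 0L)
    stop("empty series after warm-up filtering", call. = FALSE)
  if (is.null(tol)) {
    tol <- if (nrow(ref) > 1L) stats::median(diff(ref$t)) / 2 else Inf
  }
  idx <- vapply(est$t, function(ti) {
    j <- which.min(abs(ref$t - ti))
    if (abs(ref$t[j] - ti) <= tol) j else NA_integer_
  }, integer(1))
  keep <- !is.na(idx)
  if (!any(keep))
    stop("alignment error: no common timestamps within tolerance ", tol,
         call. = FALSE)
  e <- est$hr_bpm[keep]
  r <- ref$hr_bpm[idx[keep]]
  n <- length(e)
  diffs <- e - r
  error1 <- mean(abs(diffs))
  error2 <- mean(abs(diffs) / r) * 100
  if (n >= 2L) {
    bias <- mean(diffs)
    s <- stats::sd(diffs)
    ba <- c(bias = bias, loa_lower = bias - 1.96 * s,
            loa_upper = bias + 1.96 * s)
  } else {
    ba <- c(bias = mean(diffs), loa_lower = NA_real_, loa_upper = NA_real_)
  }
  if (n >= 2L && stats::var(r) > 0) {
    cf <- stats::coef(stats::lm(e ~ r))
    fit <- c(slope = unname(cf[2L]), intercept = unname(cf[1L]))
  } else {
    fit <- c(slope = NA_real_, intercept = NA_real_)
  }
  structure(list(error1 = error1, error2 = error2, n = n,
                 bland_altman = ba, fit = fit,
                 est = e, ref = r),
            class = "hr_error_report")
}

#' @export
print.hr_error_report <- function(x, ...) {
  cat(sprintf("HR agreement over %d windows\n", x$n))
  cat(sprintf("  Error1 (MAE):  %.2f BPM\n", x$error1))
  cat(sprintf("  Error2 (MAPE): %.2f %%\n", x$error2))
  if (is.finite(x$bland_altman["loa_lower"]))
    cat(sprintf("  Bland-Altman:  bias %.2f BPM, LoA [%.2f, %.2f] BPM\n",
                x$bland_altman["bias"], x$bland_altman["loa_lower"],
                x$bland_altman["loa_upper"]))
  if (is.finite(x$fit["slope"]))
    cat(sprintf("  Fit: est = %.4f * ref + %.3f\n",
                x$fit["slope"], x$fit["intercept"]))
  invisible(x)
}

#' @export
plot.hr_error_report <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  m <- (x$est + x$ref) / 2
  d <- x$est - x$ref
  plot(m, d, xlab = "mean of methods (BPM)",
       ylab = "estimated - reference (BPM)", main = "Bland-Altman", ...)
  abline(h = x$bland_altman, lty = c(1, 2, 2), col = "red3")
  plot(x$ref, x$est, xlab = "reference HR (BPM)",
       ylab = "estimated HR (BPM)", main = "Agreement", ...)
  abline(0, 1, col = "grey60")
  if (is.finite(x$fit["slope"]))
    abline(x$fit["intercept"], x$fit["slope"], col = "red3")
  invisible(x)
}
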