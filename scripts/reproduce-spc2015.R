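#!/usr/bin/env Rscript

# Re-runs the full estimator on the IEEE Signal Processing Cup 2015 wrist
# recordings (not shipped here; obtain them separately) and reports per-set
# Error1/Error2 against the bundled ECG-derived reference heart rates.
#
# Usage:
#   Rscript scripts/reproduce-spc2015.R --data <dir> [--config <yaml>]
#
# <dir> must contain the DATA_*.mat recordings and the matching *BPM*.mat
# reference files. The MATLAB containers are converted to CSV with the
# system Python (scipy.io.loadmat); the channel-to-role layout and raw
# sampling rate are read from the YAML config (defaults below), never
# hard-coded.

suppressPackageStartupMessages(library(ppganf))

argv <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(argv == flag)
  if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
}
data_dir <- get_arg("--data")
if (is.null(data_dir)) stop("usage: reproduce-spc2015.R --data <dir> [--config <yaml>]")

cfg <- list(fs_raw = 125, fs_target = 25, band_low_hz = 0.4, band_high_hz = 4,
            ppg_rows = c(2, 3), accel_rows = c(4, 5, 6), ref_cadence_s = 2,
            window_s = 8)
cfg_path <- get_arg("--config")
if (!is.null(cfg_path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(cfg_path))

mat_to_csv <- function(mat, rows_ppg, rows_acc) {
  csv <- tempfile(fileext = ".csv")
  py <- sprintf(
    "import sys, numpy as np; from scipy.io import loadmat
m = loadmat(sys.argv[1]); sig = [v for k, v in m.items() if not k.startswith('__')][0]
rows = [%s]
np.savetxt(sys.argv[2], sig[np.array(rows) - 1].T, delimiter=',',
           header=','.join(['c%%d' %% r for r in rows]), comments='')",
    paste(c(rows_ppg, rows_acc), collapse = ","))
  status <- system2("python", c("-c", shQuote(py), shQuote(mat), shQuote(csv)))
  if (status != 0) stop("python/scipy conversion failed for ", mat)
  csv
}

recs <- sort(list.files(data_dir, pattern = "^DATA_.*\\.mat$", full.names = TRUE))
if (!length(recs)) stop("no DATA_*.mat recordings found under ", data_dir)
cat(sprintf("%-28s %8s %8s\n", "record", "Error1", "Error2"))
e1 <- e2 <- numeric(0)
for (rec in recs) {
  ref_mat <- list.files(data_dir, full.names = TRUE,
                        pattern = paste0(".*BPM.*",
                                         sub("^DATA_", "", basename(rec))))
  if (!length(ref_mat)) { warning("no reference for ", basename(rec)); next }

  csv <- mat_to_csv(rec, cfg$ppg_rows, cfg$accel_rows)
  cols <- as.list(paste0("c", c(cfg$ppg_rows, cfg$accel_rows)))
  names(cols) <- c("ppg", "ppg2", "ax", "ay", "az")[seq_along(cols)]
  frame <- read_sensor_csv(csv, columns = cols, fs = cfg$fs_raw)
  frame <- bandpass_prefilter(resample_frame(frame, cfg$fs_target),
                              cfg$band_low_hz, cfg$band_high_hz)
  fit <- estimate_hr(frame, hr_config(
    window = list(window_s = cfg$window_s, step_s = cfg$ref_cadence_s)))

  ref_csv <- tempfile(fileext = ".csv")
  system2("python", c("-c", shQuote(
    "import sys, numpy as np; from scipy.io import loadmat
m = loadmat(sys.argv[1]); bpm = [v for k, v in m.items() if not k.startswith('__')][0]
np.savetxt(sys.argv[2], np.ravel(bpm), delimiter=',')"),
    shQuote(ref_mat[1]), shQuote(ref_csv)))
  bpm <- scan(ref_csv, quiet = TRUE)
  # reference windows: 8 s advanced by 2 s, stamped at window end
  ref <- hr_series(t = cfg$window_s + cfg$ref_cadence_s * (seq_along(bpm) - 1),
                   hr_bpm = bpm)
  rep <- hr_errors(fitted(fit), ref)
  cat(sprintf("%-28s %8.2f %8.2f\n", basename(rec), rep$error1, rep$error2))
  e1 <- c(e1, rep$error1); e2 <- c(e2, rep$error2)
}
cat(sprintf("%-28s %8.2f %8.2f   (mean +/- sd Error1: %.2f +/- %.2f BPM)\n",
            "mean", mean(e1), mean(e2), mean(e1), sd(e1)))
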