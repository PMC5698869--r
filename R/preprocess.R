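#' Preprocessing configuration for the ERP pipeline
#'
#' Collects every tunable of the continuous-EEG-to-MMR reduction with the
#' study defaults: mastoid-average re-reference, 30 Hz low-pass, decimation
#' to 250 Hz, 0.5 Hz high-pass, epochs on `[-200, 1250)` ms, baseline
#' `[-200, 0)` ms, rejection of trials exceeding +/-80 uV within any 200 ms
#' window, and quantification of the late MMR as the mean over the anterior
#' ROI (F3, Fz, F4) within `[300, 600)` ms.  Set `lowpass_hz` or
#' `highpass_hz` to `NULL` to disable a filter (used e.g. for noiseless
#' identity checks).
#'
#' @param lowpass_hz low-pass cutoff (Hz) or `NULL`.
#' @param highpass_hz high-pass cutoff (Hz) or `NULL`.
#' @param resample_hz target rate after decimation.
#' @param reject_threshold_uv absolute amplitude bound for artifact
#'   rejection.
#' @param reject_window_ms sliding-window length for the rejection criterion.
#' @param reject_criterion `"absolute"` (any sample beyond the bound) or
#'   `"peak_to_peak"` (range within any window beyond twice the bound).
#' @param epoch_window_ms,baseline_window_ms,mmr_window_ms half-open windows
#'   in ms relative to stimulus onset.
#' @param roi anterior region-of-interest channels.
#' @param reference mastoid reference labels.
#' @param filter_order Butterworth order of each zero-phase filter.
#' @param contrast `"pooled"` (all deviants minus all retained standards) or
#'   `"matched"` (same-syllable contrast averaged over syllables).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(lowpass_hz = 30, highpass_hz = 0.5,
                              resample_hz = 250,
                              reject_threshold_uv = 80,
                              reject_window_ms = 200,
                              reject_criterion = c("absolute", "peak_to_peak"),
                              epoch_window_ms = c(-200, 1250),
                              baseline_window_ms = c(-200, 0),
                              mmr_window_ms = c(300, 600),
                              roi = c("F3", "Fz", "F4"),
                              reference = c("A1", "A2"),
                              filter_order = 4,
                              contrast = c("pooled", "matched")) {
  reject_criterion <- match.arg(reject_criterion)
  contrast <- match.arg(contrast)
  stopifnot(length(epoch_window_ms) == 2, diff(epoch_window_ms) > 0,
            length(baseline_window_ms) == 2, length(mmr_window_ms) == 2)
  if (baseline_window_ms[1] < epoch_window_ms[1] ||
      baseline_window_ms[2] > epoch_window_ms[2]) {
    stop("baseline window must lie within the epoch window")
  }
  if (mmr_window_ms[1] < epoch_window_ms[1] ||
      mmr_window_ms[2] > epoch_window_ms[2]) {
    stop("MMR window must lie within the epoch window")
  }
  structure(list(lowpass_hz = lowpass_hz, highpass_hz = highpass_hz,
                 resample_hz = resample_hz,
                 reject_threshold_uv = reject_threshold_uv,
                 reject_window_ms = reject_window_ms,
                 reject_criterion = reject_criterion,
                 epoch_window_ms = epoch_window_ms,
                 baseline_window_ms = baseline_window_ms,
                 mmr_window_ms = mmr_window_ms,
                 roi = roi, reference = reference,
                 filter_order = filter_order, contrast = contrast),
            class = "preprocess_config")
}

#' Re-reference to the mastoid average
#'
#' Subtracts the instantaneous mean of the two mastoid channels from every
#' channel.  Idempotent: applying it twice equals applying it once.
#'
#' @param eeg a `continuous_eeg`.
#' @param labels the two mastoid labels (default A1, A2).
#' @return The re-referenced `continuous_eeg`.
#' @export
rereference <- function(eeg, labels = c("A1", "A2")) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (!all(labels %in% eeg$channel_labels)) {
    stop("missing mastoid channel(s): ",
         paste(setdiff(labels, eeg$channel_labels), collapse = ", "))
  }
  ref <- colMeans(eeg$samples[labels, , drop = FALSE])
  eeg$samples <- sweep(eeg$samples, 2, ref)
  eeg$reference_label <- paste0("mean(", paste(labels, collapse = ","), ")")
  eeg
}

# squared magnitude response |H(f)|^2 of a rational digital filter
filter_mag2 <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(b * zz^(seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(seq_along(a) - 1)), complex(1))
  Mod(num / den)^2
}

# measured -3 dB point of the two-pass (zero-phase) filter: amplitude gain
# of filtfilt is |H|^2, so solve |H(f)|^2 = 2^(-1/2)
measure_minus3db <- function(b, a, fs, kind, cutoff) {
  f <- seq(max(cutoff / 4, 1e-4), min(4 * cutoff, fs / 2 * 0.999),
           length.out = 2000)
  g <- filter_mag2(b, a, f, fs)
  target <- 2^(-1 / 2)
  s <- if (kind == "lowpass") g - target else target - g
  i <- which(diff(sign(s)) != 0)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  f[i] + (f[i + 1] - f[i]) * (0 - s[i]) / (s[i + 1] - s[i])
}

#' Zero-phase low-pass / high-pass filtering
#'
#' Butterworth filter applied forward and backward (`signal::filtfilt`), so
#' the net response is zero-phase with squared magnitude.  The design cutoff
#' is analytically pre-compensated so that the *realized* two-pass -3 dB
#' point sits at the nominal cutoff; the realized point, measured from the
#' magnitude response, is attached as attribute `minus3db_hz` of the result.
#'
#' @param eeg a `continuous_eeg`.
#' @param kind `"lowpass"` or `"highpass"`.
#' @param cutoff_hz nominal cutoff (must be below Nyquist).
#' @param order Butterworth order (default 4).
#' @return Filtered `continuous_eeg` with attribute `minus3db_hz`.
#' @export
filter_signal <- function(eeg, kind = c("lowpass", "highpass"), cutoff_hz,
                          order = 4) {
  kind <- match.arg(kind)
  stopifnot(inherits(eeg, "continuous_eeg"), is_num1(cutoff_hz))
  nyq <- eeg$fs_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff must be below the Nyquist frequency")
  # two passes of an order-n Butterworth reach -3 dB where
  # (f/fc)^(2n) = sqrt(2) - 1; compensate the design cutoff accordingly
  k <- (sqrt(2) - 1)^(1 / (2 * order))
  design <- if (kind == "lowpass") cutoff_hz / k else cutoff_hz * k
  design <- min(design, nyq * 0.999)
  filt <- signal::butter(order, design / nyq,
                         type = if (kind == "lowpass") "low" else "high")
  eeg$samples <- t(apply(eeg$samples, 1, function(ch) {
    signal::filtfilt(filt, ch)
  }))
  rownames(eeg$samples) <- eeg$channel_labels
  attr(eeg, "minus3db_hz") <- measure_minus3db(filt$b, filt$a, eeg$fs_hz,
                                               kind, cutoff_hz)
  eeg
}

#' Decimate a recording to a lower sampling rate
#'
#' Integer-factor decimation (sample picking).  The caller contract is that
#' an anti-alias low-pass has already been applied ([filter_signal()] at the
#' study's 30 Hz is well below the post-decimation Nyquist).  Upsampling and
#' non-integer factors are refused.
#'
#' @param eeg a `continuous_eeg`.
#' @param target_hz target rate (default 250).
#' @return The decimated `continuous_eeg`.
#' @export
resample_eeg <- function(eeg, target_hz = 250) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (target_hz > eeg$fs_hz) stop("upsampling is not supported")
  fac <- eeg$fs_hz / target_hz
  if (abs(fac - round(fac)) > 1e-9) {
    stop("sampling-rate ratio must be an integer")
  }
  fac <- as.integer(round(fac))
  if (fac > 1) {
    eeg$samples <- eeg$samples[, seq(1, ncol(eeg$samples), by = fac),
                               drop = FALSE]
    eeg$fs_hz <- target_hz
  }
  eeg
}
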