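#' Cut a continuous recording into baseline-corrected epochs
#'
#' Extracts per-trial windows on the half-open grid
#' `[epoch_window_ms[1], epoch_window_ms[2])` (sample count =
#' `floor(span / step)`, i.e. 362 samples for `[-200, 1250)` at 250 Hz) and
#' subtracts the per-channel mean over the baseline window.  A standard
#' presented directly after a deviant is flagged
#' `excluded_reason = "standard_after_deviant"`; trials whose window falls
#' outside the recording are flagged `"edge"` rather than erroring.
#'
#' @param eeg a (preprocessed) `continuous_eeg`.
#' @param events data frame with `onset_ms` (recording time), `condition`,
#'   and optionally `syllable` and `block`.
#' @param config a [preprocess_config()].
#' @return An `epoch_set`: list with `data` (trials x channels x time array),
#'   `times_ms`, `condition`, `syllable`, `block`, `valid`,
#'   `excluded_reason`, `channel_labels`, `fs_hz`.
#' @export
epoch_eeg <- function(eeg, events, config = preprocess_config()) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  fs <- eeg$fs_hz
  step <- 1000 / fs
  win <- config$epoch_window_ms
  n_t <- floor((win[2] - win[1]) / step)
  times <- win[1] + step * (0:(n_t - 1))
  rel_idx <- round(times / step)               # sample offsets from onset
  bl <- which(times >= config$baseline_window_ms[1] &
              times < config$baseline_window_ms[2])
  n_tr <- nrow(events)
  nch <- nrow(eeg$samples)
  dat <- array(NA_real_, dim = c(n_tr, nch, n_t))
  valid <- rep(TRUE, n_tr)
  reason <- rep("none", n_tr)

  blocks <- events$block %||% rep(1L, n_tr)
  ord <- order(blocks, events$onset_ms)
  prev_dev <- c(FALSE, events$condition[ord][-n_tr] == "deviant" &
                  blocks[ord][-n_tr] == blocks[ord][-1])
  after_dev <- logical(n_tr)
  after_dev[ord] <- prev_dev
  flag_sad <- after_dev & events$condition == "standard"
  reason[flag_sad] <- "standard_after_deviant"
  valid[flag_sad] <- FALSE

  onset_sample <- round(events$onset_ms / step)  # 0-based
  n_samp <- ncol(eeg$samples)
  for (k in seq_len(n_tr)) {
    idx <- onset_sample[k] + rel_idx + 1         # 1-based
    if (idx[1] < 1 || idx[n_t] > n_samp) {
      valid[k] <- FALSE
      if (reason[k] == "none") reason[k] <- "edge"
      next
    }
    ep <- eeg$samples[, idx, drop = FALSE]
    ep <- ep - rowMeans(ep[, bl, drop = FALSE])
    dat[k, , ] <- ep
  }

  structure(list(data = dat, times_ms = times,
                 condition = events$condition,
                 syllable = events$syllable %||% rep(NA_character_, n_tr),
                 block = blocks,
                 valid = valid, excluded_reason = reason,
                 channel_labels = eeg$channel_labels, fs_hz = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d trials x %d channels x %d samples @ %g Hz; %d valid\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs_hz,
              sum(x$valid)))
  invisible(x)
}

# running range (max - min) over a centred window of w samples
rolling_exceeds <- function(v, w, thr, criterion) {
  if (criterion == "absolute") return(any(abs(v) > thr, na.rm = TRUE))
  n <- length(v)
  if (n <= w) return(diff(range(v)) > 2 * thr)
  starts <- seq_len(n - w + 1)
  for (s in starts) {
    seg <- v[s:(s + w - 1)]
    if (max(seg) - min(seg) > 2 * thr) return(TRUE)
  }
  FALSE
}

#' Flag artifact-contaminated epochs
#'
#' Default semantics: a trial is invalid if any channel sample within any
#' 200 ms sliding window exceeds the +/-80 uV amplitude bound (for an
#' absolute bound this is equivalent to a global amplitude criterion).  A
#' peak-to-peak alternative (window range above twice the bound) is
#' available via the config.  Flags only; nothing errors.  Per-condition
#' exclusion fractions are recorded in attribute `exclusion_fractions`.
#'
#' @param epochs an `epoch_set` (baseline-corrected).
#' @param config a [preprocess_config()].
#' @return The `epoch_set` with updated `valid`/`excluded_reason`.
#' @export
reject_artifacts <- function(epochs, config = preprocess_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  thr <- config$reject_threshold_uv
  w <- max(1L, round(config$reject_window_ms / 1000 * epochs$fs_hz))
  for (k in seq_len(dim(epochs$data)[1])) {
    if (epochs$excluded_reason[k] == "edge") next
    bad <- FALSE
    for (ch in seq_len(dim(epochs$data)[2])) {
      if (rolling_exceeds(epochs$data[k, ch, ], w, thr,
                          config$reject_criterion)) {
        bad <- TRUE
        break
      }
    }
    if (bad) {
      epochs$valid[k] <- FALSE
      if (epochs$excluded_reason[k] == "none") {
        epochs$excluded_reason[k] <- "artifact"
      }
    }
  }
  attr(epochs, "exclusion_fractions") <- exclusion_fractions(epochs)
  epochs
}

# artifact-exclusion fraction per condition, among trials eligible for
# analysis (standard-after-deviant trials are excluded by design, not
# counted as artifact losses)
exclusion_fractions <- function(epochs) {
  out <- c(standard = NA_real_, deviant = NA_real_)
  for (cond in names(out)) {
    sel <- epochs$condition == cond &
      epochs$excluded_reason != "standard_after_deviant"
    if (any(sel)) {
      out[cond] <- mean(epochs$excluded_reason[sel] %in% c("artifact", "edge"))
    }
  }
  out
}

#' Compare artifact-exclusion rates between conditions
#'
#' Paired two-sided t-test across subjects of the per-condition exclusion
#' fractions (standard vs deviant).  With zero variance of the paired
#' differences the test is degenerate: all-zero differences give `t = 0`,
#' `p = 1`; constant nonzero differences give `p = NA` with a warning.
#'
#' @param standard_frac,deviant_frac per-subject exclusion fractions.
#' @return list with `t`, `p`, `df`, `mean_difference`.
#' @export
compare_exclusion_rates <- function(standard_frac, deviant_frac) {
  stopifnot(length(standard_frac) == length(deviant_frac))
  if (length(standard_frac) < 2) stop("need at least 2 subjects")
  d <- standard_frac - deviant_frac
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p = 1, df = n - 1, mean_difference = 0))
    }
    warning("zero variance of paired differences; p is undefined")
    return(list(t = sign(mean(d)) * Inf, p = NA_real_, df = n - 1,
                mean_difference = mean(d)))
  }
  tt <- t.test(standard_frac, deviant_frac, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d))
}
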