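#' Per-subject deviant-minus-standard difference wave
#'
#' Averages valid trials per condition and subtracts: mean over valid
#' deviants minus mean over valid (retained) standards.  Under the
#' `"pooled"` contrast all deviants and standards enter regardless of block
#' or syllable; under `"matched"` the contrast is computed within syllable
#' (deviant /pa/ vs standard /pa/, etc.) and the per-syllable differences
#' are averaged, removing acoustic stimulus differences from the contrast.
#'
#' @param epochs an `epoch_set` after [reject_artifacts()].
#' @param contrast `"pooled"` (default) or `"matched"`.
#' @param subject_id carried into the result.
#' @return A `difference_wave`: channels x time matrix with attributes
#'   `times_ms`, `channel_labels`, `n_valid_deviant`, `n_valid_standard`,
#'   `exclusion_fractions`, `subject_id`.
#' @export
average_and_difference <- function(epochs, contrast = c("pooled", "matched"),
                                   subject_id = NA_character_) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(epochs, "epoch_set"))
  vdev <- epochs$valid & epochs$condition == "deviant"
  vstd <- epochs$valid & epochs$condition == "standard"
  if (!any(vdev) || !any(vstd)) {
    stop("empty condition after exclusions; subject cannot contribute")
  }
  cond_mean <- function(sel) {
    apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  }
  if (contrast == "pooled") {
    d <- cond_mean(vdev) - cond_mean(vstd)
  } else {
    syls <- unique(epochs$syllable[vdev])
    diffs <- lapply(syls, function(s) {
      sd_ <- vdev & epochs$syllable == s
      ss <- vstd & epochs$syllable == s
      if (!any(sd_) || !any(ss)) return(NULL)
      cond_mean(sd_) - cond_mean(ss)
    })
    diffs <- Filter(Negate(is.null), diffs)
    if (!length(diffs)) stop("no syllable with both conditions valid")
    d <- Reduce(`+`, diffs) / length(diffs)
  }
  rownames(d) <- epochs$channel_labels
  structure(d, times_ms = epochs$times_ms,
            channel_labels = epochs$channel_labels,
            n_valid_deviant = sum(vdev), n_valid_standard = sum(vstd),
            exclusion_fractions = exclusion_fractions(epochs),
            subject_id = subject_id,
            class = c("difference_wave", class(d)))
}

#' Quantify the late MMR amplitude
#'
#' Scalar endophenotype: mean over the ROI channels of the mean signal over
#' samples in the half-open MMR window (default `[300, 600)` ms).
#'
#' @param diff_wave a `difference_wave`.
#' @param config a [preprocess_config()].
#' @return An `mmr_measure` list: `subject_id`, `mmr_uv`,
#'   `n_valid_deviant`, `n_valid_standard`, `exclusion_fraction_standard`,
#'   `exclusion_fraction_deviant`.
#' @export
mmr_amplitude <- function(diff_wave, config = preprocess_config()) {
  stopifnot(inherits(diff_wave, "difference_wave"))
  roi <- config$roi
  labs <- attr(diff_wave, "channel_labels")
  if (!all(roi %in% labs)) {
    stop("missing ROI channel(s): ", paste(setdiff(roi, labs), collapse = ", "))
  }
  t_ms <- attr(diff_wave, "times_ms")
  sel <- t_ms >= config$mmr_window_ms[1] & t_ms < config$mmr_window_ms[2]
  if (!any(sel)) stop("MMR window contains no samples")
  m <- mean(rowMeans(diff_wave[roi, sel, drop = FALSE]))
  ef <- attr(diff_wave, "exclusion_fractions")
  structure(list(subject_id = attr(diff_wave, "subject_id"),
                 mmr_uv = m,
                 n_valid_deviant = attr(diff_wave, "n_valid_deviant"),
                 n_valid_standard = attr(diff_wave, "n_valid_standard"),
                 exclusion_fraction_standard = unname(ef["standard"]),
                 exclusion_fraction_deviant = unname(ef["deviant"])),
            class = "mmr_measure")
}

#' @export
print.mmr_measure <- function(x, ...) {
  cat(sprintf("Late MMR (300-600 ms, anterior ROI): %.3f uV [%s; %d deviant / %d standard trials]\n",
              x$mmr_uv, x$subject_id, x$n_valid_deviant, x$n_valid_standard))
  invisible(x)
}

# ROI-mean time course of a difference wave
roi_mean_wave <- function(diff_wave, roi = c("F3", "Fz", "F4")) {
  colMeans(diff_wave[roi, , drop = FALSE])
}

#' Sliding-window t-test between group difference waves
#'
#' Tiles the span (default `[0, 1200)` ms) into consecutive windows of
#' `window_ms` (default 3.2 ms, giving 375 windows) on the continuous time
#' axis.  Each subject contributes the mean of the ROI-mean difference wave
#' over the samples falling in a window; windows containing no sample centre
#' inherit the value of the sample nearest to the window centre.  Groups are
#' compared per window with Welch's two-sample t-test by default (pooled
#' Student's variant via `var_equal = TRUE`).  Windows where both group
#' variances vanish are flagged `degenerate` (t is 0 or +/-Inf there).
#'
#' @param waves_a,waves_b lists of `difference_wave` objects (one per
#'   subject), or subjects x time matrices of ROI-mean waves with attribute
#'   `times_ms`.
#' @param window_ms window length (ms).
#' @param span_ms length-2 half-open span (ms).
#' @param roi ROI used when difference waves are supplied.
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return A data frame of class `sliding_test` with columns `start_ms`,
#'   `end_ms`, `t`, `df`, `p`, `degenerate`.
#' @export
sliding_ttest <- function(waves_a, waves_b, window_ms = 3.2,
                          span_ms = c(0, 1200), roi = c("F3", "Fz", "F4"),
                          var_equal = FALSE) {
  as_mat <- function(w) {
    if (is.matrix(w)) return(w)
    t_ms <- attr(w[[1]], "times_ms")
    m <- do.call(rbind, lapply(w, roi_mean_wave, roi = roi))
    attr(m, "times_ms") <- t_ms
    m
  }
  A <- as_mat(waves_a)
  B <- as_mat(waves_b)
  if (nrow(A) < 2 || nrow(B) < 2) stop("need at least 2 subjects per group")
  t_ms <- attr(A, "times_ms")
  stopifnot(!is.null(t_ms))

  n_win <- round((span_ms[2] - span_ms[1]) / window_ms)
  starts <- span_ms[1] + window_ms * (0:(n_win - 1))
  res <- data.frame(start_ms = starts, end_ms = starts + window_ms,
                    t = NA_real_, df = NA_real_, p = NA_real_,
                    degenerate = FALSE)
  for (i in seq_len(n_win)) {
    sel <- which(t_ms >= res$start_ms[i] & t_ms < res$end_ms[i])
    if (!length(sel)) {
      sel <- which.min(abs(t_ms - (res$start_ms[i] + window_ms / 2)))
    }
    xa <- rowMeans(A[, sel, drop = FALSE])
    xb <- rowMeans(B[, sel, drop = FALSE])
    va <- var(xa); vb <- var(xb)
    na <- length(xa); nb <- length(xb)
    if (va == 0 && vb == 0) {
      res$degenerate[i] <- TRUE
      res$t[i] <- if (mean(xa) == mean(xb)) 0 else sign(mean(xa) - mean(xb)) * Inf
      res$p[i] <- if (mean(xa) == mean(xb)) 1 else 0
      next
    }
    if (var_equal) {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    tt <- (mean(xa) - mean(xb)) / se
    res$t[i] <- tt
    res$df[i] <- df
    res$p[i] <- 2 * pt(-abs(tt), df)
  }
  class(res) <- c("sliding_test", "data.frame")
  res
}

#' Pointwise group mean with confidence band
#'
#' Pointwise mean of the ROI-mean difference waves across subjects with a
#' t-based confidence band (mean +/- t-quantile x SEM).
#'
#' @param waves list of `difference_wave` objects or a subjects x time
#'   matrix with attribute `times_ms`.
#' @param level confidence level in (0, 1).
#' @param roi ROI channels.
#' @return Data frame `time_ms`, `mean_uv`, `lower_uv`, `upper_uv`, with
#'   attribute `n`.
#' @export
group_average_with_ci <- function(waves, level = 0.95,
                                  roi = c("F3", "Fz", "F4")) {
  if (!is_num1(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1")
  }
  if (!is.matrix(waves)) {
    t_ms <- attr(waves[[1]], "times_ms")
    waves <- do.call(rbind, lapply(waves, roi_mean_wave, roi = roi))
    attr(waves, "times_ms") <- t_ms
  }
  n <- nrow(waves)
  if (n < 2) stop("need at least 2 subjects")
  mu <- colMeans(waves)
  sem <- apply(waves, 2, sd) / sqrt(n)
  q <- qt(1 - (1 - level) / 2, df = n - 1)
  out <- data.frame(time_ms = attr(waves, "times_ms"), mean_uv = mu,
                    lower_uv = mu - q * sem, upper_uv = mu + q * sem)
  attr(out, "n") <- n
  attr(out, "level") <- level
  out
}

#' Run the full ERP reduction for one subject
#'
#' Chains the processing steps over one or more block recordings:
#' re-reference to the mastoid average, 30 Hz zero-phase low-pass,
#' decimation to 250 Hz, 0.5 Hz zero-phase high-pass, epoching with
#' baseline correction, exclusion of standards following deviants, artifact
#' rejection, condition averaging, and late-MMR quantification.  Epochs are
#' pooled across the supplied blocks before averaging.
#'
#' @param recordings list of per-block `list(eeg, events)` (as produced by
#'   [generate_subject_block()]), or a single such list.
#' @param config a [preprocess_config()].
#' @param subject_id subject identifier.
#' @return list with `measure` (an `mmr_measure`), `diff_wave` and the
#'   pooled `epochs`.
#' @export
erp_process_subject <- function(recordings, config = preprocess_config(),
                                subject_id = NA_character_) {
  if (!is.null(recordings$eeg)) recordings <- list(recordings)
  ep_list <- lapply(recordings, function(rec) {
    eeg <- rereference(rec$eeg, config$reference)
    if (!is.null(config$lowpass_hz)) {
      eeg <- filter_signal(eeg, "lowpass", config$lowpass_hz,
                           config$filter_order)
    }
    eeg <- resample_eeg(eeg, config$resample_hz)
    if (!is.null(config$highpass_hz)) {
      eeg <- filter_signal(eeg, "highpass", config$highpass_hz,
                           config$filter_order)
    }
    reject_artifacts(epoch_eeg(eeg, rec$events, config), config)
  })
  epochs <- pool_epochs(ep_list)
  dw <- average_and_difference(epochs, config$contrast, subject_id)
  list(measure = mmr_amplitude(dw, config), diff_wave = dw, epochs = epochs)
}

# concatenate epoch sets sharing grid and channels
pool_epochs <- function(ep_list) {
  if (length(ep_list) == 1) return(ep_list[[1]])
  e1 <- ep_list[[1]]
  dat <- do.call(abind_trials, lapply(ep_list, `[[`, "data"))
  out <- list(data = dat, times_ms = e1$times_ms,
              condition = unlist(lapply(ep_list, `[[`, "condition")),
              syllable = unlist(lapply(ep_list, `[[`, "syllable")),
              block = unlist(lapply(ep_list, `[[`, "block")),
              valid = unlist(lapply(ep_list, `[[`, "valid")),
              excluded_reason = unlist(lapply(ep_list, `[[`, "excluded_reason")),
              channel_labels = e1$channel_labels, fs_hz = e1$fs_hz)
  class(out) <- "epoch_set"
  out
}

abind_trials <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0))
  out <- array(NA_real_, dim = c(n, d[2], d[3]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Build the per-subject MMR table from a simulated dataset
#'
#' Convenience wrapper running [erp_process_subject()] for every subject of
#' a [generate_eeg_dataset()] result.
#'
#' @param dataset result of [generate_eeg_dataset()].
#' @param config a [preprocess_config()].
#' @return list with `mmr_table` (data frame: `subject_id`, `mmr_uv`,
#'   `n_valid_deviant`, `n_valid_standard`, exclusion fractions) and
#'   `diff_waves` (named list of `difference_wave`).
#' @export
erp_process_dataset <- function(dataset, config = preprocess_config()) {
  ids <- names(dataset)
  rows <- vector("list", length(ids))
  waves <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    r <- erp_process_subject(dataset[[i]], config, ids[i])
    rows[[i]] <- as.data.frame(unclass(r$measure)[c(
      "subject_id", "mmr_uv", "n_valid_deviant", "n_valid_standard",
      "exclusion_fraction_standard", "exclusion_fraction_deviant")])
    waves[[i]] <- r$diff_wave
  }
  names(waves) <- ids
  list(mmr_table = do.call(rbind, rows), diff_waves = waves)
}
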