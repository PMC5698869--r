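#' Simulate one subject's continuous oddball EEG recording
#'
#' Builds one continuous recording per block: background noise on every
#' channel, the common auditory response at every stimulus onset on scalp
#' channels, the group/genotype-dependent difference component on the frontal
#' ROI channels of deviant trials, and high-amplitude artifact transients in
#' a configured fraction of trial windows.  Mastoid reference channels carry
#' noise only.
#'
#' @param events a `stimulus_sequence` for the block.
#' @param template an [erp_template_model()].
#' @param group `"control"` or `"poor"`.
#' @param shift_uv genotype-dependent shift of the 300--600 ms window mean
#'   (uV), added to deviant trials.
#' @param montage channel labels; must include F3, Fz, F4, A1, A2.
#' @param fs_hz sampling rate (default 500).
#' @param pre_roll_ms,post_roll_ms padding before the first onset / after the
#'   last offset.
#' @param seed optional integer seed.
#' @return list with `eeg` (a `continuous_eeg`) and `events` (data frame with
#'   `onset_ms` shifted to recording time, plus `condition`, `syllable`,
#'   `block`).
#' @export
generate_subject_block <- function(events, template = erp_template_model(),
                                   group = "control", shift_uv = 0,
                                   montage = c("F3", "Fz", "F4", "A1", "A2"),
                                   fs_hz = 500, pre_roll_ms = 2000,
                                   post_roll_ms = 2000, seed = NULL) {
  roi <- c("F3", "Fz", "F4")
  refs <- c("A1", "A2")
  if (!all(c(roi, refs) %in% montage)) {
    stop("montage must include the ROI channels (F3, Fz, F4) and mastoids (A1, A2)")
  }
  maybe_seed(seed)
  dur <- syllable_duration_ms[events$syllable]
  total_ms <- pre_roll_ms + max(events$onset_ms + dur) + post_roll_ms
  n <- ceiling(total_ms * fs_hz / 1000)
  nch <- length(montage)
  scalp <- setdiff(montage, refs)

  sig <- matrix(0, nrow = nch, ncol = n, dimnames = list(montage, NULL))
  if (template$noise$amplitude_uv > 0) {
    for (ch in seq_len(nch)) {
      sig[ch, ] <- pink_noise(n, fs_hz, template$noise$exponent,
                              template$noise$amplitude_uv)
    }
  }
  if ((template$noise$alpha_uv %||% 0) > 0) {
    tt <- seq_len(n) / fs_hz
    phase <- runif(1, 0, 2 * pi)
    alpha <- template$noise$alpha_uv * sin(2 * pi * 10 * tt + phase)
    for (ch in which(montage %in% scalp)) sig[ch, ] <- sig[ch, ] + alpha
  }

  # epoch-support template grid, one evaluation reused for all trials
  t_rel <- seq(0, 900, by = 1000 / fs_hz)   # templates vanish beyond 900 ms
  std_wave <- template_standard_wave(template, t_rel)
  diff_wave <- template_difference_wave(template, group, shift_uv, t_rel)
  onset_idx <- round(((events$onset_ms + pre_roll_ms) / 1000) * fs_hz) # 0-based

  for (k in seq_len(nrow(events))) {
    idx <- onset_idx[k] + seq_along(t_rel)   # 1-based sample indices
    keep <- idx >= 1 & idx <= n
    for (ch in scalp) {
      sig[ch, idx[keep]] <- sig[ch, idx[keep]] + std_wave[keep]
    }
    if (events$condition[k] == "deviant") {
      for (ch in roi) {
        sig[ch, idx[keep]] <- sig[ch, idx[keep]] + diff_wave[keep]
      }
    }
  }

  if (template$artifact_rate > 0) {
    hit <- runif(nrow(events)) < template$artifact_rate
    for (k in which(hit)) {
      ch <- sample(montage, 1)
      dur_a <- runif(1, template$artifact_dur_ms[1], template$artifact_dur_ms[2])
      start_ms <- events$onset_ms[k] + pre_roll_ms +
        runif(1, -150, 1200 - dur_a)
      i0 <- max(1, round(start_ms * fs_hz / 1000))
      i1 <- min(n, i0 + round(dur_a * fs_hz / 1000))
      sig[ch, i0:i1] <- sig[ch, i0:i1] +
        sample(c(-1, 1), 1) * template$artifact_amp_uv
    }
  }

  ev <- data.frame(onset_ms = events$onset_ms + pre_roll_ms,
                   condition = events$condition,
                   syllable = events$syllable,
                   block = attr(events, "block_id"),
                   stringsAsFactors = FALSE)
  list(eeg = continuous_eeg(sig, fs_hz, montage), events = ev)
}

#' Simulate a full oddball EEG dataset
#'
#' Generates, for each subject, the two-block oddball experiment: per-block
#' stimulus sequences ([generate_stimulus_block()]) and continuous EEG
#' recordings ([generate_subject_block()]).  The genotype-dependent shift per
#' subject is the additive sum over causal SNPs of dosage times the
#' template's per-allele shift; the group morphology follows the phenotype's
#' `poor_speller` flag.  Child seeds are derived per subject and block with
#' [child_seed()], so any subject can be regenerated alone.
#'
#' @param phenotypes a `phenotype_table` (defines subjects and groups).
#' @param genotypes optional `genotype_matrix` aligned with `phenotypes`
#'   rows; missing dosages contribute their per-SNP mean.
#' @param template an [erp_template_model()].
#' @param blocks block identifiers to simulate (default `1:2`).
#' @param montage,fs_hz,seed see [generate_subject_block()].
#' @param n_total,n_deviant,min_spacing,isi_range_ms block design; defaults
#'   600 trials, 90 deviants, spacing 2, ISI 1450--1750 ms.
#' @param edf_dir if non-`NULL`, recordings are also written as EDF plus a
#'   per-subject events TSV into this directory.
#' @return Named list (one element per subject) of lists of per-block
#'   `list(eeg, events)` results; attribute `shift_uv` records the injected
#'   genotype shifts.
#' @export
generate_eeg_dataset <- function(phenotypes, genotypes = NULL,
                                 template = erp_template_model(),
                                 blocks = 1:2,
                                 montage = c("F3", "Fz", "F4", "A1", "A2"),
                                 fs_hz = 500, seed = 1,
                                 n_total = 600, n_deviant = 90,
                                 min_spacing = 2,
                                 isi_range_ms = c(1450, 1750),
                                 edf_dir = NULL) {
  ids <- phenotypes$individual_id
  shift <- setNames(numeric(length(ids)), ids)
  if (!is.null(genotypes) && length(template$per_allele_shift_uv)) {
    causal <- intersect(names(template$per_allele_shift_uv),
                        colnames(genotypes))
    rows <- match(ids, rownames(genotypes))
    if (anyNA(rows)) {
      stop("genotypes are missing individuals: ",
           paste(ids[is.na(rows)], collapse = ", "))
    }
    for (s in causal) {
      d <- genotypes[rows, s]
      d[is.na(d)] <- mean(genotypes[, s], na.rm = TRUE)
      shift <- shift + d * template$per_allele_shift_uv[[s]]
    }
  }
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    group <- if (isTRUE(phenotypes$poor_speller[i])) "poor" else "control"
    recs <- lapply(blocks, function(b) {
      sseq <- generate_stimulus_block(b, n_total, n_deviant, min_spacing,
                                      isi_range_ms,
                                      seed = child_seed(seed, i, b),
                                      grid_ms = 4)
      generate_subject_block(sseq, template, group, shift[i], montage,
                             fs_hz, seed = child_seed(seed, i, b, 1))
    })
    names(recs) <- paste0("block", blocks)
    if (!is.null(edf_dir)) {
      dir.create(edf_dir, showWarnings = FALSE, recursive = TRUE)
      for (b in seq_along(recs)) {
        base <- file.path(edf_dir, sprintf("%s_block%d", ids[i], blocks[b]))
        write_edf(recs[[b]]$eeg, paste0(base, ".edf"),
                  recording_id = sprintf("%s block %d", ids[i], blocks[b]))
        utils::write.table(recs[[b]]$events, paste0(base, "_events.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    out[[i]] <- recs
  }
  attr(out, "shift_uv") <- shift
  out
}
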