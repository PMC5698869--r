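#' Syllable durations used by the oddball design (ms)
#'
#' The two consonant-vowel syllables used as standard and deviant.  Durations
#' are carried as metadata for offset-to-onset inter-stimulus-interval (ISI)
#' bookkeeping.
#' @export
syllable_duration_ms <- c(pa = 266, ga = 409)

#' Generate one pseudorandomized oddball stimulus block
#'
#' Builds the trial list of a passive oddball block: `n_total` stimuli of
#' which `n_deviant` are deviants, pseudorandomized so that at least
#' `min_spacing` standards separate any two deviants.  In block 1 the standard
#' syllable is /ga/ and the deviant /pa/; block 2 swaps the assignment.
#' Offset-to-onset ISIs are drawn uniformly within `isi_range_ms`; onsets are
#' snapped to a `grid_ms` grid (the sampling grid of the decimated EEG) with
#' the jitter drawn `grid_ms/2` inside the ISI bounds, so realized ISIs remain
#' within the requested range after snapping.
#'
#' @param block_id 1 or 2; selects the standard/deviant syllable assignment.
#' @param n_total total number of trials (default 600).
#' @param n_deviant number of deviant trials (default 90, i.e. 15%).
#' @param min_spacing minimum number of standards between two deviants
#'   (default 2).
#' @param isi_range_ms length-2 numeric, offset-to-onset ISI bounds in ms
#'   (default `c(1450, 1750)`).
#' @param seed optional integer seed; identical seeds give identical blocks.
#' @param grid_ms onset quantization step in ms (default 4, one sample at
#'   250 Hz).
#' @return An object of class `stimulus_sequence`: a data frame with columns
#'   `onset_ms`, `condition` (`"standard"`/`"deviant"`) and `syllable`
#'   (`"pa"`/`"ga"`), with attributes `block_id` and `isi_range_ms`.
#' @export
#' @examples
#' blk <- generate_stimulus_block(1, seed = 7)
#' table(blk$condition)
generate_stimulus_block <- function(block_id = 1, n_total = 600, n_deviant = 90,
                                    min_spacing = 2,
                                    isi_range_ms = c(1450, 1750),
                                    seed = NULL, grid_ms = 4) {
  stopifnot(block_id %in% c(1, 2), is_num1(n_total), is_num1(n_deviant),
            n_total > n_deviant, n_deviant >= 0, min_spacing >= 0,
            length(isi_range_ms) == 2, diff(isi_range_ms) >= 2 * grid_ms)
  max_dev <- floor((n_total + min_spacing) / (min_spacing + 1))
  if (n_deviant > max_dev) {
    stop(sprintf(
      "spacing constraint infeasible: with n_total = %d and min_spacing = %d at most %d deviants fit",
      n_total, min_spacing, max_dev), call. = FALSE)
  }
  maybe_seed(seed)

  cond <- rep("standard", n_total)
  if (n_deviant > 0) {
    # distribute the free standards (those beyond the mandatory spacing) into
    # the n_deviant + 1 gaps around the deviants
    n_std <- n_total - n_deviant
    free <- n_std - (n_deviant - 1) * min_spacing
    gaps <- tabulate(sample.int(n_deviant + 1, free, replace = TRUE),
                     nbins = n_deviant + 1)
    if (n_deviant >= 2) {
      gaps[2:n_deviant] <- gaps[2:n_deviant] + min_spacing
    }
    pos <- cumsum(gaps[seq_len(n_deviant)] + 1) # trial index of each deviant
    cond[pos] <- "deviant"
  }

  if (block_id == 1) {
    syll <- ifelse(cond == "standard", "ga", "pa")
  } else {
    syll <- ifelse(cond == "standard", "pa", "ga")
  }

  isi <- runif(n_total - 1, isi_range_ms[1] + grid_ms / 2,
               isi_range_ms[2] - grid_ms / 2)
  onset <- numeric(n_total)
  for (k in seq_len(n_total - 1)) {
    raw <- onset[k] + syllable_duration_ms[[syll[k]]] + isi[k]
    onset[k + 1] <- round(raw / grid_ms) * grid_ms
  }

  out <- data.frame(onset_ms = onset, condition = cond, syllable = syll,
                    stringsAsFactors = FALSE)
  attr(out, "block_id") <- block_id
  attr(out, "isi_range_ms") <- isi_range_ms
  attr(out, "min_spacing") <- min_spacing
  class(out) <- c("stimulus_sequence", "data.frame")
  out
}

#' Validate the invariants of a stimulus sequence
#'
#' Checks trial counts, the deviant spacing constraint, ISI bounds and the
#' block-wise syllable assignment.  Errors on the first violation.
#'
#' @param x a `stimulus_sequence`.
#' @param n_total,n_deviant expected counts (optional).
#' @return `TRUE`, invisibly.
#' @export
validate_stimulus_sequence <- function(x, n_total = NULL, n_deviant = NULL) {
  stopifnot(inherits(x, "stimulus_sequence"))
  if (!is.null(n_total) && nrow(x) != n_total) stop("wrong trial count")
  ndev <- sum(x$condition == "deviant")
  if (!is.null(n_deviant) && ndev != n_deviant) stop("wrong deviant count")
  m <- attr(x, "min_spacing")
  dev_idx <- which(x$condition == "deviant")
  if (length(dev_idx) > 1 && any(diff(dev_idx) < m + 1)) {
    stop("deviant spacing constraint violated")
  }
  dur <- syllable_duration_ms[x$syllable]
  isi <- x$onset_ms[-1] - (x$onset_ms[-nrow(x)] + dur[-nrow(x)])
  rng <- attr(x, "isi_range_ms")
  if (any(isi < rng[1] - 1e-9 | isi > rng[2] + 1e-9)) {
    stop("ISI outside configured range")
  }
  std_syll <- unique(x$syllable[x$condition == "standard"])
  expected_std <- if (attr(x, "block_id") == 1) "ga" else "pa"
  if (length(std_syll) && !identical(std_syll, expected_std)) {
    stop("syllable assignment does not match block identity")
  }
  invisible(TRUE)
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("Oddball stimulus block %d: %d trials (%d deviant), ISI %g-%g ms\n",
              attr(x, "block_id"), nrow(x), sum(x$condition == "deviant"),
              attr(x, "isi_range_ms")[1], attr(x, "isi_range_ms")[2]))
  print(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}
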