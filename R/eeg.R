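#' Construct a continuous multichannel EEG object
#'
#' Thin container for a channels-by-time matrix of physical amplitudes (uV)
#' with its sampling rate and channel labels.
#'
#' @param samples numeric matrix, channels x time, in uV.
#' @param fs_hz sampling rate in Hz.
#' @param channel_labels unique channel names (10-20 nomenclature), length
#'   `nrow(samples)`.
#' @param reference_label label of the recording reference (default `"Cz"`).
#' @return An object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(samples, fs_hz, channel_labels,
                           reference_label = "Cz") {
  samples <- as.matrix(samples)
  stopifnot(is_num1(fs_hz), fs_hz > 0,
            length(channel_labels) == nrow(samples))
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs_hz = fs_hz,
                 channel_labels = channel_labels,
                 reference_label = reference_label),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("Continuous EEG: %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              ncol(x$samples) / x$fs_hz, x$reference_label))
  invisible(x)
}

#' Pink (1/f) noise generator
#'
#' Spectrally shaped Gaussian noise: a white spectrum scaled by
#' `f^(-exponent/2)` (zero DC), inverse-transformed and rescaled to the
#' requested RMS amplitude.  Uses the current RNG stream.
#'
#' @param n number of samples.
#' @param fs_hz sampling rate (Hz).
#' @param exponent spectral exponent of the power spectrum (1 = pink).
#' @param amplitude_rms_uv target RMS in uV.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs_hz, exponent = 1, amplitude_rms_uv = 1) {
  if (amplitude_rms_uv == 0) return(numeric(n))
  nfft <- n
  white <- fft(rnorm(nfft))
  f <- seq(0, fs_hz, length.out = nfft + 1)[seq_len(nfft)]
  f[1] <- Inf                       # kill DC
  k <- floor(nfft / 2)
  f[(k + 2):nfft] <- f[nfft + 2 - ((k + 2):nfft)] # mirror for real output
  shaped <- white * f^(-exponent / 2)
  x <- Re(fft(shaped, inverse = TRUE)) / nfft
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x <- x * amplitude_rms_uv / s
  x
}
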