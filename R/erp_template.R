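#' ERP template model for the oddball simulation
#'
#' Describes how simulated event-related responses are composed.  Every trial
#' (standard and deviant) receives a common auditory response; deviant trials
#' additionally receive a *difference component* on the frontal channels,
#' made of a group-dependent morphology plus a genotype-dependent amplitude
#' shift:
#'
#' * controls: a negativity around 200 ms followed by a second negativity
#'   around 400 ms (Gaussian components);
#' * poor spellers: a positivity of up to `poor_positivity_uv` uV spanning
#'   200--600 ms (Hann-windowed);
#' * per risk allele of each causal SNP, `per_allele_shift_uv` uV are added
#'   as a rectangular component over exactly the 300--600 ms quantification
#'   window, so the injected shift of the window mean equals dosage times
#'   shift by construction (additive model).
#'
#' The default per-allele shifts are of the magnitude reported for candidate
#' SNP effects on the late MMR (about 1.4--3 uV per allele).
#'
#' @param per_allele_shift_uv named numeric; uV added to the 300--600 ms
#'   window mean per risk allele of each causal SNP.
#' @param control_neg1_uv,control_neg2_uv amplitudes (uV, negative) of the
#'   control-group negativities at 200 and 400 ms.
#' @param poor_positivity_uv peak amplitude (uV) of the poor-speller
#'   positivity between 200 and 600 ms.
#' @param standard_response_uv amplitude of the common auditory response
#'   present in every trial.
#' @param noise list: `exponent` (power-spectral exponent, 1 = pink),
#'   `amplitude_uv` (RMS per channel), `alpha_uv` (optional 10 Hz component
#'   amplitude).
#' @param artifact_rate fraction of trials receiving an injected
#'   high-amplitude transient, in `[0, 1)`.
#' @param artifact_amp_uv amplitude of injected transients (default 150, well
#'   beyond the 80 uV rejection bound so detection is certain).
#' @param artifact_dur_ms duration range of injected transients.
#' @return An object of class `erp_template_model`.
#' @export
erp_template_model <- function(per_allele_shift_uv = c(rs17819126 = 3.0,
                                                       rs8053211 = -1.8,
                                                       rs2875891 = -1.5,
                                                       rs3743204 = -1.7,
                                                       rs16973771 = -1.4),
                               control_neg1_uv = -1.5,
                               control_neg2_uv = -1.2,
                               poor_positivity_uv = 5,
                               standard_response_uv = 2,
                               noise = list(exponent = 1, amplitude_uv = 12,
                                            alpha_uv = 3),
                               artifact_rate = 0.2,
                               artifact_amp_uv = 150,
                               artifact_dur_ms = c(200, 400)) {
  if (!is_num1(artifact_rate) || artifact_rate < 0 || artifact_rate >= 1) {
    stop("artifact_rate must lie in [0, 1)")
  }
  noise <- modifyList(list(exponent = 1, amplitude_uv = 12, alpha_uv = 0),
                      noise)
  structure(list(per_allele_shift_uv = per_allele_shift_uv,
                 control_neg1_uv = control_neg1_uv,
                 control_neg2_uv = control_neg2_uv,
                 poor_positivity_uv = poor_positivity_uv,
                 standard_response_uv = standard_response_uv,
                 noise = noise,
                 artifact_rate = artifact_rate,
                 artifact_amp_uv = artifact_amp_uv,
                 artifact_dur_ms = artifact_dur_ms),
            class = "erp_template_model")
}

# common auditory response added to every trial (uV at time t_ms post onset)
template_standard_wave <- function(model, t_ms) {
  model$standard_response_uv *
    (exp(-0.5 * ((t_ms - 100) / 30)^2) - 0.6 * exp(-0.5 * ((t_ms - 250) / 60)^2)) *
    (t_ms >= 0)
}

#' Evaluate the deviant-minus-standard difference template
#'
#' Returns the difference component injected on frontal channels of deviant
#' trials: group morphology plus the genotype shift (a rectangle over
#' [300, 600) ms whose height is `shift_uv`).
#'
#' @param model an `erp_template_model`.
#' @param group `"control"` or `"poor"`.
#' @param shift_uv total genotype-dependent shift in uV (sum over causal SNPs
#'   of dosage times per-allele shift).
#' @param t_ms numeric vector of times (ms relative to stimulus onset).
#' @return uV values at `t_ms`.
#' @export
template_difference_wave <- function(model, group = c("control", "poor"),
                                     shift_uv = 0, t_ms) {
  group <- match.arg(group)
  base <- if (group == "control") {
    model$control_neg1_uv * exp(-0.5 * ((t_ms - 200) / 40)^2) +
      model$control_neg2_uv * exp(-0.5 * ((t_ms - 450) / 80)^2)
  } else {
    w <- numeric(length(t_ms))
    inside <- t_ms >= 200 & t_ms < 600
    w[inside] <- model$poor_positivity_uv *
      0.5 * (1 - cos(2 * pi * (t_ms[inside] - 200) / 400))
    w
  }
  base + shift_uv * (t_ms >= 300 & t_ms < 600)
}
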