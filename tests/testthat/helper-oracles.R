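# Independent brute-force oracles used to cross-check the implementation.

# AUC as the fraction of concordant case/control pairs (ties count 1/2)
auc_brute <- function(scores, labels) {
  y <- as.logical(labels)
  ca <- scores[y]
  co <- scores[!y]
  tot <- 0
  for (a in ca) for (b in co) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ca) * length(co))
}

# Benjamini-Hochberg step-up by direct definition: q(i) = min_{k>=i} m p(k)/k
bh_brute <- function(p, m = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  q <- numeric(k)
  for (i in seq_len(k)) {
    q[i] <- min(1, min(m * ps[i:k] / (i:k)))
  }
  out <- numeric(k)
  out[ord] <- q
  out
}

# Cook's distance by explicit leave-one-out refits
cooks_loo <- function(fit) {
  df <- fit$model
  n <- nrow(df)
  p <- length(coef(fit))
  s2 <- sum(residuals(fit)^2) / (n - p)
  yhat <- fitted(fit)
  vapply(seq_len(n), function(i) {
    refit <- lm(formula(fit), data = df[-i, , drop = FALSE])
    yhat_i <- predict(refit, newdata = df)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, 0)
}

# mean of a difference-wave template over the quantification grid
template_window_mean <- function(model, group, shift_uv,
                                 window = c(300, 600), step = 4) {
  t_ms <- seq(window[1], window[2] - step, by = step)
  mean(template_difference_wave(model, group, shift_uv, t_ms))
}

# noiseless, artifact-free template model for identity checks
noiseless_template <- function(...) {
  erp_template_model(noise = list(exponent = 1, amplitude_uv = 0,
                                  alpha_uv = 0),
                     artifact_rate = 0, ...)
}

# configuration with the filters disabled: every remaining step (re-
# reference, decimation, epoching, baseline, averaging, window mean) is
# exact in exact arithmetic
identity_config <- function(...) {
  preprocess_config(lowpass_hz = NULL, highpass_hz = NULL, ...)
}

# small simulated study: genotypes, phenotypes, per-subject EEG
simulate_small_study <- function(n_subjects = 6, n_total = 30, n_deviant = 4,
                                 template = noiseless_template(),
                                 blocks = 1, maf = 0.3, seed = 42,
                                 poor = NULL) {
  panel <- load_snp_panel()
  n_gen <- max(n_subjects, 10)   # the decile rule needs >= 10 individuals
  g <- generate_genotypes(n_gen, panel, maf = maf,
                          seed = child_seed(seed, 1))
  ph <- generate_phenotypes(g, seed = child_seed(seed, 2))
  g <- g[seq_len(n_subjects), , drop = FALSE]
  class(g) <- c("genotype_matrix", "matrix", "array")
  attr(g, "panel") <- panel
  ph <- ph[seq_len(n_subjects), , drop = FALSE]
  if (!is.null(poor)) ph$poor_speller <- poor
  ds <- generate_eeg_dataset(ph, g, template, blocks = seq_len(blocks),
                             seed = child_seed(seed, 3),
                             n_total = n_total, n_deviant = n_deviant)
  list(panel = panel, genotypes = g, phenotypes = ph, dataset = ds,
       shift_uv = attr(ds, "shift_uv"))
}
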