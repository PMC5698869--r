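#' Plot group difference waves with confidence bands
#'
#' ROI-mean deviant-minus-standard waves per group with shaded pointwise
#' confidence bands (base graphics).
#'
#' @param groups named list of per-group wave collections (each a list of
#'   `difference_wave` or a subjects x time matrix with `times_ms`).
#' @param level band level.
#' @param roi ROI channels.
#' @param col colours, recycled over groups.
#' @export
plot_difference_waves <- function(groups, level = 0.95,
                                  roi = c("F3", "Fz", "F4"),
                                  col = c("#D55E00", "#0072B2")) {
  bands <- lapply(groups, group_average_with_ci, level = level, roi = roi)
  col <- rep_len(col, length(bands))
  ylim <- range(unlist(lapply(bands, function(b) c(b$lower_uv, b$upper_uv))))
  plot(NULL, xlim = range(bands[[1]]$time_ms), ylim = ylim,
       xlab = "Time after stimulus onset (ms)",
       ylab = "Difference wave deviant - standard (uV)")
  abline(h = 0, v = 0, col = "grey70")
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    polygon(c(b$time_ms, rev(b$time_ms)), c(b$lower_uv, rev(b$upper_uv)),
            col = adjustcolor(col[i], alpha.f = 0.25), border = NA)
    lines(b$time_ms, b$mean_uv, col = col[i], lwd = 2)
  }
  legend("topright", legend = names(bands), col = col, lwd = 2, bty = "n")
  invisible(bands)
}

#' QQ plot of association p-values with confidence envelope
#'
#' Observed versus expected -log10 p-values for `m` tests with the
#' order-statistic envelope of [qq_envelope()].
#'
#' @param pvals observed p-values.
#' @param m family size (default `length(pvals)`).
#' @param level envelope level.
#' @export
plot_qq <- function(pvals, m = length(pvals), level = 0.95) {
  env <- qq_envelope(m, level)
  obs <- sort(pvals)
  k <- length(obs)
  ex <- env$expected[seq_len(k)]
  xlim <- c(0, max(-log10(env$expected[1]), -log10(obs)))
  plot(-log10(ex), -log10(obs), pch = 19,
       xlim = xlim, ylim = xlim,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)))
  abline(0, 1, col = "grey50")
  lines(-log10(env$expected), -log10(env$lower), lty = 2)
  lines(-log10(env$expected), -log10(env$upper), lty = 2)
  invisible(env)
}

#' Boxplots of MMR amplitude by risk-allele count
#'
#' One panel per SNP, amplitude stratified by dosage 0/1/2.
#'
#' @param mmr numeric amplitudes.
#' @param genotypes `genotype_matrix` aligned with `mmr`.
#' @param snps rsIDs to display.
#' @export
plot_genotype_boxplots <- function(mmr, genotypes, snps) {
  snps <- intersect(snps, colnames(genotypes))
  if (!length(snps)) stop("no requested SNP present in the genotypes")
  old <- par(mfrow = c(1, length(snps)))
  on.exit(par(old))
  for (s in snps) {
    boxplot(mmr ~ factor(unclass(genotypes)[, s], levels = 0:2),
            xlab = "Risk alleles", ylab = "Late MMR (uV)", main = s)
  }
  invisible(NULL)
}
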