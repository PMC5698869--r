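#' Additive single-SNP linear model for the late MMR
#'
#' Ordinary least squares of the MMR amplitude on the risk-allele dosage
#' (0/1/2, additive coding) with optional covariates (by default the
#' poor-speller indicator; ADD status may be added for the adjustment
#' comparison).  Rows with missing dosage, outcome or covariates are
#' dropped (complete-case; `n_used` records the rows fitted).  A constant
#' dosage is flagged untestable rather than fitted; a singular design
#' errors with the offending columns named.
#'
#' @param mmr numeric outcome (uV).
#' @param dosage risk-allele counts, may contain `NA`.
#' @param covariates optional data frame of covariates.
#' @param snp label carried into the result.
#' @return list of class `snp_fit`: `snp`, `beta` (uV per risk allele),
#'   `se`, `t`, `p`, `n_used`, `untestable`, and `model` (the `lm` fit,
#'   `NULL` if untestable).
#' @export
fit_additive_model <- function(mmr, dosage, covariates = NULL, snp = "") {
  n <- length(mmr)
  stopifnot(length(dosage) == n)
  df <- data.frame(.mmr = mmr, .dosage = as.numeric(dosage))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    df <- cbind(df, covariates)
  }
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n_used <- nrow(df)
  p_pred <- ncol(df)                     # predictors + intercept proxy
  if (n_used <= p_pred) stop("too few complete observations to fit")
  if (var(df$.dosage) == 0) {
    return(structure(list(snp = snp, beta = NA_real_, se = NA_real_,
                          t = NA_real_, p = NA_real_, n_used = n_used,
                          untestable = TRUE, model = NULL),
                     class = "snp_fit"))
  }
  fit <- lm(.mmr ~ ., data = df)
  co <- coef(fit)
  if (anyNA(co)) {
    stop("singular design; collinear columns: ",
         paste(names(co)[is.na(co)], collapse = ", "))
  }
  s <- summary(fit)$coefficients
  structure(list(snp = snp, beta = unname(s[".dosage", 1]),
                 se = unname(s[".dosage", 2]), t = unname(s[".dosage", 3]),
                 p = unname(s[".dosage", 4]), n_used = n_used,
                 untestable = FALSE, model = fit),
            class = "snp_fit")
}

#' @export
print.snp_fit <- function(x, ...) {
  if (x$untestable) {
    cat(sprintf("%s: untestable (constant dosage), n = %d\n", x$snp, x$n_used))
  } else {
    cat(sprintf("%s: beta = %.3f uV/allele (se %.3f), t = %.2f, p = %.4g, n = %d\n",
                x$snp, x$beta, x$se, x$t, x$p, x$n_used))
  }
  invisible(x)
}

#' Per-SNP association scan with FDR control
#'
#' Fits [fit_additive_model()] for every SNP of the genotype matrix and
#' controls the family with Benjamini-Hochberg FDR.  By default only the
#' dyslexia-candidate SNPs form the FDR family (`m` = their count); SNPs
#' whose panel `source` is `"mmr_candidate"` are tested and reported but
#' adjusted separately, mirroring the separate replication analysis.
#'
#' @param mmr_table data frame with `subject_id` and `mmr_uv`.
#' @param genotypes `genotype_matrix` with matching row names.
#' @param phenotypes `phenotype_table` providing covariates.
#' @param covariates character vector of phenotype columns to adjust for
#'   (default `"poor_speller"`).
#' @param panel optional `snp_panel` (defaults to the genotype attribute)
#'   used for the gene column and the FDR family split.
#' @param m_fdr override for the FDR family size of the candidate SNPs.
#' @return data frame of class `mmr_assoc`: `snp`, `gene`, `beta`, `se`,
#'   `t`, `p`, `fdr_q`, `n_used`, `family`.
#' @export
assoc_scan <- function(mmr_table, genotypes, phenotypes,
                       covariates = "poor_speller", panel = NULL,
                       m_fdr = NULL) {
  panel <- panel %||% attr(genotypes, "panel")
  ids <- mmr_table$subject_id
  stopifnot(!is.null(rownames(genotypes)))
  g <- genotypes[match(ids, rownames(genotypes)), , drop = FALSE]
  ph <- phenotypes[match(ids, phenotypes$individual_id), , drop = FALSE]
  covs <- if (length(covariates)) ph[, covariates, drop = FALSE] else NULL

  rows <- lapply(colnames(g), function(s) {
    f <- fit_additive_model(mmr_table$mmr_uv, g[, s], covs, snp = s)
    data.frame(snp = s, beta = f$beta, se = f$se, t = f$t, p = f$p,
               n_used = f$n_used, untestable = f$untestable,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$gene <- if (!is.null(panel)) {
    panel$gene[match(res$snp, panel$rsid)]
  } else NA_character_
  res$family <- if (!is.null(panel)) {
    ifelse(panel$source[match(res$snp, panel$rsid)] == "mmr_candidate",
           "mmr_replication", "candidate")
  } else "candidate"

  res$fdr_q <- NA_real_
  for (fam in unique(res$family)) {
    sel <- res$family == fam & !res$untestable
    if (!any(sel)) next
    m <- if (fam == "candidate" && !is.null(m_fdr)) m_fdr else sum(sel)
    res$fdr_q[sel] <- bh_fdr(res$p[sel], m = m)
  }
  res <- res[order(res$family, res$p), ]
  rownames(res) <- NULL
  class(res) <- c("mmr_assoc", "data.frame")
  res
}

#' @export
print.mmr_assoc <- function(x, digits = 3, ...) {
  cat("Per-SNP additive association with the late MMR\n")
  df <- data.frame(SNP = x$snp, p = signif(x$p, digits),
                   FDR = signif(x$fdr_q, 2), Beta = round(x$beta, 1),
                   Gene = x$gene)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment `q(i) = min_{k >= i} m p(k) / k`, capped at 1, where
#' `m` may exceed the number of observed p-values (e.g. the full family
#' size when only top hits are supplied).  Delegates to
#' `stats::p.adjust(method = "BH", n = m)` after validation.
#'
#' @param pvals p-values in (0, 1].
#' @param m family size; defaults to `length(pvals)`.
#' @return adjusted values, same order as input.
#' @export
#' @examples
#' bh_fdr(c(.0037, .0039, .0146, .0157, .0199), m = 25)
bh_fdr <- function(pvals, m = NULL) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  m <- m %||% length(pvals)
  if (m < length(pvals)) stop("m must be at least length(pvals)")
  p.adjust(pvals, method = "BH", n = m)
}

#' Expected order statistics and confidence envelope for a QQ plot
#'
#' Under the global null the i-th smallest of `m` p-values is
#' `Beta(i, m - i + 1)`; the envelope takes the central quantiles of that
#' distribution per rank, and the expected value is `i / (m + 1)`.
#'
#' @param m number of p-values.
#' @param level envelope coverage (default 0.95).
#' @return data frame `rank`, `expected`, `lower`, `upper`.
#' @export
qq_envelope <- function(m, level = 0.95) {
  stopifnot(m >= 1)
  if (!is_num1(level) || level <= 0 || level >= 1) {
    stop("level must lie strictly between 0 and 1")
  }
  i <- seq_len(m)
  a <- (1 - level) / 2
  data.frame(rank = i, expected = i / (m + 1),
             lower = qbeta(a, i, m - i + 1),
             upper = qbeta(1 - a, i, m - i + 1))
}

#' Influence diagnostics for a SNP fit
#'
#' Cook's distance per observation of the fitted model; observations with
#' `D` above the threshold (default the conventional `4/n`) are flagged,
#' the model is refit without them, and the shift of the dosage effect is
#' reported.
#'
#' @param fit a `snp_fit` from [fit_additive_model()] (with a model).
#' @param threshold flagging cutoff; default `4 / n_used`.
#' @return list: `cooks_d`, `flagged` (indices), `threshold`,
#'   `beta_refit`, `beta_shift`, `refit_possible`.
#' @export
cooks_sensitivity <- function(fit, threshold = NULL) {
  stopifnot(inherits(fit, "snp_fit"), !is.null(fit$model))
  d <- cooks.distance(fit$model)
  # an (essentially) exact fit has no influential points; the ratio in
  # Cook's formula is 0/0 there, so define D = 0
  scale_y <- mean(abs(fitted(fit$model))) + 1
  if (sqrt(mean(residuals(fit$model)^2)) < 1e-10 * scale_y) {
    d[] <- 0
  }
  thr <- threshold %||% (4 / fit$n_used)
  flagged <- which(d > thr)
  out <- list(cooks_d = d, flagged = flagged, threshold = thr,
              beta_refit = NA_real_, beta_shift = 0,
              refit_possible = TRUE)
  if (length(flagged)) {
    df <- fit$model$model
    keep <- setdiff(seq_len(nrow(df)), flagged)
    if (length(keep) <= ncol(df)) {
      out$refit_possible <- FALSE
      return(out)
    }
    refit <- lm(.mmr ~ ., data = df[keep, , drop = FALSE])
    out$beta_refit <- unname(coef(refit)[".dosage"])
    out$beta_shift <- out$beta_refit - fit$beta
  } else {
    out$beta_refit <- fit$beta
  }
  out
}

#' Compare associations with and without a covariate adjustment
#'
#' Joins two `mmr_assoc` scans (e.g. with and without the ADD-status
#' covariate) by SNP and tabulates effect-size and p-value changes.
#'
#' @param results_base,results_adjusted `mmr_assoc` tables over the same
#'   SNP set.
#' @return data frame: `snp`, `beta_base`, `beta_adjusted`, `delta_beta`,
#'   `p_base`, `p_adjusted`.
#' @export
compare_covariate_adjustment <- function(results_base, results_adjusted) {
  if (!setequal(results_base$snp, results_adjusted$snp)) {
    stop("SNP sets differ between the two scans")
  }
  i <- match(results_base$snp, results_adjusted$snp)
  data.frame(snp = results_base$snp,
             beta_base = results_base$beta,
             beta_adjusted = results_adjusted$beta[i],
             delta_beta = results_adjusted$beta[i] - results_base$beta,
             p_base = results_base$p,
             p_adjusted = results_adjusted$p[i],
             stringsAsFactors = FALSE)
}
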