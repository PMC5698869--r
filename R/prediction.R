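#' Unweighted polygenic risk score
#'
#' Sums risk-allele dosages over the dyslexia-candidate panel SNPs that
#' carry a literature risk allele (SNPs without one, and the separately
#' analysed MMR-replication SNPs, do not contribute).  Missing dosages are
#' imputed with the per-SNP mean of the observed dosages; which entries
#' were imputed is recorded.
#'
#' @param genotypes a `genotype_matrix` oriented to risk-allele counts.
#' @param panel matching `snp_panel`; only rows with a non-missing
#'   `risk_allele` and present in the matrix are scored.
#' @return numeric vector of class `risk_score` (one value per individual)
#'   with attributes `n_snps_scored`, `scored_snps`, `n_imputed`.
#' @export
#' @examples
#' g <- generate_genotypes(20, load_snp_panel(), seed = 1)
#' prs <- compute_prs(g, load_snp_panel())
#' attr(prs, "n_snps_scored")  # 20 scored SNPs
compute_prs <- function(genotypes, panel = attr(genotypes, "panel")) {
  validate_snp_panel(panel)
  cand <- if ("source" %in% names(panel)) {
    panel$source == "dyslexia_candidate"
  } else rep(TRUE, nrow(panel))
  scored <- panel$rsid[cand & !is.na(panel$risk_allele) &
                         panel$rsid %in% colnames(genotypes)]
  if (!length(scored)) stop("no scorable SNPs (no risk alleles in panel)")
  X <- unclass(genotypes)[, scored, drop = FALSE]
  n_imputed <- sum(is.na(X))
  X <- apply(X, 2, function(col) {
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    col
  })
  prs <- rowSums(X)
  structure(prs, n_snps_scored = length(scored), scored_snps = scored,
            n_imputed = n_imputed, class = "risk_score")
}

#' Logistic risk model returning fitted probabilities
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via `stats::glm`, convergence tolerance 1e-8).  Perfect or
#' quasi-perfect separation is detected from fitted probabilities pinned at
#' 0/1 and reported with a warning; probabilities are still returned.
#'
#' @param outcome logical or 0/1 vector; both classes must be present.
#' @param predictors vector, matrix or data frame of predictors.
#' @return list: `probabilities`, `coefficients`, `model` (the `glm`),
#'   `separation` flag.
#' @export
fit_logistic <- function(outcome, predictors) {
  y <- as.integer(outcome)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("outcome must contain both classes")
  }
  X <- as.data.frame(predictors)
  df <- data.frame(.y = y, X)
  fit <- suppressWarnings(
    glm(.y ~ ., data = df, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)))
  pr <- fitted(fit)
  sep <- !fit$converged || any(pr < 1e-8 | pr > 1 - 1e-8)
  if (sep) warning("possible separation: fitted probabilities at the boundary")
  list(probabilities = as.numeric(pr), coefficients = coef(fit),
       model = fit, separation = sep)
}

#' ROC area under the curve with confidence interval
#'
#' Mann-Whitney AUC (ties count one half) with the orientation fixed so
#' that higher scores indicate cases; an anti-informative score therefore
#' yields AUC below 0.5.  The confidence interval uses DeLong's method by
#' default (via pROC) or a bootstrap.
#'
#' @param scores numeric predictor.
#' @param labels logical/0-1 case indicator; both classes required.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param level confidence level.
#' @param boot_n bootstrap resamples.
#' @return list: `auc`, `ci` (length 2), `ci_method`, `n_cases`,
#'   `n_controls`.
#' @export
#' @examples
#' roc_auc(c(3, 2, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    level = 0.95, boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  y <- as.logical(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = y, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  # pROC emits an informational warning for degenerate (AUC = 1) intervals
  ci <- suppressWarnings(if (ci_method == "delong") {
    as.numeric(pROC::ci.auc(r, conf.level = level, method = "delong"))
  } else {
    as.numeric(pROC::ci.auc(r, conf.level = level, method = "bootstrap",
                            boot.n = boot_n))
  })
  list(auc = as.numeric(pROC::auc(r)), ci = ci[c(1, 3)],
       ci_method = ci_method, n_cases = sum(y), n_controls = sum(!y))
}

#' Continuous net reclassification improvement
#'
#' `NRI = [P(up|event) - P(down|event)] + [P(down|nonevent) -
#' P(up|nonevent)]`, where up/down is any increase/decrease of the
#' predicted risk between the old and new model.  The asymptotic z uses the
#' standard variance `(p_up,ev + p_down,ev)/n_ev + (p_up,ne +
#' p_down,ne)/n_ne`.  If no prediction moves, NRI is 0 with a
#' degenerate-variance warning.
#'
#' @param p_old,p_new predicted probabilities in `[0, 1]`.
#' @param labels event indicator; both classes required.
#' @return list: `nri`, `z`, `p`, components `p_up_event`, `p_down_event`,
#'   `p_up_nonevent`, `p_down_nonevent`.
#' @export
nri_continuous <- function(p_old, p_new, labels) {
  check_probs(p_old, p_new, labels)
  y <- as.logical(labels)
  if (all(y) || !any(y)) stop("both events and nonevents are required")
  d <- p_new - p_old
  up <- d > 0
  down <- d < 0
  n_ev <- sum(y); n_ne <- sum(!y)
  pue <- mean(up[y]); pde <- mean(down[y])
  pun <- mean(up[!y]); pdn <- mean(down[!y])
  nri <- (pue - pde) + (pdn - pun)
  v <- (pue + pde) / n_ev + (pun + pdn) / n_ne
  if (v == 0) {
    warning("no reclassification movement; variance degenerate")
    return(list(nri = 0, z = NA_real_, p = NA_real_,
                p_up_event = pue, p_down_event = pde,
                p_up_nonevent = pun, p_down_nonevent = pdn))
  }
  z <- nri / sqrt(v)
  list(nri = nri, z = z, p = 2 * pnorm(-abs(z)),
       p_up_event = pue, p_down_event = pde,
       p_up_nonevent = pun, p_down_nonevent = pdn)
}

#' Integrated discrimination improvement
#'
#' Difference of discrimination slopes: `IDI = [mean(p_new|event) -
#' mean(p_new|nonevent)] - [mean(p_old|event) - mean(p_old|nonevent)]`,
#' with z from the paired per-class differences.
#'
#' @inheritParams nri_continuous
#' @return list: `idi`, `z`, `p`, `slope_old`, `slope_new`.
#' @export
idi <- function(p_old, p_new, labels) {
  check_probs(p_old, p_new, labels)
  y <- as.logical(labels)
  if (all(y) || !any(y)) stop("both events and nonevents are required")
  d_ev <- (p_new - p_old)[y]
  d_ne <- (p_new - p_old)[!y]
  slope_old <- mean(p_old[y]) - mean(p_old[!y])
  slope_new <- mean(p_new[y]) - mean(p_new[!y])
  est <- slope_new - slope_old
  v <- var(d_ev) / length(d_ev) + var(d_ne) / length(d_ne)
  if (is.na(v) || v == 0) {
    warning("degenerate variance for IDI")
    return(list(idi = est, z = NA_real_, p = NA_real_,
                slope_old = slope_old, slope_new = slope_new))
  }
  z <- est / sqrt(v)
  list(idi = est, z = z, p = 2 * pnorm(-abs(z)),
       slope_old = slope_old, slope_new = slope_new)
}

check_probs <- function(p_old, p_new, labels) {
  stopifnot(length(p_old) == length(p_new),
            length(labels) == length(p_old))
  if (any(p_old < 0 | p_old > 1 | p_new < 0 | p_new > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  invisible(TRUE)
}

#' Compare MMR, PRS and combined risk models
#'
#' Fits three logistic models for the poor-spelling outcome -- late MMR
#' alone, PRS alone, and MMR + PRS -- and reports each AUC with its
#' confidence interval plus the reclassification gain of adding the PRS to
#' the MMR model (continuous NRI and IDI, old = MMR alone, new =
#' combined).
#'
#' @param mmr numeric late-MMR amplitudes (uV).
#' @param prs risk scores.
#' @param labels poor-spelling indicator.
#' @param ci_method passed to [roc_auc()].
#' @return list of class `model_comparison`: `auc_mmr`, `auc_prs`,
#'   `auc_combined` (each a [roc_auc()] result), `nri` and `idi_result`,
#'   and `n`.
#' @export
compare_models <- function(mmr, prs, labels, ci_method = "delong") {
  cc <- complete.cases(mmr, prs, labels)
  mmr <- mmr[cc]; prs <- as.numeric(prs)[cc]; y <- as.logical(labels)[cc]
  f_mmr <- fit_logistic(y, data.frame(mmr = mmr))
  f_prs <- fit_logistic(y, data.frame(prs = prs))
  f_both <- fit_logistic(y, data.frame(mmr = mmr, prs = prs))
  out <- list(
    auc_mmr = roc_auc(f_mmr$probabilities, y, ci_method),
    auc_prs = roc_auc(f_prs$probabilities, y, ci_method),
    auc_combined = roc_auc(f_both$probabilities, y, ci_method),
    nri = nri_continuous(f_mmr$probabilities, f_both$probabilities, y),
    idi_result = idi(f_mmr$probabilities, f_both$probabilities, y),
    n = length(y), n_events = sum(y))
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  f <- function(a) sprintf("%.2f (CI %.2f-%.2f)", a$auc, a$ci[1], a$ci[2])
  cat(sprintf("Poor-spelling classification, n = %d (%d events)\n",
              x$n, x$n_events))
  cat("  AUC late MMR:  ", f(x$auc_mmr), "\n")
  cat("  AUC PRS:       ", f(x$auc_prs), "\n")
  cat("  AUC MMR + PRS: ", f(x$auc_combined), "\n")
  cat(sprintf("  NRI(cont) = %.2f (p = %.3g); IDI = %.2f (p = %.3g)\n",
              x$nri$nri, x$nri$p, x$idi_result$idi, x$idi_result$p))
  invisible(x)
}
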