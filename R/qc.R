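#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Chi-square goodness-of-fit (1 df, no continuity correction) of the
#' observed genotype counts against the Hardy-Weinberg expectations at the
#' sample allele frequency.  The exact test (full enumeration of the
#' conditional heterozygote distribution) is available as an alternative.
#' Monomorphic SNPs return `p = 1` with `monomorphic = TRUE`.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (AA = two copies of the dosage-coded
#'   allele).
#' @param method `"chisq"` (default) or `"exact"`.
#' @return list with `p`, `chisq` (chisq method), `monomorphic`.
#' @export
#' @examples
#' hwe_test(36, 48, 16)$p   # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)$p    # extreme departure
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("chisq", "exact")) {
  method <- match.arg(method)
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(p = 1, chisq = 0, monomorphic = TRUE))
  }
  if (method == "chisq") {
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
    list(p = pchisq(x2, df = 1, lower.tail = FALSE), chisq = x2,
         monomorphic = FALSE)
  } else {
    list(p = hwe_exact_p(n_AA, n_Aa, n_aa), chisq = NA_real_,
         monomorphic = FALSE)
  }
}

# exact HWE p-value: sum of probabilities of heterozygote counts no more
# likely than the observed one, conditional on allele counts
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  het <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logp <- vapply(het, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(het == n_Aa)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

# per-SNP HWE p from a dosage vector
hwe_from_dosage <- function(d, method = "chisq") {
  d <- d[!is.na(d)]
  hwe_test(sum(d == 2), sum(d == 1), sum(d == 0), method = method)
}

#' Genotype QC thresholds
#'
#' @param hwe_alpha per-family alpha for the Hardy-Weinberg test (Bonferroni
#'   corrected over the SNPs entering the test).
#' @param snp_call_rate_min SNPs with call rate not above this are removed.
#' @param ind_call_rate_min individuals with call rate not above this are
#'   removed.
#' @param maf_min SNPs with minor-allele frequency not above this are
#'   removed.
#' @param hwe_method `"chisq"` or `"exact"`.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_alpha = 0.05, snp_call_rate_min = 0.97,
                          ind_call_rate_min = 0.90, maf_min = 0.05,
                          hwe_method = "chisq") {
  vals <- c(hwe_alpha, snp_call_rate_min, ind_call_rate_min, maf_min)
  if (any(vals <= 0 | vals >= 1)) stop("thresholds must lie in (0, 1)")
  structure(list(hwe_alpha = hwe_alpha,
                 snp_call_rate_min = snp_call_rate_min,
                 ind_call_rate_min = ind_call_rate_min,
                 maf_min = maf_min, hwe_method = hwe_method),
            class = "qc_thresholds")
}

#' Apply genotype quality control
#'
#' Filters in a fixed order: (1) individuals by call rate, (2) SNPs by call
#' rate, (3) SNPs by minor-allele frequency, (4) SNPs by Hardy-Weinberg
#' equilibrium with Bonferroni correction over the SNPs entering the HWE
#' test.  Call-rate and MAF bounds are strict (`> threshold` passes).  The
#' report records every removal with its reason; the operation is
#' idempotent.
#'
#' @param genotypes a `genotype_matrix`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered) and `report` (class
#'   `qc_report`: per-SNP and per-individual tables plus surviving
#'   dimensions).
#' @export
apply_qc <- function(genotypes, thresholds = qc_thresholds()) {
  g <- genotypes
  th <- thresholds

  ind_cr <- rowMeans(!is.na(g))
  ind_pass <- ind_cr > th$ind_call_rate_min
  g1 <- g[ind_pass, , drop = FALSE]

  snp_cr <- colMeans(!is.na(g1))
  maf <- apply(g1, 2, function(d) {
    p <- mean(d, na.rm = TRUE) / 2
    if (is.nan(p)) 0 else min(p, 1 - p)
  })
  cr_pass <- snp_cr > th$snp_call_rate_min
  maf_pass <- maf > th$maf_min

  enters_hwe <- cr_pass & maf_pass
  m_hwe <- sum(enters_hwe)
  hwe_p <- rep(NA_real_, ncol(g1))
  hwe_pass <- rep(NA, ncol(g1))
  if (m_hwe > 0) {
    hwe_p[enters_hwe] <- apply(g1[, enters_hwe, drop = FALSE], 2,
                               function(d) hwe_from_dosage(d, th$hwe_method)$p)
    hwe_pass[enters_hwe] <- hwe_p[enters_hwe] > th$hwe_alpha / m_hwe
  }
  snp_pass <- enters_hwe & !is.na(hwe_pass) & hwe_pass

  reason <- rep("pass", ncol(g1))
  reason[!maf_pass] <- "maf"
  reason[!cr_pass] <- "snp_call_rate"      # call rate reported first
  reason[enters_hwe & !snp_pass] <- "hwe"

  out <- g1[, snp_pass, drop = FALSE]
  if (nrow(out) == 0 || ncol(out) == 0) {
    stop("no data survive quality control")
  }
  panel <- attr(genotypes, "panel")
  if (!is.null(panel)) {
    attr(out, "panel") <- panel[panel$rsid %in% colnames(out), , drop = FALSE]
  }
  class(out) <- c("genotype_matrix", class(unclass(out)))

  report <- structure(list(
    snps = data.frame(rsid = colnames(g1), call_rate = snp_cr, maf = maf,
                      hwe_p = hwe_p, pass = snp_pass, reason = reason,
                      row.names = NULL, stringsAsFactors = FALSE),
    individuals = data.frame(individual_id = rownames(g),
                             call_rate = ind_cr, pass = ind_pass,
                             row.names = NULL, stringsAsFactors = FALSE),
    hwe_bonferroni_m = m_hwe,
    dim_in = dim(g), dim_out = dim(out)), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Genotype QC: %d/%d individuals and %d/%d SNPs retained\n",
              x$dim_out[1], x$dim_in[1], x$dim_out[2], x$dim_in[2]))
  tab <- table(x$snps$reason)
  for (r in setdiff(names(tab), "pass")) {
    cat(sprintf("  removed for %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Pairwise LD (r-squared) between SNPs
#'
#' Squared Pearson correlation of dosages, pairwise-complete.
#' @param genotypes dosage matrix.
#' @return symmetric matrix with unit diagonal.
#' @export
ld_r2 <- function(genotypes) {
  r <- suppressWarnings(cor(unclass(genotypes),
                            use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r^2
}

#' Greedy LD-based clumping
#'
#' Repeatedly takes the unassigned SNP with the smallest association p-value
#' as a clump index and assigns every unassigned SNP with `r2 >=
#' r2_threshold` (and, when positions are supplied, within `window_kb`) to
#' its clump, keeping the more strongly associated SNP of any correlated
#' pair.  Index SNPs form the independent subset.
#'
#' @param snp_stats data frame with `rsid` and `p`; optional `chrom`, `pos`
#'   (base pairs) enable the window constraint.
#' @param r2_matrix symmetric r-squared matrix (unit diagonal), dimnames
#'   matching `rsid`.
#' @param r2_threshold clumping threshold (default 0.5).
#' @param window_kb maximum distance for clumping (default 250; ignored
#'   without positions).
#' @param p_index maximum p for a SNP to seed a clump (default 1, so every
#'   candidate is clumpable).
#' @return data frame: `rsid`, `p`, `clump_index` (rsID of the clump's
#'   index SNP), `is_index`.
#' @export
ld_clump <- function(snp_stats, r2_matrix, r2_threshold = 0.5,
                     window_kb = 250, p_index = 1.0) {
  stopifnot(all(c("rsid", "p") %in% names(snp_stats)))
  m <- nrow(snp_stats)
  if (!is.matrix(r2_matrix) || nrow(r2_matrix) != m || ncol(r2_matrix) != m) {
    stop("r2_matrix dimensions do not match snp_stats")
  }
  if (!isTRUE(all.equal(r2_matrix, t(r2_matrix), tolerance = 1e-8))) {
    stop("r2_matrix must be symmetric")
  }
  if (!is.null(dimnames(r2_matrix)) &&
      !identical(rownames(r2_matrix), snp_stats$rsid)) {
    r2_matrix <- r2_matrix[snp_stats$rsid, snp_stats$rsid]
  }
  has_pos <- all(c("chrom", "pos") %in% names(snp_stats))

  assigned <- rep(NA_character_, m)
  ord <- order(snp_stats$p)
  for (i in ord) {
    if (!is.na(assigned[i])) next
    if (snp_stats$p[i] > p_index) next
    assigned[i] <- snp_stats$rsid[i]
    mates <- which(is.na(assigned) & r2_matrix[i, ] >= r2_threshold)
    if (has_pos && length(mates)) {
      near <- snp_stats$chrom[mates] == snp_stats$chrom[i] &
        abs(snp_stats$pos[mates] - snp_stats$pos[i]) <= window_kb * 1000
      mates <- mates[near]
    }
    assigned[mates] <- snp_stats$rsid[i]
  }
  # SNPs above p_index that were never absorbed stay as their own index
  left <- which(is.na(assigned))
  assigned[left] <- snp_stats$rsid[left]
  data.frame(rsid = snp_stats$rsid, p = snp_stats$p,
             clump_index = assigned,
             is_index = assigned == snp_stats$rsid,
             stringsAsFactors = FALSE)
}
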