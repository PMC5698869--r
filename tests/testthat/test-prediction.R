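panel <- load_snp_panel()

test_that("the unweighted PRS counts risk alleles over the 20 scored SNPs", {
  g <- generate_genotypes(5, panel, seed = 1)
  scored <- attr(compute_prs(g, panel), "scored_snps")
  expect_length(scored, 20)
  # homozygous risk everywhere -> 40; heterozygous -> 20
  g2 <- g
  g2[1, ] <- 2L; g2[2, ] <- 1L; g2[3, ] <- 0L
  prs <- compute_prs(g2, panel)
  expect_equal(as.numeric(prs[1:3]), c(40, 20, 0))
  # missing dosage contributes the per-SNP mean of observed dosages
  g3 <- g2
  g3[, scored[1]] <- c(NA, 1L, 0L, 1L, 0L)
  prs3 <- compute_prs(g3, panel)
  expect_equal(as.numeric(prs3[1]) - sum(g3[1, scored[-1]]), 0.5)
  expect_equal(attr(prs3, "n_imputed"), 1L)
  # a panel without risk alleles is not scorable
  p0 <- panel; p0$risk_allele <- NA
  expect_error(compute_prs(g, p0), "scorable")
})

test_that("logistic fitting matches closed-form log odds", {
  # 2x2 table: exposed 40/10 events vs unexposed 10/40 -> OR = 16
  x <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  f <- fit_logistic(y, data.frame(x = x))
  expect_equal(unname(f$coefficients["x"]), log(16), tolerance = 1e-6)
  # orthogonal predictor: slope ~ 0, intercept = logit(prevalence)
  set.seed(2)
  y2 <- rep(c(0, 1), 50)
  x2 <- rep(c(0, 1), each = 50)   # independent of y2
  f2 <- fit_logistic(y2, data.frame(x = x2))
  expect_equal(unname(f2$coefficients["x"]), 0, tolerance = 1e-6)
  expect_equal(unname(f2$coefficients["(Intercept)"]), 0, tolerance = 1e-6)
  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "both classes")
  # perfect separation warns but returns probabilities
  expect_warning(fs <- fit_logistic(c(0, 0, 0, 1, 1, 1),
                                    data.frame(x = 1:6)), "separation")
  expect_length(fs$probabilities, 6)
})

test_that("AUC equals brute-force pair counting", {
  # worked example: cases {3, 2}, controls {1, 2.5} -> 3 of 4 pairs
  expect_equal(roc_auc(c(3, 2, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))$auc,
               0.75)
  # degenerate cases
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # randomized cross-check against exhaustive enumeration, with ties
  set.seed(31)
  for (r in 1:1000) {
    n <- sample(6:30, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    s <- sample(1:8, n, replace = TRUE) + ifelse(y, 0.5 * rbinom(n, 1, 0.5), 0)
    expect_equal(roc_auc(s, y)$auc, auc_brute(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong intervals are sane and bootstrap agrees roughly", {
  set.seed(32)
  y <- rbinom(120, 1, 0.3) == 1
  s <- rnorm(120) + y
  a <- roc_auc(s, y)
  expect_true(a$ci[1] < a$auc && a$auc < a$ci[2])
  b <- roc_auc(s, y, ci_method = "bootstrap", boot_n = 300)
  expect_equal(a$ci, b$ci, tolerance = 0.05)
})

test_that("continuous NRI follows its defining enumeration", {
  # events (+,+,-), nonevents (-,-): (2/3 - 1/3) + (1 - 0) = 4/3
  p_old <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  p_new <- c(0.6, 0.7, 0.4, 0.3, 0.2)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  r <- nri_continuous(p_old, p_new, y)
  expect_equal(r$nri, 4 / 3)
  expect_equal(r$p_up_event, 2 / 3)
  expect_equal(r$p_down_nonevent, 1)
  # identical models
  expect_warning(r0 <- nri_continuous(p_old, p_old, y), "movement")
  expect_equal(r0$nri, 0)
  expect_error(nri_continuous(p_old, p_new, rep(TRUE, 5)), "nonevents")
  expect_error(nri_continuous(c(0.2, 1.4), c(0.1, 0.2), c(TRUE, FALSE)),
               "probabilities")
})

test_that("IDI equals the difference of discrimination slopes", {
  # constructed slopes: old 0.2, new 0.3 -> IDI = 0.1
  y <- c(TRUE, TRUE, FALSE, FALSE)
  p_old <- c(0.6, 0.6, 0.4, 0.4)      # slope 0.2
  p_new <- c(0.66, 0.64, 0.36, 0.34)  # slope 0.3
  r <- idi(p_old, p_new, y)
  expect_equal(r$idi, 0.1)
  expect_equal(r$slope_old, 0.2)
  expect_equal(r$slope_new, 0.3)
  # identical models: 0 with degenerate variance
  expect_warning(r0 <- idi(p_old, p_old, y), "degenerate")
  expect_equal(r0$idi, 0)
  # anti-informative update has negative IDI
  p_bad <- c(0.3, 0.3, 0.7, 0.7)
  expect_lt(suppressWarnings(idi(p_old, p_bad, y))$idi, 0)
  expect_error(idi(p_old, p_new, rep(FALSE, 4)), "events")
})

test_that("NRI is invariant to monotone transforms of the risk difference sign", {
  set.seed(33)
  n <- 60
  y <- rbinom(n, 1, 0.3) == 1
  p_old <- runif(n)
  p_new <- pmin(1, pmax(0, p_old + rnorm(n, sd = 0.2)))
  base <- nri_continuous(p_old, p_new, y)$nri
  # squashing both vectors through a strictly increasing map preserves all
  # up/down indicators
  sq <- function(p) p^2
  expect_equal(nri_continuous(sq(p_old), sq(p_new), y)$nri, base)
})

test_that("the three-model comparison runs end-to-end at study size", {
  set.seed(34)
  n <- 67
  y <- rep(c(TRUE, FALSE), c(14, 53))
  mmr <- rnorm(n, mean = ifelse(y, 2, -1), sd = 3)
  prs <- rnorm(n, mean = ifelse(y, 21, 20), sd = 2.5)
  cmp <- compare_models(mmr, prs, y)
  expect_s3_class(cmp, "model_comparison")
  for (a in list(cmp$auc_mmr, cmp$auc_prs, cmp$auc_combined)) {
    expect_true(a$auc >= 0 && a$auc <= 1)
    expect_length(a$ci, 2)
  }
  expect_true(is.finite(cmp$nri$nri))
  expect_true(is.finite(cmp$idi_result$idi))
  expect_equal(cmp$n_events, 14)
  expect_output(print(cmp), "AUC")
})

test_that("a pure-noise PRS neither helps nor hurts on average", {
  set.seed(35)
  reps <- 200
  d_auc <- idi_v <- nri_v <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 67
    y <- rep(c(TRUE, FALSE), c(14, 53))
    mmr <- rnorm(n, mean = ifelse(y, 1.5, -0.5), sd = 2.5)
    prs <- rnorm(n, 20, 2.5)                 # informationless
    cmp <- compare_models(mmr, prs, y)
    d_auc[r] <- cmp$auc_combined$auc - cmp$auc_mmr$auc
    idi_v[r] <- cmp$idi_result$idi
    nri_v[r] <- cmp$nri$nri
  }
  # training optimism keeps the combined model at or slightly above the
  # MMR-only model; the average gain stays small for a noise PRS
  expect_gte(mean(d_auc), 0)
  expect_lt(mean(d_auc), 0.05)
  expect_lt(abs(mean(nri_v)), 0.25)
  expect_lt(mean(idi_v), 0.05)
})

test_that("an informative PRS increases the combined AUC in expectation", {
  set.seed(36)
  reps <- 100
  gain <- numeric(reps)
  for (r in seq_len(reps)) {
    n <- 67
    y <- rep(c(TRUE, FALSE), c(14, 53))
    mmr <- rnorm(n, mean = ifelse(y, 1.5, -0.5), sd = 2.5)
    prs <- rnorm(n, mean = ifelse(y, 22, 20), sd = 2.5)
    cmp <- compare_models(mmr, prs, y)
    gain[r] <- cmp$auc_combined$auc - cmp$auc_mmr$auc
  }
  expect_gt(mean(gain), 0.02)
})
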