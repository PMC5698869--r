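test_that("the additive model reproduces exact closed-form fits", {
  # perfect line through (0,0), (1,1.5), (2,3): beta = 1.5, zero residuals
  f <- suppressWarnings(fit_additive_model(c(0, 1.5, 3), c(0, 1, 2)))  # exact fit
  expect_equal(f$beta, 1.5)
  expect_equal(sum(residuals(f$model)^2), 0, tolerance = 1e-20)
  # dosage orthogonal to outcome by construction: beta = 0 exactly
  x <- c(-1, 0, 1, -1, 0, 1)
  y <- c(1, -2, 1, 1, -2, 1)      # sum(x * y) = 0, sum(x) = 0
  f0 <- fit_additive_model(y, x)
  expect_equal(f0$beta, 0)
  # missing dosages are dropped and counted
  f2 <- suppressWarnings(fit_additive_model(c(0, 1.5, 3, 9), c(0, 1, 2, NA)))
  expect_equal(f2$n_used, 3)
  expect_equal(f2$beta, 1.5)
  # constant dosage is untestable, not an error
  f3 <- fit_additive_model(rnorm(10), rep(1, 10))
  expect_true(f3$untestable)
  # collinear covariate errors with the column named
  cov <- data.frame(dup = c(0, 1, 2, 0, 1, 2))
  expect_error(fit_additive_model(rnorm(6), c(0, 1, 2, 0, 1, 2), cov),
               "collinear.*dup")
})

test_that("simulated per-allele effects are recovered within sampling error", {
  set.seed(61)
  n <- 2000
  dose <- rbinom(n, 2, 0.3)
  poor <- rbinom(n, 1, 0.2) == 1
  y <- 3.0 * dose + 2 * poor + rnorm(n, sd = 4)
  f <- fit_additive_model(y, dose, data.frame(poor_speller = poor))
  expect_lt(abs(f$beta - 3.0), 3 * f$se)
})

test_that("per-allele effect estimates are unbiased at study magnitudes", {
  set.seed(62)
  n <- 2000
  reps <- 200
  beta_true <- 1.7
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    dose <- rbinom(n, 2, 0.3)
    y <- beta_true * dose + rnorm(n, sd = 4)
    f <- fit_additive_model(y, dose)
    est[r] <- f$beta; se[r] <- f$se
  }
  bias <- mean(est) - beta_true
  expect_lt(abs(bias), mean(se) / 3)
})

test_that("type-I error is at the nominal level under the null", {
  set.seed(63)
  n <- 67
  reps <- 2000
  p <- numeric(reps)
  for (r in seq_len(reps)) {
    dose <- rbinom(n, 2, 0.3)
    poor <- rbinom(n, 1, 0.2) == 1
    y <- 2 * poor + rnorm(n, sd = 3)        # no genetic effect
    p[r] <- fit_additive_model(y, dose, data.frame(poor = poor))$p
  }
  # 99% binomial interval around 0.05 with 2000 replicates
  hits <- mean(p < 0.05)
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / reps)
  expect_gt(hits, 0.05 - half)
  expect_lt(hits, 0.05 + half)
  # QQ calibration: order statistics fall inside the 95% envelope at the
  # expected rate (the envelope is pointwise)
  m <- 25
  env <- qq_envelope(m)
  inside <- logical(0)
  for (b in seq_len(floor(reps / m))) {
    ps <- sort(p[((b - 1) * m + 1):(b * m)])
    inside <- c(inside, ps >= env$lower & ps <= env$upper)
  }
  expect_equal(mean(inside), 0.95, tolerance = 0.02)
})

test_that("BH adjustment equals the brute-force step-up on random inputs", {
  set.seed(64)
  for (r in 1:1000) {
    k <- sample(1:12, 1)
    p <- runif(k)
    m <- k + sample(0:10, 1)
    expect_equal(bh_fdr(p, m), bh_brute(p, m), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(0.5, m = 1), 0.5)
  # equal p-values collapse to m * p / k
  expect_equal(bh_fdr(rep(0.02, 4), m = 10), rep(0.05, 4))
  expect_error(bh_fdr(c(0.1, 0)), "0, 1")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "at least")
})

test_that("QQ envelope matches closed-form beta order statistics", {
  e1 <- qq_envelope(1)
  expect_equal(e1$expected, 0.5)
  expect_equal(e1$lower, 0.025)
  expect_equal(e1$upper, 0.975)
  e25 <- qq_envelope(25)
  expect_equal(e25$lower[1], 1 - 0.975^(1 / 25), tolerance = 1e-12)
  expect_equal(e25$expected, (1:25) / 26)
  expect_true(all(diff(e25$lower) > 0))
  expect_true(all(diff(e25$upper) > 0))
  expect_true(all(e25$lower < e25$expected & e25$expected < e25$upper))
  expect_error(qq_envelope(10, level = 1.2), "level")
})

test_that("Cook's distance flags gross outliers and matches the LOO oracle", {
  # perfectly linear data: all distances 0, nothing flagged, no beta shift
  fl <- suppressWarnings(fit_additive_model(c(0, 1.5, 3, 4.5), c(0, 1, 2, 3)))
  cs0 <- cooks_sensitivity(fl)
  expect_equal(max(cs0$cooks_d), 0, tolerance = 1e-20)
  expect_length(cs0$flagged, 0)
  expect_equal(cs0$beta_shift, 0)
  # append one gross outlier to a near-perfect line
  set.seed(65)
  x <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 1)
  y <- 1.5 * x + rnorm(10, sd = 0.1)
  x2 <- c(x, 2); y2 <- c(y, 25)
  f2 <- fit_additive_model(y2, x2)
  cs <- cooks_sensitivity(f2)
  expect_equal(unname(which.max(cs$cooks_d)), 11L)
  expect_gt(max(cs$cooks_d), 4 / 11)
  expect_true(11 %in% cs$flagged)
  # the refit moves beta back toward the clean value
  expect_lt(abs(cs$beta_refit - 1.5), abs(f2$beta - 1.5))
  # formula-based distances equal leave-one-out refits
  expect_equal(unname(cs$cooks_d), cooks_loo(f2$model), tolerance = 1e-8)
})

test_that("covariate adjustment comparison isolates beta and p changes", {
  set.seed(66)
  n <- 300
  dose <- rbinom(n, 2, 0.3)
  add <- rbinom(n, 1, 0.18) == 1
  poor <- rbinom(n, 1, 0.2) == 1
  y <- 1.5 * dose + 3 * add + rnorm(n)
  g <- matrix(dose, ncol = 1, dimnames = list(sprintf("S%03d", 1:n), "snp1"))
  mmr_tab <- data.frame(subject_id = rownames(g), mmr_uv = y)
  ph <- data.frame(individual_id = rownames(g), poor_speller = poor,
                   add_status = add)
  base <- assoc_scan(mmr_tab, g, ph, covariates = "poor_speller")
  with_add <- assoc_scan(mmr_tab, g, ph,
                         covariates = c("poor_speller", "add_status"))
  cmp <- compare_covariate_adjustment(base, with_add)
  # ADD is independent of dosage: beta stable, p changes with noise removed
  expect_lt(abs(cmp$delta_beta), 2 * base$se)
  expect_false(identical(cmp$p_base, cmp$p_adjusted))
  expect_error(compare_covariate_adjustment(base, base[0, ]), "differ")
})

test_that("assoc_scan splits FDR families and orders by p", {
  study <- simulate_small_study(n_subjects = 40, seed = 71)
  mmr_tab <- data.frame(subject_id = rownames(study$genotypes),
                        mmr_uv = rnorm(40))
  res <- assoc_scan(mmr_tab, study$genotypes, study$phenotypes)
  expect_s3_class(res, "mmr_assoc")
  expect_setequal(unique(res$family), c("candidate", "mmr_replication"))
  expect_equal(sum(res$family == "mmr_replication"), 2)
  cand <- res[res$family == "candidate" & !res$untestable, ]
  expect_equal(cand$fdr_q, bh_brute(cand$p, m = nrow(cand)),
               tolerance = 1e-12)
  expect_false(is.unsorted(cand$p))
})
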