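test_that("difference wave and window mean satisfy exact identities", {
  # constant 2 uV difference -> MMR 2.0; ROI channels at 1/2/3 -> 2.0
  times <- seq(-200, 1244, by = 4)
  mk_wave <- function(vals_by_channel) {
    m <- matrix(rep(vals_by_channel, length(times)), nrow = 3,
                dimnames = list(c("F3", "Fz", "F4"), NULL))
    structure(m, times_ms = times, channel_labels = c("F3", "Fz", "F4"),
              n_valid_deviant = 5, n_valid_standard = 20,
              exclusion_fractions = c(standard = 0, deviant = 0),
              subject_id = "S", class = c("difference_wave", "matrix"))
  }
  expect_equal(mmr_amplitude(mk_wave(c(2, 2, 2)))$mmr_uv, 2)
  expect_equal(mmr_amplitude(mk_wave(c(1, 2, 3)))$mmr_uv, 2)
  # linear ramp 0 -> 1 across [300, 600): discrete mean on the 4 ms grid
  w <- mk_wave(c(0, 0, 0))
  sel <- times >= 300 & times < 600
  ramp <- (times[sel] - 300) / 300
  w[, sel] <- matrix(rep(ramp, each = 3), nrow = 3)
  expect_equal(mmr_amplitude(w)$mmr_uv, mean(ramp))
  expect_equal(mean(ramp), 0.49333333, tolerance = 1e-8)
})

test_that("noiseless generation round-trips through the ERP reduction", {
  tmpl <- noiseless_template()
  cfg <- identity_config()
  for (case in list(list(group = "poor", shift = 0),
                    list(group = "control", shift = 3),
                    list(group = "control", shift = -1.7))) {
    sseq <- generate_stimulus_block(1, 20, 3, 2, seed = 13)
    rec <- generate_subject_block(sseq, tmpl, group = case$group,
                                  shift_uv = case$shift, seed = 14)
    res <- erp_process_subject(rec, cfg, "S1")
    expected <- template_window_mean(tmpl, case$group, case$shift)
    expect_lt(abs(res$measure$mmr_uv - expected), 1e-9)
  }
})

test_that("recovered MMR is affine in dosage with slope = per-allele shift", {
  tmpl <- noiseless_template()
  cfg <- identity_config()
  shift_per_allele <- 3.0
  mmr <- vapply(0:2, function(dose) {
    sseq <- generate_stimulus_block(1, 20, 3, 2, seed = 5)
    rec <- generate_subject_block(sseq, tmpl, group = "control",
                                  shift_uv = dose * shift_per_allele,
                                  seed = 6)
    erp_process_subject(rec, cfg)$measure$mmr_uv
  }, 0)
  expect_lt(abs((mmr[3] - mmr[1]) - 2 * shift_per_allele), 1e-9)
  expect_lt(abs((mmr[2] - mmr[1]) - shift_per_allele), 1e-9)
  # pipeline linearity: scaling the EEG scales the MMR
  sseq <- generate_stimulus_block(1, 20, 3, 2, seed = 5)
  rec <- generate_subject_block(sseq, tmpl, group = "poor", shift_uv = 1,
                                seed = 6)
  m1 <- erp_process_subject(rec, cfg)$measure$mmr_uv
  rec$eeg$samples <- rec$eeg$samples * 2.5
  expect_lt(abs(erp_process_subject(rec, cfg)$measure$mmr_uv - 2.5 * m1),
            1e-9)
  # baseline invariance: per-channel constants cancel
  rec$eeg$samples <- rec$eeg$samples / 2.5 + c(7, -3, 2, 1, -5)
  expect_lt(abs(erp_process_subject(rec, cfg)$measure$mmr_uv - m1), 1e-9)
})

test_that("injected 150 uV artifacts are rejected with recall 1 and no false alarms", {
  tmpl <- erp_template_model(noise = list(amplitude_uv = 0, alpha_uv = 0),
                             artifact_rate = 0.5)
  sseq <- generate_stimulus_block(1, 40, 6, 2, seed = 8)
  rec <- generate_subject_block(sseq, tmpl, group = "control", shift_uv = 0,
                                seed = 9)
  cfg <- identity_config()
  eeg <- rereference(rec$eeg, cfg$reference)
  eeg <- resample_eeg(eeg, cfg$resample_hz)
  ep <- reject_artifacts(epoch_eeg(eeg, rec$events, cfg), cfg)
  # oracle: trials whose epoch window contains a sample beyond 80 uV after
  # re-referencing (clean template peaks are far below the bound)
  contaminated <- vapply(seq_len(dim(ep$data)[1]), function(k) {
    any(abs(ep$data[k, , ]) > 80, na.rm = TRUE)
  }, TRUE)
  flagged <- ep$excluded_reason == "artifact"
  eligible <- ep$excluded_reason != "standard_after_deviant"
  expect_identical(flagged[eligible], contaminated[eligible])
  expect_gt(sum(flagged), 0)
})

test_that("artifact contamination count is binomial at the configured rate", {
  tmpl <- erp_template_model(noise = list(amplitude_uv = 0, alpha_uv = 0),
                             artifact_rate = 0.2)
  n_trials <- 300
  sseq <- generate_stimulus_block(1, n_trials, 30, 2, seed = 10)
  rec <- generate_subject_block(sseq, tmpl, group = "control",
                                shift_uv = 0, seed = 11)
  cfg <- identity_config()
  eeg <- resample_eeg(rereference(rec$eeg, cfg$reference), 250)
  ep <- reject_artifacts(epoch_eeg(eeg, rec$events, cfg), cfg)
  n_art <- sum(ep$excluded_reason == "artifact")
  # some transients fall between epochs or on already-excluded trials;
  # allow 4 binomial SDs around the 20% target
  expect_lt(abs(n_art - 0.2 * n_trials), 4 * sqrt(n_trials * 0.2 * 0.8) + 5)
})

test_that("sliding t-test tiles the span and matches Welch's t", {
  times <- seq(-200, 1244, by = 4)
  n_t <- length(times)
  mk <- function(rows) {
    m <- matrix(rows, ncol = n_t, nrow = length(rows))
    attr(m, "times_ms") <- times
    m
  }
  set.seed(3)
  A <- mk(c(1, 2, 3)) + matrix(rnorm(3 * n_t, sd = 0.1), 3)
  B <- mk(c(0, 0.5)) + matrix(rnorm(2 * n_t, sd = 0.1), 2)
  attr(A, "times_ms") <- times; attr(B, "times_ms") <- times
  res <- sliding_ttest(A, B, window_ms = 3.2, span_ms = c(0, 1200))
  expect_equal(nrow(res), 375)
  expect_equal(res$start_ms, 3.2 * (0:374))
  expect_false(any(is.na(res$t)))
  # cross-check one window against stats::t.test (Welch)
  i <- 100
  sel <- which(times >= res$start_ms[i] & times < res$end_ms[i])
  if (!length(sel)) sel <- which.min(abs(times - (res$start_ms[i] + 1.6)))
  xa <- rowMeans(A[, sel, drop = FALSE]); xb <- rowMeans(B[, sel, drop = FALSE])
  tt <- t.test(xa, xb)
  expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
  # identical groups give t = 0 everywhere
  res0 <- sliding_ttest(mk(c(1, 1, 1)), mk(c(1, 1, 1)))
  expect_true(all(res0$t == 0))
  expect_true(all(res0$degenerate))
  expect_error(sliding_ttest(mk(c(1, 1)), mk(1)), "2 subjects")
})

test_that("group confidence band matches the closed-form t interval", {
  times <- seq(-200, 1244, by = 4)
  vals <- c(1.2, 0.7, 2.1, 1.5)
  m <- matrix(vals, nrow = 4, ncol = length(times))
  attr(m, "times_ms") <- times
  ci <- group_average_with_ci(m, level = 0.95)
  mu <- mean(vals); s <- sd(vals) / 2
  q <- qt(0.975, 3)
  expect_equal(ci$mean_uv[1], mu)
  expect_equal(ci$lower_uv[1], mu - q * s)
  expect_equal(ci$upper_uv[1], mu + q * s)
  # identical subjects -> zero-width band
  m0 <- matrix(1, nrow = 3, ncol = length(times))
  attr(m0, "times_ms") <- times
  ci0 <- group_average_with_ci(m0)
  expect_true(all(ci0$lower_uv == ci0$upper_uv))
  expect_error(group_average_with_ci(m, level = 0), "level")
})

test_that("poor spellers show a more positive late MMR than controls", {
  tmpl <- erp_template_model()   # default noise and 20% artifacts
  poor <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  study <- simulate_small_study(n_subjects = 6, n_total = 40, n_deviant = 6,
                                template = tmpl, seed = 17, poor = poor)
  res <- erp_process_dataset(study$dataset, preprocess_config())
  m <- res$mmr_table$mmr_uv
  expect_gt(mean(m[poor]) - mean(m[!poor]), 0)
})
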