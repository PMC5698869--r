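test_that("HWE chi-square matches hand-computed values", {
  # exact HWE proportions at allele frequency 0.6: chi-square 0, p = 1
  r <- hwe_test(36, 48, 16)
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  # (50, 0, 50): expected 25/50/25, terms 25 + 50 + 25 = 100
  r2 <- hwe_test(50, 0, 50)
  expect_equal(r2$chisq, 100)
  expect_lt(r2$p, 1e-20)
  # monomorphic SNP
  r3 <- hwe_test(100, 0, 0)
  expect_true(r3$monomorphic)
  expect_equal(r3$p, 1)
  expect_error(hwe_test(0, 0, 0), "positive")
})

test_that("exact HWE test agrees with enumeration-based expectations", {
  # at (36, 48, 16) the observed heterozygote count is the modal one
  expect_equal(hwe_test(36, 48, 16, method = "exact")$p, 1, tolerance = 1e-9)
  # strong departure is extreme under both tests
  expect_lt(hwe_test(50, 0, 50, method = "exact")$p, 1e-10)
  # exact and chi-square broadly agree at moderate departure
  p_chi <- hwe_test(40, 40, 20)$p
  p_ex <- hwe_test(40, 40, 20, method = "exact")$p
  expect_lt(abs(p_chi - p_ex), 0.1)
})

test_that("HWE p-values are uniform under simulated equilibrium genotypes", {
  set.seed(99)
  n <- 500
  ps <- replicate(5000, {
    maf <- runif(1, 0.1, 0.5)
    d <- rbinom(n, 2, maf)
    hwe_test(sum(d == 2), sum(d == 1), sum(d == 0))$p
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("QC removes exactly the injected failures, in the fixed order", {
  panel <- load_snp_panel()
  g <- generate_genotypes(200, panel, maf = 0.3, seed = 51)
  # clean data: nothing removed
  r <- apply_qc(g)
  expect_equal(dim(r$genotypes), dim(g))
  expect_true(all(r$report$snps$pass))
  # inject a low-MAF SNP
  g_maf <- g
  g_maf[, "rs1419228"] <- rbinom(200, 2, 0.02)
  r2 <- apply_qc(g_maf)
  expect_false("rs1419228" %in% colnames(r2$genotypes))
  expect_equal(r2$report$snps$reason[r2$report$snps$rsid == "rs1419228"],
               "maf")
  # individual with 85% call rate is removed
  g_ind <- g
  g_ind[3, sample(ncol(g), round(0.15 * ncol(g)) + 1)] <- NA
  r3 <- apply_qc(g_ind)
  expect_false(rownames(g)[3] %in% rownames(r3$genotypes))
  expect_false(r3$report$individuals$pass[3])
  # SNP violating HWE is removed with reason "hwe"
  g_hwe <- g
  g_hwe[, "rs793862"] <- rep(c(0L, 2L), each = 100)  # no heterozygotes
  r4 <- apply_qc(g_hwe)
  expect_equal(r4$report$snps$reason[r4$report$snps$rsid == "rs793862"],
               "hwe")
  # low SNP call rate wins over other labels
  g_cr <- g
  g_cr[sample(200, 20), "rs555879"] <- NA
  r5 <- apply_qc(g_cr)
  expect_equal(r5$report$snps$reason[r5$report$snps$rsid == "rs555879"],
               "snp_call_rate")
})

test_that("QC is idempotent and errors on an empty result", {
  panel <- load_snp_panel()
  g <- generate_genotypes(150, panel, maf = 0.3, missing_rate = 0.01,
                          seed = 52)
  g[, 1] <- rbinom(150, 2, 0.01)
  r1 <- apply_qc(g)
  r2 <- apply_qc(r1$genotypes)
  expect_identical(unclass(r2$genotypes)[, ], unclass(r1$genotypes)[, ])
  g_bad <- g
  g_bad[] <- NA_integer_
  expect_error(apply_qc(g_bad), "survive")
})

test_that("greedy clumping keeps the stronger-associated index SNPs", {
  # all independent: everything retained
  st <- data.frame(rsid = c("a", "b", "c"), p = c(.01, .02, .03))
  r2m <- diag(3); dimnames(r2m) <- list(st$rsid, st$rsid)
  cl <- ld_clump(st, r2m)
  expect_true(all(cl$is_index))
  # correlated pair: the smaller p survives
  st2 <- data.frame(rsid = c("a", "b"), p = c(.001, .01))
  r2b <- matrix(c(1, .9, .9, 1), 2, dimnames = list(st2$rsid, st2$rsid))
  cl2 <- ld_clump(st2, r2b, r2_threshold = 0.5)
  expect_identical(cl2$rsid[cl2$is_index], "a")
  expect_identical(cl2$clump_index, c("a", "a"))
  # chain a-b, b-c with a-c independent: retained {a, c}
  st3 <- data.frame(rsid = c("a", "b", "c"), p = c(.001, .005, .01))
  r2c <- matrix(c(1, .8, 0, .8, 1, .8, 0, .8, 1), 3,
                dimnames = list(st3$rsid, st3$rsid))
  cl3 <- ld_clump(st3, r2c)
  expect_setequal(cl3$rsid[cl3$is_index], c("a", "c"))
  # dimension mismatch errors
  expect_error(ld_clump(st3, r2b), "dimensions")
})

test_that("clumped index sets are maximal independent sets", {
  set.seed(7)
  for (rep in 1:20) {
    m <- 12
    x <- matrix(rnorm(m * 30), 30, m)
    # induce blocks of correlation
    x[, 2] <- x[, 1] + rnorm(30, sd = 0.3)
    x[, 5] <- x[, 4] + rnorm(30, sd = 0.2)
    r2m <- cor(x)^2
    dimnames(r2m) <- list(sprintf("s%02d", 1:m), sprintf("s%02d", 1:m))
    st <- data.frame(rsid = rownames(r2m), p = runif(m))
    cl <- ld_clump(st, r2m, r2_threshold = 0.5)
    idx <- which(cl$is_index)
    pairs <- r2m[idx, idx, drop = FALSE]
    diag(pairs) <- 0
    expect_true(all(pairs < 0.5))
  }
})

test_that("window constraint limits clumping to nearby SNPs", {
  st <- data.frame(rsid = c("a", "b"), p = c(.001, .01),
                   chrom = c("1", "1"), pos = c(1e6, 2e6))
  r2b <- matrix(c(1, .9, .9, 1), 2, dimnames = list(st$rsid, st$rsid))
  # 1 Mb apart with a 250 kb window: both survive despite high r2
  cl <- ld_clump(st, r2b, r2_threshold = 0.5, window_kb = 250)
  expect_true(all(cl$is_index))
  cl2 <- ld_clump(st, r2b, r2_threshold = 0.5, window_kb = 2000)
  expect_identical(cl2$rsid[cl2$is_index], "a")
})
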