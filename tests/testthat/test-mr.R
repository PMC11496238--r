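test_that("Wald ratio arithmetic, sign and degenerate input", {
  p <- make_pair(bx = 0.1, by = 0.02, sey = 0.01)
  f <- mr_fit(p, "wald")
  expect_equal(f$beta, 0.2)
  expect_equal(f$se, 0.1)
  pn <- make_pair(bx = -0.1, by = 0.02, sey = 0.01)
  fn <- mr_fit(pn, "wald")
  expect_equal(fn$beta, -0.2)
  expect_equal(fn$se, 0.1)
  expect_error(mr_fit(make_pair(bx = 0, by = 0.02), "wald"), "beta_exp = 0")
})

test_that("IVW equals the closed-form inverse-variance mean and the WLS oracle", {
  p <- make_pair(bx = c(0.1, 0.2), by = c(0.02, 0.05), sey = c(0.01, 0.02))
  f <- mr_fit(p, "ivw", model = "fixed")
  expect_equal(f$beta, 0.225, tolerance = 1e-12)
  expect_equal(f$se, 1 / sqrt(200), tolerance = 1e-12)
  o <- oracle_ivw(p$beta_exp, p$beta_out, p$se_out)
  expect_equal(f$beta, o$beta, tolerance = 1e-10)
  expect_equal(f$se, o$se_fixed, tolerance = 1e-10)
})

test_that("single-instrument IVW falls back to the Wald ratio with a warning", {
  p <- make_pair(bx = 0.1, by = 0.02, sey = 0.01)
  expect_warning(f <- mr_fit(p, "ivw"), "single instrument")
  expect_equal(f$beta, 0.2)
  expect_equal(f$method, "ivw")
})

test_that("identical ratios give Q = 0 and mre se equals fixed se", {
  p <- make_pair(bx = c(0.1, 0.2, 0.4), by = c(0.02, 0.04, 0.08),
                 sey = c(0.01, 0.01, 0.01))
  f_mre <- mr_fit(p, "ivw", model = "mre")
  f_fix <- mr_fit(p, "ivw", model = "fixed")
  expect_equal(f_mre$Q, 0, tolerance = 1e-20)
  expect_equal(f_mre$se, f_fix$se)
  expect_equal(f_mre$beta, 0.2)
})

test_that("IVW and Egger are invariant to joint sign-flips of variant subsets", {
  pair <- simulate_mr_pair(n_snps = 10, theta = 0.1, seed = 7)
  flip <- c(2, 5, 9)
  pair2 <- pair
  pair2$beta_exp[flip] <- -pair2$beta_exp[flip]
  pair2$beta_out[flip] <- -pair2$beta_out[flip]
  expect_equal(mr_fit(pair2, "ivw")$beta, mr_fit(pair, "ivw")$beta, tolerance = 1e-12)
  expect_equal(mr_fit(pair2, "egger")$beta, mr_fit(pair, "egger")$beta, tolerance = 1e-12)
  expect_equal(mr_fit(pair2, "egger")$intercept, mr_fit(pair, "egger")$intercept,
               tolerance = 1e-12)
})

test_that("Egger recovers an exact line and matches the WLS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  by <- 0.03 + 0.4 * bx  # exact line, zero noise
  p <- make_pair(bx = bx, by = by, sey = c(0.01, 0.012, 0.014, 0.02))
  f <- mr_fit(p, "egger")
  expect_equal(f$beta, 0.4, tolerance = 1e-10)
  expect_equal(f$intercept, 0.03, tolerance = 1e-10)

  pair <- simulate_mr_pair(n_snps = 15, theta = 0.1, pleiotropy_mean = 0.002,
                           seed = 11)
  f2 <- mr_fit(pair, "egger")
  o <- oracle_egger(pair$beta_exp, pair$beta_out, pair$se_out)
  expect_equal(f2$beta, o$slope, tolerance = 1e-10)
  expect_equal(f2$se, o$slope_se, tolerance = 1e-10)
  expect_equal(f2$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(f2$intercept_se, o$intercept_se, tolerance = 1e-10)
  expect_equal(f2$pval, o$slope_p, tolerance = 1e-10)
})

test_that("Egger with the intercept suppressed equals IVW with 1/se_out^2 weights", {
  pair <- simulate_mr_pair(n_snps = 12, theta = 0.1, seed = 5)
  s <- ifelse(pair$beta_exp < 0, -1, 1)
  no_int <- stats::lm(I(pair$beta_out * s) ~ 0 + I(pair$beta_exp * s),
                      weights = 1 / pair$se_out^2)
  expect_equal(unname(coef(no_int)[1]), mr_fit(pair, "ivw")$beta, tolerance = 1e-10)
})

test_that("Egger intercept is near zero without pleiotropy and detects it when present", {
  n_rep <- 100
  ints <- vapply(seq_len(n_rep), function(r) {
    mr_fit(simulate_mr_pair(n_snps = 30, theta = 0.1, seed = child_seed(21, r)),
           "egger")$intercept
  }, numeric(1))
  expect_lt(abs(mean(ints)), 3 * sd(ints) / sqrt(n_rep))

  dir <- vapply(seq_len(n_rep), function(r) {
    mr_fit(simulate_mr_pair(n_snps = 30, theta = 0.1, pleiotropy_mean = 0.003,
                            seed = child_seed(22, r)), "egger")$intercept
  }, numeric(1))
  expect_gt(mean(dir), 0.002)
})

test_that("weighted median interpolates standardized cumulative weights", {
  p <- make_pair(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.6), sey = c(1, 1, 1))
  f <- mr_fit(p, "weighted_median", seed = 1, n_boot = 50)
  expect_equal(f$beta, 0.2)

  # a variant holding > 50% of the weight dictates the estimate
  p2 <- make_pair(bx = c(1, 1, 1, 1), by = c(0.1, 0.2, 0.5, 0.9),
                  sey = c(1, 1, 0.1, 1))
  f2 <- mr_fit(p2, "weighted_median", seed = 1, n_boot = 50)
  w <- (p2$beta_exp / p2$se_out)^2
  expect_equal(f2$beta, oracle_wmedian(p2$beta_out / p2$beta_exp, w),
               tolerance = 1e-12)
  expect_lt(abs(f2$beta - 0.5), 0.1)

  # random panels against the walk oracle
  for (s in 1:10) {
    pair <- simulate_mr_pair(n_snps = 9, theta = 0.05, seed = child_seed(31, s))
    f3 <- mr_fit(pair, "weighted_median", seed = 2, n_boot = 10)
    w3 <- (pair$beta_exp / pair$se_out)^2
    expect_equal(f3$beta, oracle_wmedian(pair$beta_out / pair$beta_exp, w3),
                 tolerance = 1e-10)
  }
})

test_that("bootstrap standard errors are bit-identical under the same seed", {
  pair <- simulate_mr_pair(n_snps = 10, theta = 0.1, seed = 13)
  a <- mr_fit(pair, "weighted_median", seed = 99, n_boot = 200)
  b <- mr_fit(pair, "weighted_median", seed = 99, n_boot = 200)
  expect_identical(a$se, b$se)
  c1 <- mr_fit(pair, "weighted_mode", seed = 99, n_boot = 50)
  c2 <- mr_fit(pair, "weighted_mode", seed = 99, n_boot = 50)
  expect_identical(c1$se, c2$se)
  expect_error(mr_fit(pair, "weighted_median"), "seed")
})

test_that("weighted mode finds the dominant ratio cluster", {
  p <- make_pair(bx = rep(1, 4), by = c(0.1, 0.1, 0.1, 0.9), sey = rep(1, 4))
  f <- mr_fit(p, "weighted_mode", seed = 1, n_boot = 10)
  expect_lt(abs(f$beta - 0.1), 0.05)
  w <- (p$beta_exp / p$se_out)^2
  expect_equal(f$beta, oracle_wmode(p$beta_out / p$beta_exp, w), tolerance = 1e-8)

  # all ratios identical -> exactly that value
  p2 <- make_pair(bx = c(0.1, 0.2, 0.5), by = c(0.02, 0.04, 0.10),
                  sey = c(0.01, 0.02, 0.01))
  f2 <- mr_fit(p2, "weighted_mode", seed = 1, n_boot = 10)
  expect_identical(f2$beta, 0.2)
})

test_that("Cochran's Q is order-invariant and equals term-by-term summation", {
  pair <- simulate_mr_pair(n_snps = 4, theta = 0.1, seed = 17)
  ivw <- mr_fit(pair, "ivw")
  q <- cochran_q(pair, ivw)
  w <- pair$beta_exp^2 / pair$se_out^2
  ratio <- pair$beta_out / pair$beta_exp
  expect_equal(q$Q, sum(w * (ratio - ivw$beta)^2), tolerance = 1e-12)
  expect_equal(q$df, 3L)
  perm <- pair_subset(pair, c(3, 1, 4, 2))
  expect_equal(cochran_q(perm, ivw)$Q, q$Q, tolerance = 1e-12)

  same <- make_pair(bx = c(0.1, 0.2), by = c(0.02, 0.04), sey = c(0.01, 0.01))
  ivw_same <- mr_fit(same, "ivw")
  q0 <- cochran_q(same, ivw_same)
  expect_equal(q0$Q, 0, tolerance = 1e-18)
  expect_equal(q0$pval, 1)
})

test_that("instrument strength: F statistics and I2GX match direct formulas", {
  p <- make_pair(bx = 0.1, by = 0.01, sex = 0.01)
  expect_equal(instrument_strength(p)$F, 100)

  same <- make_pair(bx = rep(0.1, 3), by = rep(0.02, 3), sex = rep(0.01, 3))
  s <- instrument_strength(same)
  expect_equal(s$Q_gx, 0)
  expect_equal(s$i2_gx, 0)

  pair <- simulate_mr_pair(n_snps = 5, theta = 0, seed = 23)
  st <- instrument_strength(pair)
  bxa <- abs(pair$beta_exp); wx <- 1 / pair$se_exp^2
  bw <- sum(wx * bxa) / sum(wx)
  Qgx <- sum((bxa - bw)^2 * wx)
  expect_equal(st$Q_gx, Qgx, tolerance = 1e-10)
  expect_equal(st$i2_gx, max(0, (Qgx - 4) / Qgx), tolerance = 1e-10)
  expect_equal(st$mean_F, mean((pair$beta_exp / pair$se_exp)^2), tolerance = 1e-10)
})

test_that("Steiger filtering keeps variants explaining more exposure variance", {
  p <- make_pair(bx = 0.1, by = 0.01, sex = 0.01, sey = 0.01,
                 n_exp = 400000, n_out = 50000)
  st <- steiger_filter(p)
  expect_equal(st$table$r2_exposure, 100 / (100 + 400000 - 2), tolerance = 1e-12)
  expect_equal(st$table$r2_outcome, 1 / (1 + 50000 - 2), tolerance = 1e-12)
  expect_true(st$table$keep)
  expect_true(st$direction_ok)

  # identical statistics on both sides: strict inequality drops the variant
  tie <- make_pair(bx = 0.1, by = 0.1, sex = 0.01, sey = 0.01,
                   n_exp = 1e5, n_out = 1e5)
  st2 <- steiger_filter(tie)
  expect_false(st2$table$keep)
  expect_equal(st2$n_removed, 1L)

  no_n <- make_pair(bx = 0.1, by = 0.1)
  expect_error(steiger_filter(no_n), "sample size missing")
})

test_that("Steiger flags reverse causation in a flipped simulation", {
  # exposure truly downstream: simulate with roles swapped, then relabel
  flipped <- simulate_mr_pair(n_snps = 40, theta = 0.3, h2 = 0.05,
                              n_exp = 50000, n_out = 50000, seed = 41)
  rev <- flipped
  rev$beta_exp <- flipped$beta_out; rev$se_exp <- flipped$se_out
  rev$beta_out <- flipped$beta_exp; rev$se_out <- flipped$se_exp
  st <- steiger_filter(rev)
  expect_gt(st$n_removed, st$n_kept)
  expect_false(st$direction_ok)
})

test_that("leave-one-out reproduces subset IVW fits", {
  pair <- simulate_mr_pair(n_snps = 3, theta = 0.1, seed = 29)
  loo <- leave_one_out(pair)
  expect_equal(nrow(loo), 3L)
  for (j in 1:3) {
    sub <- mr_fit(pair_subset(pair, -j), "ivw")
    expect_equal(loo$beta[j], sub$beta, tolerance = 1e-12)
    expect_equal(loo$se[j], sub$se, tolerance = 1e-12)
  }
  # homogeneous instruments: no single SNP moves the estimate much
  hom <- simulate_mr_pair(n_snps = 30, theta = 0.1, seed = 31)
  full <- mr_fit(hom, "ivw")
  loo2 <- leave_one_out(hom)
  expect_lt(max(abs(loo2$beta - full$beta)), 4 * full$se)
})

test_that("per-doubling scaling multiplies estimates by ln 2 and guards scale", {
  est <- structure(list(method = "ivw", beta = 1, se = 0.5, ci_low = -0.1,
                        ci_high = 0.1, pval = 0.04, nsnp = 5,
                        exposure_type = "binary"), class = "mr_result")
  sc <- scale_to_doubling(est)
  expect_equal(sc$beta, log(2))
  expect_equal(sc$ci_low, -0.1 * log(2))
  expect_equal(sc$ci_high, 0.1 * log(2))
  expect_equal(sc$pval, 0.04)  # invariant under scaling
  est$exposure_type <- "continuous"
  expect_error(scale_to_doubling(est), "binary")
})

test_that("SIMEX reduces to plain Egger without measurement error and corrects dilution", {
  pair <- simulate_mr_pair(n_snps = 10, theta = 0.1, seed = 37)
  pair$se_exp <- rep(0, 10)
  sx <- simex_egger(pair, n_sim = 20, seed = 1)
  expect_equal(sx$beta, mr_fit(pair, "egger")$beta, tolerance = 1e-8)

  # attenuated instruments: SIMEX closer to truth than naive Egger most of the time
  n_rep <- 60
  wins <- vapply(seq_len(n_rep), function(r) {
    p <- simulate_mr_pair(n_snps = 50, theta = 0.3, h2 = 0.05,
                          n_exp = 1000, n_out = 1e6,
                          seed = child_seed(43, r))
    naive <- mr_fit(p, "egger")$beta
    corr <- simex_egger(p, n_sim = 100, seed = child_seed(44, r))$beta
    abs(corr - 0.3) < abs(naive - 0.3)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("all estimators are consistent under a strong causal simulation", {
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 4,
                dimnames = list(NULL, c("ivw", "egger", "wmedian", "wmode")))
  for (r in seq_len(n_rep)) {
    pair <- simulate_mr_pair(n_snps = 50, theta = 0.1, seed = child_seed(51, r))
    est[r, 1] <- mr_fit(pair, "ivw")$beta
    est[r, 2] <- mr_fit(pair, "egger")$beta
    est[r, 3] <- mr_fit(pair, "weighted_median", seed = 1, n_boot = 2)$beta
    est[r, 4] <- mr_fit(pair, "weighted_mode", seed = 1, n_boot = 2,
                        n_grid = 2000)$beta
  }
  for (m in colnames(est)) {
    mc_se <- sd(est[, m]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, m]) - 0.1), 3 * mc_se + 1e-3)
  }
})

test_that("weighted median resists pleiotropy that breaks IVW", {
  n_rep <- 100
  dev <- matrix(NA_real_, n_rep, 2, dimnames = list(NULL, c("ivw", "wmedian")))
  for (r in seq_len(n_rep)) {
    pair <- simulate_mr_pair(n_snps = 30, theta = 0.1, seed = child_seed(61, r))
    k <- 12  # 40% of instruments strongly pleiotropic, InSIDE violated
    set.seed(child_seed(62, r))
    idx <- sample(30, k)  # pleiotropy proportional to strength within the subset
    pair$beta_out[idx] <- pair$beta_out[idx] + 0.3 * abs(pair$beta_exp[idx])
    dev[r, 1] <- mr_fit(pair, "ivw")$beta - 0.1
    dev[r, 2] <- mr_fit(pair, "weighted_median", seed = 1, n_boot = 2)$beta - 0.1
  }
  expect_lt(abs(mean(dev[, "wmedian"])), abs(mean(dev[, "ivw"])))
})

test_that("estimator outputs share the harmonization provenance stamp", {
  pair <- simulate_mr_pair(n_snps = 6, theta = 0.1, seed = 71)
  h <- attr(pair, "hash")
  expect_true(is.character(h) && nzchar(h))
  expect_identical(mr_fit(pair, "ivw")$pair_hash, h)
  expect_identical(mr_fit(pair, "egger")$pair_hash, h)
  expect_identical(mr_fit(pair, "weighted_median", seed = 1, n_boot = 5)$pair_hash, h)
  # a different instrument set carries a different stamp
  expect_false(identical(attr(pair_subset(pair, -1), "hash"), h))
})
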