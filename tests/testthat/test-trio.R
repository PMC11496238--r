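test_that("an exact linear outcome is fitted with zero residual", {
  d <- make_trio_data(200, seed = 2)
  d$outcome <- 0.5 * d$pgs_mother  # no noise
  f <- suppressWarnings(fit_maternal_unadjusted(d, "outcome"))  # lm flags the perfect fit
  term <- f$terms[f$terms$term == "pgs_mother", ]
  # outcome is z-standardized before fitting, so the slope is 0.5/sd(outcome)
  expect_equal(term$beta, 0.5 / sd(d$outcome), tolerance = 1e-8)
  expect_lt(term$se, 1e-10)
})

test_that("trio OLS coefficients equal the normal-equations oracle", {
  d <- make_trio_data(300, b_mother = 0.1, b_child = 0.2, seed = 3)
  f <- fit_trio_adjusted(d, "outcome")
  y <- (d$outcome - mean(d$outcome)) / sd(d$outcome)
  X <- stats::model.matrix(~ pgs_mother + pgs_child + pgs_father + child_sex +
                             pc1 + pc2 + pc3 + pc4 + pc5 + pc6 + pc7 + pc8 +
                             pc9 + pc10 + batch, data = as.data.frame(d))
  o <- oracle_ols(y, X)
  got <- f$terms[match(colnames(X), f$terms$term), ]
  expect_equal(got$beta, o$beta, tolerance = 1e-8)
  expect_equal(got$se, o$se, tolerance = 1e-8)
})

test_that("a permuted maternal PGS shows no association", {
  d <- make_trio_data(500, b_mother = 0.3, seed = 4)
  d$pgs_mother <- sample(d$pgs_mother)
  f <- fit_maternal_unadjusted(d, "outcome")
  term <- f$terms[f$terms$term == "pgs_mother", ]
  expect_lt(abs(term$beta), 3 * term$se)
})

test_that("the complete-case floor and constant outcomes are enforced", {
  d <- make_trio_data(40, seed = 5)
  d$outcome[1:15] <- NA
  expect_error(fit_maternal_unadjusted(d, "outcome", min_n = 30), "complete cases")
  d2 <- make_trio_data(50, seed = 6)
  d2$outcome <- 1
  expect_error(fit_maternal_unadjusted(d2, "outcome"), "constant")
})

test_that("swapping parental columns swaps their estimates exactly", {
  d <- make_trio_data(400, b_mother = 0.2, b_father = 0.05, seed = 7)
  f <- fit_trio_adjusted(d, "outcome")
  d_swap <- d
  d_swap$pgs_mother <- d$pgs_father
  d_swap$pgs_father <- d$pgs_mother
  f_swap <- fit_trio_adjusted(d_swap, "outcome")
  get <- function(f, t) f$terms$beta[f$terms$term == t]
  expect_equal(get(f, "pgs_mother"), get(f_swap, "pgs_father"), tolerance = 1e-12)
  expect_equal(get(f, "pgs_father"), get(f_swap, "pgs_mother"), tolerance = 1e-12)
})

test_that("paternal negative control is null under a maternal-only effect", {
  d <- make_trio_data(2000, b_mother = 0.2, seed = 8)
  fits <- fit_paternal_control(d, "outcome")
  for (f in fits) {
    term <- f$terms[f$terms$term == "pgs_father", ]
    expect_lt(abs(term$beta), 3.5 * term$se)
  }
  # a household effect through both parents shows up in the paternal PGS too
  d2 <- make_trio_data(2000, b_mother = 0.15, b_father = 0.15, seed = 9)
  f2 <- fit_paternal_control(d2, "outcome")$unadjusted
  term2 <- f2$terms[f2$terms$term == "pgs_father", ]
  expect_gt(term2$beta, 0.1)
})

test_that("child models attenuate an inherited proxy association", {
  # maternal-only effect: the child PGS associates only via transmission
  d <- make_trio_data(4000, b_mother = 0.3, seed = 10)
  fits <- fit_child_model(d, "outcome")
  un <- fits$unadjusted$terms
  ad <- fits$adjusted$terms
  child_un <- un[un$term == "pgs_child", ]
  child_ad <- ad[ad$term == "pgs_child", ]
  expect_gt(child_un$beta, 3 * child_un$se)       # inherited proxy signal
  expect_lt(abs(child_ad$beta), 3.5 * child_ad$se)  # gone after adjustment
})

test_that("orthogonal covariates do not move the PGS estimates", {
  d <- make_trio_data(500, b_mother = 0.2, seed = 11)
  set.seed(99)
  # pc10 variants exactly orthogonal to every other model column leave the
  # remaining coefficients untouched
  M <- stats::model.matrix(~ pgs_mother + child_sex + pc1 + pc2 + pc3 + pc4 +
                             pc5 + pc6 + pc7 + pc8 + pc9 + batch,
                           data = as.data.frame(d))
  d$pc10 <- qr.resid(qr(M), rnorm(nrow(d)))
  f1 <- fit_maternal_unadjusted(d, "outcome")
  d2 <- d
  d2$pc10 <- qr.resid(qr(M), rnorm(nrow(d)))
  f2 <- fit_maternal_unadjusted(d2, "outcome")
  b1 <- f1$terms$beta[f1$terms$term == "pgs_mother"]
  b2 <- f2$terms$beta[f2$terms$term == "pgs_mother"]
  expect_equal(b1, b2, tolerance = 1e-8)
})

test_that("sex stratification recovers stratum-specific effects", {
  set.seed(12)
  d <- make_trio_data(3000, seed = 12)
  d$outcome <- ifelse(d$child_sex == 1, 0.3 * d$pgs_mother, 0) + rnorm(3000)
  fits <- stratify_by_sex(d, "outcome", "maternal_unadjusted")
  bm <- fits$male$terms[fits$male$terms$term == "pgs_mother", ]
  bf <- fits$female$terms[fits$female$terms$term == "pgs_mother", ]
  expect_gt(bm$beta, 0.2)
  expect_lt(abs(bf$beta), 3.5 * bf$se)
  expect_identical(fits$male$stratum, "male")

  # homogeneous effect: strata agree within joint uncertainty
  d2 <- make_trio_data(3000, b_mother = 0.2, seed = 13)
  f2 <- stratify_by_sex(d2, "outcome", "maternal_unadjusted")
  diff <- f2$male$terms$beta[f2$male$terms$term == "pgs_mother"] -
    f2$female$terms$beta[f2$female$terms$term == "pgs_mother"]
  joint_se <- sqrt(f2$male$terms$se[f2$male$terms$term == "pgs_mother"]^2 +
                   f2$female$terms$se[f2$female$terms$term == "pgs_mother"]^2)
  expect_lt(abs(diff), 3.5 * joint_se)
})

test_that("parental PGS correlation has exact degenerate cases", {
  d <- make_trio_data(500, seed = 14)
  pc <- parental_pgs_correlation(d)
  expect_lt(abs(pc$r), 3 / sqrt(pc$n))
  d$pgs_father <- d$pgs_mother
  expect_equal(parental_pgs_correlation(d)$r, 1)
  d$pgs_father <- -d$pgs_mother
  expect_equal(parental_pgs_correlation(d)$r, -1)
  d$pgs_father <- 0
  expect_error(parental_pgs_correlation(d), "zero variance")
})

test_that("SNP-outcome regressions equal looped single-variant OLS fits", {
  set.seed(15)
  n <- 120; m <- 8
  D <- sapply(runif(m, 0.1, 0.5), function(p) rbinom(n, 2, p))
  g <- genotype_matrix(D, data.frame(variant_id = sprintf("v%d", 1:m),
                                     counted_allele = "A", other_allele = "G"),
                       "mother")
  covs <- data.frame(matrix(rnorm(n * 10), n, 10,
                            dimnames = list(NULL, paste0("pc", 1:10))),
                     batch = sample(c("x", "y"), n, TRUE))
  y <- 0.2 * D[, 3] + rnorm(n)
  tab <- snp_outcome_regression(g, y, covs, standardize_outcome = FALSE)
  for (j in seq_len(m)) {
    fit <- lm(y ~ D[, j] + ., data = covs)
    ct <- summary(fit)$coefficients[2, ]
    expect_equal(tab$beta[j], unname(ct[1]), tolerance = 1e-8)
    expect_equal(tab$se[j], unname(ct[2]), tolerance = 1e-8)
    expect_equal(tab$pval[j], unname(ct[4]), tolerance = 1e-8)
  }
})

test_that("SNP-outcome regressions recover a planted effect and stay calibrated", {
  set.seed(16)
  n <- 2000; m <- 40
  D <- sapply(runif(m, 0.1, 0.5), function(p) rbinom(n, 2, p))
  g <- genotype_matrix(D, data.frame(variant_id = sprintf("v%d", 1:m),
                                     counted_allele = "A", other_allele = "G"),
                       "mother")
  y <- 0.2 * D[, 1] + rnorm(n)
  tab <- snp_outcome_regression(g, y, NULL, standardize_outcome = FALSE)
  expect_lt(abs(tab$beta[1] - 0.2), 3 * tab$se[1])

  # dosage-free outcome: about 5% of variants at p < 0.05
  y0 <- rnorm(n)
  tab0 <- snp_outcome_regression(g, y0, NULL)
  expect_lt(mean(tab0$pval < 0.05), 0.20)

  # monomorphic variants are skipped with a reason
  D2 <- cbind(D[, 1:3], mono = 2)
  g2 <- genotype_matrix(D2, data.frame(variant_id = c("v1", "v2", "v3", "mono"),
                                       counted_allele = "A", other_allele = "G"),
                        "mother")
  tab2 <- snp_outcome_regression(g2, y0, NULL)
  expect_false("mono" %in% tab2$variant_id)
  expect_equal(attr(tab2, "skipped")$reason, "monomorphic")
})

test_that("trio frames round-trip through TSV", {
  d <- make_trio_data(30, seed = 17)
  path <- tempfile(fileext = ".tsv")
  write_trio_frame(d, path)
  back <- read_trio_frame(path)
  expect_s3_class(back, "trio_frame")
  expect_equal(back$pgs_mother, d$pgs_mother, tolerance = 1e-12)
  expect_equal(as.character(back$batch), as.character(d$batch))
})
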