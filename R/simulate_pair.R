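#' Simulate a harmonized two-sample MR instrument set directly
#'
#' Draws a complete exposure-outcome instrument panel on the summary
#' statistic scale, for calibration and power studies of the MR
#' estimators without individual-level simulation. True SNP-exposure
#' effects are scaled to explain `h2` of a unit-variance exposure;
#' estimated effects are sampled as `N(true, se^2)` with
#' `se = 1/(sd(dosage) sqrt(n))`, the standard large-sample marginal-OLS
#' approximation. True SNP-outcome effects are
#' `theta * beta_exposure + alpha_j` with per-SNP pleiotropic effects
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` (InSIDE holds unless
#' `inside = FALSE`, which couples `alpha` to the instrument strengths).
#'
#' @param n_snps number of instruments.
#' @param theta true causal effect of the exposure on the outcome.
#' @param h2 exposure variance explained by the panel.
#' @param n_exp,n_out GWAS sample sizes.
#' @param pleiotropy_mean,pleiotropy_sd directional pleiotropy.
#' @param inside set `FALSE` to violate the InSIDE assumption.
#' @param seed integer seed.
#' @return a `harmonized_pair` (with per-variant `n_exp`/`n_out`).
#' @export
simulate_mr_pair <- function(n_snps = 50, theta = 0, h2 = 0.031,
                             n_exp = 401460, n_out = 23713,
                             pleiotropy_mean = 0, pleiotropy_sd = 0,
                             inside = TRUE, seed) {
  stopifnot(n_snps >= 1, h2 > 0, h2 < 1, n_exp >= 100, n_out >= 100)
  if (missing(seed)) stop("a seed is mandatory")
  with_preserved_seed(seed, {
    maf <- stats::runif(n_snps, 0.05, 0.5)
    # effects oriented positive (the exposure-increasing allele is the
    # effect allele), the convention under which directional pleiotropy
    # has a well-defined sign
    b <- abs(stats::rnorm(n_snps))
    b <- b * sqrt(h2 / sum(2 * maf * (1 - maf) * b^2))
    alpha <- if (inside) {
      stats::rnorm(n_snps, pleiotropy_mean, pleiotropy_sd)
    } else {
      pleiotropy_mean + pleiotropy_sd * abs(b) / stats::sd(b)
    }
    sdg <- sqrt(2 * maf * (1 - maf))
    se_x <- 1 / (sdg * sqrt(n_exp))
    se_y <- 1 / (sdg * sqrt(n_out))
    bx <- stats::rnorm(n_snps, b, se_x)
    by <- stats::rnorm(n_snps, theta * b + alpha, se_y)
    alleles <- t(vapply(seq_len(n_snps), function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    pair <- data.frame(
      variant_id = sprintf("sim%03d", seq_len(n_snps)),
      chrom = as.character(rep_len(1:22, n_snps)),
      pos = 1e6 * seq_len(n_snps),
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      beta_exp = bx, se_exp = se_x, eaf_exp = maf,
      beta_out = by, se_out = se_y, eaf_out = maf,
      n_exp = n_exp, n_out = n_out,
      action = "none", stringsAsFactors = FALSE)
    structure(pair, class = c("harmonized_pair", "data.frame"),
              hash = content_hash(pair$variant_id, pair$beta_exp, pair$se_exp,
                                  pair$beta_out, pair$se_out),
              dropped = data.frame(variant_id = character(0), reason = character(0)),
              exposure_label = "simulated_exposure",
              outcome_label = "simulated_outcome",
              exposure_type = "continuous", outcome_type = "continuous",
              truth = list(theta = theta, b = b, alpha = alpha, maf = maf))
  })
}
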