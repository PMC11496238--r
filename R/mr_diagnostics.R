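#' Cochran's Q heterogeneity statistic
#'
#' Measures heterogeneity of per-variant ratio estimates around a central
#' MR estimate: `Q = sum(w_j (ratio_j - beta)^2)` with inverse-variance
#' weights `w_j = beta_exp_j^2 / se_out_j^2`, referred to a chi-squared
#' distribution with `nsnp - 1` df (IVW centre) or `nsnp - 2` (Egger
#' centre).
#'
#' @param pair a `harmonized_pair` with at least 2 variants.
#' @param center an `mr_result` giving the central estimate (its `method`
#'   decides the df).
#' @return list with `Q`, `df`, `pval`.
#' @export
cochran_q <- function(pair, center) {
  stopifnot(inherits(pair, "harmonized_pair"), nrow(pair) >= 2L,
            inherits(center, "mr_result"))
  ratio <- pair$beta_out / pair$beta_exp
  w <- pair$beta_exp^2 / pair$se_out^2
  Q <- sum(w * (ratio - center$beta)^2)
  df <- nrow(pair) - if (center$method == "egger") 2L else 1L
  list(Q = Q, df = df, pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Instrument strength: per-SNP F statistics and I2GX
#'
#' The F statistic `(beta_exp/se_exp)^2` indexes instrument strength
#' (mean F > 10 is the usual low-weak-instrument-bias heuristic). I2GX
#' quantifies relative measurement error in the SNP-exposure estimates:
#' low values signal regression dilution of the MR-Egger slope and argue
#' for SIMEX correction. It is computed as
#' `max(0, (Q_GX - (nsnp - 1)) / Q_GX)` with
#' `Q_GX = sum((beta_exp_j - bw)^2 / se_exp_j^2)` around the
#' `1/se_exp^2`-weighted mean `bw` of the (magnitude-oriented) exposure
#' betas.
#'
#' @param pair a `harmonized_pair`.
#' @return list with `F` (per-SNP), `mean_F`, `Q_gx`, `i2_gx`.
#' @export
instrument_strength <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  Fj <- (pair$beta_exp / pair$se_exp)^2
  out <- list(F = Fj, mean_F = mean(Fj), Q_gx = NA_real_, i2_gx = NA_real_)
  n <- nrow(pair)
  if (n >= 2L) {
    bx <- abs(pair$beta_exp)  # orientation-free, as in the Egger setting
    wx <- 1 / pair$se_exp^2
    bw <- sum(wx * bx) / sum(wx)
    Qgx <- sum((bx - bw)^2 * wx)
    out$Q_gx <- Qgx
    out$i2_gx <- if (Qgx > 0) max(0, (Qgx - (n - 1)) / Qgx) else 0
  }
  out
}

#' SIMEX-corrected MR-Egger slope
#'
#' Simulation-extrapolation correction for measurement error in the
#' SNP-exposure estimates, applied when I2GX indicates regression
#' dilution. For each `lambda` in `lambda_grid`, `n_sim` seeded replicates
#' add `N(0, lambda * se_exp_j^2)` noise to the exposure betas and refit
#' MR-Egger; the per-lambda mean slopes are fitted with a quadratic in
#' lambda and extrapolated to `lambda = -1` (the no-measurement-error
#' limit). The standard error is a leave-one-SNP-out jackknife of the
#' whole procedure (same seeds).
#'
#' @param pair a `harmonized_pair` with >= 3 variants.
#' @param lambda_grid non-negative noise-inflation multipliers; must
#'   include at least 3 distinct values for the quadratic.
#' @param n_sim replicates per lambda.
#' @param seed integer seed.
#' @return an `mr_result` with method `"egger_simex"`, plus
#'   `lambda_grid` and `lambda_means`.
#' @export
simex_egger <- function(pair, lambda_grid = c(0, 0.5, 1, 1.5, 2),
                        n_sim = 1000, seed) {
  stopifnot(inherits(pair, "harmonized_pair"), nrow(pair) >= 3L,
            all(lambda_grid >= 0))
  if (length(unique(lambda_grid)) < 3L) {
    stop("lambda_grid must contain at least 3 distinct values for quadratic extrapolation")
  }
  n <- nrow(pair)
  s <- ifelse(pair$beta_exp < 0, -1, 1)
  bx <- pair$beta_exp * s
  by <- pair$beta_out * s
  sex <- pair$se_exp
  w <- 1 / pair$se_out^2

  # one noise array per lambda, shared across the jackknife
  noise <- with_preserved_seed(seed, {
    lapply(lambda_grid, function(l) {
      if (l == 0) NULL
      else matrix(stats::rnorm(n * n_sim, 0, sqrt(l) * sex), nrow = n)
    })
  })

  extrapolate <- function(keep) {
    means <- vapply(seq_along(lambda_grid), function(i) {
      if (is.null(noise[[i]])) {
        .wls_slope(bx[keep], by[keep], w[keep])
      } else {
        mean(.wls_slope(bx[keep] + noise[[i]][keep, , drop = FALSE],
                        by[keep], w[keep]))
      }
    }, numeric(1))
    fit <- stats::lm.fit(cbind(1, lambda_grid, lambda_grid^2), means)
    if (fit$rank < 3L) stop("SIMEX extrapolation fit is rank-deficient")
    co <- fit$coefficients
    list(est = co[1] - co[2] + co[3], means = means)
  }

  full <- extrapolate(seq_len(n))
  jack <- vapply(seq_len(n), function(j) extrapolate(setdiff(seq_len(n), j))$est,
                 numeric(1))
  se <- sqrt((n - 1) / n * sum((jack - mean(jack))^2))
  z <- stats::qnorm(0.975)
  structure(list(method = "egger_simex",
                 beta = unname(full$est), se = se,
                 ci_low = unname(full$est) - z * se,
                 ci_high = unname(full$est) + z * se,
                 pval = 2 * stats::pnorm(-abs(full$est / se)),
                 nsnp = n, lambda_grid = lambda_grid,
                 lambda_means = full$means, seed = seed,
                 pair_hash = attr(pair, "hash"),
                 exposure = attr(pair, "exposure_label"),
                 outcome = attr(pair, "outcome_label"),
                 exposure_type = attr(pair, "exposure_type") %||% "continuous"),
            class = "mr_result")
}

#' Steiger filtering for directionality
#'
#' Guards against reverse causation by asking, per variant, whether the
#' SNP explains more variance in the exposure than in the outcome. The
#' variance explained is computed from the t statistic,
#' `r2 = t^2 / (t^2 + n - 2)` with `t = beta/se`, on each side; a variant
#' is kept iff `r2_exposure > r2_outcome` (strict). The same formula is
#' applied to binary traits on the observed scale (a documented
#' approximation).
#'
#' @param pair a `harmonized_pair`.
#' @param n_exp,n_out sample sizes; per-variant `n_exp`/`n_out` columns in
#'   the pair take precedence. Missing sizes are an error.
#' @return list with `table` (per-variant r2 and keep flag), `n_kept`,
#'   `n_removed`, `direction_ok` (majority kept), and `pair_kept` (the
#'   filtered `harmonized_pair`).
#' @export
steiger_filter <- function(pair, n_exp = NULL, n_out = NULL) {
  stopifnot(inherits(pair, "harmonized_pair"))
  ne <- if (!all(is.na(pair$n_exp))) pair$n_exp else rep(n_exp %||% NA_real_, nrow(pair))
  no <- if (!all(is.na(pair$n_out))) pair$n_out else rep(n_out %||% NA_real_, nrow(pair))
  if (any(is.na(ne))) stop("exposure sample size missing: supply n_exp for trait '",
                           attr(pair, "exposure_label"), "'")
  if (any(is.na(no))) stop("outcome sample size missing: supply n_out for trait '",
                           attr(pair, "outcome_label"), "'")
  r2_from_t <- function(beta, se, n) {
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  }
  r2x <- r2_from_t(pair$beta_exp, pair$se_exp, ne)
  r2y <- r2_from_t(pair$beta_out, pair$se_out, no)
  keep <- r2x > r2y
  tab <- data.frame(variant_id = pair$variant_id, r2_exposure = r2x,
                    r2_outcome = r2y, keep = keep, stringsAsFactors = FALSE)
  list(table = tab,
       n_kept = sum(keep), n_removed = sum(!keep),
       direction_ok = sum(keep) > sum(!keep),
       pair_kept = pair_subset(pair, keep))
}

#' Leave-one-out IVW analysis
#'
#' Refits the IVW estimator `nsnp` times, each time excluding one variant,
#' to flag variants whose removal moves the estimate (potential outliers
#' or pleiotropic instruments).
#'
#' @param pair a `harmonized_pair` with >= 3 variants.
#' @param ... forwarded to [mr_fit()] (e.g. `model`).
#' @return data frame with one row per excluded variant: `excluded`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, `nsnp`.
#' @export
leave_one_out <- function(pair, ...) {
  stopifnot(inherits(pair, "harmonized_pair"), nrow(pair) >= 3L)
  do.call(rbind, lapply(seq_len(nrow(pair)), function(j) {
    fit <- mr_fit(pair_subset(pair, -j), method = "ivw", ...)
    data.frame(excluded = pair$variant_id[j], beta = fit$beta, se = fit$se,
               ci_low = fit$ci_low, ci_high = fit$ci_high, pval = fit$pval,
               nsnp = fit$nsnp, stringsAsFactors = FALSE)
  }))
}

#' Rescale a binary-exposure MR estimate to a per-doubling interpretation
#'
#' Estimates with a binary exposure on the log-odds scale are multiplied
#' by `ln 2` (about 0.693) so they read as the average change in the
#' outcome per doubling (2-fold increase) in the odds of liability to the
#' exposure. The p-value is unchanged.
#'
#' @param estimate an `mr_result` whose exposure is binary (log-odds scale).
#' @return the rescaled `mr_result`, method label suffixed
#'   `"_per_doubling"`.
#' @export
scale_to_doubling <- function(estimate) {
  stopifnot(inherits(estimate, "mr_result"))
  if (!identical(estimate$exposure_type, "binary")) {
    stop("per-doubling scaling applies only to binary (log-odds) exposures")
  }
  k <- log(2)
  for (f in c("beta", "se", "ci_low", "ci_high")) estimate[[f]] <- estimate[[f]] * k
  estimate$method <- paste0(estimate$method, "_per_doubling")
  estimate
}
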