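#' Fit a two-sample Mendelian randomization model
#'
#' The single fitting entry point for all two-sample MR estimators:
#' inverse-variance weighted (the primary method), MR-Egger, weighted
#' median, weighted mode, and the single-variant Wald ratio. All methods
#' consume a [harmonize()]d exposure-outcome pair and return an
#' `mr_result` with `print`, `summary`, `coef` and `confint` methods.
#'
#' Estimator details:
#'
#' * **wald**: `beta_out / beta_exp`, first-order delta-method standard
#'   error `se_out / |beta_exp|` by default (`se_type = "second"` adds the
#'   exposure-uncertainty term).
#' * **ivw**: inverse-variance weighted mean of Wald ratios with weights
#'   `beta_exp^2 / se_out^2`, equivalent to weighted regression of
#'   `beta_out` on `beta_exp` through the origin with weights `1/se_out^2`.
#'   `model = "mre"` (default) multiplies the fixed-effect standard error
#'   by `max(1, sqrt(Q/(nsnp-1)))` (multiplicative random effects);
#'   `model = "fixed"` does not.
#' * **egger**: each variant is oriented so `beta_exp >= 0`, then weighted
#'   least squares of `beta_out` on `beta_exp` with a free intercept and
#'   weights `1/se_out^2`; classical WLS standard errors (scaled by the
#'   root weighted residual mean square) with t(nsnp-2) inference. The
#'   intercept estimates directional horizontal pleiotropy.
#' * **weighted_median**: the 50% point of the inverse-variance-weighted
#'   empirical distribution of ratio estimates (linear interpolation of
#'   standardized cumulative weights); standard error by seeded parametric
#'   bootstrap.
#' * **weighted_mode**: argmax of a weighted Gaussian-kernel density of the
#'   ratio estimates with bandwidth `phi` times a MAD-based default;
#'   standard error by seeded parametric bootstrap.
#'
#' Confidence intervals use normal quantiles except MR-Egger (t with
#' nsnp - 2 df).
#'
#' @param pair a `harmonized_pair`.
#' @param method one of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"`, `"wald"`.
#' @param model IVW error model, `"mre"` (multiplicative random effects,
#'   default) or `"fixed"`.
#' @param se_type Wald-ratio delta-method order, `"first"` (default) or
#'   `"second"`.
#' @param n_boot bootstrap replicates for median/mode standard errors.
#' @param seed integer seed for the bootstrap (required by the
#'   median/mode methods).
#' @param phi bandwidth multiplier for the weighted mode.
#' @param n_grid grid size for the mode density search.
#' @param conf_level confidence level (default 0.95).
#' @return An `mr_result` list with elements `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `nsnp`, `Q`, `Q_df`, `Q_pval` (IVW/Egger),
#'   `intercept`, `intercept_se`, `intercept_pval` (Egger), and provenance
#'   (`exposure`, `outcome`, `exposure_type`).
#' @export
mr_fit <- function(pair,
                   method = c("ivw", "egger", "weighted_median", "weighted_mode", "wald"),
                   model = c("mre", "fixed"),
                   se_type = c("first", "second"),
                   n_boot = 1000, seed = NULL, phi = 1, n_grid = 10000,
                   conf_level = 0.95) {
  method <- match.arg(method)
  model <- match.arg(model)
  se_type <- match.arg(se_type)
  stopifnot(inherits(pair, "harmonized_pair"))
  res <- switch(method,
    wald = .mr_wald(pair, se_type, conf_level),
    ivw = .mr_ivw(pair, model, conf_level),
    egger = .mr_egger(pair, conf_level),
    weighted_median = .mr_wmedian(pair, n_boot, seed, conf_level),
    weighted_mode = .mr_wmode(pair, phi, n_grid, n_boot, seed, conf_level)
  )
  res$exposure <- attr(pair, "exposure_label")
  res$outcome <- attr(pair, "outcome_label")
  res$exposure_type <- attr(pair, "exposure_type") %||% "continuous"
  # provenance stamp: estimators compared in a report must share it
  res$pair_hash <- attr(pair, "hash")
  class(res) <- "mr_result"
  res
}

.ratio_se <- function(pair, se_type = "first") {
  if (any(pair$beta_exp == 0)) stop("Wald ratio undefined: beta_exp = 0")
  se1 <- pair$se_out / abs(pair$beta_exp)
  if (se_type == "second") {
    sqrt(se1^2 + pair$beta_out^2 * pair$se_exp^2 / pair$beta_exp^4)
  } else se1
}

.ci_p_normal <- function(beta, se, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(ci_low = beta - z * se, ci_high = beta + z * se,
       pval = 2 * stats::pnorm(-abs(beta / se)))
}

.mr_wald <- function(pair, se_type, conf_level) {
  if (nrow(pair) != 1L) stop("wald ratio expects a single-variant pair")
  beta <- pair$beta_out / pair$beta_exp
  se <- .ratio_se(pair, se_type)
  c(list(method = "wald", beta = beta, se = se), .ci_p_normal(beta, se, conf_level),
    list(nsnp = 1L))
}

.mr_ivw <- function(pair, model, conf_level) {
  n <- nrow(pair)
  if (n < 1L) stop("empty pair")
  if (n == 1L) {
    warning("single instrument: IVW reduces to the Wald ratio")
    out <- .mr_wald(pair, "first", conf_level)
    out$method <- "ivw"
    return(out)
  }
  ratio <- pair$beta_out / pair$beta_exp
  w <- pair$beta_exp^2 / pair$se_out^2
  beta <- sum(w * ratio) / sum(w)
  Q <- sum(w * (ratio - beta)^2)
  se_fixed <- sqrt(1 / sum(w))
  infl <- if (model == "mre") max(1, sqrt(Q / (n - 1))) else 1
  se <- se_fixed * infl
  c(list(method = "ivw", beta = beta, se = se),
    .ci_p_normal(beta, se, conf_level),
    list(nsnp = n, model = model, Q = Q, Q_df = n - 1,
         Q_pval = stats::pchisq(Q, n - 1, lower.tail = FALSE)))
}

# closed-form weighted regression with intercept; bx may be a matrix with
# one simulation per column (used by SIMEX)
.wls_slope <- function(bx, by, w) {
  if (is.matrix(bx)) {
    sw <- sum(w)
    swy <- sum(w * by)
    swx <- colSums(w * bx)
    swxy <- colSums(w * bx * by)
    swx2 <- colSums(w * bx * bx)
    (sw * swxy - swx * swy) / (sw * swx2 - swx^2)
  } else {
    .wls_slope(matrix(bx, ncol = 1L), by, w)
  }
}

.mr_egger <- function(pair, conf_level) {
  n <- nrow(pair)
  if (n < 3L) stop("MR-Egger requires at least 3 instruments")
  s <- ifelse(pair$beta_exp < 0, -1, 1)
  bx <- pair$beta_exp * s
  by <- pair$beta_out * s
  w <- 1 / pair$se_out^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coefs <- solve(XtWX, crossprod(X, w * by))
  fitted <- X %*% coefs
  rss_w <- sum(w * (by - fitted)^2)
  sigma <- sqrt(rss_w / (n - 2))
  se <- unname(sqrt(diag(solve(XtWX)))) * sigma  # classical WLS scaling, t inference
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  est <- as.numeric(coefs)
  pvals <- unname(2 * stats::pt(-abs(est / se), df = n - 2))
  list(method = "egger",
       beta = est[2], se = se[2],
       ci_low = est[2] - tq * se[2], ci_high = est[2] + tq * se[2],
       pval = pvals[2],
       intercept = est[1], intercept_se = se[1],
       intercept_ci_low = est[1] - tq * se[1],
       intercept_ci_high = est[1] + tq * se[1],
       intercept_pval = pvals[1],
       nsnp = n, Q = rss_w, Q_df = n - 2,
       Q_pval = stats::pchisq(rss_w, n - 2, lower.tail = FALSE))
}

.wmedian_point <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]
  ww <- w[ord]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

.mr_wmedian <- function(pair, n_boot, seed, conf_level) {
  n <- nrow(pair)
  if (n < 3L) stop("weighted median requires at least 3 instruments")
  if (is.null(seed)) stop("weighted_median needs an explicit seed for its bootstrap")
  ratio <- pair$beta_out / pair$beta_exp
  w <- 1 / .ratio_se(pair)^2
  beta <- .wmedian_point(ratio, w)
  boot <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, pair$beta_exp, pair$se_exp)
      by <- stats::rnorm(n, pair$beta_out, pair$se_out)
      bad <- bx == 0
      if (any(bad)) bx[bad] <- pair$beta_exp[bad]
      .wmedian_point(by / bx, (bx / pair$se_out)^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  c(list(method = "weighted_median", beta = beta, se = se),
    .ci_p_normal(beta, se, conf_level),
    list(nsnp = n, n_boot = n_boot, seed = seed))
}

.wmode_point <- function(ratio, w, phi, n_grid) {
  if (length(unique(ratio)) == 1L) return(ratio[1])
  h0 <- stats::mad(ratio, constant = 1.4826)
  if (h0 == 0) h0 <- stats::sd(ratio)
  if (h0 == 0) return(ratio[1])
  h <- phi * h0
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  dens <- colSums(w * stats::dnorm(outer(ratio, grid, "-") / h)) / h
  grid[which.max(dens)]
}

.mr_wmode <- function(pair, phi, n_grid, n_boot, seed, conf_level) {
  n <- nrow(pair)
  if (n < 3L) stop("weighted mode requires at least 3 instruments")
  if (is.null(seed)) stop("weighted_mode needs an explicit seed for its bootstrap")
  ratio <- pair$beta_out / pair$beta_exp
  w <- 1 / .ratio_se(pair)^2
  beta <- .wmode_point(ratio, w, phi, n_grid)
  boot <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, pair$beta_exp, pair$se_exp)
      by <- stats::rnorm(n, pair$beta_out, pair$se_out)
      bad <- bx == 0
      if (any(bad)) bx[bad] <- pair$beta_exp[bad]
      .wmode_point(by / bx, (bx / pair$se_out)^2, phi, 512L)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  c(list(method = "weighted_mode", beta = beta, se = se),
    .ci_p_normal(beta, se, conf_level),
    list(nsnp = n, phi = phi, n_boot = n_boot, seed = seed))
}

#' Run several MR methods on one harmonized pair
#'
#' @param pair a `harmonized_pair`.
#' @param methods character vector of [mr_fit()] methods.
#' @param seed seed for bootstrap-based methods.
#' @param ... forwarded to [mr_fit()].
#' @return A list of `mr_result`s, named by method.
#' @export
mr_all <- function(pair, methods = c("ivw", "egger", "weighted_median", "weighted_mode"),
                   seed = NULL, ...) {
  if (nrow(pair) < 3L) {
    methods <- intersect(methods, c("ivw", "wald"))
    if (length(methods) == 0L) methods <- "ivw"
  }
  out <- lapply(methods, function(m) mr_fit(pair, method = m, seed = seed, ...))
  names(out) <- methods
  out
}

#' Tidy one or several MR results into a data frame
#' @param x an `mr_result` or a list of them.
#' @return data frame with one row per method.
#' @export
mr_tidy <- function(x) {
  if (inherits(x, "mr_result")) x <- list(x)
  do.call(rbind, lapply(x, function(r) {
    data.frame(exposure = r$exposure %||% NA_character_,
               outcome = r$outcome %||% NA_character_,
               method = r$method, beta = r$beta, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high, pval = r$pval,
               nsnp = r$nsnp,
               Q = r$Q %||% NA_real_, Q_pval = r$Q_pval %||% NA_real_,
               egger_intercept = r$intercept %||% NA_real_,
               egger_intercept_pval = r$intercept_pval %||% NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat("Two-sample MR (", x$method, "): ",
      x$exposure %||% "exposure", " -> ", x$outcome %||% "outcome", "\n", sep = "")
  cat(sprintf("  beta = %.*g (se %.*g), 95%% CI [%.*g, %.*g], p = %.3g, nsnp = %d\n",
              digits, x$beta, digits, x$se, digits, x$ci_low, digits, x$ci_high,
              x$pval, x$nsnp))
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept = %.*g (se %.*g), p = %.3g\n",
                digits, x$intercept, digits, x$intercept_se, x$intercept_pval))
  }
  if (!is.null(x$Q)) {
    cat(sprintf("  Cochran's Q = %.*g on %d df (p = %.3g)\n",
                digits, x$Q, x$Q_df, x$Q_pval))
  }
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  out <- c(beta = object$beta)
  if (!is.null(object$intercept)) out <- c(out, intercept = object$intercept)
  out
}

#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("beta", c("low", "high")))
  if (!is.null(object$intercept)) {
    m <- rbind(m, intercept = c(object$intercept_ci_low, object$intercept_ci_high))
  }
  m
}

#' @export
summary.mr_result <- function(object, ...) {
  print(object, ...)
  invisible(mr_tidy(object))
}
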