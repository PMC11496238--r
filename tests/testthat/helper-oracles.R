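# Independent brute-force oracles and fixture builders. These deliberately
# re-derive each statistic from its definition (lm fits, explicit sums,
# exhaustive walks) rather than reusing package internals.

make_pair <- function(bx, by, sex = rep(0.01, length(bx)),
                      sey = rep(0.01, length(bx)),
                      n_exp = NA_real_, n_out = NA_real_,
                      exposure_type = "continuous") {
  m <- length(bx)
  pair <- data.frame(
    variant_id = sprintf("rs%03d", seq_len(m)),
    chrom = "1", pos = 1e6 * seq_len(m),
    effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = sex, eaf_exp = 0.3,
    beta_out = by, se_out = sey, eaf_out = 0.3,
    n_exp = n_exp, n_out = n_out, action = "none",
    stringsAsFactors = FALSE)
  structure(pair, class = c("harmonized_pair", "data.frame"),
            dropped = data.frame(variant_id = character(0), reason = character(0)),
            exposure_label = "exp", outcome_label = "out",
            exposure_type = exposure_type, outcome_type = "continuous")
}

make_table <- function(pval, chrom = "1", pos = seq_along(pval) * 1e5,
                       beta = 0.1, se = 0.01, eaf = 0.3,
                       effect_allele = "A", other_allele = "G",
                       variant_id = sprintf("rs%03d", seq_along(pval)),
                       label = "trait", type = "continuous") {
  sumstat_table(data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
                           effect_allele = effect_allele,
                           other_allele = other_allele,
                           eaf = eaf, beta = beta, se = se, pval = pval,
                           stringsAsFactors = FALSE),
                trait_label = label, trait_type = type)
}

# inverse-variance weighted mean via weighted no-intercept regression
oracle_ivw <- function(bx, by, sey) {
  fit <- stats::lm(by ~ 0 + bx, weights = 1 / sey^2)
  beta <- unname(coef(fit)[1])
  w <- bx^2 / sey^2
  Q <- sum(w * (by / bx - beta)^2)
  list(beta = beta, se_fixed = sqrt(1 / sum(w)), Q = Q)
}

oracle_egger <- function(bx, by, sey) {
  s <- ifelse(bx < 0, -1, 1)
  fit <- stats::lm(I(by * s) ~ I(bx * s), weights = 1 / sey^2)
  ct <- summary(fit)$coefficients
  list(intercept = ct[1, 1], slope = ct[2, 1],
       intercept_se = ct[1, 2], slope_se = ct[2, 2],
       slope_p = ct[2, 4], intercept_p = ct[1, 4])
}

# cumulative-weight walk for the weighted median
oracle_wmedian <- function(ratio, w) {
  ord <- order(ratio)
  r <- ratio[ord]; ww <- w[ord]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= s[1]) return(r[1])
  for (j in 2:length(r)) {
    if (s[j] >= 0.5) {
      return(r[j - 1] + (r[j] - r[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1]))
    }
  }
  r[length(r)]
}

# dense-grid weighted kernel density argmax, looped from first principles
oracle_wmode <- function(ratio, w, phi = 1, n_grid = 10000) {
  h0 <- stats::mad(ratio, constant = 1.4826)
  if (h0 == 0) h0 <- stats::sd(ratio)
  h <- phi * h0
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm((x - ratio) / h)) / h,
                 numeric(1))
  grid[which.max(dens)]
}

# greedy clumping re-implemented as an explicit exhaustive loop
oracle_clump_ids <- function(tab, r2mat, r2_threshold, window_kb) {
  df <- as.data.frame(tab)
  df <- df[order(df$pval, df$chrom, df$pos, df$variant_id), ]
  kept <- character(0)
  discarded <- character(0)
  while (nrow(df) > 0) {
    idx <- df[1, ]
    kept <- c(kept, idx$variant_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) > 0) {
      near <- df$chrom == idx$chrom & abs(df$pos - idx$pos) <= window_kb * 1000
      hit <- near & r2mat[idx$variant_id, df$variant_id] >= r2_threshold
      discarded <- c(discarded, df$variant_id[hit])
      df <- df[!hit, , drop = FALSE]
    }
  }
  kept
}

# normal-equations solve for OLS terms
oracle_ols <- function(y, X) {
  beta <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  list(beta = as.numeric(beta), se = as.numeric(se), df = df)
}

# small synthetic trio frame with configurable direct effects
make_trio_data <- function(n, b_mother = 0, b_father = 0, b_child = 0,
                           noise = 1, seed = 1) {
  set.seed(seed)
  pm <- rnorm(n); pf <- rnorm(n)
  pc <- (pm + pf) / 2 + rnorm(n, 0, sqrt(0.5))
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("pc", 1:10)))
  df <- data.frame(family_id = seq_len(n),
                   outcome = b_mother * pm + b_father * pf + b_child * pc +
                     rnorm(n, 0, noise),
                   pgs_mother = pm, pgs_father = pf, pgs_child = pc,
                   child_sex = rbinom(n, 1, 0.5), pcs,
                   batch = sample(c("b1", "b2", "b3"), n, TRUE),
                   stringsAsFactors = FALSE)
  trio_frame(df)
}
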