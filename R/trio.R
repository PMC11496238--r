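#' Assemble a trio analysis frame
#'
#' One row per family: child outcome score(s), standardized maternal /
#' paternal / child polygenic scores, and the regression covariates
#' (child sex, the first 10 principal components, genotype batch).
#'
#' @param data data frame with columns `family_id`, `pgs_mother`,
#'   `pgs_father`, `pgs_child`, `child_sex`, `pc1`..`pc10`, `batch`, plus
#'   one or more outcome columns.
#' @return A `trio_frame` data frame.
#' @export
trio_frame <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("family_id", "pgs_mother", "pgs_father", "pgs_child",
                "child_sex", paste0("pc", 1:10), "batch")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("trio frame lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(data$family_id)) stop("duplicated family_id")
  data$batch <- factor(data$batch)
  structure(data, class = c("trio_frame", "data.frame"))
}

#' Read / write a trio frame as tab-separated text
#'
#' The TSV dialect carries the documented column names (`family_id`,
#' outcome column(s), `pgs_mother`, `pgs_father`, `pgs_child`,
#' `child_sex`, `pc1`..`pc10`, `batch`).
#'
#' @param path TSV path.
#' @return [read_trio_frame()] returns a `trio_frame`;
#'   `write_trio_frame()` returns `path` invisibly.
#' @export
read_trio_frame <- function(path) {
  trio_frame(utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' @rdname read_trio_frame
#' @param data a `trio_frame`.
#' @export
write_trio_frame <- function(data, path) {
  stopifnot(inherits(data, "trio_frame"))
  utils::write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.trio_covariates <- function(include_sex = TRUE) {
  c(if (include_sex) "child_sex", paste0("pc", 1:10), "batch")
}

# Shared OLS engine for the trio models. Continuous outcomes are
# z-standardized before fitting so that effects are reported per SD of
# the outcome. Batch enters as a factor with first-level reference;
# redundant levels are handled by lm's pivoting, and complete cases only
# are used.
.trio_ols <- function(data, outcome, predictors, covariates, model_label,
                      stratum = "all", min_n = 30, standardize_outcome = TRUE) {
  stopifnot(inherits(data, "trio_frame"), outcome %in% names(data))
  cols <- c(outcome, predictors, covariates)
  d <- as.data.frame(data)[, cols, drop = FALSE]
  cc <- stats::complete.cases(d)
  d <- d[cc, , drop = FALSE]
  n <- nrow(d)
  if (n < min_n) {
    stop("only ", n, " complete cases for model '", model_label,
         "' (floor ", min_n, ")")
  }
  y <- d[[outcome]]
  if (standardize_outcome) {
    if (stats::sd(y) == 0) stop("outcome '", outcome, "' is constant")
    y <- (y - mean(y)) / stats::sd(y)
  }
  d$.y <- y
  d$batch <- droplevels(factor(d$batch))
  if ("batch" %in% covariates && nlevels(d$batch) < 2L) {
    covariates <- setdiff(covariates, "batch")  # constant batch is collinear with the intercept
  }
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  ct <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  terms_df <- data.frame(term = rownames(ct), beta = ct[, 1], se = ct[, 2],
                         ci_low = ct[, 1] - z * ct[, 2],
                         ci_high = ct[, 1] + z * ct[, 2],
                         pval = ct[, 4], row.names = NULL,
                         stringsAsFactors = FALSE)
  structure(list(model = model_label, stratum = stratum, terms = terms_df,
                 n = n, n_dropped = sum(!cc), outcome = outcome, lm = fit),
            class = "trio_fit")
}

#' @export
print.trio_fit <- function(x, digits = 4, ...) {
  cat("Trio model '", x$model, "' (", x$stratum, "), outcome ", x$outcome,
      ", n = ", x$n, "\n", sep = "")
  show <- x$terms[grepl("^pgs_", x$terms$term) | x$terms$term == "(Intercept)", ]
  print(format(show, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
coef.trio_fit <- function(object, ...) {
  stats::setNames(object$terms$beta, object$terms$term)
}

#' Extract the PGS rows of a trio fit (or list of fits) as a tidy table
#' @param x a `trio_fit` or list of them.
#' @return data frame in forest-table layout: `model`, `stratum`, `term`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, `n`.
#' @export
trio_tidy <- function(x) {
  if (inherits(x, "trio_fit")) x <- list(x)
  do.call(rbind, lapply(x, function(f) {
    rows <- f$terms[grepl("^pgs_", f$terms$term), , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    data.frame(model = f$model, stratum = f$stratum, outcome = f$outcome,
               rows, n = f$n, row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Maternal PGS association, unadjusted for family genotype
#'
#' OLS of the child outcome on the maternal PGS plus covariates (child
#' sex, 10 PCs, genotype batch). Without adjustment for child and
#' paternal genotype this association mixes a maternal causal path with
#' transmission-induced genetic confounding.
#'
#' @param data a `trio_frame`.
#' @param outcome outcome column name.
#' @param min_n complete-case floor (default 30).
#' @return A `trio_fit`.
#' @export
fit_maternal_unadjusted <- function(data, outcome, min_n = 30) {
  .trio_ols(data, outcome, "pgs_mother", .trio_covariates(),
            "maternal_unadjusted", min_n = min_n)
}

#' Trio-adjusted maternal PGS association
#'
#' OLS of the child outcome on maternal, child and paternal PGS plus
#' covariates. Adjusting for the child PGS alone would open a back-door
#' path through the paternal genotype (collider bias), so the paternal
#' PGS is always included. The maternal term isolates maternal-specific
#' (e.g. intrauterine) paths from transmitted genetic predisposition.
#'
#' @inheritParams fit_maternal_unadjusted
#' @return A `trio_fit` reporting all three PGS terms.
#' @export
fit_trio_adjusted <- function(data, outcome, min_n = 30) {
  r <- stats::cor(data$pgs_mother, data$pgs_child, use = "complete.obs")
  if (is.finite(r) && abs(r) > 0.9) {
    warning("maternal and child PGS are nearly collinear (r = ", round(r, 3), ")")
  }
  .trio_ols(data, outcome, c("pgs_mother", "pgs_child", "pgs_father"),
            .trio_covariates(), "trio_adjusted", min_n = min_n)
}

#' Paternal negative-control models
#'
#' If causal effects are maternal-specific (intrauterine), the paternal
#' PGS should show no association with the child outcome. Fits the
#' paternal PGS alone plus covariates, and then with maternal and child
#' PGS added.
#'
#' @inheritParams fit_maternal_unadjusted
#' @return list of two `trio_fit`s: `unadjusted`, `adjusted`.
#' @export
fit_paternal_control <- function(data, outcome, min_n = 30) {
  list(
    unadjusted = .trio_ols(data, outcome, "pgs_father", .trio_covariates(),
                           "paternal_control", min_n = min_n),
    adjusted = .trio_ols(data, outcome, c("pgs_father", "pgs_mother", "pgs_child"),
                         .trio_covariates(), "paternal_control_adjusted",
                         min_n = min_n)
  )
}

#' Child PGS models
#'
#' Association of the child's own PGS with the outcome, first alone
#' (plus covariates), then additionally adjusted for both parental PGS.
#'
#' @inheritParams fit_maternal_unadjusted
#' @return list of two `trio_fit`s: `unadjusted`, `adjusted`.
#' @export
fit_child_model <- function(data, outcome, min_n = 30) {
  list(
    unadjusted = .trio_ols(data, outcome, "pgs_child", .trio_covariates(),
                           "child_model", min_n = min_n),
    adjusted = .trio_ols(data, outcome, c("pgs_child", "pgs_mother", "pgs_father"),
                         .trio_covariates(), "child_model_adjusted", min_n = min_n)
  )
}

#' Sex-stratified trio models
#'
#' Fits the requested model separately in male and female children
#' (`child_sex` is dropped from the covariates within strata).
#'
#' @param data a `trio_frame`; `child_sex` coded 0/1 (0 = female,
#'   1 = male by the simulator's convention).
#' @param outcome outcome column name.
#' @param model which model to stratify: `"maternal_unadjusted"` or
#'   `"trio_adjusted"`.
#' @param min_n per-stratum complete-case floor.
#' @return named list of `trio_fit`s (`female`, `male`).
#' @export
stratify_by_sex <- function(data, outcome,
                            model = c("maternal_unadjusted", "trio_adjusted"),
                            min_n = 30) {
  model <- match.arg(model)
  predictors <- switch(model,
                       maternal_unadjusted = "pgs_mother",
                       trio_adjusted = c("pgs_mother", "pgs_child", "pgs_father"))
  out <- lapply(c(female = 0, male = 1), function(s) {
    d <- data[data$child_sex == s, , drop = FALSE]
    if (nrow(d) == 0L) stop("empty child_sex stratum: ", s)
    class(d) <- class(data)
    .trio_ols(d, outcome, predictors, .trio_covariates(include_sex = FALSE),
              model, stratum = ifelse(s == 0, "female", "male"), min_n = min_n)
  })
  out
}

#' Parental PGS correlation (assortative-mating check)
#'
#' Pearson correlation between maternal and paternal PGS with a Fisher-z
#' 95% confidence interval. Under random mating this is near zero; a
#' clear positive correlation flags assortative mating, which biases
#' family-based adjustment.
#'
#' @param data a `trio_frame` with >= 3 couples.
#' @return list with `r`, `ci_low`, `ci_high`, `pval`, `n`.
#' @export
parental_pgs_correlation <- function(data) {
  stopifnot(inherits(data, "trio_frame"))
  cc <- stats::complete.cases(data$pgs_mother, data$pgs_father)
  x <- data$pgs_mother[cc]; y <- data$pgs_father[cc]
  if (length(x) < 3L) stop("need at least 3 couples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in parental PGS")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
       pval = ct$p.value, n = length(x))
}

#' Per-variant SNP-outcome regressions
#'
#' One OLS per variant of the outcome on the variant's dosage plus
#' covariates (10 PCs and genotype batch by convention), emitting a
#' summary-statistic table whose effect allele is the counted allele —
#' the individual-level analogue of an outcome GWAS, consumable by
#' [harmonize()]. Implemented by Frisch-Waugh-Lovell residualization
#' (outcome and dosages residualized on the covariates once), which is
#' numerically identical to the full per-variant OLS.
#'
#' Monomorphic variants yield NA effect rows and are dropped from the
#' returned table with a recorded reason.
#'
#' @param genotypes a `genotype_matrix`.
#' @param outcome numeric vector, one value per individual (same order as
#'   the dosage rows).
#' @param covariates data frame of covariates (numeric columns and/or
#'   factors), same order; an intercept is always included.
#' @param trait_label label for the resulting table.
#' @param standardize_outcome z-standardize the outcome first (default
#'   TRUE, matching the per-SD reporting scale).
#' @return A `sumstat_table` with per-variant `beta`, `se`, `pval`, `n`,
#'   `eaf` and attribute `skipped` (data frame of variant_id/reason).
#' @export
snp_outcome_regression <- function(genotypes, outcome, covariates = NULL,
                                   trait_label = "outcome",
                                   standardize_outcome = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            is.numeric(outcome), length(outcome) == nrow(genotypes$dosages))
  D <- genotypes$dosages
  keep <- stats::complete.cases(outcome) &
    (if (is.null(covariates)) TRUE else stats::complete.cases(covariates))
  D <- D[keep, , drop = FALSE]
  y <- outcome[keep]
  n <- length(y)
  if (standardize_outcome) y <- (y - mean(y)) / stats::sd(y)
  if (is.null(covariates)) {
    C <- matrix(1, n, 1)
  } else {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates)[keep, , drop = FALSE])
  }
  qrC <- qr(C)
  p <- qrC$rank
  ry <- qr.resid(qrC, y)
  mono <- apply(D, 2L, function(g) {
    v <- stats::var(g, na.rm = TRUE)
    is.na(v) || v == 0
  })
  # mean-impute sporadic missing dosages so residualization stays aligned
  if (anyNA(D)) {
    for (k in which(colSums(is.na(D)) > 0)) {
      D[is.na(D[, k]), k] <- mean(D[, k], na.rm = TRUE)
    }
  }
  RG <- qr.resid(qrC, D)
  sg2 <- colSums(RG^2)
  beta <- as.numeric(crossprod(RG, ry)) / sg2
  rss <- sum(ry^2) - beta^2 * sg2
  df <- n - p - 1L
  se <- sqrt(pmax(rss, 0) / df / sg2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  v <- genotypes$variants
  tab <- data.frame(variant_id = v$variant_id,
                    chrom = if ("chrom" %in% names(v)) v$chrom else NA_character_,
                    pos = if ("pos" %in% names(v)) v$pos else NA_real_,
                    effect_allele = v$counted_allele,
                    other_allele = v$other_allele,
                    eaf = colMeans(D) / 2,
                    beta = beta, se = se, pval = pval, n = n,
                    stringsAsFactors = FALSE)
  skipped <- data.frame(variant_id = v$variant_id[mono],
                        reason = rep("monomorphic", sum(mono)),
                        stringsAsFactors = FALSE)
  tab <- tab[!mono, , drop = FALSE]
  out <- sumstat_table(tab, trait_label = trait_label, trait_type = "continuous")
  attr(out, "skipped") <- skipped
  out
}
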