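#' Configure the synthetic trio-cohort generative model
#'
#' The generator emulates the two input classes of a trio-MR study:
#' individual-level mother-father-child genotype and phenotype data, and
#' two-sample GWAS summary statistics for a nutrient exposure and (when
#' reverse causation is simulated) a binary liability trait.
#'
#' The generative model, per family: unlinked SNP dosages for parents
#' under Hardy-Weinberg at MAFs drawn from `maf_range` (couples optionally
#' rank-matched on their instrument score to induce assortative mating);
#' child dosages by Mendelian transmission, one allele per parent per
#' locus. Each role's nutrient level is
#' `sqrt(h2) * Z + sqrt(1 - h2) * noise` (unit variance), where `Z` is the
#' standardized genetic nutrient score `(G b - mu)/sigma_g` and `h2` is
#' the target instrument variance-explained. Causal path coefficients act
#' on the standardized genetic scores (the component a polygenic score
#' measures), so they are directly the estimands of the trio regressions:
#'
#' `outcome = theta_maternal * Z_mother + theta_child * Z_child +
#'   theta_dynastic * (Z_mother + Z_father)/2 + G_child alpha + noise`
#'
#' with per-SNP pleiotropic effects `alpha_j ~ N(pleiotropy_mean,
#' pleiotropy_sd^2)` applied to centred child dosages (violating InSIDE
#' when `inside = FALSE` couples them to the instrument effects). When
#' `reverse_effect != 0`, every role's nutrient additionally receives
#' `reverse_effect * liability_z` from a second, independent SNP panel
#' (`n_snps_liability`, variance-explained `h2_liability`) representing
#' genetic predisposition to a neurodevelopmental condition; the binary
#' diagnosis is the liability thresholded at `liability_prevalence`.
#'
#' Defaults emulate the vitamin-D arm of the study the package models:
#' 38 genome-wide significant SNPs explaining 3.1% of variance in a GWAS
#' of N = 401 460, an outcome GWAS of N = 23 713 mothers, and 16 298
#' genotyped trios.
#'
#' @param n_trios number of families.
#' @param n_snps nutrient instrument SNPs.
#' @param maf_range uniform MAF sampling range.
#' @param h2_target variance in nutrient explained by the instruments.
#' @param theta_maternal maternal (intrauterine) causal path, per SD of
#'   maternal genetic nutrient score on the outcome scale.
#' @param theta_child child's own nutrient path.
#' @param theta_dynastic postnatal parental-environment path, applied
#'   through the mid-parent genetic score.
#' @param pleiotropy_mean,pleiotropy_sd direct SNP-to-outcome effects.
#' @param inside if `FALSE`, pleiotropic effects are proportional to the
#'   instrument effects (InSIDE violated).
#' @param assortment_r target correlation of parental instrument scores
#'   (rank-matching); must lie in (-0.95, 0.95).
#' @param reverse_effect liability-to-nutrient path (negative values
#'   emulate genetic predisposition to a condition lowering nutrient
#'   levels).
#' @param n_snps_liability,h2_liability,liability_prevalence liability
#'   panel size, variance explained, and case fraction of the thresholded
#'   diagnosis (the default 0.4 emulates a case-enriched case-control
#'   GWAS).
#' @param outcome_noise_sd residual outcome noise; `NULL` (default) picks
#'   the noise so the outcome has unit total variance, keeping the path
#'   coefficients on the per-SD reporting scale.
#' @param pc_sd loading of the synthetic PCs on the outcome (0 disables
#'   confounding; PCs then only exercise covariate plumbing).
#' @param gwas_n_exposure,gwas_n_outcome,gwas_n_liability GWAS sample
#'   sizes for simulated summary statistics.
#' @param seed mandatory integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trios = 16298, n_snps = 38,
                       maf_range = c(0.05, 0.5), h2_target = 0.031,
                       theta_maternal = 0, theta_child = 0, theta_dynastic = 0,
                       pleiotropy_mean = 0, pleiotropy_sd = 0, inside = TRUE,
                       assortment_r = 0, reverse_effect = 0,
                       n_snps_liability = 34, h2_liability = 0.05,
                       liability_prevalence = 0.4,
                       outcome_noise_sd = NULL, pc_sd = 0,
                       gwas_n_exposure = 401460, gwas_n_outcome = 23713,
                       gwas_n_liability = 46350,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(n_trios >= 2, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            h2_target > 0, h2_target < 1,
            h2_liability > 0, h2_liability < 1,
            liability_prevalence > 0, liability_prevalence < 1,
            is.null(outcome_noise_sd) || outcome_noise_sd >= 0,
            pleiotropy_sd >= 0,
            abs(assortment_r) < 0.95)
  cfg <- list(n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
              maf_range = maf_range, h2_target = h2_target,
              theta_maternal = theta_maternal, theta_child = theta_child,
              theta_dynastic = theta_dynastic,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              inside = inside, assortment_r = assortment_r,
              reverse_effect = reverse_effect,
              n_snps_liability = as.integer(n_snps_liability),
              h2_liability = h2_liability,
              liability_prevalence = liability_prevalence,
              outcome_noise_sd = outcome_noise_sd, pc_sd = pc_sd,
              gwas_n_exposure = as.integer(gwas_n_exposure),
              gwas_n_outcome = as.integer(gwas_n_outcome),
              gwas_n_liability = as.integer(gwas_n_liability),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Named simulation scenarios
#'
#' Presets in which only the named causal mechanism is active, mapping to
#' the competing explanations a trio-MR design discriminates:
#' `"null"` (no paths), `"maternal_causal"` (true intrauterine effect,
#' theta_maternal = 0.2), `"genetic_confounding"` (child direct genetic
#' effect only, theta_child = 0.3, producing a spurious unadjusted
#' maternal association by transmission), `"pleiotropic"` (directional
#' horizontal pleiotropy), `"reverse_causation"` (liability lowers the
#' nutrient, reverse_effect = -0.2), and `"assortative"` (parental score
#' correlation 0.3).
#'
#' @param name scenario name.
#' @param seed master seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario <- function(name = c("null", "maternal_causal", "genetic_confounding",
                              "pleiotropic", "reverse_causation", "assortative"),
                     seed, ...) {
  name <- match.arg(name)
  args <- switch(name,
    null = list(),
    maternal_causal = list(theta_maternal = 0.2),
    genetic_confounding = list(theta_child = 0.3),
    pleiotropic = list(pleiotropy_mean = 0.02, pleiotropy_sd = 0.02),
    reverse_causation = list(reverse_effect = -0.2),
    assortative = list(assortment_r = 0.3)
  )
  user <- list(...)
  args[names(user)] <- user
  cfg <- do.call(sim_config, c(args, list(seed = seed)))
  cfg$scenario <- name
  cfg
}

# Deterministic genetic architecture shared by every stage: MAFs, allele
# labels, instrument effects scaled to hit the h2 targets, pleiotropic
# effects. Uses its own child seed so genotype/phenotype/GWAS stages can
# be re-run independently.
.sim_truth <- function(config) {
  with_preserved_seed(child_seed(config$seed, 1L), {
    draw_panel <- function(m, h2, prefix) {
      maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
      b <- stats::rnorm(m)
      vg <- sum(2 * maf * (1 - maf) * b^2)
      b <- b * sqrt(h2 / vg)  # realized genetic variance = h2 exactly in expectation scale
      alleles <- t(vapply(seq_len(m), function(i) sample(c("A", "C", "G", "T"), 2),
                          character(2)))
      # spread variants far apart on chromosomes so the panel is unlinked
      # by position as well as by construction
      chrom <- as.character(rep_len(1:22, m))
      pos <- 1e6 + 2e7 * (seq_len(m) - 1) %/% 22
      list(variant_id = sprintf("%s%03d", prefix, seq_len(m)), maf = maf, b = b,
           effect_allele = alleles[, 1], other_allele = alleles[, 2],
           chrom = chrom, pos = pos,
           mu = sum(2 * maf * b), sigma_g = sqrt(sum(2 * maf * (1 - maf) * b^2)))
    }
    nut <- draw_panel(config$n_snps, config$h2_target, "rsN")
    liab <- draw_panel(config$n_snps_liability, config$h2_liability, "rsL")
    alpha <- if (config$inside) {
      stats::rnorm(config$n_snps, config$pleiotropy_mean, config$pleiotropy_sd)
    } else {
      config$pleiotropy_mean + config$pleiotropy_sd * nut$b / stats::sd(nut$b)
    }
    list(nutrient = nut, liability = liab, alpha = alpha)
  })
}

.panel_variants <- function(panel) {
  data.frame(variant_id = panel$variant_id, chrom = panel$chrom, pos = panel$pos,
             counted_allele = panel$effect_allele, other_allele = panel$other_allele,
             stringsAsFactors = FALSE)
}

.draw_parents <- function(n, maf) {
  m <- length(maf)
  matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
}

.transmit <- function(G) {
  # one allele per parent per locus: Bernoulli(dosage/2)
  matrix(stats::rbinom(length(G), 1L, G / 2), nrow = nrow(G))
}

.std_score <- function(G, panel) {
  as.numeric(G %*% panel$b - panel$mu) / panel$sigma_g
}

#' Simulate trio genotypes
#'
#' Parental genotypes under Hardy-Weinberg equilibrium at each MAF;
#' optional assortative mating by rank-matching couples on their
#' nutrient instrument score to reach `assortment_r`; child dosages by
#' Mendelian transmission (one Bernoulli(dosage/2) allele per parent per
#' locus). The liability panel is simulated alongside whenever
#' `reverse_effect != 0`.
#'
#' @param config a [sim_config()].
#' @return A `sim_cohort` list with `genotypes` (per-role
#'   [genotype_matrix()]s), `liability_genotypes` (or NULL), `truth`
#'   (architecture record) and `config`.
#' @export
simulate_trio_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- .sim_truth(config)
  n <- config$n_trios
  cohort <- with_preserved_seed(child_seed(config$seed, 2L), {
    Gm <- .draw_parents(n, truth$nutrient$maf)
    Gf <- .draw_parents(n, truth$nutrient$maf)
    Lm <- Lf <- NULL
    if (config$reverse_effect != 0) {
      Lm <- .draw_parents(n, truth$liability$maf)
      Lf <- .draw_parents(n, truth$liability$maf)
    }
    if (config$assortment_r != 0) {
      r <- config$assortment_r
      sm <- .std_score(Gm, truth$nutrient)
      sf <- .std_score(Gf, truth$nutrient)
      target <- sign(r) * sm + stats::rnorm(n, 0, sqrt(1 / r^2 - 1) * stats::sd(sm))
      ord <- order(sf)[rank(target, ties.method = "first")]
      Gf <- Gf[ord, , drop = FALSE]
      if (!is.null(Lf)) Lf <- Lf[ord, , drop = FALSE]
      achieved <- stats::cor(sm, .std_score(Gf, truth$nutrient))
      if (abs(achieved - r) > 0.05 + 3 / sqrt(n)) {
        stop("assortment_r = ", r, " not attainable by rank matching (achieved ",
             round(achieved, 3), ")")
      }
    }
    Gc <- .transmit(Gm) + .transmit(Gf)
    Lc <- if (!is.null(Lm)) .transmit(Lm) + .transmit(Lf) else NULL
    list(Gm = Gm, Gf = Gf, Gc = Gc, Lm = Lm, Lf = Lf, Lc = Lc)
  })
  v <- .panel_variants(truth$nutrient)
  ids <- sprintf("fam%06d", seq_len(n))
  gm <- function(M, role) {
    rownames(M) <- ids
    genotype_matrix(M, v, role)
  }
  liab <- NULL
  if (!is.null(cohort$Lm)) {
    vl <- .panel_variants(truth$liability)
    liab <- list(mother = genotype_matrix(`rownames<-`(cohort$Lm, ids), vl, "mother"),
                 father = genotype_matrix(`rownames<-`(cohort$Lf, ids), vl, "father"),
                 child = genotype_matrix(`rownames<-`(cohort$Lc, ids), vl, "child"))
  }
  structure(list(genotypes = list(mother = gm(cohort$Gm, "mother"),
                                  father = gm(cohort$Gf, "father"),
                                  child = gm(cohort$Gc, "child")),
                 liability_genotypes = liab,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' Simulate phenotypes on a genotyped trio cohort
#'
#' Adds, per role, the latent standardized genetic nutrient score `Z`,
#' the observed nutrient level, liability scores/diagnoses when the
#' reverse-causation path is active, the child outcome under the
#' configured causal structure, and covariates (child sex, 10 synthetic
#' PCs, genotype batch). The realized instrument variance-explained is
#' recorded in `ground_truth`.
#'
#' @param cohort a `sim_cohort` from [simulate_trio_genotypes()].
#' @return the completed `sim_cohort`, with elements `phenotypes` (data
#'   frame) and `ground_truth`.
#' @export
simulate_phenotypes <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  config <- cohort$config
  truth <- cohort$truth
  n <- config$n_trios
  pheno <- with_preserved_seed(child_seed(config$seed, 3L), {
    Z <- lapply(cohort$genotypes, function(g) .std_score(g$dosages, truth$nutrient))
    h2 <- config$h2_target
    liab_z <- list(mother = 0, father = 0, child = 0)
    diagnosis <- NULL
    if (config$reverse_effect != 0) {
      h2l <- config$h2_liability
      liab_z <- lapply(cohort$liability_genotypes, function(g) {
        sqrt(h2l) * .std_score(g$dosages, truth$liability) +
          sqrt(1 - h2l) * stats::rnorm(n)
      })
      thr <- stats::qnorm(1 - config$liability_prevalence)
      diagnosis <- lapply(liab_z, function(l) as.integer(l > thr))
    }
    rv <- config$reverse_effect
    env_var <- max(0, 1 - h2 - rv^2)
    nutrient <- lapply(names(Z), function(role) {
      sqrt(h2) * Z[[role]] + rv * liab_z[[role]] + sqrt(env_var) * stats::rnorm(n)
    })
    names(nutrient) <- names(Z)
    Gc_centred <- sweep(cohort$genotypes$child$dosages, 2L, 2 * truth$nutrient$maf)
    pleio <- as.numeric(Gc_centred %*% truth$alpha)
    sex <- stats::rbinom(n, 1L, 0.51)
    pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    batch <- sample(paste0("batch", 1:3), n, replace = TRUE)
    systematic <- config$theta_maternal * Z$mother +
      config$theta_child * Z$child +
      config$theta_dynastic * (Z$mother + Z$father) / 2 +
      pleio +
      config$pc_sd * pcs[, 1]
    if (config$reverse_effect != 0) {
      # genetic predisposition is transmitted to the child independently
      # of nutrient levels
      systematic <- systematic + 0.3 * liab_z$child
    }
    noise_sd <- config$outcome_noise_sd %||%
      sqrt(max(0, 1 - stats::var(systematic)))
    outcome <- systematic + stats::rnorm(n, 0, noise_sd)
    df <- data.frame(family_id = rownames(cohort$genotypes$mother$dosages),
                     outcome = outcome,
                     nutrient_mother = nutrient$mother,
                     nutrient_father = nutrient$father,
                     nutrient_child = nutrient$child,
                     z_mother = Z$mother, z_father = Z$father, z_child = Z$child,
                     child_sex = sex, pcs, batch = batch,
                     stringsAsFactors = FALSE)
    if (!is.null(diagnosis)) {
      df$liability_mother <- liab_z$mother
      df$diagnosis_mother <- diagnosis$mother
    }
    df
  })
  cohort$phenotypes <- pheno
  cohort$ground_truth <- list(
    config = unclass(config),
    realized_h2 = stats::cor(pheno$nutrient_mother, pheno$z_mother)^2,
    expected_marginal_beta = sqrt(config$h2_target) * truth$nutrient$b /
      truth$nutrient$sigma_g
  )
  cohort
}

#' Simulate a complete trio cohort (genotypes + phenotypes)
#' @param config a [sim_config()].
#' @return a complete `sim_cohort`.
#' @export
simulate_cohort <- function(config) {
  simulate_phenotypes(simulate_trio_genotypes(config))
}

#' Simulate GWAS summary statistics
#'
#' Produces the two-sample MR inputs. For continuous traits either an
#' individual-level simulation (an independently drawn unrelated sample
#' of size `n` with per-SNP marginal OLS) or the analytic approximation
#' `beta_hat ~ N(true marginal beta, se^2)` with
#' `se = 1 / (sd(dosage) sqrt(n))` on the unit-variance trait scale. The
#' binary liability trait is always individual-level: the latent
#' liability is thresholded at the configured prevalence and each SNP is
#' fitted by marginal logistic regression (log-odds betas).
#'
#' The returned table covers the nutrient instrument panel and, when the
#' reverse-causation path is active, also the liability panel, so that
#' forward and reverse MR draw from the same tables.
#'
#' @param config a [sim_config()].
#' @param trait `"nutrient"` or `"liability"`.
#' @param n GWAS sample size (>= 100); defaults to the config's
#'   `gwas_n_exposure` / `gwas_n_liability`.
#' @param method `"analytic"` or `"individual"` (continuous traits only).
#' @param seed_offset counter for the stage child seed, so exposure and
#'   outcome GWAS of the same trait are independent samples.
#' @return A `sumstat_table`.
#' @export
simulate_gwas_sumstats <- function(config, trait = c("nutrient", "liability"),
                                   n = NULL,
                                   method = c("analytic", "individual"),
                                   seed_offset = 10L) {
  trait <- match.arg(trait)
  method <- match.arg(method)
  stopifnot(inherits(config, "sim_config"))
  truth <- .sim_truth(config)
  if (is.null(n)) {
    n <- if (trait == "nutrient") config$gwas_n_exposure else config$gwas_n_liability
  }
  if (n < 100) stop("GWAS sample size must be at least 100")

  panels <- list(nutrient = truth$nutrient)
  if (config$reverse_effect != 0) panels$liability <- truth$liability
  h2 <- config$h2_target
  h2l <- config$h2_liability
  rv <- config$reverse_effect

  make_table <- function(records, label, type) {
    sumstat_table(do.call(rbind, records), trait_label = label, trait_type = type)
  }

  if (trait == "nutrient" && method == "analytic") {
    recs <- with_preserved_seed(child_seed(config$seed, seed_offset), {
      lapply(names(panels), function(pn) {
        p <- panels[[pn]]
        slope_scale <- if (pn == "nutrient") sqrt(h2) / p$sigma_g
                       else rv * sqrt(h2l) / p$sigma_g
        beta_true <- slope_scale * p$b
        se <- 1 / sqrt(2 * p$maf * (1 - p$maf) * n)
        beta_hat <- stats::rnorm(length(p$b), beta_true, se)
        data.frame(variant_id = p$variant_id, chrom = p$chrom, pos = p$pos,
                   effect_allele = p$effect_allele, other_allele = p$other_allele,
                   eaf = p$maf, beta = beta_hat, se = se,
                   pval = 2 * stats::pnorm(-abs(beta_hat / se)), n = n,
                   stringsAsFactors = FALSE)
      })
    })
    return(make_table(recs, "nutrient", "continuous"))
  }

  # individual-level sample, shared across the panels
  with_preserved_seed(child_seed(config$seed, seed_offset), {
    G <- .draw_parents(n, truth$nutrient$maf)
    Zn <- .std_score(G, truth$nutrient)
    L <- NULL; Zl <- 0
    if (config$reverse_effect != 0) {
      L <- .draw_parents(n, truth$liability$maf)
      Zl <- sqrt(h2l) * .std_score(L, truth$liability) + sqrt(1 - h2l) * stats::rnorm(n)
    }
    env_var <- max(0, 1 - h2 - rv^2)
    nutrient <- sqrt(h2) * Zn + rv * Zl + sqrt(env_var) * stats::rnorm(n)

    marginal_ols <- function(D, y) {
      mu <- colMeans(D)
      sg2 <- colSums(sweep(D, 2L, mu)^2)
      beta <- as.numeric(crossprod(sweep(D, 2L, mu), y - mean(y))) / sg2
      rss <- sum((y - mean(y))^2) - beta^2 * sg2
      se <- sqrt(pmax(rss, 0) / (length(y) - 2) / sg2)
      list(beta = beta, se = se, eaf = mu / 2)
    }
    panel_records <- function(p, D, fit) {
      data.frame(variant_id = p$variant_id, chrom = p$chrom, pos = p$pos,
                 effect_allele = p$effect_allele, other_allele = p$other_allele,
                 eaf = fit$eaf, beta = fit$beta, se = fit$se,
                 pval = 2 * stats::pnorm(-abs(fit$beta / fit$se)), n = n,
                 stringsAsFactors = FALSE)
    }

    if (trait == "nutrient") {
      recs <- list(panel_records(truth$nutrient, G, marginal_ols(G, nutrient)))
      if (!is.null(L)) recs <- c(recs, list(panel_records(truth$liability, L,
                                                          marginal_ols(L, nutrient))))
      make_table(recs, "nutrient", "continuous")
    } else {
      if (is.null(L)) stop("liability trait requires reverse_effect != 0 in the config")
      case <- as.integer(Zl > stats::qnorm(1 - config$liability_prevalence))
      logistic_fit <- function(D) {
        res <- apply(D, 2L, function(g) {
          fit <- stats::glm(case ~ g, family = stats::binomial())
          ct <- summary(fit)$coefficients
          c(ct["g", 1], ct["g", 2])
        })
        list(beta = res[1, ], se = res[2, ], eaf = colMeans(D) / 2)
      }
      recs <- list(panel_records(truth$liability, L, logistic_fit(L)),
                   panel_records(truth$nutrient, G, logistic_fit(G)))
      make_table(recs, "liability", "binary")
    }
  })
}

#' Identity LD source for a simulated (unlinked) SNP panel
#'
#' The generator simulates SNPs without linkage, so the truthful LD
#' matrix is the identity over the panel's variant ids (covering both the
#' nutrient and, when present, the liability panel).
#'
#' @param config a [sim_config()].
#' @return an [ld_source()].
#' @export
sim_ld_source <- function(config) {
  truth <- .sim_truth(config)
  ids <- truth$nutrient$variant_id
  if (config$reverse_effect != 0) ids <- c(ids, truth$liability$variant_id)
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  ld_source(m)
}

#' Build a trio analysis frame from a simulated cohort
#'
#' Computes polygenic scores for all three roles and binds them with the
#' simulated outcome and covariates. By default the generator's true
#' instrument effects are the score weights (the estimand-defining
#' scores); alternatively pass `weights` built from simulated GWAS
#' summary statistics via [build_pgs_weights()] to include
#' weight-estimation noise.
#'
#' @param cohort a complete `sim_cohort`.
#' @param weights optional `pgs_weights`; defaults to the true effects.
#' @return A [trio_frame()].
#' @export
cohort_trio_frame <- function(cohort, weights = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"), !is.null(cohort$phenotypes))
  truth <- cohort$truth
  if (is.null(weights)) {
    weights <- data.frame(variant_id = truth$nutrient$variant_id,
                          effect_allele = truth$nutrient$effect_allele,
                          other_allele = truth$nutrient$other_allele,
                          weight = truth$nutrient$b,
                          eaf = truth$nutrient$maf,
                          stringsAsFactors = FALSE)
  }
  sc <- lapply(cohort$genotypes, pgs_score, weights = weights)
  ph <- cohort$phenotypes
  trio_frame(data.frame(ph[, c("family_id", "outcome")],
                        pgs_mother = sc$mother$z,
                        pgs_father = sc$father$z,
                        pgs_child = sc$child$z,
                        child_sex = ph$child_sex,
                        ph[, paste0("pc", 1:10)],
                        batch = ph$batch,
                        stringsAsFactors = FALSE))
}

#' Write a simulated cohort to plain-text files
#'
#' Writes per-role genotype TSVs (+ metadata), a phenotype TSV and a
#' `ground_truth.json` provenance record into `out_dir`.
#'
#' @param cohort a complete `sim_cohort`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"), !is.null(cohort$phenotypes))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (role in names(cohort$genotypes)) {
    write_genotypes(cohort$genotypes[[role]],
                    file.path(out_dir, paste0("genotypes_", role, ".tsv")),
                    file.path(out_dir, paste0("variants_", role, ".tsv")))
  }
  utils::write.table(cohort$phenotypes, file.path(out_dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
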