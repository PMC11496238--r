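#' Bonferroni-corrected significance threshold
#'
#' Family-wise correction for a grid of primary tests (outcomes x
#' exposures): `raw = alpha / (n_outcomes * n_exposures)`, with a
#' 3-decimal display rounding for reporting. Comparisons always use the
#' raw value. With the defaults (alpha 0.05, 19 outcomes, 2 exposures)
#' the threshold is 0.05/38, displayed as 0.001.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_outcomes,n_exposures positive test-grid dimensions.
#' @return list with `raw` and `display`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_outcomes = 19, n_exposures = 2) {
  stopifnot(alpha > 0, alpha < 1, n_outcomes >= 1, n_exposures >= 1)
  raw <- alpha / (n_outcomes * n_exposures)
  list(raw = raw, display = round(raw, 3))
}

#' Read and validate a declarative analysis configuration
#'
#' A single YAML document drives the pipeline. Recognised keys:
#' `scenario` (+ optional `sim` overrides and mandatory `seed`) or
#' `exposure`/`outcome` summary-statistic paths with an `ld` TSV;
#' `p_threshold`, `clump_r2`, `clump_kb`, `pgs_clump_r2`, `pgs_clump_kb`,
#' `methods`, `alpha`, `n_outcomes`, `n_exposures`, `i2gx_simex_trigger`,
#' `out_dir`.
#'
#' @param path YAML file path.
#' @return a validated named list (class `analysis_config`).
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  analysis_config(cfg)
}

#' @rdname read_analysis_config
#' @param cfg a named list of configuration values.
#' @export
analysis_config <- function(cfg) {
  defaults <- list(p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 10000,
                   pgs_clump_r2 = 0.25, pgs_clump_kb = 500,
                   reverse_p_threshold = 5e-6,
                   methods = c("ivw", "egger", "weighted_median", "weighted_mode"),
                   alpha = 0.05, n_outcomes = 19, n_exposures = 2,
                   i2gx_simex_trigger = 0.9, out_dir = NULL)
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  if (is.null(cfg$seed)) stop("analysis config requires a seed")
  if (!is.null(cfg$exposure) && !file.exists(cfg$exposure)) {
    stop("exposure sumstats path does not exist: ", cfg$exposure)
  }
  if (!is.null(cfg$outcome) && !file.exists(cfg$outcome)) {
    stop("outcome sumstats path does not exist: ", cfg$outcome)
  }
  if (is.null(cfg$scenario) && (is.null(cfg$exposure) || is.null(cfg$outcome))) {
    stop("config needs either a simulation 'scenario' or exposure+outcome paths")
  }
  stopifnot(cfg$p_threshold > 0, cfg$p_threshold < 1,
            cfg$clump_r2 >= 0, cfg$clump_kb > 0)
  class(cfg) <- "analysis_config"
  cfg
}

.config_sim <- function(cfg) {
  do.call(scenario, c(list(name = cfg$scenario, seed = cfg$seed),
                      cfg$sim %||% list()))
}

.write_report_tables <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(report))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$tables)) {
    utils::write.table(report$tables[[nm]],
                       file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.new_report <- function(analysis, cfg) {
  list(analysis = analysis,
       tables = list(),
       provenance = list(analysis = analysis,
                         config = unclass(cfg)[!vapply(cfg, is.function, logical(1))],
                         seed = cfg$seed,
                         package_version = as.character(utils::packageVersion("triomr"))),
       log = character(0),
       warnings = character(0))
}

.log_report <- function(report, msg) {
  report$log <- c(report$log, msg)
  report
}

#' Analysis 1: two-sample MR of nutrient levels on the outcome
#'
#' Instrument selection (p < 5e-8) -> LD clumping (r2 < 0.001, 10 000 kb)
#' -> harmonization -> all configured MR methods with heterogeneity and
#' instrument-strength diagnostics -> SIMEX-corrected Egger when I2GX
#' falls below the configured trigger (regression dilution) ->
#' leave-one-out and Steiger filtering when the IVW p-value passes the
#' raw Bonferroni threshold (follow-up "where there is evidence").
#'
#' @param cfg an [analysis_config()] (or list coercible to one). With a
#'   `scenario`, the exposure GWAS is simulated and the SNP-outcome table
#'   is estimated from the simulated trio cohort by
#'   [snp_outcome_regression()] on maternal dosages (the trio-study
#'   convention for maternal exposures); set `cfg$snp_outcome_role =
#'   "child"` for the child-genotype sensitivity analysis.
#' @return a `run_report` list: `tables` (`mr`, `diagnostics`,
#'   `leave_one_out`, `steiger`), `provenance`, `log`.
#' @export
run_analysis1 <- function(cfg) {
  if (!inherits(cfg, "analysis_config")) cfg <- analysis_config(cfg)
  report <- .new_report("analysis1", cfg)
  if (!is.null(cfg$scenario)) {
    sim <- .config_sim(cfg)
    exposure <- simulate_gwas_sumstats(sim, "nutrient", method = "analytic",
                                       seed_offset = 10L)
    cohort <- simulate_cohort(sim)
    role <- cfg$snp_outcome_role %||% "mother"
    covs <- data.frame(cohort$phenotypes[, paste0("pc", 1:10)],
                       batch = cohort$phenotypes$batch)
    outcome <- snp_outcome_regression(cohort$genotypes[[role]],
                                      cohort$phenotypes$outcome, covs,
                                      trait_label = "simulated_outcome")
    ld <- sim_ld_source(sim)
  } else {
    exposure <- read_sumstats(cfg$exposure, trait_label = cfg$exposure_label %||% "exposure")
    outcome <- read_sumstats(cfg$outcome, trait_label = cfg$outcome_label %||% "outcome")
    ld <- read_ld(cfg$ld)
  }
  report <- .log_report(report, paste0("exposure variants read: ", nrow(exposure)))
  inst <- select_instruments(exposure, cfg$p_threshold)
  report <- .log_report(report, paste0("instruments at p<", cfg$p_threshold, ": ", nrow(inst)))
  inst <- clump(inst, ld, cfg$clump_r2, cfg$clump_kb)
  report <- .log_report(report, paste0("instruments after clumping: ", nrow(inst)))
  pair <- harmonize(inst, outcome)
  report <- .log_report(report, paste0("variants harmonized: ", nrow(pair),
                                       "; dropped: ", nrow(attr(pair, "dropped"))))

  fits <- mr_all(pair, methods = cfg$methods, seed = child_seed(cfg$seed, 20L))
  strength <- instrument_strength(pair)
  if (strength$mean_F <= 10) {
    report$warnings <- c(report$warnings, "mean F <= 10: weak instruments")
  }
  diag_tab <- data.frame(mean_F = strength$mean_F, i2_gx = strength$i2_gx,
                         nsnp = nrow(pair))
  if (!is.na(strength$i2_gx) && strength$i2_gx < cfg$i2gx_simex_trigger &&
      nrow(pair) >= 3L) {
    report <- .log_report(report, paste0("I2GX = ", round(strength$i2_gx, 3),
                                         " < ", cfg$i2gx_simex_trigger,
                                         ": SIMEX-corrected Egger triggered"))
    fits$egger_simex <- simex_egger(pair, seed = child_seed(cfg$seed, 21L),
                                    n_sim = cfg$simex_n_sim %||% 200)
  }
  report$tables$mr <- mr_tidy(fits)
  report$tables$diagnostics <- diag_tab

  bonf <- bonferroni_threshold(cfg$alpha, cfg$n_outcomes, cfg$n_exposures)
  ivw_p <- if (!is.null(fits$ivw)) fits$ivw$pval else NA_real_
  if (!is.na(ivw_p) && ivw_p < bonf$raw && nrow(pair) >= 3L) {
    report <- .log_report(report, "IVW passes the Bonferroni threshold: follow-ups run")
    report$tables$leave_one_out <- leave_one_out(pair)
    st <- steiger_filter(pair,
                         n_exp = cfg$n_exp %||% NULL, n_out = cfg$n_out %||% NULL)
    report$tables$steiger <- st$table
    report$steiger <- st[c("n_kept", "n_removed", "direction_ok")]
  }
  report$pair <- pair
  .write_report_tables(report, cfg$out_dir)
}

#' Analysis 2: trio-MR with polygenic scores
#'
#' Builds PGS weights from the exposure GWAS (p < 5e-8, clumped at
#' r2 = 0.25 within 500 kb), scores mothers, fathers and children,
#' and fits the trio regression battery: maternal unadjusted and
#' trio-adjusted models, child models, the paternal negative control,
#' sex-stratified maternal models, and the parental-PGS correlation
#' (assortative-mating check).
#'
#' @param cfg an [analysis_config()]; with a `scenario` the cohort and
#'   exposure GWAS are simulated. `cfg$use_true_weights = TRUE` scores
#'   with the generator's true effects instead of estimated ones.
#' @return a `run_report` with tables `trio` (forest layout) and
#'   `parental_correlation`.
#' @export
run_analysis2 <- function(cfg) {
  if (!inherits(cfg, "analysis_config")) cfg <- analysis_config(cfg)
  report <- .new_report("analysis2", cfg)
  if (is.null(cfg$scenario)) stop("run_analysis2 currently drives the simulated cohort; supply a scenario")
  sim <- .config_sim(cfg)
  cohort <- simulate_cohort(sim)
  if (isTRUE(cfg$use_true_weights %||% TRUE)) {
    frame <- cohort_trio_frame(cohort)
    report <- .log_report(report, "PGS weights: generator ground truth")
  } else {
    exposure <- simulate_gwas_sumstats(sim, "nutrient", method = "analytic",
                                       seed_offset = 10L)
    w <- build_pgs_weights(exposure, sim_ld_source(sim),
                           r2_threshold = cfg$pgs_clump_r2,
                           window_kb = cfg$pgs_clump_kb)
    frame <- cohort_trio_frame(cohort, weights = w)
    report <- .log_report(report, paste0("PGS weights estimated from simulated GWAS: ",
                                         nrow(w), " variant(s)"))
  }
  fits <- list(
    fit_maternal_unadjusted(frame, "outcome"),
    fit_trio_adjusted(frame, "outcome"),
    fit_child_model(frame, "outcome")$unadjusted,
    fit_child_model(frame, "outcome")$adjusted,
    fit_paternal_control(frame, "outcome")$unadjusted,
    fit_paternal_control(frame, "outcome")$adjusted
  )
  strat <- stratify_by_sex(frame, "outcome", "maternal_unadjusted")
  report$tables$trio <- trio_tidy(c(fits, strat))
  pc <- parental_pgs_correlation(frame)
  report$tables$parental_correlation <- as.data.frame(pc)
  report$frame <- frame
  .write_report_tables(report, cfg$out_dir)
}

#' Analysis 3: reverse-direction MR (liability on nutrient levels)
#'
#' The binary liability trait (diagnosis GWAS) is the exposure at the
#' relaxed threshold p < 5e-6; the nutrient GWAS is the outcome. The MR
#' engine runs as in Analysis 1, estimates are rescaled to a per-doubling
#' (ln 2) interpretation, Steiger filtering checks the orientation, and
#' leave-one-out iteratively removes variants.
#'
#' @param cfg an [analysis_config()] whose scenario has
#'   `reverse_effect != 0` (e.g. `"reverse_causation"`).
#' @return a `run_report` with tables `mr` (per-doubling scale),
#'   `steiger`, `leave_one_out`.
#' @export
run_analysis3 <- function(cfg) {
  if (!inherits(cfg, "analysis_config")) cfg <- analysis_config(cfg)
  report <- .new_report("analysis3", cfg)
  if (!is.null(cfg$scenario)) {
    sim <- .config_sim(cfg)
    exposure <- simulate_gwas_sumstats(sim, "liability", seed_offset = 30L)
    outcome <- simulate_gwas_sumstats(sim, "nutrient", method = "analytic",
                                      seed_offset = 31L)
    ld <- sim_ld_source(sim)
  } else {
    exposure <- read_sumstats(cfg$exposure, trait_label = "liability",
                              trait_type = "binary")
    outcome <- read_sumstats(cfg$outcome, trait_label = "nutrient")
    ld <- read_ld(cfg$ld)
  }
  inst <- select_instruments(exposure, cfg$reverse_p_threshold)
  report <- .log_report(report, paste0("liability instruments at p<",
                                       cfg$reverse_p_threshold, ": ", nrow(inst)))
  inst <- clump(inst, ld, cfg$clump_r2, cfg$clump_kb)
  pair <- harmonize(inst, outcome)
  report <- .log_report(report, paste0("variants harmonized: ", nrow(pair)))
  fits <- mr_all(pair, methods = cfg$methods, seed = child_seed(cfg$seed, 32L))
  fits <- lapply(fits, scale_to_doubling)
  report$tables$mr <- mr_tidy(fits)
  st <- steiger_filter(pair)
  report$tables$steiger <- st$table
  report$steiger <- st[c("n_kept", "n_removed", "direction_ok")]
  if (nrow(pair) >= 3L) report$tables$leave_one_out <- leave_one_out(pair)
  report$pair <- pair
  .write_report_tables(report, cfg$out_dir)
}
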