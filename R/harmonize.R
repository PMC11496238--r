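.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Harmonize exposure and outcome summary statistics onto a shared effect allele
#'
#' Aligns SNP-outcome effects to the exposure's effect allele, the
#' prerequisite for combining two independent GWAS in two-sample MR. For
#' each variant present in both tables:
#'
#' * alleles identical: keep (`none`);
#' * alleles swapped: negate the outcome beta and flip its eaf (`sign_flip`);
#' * alleles on the opposite strand: complement, then re-apply the two rules
#'   above (`strand_flip`, or `sign_flip` when the complemented alleles are
#'   also swapped);
#' * palindromic (A/T or C/G): strand cannot be resolved from alleles, so
#'   orientation is inferred from allele frequencies — the variant is kept
#'   only when both eafs are available, both lie outside
#'   `[0.5 - palindrome_eaf_tol, 0.5 + palindrome_eaf_tol]`, and are
#'   concordant either directly or after a frequency flip (in which case the
#'   outcome beta is negated); otherwise dropped as ambiguous;
#' * anything else: dropped as an allele mismatch.
#'
#' @param exposure,outcome `sumstat_table`s.
#' @param palindrome_eaf_tol half-width of the ambiguous frequency band
#'   around 0.5 for palindromic SNPs (default 0.08, i.e. drop when either
#'   eaf falls in \[0.42, 0.58\]).
#' @return A `harmonized_pair`: data frame with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `beta_exp`, `se_exp`, `eaf_exp`,
#'   `beta_out`, `se_out`, `eaf_out`, `n_exp`, `n_out`, `action`, plus
#'   attributes `dropped` (data frame of variant_id/reason),
#'   `exposure_label`, `outcome_label`, `exposure_type`, `outcome_type`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_tol = 0.08) {
  stopifnot(inherits(exposure, "sumstat_table"), inherits(outcome, "sumstat_table"),
            palindrome_eaf_tol >= 0, palindrome_eaf_tol < 0.5)
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0L) stop("exposure and outcome share no variants")

  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  get <- function(df, col) if (col %in% names(df)) df[[col]] else rep(NA_real_, nrow(df))

  n <- length(shared)
  beta_out <- ou$beta
  eaf_out <- get(ou, "eaf")
  action <- character(n)
  reason <- rep(NA_character_, n)

  oe <- ou$effect_allele
  oo <- ou$other_allele
  for (k in seq_len(n)) {
    ee <- ex$effect_allele[k]; eo <- ex$other_allele[k]
    pal <- .is_palindromic(ee, eo)
    a1 <- oe[k]; a2 <- oo[k]
    if (!pal && !(identical(c(a1, a2), c(ee, eo)) || identical(c(a1, a2), c(eo, ee)))) {
      # try the opposite strand
      ca1 <- unname(.complement[a1]); ca2 <- unname(.complement[a2])
      if (identical(c(ca1, ca2), c(ee, eo)) || identical(c(ca1, ca2), c(eo, ee))) {
        a1 <- ca1; a2 <- ca2
        action[k] <- "strand_flip"
      }
    }
    if (pal) {
      ok_alleles <- identical(sort(c(a1, a2)), sort(c(ee, eo)))
      fe <- get(ex, "eaf")[k]; fo <- eaf_out[k]
      band <- function(f) !is.na(f) && abs(f - 0.5) > palindrome_eaf_tol
      if (!ok_alleles) {
        action[k] <- "dropped"; reason[k] <- "allele_mismatch"
      } else if (!band(fe) || !band(fo)) {
        action[k] <- "dropped"; reason[k] <- "palindromic_ambiguous"
      } else {
        fo_use <- if (identical(a1, ee)) fo else 1 - fo
        if ((fe > 0.5) == (fo_use > 0.5)) {
          # same orientation: align as a plain swap if alleles are swapped
          if (!identical(a1, ee)) {
            beta_out[k] <- -beta_out[k]; eaf_out[k] <- 1 - eaf_out[k]
            action[k] <- "sign_flip"
          } else action[k] <- "none"
        } else {
          # frequencies discordant: outcome reported on the opposite strand
          # orientation, which for a palindrome flips the effect direction
          if (identical(a1, ee)) {
            beta_out[k] <- -beta_out[k]; eaf_out[k] <- 1 - eaf_out[k]
            action[k] <- "sign_flip"
          } else action[k] <- "none"
        }
      }
    } else if (identical(c(a1, a2), c(ee, eo))) {
      if (action[k] != "strand_flip") action[k] <- "none"
    } else if (identical(c(a1, a2), c(eo, ee))) {
      beta_out[k] <- -beta_out[k]
      eaf_out[k] <- 1 - eaf_out[k]
      action[k] <- "sign_flip"
    } else {
      action[k] <- "dropped"; reason[k] <- "allele_mismatch"
    }
  }

  keep <- action != "dropped"
  dropped <- data.frame(variant_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  absent_exp <- setdiff(outcome$variant_id, exposure$variant_id)
  absent_out <- setdiff(exposure$variant_id, outcome$variant_id)
  if (length(absent_out) || length(absent_exp)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = c(absent_out, absent_exp),
      reason = rep(c("absent_from_outcome", "absent_from_exposure"),
                   c(length(absent_out), length(absent_exp))),
      stringsAsFactors = FALSE))
  }

  pair <- data.frame(
    variant_id = shared[keep],
    chrom = if ("chrom" %in% names(ex)) ex$chrom[keep] else NA_character_,
    pos = if ("pos" %in% names(ex)) ex$pos[keep] else NA_real_,
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    beta_exp = ex$beta[keep],
    se_exp = ex$se[keep],
    eaf_exp = get(ex, "eaf")[keep],
    beta_out = beta_out[keep],
    se_out = ou$se[keep],
    eaf_out = eaf_out[keep],
    n_exp = get(ex, "n")[keep],
    n_out = get(ou, "n")[keep],
    action = action[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(pair) == 0L) stop("no variants survive harmonization")
  structure(pair,
            class = c("harmonized_pair", "data.frame"),
            hash = content_hash(pair$variant_id, pair$beta_exp, pair$se_exp,
                                pair$beta_out, pair$se_out),
            dropped = dropped,
            exposure_label = attr(exposure, "trait_label"),
            outcome_label = attr(outcome, "trait_label"),
            exposure_type = attr(exposure, "trait_type"),
            outcome_type = attr(outcome, "trait_type"))
}

#' Subset a harmonized pair, preserving attributes
#' @param pair a `harmonized_pair`.
#' @param idx logical or integer index over variants.
#' @return the subset `harmonized_pair`.
#' @export
pair_subset <- function(pair, idx) {
  out <- as.data.frame(pair)[idx, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("dropped", "exposure_label", "outcome_label",
              "exposure_type", "outcome_type")) {
    attr(out, a) <- attr(pair, a)
  }
  attr(out, "hash") <- content_hash(out$variant_id, out$beta_exp, out$se_exp,
                                    out$beta_out, out$se_out)
  class(out) <- class(pair)
  out
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat("Harmonized exposure-outcome pair: ",
      attr(x, "exposure_label"), " -> ", attr(x, "outcome_label"),
      " (", nrow(x), " variant(s), ", nrow(attr(x, "dropped")), " dropped)\n",
      sep = "")
  print(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}
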