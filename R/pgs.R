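#' Construct a genotype dosage matrix
#'
#' Container for effect-allele dosages in \[0, 2\] (missing allowed) for
#' one family role (mothers, fathers or children), with per-variant
#' metadata naming the counted allele.
#'
#' @param dosages numeric matrix, individuals x variants, values in
#'   \[0, 2\] or `NA`; rownames are individual ids, colnames variant ids.
#' @param variants data frame with columns `variant_id`, `counted_allele`,
#'   `other_allele` and optionally `chrom`, `pos`; one row per dosage
#'   column, in order.
#' @param role `"mother"`, `"father"` or `"child"`.
#' @return A `genotype_matrix` (list with `dosages`, `variants`, `role`).
#' @export
genotype_matrix <- function(dosages, variants, role = c("mother", "father", "child")) {
  role <- match.arg(role)
  stopifnot(is.matrix(dosages), is.data.frame(variants),
            all(c("variant_id", "counted_allele", "other_allele") %in% names(variants)),
            nrow(variants) == ncol(dosages))
  if (anyDuplicated(variants$variant_id)) stop("duplicated variant metadata")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  colnames(dosages) <- variants$variant_id
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("%s_%06d", role, seq_len(nrow(dosages)))
  }
  structure(list(dosages = dosages, variants = variants, role = role),
            class = "genotype_matrix")
}

#' Read a genotype dosage TSV
#'
#' Wide dialect: one row per individual, first column `individual_id`,
#' remaining column headers `variant_id:counted_allele`. A companion
#' metadata TSV (columns `variant_id`, `counted_allele`, `other_allele`,
#' optionally `chrom`, `pos`) supplies the other allele; without it the
#' other allele is recorded as `NA` and allele flipping is unavailable.
#'
#' @param path dosage TSV.
#' @param meta_path optional variant metadata TSV.
#' @param role family role label.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, meta_path = NULL, role = c("mother", "father", "child")) {
  role <- match.arg(role)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "individual_id") stop("first column must be individual_id")
  ids <- as.character(raw[[1]])
  dos <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- ids
  parts <- strsplit(colnames(dos), ":", fixed = TRUE)
  vid <- vapply(parts, `[`, character(1), 1L)
  counted <- toupper(vapply(parts, function(p) p[2] %||% NA_character_, character(1)))
  variants <- data.frame(variant_id = vid, counted_allele = counted,
                         other_allele = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    m <- match(variants$variant_id, meta$variant_id)
    variants$other_allele <- toupper(meta$other_allele[m])
    if ("counted_allele" %in% names(meta)) {
      ca <- toupper(meta$counted_allele[m])
      if (any(!is.na(counted) & !is.na(ca) & counted != ca)) {
        stop("counted_allele disagrees between dosage header and metadata")
      }
      variants$counted_allele <- ifelse(is.na(counted), ca, counted)
    }
    for (col in intersect(c("chrom", "pos"), names(meta))) variants[[col]] <- meta[[col]][m]
  }
  colnames(dos) <- vid
  genotype_matrix(dos, variants, role)
}

#' Read genotype dosages from a VCF file
#'
#' Optional VCF ingestion for polygenic scoring: uses the `DS` (dosage)
#' FORMAT field when present, falling back to counting alternate alleles
#' in `GT`. The counted allele is the ALT allele. Requires the `vcfR`
#' package. Multi-allelic records are dropped with a message.
#'
#' @param path VCF file (plain or bgzipped).
#' @param role family role label.
#' @return A `genotype_matrix`.
#' @export
read_genotypes_vcf <- function(path, role = c("mother", "father", "child")) {
  role <- match.arg(role)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(!biallelic)) {
    message(sum(!biallelic), " multi-allelic VCF record(s) dropped")
    v <- v[biallelic, ]
    fix <- fix[biallelic, , drop = FALSE]
  }
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    D <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    D <- apply(gt, 2L, function(col) {
      vapply(strsplit(gsub("\\|", "/", col), "/", fixed = FALSE), function(a) {
        if (length(a) == 0L || anyNA(a) || any(a == ".")) NA_real_ else sum(a != "0")
      }, numeric(1))
    })
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  variants <- data.frame(variant_id = ids,
                         chrom = fix[, "CHROM"],
                         pos = as.numeric(fix[, "POS"]),
                         counted_allele = toupper(fix[, "ALT"]),
                         other_allele = toupper(fix[, "REF"]),
                         stringsAsFactors = FALSE)
  genotype_matrix(t(D), variants, role)
}

#' Write a genotype dosage TSV (round-trips with [read_genotypes()])
#' @param genotypes a `genotype_matrix`.
#' @param path dosage TSV path.
#' @param meta_path optional metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path, meta_path = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  hdr <- paste(genotypes$variants$variant_id, genotypes$variants$counted_allele, sep = ":")
  out <- data.frame(individual_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("individual_id", hdr)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(meta_path)) {
    utils::write.table(genotypes$variants, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Build polygenic-score weights from GWAS summary statistics
#'
#' Selects genome-wide significant variants (p < 5e-8 by default) and
#' clumps them at the PGS convention (r2 = 0.25 within 500 kb); the
#' surviving (variant, effect allele, GWAS beta) triples are the score
#' weights.
#'
#' @param sumstats a `sumstat_table`.
#' @param ld an [ld_source()] covering the significant variants.
#' @param p_threshold significance threshold.
#' @param r2_threshold,window_kb clumping parameters.
#' @return A `pgs_weights` data frame: `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`, `eaf`.
#' @export
build_pgs_weights <- function(sumstats, ld, p_threshold = 5e-8,
                              r2_threshold = 0.25, window_kb = 500) {
  sig <- select_instruments(sumstats, p_threshold)
  kept <- clump(sig, ld, r2_threshold = r2_threshold, window_kb = window_kb)
  out <- data.frame(variant_id = kept$variant_id,
                    effect_allele = kept$effect_allele,
                    other_allele = kept$other_allele,
                    weight = kept$beta,
                    eaf = if ("eaf" %in% names(kept)) kept$eaf else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("pgs_weights", "data.frame")
  out
}

#' Score individuals: polygenic score as a weighted sum of effect alleles
#'
#' `raw_i = sum_v weight_v * aligned_dosage_iv`, where the dosage is
#' flipped (`d -> 2 - d`) whenever the genotype's counted allele is the
#' weight's other allele. Missing dosages are imputed to `2 * eaf` from
#' the weights (falling back to the per-variant sample mean) or the
#' individual is scored on non-missing variants only, per
#' `missing_policy`. Scores are z-standardized within the genotype
#' matrix's role, since trio regressions mix roles.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights a `pgs_weights` (or data frame with `variant_id`,
#'   `effect_allele`, `weight`, optionally `other_allele`, `eaf`).
#' @param missing_policy `"impute_eaf"` (default) or `"exclude"`.
#' @param strict error (instead of warn and skip) when a weight variant is
#'   absent from the genotypes.
#' @return A `pgs_vector` data frame: `individual_id`, `raw`, `z`; with
#'   attributes `n_variants_used`, `role`, `missing_policy`.
#' @export
pgs_score <- function(genotypes, weights,
                      missing_policy = c("impute_eaf", "exclude"),
                      strict = FALSE) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(genotypes, "genotype_matrix"), is.data.frame(weights),
            all(c("variant_id", "effect_allele", "weight") %in% names(weights)))
  gv <- genotypes$variants
  m <- match(weights$variant_id, gv$variant_id)
  absent <- is.na(m)
  if (any(absent)) {
    msg <- paste0(sum(absent), " weight variant(s) absent from genotypes")
    if (strict) stop(msg)
    warning(msg, "; skipped")
  }
  use <- which(!absent)
  if (length(use) == 0L) stop("no weight variants present in genotypes")
  mi <- m[use]
  D <- genotypes$dosages[, mi, drop = FALSE]
  flip <- logical(length(use))
  for (k in seq_along(use)) {
    wa <- weights$effect_allele[use[k]]
    ca <- gv$counted_allele[mi[k]]
    if (identical(wa, ca)) {
      flip[k] <- FALSE
    } else if (identical(wa, gv$other_allele[mi[k]]) ||
               (is.na(gv$other_allele[mi[k]]) &&
                "other_allele" %in% names(weights) &&
                identical(ca, weights$other_allele[use[k]]))) {
      flip[k] <- TRUE
    } else {
      stop("cannot align alleles for variant ", weights$variant_id[use[k]])
    }
  }
  D[, flip] <- 2 - D[, flip, drop = FALSE]
  wv <- weights$weight[use]
  if (anyNA(D)) {
    if (missing_policy == "impute_eaf") {
      fill <- if ("eaf" %in% names(weights)) 2 * weights$eaf[use] else rep(NA_real_, length(use))
      # eaf refers to the effect allele, which D now counts after flipping
      smean <- colMeans(D, na.rm = TRUE)
      fill[is.na(fill)] <- smean[is.na(fill)]
      for (k in which(colSums(is.na(D)) > 0)) D[is.na(D[, k]), k] <- fill[k]
      raw <- as.numeric(D %*% wv)
    } else {
      W <- matrix(wv, nrow(D), ncol(D), byrow = TRUE)
      W[is.na(D)] <- 0
      D0 <- D; D0[is.na(D0)] <- 0
      raw <- rowSums(D0 * W)
    }
  } else {
    raw <- as.numeric(D %*% wv)
  }
  sdr <- stats::sd(raw)
  z <- if (is.na(sdr) || sdr == 0) rep(0, length(raw)) else (raw - mean(raw)) / sdr
  structure(data.frame(individual_id = rownames(genotypes$dosages),
                       raw = raw, z = z, stringsAsFactors = FALSE),
            class = c("pgs_vector", "data.frame"),
            n_variants_used = length(use),
            role = genotypes$role,
            missing_policy = missing_policy)
}
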