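#' Construct and validate a GWAS summary-statistic table
#'
#' A `sumstat_table` is a data frame of per-variant association records for
#' one trait, the basic currency of two-sample Mendelian randomization.
#' Required columns are `variant_id`, `effect_allele`, `other_allele`,
#' `beta`, `se` and `pval`; `chrom`, `pos`, `eaf`, `n`, `ncase` and
#' `ncontrol` are carried along when present.
#'
#' Validation drops (with a message) rows that violate the record
#' invariants: non-SNP or identical alleles, `se <= 0`, `pval` outside
#' \[0, 1\], `eaf` outside \[0, 1\]. Alleles are upper-cased. Indels and
#' multi-allelic sites (allele strings longer than one base) are rejected:
#' the instrument sets this package targets are biallelic SNPs.
#'
#' @param records data frame of per-variant records.
#' @param trait_label character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"`.
#' @return A `sumstat_table`: the validated data frame with attributes
#'   `trait_label`, `trait_type` and `n_dropped`.
#' @export
sumstat_table <- function(records, trait_label, trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("summary statistics lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records$variant_id <- as.character(records$variant_id)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in intersect(c("beta", "se", "pval", "eaf", "n", "pos"), names(records))) {
    records[[col]] <- as.numeric(records[[col]])
  }
  if ("chrom" %in% names(records)) records$chrom <- as.character(records$chrom)

  snp_alleles <- c("A", "C", "G", "T")
  ok <- records$effect_allele %in% snp_alleles &
    records$other_allele %in% snp_alleles &
    records$effect_allele != records$other_allele &
    is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval >= 0 & records$pval <= 1
  if ("eaf" %in% names(records)) {
    ok <- ok & (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1))
  }
  ok[is.na(ok)] <- FALSE
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    message(n_dropped, " record(s) dropped during summary-statistic validation (",
            trait_label, ")")
  }
  records <- records[ok, , drop = FALSE]

  dup <- duplicated(records$variant_id)
  if (any(dup)) {
    message(sum(dup), " duplicated variant_id(s) dropped, keeping first occurrence")
    records <- records[!dup, , drop = FALSE]
    n_dropped <- n_dropped + sum(dup)
  }
  if (nrow(records) == 0L) {
    stop("no valid summary-statistic records for trait '", trait_label, "'")
  }
  rownames(records) <- NULL
  structure(records,
            class = c("sumstat_table", "data.frame"),
            trait_label = trait_label,
            trait_type = trait_type,
            n_dropped = n_dropped)
}

# Canonical GWAS-SSF-style header -> internal names
.ssf_default_map <- c(
  variant_id = "variant_id",
  chrom = "chromosome",
  pos = "base_pair_location",
  effect_allele = "effect_allele",
  other_allele = "other_allele",
  eaf = "effect_allele_frequency",
  beta = "beta",
  se = "standard_error",
  pval = "p_value",
  n = "n"
)

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated file with a header (gzip handled transparently by
#' R's connections), maps columns to the internal schema, and validates via
#' [sumstat_table()]. The default column names follow the GWAS-SSF
#' convention (`variant_id`, `chromosome`, `base_pair_location`,
#' `effect_allele`, `other_allele`, `effect_allele_frequency`, `beta`,
#' `standard_error`, `p_value`, `n`).
#'
#' @param path file path.
#' @param column_map named character vector mapping internal names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to file column names; merged over the
#'   GWAS-SSF defaults.
#' @param trait_label,trait_type passed to [sumstat_table()].
#' @param sep field separator, tab by default.
#' @return A `sumstat_table`.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = basename(path),
                          trait_type = c("continuous", "binary"), sep = "\t") {
  trait_type <- match.arg(trait_type)
  map <- .ssf_default_map
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    map[names(column_map)] <- column_map
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), comment.char = "")
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "pval")
  for (field in required) {
    if (!map[[field]] %in% names(raw)) {
      stop("required column '", map[[field]], "' (", field, ") not found in ", path)
    }
  }
  present <- map[map %in% names(raw)]
  records <- raw[, unname(present), drop = FALSE]
  names(records) <- names(present)
  sumstat_table(records, trait_label = trait_label, trait_type = trait_type)
}

#' Write a summary-statistic table to tab-separated text
#'
#' Writes GWAS-SSF-style column names so that
#' `read_sumstats(write_sumstats(x, path))` round-trips the records.
#' Missing values are serialized as `NA`. Full numeric precision is kept
#' (up to 17 significant digits).
#'
#' @param table a `sumstat_table`.
#' @param path output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstat_table"))
  out <- as.data.frame(table)
  inv <- names(.ssf_default_map)
  keep <- intersect(inv, names(out))
  out <- out[, keep, drop = FALSE]
  names(out) <- unname(.ssf_default_map[keep])
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Select genetic instruments by p-value threshold
#'
#' Retains variants with `pval < p_threshold` (strict, matching the
#' genome-wide significance convention p < 5e-8 and the relaxed reverse-MR
#' threshold p < 5e-6), preserving input order.
#'
#' @param table a `sumstat_table`.
#' @param p_threshold significance threshold in (0, 1).
#' @return A `sumstat_table` of surviving records.
#' @export
select_instruments <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "sumstat_table"),
            is.numeric(p_threshold), length(p_threshold) == 1L,
            p_threshold > 0, p_threshold < 1)
  keep <- table$pval < p_threshold
  if (!any(keep)) {
    stop("no instruments survive the p-value threshold ",
         format(p_threshold), " for trait '", attr(table, "trait_label"), "'")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table),
            trait_label = attr(table, "trait_label"),
            trait_type = attr(table, "trait_type"))
}

#' @export
print.sumstat_table <- function(x, ...) {
  cat("GWAS summary statistics: ", attr(x, "trait_label"),
      " (", attr(x, "trait_type"), "), ", nrow(x), " variant(s)\n", sep = "")
  print(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... ", nrow(x) - 10L, " more row(s)\n", sep = "")
  invisible(x)
}
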