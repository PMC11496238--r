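#' Build an LD lookup from pairwise r2 values or reference dosages
#'
#' Linkage-disequilibrium information for clumping can come either as a
#' precomputed pairwise r-squared table or as a reference genotype dosage
#' matrix, in which case r-squared is the squared Pearson correlation of
#' dosages.
#'
#' @param x one of: a square numeric matrix with variant ids as dimnames
#'   (r-squared values); a data frame with columns `id1`, `id2`, `r2`
#'   (unlisted pairs are treated as r2 = 0); or a numeric matrix of dosages
#'   with individuals in rows and variant ids as column names (detected by
#'   `from_dosages = TRUE` or a non-square shape).
#' @param from_dosages force interpretation of a matrix as dosages.
#' @return An `ld_source` object: a symmetric r-squared matrix with unit
#'   diagonal.
#' @export
ld_source <- function(x, from_dosages = FALSE) {
  if (inherits(x, "ld_source")) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("id1", "id2", "r2") %in% names(x)))
    ids <- sort(unique(c(as.character(x$id1), as.character(x$id2))))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    i <- match(as.character(x$id1), ids)
    j <- match(as.character(x$id2), ids)
    m[cbind(i, j)] <- x$r2
    m[cbind(j, i)] <- x$r2
    diag(m) <- 1
  } else if (is.matrix(x) && !from_dosages && nrow(x) == ncol(x) &&
             !is.null(rownames(x)) && identical(rownames(x), colnames(x))) {
    m <- (x + t(x)) / 2  # enforce symmetry against rounding
    diag(m) <- 1
  } else if (is.matrix(x)) {
    if (is.null(colnames(x))) stop("dosage matrix must carry variant ids as column names")
    m <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))^2
    m[!is.finite(m)] <- 0  # monomorphic reference columns
    diag(m) <- 1
  } else {
    stop("unsupported LD source; supply an r2 matrix, an (id1, id2, r2) data frame, or a dosage matrix")
  }
  if (any(m < -1e-8 | m > 1 + 1e-8, na.rm = TRUE)) stop("r2 values must lie in [0, 1]")
  m <- pmin(pmax(m, 0), 1)
  structure(m, class = c("ld_source", "matrix"))
}

#' Read a pairwise LD table from a 3-column TSV
#'
#' @param path TSV with header columns `id1`, `id2`, `r2`.
#' @return An `ld_source`.
#' @export
read_ld <- function(path) {
  ld_source(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Greedy LD clumping of summary statistics
#'
#' Standard p-value-ordered clumping: repeatedly take the unassigned
#' variant with the lowest p-value as the index, then discard unassigned
#' variants on the same chromosome within `window_kb` of the index whose
#' r-squared with it is at least `r2_threshold`. Ties on p-value are broken
#' deterministically by (chrom, pos, variant_id). The defaults match the
#' instrument-selection convention for two-sample MR (r2 < 0.001 within
#' 10 000 kb); polygenic-score construction typically relaxes these to
#' r2 = 0.25 within 500 kb.
#'
#' @param table a `sumstat_table` carrying `chrom` and `pos`.
#' @param ld an [ld_source()] (or anything coercible by it) covering the
#'   retained variants.
#' @param r2_threshold discard when r2 >= this value.
#' @param window_kb half-width of the symmetric window around the index
#'   variant, in kilobases.
#' @param missing_ld `"drop"` (default) drops, with a warning, variants
#'   absent from the LD source; `"error"` stops.
#' @return A `sumstat_table` of index (kept) variants, in the order of the
#'   input table.
#' @export
clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000,
                  missing_ld = c("drop", "error")) {
  missing_ld <- match.arg(missing_ld)
  stopifnot(inherits(table, "sumstat_table"),
            all(c("chrom", "pos") %in% names(table)),
            r2_threshold >= 0, window_kb > 0)
  ld <- ld_source(ld)
  covered <- table$variant_id %in% rownames(ld)
  if (!all(covered)) {
    msg <- paste0(sum(!covered), " variant(s) missing from the LD source")
    if (missing_ld == "error") stop(msg)
    warning(msg, "; dropped from clumping")
    table <- table[covered, , drop = FALSE]
    if (nrow(table) == 0L) stop("no variants left to clump")
  }
  ord <- order(table$pval, table$chrom, table$pos, table$variant_id)
  ids <- table$variant_id[ord]
  chrom <- table$chrom[ord]
  pos <- table$pos[ord]
  window_bp <- window_kb * 1000
  state <- rep.int(0L, length(ids))  # 0 unassigned, 1 kept, -1 discarded
  for (k in seq_along(ids)) {
    if (state[k] != 0L) next
    state[k] <- 1L
    cand <- which(state == 0L & chrom == chrom[k] & abs(pos - pos[k]) <= window_bp)
    if (length(cand) > 0L) {
      r2 <- ld[ids[k], ids[cand]]
      state[cand[r2 >= r2_threshold]] <- -1L
    }
  }
  kept_ids <- ids[state == 1L]
  out <- table[table$variant_id %in% kept_ids, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table),
            trait_label = attr(table, "trait_label"),
            trait_type = attr(table, "trait_type"))
}
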