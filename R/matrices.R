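#' Build per-cell reference/alternative allele count matrices
#'
#' Assembles the two cell x variant count matrices (reference and
#' alternative allele counts) over the candidate variants.  The derived
#' frequency matrix is obtained with [allele_freq()]; entries with zero
#' depth are *missing*, not 0 — the germline filter counts cells with a
#' non-zero VAF among observed cells only, so conflating missing with 0
#' would change its denominator.
#'
#' @param pileup A `mito_pileup` object (its `percell` slot is used).
#' @param variants A `variant_table` data.frame.
#' @param barcodes Cell barcodes defining the rows (zero rows allowed).
#' @return An `allele_matrices` object: sparse `ref` and `alt` matrices
#'   (barcode x variant) plus the `variants` table.
#' @export
build_matrices <- function(pileup, variants, barcodes) {
  stopifnot(inherits(pileup, "mito_pileup"))
  if (nrow(variants) == 0L) stop("variant table is empty")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in whitelist")
  pc <- pileup$percell
  pc <- pc[pc$barcode %in% barcodes, , drop = FALSE]

  # A pileup row feeds every variant record matching its (pos, base) so
  # multi-allelic sites share their reference counts across records.
  fill <- function(allele) {
    grp <- split(seq_len(nrow(pc)), paste(pc$pos, pc$base))
    key_v <- paste(variants$position, allele)
    i <- j <- integer(0); x <- numeric(0)
    for (col in seq_along(key_v)) {
      rows <- grp[[key_v[col]]]
      if (is.null(rows)) next
      i <- c(i, match(pc$barcode[rows], barcodes))
      j <- c(j, rep(col, length(rows)))
      x <- c(x, pc$count[rows])
    }
    Matrix::sparseMatrix(
      i = i, j = j, x = x,
      dims = c(length(barcodes), nrow(variants)),
      dimnames = list(barcodes, variants$id)
    )
  }
  structure(list(ref = fill(variants$ref), alt = fill(variants$alt),
                 variants = variants),
            class = "allele_matrices")
}

#' Wrap simulated counts as allele matrices
#'
#' @param sim A `mito_sim` object.
#' @return An `allele_matrices` object sharing the simulated counts.
#' @export
as_allele_matrices <- function(sim) {
  stopifnot(inherits(sim, "mito_sim"))
  structure(list(ref = sim$ref_counts, alt = sim$alt_counts,
                 variants = sim$haplotypes$variants),
            class = "allele_matrices")
}

#' @export
print.allele_matrices <- function(x, ...) {
  cat("allele_matrices:", nrow(x$ref), "cells x", ncol(x$ref), "variants\n")
  invisible(x)
}

#' Variant allele frequency matrix
#'
#' `alt / (alt + ref)` per cell and variant.  Where the total count is zero
#' the frequency is undefined: `NA` under `missing = "na"` (the default,
#' required by the germline filter) or 0 under `missing = "zero"` (the
#' imputation used as clustering input, where uncovered cells behave as
#' reference).
#'
#' @param x An `allele_matrices` object.
#' @param missing `"na"` or `"zero"`.
#' @return Dense numeric matrix, cells x variants.
#' @export
allele_freq <- function(x, missing = c("na", "zero")) {
  missing <- match.arg(missing)
  ref <- as.matrix(x$ref)
  alt <- as.matrix(x$alt)
  tot <- ref + alt
  f <- alt / tot                      # 0/0 -> NaN
  f[tot == 0] <- if (missing == "na") NA_real_ else 0
  f
}

#' Write allele matrices to disk
#'
#' Emits `ref.mtx`, `alt.mtx` (MatrixMarket), sidecar `barcodes.tsv` and
#' `variants.tsv` label files, and `frequency.tsv.gz`.
#'
#' @param x An `allele_matrices` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_allele_matrices <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$ref, file.path(dir, "ref.mtx"))
  Matrix::writeMM(x$alt, file.path(dir, "alt.mtx"))
  writeLines(rownames(x$ref), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  f <- allele_freq(x)
  con <- gzfile(file.path(dir, "frequency.tsv.gz"), "w")
  utils::write.table(as.data.frame(f), con, sep = "\t", quote = FALSE,
                     col.names = NA)
  close(con)
  invisible(dir)
}

#' Read allele matrices written by [write_allele_matrices()]
#'
#' @param dir Directory holding `ref.mtx`, `alt.mtx`, `barcodes.tsv`,
#'   `variants.tsv`.
#' @return An `allele_matrices` object.
#' @export
read_allele_matrices <- function(dir) {
  ref <- methods::as(Matrix::readMM(file.path(dir, "ref.mtx")), "CsparseMatrix")
  alt <- methods::as(Matrix::readMM(file.path(dir, "alt.mtx")), "CsparseMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  variants <- utils::read.delim(file.path(dir, "variants.tsv"),
                                stringsAsFactors = FALSE)
  dimnames(ref) <- dimnames(alt) <- list(barcodes, variants$id)
  structure(list(ref = ref, alt = alt, variants = variants),
            class = "allele_matrices")
}
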