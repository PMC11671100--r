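# Shared fixture builders (everything is generated in code at test time).

# Small allele_matrices from explicit dense matrices.
make_mats <- function(ref, alt, ids = NULL) {
  ids <- ids %||% sprintf("v%d", seq_len(ncol(ref)))
  bcs <- rownames(ref) %||% sprintf("BC%03d", seq_len(nrow(ref)))
  dimnames(ref) <- dimnames(alt) <- list(bcs, ids)
  structure(list(
    ref = methods::as(Matrix::Matrix(ref, sparse = TRUE), "CsparseMatrix"),
    alt = methods::as(Matrix::Matrix(alt, sparse = TRUE), "CsparseMatrix"),
    variants = data.frame(id = ids)
  ), class = "allele_matrices")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ad-hoc cluster model for score_cells.
make_model <- function(labels, sets, alpha, beta = 1) {
  list(K = length(sets), labels = labels, variant_sets = sets,
       alpha = alpha, beta = beta)
}

# Random frequency matrix with missing entries, for brute-force checks.
random_freq <- function(n, m, seed) {
  withr::with_seed(seed, {
    vals <- c(NA, 0, 0.003, 0.3, 0.5, 0.985, 0.995, 1)
    matrix(sample(vals, n * m, replace = TRUE), n, m,
           dimnames = list(sprintf("c%d", 1:n), sprintf("v%d", 1:m)))
  })
}

# Quick seeded pool simulation.
quick_sim <- function(n_donors, cells = 50, reads = 2000, doublets = 0,
                      error = 0, seed = 1, n_shared = 0) {
  hap <- simulate_haplotypes(n_donors, c(5L, 30L), n_shared = n_shared,
                             seed = seed)
  simulate_cells(hap, cells, reads, doublets, error, seed = seed)
}

# Minimal SAM writer for hand-built read fixtures.
write_toy_sam <- function(path, records, contig = "chrM") {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, 16569L),
               records), path)
}

# One SAM record: single-end, CIGAR <len>M.
sam_read <- function(qname, pos, seq, qual, barcode, flag = 0L,
                     contig = "chrM") {
  sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tCB:Z:%s",
          qname, flag, contig, pos, nchar(seq), seq, qual, barcode)
}
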