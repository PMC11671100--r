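#' Simulate donor mitochondrial haplotypes
#'
#' Draws a set of homoplasmic germline variants for each of `n_donors`
#' genetically distinct donors.  Each donor carries a private set of variants
#' (pairwise disjoint across donors, sampled without replacement from the
#' 16,569 bp mitochondrial circle) plus, optionally, variants shared by two
#' or more donors.  Shared variants emulate common haplogroup polymorphisms
#' that must be removed before doublet detection.
#'
#' @param n_donors Number of pooled donors (>= 1).
#' @param n_private Number of private variants per donor; either a single
#'   integer or a length-2 range `c(min, max)` from which each donor's count
#'   is drawn uniformly.  Default `c(5L, 30L)`.
#' @param n_shared Number of variants shared by two or more donors.
#' @param seed Optional integer seed; the same seed reproduces the same
#'   haplotypes exactly.
#' @param reference Optional mitochondrial reference (character scalar,
#'   vector of bases, or `Biostrings::DNAString`) from which reference
#'   alleles are taken; when `NULL`, reference bases are sampled.
#' @return A `mito_haplotypes` object: a list with `n_donors`, `donor_ids`,
#'   `variants` (data.frame: id, position, ref, alt, type) and `carriers`
#'   (donors x variants logical matrix).
#' @export
simulate_haplotypes <- function(n_donors, n_private = c(5L, 30L), n_shared = 0L,
                                seed = NULL, reference = NULL) {
  if (n_donors < 1L) stop("n_donors must be >= 1")
  if (length(n_private) == 1L) n_private <- rep(n_private, 2L)
  n_private <- as.integer(sort(n_private))
  if (any(n_private < 0L) || n_shared < 0L) stop("variant counts must be non-negative")
  if (n_donors * n_private[2L] + n_shared > MT_LENGTH) {
    stop("requested more variants than positions on the ", MT_LENGTH,
         " bp mitochondrial genome")
  }
  if (!is.null(reference)) reference <- .reference_bases(reference)

  withr::with_seed(seed, {
    per_donor <- if (n_private[1L] == n_private[2L]) {
      rep(n_private[1L], n_donors)
    } else {
      sample(seq(n_private[1L], n_private[2L]), n_donors, replace = TRUE)
    }
    n_var <- sum(per_donor) + n_shared
    positions <- sort(sample.int(MT_LENGTH, n_var))
    ref <- if (is.null(reference)) {
      sample(BASES, n_var, replace = TRUE)
    } else {
      reference[positions]
    }
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1L))

    carriers <- matrix(FALSE, nrow = n_donors, ncol = n_var)
    type <- rep("shared", n_var)
    idx <- sample.int(n_var)                       # shuffle positions over roles
    private_idx <- idx[seq_len(sum(per_donor))]
    shared_idx <- setdiff(idx, private_idx)
    owner <- rep(seq_len(n_donors), per_donor)
    carriers[cbind(owner, private_idx)] <- TRUE
    type[private_idx] <- "private"
    for (j in shared_idx) {
      k <- if (n_donors >= 2L) {
        sizes <- seq(2L, n_donors)          # sample() would misread a scalar
        sizes[sample.int(length(sizes), 1L)]
      } else 1L
      carriers[sample.int(n_donors, k), j] <- TRUE
    }

    donor_ids <- sprintf("donor%d", seq_len(n_donors))
    variants <- data.frame(
      id = variant_id(positions, ref, alt),
      position = positions, ref = ref, alt = alt, type = type,
      stringsAsFactors = FALSE
    )
    dimnames(carriers) <- list(donor_ids, variants$id)
    structure(
      list(n_donors = n_donors, donor_ids = donor_ids,
           variants = variants, carriers = carriers),
      class = "mito_haplotypes"
    )
  })
}

#' @export
print.mito_haplotypes <- function(x, ...) {
  cat("mito_haplotypes:", x$n_donors, "donors,",
      sum(x$variants$type == "private"), "private +",
      sum(x$variants$type == "shared"), "shared variants\n")
  invisible(x)
}

#' Private variant ids of one donor
#' @param haplotypes A `mito_haplotypes` object.
#' @param donor Donor index or id.
#' @return Character vector of variant ids private to that donor.
#' @export
private_variants <- function(haplotypes, donor) {
  priv <- haplotypes$variants$type == "private"
  haplotypes$variants$id[priv & haplotypes$carriers[donor, ]]
}

#' Simulate a pooled single-cell mitochondrial dataset
#'
#' Generates per-cell reference/alternative allele counts over the simulated
#' variants, then forms doublets by merging the counts of two uniformly
#' chosen parent cells (parents are removed, so the output barcode count
#' equals `n_donors * cells_per_donor`).  Per-cell, per-variant sequencing
#' depth is Poisson with mean `reads_per_cell * 4 / 1000` (1000 mitochondrial
#' reads per cell correspond to roughly 4x mean coverage).  Base errors flip
#' alleles independently with probability `error_rate`.
#'
#' @param haplotypes A `mito_haplotypes` object.
#' @param cells_per_donor Singlet cells per donor.
#' @param reads_per_cell Mitochondrial reads per cell (250-2000 covers the
#'   depth range usually seen in mtscATAC-seq libraries).
#' @param doublet_fraction Fraction of output barcodes that are doublets
#'   (in `[0, 1)`).
#' @param error_rate Per-base substitution error rate; default 0.002.
#' @param seed Optional integer seed.
#' @return A `mito_sim` object: `haplotypes`, `truth` (data.frame: barcode,
#'   kind, donor1, donor2), `ref_counts`/`alt_counts` (sparse barcode x
#'   variant matrices), `parents` (the two parent count matrices and pairing,
#'   kept so doublet conservation can be audited), and `params`.
#' @export
simulate_cells <- function(haplotypes, cells_per_donor, reads_per_cell,
                           doublet_fraction = 0, error_rate = 0.002,
                           seed = NULL) {
  stopifnot(inherits(haplotypes, "mito_haplotypes"))
  .assert_proportion(error_rate, "error_rate")
  if (doublet_fraction < 0 || doublet_fraction >= 1) {
    stop("doublet_fraction must be in [0, 1)")
  }
  if (reads_per_cell <= 0) stop("reads_per_cell must be positive")
  n_donors <- haplotypes$n_donors
  n0 <- n_donors * cells_per_donor
  n_dbl <- as.integer(round(doublet_fraction * n0))
  if (doublet_fraction > 0 && n0 + n_dbl < 2L) {
    stop("need at least 2 cells to form doublets")
  }
  mean_depth <- reads_per_cell * 4 / 1000
  vid <- haplotypes$variants$id
  n_var <- length(vid)

  withr::with_seed(seed, {
    # parent singlets: the advertised cells plus one extra per doublet
    donors <- c(rep(seq_len(n_donors), each = cells_per_donor),
                sample.int(n_donors, n_dbl, replace = TRUE))
    m <- n0 + n_dbl
    depth <- matrix(stats::rpois(m * n_var, mean_depth), nrow = m)
    carried <- haplotypes$carriers[donors, , drop = FALSE]
    flips <- matrix(stats::rbinom(m * n_var, depth, error_rate), nrow = m)
    alt <- ifelse(carried, depth - flips, flips)
    ref <- depth - alt

    if (n_dbl > 0L) {
      pids <- sample.int(m, 2L * n_dbl)      # uniform pairing over all cells
      p1 <- pids[seq_len(n_dbl)]
      p2 <- pids[n_dbl + seq_len(n_dbl)]
      dbl_ref <- ref[p1, , drop = FALSE] + ref[p2, , drop = FALSE]
      dbl_alt <- alt[p1, , drop = FALSE] + alt[p2, , drop = FALSE]
      keep <- setdiff(seq_len(m), pids)
    } else {
      p1 <- p2 <- integer(0)
      dbl_ref <- dbl_alt <- matrix(0L, 0L, n_var)
      keep <- seq_len(m)
    }

    out_ref <- rbind(ref[keep, , drop = FALSE], dbl_ref)
    out_alt <- rbind(alt[keep, , drop = FALSE], dbl_alt)
    n_out <- nrow(out_ref)
    barcodes <- sprintf("BC%06d", seq_len(n_out))
    dimnames(out_ref) <- dimnames(out_alt) <- list(barcodes, vid)

    ids <- haplotypes$donor_ids
    truth <- data.frame(
      barcode = barcodes,
      kind = c(rep("singlet", length(keep)), rep("doublet", n_dbl)),
      donor1 = c(ids[donors[keep]], ids[donors[p1]]),
      donor2 = c(rep(NA_character_, length(keep)), ids[donors[p2]]),
      stringsAsFactors = FALSE
    )

    parents <- NULL
    if (n_dbl > 0L) {
      parents <- list(
        ref1 = ref[p1, , drop = FALSE], alt1 = alt[p1, , drop = FALSE],
        ref2 = ref[p2, , drop = FALSE], alt2 = alt[p2, , drop = FALSE],
        donor1 = ids[donors[p1]], donor2 = ids[donors[p2]]
      )
    }

    structure(
      list(haplotypes = haplotypes, truth = truth,
           ref_counts = methods::as(Matrix::Matrix(out_ref, sparse = TRUE), "CsparseMatrix"),
           alt_counts = methods::as(Matrix::Matrix(out_alt, sparse = TRUE), "CsparseMatrix"),
           parents = parents,
           params = list(n_donors = n_donors, cells_per_donor = cells_per_donor,
                         reads_per_cell = reads_per_cell,
                         doublet_fraction = doublet_fraction,
                         error_rate = error_rate, seed = seed)),
      class = "mito_sim"
    )
  })
}

#' @export
print.mito_sim <- function(x, ...) {
  cat("mito_sim:", nrow(x$truth), "barcodes (",
      sum(x$truth$kind == "doublet"), "doublets ),",
      ncol(x$ref_counts), "variants,",
      x$params$n_donors, "donors\n")
  invisible(x)
}

#' Ground-truth class labels of a simulated dataset
#'
#' Singlets are labelled with their donor id, doublets with `"doublet"`;
#' this is the truth vector the evaluation metrics consume.
#'
#' @param sim A `mito_sim` object.
#' @return Named character vector (names are barcodes).
#' @export
truth_labels <- function(sim) {
  lab <- ifelse(sim$truth$kind == "doublet", "doublet", sim$truth$donor1)
  stats::setNames(lab, sim$truth$barcode)
}

#' Write a simulated dataset to disk
#'
#' Emits `truth.tsv`, `ref.mtx`, `alt.mtx`, `barcodes.tsv` and
#' `variants.tsv` under `dir`.
#'
#' @param sim A `mito_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mat <- as_allele_matrices(sim)
  write_allele_matrices(mat, dir)
  invisible(dir)
}

#' Synthetic mitochondrial reference sequence
#'
#' Generates a random 16,569 bp sequence standing in for a mitochondrial
#' reference in read-level simulations and pileup tests (the real rCRS is
#' not shipped).  When `variants` is supplied, the recorded reference
#' alleles are written into the sequence so pileups against it are
#' consistent with the simulated haplotypes.
#'
#' @param seed Optional integer seed.
#' @param variants Optional variant data.frame with `position` and `ref`
#'   columns (e.g. `haplotypes$variants`).
#' @return Character vector of 16,569 single bases.
#' @export
synthetic_mito_reference <- function(seed = NULL, variants = NULL) {
  ref <- withr::with_seed(seed, sample(BASES, MT_LENGTH, replace = TRUE))
  if (!is.null(variants)) ref[variants$position] <- variants$ref
  ref
}

#' Write a simulated dataset as a toy SAM file
#'
#' Read-level export used to exercise the pileup stage end-to-end: every
#' counted allele becomes one single-base read (CIGAR `1M`) carrying the
#' cell barcode in the `CB` tag.  Optionally appends duplicate-flagged
#' copies of the first reads to exercise flag filtering.
#'
#' @param sim A `mito_sim` object.
#' @param path Output SAM path.
#' @param contig Mitochondrial contig name written to the header.
#' @param base_quality Phred quality assigned to every base.
#' @param n_duplicates Number of duplicate-flagged extra records to append.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(sim, path, contig = "chrM", base_quality = 37L,
                          n_duplicates = 0L) {
  v <- sim$haplotypes$variants
  ref <- as.matrix(sim$ref_counts)
  alt <- as.matrix(sim$alt_counts)
  bcs <- rownames(ref)
  qchar <- rawToChar(as.raw(base_quality + 33L))

  recs <- character(0)
  emit <- function(counts, base_by_var) {
    nz <- which(counts > 0L, arr.ind = TRUE)
    if (nrow(nz) == 0L) return(character(0))
    n <- counts[nz]
    i <- rep(nz[, 1L], n)
    j <- rep(nz[, 2L], n)
    sprintf("r%07d\t0\t%s\t%d\t60\t1M\t*\t0\t0\t%s\t%s\tCB:Z:%s",
            seq_along(i) + length(recs), contig, v$position[j],
            base_by_var[j], qchar, bcs[i])
  }
  recs <- c(emit(ref, v$ref), emit(alt, v$alt))
  recs <- sprintf("r%07d%s", seq_along(recs), sub("^r[0-9]+", "", recs))
  if (n_duplicates > 0L) {
    dup <- recs[seq_len(min(n_duplicates, length(recs)))]
    dup <- sub("^(r[0-9]+)\t0\t", "\\1dup\t1024\t", dup)
    recs <- c(recs, dup)
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contig, MT_LENGTH))
  ord <- order(as.integer(sub("^[^\t]*\t[^\t]*\t[^\t]*\t([0-9]+)\t.*", "\\1", recs)))
  writeLines(c(header, recs[ord]), path)
  invisible(path)
}
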