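#' Extract barcoded mitochondrial reads from a BAM/SAM file
#'
#' Reads aligned records on the mitochondrial contig and explodes them into
#' per-aligned-base records `(barcode, pos, base, qual)`.  Duplicate,
#' secondary and supplementary alignments are excluded.  Cell barcodes are
#' taken from a tag (default `CB`) or, failing that, extracted from the read
#' name with `barcode_regex` (first capture group).  Local realignment
#' around indels (e.g. GATK IndelRealigner) is a recommended external
#' pre-step for aligner artifact reduction; any coordinate-sorted BAM is
#' accepted.
#'
#' @param path BAM or SAM file (SAM is converted and indexed on the fly).
#' @param contig Mitochondrial contig name; by default `"chrM"`/`"MT"` are
#'   tried against the header.
#' @param barcode_tag BAM tag holding the cell barcode (default `"CB"`).
#' @param barcode_regex Optional regex with one capture group applied to
#'   read names when the tag is absent.
#' @param valid_barcodes Optional barcode whitelist (character vector or a
#'   path to a one-per-line text file, optionally gzipped).
#' @return A `mito_reads` data.frame with columns barcode, pos, base, qual.
#' @export
extract_mito_reads <- function(path, contig = NULL, barcode_tag = "CB",
                               barcode_regex = NULL, valid_barcodes = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai")) &&
             !file.exists(sub("\\.bam$", ".bai", path))) {
    stop("BAM index missing for ", path, "; run samtools index first")
  }
  header <- Rsamtools::scanBamHeader(path)[[1L]]$targets
  if (!is.null(contig)) {
    if (!contig %in% names(header)) {
      stop("contig '", contig, "' not found in BAM header")
    }
  } else {
    candidates <- c("chrM", "MT", "chrMT", "M")
    contig <- candidates[candidates %in% names(header)][1L]
    if (is.na(contig)) {
      stop("mitochondrial contig not found in BAM header (looked for ",
           paste(candidates, collapse = ", "), ")")
    }
  }

  which <- GenomicRanges::GRanges(contig, IRanges::IRanges(1L, header[[contig]]))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "pos", "cigar", "seq", "qual"),
    tag = barcode_tag,
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    which = which
  )
  rec <- Rsamtools::scanBam(path, param = param)[[1L]]
  empty <- structure(
    data.frame(barcode = character(0), pos = integer(0),
               base = character(0), qual = integer(0)),
    class = c("mito_reads", "data.frame")
  )
  if (length(rec$pos) == 0L) return(empty)

  barcode <- rec$tag[[barcode_tag]]
  if (is.null(barcode) || all(is.na(barcode))) {
    if (is.null(barcode_regex)) {
      stop("no '", barcode_tag, "' tag found and no barcode_regex given")
    }
    m <- regmatches(rec$qname, regexec(barcode_regex, rec$qname))
    barcode <- vapply(m, function(x) if (length(x) >= 2L) x[2L] else NA_character_,
                      character(1L))
    if (all(is.na(barcode))) stop("barcode_regex matched no read names")
  }

  # Map aligned query bases to reference positions through the CIGAR.
  ops <- c("M", "=", "X")
  ref_rl <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    rec$cigar, pos = rec$pos, ops = ops)
  qry_rl <- GenomicAlignments::cigarRangesAlongQuerySpace(rec$cigar, ops = ops)
  ref_u <- unlist(ref_rl, use.names = FALSE)
  qry_u <- unlist(qry_rl, use.names = FALSE)
  rid <- rep(seq_along(rec$cigar), S4Vectors::elementNROWS(ref_rl))
  w <- IRanges::width(ref_u)
  keep <- w > 0L
  ref_u <- ref_u[keep]; qry_u <- qry_u[keep]; rid <- rid[keep]; w <- w[keep]

  pos <- sequence(w, from = IRanges::start(ref_u))
  qidx <- sequence(w, from = IRanges::start(qry_u))
  rr <- rep(rid, w)

  seqs <- as.character(rec$seq)
  base <- substring(seqs[rr], qidx, qidx)
  quals <- as.character(rec$qual)
  qchr <- substring(quals[rr], qidx, qidx)
  qual <- match(qchr, rawToChar(as.raw(33:126), multiple = TRUE)) - 1L

  df <- data.frame(barcode = barcode[rr], pos = pos, base = base, qual = qual,
                   stringsAsFactors = FALSE)
  df <- df[df$base %in% BASES & !is.na(df$barcode) &
             df$pos >= 1L & df$pos <= MT_LENGTH, , drop = FALSE]
  if (!is.null(valid_barcodes)) {
    if (is.character(valid_barcodes) && length(valid_barcodes) == 1L &&
        file.exists(valid_barcodes)) {
      valid_barcodes <- readLines(gzfile(valid_barcodes))
    }
    df <- df[df$barcode %in% valid_barcodes, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("mito_reads", "data.frame")
  df
}

#' Barcode-aware mitochondrial pileup
#'
#' Tallies base counts per position, both in bulk and per cell barcode,
#' after discarding bases below `min_base_quality`.  Bulk counts equal the
#' per-barcode counts summed over barcodes by construction.
#'
#' @param reads A `mito_reads` data.frame from [extract_mito_reads()].
#' @param reference Mitochondrial reference sequence (16,569 bases;
#'   character scalar/vector or `Biostrings::DNAString`).
#' @param min_base_quality Minimum phred base quality (default 20).
#' @return A `mito_pileup` object: `bulk` (16,569 x 4 count matrix with
#'   columns A/C/G/T), `percell` (data.frame barcode, pos, base, count),
#'   `reference` (base vector) and `min_base_quality`.
#' @export
pileup <- function(reads, reference, min_base_quality = 20L) {
  reference <- .reference_bases(reference)
  reads <- reads[reads$qual >= min_base_quality, , drop = FALSE]

  bulk <- matrix(0L, nrow = MT_LENGTH, ncol = 4L, dimnames = list(NULL, BASES))
  percell <- data.frame(barcode = character(0), pos = integer(0),
                        base = character(0), count = integer(0),
                        stringsAsFactors = FALSE)
  if (nrow(reads) > 0L) {
    bidx <- match(reads$base, BASES)
    flat <- (bidx - 1L) * MT_LENGTH + reads$pos
    tab <- tabulate(flat, nbins = 4L * MT_LENGTH)
    bulk[] <- tab

    key <- paste(reads$barcode, reads$pos, reads$base, sep = "\t")
    tt <- table(key)
    parts <- strsplit(names(tt), "\t", fixed = TRUE)
    percell <- data.frame(
      barcode = vapply(parts, `[`, character(1L), 1L),
      pos = as.integer(vapply(parts, `[`, character(1L), 2L)),
      base = vapply(parts, `[`, character(1L), 3L),
      count = as.integer(tt),
      stringsAsFactors = FALSE
    )
    percell <- percell[order(percell$pos, percell$barcode, percell$base), ]
    rownames(percell) <- NULL
  }
  structure(list(bulk = bulk, percell = percell, reference = reference,
                 min_base_quality = min_base_quality),
            class = "mito_pileup")
}

#' @export
print.mito_pileup <- function(x, ...) {
  cat("mito_pileup:", sum(x$bulk), "bases over",
      sum(rowSums(x$bulk) > 0), "covered positions,",
      length(unique(x$percell$barcode)), "barcodes\n")
  invisible(x)
}

#' Call candidate mitochondrial SNVs from a bulk pileup
#'
#' VarScan-style single-sample SNV calling: a `(position, alt)` pair is
#' emitted iff bulk depth >= `min_depth`, alternative reads >= `min_reads2`
#' and bulk VAF >= `min_var_freq`.  Because the bulk mixes several donors,
#' only variants with bulk VAF strictly inside `vaf_window` (default
#' 1%-99%) are retained as potential germline variants: a variant private
#' to one donor of a pool sits at an intermediate bulk VAF, while
#' pool-wide homoplasmies and sequencing noise sit at the edges.  SNVs
#' only; each alt base at a position is an independent record.
#'
#' @param pileup A `mito_pileup` object.
#' @param min_var_freq Minimum bulk VAF (default 0.01).
#' @param min_depth Minimum bulk depth (default 8).
#' @param min_reads2 Minimum supporting alternative reads (default 2).
#' @param vaf_window Open interval for the bulk VAF (default `c(0.01, 0.99)`).
#' @return A `variant_table` data.frame: id, position, ref, alt,
#'   bulk_depth, bulk_alt_count, bulk_vaf.
#' @export
call_variants <- function(pileup, min_var_freq = 0.01, min_depth = 8L,
                          min_reads2 = 2L, vaf_window = c(0.01, 0.99)) {
  stopifnot(inherits(pileup, "mito_pileup"))
  if (min_depth <= 0L || min_reads2 <= 0L || min_var_freq <= 0) {
    stop("thresholds must be positive")
  }
  bulk <- pileup$bulk
  depth <- rowSums(bulk)
  refb <- pileup$reference

  nz <- which(bulk > 0L, arr.ind = TRUE)
  pos <- nz[, 1L]
  alt <- BASES[nz[, 2L]]
  keep <- alt != refb[pos]
  pos <- pos[keep]; alt <- alt[keep]
  cnt <- bulk[cbind(pos, match(alt, BASES))]
  dp <- depth[pos]
  vaf <- cnt / dp

  ok <- dp >= min_depth & cnt >= min_reads2 & vaf >= min_var_freq &
    vaf > vaf_window[1L] & vaf < vaf_window[2L]
  ord <- order(pos[ok], alt[ok])
  out <- data.frame(
    id = variant_id(pos[ok], refb[pos[ok]], alt[ok]),
    position = pos[ok], ref = refb[pos[ok]], alt = alt[ok],
    bulk_depth = as.integer(dp[ok]), bulk_alt_count = as.integer(cnt[ok]),
    bulk_vaf = vaf[ok], stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Write a variant table as TSV and minimal VCF
#'
#' @param variants A `variant_table` data.frame.
#' @param tsv Output TSV path (`NULL` to skip).
#' @param vcf Output VCF path (`NULL` to skip); records CHROM, POS, REF,
#'   ALT and INFO `DP`/`AF`.
#' @param contig Contig name written into the VCF.
#' @return Invisibly, the paths written.
#' @export
write_variants <- function(variants, tsv = NULL, vcf = NULL, contig = "chrM") {
  if (!is.null(tsv)) {
    utils::write.table(variants, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(vcf)) {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", contig, MT_LENGTH),
             "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Bulk depth\">",
             "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Bulk variant allele frequency\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\tDP=%d;AF=%.6g",
                    contig, variants$position, variants$id, variants$ref,
                    variants$alt, variants$bulk_depth, variants$bulk_vaf)
    writeLines(c(hdr, body), vcf)
  }
  invisible(c(tsv = tsv, vcf = vcf))
}
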