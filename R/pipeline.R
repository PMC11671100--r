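#' Pipeline configuration
#'
#' Collects every tunable parameter with its default.  Defaults follow
#' the method's standard settings: VarScan-style calling thresholds
#' (`min_var_freq` 0.01, `min_depth` 8, `min_reads2` 2), the 1%-99% bulk
#' VAF window, the 99%/50% germline homoplasmy rule, K-means with 10
#' restarts, the Beta(alpha, 1) posterior with `p1`/`p2` thresholds
#' 0.99/0.01 and 0.8/0.2, and 5-nearest-neighbour rescue.  `trust_p1` is
#' on by default: singlets are called from `p1` alone, the recommended
#' setting because shared somatic mutations can inflate `p2` past 0.01
#' even for clean singlets.
#'
#' @param ... Overrides of any default (unknown names are an error).
#' @return A `demux_config` list.
#' @export
demux_config <- function(...) {
  cfg <- list(
    contig = NULL, barcode_tag = "CB", barcode_regex = NULL,
    min_base_quality = 20L,
    min_var_freq = 0.01, min_depth = 8L, min_reads2 = 2L,
    vaf_window = c(0.01, 0.99),
    homoplasmy = 0.99, min_fraction = 0.5, min_carrier_fraction = 0.5,
    K = NULL, k_range = 2:12, method = "kmeans", seed = 42L,
    max_sets = 1L, direct_fallback = TRUE,
    first = "label",
    p1_singlet = 0.99, p2_singlet = 0.01,
    p1_doublet = 0.8, p2_doublet = 0.2,
    knn_k = 5L, trust_p1 = TRUE,
    direct = FALSE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "demux_config")
}

#' Demultiplex a pool from allele count matrices
#'
#' In-memory core pipeline: germline filtering, genotype clustering (or
#' direct variant clustering), beta-binomial scoring, singlet/doublet
#' classification and donor assignment.
#'
#' @param mat An `allele_matrices` object.
#' @param K Number of pooled donors; `NULL` to estimate by silhouette.
#' @param config A [demux_config()] (K given here overrides the config).
#' @return A `demux_run` list: `result` (a `demux_result`), `model`
#'   (`genotype_clusters`, or the direct-mode sets), `scores`, `config`.
#' @export
demux_pool <- function(mat, K = NULL, config = demux_config()) {
  cfg <- config
  K <- K %||% cfg$K
  direct <- function(K) {
    scores <- demux_direct(mat, K, seed = cfg$seed,
                           homoplasmy = cfg$homoplasmy,
                           min_fraction = cfg$min_fraction,
                           min_carrier_fraction = cfg$min_carrier_fraction)
    list(scores = scores,
         model = list(K = K, variant_sets = attr(scores, "variant_sets"),
                      alpha = attr(scores, "alpha"), direct = TRUE))
  }
  if (isTRUE(cfg$direct)) {
    if (is.null(K)) stop("direct mode requires K")
    fit <- direct(K)
  } else {
    fit <- tryCatch({
      model <- fit_genotypes(mat, K = K, k_range = cfg$k_range,
                             method = cfg$method, seed = cfg$seed,
                             homoplasmy = cfg$homoplasmy,
                             min_fraction = cfg$min_fraction,
                             min_carrier_fraction = cfg$min_carrier_fraction,
                             max_sets = cfg$max_sets)
      list(scores = score_cells(mat, model, first = cfg$first), model = model)
    }, error = function(e) {
      # cell clustering collapsed (a cluster without sample-specific
      # variants): fall back to clustering the variants instead
      if (!isTRUE(cfg$direct_fallback) || is.null(K) ||
          !grepl("sample-specific|empty", conditionMessage(e))) stop(e)
      warning("initial cell clustering left cluster(s) without ",
              "sample-specific variants; falling back to direct mode")
      direct(K)
    })
  }
  scores <- fit$scores
  model <- fit$model
  scores <- classify_cells(scores,
                           p1_singlet = cfg$p1_singlet,
                           p2_singlet = cfg$p2_singlet,
                           p1_doublet = cfg$p1_doublet,
                           p2_doublet = cfg$p2_doublet,
                           knn_k = cfg$knn_k, trust_p1 = cfg$trust_p1,
                           seed = cfg$seed)
  result <- assign_singlets(scores)
  structure(list(result = result, model = model, scores = scores,
                 config = cfg),
            class = "demux_run")
}

#' @export
print.demux_run <- function(x, ...) {
  tab <- table(x$result$label)
  cat("demux_run: K =", x$model$K, "|",
      paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  invisible(x)
}

#' Run the full demultiplexing pipeline on files
#'
#' End-to-end orchestration: barcode-aware pileup of the alignment file,
#' variant calling, allele matrix construction, genotype clustering,
#' doublet detection and donor assignment.  All artifacts (variant table,
#' matrices, model, `demux_result.tsv`, the effective configuration and a
#' stage-timing log) are written under `out_dir`.  Alternatively a
#' directory of precomputed matrices (as written by
#' [write_allele_matrices()]) may be given instead of an alignment file.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM (or SAM) file, or
#'   `NULL` when `matrices_dir` is given.
#' @param reference Mitochondrial reference sequence or FASTA path
#'   (required with `bam`).
#' @param barcodes Barcode whitelist (vector or file path), required with
#'   `bam`.
#' @param matrices_dir Directory of precomputed `ref.mtx`/`alt.mtx`.
#' @param out_dir Output directory.
#' @param K Number of pooled donors; `NULL` to estimate.
#' @param config A [demux_config()].
#' @return The `demux_run`, invisibly; artifacts are in `out_dir`.
#' @export
run_pipeline <- function(bam = NULL, reference = NULL, barcodes = NULL,
                         matrices_dir = NULL, out_dir, K = NULL,
                         config = demux_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  stamp <- function(stage, detail) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, detail)
    message(line)
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stamp(stage, paste("FAILED -", conditionMessage(e)))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stamp(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    out
  }

  cfg <- config
  if (!is.null(K)) cfg$K <- K

  if (!is.null(matrices_dir)) {
    mat <- run_stage("read_matrices", read_allele_matrices(matrices_dir))
  } else {
    if (is.null(bam)) stop("give either a BAM/SAM file or a matrices_dir")
    if (is.null(reference)) stop("a mitochondrial reference is required with a BAM")
    if (is.character(reference) && length(reference) == 1L &&
        file.exists(reference)) {
      reference <- Biostrings::readDNAStringSet(reference)[[1L]]
    }
    if (is.character(barcodes) && length(barcodes) == 1L &&
        file.exists(barcodes)) {
      barcodes <- readLines(gzfile(barcodes))
    }
    reads <- run_stage("extract_reads", extract_mito_reads(
      bam, contig = cfg$contig, barcode_tag = cfg$barcode_tag,
      barcode_regex = cfg$barcode_regex, valid_barcodes = barcodes))
    pl <- run_stage("pileup", pileup(reads, reference, cfg$min_base_quality))
    variants <- run_stage("call_variants", call_variants(
      pl, min_var_freq = cfg$min_var_freq, min_depth = cfg$min_depth,
      min_reads2 = cfg$min_reads2, vaf_window = cfg$vaf_window))
    stamp("call_variants", paste(nrow(variants), "candidate variants"))
    if (is.null(barcodes)) barcodes <- sort(unique(reads$barcode))
    mat <- run_stage("build_matrices", build_matrices(pl, variants, barcodes))
    write_variants(variants, tsv = file.path(out_dir, "variants_called.tsv"),
                   vcf = file.path(out_dir, "variants_called.vcf"))
  }
  write_allele_matrices(mat, file.path(out_dir, "matrices"))

  run <- run_stage("demux", demux_pool(mat, K = cfg$K, config = cfg))
  if (inherits(run$model, "genotype_clusters")) {
    write_genotype_model(run$model, out_dir, variants = mat$variants)
  }
  write_demux_result(run$result, file.path(out_dir, "demux_result.tsv"))
  cfg_json <- cfg
  cfg_json$k_range <- as.integer(cfg_json$k_range)
  jsonlite::write_json(cfg_json[!vapply(cfg_json, is.null, logical(1L))],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  stamp("summary", paste(nrow(run$result), "cells |",
                         sum(run$result$label == "Singlet"), "singlets |",
                         sum(run$result$label == "Doublet"), "doublets"))
  invisible(run)
}
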