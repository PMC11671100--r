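#' Select high-confidence germline variants
#'
#' A variant is retained iff, among cells with a non-zero VAF at that
#' variant, the proportion with VAF above the homoplasmy cutoff exceeds
#' `min_fraction`:
#' `|cells VAF > 0.99| / |cells VAF > 0| > 0.5` by default.  Inherited
#' mitochondrial variants are homoplasmic (VAF ~ 1) in essentially every
#' carrier cell, so this keeps germline variants while discarding
#' low-coverage sites and low-VAF somatic variants.  Ratios are computed
#' over non-missing (covered) cells only; variants with no non-zero cell
#' are dropped.
#'
#' @param freq Frequency matrix with `NA` marking zero-depth entries
#'   (see [allele_freq()]).
#' @param homoplasmy VAF cutoff counting a cell as homoplasmic
#'   (strictly `>`; default 0.99).
#' @param min_fraction Required homoplasmic fraction among non-zero cells
#'   (strictly `>`; default 0.5).
#' @return Character vector of retained variant ids (column names).
#' @export
filter_germline <- function(freq, homoplasmy = 0.99, min_fraction = 0.5) {
  if (is.null(dim(freq)) || nrow(freq) == 0L || ncol(freq) == 0L) {
    stop("frequency matrix is empty")
  }
  nz <- colSums(freq > 0, na.rm = TRUE)
  hi <- colSums(freq > homoplasmy, na.rm = TRUE)
  keep <- nz > 0 & hi / nz > min_fraction
  colnames(freq)[keep]
}

# K-means with k-means++ seeding: D^2-weighted sampling of initial
# centers, `n_init` independent restarts, best total within-SS kept.
# Plain random restarts frequently split a variant-rich donor while
# merging two variant-poor ones on VAF block matrices.
.kmeans_pp <- function(x, K, max_iter = 1000L, n_init = 10L) {
  n <- nrow(x)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- matrix(NA_real_, K, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (k in seq_len(K - 1L) + 1L) {
      if (all(d2 == 0)) {
        pick <- sample.int(n, 1L)
      } else {
        pick <- sample.int(n, 1L, prob = d2)
      }
      centers[k, ] <- x[pick, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[k, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = max_iter)
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Initial genotype clustering of cells
#'
#' Clusters cells into `K` genotypes from their VAF profiles over the
#' retained germline variants, by K-means (default) or a Gaussian mixture
#' model.  Missing frequencies are imputed as 0 for clustering (uncovered
#' cells behave as reference).  K-means uses `iter.max = 1000`,
#' convergence handled by stats::kmeans, and `n_init = 10` restarts under
#' a fixed seed, mirroring common single-cell practice.
#'
#' @param freq Frequency matrix restricted to retained variants (`NA`
#'   allowed; imputed as 0).
#' @param K Number of clusters (number of pooled donors).
#' @param method `"kmeans"` or `"gmm"`.
#' @param seed Clustering seed (default 42).
#' @param max_iter,n_init K-means iteration cap and restarts.
#' @return Integer vector of cluster labels in `1..K`, named by barcode.
#' @export
initial_cluster <- function(freq, K, method = c("kmeans", "gmm"), seed = 42L,
                            max_iter = 1000L, n_init = 10L) {
  method <- match.arg(method)
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(freq)) stop("K (", K, ") exceeds the number of cells (", nrow(freq), ")")
  x <- freq
  x[is.na(x)] <- 0
  if (K == 1L) {
    return(stats::setNames(rep(1L, nrow(x)), rownames(x)))
  }
  labels <- withr::with_seed(seed, {
    if (method == "kmeans") {
      .kmeans_pp(x, K, max_iter = max_iter, n_init = n_init)$cluster
    } else {
      fit <- tryCatch(
        mclust::Mclust(x, G = K, modelNames = c("EII", "VII"),
                       verbose = FALSE),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning("GMM fit degenerate; falling back to K-means")
        .kmeans_pp(x, K, max_iter = max_iter, n_init = n_init)$cluster
      } else {
        fit$classification
      }
    }
  })
  labels <- as.integer(labels)
  if (length(unique(labels)) < K) {
    warning("degenerate clustering: only ", length(unique(labels)),
            " of ", K, " clusters occupied")
  }
  stats::setNames(labels, rownames(x))
}

#' Per-cluster germline variant sets
#'
#' Applies the same homoplasmic-fraction rule as [filter_germline()]
#' within each cluster's cells: a variant joins cluster i's set iff, among
#' cluster-i cells with non-zero VAF, more than `min_fraction` have VAF
#' above `homoplasmy`.
#'
#' @param labels Cluster labels from [initial_cluster()].
#' @param freq Frequency matrix (with `NA` missing markers).
#' @param min_carrier_fraction Optional additional criterion: the variant
#'   must also be homoplasmic in more than this fraction of the cluster's
#'   *covered* (non-missing) cells.  A true germline variant of the
#'   cluster's donor is homoplasmic in essentially every covered cell, so
#'   the criterion costs nothing when clustering is correct, but at ~1x
#'   coverage it suppresses single-read cells (VAF exactly 1 at depth 1)
#'   that otherwise let another donor's variants leak into the set.  0
#'   (default) disables it, leaving the plain homoplasmic-fraction rule;
#'   the pipeline enables it at 0.5.
#' @inheritParams filter_germline
#' @return Named list of K character vectors of variant ids.
#' @export
cluster_variant_sets <- function(labels, freq, homoplasmy = 0.99,
                                 min_fraction = 0.5,
                                 min_carrier_fraction = 0) {
  K <- max(labels)
  sets <- vector("list", K)
  names(sets) <- as.character(seq_len(K))
  for (k in seq_len(K)) {
    cells <- which(labels == k)
    if (length(cells) == 0L) {
      warning("cluster ", k, " is empty; its variant set is empty")
      sets[[k]] <- character(0)
      next
    }
    sub <- freq[cells, , drop = FALSE]
    nz <- colSums(sub > 0, na.rm = TRUE)
    hi <- colSums(sub > homoplasmy, na.rm = TRUE)
    keep <- nz > 0 & hi / nz > min_fraction
    if (min_carrier_fraction > 0) {
      covered <- colSums(!is.na(sub))
      keep <- keep & covered > 0 & hi / covered > min_carrier_fraction
    }
    sets[[k]] <- colnames(freq)[keep]
  }
  sets
}

#' Remove common variants from per-cluster sets
#'
#' Variants occurring in more than `max_sets` cluster sets are removed
#' from all sets, leaving sample-specific germline variants.  The default
#' `max_sets = 1` enforces strict sample-specificity (any variant shared
#' by two or more clusters is removed), which the doublet model requires:
#' its per-cluster allele summaries assume disjoint variant sets.  Setting
#' `max_sets = 2` gives the looser reading where only variants present in
#' more than two sets are removed.
#'
#' @param sets List of per-cluster variant id vectors.
#' @param max_sets Maximum number of sets a variant may occur in.
#' @return List of the same shape with common variants removed.
#' @export
remove_common <- function(sets, max_sets = 1L) {
  occ <- table(unlist(sets))
  common <- names(occ)[occ > max_sets]
  out <- lapply(sets, setdiff, y = common)
  empty <- lengths(out) == 0L
  if (any(empty)) {
    stop("cluster(s) ", paste(which(empty), collapse = ", "),
         " retain no sample-specific variants after common-variant removal; ",
         "try direct mode (demux_direct) or a different K")
  }
  out
}

#' Estimate the number of pooled donors by silhouette score
#'
#' Runs [initial_cluster()] for each candidate `k` and returns the `k`
#' maximising the mean silhouette width (ties broken towards smaller k).
#' The silhouette reaches its global maximum when cells split into their
#' true genotype groups.
#'
#' @param freq Frequency matrix restricted to retained germline variants.
#' @param k_range Candidate cluster numbers (within `2..cells-1`).
#' @inheritParams initial_cluster
#' @return The selected `K` (integer), with the silhouette profile in
#'   attribute `"silhouette"`.
#' @export
estimate_k <- function(freq, k_range = 2:12, method = "kmeans", seed = 42L) {
  x <- freq
  x[is.na(x)] <- 0
  if (nrow(unique(x)) < 2L) stop("all cells identical; cannot estimate K")
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= nrow(x) - 1L]
  if (length(k_range) == 0L) stop("k_range must lie within 2..cells-1")
  d <- stats::dist(x)
  sil <- vapply(k_range, function(k) {
    # candidate k above the true donor count legitimately leaves clusters
    # empty; that shows up as a low silhouette, not a user-facing warning
    labels <- suppressWarnings(
      initial_cluster(freq, k, method = method, seed = seed))
    mean(cluster::silhouette(labels, d)[, 3L])
  }, numeric(1L))
  best <- k_range[which.max(sil)]            # which.max: first max = smallest k
  structure(best, silhouette = stats::setNames(sil, k_range))
}

#' Estimate the per-cluster Beta prior scale
#'
#' For cluster i, `alpha_i = 1 +` the mean over its sample-specific
#' variants of the mean alternative allele count among cluster-i cells;
#' `beta = 1`.  With no alternative counts the prior collapses to the
#' uniform Beta(1, 1).
#'
#' @param alt Alternative count matrix (cells x variants).
#' @param labels Cluster labels.
#' @param variant_sets Per-cluster variant sets from [remove_common()].
#' @return Numeric vector of length K of alpha values (all >= 1).
#' @export
estimate_alpha <- function(alt, labels, variant_sets) {
  K <- length(variant_sets)
  vapply(seq_len(K), function(k) {
    cells <- which(labels == k)
    vars <- variant_sets[[k]]
    if (length(cells) == 0L || length(vars) == 0L) {
      stop("cluster ", k, " has no cells or no variants; cannot estimate alpha")
    }
    1 + mean(Matrix::colMeans(alt[cells, vars, drop = FALSE]))
  }, numeric(1L))
}

#' Fit the genotype cluster model
#'
#' Convenience wrapper chaining [filter_germline()], [initial_cluster()]
#' (or [estimate_k()] when `K` is `NULL`), [cluster_variant_sets()],
#' [remove_common()] and [estimate_alpha()].
#'
#' @param mat An `allele_matrices` object.
#' @param K Number of pooled donors, or `NULL` to estimate it.
#' @param k_range Candidate K values when estimating.
#' @param method Clustering method, `"kmeans"` or `"gmm"`.
#' @param seed Clustering seed.
#' @param homoplasmy,min_fraction Germline-rule cutoffs.
#' @param min_carrier_fraction See [cluster_variant_sets()].
#' @param max_sets Common-variant removal threshold (see [remove_common()]).
#' @return A `genotype_clusters` object: `K`, `labels`, `variant_sets`,
#'   `alpha`, `beta` (fixed 1), `germline_variants`.
#' @export
fit_genotypes <- function(mat, K = NULL, k_range = 2:12,
                          method = "kmeans", seed = 42L,
                          homoplasmy = 0.99, min_fraction = 0.5,
                          min_carrier_fraction = 0, max_sets = 1L) {
  freq <- allele_freq(mat)
  germ <- filter_germline(freq, homoplasmy, min_fraction)
  if (length(germ) == 0L) stop("no germline variants pass the filter")
  fg <- freq[, germ, drop = FALSE]
  if (is.null(K)) K <- as.integer(estimate_k(fg, k_range, method, seed))
  labels <- initial_cluster(fg, K, method = method, seed = seed)
  sets <- cluster_variant_sets(labels, fg, homoplasmy, min_fraction,
                               min_carrier_fraction)
  sets <- remove_common(sets, max_sets = max_sets)
  alpha <- estimate_alpha(mat$alt, labels, sets)
  structure(list(K = K, labels = labels, variant_sets = sets,
                 alpha = alpha, beta = 1, germline_variants = germ),
            class = "genotype_clusters")
}

#' @export
print.genotype_clusters <- function(x, ...) {
  cat("genotype_clusters: K =", x$K, "|",
      paste(lengths(x$variant_sets), collapse = "/"),
      "specific variants | alpha =",
      paste(sprintf("%.2f", x$alpha), collapse = ", "), "\n")
  invisible(x)
}

#' Write a genotype cluster model to disk
#'
#' Emits `cluster_labels.tsv`, `specific_variants.tsv` and `model.json`.
#'
#' @param model A `genotype_clusters` object.
#' @param dir Output directory.
#' @param variants Optional variant table supplying position/ref/alt for
#'   `specific_variants.tsv`.
#' @return `dir`, invisibly.
#' @export
write_genotype_model <- function(model, dir, variants = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(barcode = names(model$labels), cluster = model$labels),
    file.path(dir, "cluster_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  sv <- data.frame(
    cluster = rep(seq_along(model$variant_sets), lengths(model$variant_sets)),
    id = unlist(model$variant_sets, use.names = FALSE)
  )
  if (!is.null(variants)) {
    m <- match(sv$id, variants$id)
    sv$position <- variants$position[m]
    sv$ref <- variants$ref[m]
    sv$alt <- variants$alt[m]
  }
  utils::write.table(sv, file.path(dir, "specific_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(K = model$K, alpha = model$alpha, beta = model$beta,
         n_specific = lengths(model$variant_sets)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
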