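#' Binomial likelihood of an alternative allele count
#'
#' Probability of observing `A1` alternative alleles out of `N` total
#' counts at a cluster's specific variants when the alternative allele
#' frequency is `p`: `C(N, A1) p^A1 (1 - p)^(N - A1)` (evaluated in log
#' space for large `N`).
#'
#' @param A1 Alternative allele count(s).
#' @param N Total allele count(s).
#' @param p Alternative allele frequency in `[0, 1]`.
#' @return Probability (vectorised).
#' @export
binomial_likelihood <- function(A1, N, p) {
  if (any(A1 < 0L) || any(N < 0L) || any(A1 > N)) {
    stop("require 0 <= A1 <= N")
  }
  if (any(p < 0) || any(p > 1)) stop("p must be in [0, 1]")
  stats::dbinom(A1, N, p)
}

#' Posterior mode of the per-cluster allele frequency
#'
#' The conjugate Beta(`alpha`, `beta`) prior combined with the binomial
#' count model gives a Beta(`alpha + A1`, `beta + A0`) posterior; the
#' point estimate is its mode:
#' `p = (alpha + A1 - 1) / (alpha + beta + A1 + A0 - 2)`.
#' When the denominator is 0 (uniform prior with no data) the mode is
#' undefined and `NA` is returned.
#'
#' @param A1 Alternative allele count(s).
#' @param A0 Reference allele count(s).
#' @param alpha Beta prior alpha (>= 1; see [estimate_alpha()]).
#' @param beta Beta prior beta (fixed at 1 in the pipeline).
#' @return Posterior mode(s) in `[0, 1]`, `NA` where undefined.
#' @export
posterior_p <- function(A1, A0, alpha, beta = 1) {
  if (any(alpha < 1)) stop("alpha must be >= 1")
  den <- alpha + beta + A1 + A0 - 2
  out <- (alpha + A1 - 1) / den
  out[den == 0] <- NA_real_
  out
}

# Shared scoring core: posterior of every cell against every cluster's
# variant set, restricted per cell to variants with observed data.
# `first` is either a vector of initial labels or "argmax".
.score_matrix <- function(mat, variant_sets, alpha, first, beta = 1) {
  K <- length(variant_sets)
  n <- nrow(mat$ref)
  P <- matrix(NA_real_, n, K)
  n_obs_total <- integer(n)
  for (k in seq_len(K)) {
    vars <- variant_sets[[k]]
    if (length(vars) == 0L) stop("cluster ", k, " has an empty variant set")
    ref_k <- mat$ref[, vars, drop = FALSE]
    alt_k <- mat$alt[, vars, drop = FALSE]
    A0 <- Matrix::rowSums(ref_k)
    A1 <- Matrix::rowSums(alt_k)
    n_obs <- Matrix::rowSums((ref_k + alt_k) > 0)
    p <- posterior_p(A1, A0, alpha[k], beta)
    p[n_obs == 0L] <- NA_real_           # no observed data: no posterior
    P[, k] <- p
    n_obs_total <- n_obs_total + as.integer(n_obs)
  }
  dimnames(P) <- list(rownames(mat$ref), names(variant_sets))

  if (identical(first, "argmax")) {
    first_cluster <- .row_which_max_na(P)
  } else {
    first_cluster <- as.integer(first)
  }
  p1 <- P[cbind(seq_len(n), first_cluster)]
  rest <- P
  rest[cbind(seq_len(n), first_cluster)] <- NA_real_
  p2 <- .row_max_na(rest)
  second_cluster <- .row_which_max_na(rest)

  scores <- data.frame(
    barcode = rownames(mat$ref),
    first_cluster = first_cluster,
    second_cluster = second_cluster,
    p1 = p1, p2 = p2,
    n_variants_observed = n_obs_total,
    stringsAsFactors = FALSE
  )
  attr(scores, "p_matrix") <- P
  class(scores) <- c("demux_scores", "data.frame")
  scores
}

#' Score cells against every genotype cluster
#'
#' For each cell, computes the posterior-mode allele frequency against
#' every cluster's sample-specific variant set (restricted to variants
#' with observed data in that cell).  `p1` is the posterior for the
#' cell's first-fitted cluster (its initial clustering label), `p2` the
#' highest posterior among the remaining clusters.  A singlet shows
#' `p1 ~ 1` and low `p2`; a cross-genotype doublet carries alternative
#' alleles of two clusters and shows intermediate `p1` with elevated
#' `p2`.  Cells covering no specific variant of any cluster are
#' unscorable (`p1` is `NA`).
#'
#' @param mat An `allele_matrices` object.
#' @param model A `genotype_clusters` object.
#' @param first `"label"` (default: first-fitted cluster is the initial
#'   clustering label) or `"argmax"` (highest posterior).
#' @return A `demux_scores` data.frame (barcode, first_cluster,
#'   second_cluster, p1, p2, n_variants_observed) with the full cell x
#'   cluster posterior matrix in attribute `"p_matrix"`.
#' @export
score_cells <- function(mat, model, first = c("label", "argmax")) {
  first <- match.arg(first)
  sets <- model$variant_sets
  if (anyDuplicated(unlist(sets))) {
    stop("variant sets are not disjoint; run remove_common() first")
  }
  fc <- if (first == "argmax") {
    "argmax"
  } else if (!is.null(names(model$labels))) {
    model$labels[rownames(mat$ref)]
  } else {
    model$labels
  }
  .score_matrix(mat, sets, model$alpha, fc, model$beta)
}

#' Classify cells as singlets or doublets
#'
#' Threshold rules on `(p1, p2)`: cells with `p1 > 0.99` and `p2 < 0.01`
#' are singlets; cells with `p1 < 0.8` or `p2 > 0.2` are doublets.  Cells
#' matching neither rule are assigned the majority label of their
#' `knn_k = 5` nearest labelled neighbours in `(p1, p2)` space
#' (Euclidean).  With `trust_p1 = TRUE`, any cell with `p1 > 0.99` is
#' called a singlet regardless of `p2` (elevated `p2` at high `p1` is
#' typically driven by shared somatic mutations rather than a second
#' genotype); the pipeline default enables this.
#'
#' @param scores A `demux_scores` data.frame.
#' @param p1_singlet,p2_singlet Singlet rule: `p1 > p1_singlet` and
#'   `p2 < p2_singlet`.
#' @param p1_doublet,p2_doublet Doublet rule: `p1 < p1_doublet` or
#'   `p2 > p2_doublet`.
#' @param knn_k Neighbours for the rescue classifier.
#' @param trust_p1 Call singlets from `p1` alone (see above).
#' @param seed Seed for the (rarely needed) random tie-breaks inside the
#'   KNN vote, keeping reruns byte-identical.
#' @return `scores` with a `label` column added
#'   (`"Singlet"`/`"Doublet"`/`"Unlabeled"`/`"unassigned"`).
#' @export
classify_cells <- function(scores, p1_singlet = 0.99, p2_singlet = 0.01,
                           p1_doublet = 0.8, p2_doublet = 0.2,
                           knn_k = 5L, trust_p1 = FALSE, seed = 0L) {
  if (nrow(scores) == 0L) stop("empty score table")
  for (th in c(p1_singlet, p2_singlet, p1_doublet, p2_doublet)) {
    .assert_proportion(th, "threshold")
  }
  p1 <- scores$p1
  p2 <- ifelse(is.na(scores$p2), 0, scores$p2)  # no second-cluster evidence

  label <- rep("Unlabeled", nrow(scores))
  unscorable <- is.na(p1)
  singlet <- !unscorable &
    if (trust_p1) p1 > p1_singlet else p1 > p1_singlet & p2 < p2_singlet
  doublet <- !unscorable & !singlet & (p1 < p1_doublet | p2 > p2_doublet)
  label[singlet] <- "Singlet"
  label[doublet] <- "Doublet"
  label[unscorable] <- "unassigned"

  todo <- which(label == "Unlabeled")
  if (length(todo) > 0L) {
    train <- which(label %in% c("Singlet", "Doublet"))
    if (length(unique(label[train])) < 2L) {
      warning("need labelled cells of both classes for KNN rescue; ",
              "returning threshold labels only")
    } else {
      k <- min(knn_k, length(train))
      pred <- withr::with_seed(seed, class::knn(
        train = cbind(p1, p2)[train, , drop = FALSE],
        test = cbind(p1, p2)[todo, , drop = FALSE],
        cl = factor(label[train]), k = k
      ))
      label[todo] <- as.character(pred)
    }
  }
  scores$label <- label
  scores
}

#' Assign classified cells to donors
#'
#' Singlets are assigned to the cluster with the highest posterior
#' (argmax over the full posterior matrix; exact ties break to the lower
#' cluster index with a warning).  Doublets are annotated with their
#' (first-fitted, second) cluster pair.  Unscorable cells remain
#' `"unassigned"`.
#'
#' @param scores A classified `demux_scores` data.frame (with `label`).
#' @return A `demux_result` data.frame: barcode, label, donor,
#'   second_donor, p1, p2, n_variants_observed, plus the posterior matrix
#'   in attribute `"p_matrix"`.
#' @export
assign_singlets <- function(scores) {
  if (is.null(scores$label)) stop("run classify_cells() first")
  P <- attr(scores, "p_matrix")
  n <- nrow(scores)
  donor <- rep(NA_integer_, n)
  second <- rep(NA_integer_, n)

  is_s <- scores$label == "Singlet"
  if (any(is_s)) {
    Ps <- P[is_s, , drop = FALSE]
    ties <- apply(Ps, 1L, function(r) {
      sum(!is.na(r) & r == max(r, na.rm = TRUE)) > 1L
    })
    if (any(ties)) {
      warning(sum(ties), " singlet(s) with tied posteriors assigned to the ",
              "lower cluster index")
    }
    donor[is_s] <- .row_which_max_na(Ps)   # which.max: first max wins
  }
  is_d <- scores$label == "Doublet"
  donor[is_d] <- scores$first_cluster[is_d]
  second[is_d] <- scores$second_cluster[is_d]

  out <- data.frame(
    barcode = scores$barcode, label = scores$label,
    donor = donor, second_donor = second,
    p1 = scores$p1, p2 = scores$p2,
    n_variants_observed = scores$n_variants_observed,
    stringsAsFactors = FALSE
  )
  attr(out, "p_matrix") <- P
  class(out) <- c("demux_result", "data.frame")
  out
}

#' Direct-mode scoring: cluster variants instead of cells
#'
#' When cells are hard to cluster directly (low depth, highly imbalanced
#' pools), the germline variants themselves are clustered into `K`
#' groups by their across-cell frequency profiles; each group plays the
#' role of a cluster-specific variant set and cells are scored against
#' the groups, with the first-fitted cluster taken as the argmax
#' posterior.  The prior scale for each group is estimated from its
#' homoplasmic carrier cells.
#'
#' @param mat An `allele_matrices` object.
#' @param K Number of pooled donors.
#' @param seed Clustering seed.
#' @param homoplasmy,min_fraction Germline-rule cutoffs.
#' @param min_carrier_fraction See [cluster_variant_sets()]; used in the
#'   refinement pass (default 0.5).
#' @param refine Run the refinement pass (default `TRUE`).
#' @return A `demux_scores` data.frame as from [score_cells()], with the
#'   fitted variant groups in attribute `"variant_sets"` and prior in
#'   attribute `"alpha"`.
#' @details
#' Variant profiles are L2-normalised before K-means so that grouping
#' reflects *which* cells carry a variant rather than how often it was
#' covered: two variants of the same donor are near-parallel even at low
#' depth, while variants of different donors are near-orthogonal.  The
#' provisional groups give each cell an argmax genotype under a uniform
#' prior; the refinement pass then re-derives sample-specific variant
#' sets from those provisional labels with the standard per-cluster
#' homoplasmy rule and common-variant removal (which also discards
#' shared haplogroup variants the grouping cannot place), re-estimates
#' the prior scale and re-scores.  If refinement collapses a set, the
#' provisional scoring is returned.
#' @export
demux_direct <- function(mat, K, seed = 42L, homoplasmy = 0.99,
                         min_fraction = 0.5, min_carrier_fraction = 0.5,
                         refine = TRUE) {
  freq <- allele_freq(mat)
  germ <- filter_germline(freq, homoplasmy, min_fraction)
  if (K > length(germ)) {
    stop("K (", K, ") exceeds the number of germline variants (",
         length(germ), ")")
  }
  x <- t(freq[, germ, drop = FALSE])
  x[is.na(x)] <- 0
  norms <- sqrt(rowSums(x^2))
  xn <- x / pmax(norms, .Machine$double.eps)
  grp <- if (K == 1L) {
    stats::setNames(rep(1L, nrow(x)), rownames(x))
  } else {
    withr::with_seed(seed, .kmeans_pp(xn, K)$cluster)
  }
  sets <- split(germ, grp)
  names(sets) <- as.character(seq_len(K))

  # provisional genotypes under a uniform prior
  scores <- .score_matrix(mat, sets, alpha = rep(1, K), first = "argmax")
  alpha <- rep(1, K)

  if (refine && K > 1L) {       # with one genotype there is nothing to refine
    labels <- scores$first_cluster
    labels[is.na(labels)] <- 1L
    refined <- tryCatch({
      s2 <- cluster_variant_sets(labels, freq[, germ, drop = FALSE],
                                 homoplasmy, min_fraction,
                                 min_carrier_fraction)
      s2 <- remove_common(s2)
      a2 <- estimate_alpha(mat$alt, labels, s2)
      list(sets = s2, alpha = a2)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(refined)) {
      sets <- refined$sets
      alpha <- refined$alpha
      scores <- .score_matrix(mat, sets, alpha, "argmax")
    }
  }
  attr(scores, "variant_sets") <- sets
  attr(scores, "alpha") <- alpha
  scores
}

#' Write a demultiplexing result table
#'
#' Emits `demux_result.tsv` with barcode, label, donor, second_donor,
#' p1, p2, semicolon-joined per-cluster posteriors and
#' n_variants_observed.
#'
#' @param result A `demux_result` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_demux_result <- function(result, path) {
  P <- attr(result, "p_matrix")
  out <- result
  out$p_by_cluster <- apply(P, 1L, function(r) {
    paste(sprintf("%.6g", r), collapse = ";")
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
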