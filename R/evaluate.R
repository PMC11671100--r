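# Evaluation metrics for demultiplexing runs: classification accuracy with
# optimal cluster-to-donor matching, adjusted Rand index, doublet AUC/TPR/FDR
# and between-method concordance tables.

# Align two labelled vectors on their barcode intersection.
.align_labels <- function(truth, predicted) {
  common <- intersect(names(truth), names(predicted))
  if (length(common) == 0L) stop("no barcodes shared between the two labelings")
  list(truth = truth[common], predicted = predicted[common])
}

# Optimal one-to-one mapping of predicted singlet classes onto truth singlet
# classes by maximum-weight bipartite matching (Hungarian algorithm).
# Returns a named vector: predicted class -> truth class (NA if unmatched).
.match_classes <- function(truth, predicted, special = c("doublet", "unassigned")) {
  ts <- !(truth %in% special)
  ps <- !(predicted %in% special)
  tc <- sort(unique(truth[ts]))
  pc <- sort(unique(predicted[ps]))
  if (length(tc) == 0L || length(pc) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  tab <- table(factor(truth[ts & ps], levels = tc),
               factor(predicted[ts & ps], levels = pc))
  n <- max(length(tc), length(pc))
  m <- matrix(0, n, n)
  m[seq_along(tc), seq_along(pc)] <- tab
  sol <- clue::solve_LSAP(m, maximum = TRUE)
  map <- rep(NA_character_, length(pc))
  for (i in seq_along(tc)) {
    j <- sol[i]
    if (j <= length(pc)) map[j] <- tc[i]
  }
  stats::setNames(map, pc)
}

#' Classification accuracy with optimal label matching
#'
#' Fraction of cells whose predicted class equals the truth, where donor
#' classes of the prediction are first mapped one-to-one onto truth donors
#' by maximum-weight matching (cluster numbering is arbitrary) and
#' `"doublet"` is a class of its own.  `"unassigned"` predictions never
#' match.
#'
#' @param truth,predicted Named character vectors (names are barcodes);
#'   doublets labelled `"doublet"`.
#' @param match_labels Map predicted classes onto truth classes by maximum
#'   weight matching before comparing (default `TRUE`).
#' @return Proportion in `[0, 1]`.
#' @export
demux_accuracy <- function(truth, predicted, match_labels = TRUE) {
  al <- .align_labels(truth, predicted)
  pred <- al$predicted
  if (match_labels) {
    map <- .match_classes(al$truth, pred)
    mapped <- !(pred %in% c("doublet", "unassigned"))
    pred[mapped] <- map[pred[mapped]]
  }
  mean(!is.na(pred) & pred == al$truth)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement, computed from the
#' contingency-table formula.  Invariant to label permutation of either
#' argument.
#'
#' @param a,b Two label vectors over the same cells (named vectors are
#'   aligned on their name intersection).
#' @return The ARI (1 for identical partitions, ~0 for independent ones).
#' @export
ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    al <- .align_labels(a, b)
    a <- al$truth; b <- al$predicted
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Doublet-detection metrics
#'
#' AUC of `p2` as a doublet score (rank statistic, equivalent to the
#' Mann-Whitney U), plus the true-positive rate (detected true doublets /
#' true doublets) and false discovery rate (false doublet calls / all
#' doublet calls; 0 when there are no calls) of the hard calls.
#'
#' @param is_doublet Logical vector: truth per cell.
#' @param score Numeric doublet score per cell (the pipeline uses `p2`;
#'   `1 - p1` is an alternative).  `NA` scores rank lowest.
#' @param called_doublet Logical vector: predicted doublet calls.
#' @return List with `auc`, `tpr`, `fdr`.
#' @export
doublet_metrics <- function(is_doublet, score, called_doublet) {
  stopifnot(length(is_doublet) == length(score),
            length(score) == length(called_doublet))
  score[is.na(score)] <- -Inf
  n_pos <- sum(is_doublet)
  n_neg <- sum(!is_doublet)
  auc <- if (n_pos == 0L || n_neg == 0L) NA_real_ else {
    r <- rank(score)
    (sum(r[is_doublet]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  tpr <- if (n_pos == 0L) NA_real_ else sum(called_doublet & is_doublet) / n_pos
  n_called <- sum(called_doublet)
  fdr <- if (n_called == 0L) 0 else sum(called_doublet & !is_doublet) / n_called
  list(auc = auc, tpr = tpr, fdr = fdr)
}

#' Concordance table between two labelings
#'
#' Row-normalised percentage of barcodes shared between the classes of
#' labeling `a` (rows) and labeling `b` (columns), over the intersection
#' of barcodes assigned by both (cells `"unassigned"` by either method
#' are excluded).  Each row sums to 100.
#'
#' @param a,b Named character label vectors.
#' @return Numeric matrix of percentages.
#' @export
concordance_table <- function(a, b) {
  al <- .align_labels(a, b)
  keep <- al$truth != "unassigned" & al$predicted != "unassigned"
  tab <- table(al$truth[keep], al$predicted[keep])
  100 * sweep(unclass(tab), 1L, rowSums(tab), "/")
}

#' Same-genotype doublet accounting for an equally mixed pool
#'
#' Genotype-based doublet detection only sees cross-genotype doublets.
#' Under equal mixing of `n_donors` donors, a doublet pairs two cells of
#' the same donor with probability `1/N`, so from an observed count of
#' cross-genotype doublets the total and same-genotype doublet loads
#' follow by arithmetic: `total = cross / ((N-1)/N)` and
#' `same = cross / (N-1)`.
#'
#' @param n_cross Number of detected cross-genotype doublets.
#' @param n_donors Number of equally pooled donors.
#' @param n_total Total number of cells (for the percentage).
#' @return List with `cross_fraction` (`(N-1)/N`), `total_doublets`,
#'   `same_genotype` and `same_genotype_pct`.
#' @export
doublet_composition <- function(n_cross, n_donors, n_total = NULL) {
  stopifnot(n_donors >= 2L, n_cross >= 0)
  cross_fraction <- (n_donors - 1) / n_donors
  total <- n_cross / cross_fraction
  same <- n_cross / (n_donors - 1)
  list(cross_fraction = cross_fraction,
       total_doublets = total,
       same_genotype = same,
       same_genotype_pct = if (is.null(n_total)) NULL else 100 * same / n_total)
}

#' Predicted class labels of a demultiplexing result
#'
#' Converts a `demux_result` into the named label vector the metrics
#' consume: donor/cluster id for singlets, `"doublet"` for doublets,
#' `"unassigned"` otherwise.
#'
#' @param result A `demux_result` data.frame.
#' @return Named character vector.
#' @export
predicted_labels <- function(result) {
  lab <- ifelse(result$label == "Singlet", as.character(result$donor),
                ifelse(result$label == "Doublet", "doublet", "unassigned"))
  stats::setNames(lab, result$barcode)
}

#' Benchmark a demultiplexing run against simulation truth
#'
#' One-stop evaluation of a pipeline run on a simulated pool: overall
#' classification accuracy (donors permutation-matched, doublet as a
#' class), singlet donor-assignment accuracy and TPR, doublet TPR over
#' cross-genotype doublets, doublet FDR, the fraction of true singlets
#' called doublets, doublet AUC (score `p2`) and the ARI between true and
#' inferred singlet assignments.
#'
#' @param sim A `mito_sim` object.
#' @param result A `demux_result` data.frame from the pipeline.
#' @return List of metrics (proportions in `[0, 1]`).
#' @export
pool_metrics <- function(sim, result) {
  truth <- truth_labels(sim)
  pred <- predicted_labels(result)
  al <- .align_labels(truth, pred)
  map <- .match_classes(al$truth, al$predicted)
  mapped <- al$predicted
  mm <- !(mapped %in% c("doublet", "unassigned"))
  mapped[mm] <- map[mapped[mm]]

  accuracy <- mean(!is.na(mapped) & mapped == al$truth)

  true_singlet <- al$truth != "doublet"
  donor_tpr <- mean(!is.na(mapped[true_singlet]) &
                      mapped[true_singlet] == al$truth[true_singlet])
  singlet_as_doublet <- mean(mapped[true_singlet] == "doublet", na.rm = FALSE)

  tt <- sim$truth[match(names(al$truth), sim$truth$barcode), ]
  is_cross <- tt$kind == "doublet" & tt$donor1 != tt$donor2
  called <- al$predicted == "doublet"
  doublet_tpr <- if (sum(is_cross) == 0L) NA_real_ else
    sum(called & is_cross) / sum(is_cross)
  p2 <- result$p2[match(names(al$truth), result$barcode)]
  dm <- doublet_metrics(al$truth == "doublet", p2, called)
  # ROC restricted to detectable (cross-genotype) doublets vs singlets:
  # same-genotype doublets carry a single mitochondrial genotype and are
  # invisible to any genotype-based score.
  det <- is_cross | al$truth != "doublet"
  dm_cross <- doublet_metrics(is_cross[det], p2[det], called[det])

  both_singlet <- true_singlet & mm
  ari_singlets <- if (sum(both_singlet) < 2L) NA_real_ else
    ari(al$truth[both_singlet], al$predicted[both_singlet])

  list(accuracy = accuracy,
       donor_tpr = donor_tpr,
       singlet_as_doublet = singlet_as_doublet,
       doublet_tpr = doublet_tpr,
       doublet_fdr = dm$fdr,
       doublet_auc = dm$auc,
       doublet_auc_cross = dm_cross$auc,
       ari_singlets = ari_singlets)
}
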