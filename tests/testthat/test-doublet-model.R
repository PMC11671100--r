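test_that("binomial likelihood matches the closed form", {
  expect_equal(binomial_likelihood(10, 10, 0.5), 0.0009765625)
  expect_equal(binomial_likelihood(0, 5, 0), 1.0)
  expect_equal(binomial_likelihood(3, 10, 0.3), 0.26682793, tolerance = 1e-8)
  expect_error(binomial_likelihood(11, 10, 0.5), "A1 <= N")
  expect_error(binomial_likelihood(1, 10, 1.5), "0, 1")
})

test_that("posterior mode follows the Beta closed form", {
  expect_equal(posterior_p(50, 0, alpha = 11), 1.0)
  expect_equal(posterior_p(0, 90, alpha = 11), 0.1)
  expect_equal(posterior_p(7, 3, alpha = 1), 0.7)      # uniform prior -> MLE
  expect_true(is.na(posterior_p(0, 0, alpha = 1)))     # undefined mode
  expect_error(posterior_p(1, 1, alpha = 0.5), "alpha")
})

test_that("posterior mode equals independent evaluations on random triples", {
  trip <- withr::with_seed(42, data.frame(
    alpha = 1 + 49 * runif(1000),
    A1 = sample(0:100, 1000, replace = TRUE),
    A0 = sample(0:100, 1000, replace = TRUE)
  ))
  got <- posterior_p(trip$A1, trip$A0, trip$alpha)
  closed <- (trip$alpha + trip$A1 - 1) / (trip$alpha + 1 + trip$A1 + trip$A0 - 2)
  expect_equal(got, closed)
  # numeric maximisation of the Beta(alpha+A1, 1+A0) density agrees
  sub <- trip[seq(1, 1000, by = 20), ]
  for (i in seq_len(nrow(sub))) {
    a <- sub$alpha[i] + sub$A1[i]
    b <- 1 + sub$A0[i]
    if (a <= 1 || b <= 1) next                         # mode at the boundary
    num <- stats::optimize(function(p) stats::dbeta(p, a, b),
                           c(0, 1), maximum = TRUE)$maximum
    expect_equal(posterior_p(sub$A1[i], sub$A0[i], sub$alpha[i]), num,
                 tolerance = 1e-4)
  }
})

test_that("posterior mode is monotone in the allele counts", {
  for (alpha in c(1, 2.5, 12)) {
    p_up <- posterior_p(0:50, 20, alpha)
    expect_true(all(diff(p_up) >= 0))                  # non-decreasing in A1
    p_down <- posterior_p(20, 0:50, alpha)
    expect_true(all(diff(p_down) <= 0))                # non-increasing in A0
  }
})

test_that("noiseless singlets and balanced doublets score as expected", {
  # two clusters with two specific variants each, uniform prior
  sets <- list(`1` = c("v1", "v2"), `2` = c("v3", "v4"))
  ref <- rbind(c(0, 0, 5, 5),    # singlet of cluster 1
               c(5, 5, 5, 5))    # balanced doublet (alt+ref at both sets)
  alt <- rbind(c(5, 5, 0, 0),
               c(5, 5, 5, 5))
  mat <- make_mats(ref, alt)
  model <- make_model(labels = stats::setNames(c(1L, 1L), rownames(mat$ref)),
                      sets = sets, alpha = c(1, 1))
  sc <- score_cells(mat, model)
  expect_equal(sc$p1[1], 1.0)
  expect_equal(sc$p2[1], 0.0)
  expect_equal(sc$p1[2], 0.5)
  expect_equal(sc$p2[2], 0.5)
  # cells with no observed variants anywhere are unscorable
  mat0 <- make_mats(rbind(c(0, 0, 0, 0)), rbind(c(0, 0, 0, 0)))
  sc0 <- score_cells(mat0, make_model(stats::setNames(1L, rownames(mat0$ref)),
                                      sets, alpha = c(2, 2)))
  expect_true(is.na(sc0$p1))
  expect_equal(sc0$n_variants_observed, 0L)
})

test_that("scores match a brute-force recomputation on a simulated pool", {
  sim <- quick_sim(4, cells = 25, reads = 1000, doublets = 0.1,
                   error = 0.002, seed = 9, n_shared = 1)
  mat <- as_allele_matrices(sim)
  model <- fit_genotypes(mat, K = 4)
  sc <- score_cells(mat, model)
  P <- attr(sc, "p_matrix")
  ref <- as.matrix(mat$ref); alt <- as.matrix(mat$alt)
  for (cell in sample(seq_len(nrow(ref)), 10)) {
    for (k in 1:4) {
      vars <- model$variant_sets[[k]]
      obs <- (ref[cell, vars] + alt[cell, vars]) > 0
      A1 <- sum(alt[cell, vars]); A0 <- sum(ref[cell, vars])
      expected <- if (!any(obs)) NA_real_ else {
        (model$alpha[k] + A1 - 1) / (model$alpha[k] + 1 + A1 + A0 - 2)
      }
      expect_equal(P[cell, k], expected)
    }
    lab <- model$labels[rownames(ref)[cell]]
    expect_equal(sc$p1[cell], P[cell, lab])
    others <- P[cell, -lab]
    expect_equal(sc$p2[cell],
                 if (all(is.na(others))) NA_real_ else max(others, na.rm = TRUE))
  }
})

test_that("threshold rules and KNN rescue classify as printed", {
  sc <- data.frame(
    barcode = sprintf("b%d", 1:8),
    first_cluster = 1L, second_cluster = 2L,
    p1 = c(0.70, 0.992, 0.991, 0.993, 0.994, 0.93, 0.50, 0.95),
    p2 = c(0.30, 0.004, 0.008, 0.002, 0.006, 0.21, 0.50, 0.05),
    n_variants_observed = 10L
  )
  attr(sc, "p_matrix") <- cbind(sc$p1, sc$p2)
  out <- classify_cells(sc)
  expect_equal(out$label[1], "Doublet")            # p1<0.8
  expect_equal(out$label[2], "Singlet")            # p1>0.99 & p2<0.01
  expect_equal(out$label[6], "Doublet")            # p2>0.2
  expect_equal(out$label[7], "Doublet")
  # b8 at (0.95, 0.05) matches neither rule; its 5 nearest labelled
  # neighbours are the 4 singlets (~0.06 away) and the doublet at
  # (0.93, 0.21): majority vote -> Singlet
  d <- sqrt((sc$p1[-8] - 0.95)^2 + (sc$p2[-8] - 0.05)^2)
  nearest <- order(d)[1:5]
  expect_equal(sum(out$label[-8][nearest] == "Singlet"), 4L)
  expect_equal(sum(out$label[-8][nearest] == "Doublet"), 1L)
  expect_equal(out$label[8], "Singlet")
})

test_that("trust_p1 ignores p2 for high-confidence singlets", {
  sc <- data.frame(barcode = c("a", "b"), first_cluster = 1L,
                   second_cluster = 2L,
                   p1 = c(0.995, 0.995), p2 = c(0.25, 0.005),
                   n_variants_observed = 5L)
  attr(sc, "p_matrix") <- cbind(sc$p1, sc$p2)
  strict <- suppressWarnings(classify_cells(sc))
  expect_equal(strict$label[1], "Doublet")         # p2 > 0.2 as printed
  trusted <- classify_cells(sc, trust_p1 = TRUE)
  expect_equal(trusted$label[1], "Singlet")
  expect_error(classify_cells(sc[0, ]), "empty")
})

test_that("singlets are assigned by argmax posterior with documented tie-break", {
  sc <- data.frame(barcode = c("a", "b", "c"), first_cluster = c(1L, 1L, 1L),
                   second_cluster = c(2L, 2L, 2L),
                   p1 = c(0.999, 0.5, 0.4), p2 = c(0.01, 0.5, 0.6),
                   n_variants_observed = 5L,
                   label = c("Singlet", "Singlet", "Doublet"))
  attr(sc, "p_matrix") <- rbind(c(0.999, 0.01, 0.02),
                                c(0.5, 0.5, 0.1),
                                c(0.4, 0.6, 0.2))
  expect_warning(out <- assign_singlets(sc), "tied")
  expect_equal(out$donor, c(1L, 1L, 1L))           # tie -> lower index
  expect_equal(out$second_donor, c(NA_integer_, NA_integer_, 2L))
  sc$label <- NULL
  expect_error(assign_singlets(sc), "classify")
})

test_that("direct mode recovers noiseless pools and ignores column order", {
  sim <- quick_sim(2, cells = 20, reads = 2000, doublets = 0, error = 0,
                   seed = 5)
  mat <- as_allele_matrices(sim)
  sc <- demux_direct(mat, K = 2)
  sets <- attr(sc, "variant_sets")
  priv <- lapply(1:2, private_variants, haplotypes = sim$haplotypes)
  expect_true(setequal(sets[[1]], priv[[1]]) || setequal(sets[[1]], priv[[2]]))
  truth <- truth_labels(sim)
  expect_equal(ari(truth, stats::setNames(sc$first_cluster, sc$barcode)), 1)

  # permuting variant columns leaves the assignment partition unchanged
  # (group numbering is arbitrary)
  perm <- withr::with_seed(1, sample(ncol(mat$ref)))
  mat_p <- mat
  mat_p$ref <- mat$ref[, perm]
  mat_p$alt <- mat$alt[, perm]
  sc_p <- demux_direct(mat_p, K = 2)
  expect_equal(ari(sc_p$first_cluster, sc$first_cluster), 1)
  expect_equal(sc_p$p1, sc$p1)

  # K = 1: single group holds every germline variant
  sc1 <- demux_direct(mat, K = 1)
  expect_equal(length(attr(sc1, "variant_sets")), 1L)
  expect_true(all(sc1$first_cluster == 1L))
  expect_error(demux_direct(mat, K = 10000), "exceeds")
})

test_that("noiseless scores satisfy the printed rules at adequate depth", {
  sim <- quick_sim(4, cells = 25, reads = 2500, doublets = 0.15, error = 0,
                   seed = 13)
  mat <- as_allele_matrices(sim)
  model <- fit_genotypes(mat, K = 4)
  sc <- score_cells(mat, model)
  tt <- sim$truth
  cluster_of <- function(donor) {
    pv <- private_variants(sim$haplotypes,
                           match(donor, sim$haplotypes$donor_ids))
    which(vapply(model$variant_sets, setequal, logical(1), y = pv))[1]
  }
  covered <- function(bc, donor) {
    vars <- model$variant_sets[[cluster_of(donor)]]
    sum(mat$ref[bc, vars] + mat$alt[bc, vars]) > 0
  }
  for (i in seq_len(nrow(tt))) {
    bc <- tt$barcode[i]
    row <- sc[sc$barcode == bc, ]
    if (tt$kind[i] == "singlet") {
      expect_gt(row$p1, 0.99)                       # singlet rule (trust-p1)
    } else if (tt$donor1[i] != tt$donor2[i] &&
               covered(bc, tt$donor1[i]) && covered(bc, tt$donor2[i])) {
      expect_true(row$p1 < 0.8 || row$p2 > 0.2)     # printed doublet rule
    }
  }
})

test_that("doublet AUC on a 4x-coverage 8-donor pool is near-perfect", {
  sim <- quick_sim(8, cells = 100, reads = 1000, doublets = 0.08,
                   error = 0.002, seed = 2, n_shared = 3)
  run <- suppressWarnings(demux_pool(as_allele_matrices(sim), K = 8))
  m <- pool_metrics(sim, run$result)
  expect_gte(m$doublet_auc_cross, 0.99)
})
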