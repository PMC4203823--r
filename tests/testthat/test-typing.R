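# Shared small filtered correlation matrix with two planted blocks.
make_filtered <- function(seed = 31, n_per_block = 6, n_chem = 5) {
  set.seed(seed)
  centers <- rbind(c(rep(0.9, 2), rep(-0.2, n_chem - 2)),
                   c(rep(-0.2, 2), rep(0.9, n_chem - 2)))
  rho <- centers[rep(1:2, each = n_per_block), ] +
    matrix(rnorm(2 * n_per_block * n_chem, 0, 0.03), 2 * n_per_block, n_chem)
  rho <- pmin(pmax(rho, -1), 1)
  dimnames(rho) <- list(sprintf("16S:o%02d", seq_len(2 * n_per_block)),
                        sprintf("icp:c%d", seq_len(n_chem)))
  structure(list(rho = rho,
                 undefined_mask = matrix(FALSE, nrow(rho), ncol(rho),
                                         dimnames = dimnames(rho)),
                 n_samples = 14L,
                 chem_blocks = rep("icp", n_chem)),
            class = "bgc_corr")
}

test_that("WCSS curve is non-increasing, near-zero at k = n, and k=1 is the total SSQ", {
  m <- make_filtered()
  n <- nrow(m$rho)
  curve <- wcss_curve(m, k_max = n, seed = 1, n_init = 20)
  expect_true(all(diff(curve$wcss) <= 1e-8))
  expect_equal(curve$wcss[n], 0, tolerance = 1e-10)
  total_ssq <- sum(sweep(m$rho, 2, colMeans(m$rho))^2)
  expect_equal(curve$wcss[1], total_ssq, tolerance = 1e-10)
  expect_error(wcss_curve(m, k_max = n + 1), "exceeds")
})

test_that("WCSS equals the exhaustive-partition minimum on 6-row toys", {
  set.seed(41)
  for (rep in 1:3) {
    x <- matrix(rnorm(6 * 3), 6, 3,
                dimnames = list(sprintf("16S:o%d", 1:6), sprintf("icp:c%d", 1:3)))
    m <- structure(list(rho = x,
                        undefined_mask = matrix(FALSE, 6, 3, dimnames = dimnames(x)),
                        n_samples = 10L, chem_blocks = rep("icp", 3)),
                   class = "bgc_corr")
    curve <- wcss_curve(m, k_max = 4, seed = rep, n_init = 100)
    expect_equal(curve$wcss[2], oracle_min_wcss(x, 2), tolerance = 1e-8)
    expect_equal(curve$wcss[3], oracle_min_wcss(x, 3), tolerance = 1e-8)
  }
})

test_that("elbow selection finds a constructed kink and flags elbowless curves", {
  kinked <- structure(list(k_values = 1:6, wcss = c(10, 7, 4, 3.5, 3, 2.5),
                           n_init = 1L, seed = 1L), class = "wcss_curve")
  expect_equal(as.integer(select_k_by_elbow(kinked)), 3L)
  d2 <- attr(select_k_by_elbow(kinked), "second_differences")
  expect_equal(d2$k, 2:5)
  expect_equal(d2$second_difference[d2$k == 3], 2.5)

  linear <- structure(list(k_values = 1:6, wcss = seq(12, 2, by = -2),
                           n_init = 1L, seed = 1L), class = "wcss_curve")
  expect_warning(k <- select_k_by_elbow(linear), "no elbow")
  expect_true(attr(k, "no_elbow"))

  # ties break toward the smaller k
  tied <- structure(list(k_values = 1:5, wcss = c(9, 4, 2, 1, 1),
                         n_init = 1L, seed = 1L), class = "wcss_curve")
  # second differences: k=2: 3, k=3: 1, k=4: 1 -> unique max at 2
  expect_equal(as.integer(select_k_by_elbow(tied)), 2L)
})

test_that("PCA decomposition conserves variance, reconstructs, and fixes signs", {
  m <- make_filtered(seed = 32)
  p <- pca_decompose(m, centering = "mean")
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # total variance conserved
  xc <- sweep(m$rho, 2, colMeans(m$rho))
  expect_equal(sum(p$explained_variance), sum(xc^2) / (nrow(xc) - 1),
               tolerance = 1e-10)
  # full reconstruction
  rec <- p$scores %*% t(p$loadings)
  rec <- sweep(rec, 2, colMeans(m$rho), "+")
  expect_equal(rec, m$rho, tolerance = 1e-8)
  # deterministic sign convention
  for (j in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  # rank-1 input has a single non-trivial component
  r1 <- outer(c(1, 2, 3, 4), c(1, 0.5, 0.25))
  dimnames(r1) <- list(sprintf("16S:o%d", 1:4), sprintf("icp:c%d", 1:3))
  m1 <- structure(list(rho = r1, undefined_mask = matrix(FALSE, 4, 3),
                       n_samples = 5L, chem_blocks = rep("icp", 3)),
                  class = "bgc_corr")
  ev <- pca_decompose(m1, centering = "mean")$explained_variance
  expect_gt(ev[1], 1e-10)
  expect_lt(ev[2] / ev[1], 1e-12)
})

test_that("k-means typing recovers planted blocks, co-assigns duplicates, is deterministic", {
  m <- make_filtered(seed = 33)
  part <- cluster_bgc_types(m, k = 2, seed = 7, n_init = 25)
  expect_setequal(unique(part$labels), 1:2)
  truth <- rep(1:2, each = 6)
  split1 <- part$labels[1:6]; split2 <- part$labels[7:12]
  expect_equal(length(unique(split1)), 1L)
  expect_equal(length(unique(split2)), 1L)
  expect_false(split1[1] == split2[1])

  again <- cluster_bgc_types(m, k = 2, seed = 7, n_init = 25)
  expect_identical(part$labels, again$labels)

  # duplicated rows always land together
  dup <- m
  dup$rho <- rbind(dup$rho, `16S:dup1` = dup$rho[1, ], `16S:dup2` = dup$rho[1, ])
  dup$undefined_mask <- matrix(FALSE, nrow(dup$rho), ncol(dup$rho),
                               dimnames = dimnames(dup$rho))
  p2 <- cluster_bgc_types(dup, k = 2, seed = 3, n_init = 25)
  expect_equal(length(unique(p2$labels[c("16S:o01", "16S:dup1", "16S:dup2")])), 1L)

  expect_error(cluster_bgc_types(m, k = 1), "at least 2")
  expect_error(cluster_bgc_types(m, k = 99), "exceeds")
})

test_that("labels are numbered by descending cluster size", {
  m <- make_filtered(seed = 34, n_per_block = 4)
  m$rho <- m$rho[-(1:2), , drop = FALSE]  # block sizes 2 and 4
  m$undefined_mask <- m$undefined_mask[-(1:2), , drop = FALSE]
  part <- cluster_bgc_types(m, k = 2, seed = 1, n_init = 25)
  sizes <- table(part$labels)
  expect_true(sizes["1"] >= sizes["2"])
})

test_that("clustering the correlation rows equals clustering all centered PC scores", {
  m <- make_filtered(seed = 35)
  p_rows <- cluster_bgc_types(m, k = 2, seed = 11, n_init = 30)
  pca <- pca_decompose(m, centering = "mean")
  scores <- pca$scores
  m2 <- m
  m2$rho <- scores  # same geometry, rotated and centered
  colnames(m2$rho) <- sprintf("icp:pc%d", seq_len(ncol(scores)))
  m2$undefined_mask <- matrix(FALSE, nrow(scores), ncol(scores),
                              dimnames = dimnames(m2$rho))
  m2$chem_blocks <- rep("icp", ncol(scores))
  p_pcs <- cluster_bgc_types(m2, k = 2, seed = 11, n_init = 30)
  expect_identical(p_rows$labels, p_pcs$labels)
})

test_that("elbow and partition recover the planted four types on generator defaults", {
  ok <- 0
  for (s in c(2, 5, 9)) {
    ds <- generate_bgc_dataset(bgc_synth_spec(seed = s))
    fit <- bgc_typing(ds$community, ds$chemicals, seed = s)
    truth <- ds$truth$otu_types
    lab <- labels(fit)
    common <- names(lab)[truth[names(lab)] > 0]
    ari <- mclust::adjustedRandIndex(lab[common], truth[common])
    if (fit$manifest$parameters$k_elbow == 4 && ari >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, 2)
})
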