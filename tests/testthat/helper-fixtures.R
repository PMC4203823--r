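# Small builders used across test files.

ft <- function(values, block = "16S", kind = "counts", taxonomy = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  feature_table(values, block = block, value_kind = kind, taxonomy = taxonomy)
}

# Independent rank-then-Pearson Spearman oracle: average ranks computed by
# hand from sorted positions, then the Pearson product-moment formula.
oracle_avg_rank <- function(x) {
  sx <- sort(x)
  vapply(x, function(v) mean(which(sx == v)), numeric(1))
}

oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) return(NA_real_)
  sum(dx * dy) / den
}

# Exhaustive minimum within-cluster SSQ over all assignments of n rows to
# at most k non-empty clusters.
oracle_min_wcss <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    g <- unique(assign)
    if (length(g) == k) {
      w <- sum(vapply(g, function(cl) {
        rows <- x[assign == cl, , drop = FALSE]
        cen <- colMeans(rows)
        sum(sweep(rows, 2L, cen)^2)
      }, numeric(1)))
      best <- min(best, w)
    }
    i <- n
    while (i >= 1 && assign[i] == k) { assign[i] <- 1L; i <- i - 1L }
    if (i == 0) break
    assign[i] <- assign[i] + 1L
  }
  best
}

# A tiny fused dataset with two planted OTU/chemical blocks driven by two
# opposite trends, for quick end-to-end checks.
tiny_fused <- function(n_samples = 10, n_per_block = 4, seed = 99) {
  withr_seed <- function(code) { old <- .GlobalEnv$.Random.seed; set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    code }
  withr_seed({
    up <- seq_len(n_samples)
    comm <- rbind(
      t(replicate(n_per_block, up + rnorm(n_samples, 0, 0.1))),
      t(replicate(n_per_block, rev(up) + rnorm(n_samples, 0, 0.1))))
    rownames(comm) <- sprintf("otu%02d", seq_len(2 * n_per_block))
    colnames(comm) <- sprintf("s%02d", seq_len(n_samples))
    comm <- comm / rep(colSums(comm), each = nrow(comm))
    chem <- rbind(up + rnorm(n_samples, 0, 0.1),
                  rev(up) + rnorm(n_samples, 0, 0.1),
                  rnorm(n_samples))
    rownames(chem) <- c("c_up", "c_down", "c_null")
    colnames(chem) <- colnames(comm)
    fuse_dataset(
      ft(comm, block = "16S", kind = "relative_abundance"),
      ft(chem, block = "icp", kind = "concentration_ppm"))
  })
}

# Map fitted type indices to planted types by majority membership.
map_types_to_truth <- function(labels, otu_truth) {
  vapply(sort(unique(labels)), function(g) {
    tt <- otu_truth[names(labels)[labels == g]]
    tt <- tt[tt > 0]
    if (!length(tt)) NA_integer_
    else as.integer(names(sort(table(tt), decreasing = TRUE))[1])
  }, integer(1))
}
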