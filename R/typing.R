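# Organization step: WCSS curve, elbow, PCA and k-means over the filtered
# correlation matrix.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Rows the clustering operates on.  Undefined correlations (constant
# profiles) are imputed as 0: no trend.
cluster_space_matrix <- function(m, cluster_space = c("corr_rows", "pc_scores_2d"),
                                 pca = NULL, centering = "mean") {
  cluster_space <- match.arg(cluster_space)
  x <- m$rho
  x[is.na(x)] <- 0
  if (cluster_space == "pc_scores_2d") {
    if (is.null(pca)) pca <- pca_decompose(m, centering = centering)
    x <- pca$scores[, 1:2, drop = FALSE]
  }
  x
}

#' Within-cluster sum-of-squares curve over candidate cluster counts
#'
#' For each k from 1 to `k_max`, runs k-means (best of `n_init` random
#' starts) on the filtered correlation rows and records the total
#' within-cluster sum of squared Euclidean distances to the centroids
#' ("least-squares structuring").  The curve against k is the basis for
#' choosing the number of BGC types.
#'
#' @param m a filtered `bgc_corr`.
#' @param k_max largest cluster count tested (default 15).
#' @param seed RNG seed controlling the k-means starts.
#' @param n_init number of random starts per k (default 50).
#' @param cluster_space `"corr_rows"` (default) to cluster the full
#'   correlation rows, or `"pc_scores_2d"` for the first two PC scores.
#' @return a `wcss_curve`: list with `k_values`, `wcss`, `n_init`, `seed`.
#' @export
wcss_curve <- function(m, k_max = 15, seed = 1L, n_init = 50L,
                       cluster_space = "corr_rows") {
  x <- cluster_space_matrix(m, cluster_space)
  if (k_max > nrow(x))
    stop("k_max (", k_max, ") exceeds the number of OTU rows (", nrow(x), ")")
  wcss <- with_seed(seed, vapply(seq_len(k_max), function(k) {
    if (k == nrow(x)) return(0)  # every row its own cluster
    km <- suppressWarnings(
      stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100L))
    km$tot.withinss
  }, numeric(1)))
  structure(list(k_values = seq_len(k_max), wcss = wcss,
                 n_init = n_init, seed = seed, cluster_space = cluster_space),
            class = "wcss_curve")
}

#' @export
print.wcss_curve <- function(x, ...) {
  cat("<wcss_curve> k = 1..", max(x$k_values), " (n_init = ", x$n_init, ")\n",
      sep = "")
  print(stats::setNames(signif(x$wcss, 4), x$k_values))
  invisible(x)
}

#' Pick the cluster count at the inflexion of the WCSS curve
#'
#' The elbow is located as the k in `2..(k_max - 1)` maximizing the discrete
#' second difference `wcss[k-1] - 2 wcss[k] + wcss[k+1]`; ties break toward
#' the smaller k.  When no second difference is positive (a straight or
#' convexity-free curve) the curve has no elbow: the smallest maximizing k
#' is still returned, with a warning, and the full profile is attached so
#' the choice can be overridden.
#'
#' @param curve a `wcss_curve`.
#' @return integer k, with attributes `second_differences` (data.frame over
#'   k) and `no_elbow` (logical).
#' @export
select_k_by_elbow <- function(curve) {
  stopifnot(inherits(curve, "wcss_curve"))
  w <- curve$wcss
  k_max <- length(w)
  if (k_max < 3) stop("need k_max >= 3 to locate an inflexion")
  ks <- 2:(k_max - 1)
  d2 <- w[ks - 1] - 2 * w[ks] + w[ks + 1]
  tol <- 1e-10 * max(abs(w), 1)
  no_elbow <- all(d2 <= tol)
  if (no_elbow)
    warning("WCSS curve shows no elbow (no positive second difference); ",
            "consider setting k explicitly")
  k <- ks[which.max(d2)]  # which.max takes the first, i.e. smallest k, on ties
  structure(as.integer(k),
            second_differences = data.frame(k = ks, second_difference = d2),
            no_elbow = no_elbow)
}

#' PCA of the filtered correlation matrix
#'
#' Decomposes the OTU x chemical correlation matrix into scores (per OTU)
#' and loadings (per chemical variable).  Columns are mean-centered by
#' default; no variance scaling is applied since every entry is already a
#' correlation on a common scale.  Component signs follow a deterministic
#' convention: each loading column is flipped so its largest-magnitude entry
#' is positive.
#'
#' @param m a filtered `bgc_corr`.
#' @param centering `"mean"` (default) or `"none"`.
#' @return a `bgc_pca`: list with `scores`, `loadings` (orthonormal
#'   columns), `explained_variance`, `centering`.
#' @export
pca_decompose <- function(m, centering = c("mean", "none")) {
  centering <- match.arg(centering)
  x <- m$rho
  x[is.na(x)] <- 0
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 OTU rows and 2 chemical columns")
  if (all(x == 0)) stop("correlation matrix has rank 0")
  p <- stats::prcomp(x, center = centering == "mean", scale. = FALSE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(scores = p$x, loadings = p$rotation,
                 explained_variance = p$sdev^2, centering = centering),
            class = "bgc_pca")
}

#' Delimit BGC types by k-means clustering
#'
#' Partitions the filtered OTUs into k BGC types with k-means
#' (squared-Euclidean, best of `n_init` random starts), either on the full
#' correlation rows (default; equivalent to clustering all PC scores) or on
#' the first two PC scores to mirror a score-plot delimitation.  Labels are
#' renumbered deterministically by descending cluster size, ties broken by
#' the lexicographically smallest member id, so "BGC type 1..k" is stable
#' across runs.
#'
#' @param m a filtered `bgc_corr`.
#' @param k number of BGC types (>= 2).
#' @param cluster_space `"corr_rows"` or `"pc_scores_2d"`.
#' @param seed RNG seed.
#' @param n_init number of random starts (default 50).
#' @param curve optional `wcss_curve` to attach.
#' @param pca optional precomputed `bgc_pca`; computed here if missing.
#' @param centering forwarded to [pca_decompose()] when `pca` is missing.
#' @return a `bgc_partition`: list with `labels` (named integer vector
#'   otu id -> 1..k), `k`, `curve`, `pca`, `cluster_space`, `seed`.
#' @export
cluster_bgc_types <- function(m, k, cluster_space = c("corr_rows", "pc_scores_2d"),
                              seed = 1L, n_init = 50L, curve = NULL,
                              pca = NULL, centering = "mean") {
  cluster_space <- match.arg(cluster_space)
  if (k < 2) stop("k must be at least 2")
  if (is.null(pca)) pca <- pca_decompose(m, centering = centering)
  x <- cluster_space_matrix(m, cluster_space, pca = pca)
  if (k > nrow(x))
    stop("k (", k, ") exceeds the number of OTU rows (", nrow(x), ")")
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100L)))
  raw <- km$cluster
  sizes <- tabulate(raw, nbins = k)
  min_id <- vapply(seq_len(k), function(g)
    min(rownames(x)[raw == g]), character(1))
  new_order <- order(-sizes, min_id)
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k)
  labels <- stats::setNames(relabel[raw], rownames(x))
  structure(list(labels = labels, k = as.integer(k), curve = curve,
                 pca = pca, cluster_space = cluster_space, seed = seed,
                 n_init = n_init),
            class = "bgc_partition")
}

#' @export
print.bgc_partition <- function(x, ...) {
  cat(sprintf("<bgc_partition> %d OTUs in %d BGC types (%s)\n",
              length(x$labels), x$k, x$cluster_space))
  print(table(`BGC type` = x$labels))
  invisible(x)
}
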