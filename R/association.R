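#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average (fractional) ranks; ties receive the mean
#' of the ranks they span.  Returns `NA` when either vector is constant,
#' since a flat profile shows no trend to correlate.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return a correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not permitted")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation matrix between community and chemicals
#'
#' Correlates every OTU row of the fused community matrix against every row
#' of the fused chemicals matrix across the shared sampling points.
#' Undefined pairs (a constant OTU or chemical profile) are `NA` and flagged
#' in `undefined_mask`.
#'
#' @param d a `fused_dataset` from [fuse_dataset()].
#' @return a `bgc_corr` object: list with `rho` (OTU x chemical matrix),
#'   `undefined_mask`, `n_samples`, and `chem_blocks` (source platform of
#'   each chemical column).
#' @export
correlation_matrix <- function(d) {
  stopifnot(inherits(d, "fused_dataset"))
  comm <- d$community$values
  chem <- d$chemicals$values
  if (ncol(comm) < 3) stop("need at least 3 sampling points")
  rho <- suppressWarnings(
    stats::cor(t(comm), t(chem), method = "spearman"))
  const_otu <- apply(comm, 1L, function(r) stats::var(r) == 0)
  const_chem <- apply(chem, 1L, function(r) stats::var(r) == 0)
  mask <- outer(const_otu, const_chem, "|")
  rho[mask] <- NA_real_
  dimnames(mask) <- dimnames(rho)
  structure(list(rho = rho, undefined_mask = mask,
                 n_samples = ncol(comm),
                 chem_blocks = sub(":.*$", "", colnames(rho))),
            class = "bgc_corr")
}

#' @export
print.bgc_corr <- function(x, ...) {
  cat(sprintf("<bgc_corr> %d OTUs x %d chemical variables (n = %d samples)\n",
              nrow(x$rho), ncol(x$rho), x$n_samples))
  if (any(x$undefined_mask))
    cat(sprintf("  %d undefined entries (constant profiles)\n",
                sum(x$undefined_mask)))
  invisible(x)
}

#' Filtration: keep OTUs reaching the correlation threshold
#'
#' Retains the OTU rows having at least one defined Spearman coefficient of
#' magnitude greater than or equal to `threshold` against any chemical
#' variable (inclusive comparison).  All chemical columns are kept, including
#' sub-threshold ones, because the downstream PCA and chemical profiling
#' span the full chemical axis.
#'
#' @param m a `bgc_corr` from [correlation_matrix()].
#' @param threshold magnitude cut in `[0, 1]`; default 0.70.
#' @return the row-subset `bgc_corr`, with a `retained_by_domain` element
#'   counting kept OTUs per source block.
#' @export
filter_otus_by_max_abs_correlation <- function(m, threshold = 0.70) {
  stopifnot(inherits(m, "bgc_corr"))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  amax <- apply(abs(m$rho), 1L, function(r)
    if (all(is.na(r))) -Inf else max(r, na.rm = TRUE))
  keep <- amax >= threshold
  m$rho <- m$rho[keep, , drop = FALSE]
  m$undefined_mask <- m$undefined_mask[keep, , drop = FALSE]
  dom <- sub(":.*$", "", rownames(m$rho))
  m$retained_by_domain <- if (nrow(m$rho)) table(dom) else table(character(0))
  m$threshold <- threshold
  m
}

#' One-dimensional STOCSY against a driver bin
#'
#' Statistical total correlation spectroscopy: the Pearson correlation and
#' covariance of one spectral bin's intensity vector against every bin in
#' the table, across samples.  High correlation flags bins fluctuating with
#' the driver, supporting a shared-compound annotation.
#'
#' @param spectra a [feature_table] of bin integrals (rows = bins).
#' @param driver_id the id of the driver bin.
#' @return data.frame with columns `feature_id`, `correlation`, `covariance`.
#' @export
stocsy_1d <- function(spectra, driver_id) {
  stopifnot(inherits(spectra, "feature_table"))
  v <- spectra$values
  if (!driver_id %in% rownames(v)) stop("driver bin not found: ", driver_id)
  if (ncol(v) < 3) stop("need at least 3 samples")
  drv <- v[driver_id, ]
  if (stats::var(drv) == 0) stop("driver bin is constant across samples")
  cors <- suppressWarnings(as.vector(stats::cor(t(v), drv)))
  covs <- as.vector(stats::cov(t(v), drv))
  data.frame(feature_id = rownames(v), correlation = cors,
             covariance = covs, row.names = NULL,
             stringsAsFactors = FALSE)
}
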