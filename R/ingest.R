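#' Drop OTUs supported by fewer than `min_total` reads
#'
#' OTUs represented by a single read over all sampling points carry no trend
#' a rank correlation could detect, so they are removed before
#' normalization.  The threshold is on the total read count across samples,
#' not on the number of samples with non-zero counts.
#'
#' @param x a [feature_table] with `value_kind = "counts"`.
#' @param min_total minimum total reads an OTU must reach to be kept
#'   (default 2, i.e. singletons are dropped).
#' @return the filtered [feature_table]; row order is preserved.
#' @export
filter_singleton_otus <- function(x, min_total = 2) {
  stopifnot(inherits(x, "feature_table"))
  if (x$value_kind != "counts")
    stop("singleton filtering is defined for count tables, got value_kind = ",
         x$value_kind)
  keep <- rowSums(x$values) >= min_total
  x$values <- x$values[keep, , drop = FALSE]
  if (!is.null(x$taxonomy))
    x$taxonomy <- x$taxonomy[intersect(names(x$taxonomy), rownames(x$values))]
  x
}

#' Convert counts to per-sample relative abundances
#'
#' Each OTU's reads are divided by the total reads of its sampling point, so
#' every column of the result sums to one.  Normalization is done within one
#' domain table at a time; fuse the domains afterwards.
#'
#' @param x a [feature_table] with `value_kind = "counts"`.
#' @return a [feature_table] with `value_kind = "relative_abundance"`.
#' @export
to_relative_abundance <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (x$value_kind != "counts")
    stop("normalization expects a count table, got value_kind = ", x$value_kind)
  tot <- colSums(x$values)
  if (any(tot <= 0))
    stop("sample(s) with zero total reads: ",
         paste(colnames(x$values)[tot <= 0], collapse = ", "))
  x$values <- sweep(x$values, 2L, tot, "/")
  x$value_kind <- "relative_abundance"
  x
}

#' Fuse several tables sharing the same sampling points
#'
#' Row-concatenates tables observed over identical, identically ordered
#' sampling points into one matrix (the "matrix community" or the "matrix
#' chemicals").  Feature ids are made globally unique by prefixing each with
#' its source block (`"16S:otu7"`); taxonomy maps are merged under the
#' prefixed ids.
#'
#' @param tables list of [feature_table]s.
#' @param target_block `"fused_community"` or `"fused_chemicals"`.
#' @return the fused [feature_table].
#' @export
fuse_tables <- function(tables, target_block) {
  stopifnot(length(tables) >= 1, all(vapply(tables, inherits, TRUE, "feature_table")))
  ref <- colnames(tables[[1]]$values)
  for (t in tables[-1]) {
    ids <- colnames(t$values)
    if (!identical(ids, ref)) {
      miss <- setdiff(ref, ids); extra <- setdiff(ids, ref)
      if (length(miss) || length(extra))
        stop("sample ids differ between tables; missing: {",
             paste(miss, collapse = ", "), "}, unexpected: {",
             paste(extra, collapse = ", "), "}")
      stop("sample ids agree but their order differs: ",
           paste(ids, collapse = ", "), " vs ", paste(ref, collapse = ", "))
    }
  }
  parts <- lapply(tables, function(t) {
    v <- t$values
    rownames(v) <- paste(t$block, rownames(v), sep = ":")
    v
  })
  v <- do.call(rbind, parts)
  tax <- NULL
  for (t in tables) {
    if (!is.null(t$taxonomy)) {
      tt <- t$taxonomy
      names(tt) <- paste(t$block, names(tt), sep = ":")
      tax <- c(tax, tt)
    }
  }
  kinds <- unique(vapply(tables, function(t) t$value_kind, character(1)))
  kind <- if (length(kinds) == 1) kinds else "mixed"
  feature_table(v, block = target_block, value_kind = kind, taxonomy = tax)
}

#' Pair a fused community matrix with a fused chemicals matrix
#'
#' @param community list of domain count tables (filtered and normalized
#'   automatically when `value_kind = "counts"`), or a single already fused
#'   relative-abundance table.
#' @param chemicals list of chemical-platform tables, or a single fused table.
#' @param min_total singleton threshold forwarded to
#'   [filter_singleton_otus()].
#' @return a `fused_dataset`: list with elements `community`, `chemicals`
#'   (both [feature_table]s over identical ordered sampling points) and
#'   `sample_ids`.
#' @export
fuse_dataset <- function(community, chemicals, min_total = 2) {
  if (inherits(community, "feature_table")) community <- list(community)
  if (inherits(chemicals, "feature_table")) chemicals <- list(chemicals)
  community <- lapply(community, function(t) {
    if (t$value_kind == "counts")
      t <- to_relative_abundance(filter_singleton_otus(t, min_total))
    t
  })
  comm <- if (length(community) == 1 && community[[1]]$block == "fused_community")
    community[[1]] else fuse_tables(community, "fused_community")
  chem <- if (length(chemicals) == 1 && chemicals[[1]]$block == "fused_chemicals")
    chemicals[[1]] else fuse_tables(chemicals, "fused_chemicals")
  if (!identical(colnames(comm$values), colnames(chem$values)))
    stop("community and chemicals matrices disagree on sampling points: ",
         paste(colnames(comm$values), collapse = ", "), " vs ",
         paste(colnames(chem$values), collapse = ", "))
  structure(list(community = comm, chemicals = chem,
                 sample_ids = colnames(comm$values)),
            class = "fused_dataset")
}

#' @export
print.fused_dataset <- function(x, ...) {
  cat(sprintf("<fused_dataset> %d OTUs x %d chemical variables over %d sampling points\n",
              nrow(x$community$values), nrow(x$chemicals$values),
              length(x$sample_ids)))
  invisible(x)
}
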