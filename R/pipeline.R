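#' Fit the biogeochemical typing pipeline
#'
#' Runs the full three-step procedure — Filtration, Organization,
#' Description — over paired community and chemical tables observed at the
#' same sampling points:
#' \enumerate{
#'   \item domain count tables are singleton-filtered, normalized to
#'     relative abundances and fused into the community matrix; chemical
#'     platform tables are fused into the chemicals matrix;
#'   \item every OTU is Spearman-correlated against every chemical
#'     variable, and OTUs reaching `|rho| >= threshold` for at least one
#'     variable are retained;
#'   \item the number of BGC types is chosen at the inflexion of the
#'     within-cluster sum-of-squares curve (k = 1..`k_max`), the retained
#'     correlation rows are decomposed by PCA, and k-means delimits the
#'     types;
#'   \item each type is described by its community distribution over
#'     sampling points, a class-level taxonomy breakdown, and the chemical
#'     profile extracted by the STDEVP rule.
#' }
#'
#' @param community list of domain count [feature_table]s (or one fused
#'   relative-abundance table), as from [read_feature_table()] or
#'   [generate_bgc_dataset()].
#' @param chemicals list of chemical platform [feature_table]s (or one
#'   fused table).
#' @param threshold Spearman magnitude cut for the Filtration step
#'   (default 0.70, inclusive).
#' @param k_max largest cluster count tested on the WCSS curve (default 15;
#'   reduced automatically when fewer OTUs are retained).
#' @param k number of BGC types; `NULL` (default) selects it from the WCSS
#'   elbow.
#' @param stdevp_cut STDEVP threshold for chemical-profile extraction
#'   (default 0.20).
#' @param stdevp_compare `"raw"` or `"scaled"` pair comparison, see
#'   [extract_chemical_profile()].
#' @param cluster_space `"corr_rows"` (default) or `"pc_scores_2d"`.
#' @param centering PCA centering, `"mean"` (default) or `"none"`.
#' @param seed RNG seed for the k-means restarts.
#' @param n_init k-means restarts per k (default 50).
#' @param min_total singleton-filter threshold (default 2).
#' @param verbose print row/column counts at stage boundaries.
#' @return an object of class `bgc_typing`; see [print.bgc_typing()],
#'   [summary.bgc_typing()], [plot.bgc_typing()], and the accessors
#'   [labels.bgc_typing()] and [chem_profile()].
#' @examples
#' ds <- generate_bgc_dataset(bgc_synth_spec(seed = 42))
#' fit <- bgc_typing(ds$community, ds$chemicals, seed = 42)
#' fit
#' @export
bgc_typing <- function(community, chemicals, threshold = 0.70, k_max = 15,
                       k = NULL, stdevp_cut = 0.20,
                       stdevp_compare = c("raw", "scaled"),
                       cluster_space = c("corr_rows", "pc_scores_2d"),
                       centering = c("mean", "none"), seed = 1L,
                       n_init = 50L, min_total = 2, verbose = FALSE) {
  cluster_space <- match.arg(cluster_space)
  stdevp_compare <- match.arg(stdevp_compare)
  centering <- match.arg(centering)
  say <- function(...) if (verbose) message(sprintf(...))

  d <- fuse_dataset(community, chemicals, min_total = min_total)
  say("fused: %d OTUs x %d chemical variables over %d sampling points",
      nrow(d$community$values), nrow(d$chemicals$values), length(d$sample_ids))

  corr <- correlation_matrix(d)
  filt <- filter_otus_by_max_abs_correlation(corr, threshold = threshold)
  if (nrow(filt$rho) < 2)
    stop("fewer than 2 OTUs reach |rho| >= ", threshold,
         "; nothing to organize")
  say("filtration |rho| >= %.2f retained %d OTUs (%s)", threshold,
      nrow(filt$rho),
      paste(sprintf("%s: %d", names(filt$retained_by_domain),
                    as.integer(filt$retained_by_domain)), collapse = ", "))

  k_max_eff <- min(k_max, nrow(filt$rho))
  curve <- wcss_curve(filt, k_max = k_max_eff, seed = seed, n_init = n_init,
                      cluster_space = cluster_space)
  k_sel <- select_k_by_elbow(curve)
  k_used <- if (is.null(k)) as.integer(k_sel) else as.integer(k)
  say("WCSS elbow suggests k = %d; using k = %d", as.integer(k_sel), k_used)

  pca <- pca_decompose(filt, centering = centering)
  partition <- cluster_bgc_types(filt, k = k_used,
                                 cluster_space = cluster_space, seed = seed,
                                 n_init = n_init, curve = curve, pca = pca)
  dist <- community_distribution(partition, d$community)
  taxa <- if (!is.null(d$community$taxonomy))
    collapse_taxonomy(partition, d$community) else NULL
  profile <- extract_chemical_profile(filt, partition, cut = stdevp_cut,
                                      compare = stdevp_compare)

  manifest <- list(
    parameters = list(threshold = threshold, k_max = k_max,
                      k_requested = if (is.null(k)) "auto" else k,
                      k_used = k_used, k_elbow = as.integer(k_sel),
                      stdevp_cut = stdevp_cut, stdevp_compare = stdevp_compare,
                      cluster_space = cluster_space,
                      centering = centering, seed = seed, n_init = n_init,
                      min_total = min_total),
    dimensions = list(
      n_samples = length(d$sample_ids),
      n_otus_fused = nrow(d$community$values),
      n_chems = nrow(d$chemicals$values),
      n_otus_retained = nrow(filt$rho),
      retained_by_domain = as.list(filt$retained_by_domain)),
    checksums = list(
      community = format(sum(d$community$values), digits = 15),
      chemicals = format(sum(d$chemicals$values), digits = 15)),
    version = as.character(utils::packageVersion("bgctyper")))

  structure(list(dataset = d, correlation = corr, filtered = filt,
                 curve = curve, k_elbow = k_sel, pca = pca,
                 partition = partition, distribution = dist,
                 taxonomy_breakdown = taxa, profile = profile,
                 manifest = manifest),
            class = "bgc_typing")
}

#' @export
print.bgc_typing <- function(x, ...) {
  p <- x$manifest$parameters
  dims <- x$manifest$dimensions
  cat("Biogeochemical typing\n")
  cat(sprintf("  %d OTUs x %d chemical variables over %d sampling points\n",
              dims$n_otus_fused, dims$n_chems, dims$n_samples))
  cat(sprintf("  Filtration |rho| >= %.2f: %d OTUs retained (%s)\n",
              p$threshold, dims$n_otus_retained,
              paste(sprintf("%s %d", names(dims$retained_by_domain),
                            unlist(dims$retained_by_domain)), collapse = ", ")))
  cat(sprintf("  Organization: k = %d BGC types (elbow suggested %d), %s\n",
              p$k_used, p$k_elbow, p$cluster_space))
  sizes <- table(x$partition$labels)
  cat(sprintf("  Type sizes: %s\n",
              paste(sprintf("%s: %d", names(sizes), as.integer(sizes)),
                    collapse = ", ")))
  n_ext <- tapply(x$profile$extracted, x$profile$type, sum)
  cat(sprintf("  Extracted chemical variables per type: %s\n",
              paste(sprintf("%s: %d", names(n_ext), as.integer(n_ext)),
                    collapse = ", ")))
  invisible(x)
}

#' Summarize a biogeochemical typing fit
#' @param object a `bgc_typing` fit.
#' @param ... unused.
#' @return a `summary.bgc_typing` list with per-type membership counts,
#'   explaining PCs and extracted chemical variables.
#' @export
summary.bgc_typing <- function(object, ...) {
  labels <- object$partition$labels
  doms <- sub(":.*$", "", names(labels))
  prof <- object$profile
  types <- sort(unique(labels))
  per_type <- lapply(types, function(g) {
    sub <- prof[prof$type == g & prof$extracted, ]
    list(size = sum(labels == g),
         by_domain = table(doms[labels == g]),
         explaining_pc = prof$explaining_pc[prof$type == g][1],
         extracted = split(sub$chem_id, sub$block))
  })
  names(per_type) <- paste("BGC type", types)
  structure(list(manifest = object$manifest, per_type = per_type,
                 wcss = object$curve),
            class = "summary.bgc_typing")
}

#' @export
print.summary.bgc_typing <- function(x, ...) {
  p <- x$manifest$parameters
  cat(sprintf("BGC typing: k = %d (elbow %d), |rho| >= %.2f, STDEVP cut %.2f\n",
              p$k_used, p$k_elbow, p$threshold, p$stdevp_cut))
  for (nm in names(x$per_type)) {
    t <- x$per_type[[nm]]
    cat(sprintf("\n%s — %d OTUs (%s), explained by PC%d\n", nm, t$size,
                paste(sprintf("%s %d", names(t$by_domain),
                              as.integer(t$by_domain)), collapse = ", "),
                t$explaining_pc))
    if (length(t$extracted) == 0) {
      cat("  no chemical variables extracted\n")
    } else {
      for (b in names(t$extracted))
        cat(sprintf("  %s: %s\n", b, paste(t$extracted[[b]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Plot the WCSS curve and the PC1/PC2 score plot of a fit
#'
#' Left panel: within-cluster sum of squares against the number of
#' clusters, with the chosen k marked.  Right panel: the retained OTUs on
#' PC1/PC2, colored by BGC type.
#'
#' @param x a `bgc_typing` fit.
#' @param ... forwarded to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bgc_typing <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$curve$k_values, x$curve$wcss, type = "b",
                 xlab = "number of clusters",
                 ylab = "within-cluster sum of squares", ...)
  graphics::abline(v = x$partition$k, lty = 2)
  cols <- grDevices::hcl.colors(x$partition$k, "Dark 3")
  sc <- x$pca$scores
  ev <- x$pca$explained_variance
  graphics::plot(sc[, 1], sc[, 2],
                 col = cols[x$partition$labels[rownames(sc)]],
                 pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * ev[1] / sum(ev)),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * ev[2] / sum(ev)), ...)
  graphics::legend("topright", legend = paste("BGC", seq_len(x$partition$k)),
                   col = cols, pch = 16, cex = 0.8)
  invisible(x)
}

#' BGC type labels of a fit
#' @param object a `bgc_typing` fit.
#' @param ... unused.
#' @return named integer vector, OTU id -> type index.
#' @export
labels.bgc_typing <- function(object, ...) object$partition$labels

#' Chemical profile table of a fit
#' @param object a `bgc_typing` fit.
#' @param extracted_only keep only the extracted variables (default FALSE).
#' @return the `chemical_profile` data.frame.
#' @export
chem_profile <- function(object, extracted_only = FALSE) {
  stopifnot(inherits(object, "bgc_typing"))
  p <- object$profile
  if (extracted_only) p[p$extracted, ] else p
}

#' Write the report files of a fit
#'
#' Writes, under `outdir`: `labels.tsv`, `wcss.tsv`, `pca_scores.tsv`,
#' `pca_loadings.tsv`, `correlation_filtered.tsv` (plus an
#' `undefined_mask.tsv` sidecar), `community_distribution.tsv`,
#' `taxonomy_breakdown.tsv` (when taxonomy is available),
#' `chemical_profile.tsv`, and `manifest.json`.
#'
#' @param fit a `bgc_typing` fit.
#' @param outdir output directory, created if needed.
#' @param plots also write `bgc_typing.pdf` with the diagnostic plots.
#' @return character vector of the files written, invisibly.
#' @export
write_bgc_reports <- function(fit, outdir, plots = FALSE) {
  stopifnot(inherits(fit, "bgc_typing"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  written <- character(0)
  w <- function(obj, name, ...) {
    path <- file.path(outdir, name)
    utils::write.table(obj, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, ...)
    written <<- c(written, path)
  }
  lab <- fit$partition$labels
  w(data.frame(otu_id = names(lab), type = as.integer(lab)), "labels.tsv")
  w(data.frame(k = fit$curve$k_values, wcss = fit$curve$wcss), "wcss.tsv")
  sc <- fit$pca$scores
  w(data.frame(otu_id = rownames(sc), sc, check.names = FALSE),
    "pca_scores.tsv")
  lo <- fit$pca$loadings
  w(data.frame(chem_id = rownames(lo), lo, check.names = FALSE),
    "pca_loadings.tsv")
  rho <- fit$filtered$rho
  w(data.frame(otu_id = rownames(rho), rho, check.names = FALSE),
    "correlation_filtered.tsv")
  w(data.frame(otu_id = rownames(rho), fit$filtered$undefined_mask,
               check.names = FALSE), "undefined_mask.tsv")
  w(fit$distribution, "community_distribution.tsv")
  if (!is.null(fit$taxonomy_breakdown))
    w(fit$taxonomy_breakdown, "taxonomy_breakdown.tsv")
  w(as.data.frame(fit$profile), "chemical_profile.tsv")
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(fit$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  written <- c(written, manifest_path)
  if (plots) {
    pdf_path <- file.path(outdir, "bgc_typing.pdf")
    grDevices::pdf(pdf_path, width = 10, height = 5)
    plot(fit)
    grDevices::dev.off()
    written <- c(written, pdf_path)
  }
  invisible(written)
}

#' Recompute the survey head-counts from the original processed tables
#'
#' Given a directory holding the six processed survey tables
#' (`archaea.tsv`, `16S.tsv`, `18S.tsv` as OTU counts; `icp.tsv`,
#' `ftir.tsv`, `nmr.tsv` as chemical variables; TSV dialect of
#' [read_feature_table()]), reruns the Filtration and Organization steps
#' and returns the head-line numbers: OTUs kept per domain by the singleton
#' filter, OTUs retained per domain at the correlation threshold, and the
#' cluster count selected from the WCSS elbow.
#'
#' @param dir directory containing the six TSV tables.
#' @param threshold,k_max,seed,n_init forwarded to the pipeline steps.
#' @return list with `singleton_kept`, `retained`, and `selected_k`.
#' @export
reproduce_survey_counts <- function(dir, threshold = 0.70, k_max = 15,
                                    seed = 1L, n_init = 50L) {
  paths <- file.path(dir, c("archaea.tsv", "16S.tsv", "18S.tsv",
                            "icp.tsv", "ftir.tsv", "nmr.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("survey table(s) not found: ", paste(missing, collapse = ", "))
  comm <- list(
    read_feature_table(paths[1], "tsv", block = "archaea"),
    read_feature_table(paths[2], "tsv", block = "16S"),
    read_feature_table(paths[3], "tsv", block = "18S"))
  chem <- list(
    read_feature_table(paths[4], "tsv", block = "icp",
                       value_kind = "concentration_ppm"),
    read_feature_table(paths[5], "tsv", block = "ftir",
                       value_kind = "integral"),
    read_feature_table(paths[6], "tsv", block = "nmr",
                       value_kind = "integral"))
  kept <- vapply(comm, function(t) nrow(filter_singleton_otus(t)$values), 1L)
  names(kept) <- c("archaea", "16S", "18S")
  fit <- bgc_typing(comm, chem, threshold = threshold, k_max = k_max,
                    seed = seed, n_init = n_init)
  list(singleton_kept = kept,
       retained = unlist(fit$manifest$dimensions$retained_by_domain),
       selected_k = fit$manifest$parameters$k_elbow)
}
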