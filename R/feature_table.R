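#' Feature-by-sample tables
#'
#' A `feature_table` is the basic container of the package: a numeric matrix
#' of features (OTUs or chemical variables) in rows against sampling points
#' in columns, together with a block label saying where the table comes from
#' (an amplicon domain, a chemical platform, or a fused matrix), the kind of
#' value it holds, and an optional taxonomy lineage per feature.
#'
#' @param values numeric matrix, rows = features, columns = sampling points.
#'   Row and column names are required and become the feature and sample ids.
#' @param block one of `"archaea"`, `"16S"`, `"18S"` (community domains),
#'   `"icp"`, `"ftir"`, `"nmr"` (chemical platforms), `"fused_community"`,
#'   `"fused_chemicals"`.
#' @param value_kind one of `"counts"`, `"relative_abundance"`,
#'   `"concentration_ppm"`, `"integral"`, or `"mixed"` (fused chemical
#'   tables combine ppm concentrations with spectral integrals).
#' @param taxonomy optional named list mapping feature id to a character
#'   vector lineage ordered from domain towards species.  Only meaningful
#'   for community blocks.
#' @return an object of class `feature_table`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' feature_table(m, block = "16S", value_kind = "counts")
#' @export
feature_table <- function(values, block, value_kind, taxonomy = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values))) {
    if (nrow(values) == 0) rownames(values) <- character(0)
    else stop("`values` must carry feature ids as rownames")
  }
  if (is.null(colnames(values)))
    stop("`values` must carry sample ids as colnames")
  block <- match.arg(block, c("archaea", "16S", "18S", "icp", "ftir", "nmr",
                              "fused_community", "fused_chemicals"))
  value_kind <- match.arg(value_kind, c("counts", "relative_abundance",
                                        "concentration_ppm", "integral", "mixed"))
  x <- structure(list(values = values, block = block, value_kind = value_kind,
                      taxonomy = taxonomy),
                 class = "feature_table")
  validate_feature_table(x)
}

validate_feature_table <- function(x) {
  v <- x$values
  dup <- unique(rownames(v)[duplicated(rownames(v))])
  if (length(dup))
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  dup <- unique(colnames(v)[duplicated(colnames(v))])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  if (anyNA(v))
    stop("missing values are not permitted in feature tables")
  if (x$value_kind == "counts") {
    if (any(v < 0) || any(v != round(v)))
      stop("counts must be non-negative integers")
  }
  if (x$value_kind == "relative_abundance" &&
      (any(v < -1e-12) || any(v > 1 + 1e-12)))
    stop("relative abundances must lie in [0, 1]")
  if (!is.null(x$taxonomy)) {
    extra <- setdiff(names(x$taxonomy), rownames(v))
    if (length(extra))
      stop("taxonomy given for unknown feature id(s): ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  x
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> block=%s kind=%s: %d features x %d samples\n",
              x$block, x$value_kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$taxonomy))
    cat(sprintf("  taxonomy present for %d features\n", length(x$taxonomy)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample ids of a table
#' @param x a [feature_table]
#' @return character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a feature table from TSV or BIOM 1.0
#'
#' TSV dialect: UTF-8, tab-delimited, header row of sample ids, first column
#' of feature ids, and an optional final column named `taxonomy` holding a
#' semicolon-delimited lineage.  Rows are features unless
#' `orientation = "samples_in_rows"` is declared explicitly — orientation is
#' never guessed.  BIOM 1.0 (JSON) tables are read through the
#' \pkg{biomformat} package; taxonomy is taken from the observation metadata
#' key `taxonomy`.
#'
#' @param path file to read.
#' @param fmt `"tsv"` or `"biom"`.
#' @param block block label, see [feature_table()].
#' @param value_kind kind of value stored, see [feature_table()].
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @return a [feature_table].
#' @export
read_feature_table <- function(path, fmt = c("tsv", "biom"), block,
                               value_kind = "counts",
                               orientation = c("features_in_rows",
                                               "samples_in_rows")) {
  fmt <- match.arg(fmt)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    v <- as(biomformat::biom_data(b), "matrix")
    tax <- NULL
    md <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    if (!is.null(md)) {
      if (is.data.frame(md)) {
        # taxonomy-named columns when present, otherwise the whole
        # metadata row is taken as the lineage (the common BIOM layout)
        tcols <- grep("taxonomy", colnames(md), value = TRUE)
        if (!length(tcols)) tcols <- colnames(md)
        if (length(tcols)) {
          tax <- lapply(seq_len(nrow(md)), function(i) {
            l <- as.character(unlist(md[i, tcols]))
            l[!is.na(l) & nzchar(l)]
          })
          names(tax) <- rownames(md)
        }
      } else if (is.list(md)) {
        tax <- lapply(md, function(e) {
          keys <- grep("taxonomy", names(e), value = TRUE)
          if (!length(keys)) keys <- names(e)
          as.character(unlist(e[keys]))
        })
      }
      if (!is.null(tax)) {
        tax <- tax[vapply(tax, length, 1L) > 0]
        if (!length(tax)) tax <- NULL
      }
    }
    return(feature_table(v, block = block, value_kind = value_kind,
                         taxonomy = tax))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", fill = FALSE)
  if (ncol(raw) < 2) stop("TSV must have a feature-id column and >= 1 sample")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s): ", paste(dup, collapse = ", "))
  tax <- NULL
  body <- raw[-1L]
  if (tolower(colnames(body)[ncol(body)]) == "taxonomy") {
    lin <- body[[ncol(body)]]
    body <- body[-ncol(body)]
    tax <- lapply(strsplit(lin, ";", fixed = TRUE),
                  function(p) trimws(p)[nzchar(trimws(p))])
    names(tax) <- ids
    tax <- tax[vapply(tax, length, 1L) > 0]
    if (!length(tax)) tax <- NULL
  }
  v <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    col <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(col) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value %s at row '%s', column '%s'",
                   dQuote(body[[j]][bad[1]]), ids[bad[1]], colnames(body)[j]))
    v[, j] <- col
  }
  if (orientation == "samples_in_rows") v <- t(v)
  feature_table(v, block = block, value_kind = value_kind, taxonomy = tax)
}

#' Write a feature table as TSV
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces them bit for bit.  Taxonomy, when present, is
#' written as a final semicolon-delimited `taxonomy` column.
#'
#' @param x a [feature_table].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  v <- x$values
  txt <- matrix(formatC(v, format = "g", digits = 17), nrow(v), ncol(v))
  header <- c("feature_id", colnames(v))
  rows <- cbind(rownames(v), txt)
  if (!is.null(x$taxonomy)) {
    lin <- vapply(rownames(v), function(id) {
      l <- x$taxonomy[[id]]
      if (is.null(l)) "" else paste(l, collapse = ";")
    }, character(1))
    header <- c(header, "taxonomy")
    rows <- cbind(rows, lin)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
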