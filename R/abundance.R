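#' Abundance matrices
#'
#' An `abundance_matrix` is a numeric samples x features matrix of
#' non-negative abundances (counts or relative abundances) with unique sample
#' and feature labels and a `feature_kind` of `"taxon"` or `"ko"`. It is the
#' common container for OTU/taxon tables and predicted KO tables.
#'
#' @name abundance_matrix
NULL

#' Construct and validate an abundance matrix
#'
#' @param values numeric matrix, rows = samples, columns = features, with
#'   dimnames set. All entries must be finite and non-negative.
#' @param feature_kind `"taxon"` or `"ko"`.
#' @return an `abundance_matrix`.
#' @export
abundance_matrix <- function(values, feature_kind = c("taxon", "ko")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have sample (row) and feature (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature ids", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("abundances must be finite and non-missing", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative abundance at sample '", rownames(values)[bad[1]],
         "', feature '", colnames(values)[bad[2]], "'", call. = FALSE)
  }
  structure(values, feature_kind = feature_kind,
            class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d samples x %d %s features\n",
              nrow(x), ncol(x), attr(x, "feature_kind")))
  invisible(x)
}

#' Sample and feature accessors
#' @param m an `abundance_matrix`.
#' @return character vector of labels.
#' @export
sample_ids <- function(m) rownames(m)

#' @rdname sample_ids
#' @export
feature_ids <- function(m) colnames(m)

#' @rdname sample_ids
#' @export
feature_kind <- function(m) attr(m, "feature_kind")

#' Subset an abundance matrix to a set of samples
#'
#' @param m an `abundance_matrix`.
#' @param samples character vector of sample ids (order preserved).
#' @return an `abundance_matrix` over those samples.
#' @export
subset_samples <- function(m, samples) {
  missing <- setdiff(samples, rownames(m))
  if (length(missing)) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  abundance_matrix(unclass(m)[samples, , drop = FALSE], feature_kind(m))
}

#' Read an abundance table
#'
#' Reads a delimited taxon or KO abundance table. Following the QIIME/PICRUSt
#' convention the default orientation is features-as-rows; set
#' `orientation = "samples_rows"` for the transpose. A column (or row,
#' depending on orientation) named `taxonomy` holding Greengenes lineage
#' strings is split off and attached as the `"lineages"` attribute. BIOM
#' files (`.biom`) are read through the biomformat package when available.
#'
#' @param path file path (TSV/CSV, delimiter sniffed unless `sep` given, or
#'   `.biom`).
#' @param feature_kind `"taxon"` or `"ko"`.
#' @param orientation `"features_rows"` (default) or `"samples_rows"`.
#' @param sep field delimiter override.
#' @param normalize if `TRUE`, rescale each sample to relative abundances
#'   summing to 1. Off by default: Spearman correlation operates on whatever
#'   scale is supplied.
#' @return an `abundance_matrix`; lineages (if present in the file) in
#'   `attr(, "lineages")`.
#' @export
read_abundance_table <- function(path, feature_kind = c("taxon", "ko"),
                                 orientation = c("features_rows",
                                                 "samples_rows"),
                                 sep = NULL, normalize = FALSE) {
  feature_kind <- match.arg(feature_kind)
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    return(read_biom_table(path, feature_kind, normalize))
  }
  sep <- sep %||% sniff_delim(path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  lineages <- NULL
  taxcol <- which(tolower(names(df)) == "taxonomy")
  if (length(taxcol) == 1L && orientation == "features_rows") {
    lineages <- parse_lineages(stats::setNames(as.character(df[[taxcol]]),
                                               rownames(df)))
    df <- df[, -taxcol, drop = FALSE]
  }
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))) &
                   !is.na(mat), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("malformed numeric cell at row '", rownames(mat)[bad[1, 1]],
           "', column '", colnames(mat)[bad[1, 2]], "'", call. = FALSE)
    }
    mode(mat) <- "numeric"
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop("malformed or missing numeric cell at row '",
         rownames(mat)[bad[1, 1]], "', column '", colnames(mat)[bad[1, 2]],
         "'", call. = FALSE)
  }
  if (orientation == "features_rows") mat <- t(mat)
  m <- abundance_matrix(mat, feature_kind)
  if (normalize) m <- normalize_relative(m)
  attr(m, "lineages") <- lineages
  m
}

read_biom_table <- function(path, feature_kind, normalize = FALSE) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading .biom files requires the biomformat package",
         call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  mat <- t(as.matrix(biomformat::biom_data(b)))  # biom stores features x samples
  m <- abundance_matrix(mat, feature_kind)
  if (normalize) m <- normalize_relative(m)
  m
}

#' Write an abundance table as TSV (features as rows)
#'
#' @param m an `abundance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(m, path) {
  stopifnot(inherits(m, "abundance_matrix"))
  out <- t(unclass(m))
  df <- data.frame(feature_id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- "#feature_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Per-sample relative-abundance normalization
#'
#' Divides each sample (row) by its total. Samples with zero total are left
#' at zero. Note Spearman correlation is invariant to per-feature monotone
#' transforms but not to this per-sample renormalization, so the choice of
#' scale is an analysis decision, off by default everywhere.
#'
#' @param m an `abundance_matrix`.
#' @return an `abundance_matrix` of row-relative abundances.
#' @export
normalize_relative <- function(m) {
  tot <- rowSums(m)
  tot[tot == 0] <- 1
  abundance_matrix(unclass(m) / tot, feature_kind(m))
}

#' Aggregate a taxon table to a taxonomic rank
#'
#' Collapses features by summing abundances over all features sharing the
#' same taxon name at the requested rank. Features lacking that rank are
#' pooled into the sentinel feature `"unassigned"`, which downstream
#' ancestor tests exclude by default; drop it here with
#' `keep_unassigned = FALSE`.
#'
#' @param m an `abundance_matrix` of kind `"taxon"`.
#' @param lineages named list of `lineage` objects covering every feature of
#'   `m` (lineage strings are also accepted).
#' @param rank one of [TAXONOMIC_RANKS].
#' @param keep_unassigned keep the `"unassigned"` bucket (default `TRUE`).
#' @return an `abundance_matrix` whose features are rank values.
#' @export
aggregate_to_rank <- function(m, lineages, rank, keep_unassigned = TRUE) {
  stopifnot(inherits(m, "abundance_matrix"))
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  if (is.character(lineages)) lineages <- parse_lineages(lineages)
  missing <- setdiff(feature_ids(m), names(lineages))
  if (length(missing)) {
    stop("no lineage for feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grp <- vapply(feature_ids(m),
                function(f) lineage_rank(lineages[[f]], rank),
                FUN.VALUE = "", USE.NAMES = FALSE)
  grp[is.na(grp)] <- "unassigned"
  agg <- t(rowsum(t(unclass(m)), group = grp))
  if (!keep_unassigned) {
    agg <- agg[, colnames(agg) != "unassigned", drop = FALSE]
  }
  abundance_matrix(agg, "taxon")
}
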