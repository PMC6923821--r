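#' KEGG module membership maps
#'
#' A `module_map` records which KO identifiers belong to each KEGG module
#' (e.g. M00159, the prokaryotic V-type ATPase, contains K02117-K02124). It
#' is consumed as a static two-column table standing in for a KEGG REST
#' lookup.
#'
#' @name module_map
NULL

#' Construct a module map
#'
#' @param modules named list: module id -> character vector of KO ids.
#'   Duplicated KOs within a module are deduplicated; empty modules or empty
#'   KO ids are rejected.
#' @return a `module_map`.
#' @export
module_map <- function(modules) {
  stopifnot(is.list(modules))
  if (length(modules) == 0L) {
    stop("module map is empty", call. = FALSE)
  }
  if (is.null(names(modules)) || any(!nzchar(names(modules)))) {
    stop("every module needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(names(modules))) {
    stop("duplicate module ids", call. = FALSE)
  }
  modules <- lapply(modules, function(k) sort(unique(as.character(k))))
  sizes <- lengths(modules)
  if (any(sizes == 0L)) {
    stop("module(s) with no KOs: ",
         paste(names(modules)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  if (any(vapply(modules, function(k) any(is.na(k) | !nzchar(k)), TRUE))) {
    stop("KO ids must be non-empty strings", call. = FALSE)
  }
  structure(modules, class = "module_map")
}

#' @export
print.module_map <- function(x, ...) {
  cat(sprintf("<module_map> %d modules, %d KO memberships\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Module size accessor
#' @param map a `module_map`.
#' @param module_id module identifier.
#' @return number of KOs in the module.
#' @export
module_size <- function(map, module_id) {
  stopifnot(inherits(map, "module_map"))
  if (!module_id %in% names(map)) {
    stop("unknown module: ", module_id, call. = FALSE)
  }
  length(map[[module_id]])
}

#' Read a KO-to-module membership table
#'
#' Two-column delimited file (module_id, ko_id); duplicate rows are allowed
#' and deduplicated.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` sniffs tab vs comma.
#' @param header whether a header row is present (default `FALSE`).
#' @return a `module_map`.
#' @export
read_module_map <- function(path, sep = NULL, header = FALSE) {
  if (file.size(path) == 0L) {
    stop("empty module map file: ", path, call. = FALSE)
  }
  sep <- sep %||% sniff_delim(path)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  if (ncol(df) < 2L) {
    stop("module map must have two columns (module_id, ko_id)",
         call. = FALSE)
  }
  module_map(split(as.character(df[[2]]), as.character(df[[1]])))
}

#' Write a module map as two-column TSV
#'
#' @param map a `module_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_module_map <- function(map, path) {
  stopifnot(inherits(map, "module_map"))
  df <- data.frame(module_id = rep(names(map), lengths(map)),
                   ko_id = unlist(map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group assignment table
#'
#' Two-column delimited file (sample_id, group label), e.g. assigning samples
#' to CDT, CDS or HCS. Every analyzed sample must carry exactly one label.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` sniffs tab vs comma.
#' @param header whether a header row is present (default `FALSE`).
#' @return named character vector: sample id -> group label.
#' @export
read_group_table <- function(path, sep = NULL, header = FALSE) {
  sep <- sep %||% sniff_delim(path)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  if (ncol(df) < 2L) {
    stop("group table must have two columns (sample_id, group)",
         call. = FALSE)
  }
  if (anyDuplicated(df[[1]])) {
    stop("sample(s) with more than one group label: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a sample-to-group table
#' @param groups named character vector (sample id -> group label).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_table <- function(groups, path) {
  utils::write.table(data.frame(names(groups), unname(groups)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
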