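#' Taxonomic lineages
#'
#' A `lineage` is an ordered assignment of taxon names to the seven canonical
#' ranks kingdom through species, parsed from Greengenes-style strings such as
#' `"k__Bacteria; p__Bacteroidetes; f__Bacteroidaceae"`. A rank whose payload
#' is empty (e.g. `"g__"`) is recorded as absent (`NA`), not as an
#' empty-string taxon.
#'
#' @name lineage
NULL

#' Canonical taxonomic rank names, kingdom to species
#' @export
TAXONOMIC_RANKS <- c("kingdom", "phylum", "class", "order",
                     "family", "genus", "species")

.rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", species = "s")

#' Parse a Greengenes-style lineage string
#'
#' Splits on semicolons, strips surrounding whitespace, and interprets the
#' single-letter rank prefixes `k__`, `p__`, `c__`, `o__`, `f__`, `g__`,
#' `s__`. Empty payloads become absent ranks.
#'
#' @param s a single lineage string.
#' @return an object of class `lineage`: a named character vector over the
#'   seven canonical ranks with `NA` for absent ranks.
#' @examples
#' parse_lineage("k__Bacteria; p__Bacteroidetes; f__Bacteroidaceae")
#' @export
parse_lineage <- function(s) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  out <- stats::setNames(rep(NA_character_, 7L), TAXONOMIC_RANKS)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  for (p in parts) {
    m <- regmatches(p, regexec("^([A-Za-z]+)__(.*)$", p))[[1]]
    if (length(m) != 3L || !(m[2] %in% .rank_prefixes)) {
      stop("unknown rank prefix in lineage field: '", p, "'", call. = FALSE)
    }
    rank <- names(.rank_prefixes)[match(m[2], .rank_prefixes)]
    payload <- trimws(m[3])
    if (nzchar(payload)) out[rank] <- payload
  }
  structure(out, class = "lineage")
}

#' Parse a vector of lineage strings
#'
#' @param x character vector of Greengenes-style strings, optionally named by
#'   feature id.
#' @return a named list of `lineage` objects.
#' @export
parse_lineages <- function(x) {
  out <- lapply(x, parse_lineage)
  names(out) <- names(x)
  out
}

#' Serialize a lineage back to Greengenes form
#'
#' Absent ranks are written with empty payloads (e.g. `"g__"`), so that
#' parse and serialize round-trip.
#'
#' @param lin a `lineage` object.
#' @return a single string.
#' @export
lineage_to_string <- function(lin) {
  stopifnot(inherits(lin, "lineage"))
  payload <- ifelse(is.na(lin), "", unclass(lin))
  paste(paste0(.rank_prefixes[TAXONOMIC_RANKS], "__", payload),
        collapse = "; ")
}

#' @export
format.lineage <- function(x, ...) lineage_to_string(x)

#' @export
print.lineage <- function(x, ...) {
  cat("<lineage> ", lineage_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Extract one rank's taxon name from a lineage
#'
#' @param lin a `lineage` object.
#' @param rank one of [TAXONOMIC_RANKS].
#' @return the taxon name at that rank, or `NA` if absent.
#' @export
lineage_rank <- function(lin, rank) {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  unname(unclass(lin)[rank])
}

#' Read a feature-to-lineage table
#'
#' Two-column delimited file (feature_id, lineage string). A header row is
#' detected by the second field failing to parse as a lineage prefix is not
#' required: the file is read headerless unless `header = TRUE`.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` sniffs tab vs comma from the first line.
#' @param header whether the file has a header row.
#' @return named list of `lineage` objects, names = feature ids.
#' @export
read_lineage_table <- function(path, sep = NULL, header = FALSE) {
  sep <- sep %||% sniff_delim(path)
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  if (ncol(df) < 2L) {
    stop("lineage table must have two columns (feature_id, lineage)",
         call. = FALSE)
  }
  if (anyDuplicated(df[[1]])) {
    stop("duplicate feature ids in lineage table", call. = FALSE)
  }
  parse_lineages(stats::setNames(as.character(df[[2]]),
                                 as.character(df[[1]])))
}

#' Write a feature-to-lineage table
#'
#' @param lineages named list of `lineage` objects.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(lineages, path) {
  df <- data.frame(feature_id = names(lineages),
                   lineage = vapply(lineages, lineage_to_string, ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Delimiter sniffing shared by the tabular readers: tab wins if present on
# the first line, otherwise comma.
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("empty file: ", path, call. = FALSE)
  }
  if (grepl("\t", first)) "\t" else ","
}
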