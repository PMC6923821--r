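#' Taxon-KO links and KO-density module associations
#'
#' The association between a taxon and a functional module is scored in two
#' steps: (1) Spearman links between taxon abundances and individual KO
#' abundances, FDR-controlled over all (taxon, KO) pairs tested together;
#' (2) for each (taxon, module), the KO density
#'
#'   density = (number of module KOs correlated with the taxon) /
#'             (total number of KOs in the module),
#'
#' an exact rational in `[0, 1]` used as the cross-edge weight of the split
#' graph. Both positively and negatively correlated KOs count toward the
#' numerator; the density is unsigned.
#'
#' @name association
NULL

#' Significant taxon-KO correlation links
#'
#' Computes Spearman rho for every (taxon, KO) pair over a shared sample
#' set, adjusts p-values by Benjamini-Hochberg across all pairs in the call,
#' and retains links with `|rho| > rho_min` and `q < q_max`.
#'
#' @param taxa an `abundance_matrix` of kind `"taxon"`.
#' @param kos an `abundance_matrix` of kind `"ko"`.
#' @param samples sample ids to use; default is all samples, which must then
#'   match between the two matrices. Samples are aligned by label.
#' @param rho_min,q_max retention thresholds (defaults 0.6 and 0.05).
#' @return data frame of class `taxon_ko_links` with columns `taxon`, `ko`,
#'   `rho`, `p`, `q`; attributes `n_tested` and `n_constant_pairs`.
#' @export
taxon_ko_links <- function(taxa, kos, samples = NULL,
                           rho_min = 0.6, q_max = 0.05) {
  stopifnot(inherits(taxa, "abundance_matrix"),
            inherits(kos, "abundance_matrix"))
  if (is.null(samples)) {
    only_t <- setdiff(sample_ids(taxa), sample_ids(kos))
    only_k <- setdiff(sample_ids(kos), sample_ids(taxa))
    if (length(only_t) || length(only_k)) {
      stop("sample sets differ between taxon and KO tables; only in taxa: [",
           paste(only_t, collapse = ", "), "], only in KOs: [",
           paste(only_k, collapse = ", "), "]", call. = FALSE)
    }
    samples <- sample_ids(taxa)
  }
  samples <- sort(samples)
  taxa <- subset_samples(taxa, samples)
  kos <- subset_samples(kos, samples)
  n <- length(samples)
  if (n < 4L) stop("need at least 4 shared samples", call. = FALSE)

  xt <- unclass(taxa)[, sort(feature_ids(taxa)), drop = FALSE]
  xk <- unclass(kos)[, sort(feature_ids(kos)), drop = FALSE]
  const_t <- apply(xt, 2L, function(v) length(unique(v)) == 1L)
  const_k <- apply(xk, 2L, function(v) length(unique(v)) == 1L)
  rho <- suppressWarnings(stats::cor(rank_columns(xt), rank_columns(xk)))
  rho[const_t, ] <- NA_real_
  rho[, const_k] <- NA_real_

  links <- data.frame(taxon = rep(rownames(rho), times = ncol(rho)),
                      ko = rep(colnames(rho), each = nrow(rho)),
                      rho = as.vector(rho), stringsAsFactors = FALSE)
  links$p <- spearman_p(links$rho, n)
  links$q <- NA_real_
  ok <- !is.na(links$p)
  links$q[ok] <- stats::p.adjust(links$p[ok], method = "BH")
  n_tested <- sum(ok)
  n_const <- sum(!ok)
  keep <- ok & abs(links$rho) > rho_min & links$q < q_max
  links <- links[keep, , drop = FALSE]
  rownames(links) <- NULL
  attr(links, "n_samples") <- n
  attr(links, "n_tested") <- n_tested
  attr(links, "n_constant_pairs") <- n_const
  attr(links, "thresholds") <- c(rho_min = rho_min, q_max = q_max)
  class(links) <- c("taxon_ko_links", "data.frame")
  links
}

#' KO density of one taxon-module association
#'
#' The density is the exact rational |module KOs linked to the taxon| /
#' |module KOs|, reported to full precision; display rounding to two
#' decimals is left to formatting.
#'
#' @param links a `taxon_ko_links` data frame (or any data frame with
#'   `taxon` and `ko` columns).
#' @param map a `module_map`.
#' @param taxon taxon label.
#' @param module_id module identifier present in `map`.
#' @return a one-row data frame with columns `taxon`, `module`,
#'   `correlated_kos` (list column), `n_correlated`, `module_size`,
#'   `density`.
#' @export
module_density <- function(links, map, taxon, module_id) {
  stopifnot(inherits(map, "module_map"))
  if (!module_id %in% names(map)) {
    stop("unknown module: ", module_id, call. = FALSE)
  }
  kos <- map[[module_id]]
  linked <- sort(unique(links$ko[links$taxon == taxon & links$ko %in% kos]))
  out <- data.frame(taxon = taxon, module = module_id,
                    n_correlated = length(linked),
                    module_size = length(kos),
                    density = length(linked) / length(kos),
                    stringsAsFactors = FALSE)
  out$correlated_kos <- I(list(linked))
  out[c("taxon", "module", "correlated_kos", "n_correlated",
        "module_size", "density")]
}

#' All taxon-module density associations above a threshold
#'
#' Evaluates the KO density for every (taxon, module) combination that has
#' at least one linked KO and retains those above `density_min`. Because
#' printed associations at exactly 0.60 appear under a "density > 0.6" rule,
#' the boundary comparison is configurable and defaults to `ge`.
#'
#' @param links a `taxon_ko_links` data frame.
#' @param map a `module_map`.
#' @param density_min retention threshold in `[0, 1]` (default 0.6).
#' @param cmp `"ge"` (default) retains density >= density_min; `"gt"` is
#'   strict.
#' @return data frame of class `density_associations` (same columns as
#'   [module_density]), sorted by taxon then module.
#' @export
all_densities <- function(links, map, density_min = 0.6,
                          cmp = c("ge", "gt")) {
  stopifnot(inherits(map, "module_map"))
  cmp <- match.arg(cmp)
  if (!is.numeric(density_min) || density_min < 0 || density_min > 1) {
    stop("density_min must lie in [0, 1]", call. = FALSE)
  }
  ko2mod <- data.frame(ko = unlist(map, use.names = FALSE),
                       module = rep(names(map), lengths(map)),
                       stringsAsFactors = FALSE)
  hits <- merge(as.data.frame(links)[c("taxon", "ko")], ko2mod, by = "ko")
  if (nrow(hits) == 0L) {
    out <- data.frame(taxon = character(), module = character(),
                      n_correlated = integer(), module_size = integer(),
                      density = numeric(), stringsAsFactors = FALSE)
    out$correlated_kos <- I(list())
  } else {
    key <- interaction(hits$taxon, hits$module, drop = TRUE)
    pieces <- lapply(split(hits, key), function(h) {
      module_density(h, map, h$taxon[1], h$module[1])
    })
    out <- do.call(rbind, pieces)
    keep <- if (cmp == "ge") out$density >= density_min else
      out$density > density_min
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$taxon, out$module), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out[c("taxon", "module", "correlated_kos", "n_correlated",
                  "module_size", "density")],
            thresholds = c(density_min = density_min),
            cmp = cmp,
            class = c("density_associations", "data.frame"))
}

#' Write density associations as TSV
#'
#' Columns: taxon, module, correlated_kos (semicolon-joined), module_size,
#' density (full precision).
#'
#' @param dens a `density_associations` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_densities_tsv <- function(dens, path) {
  flat <- data.frame(taxon = dens$taxon, module = dens$module,
                     correlated_kos = vapply(dens$correlated_kos,
                                             paste, "", collapse = ";"),
                     module_size = dens$module_size,
                     density = dens$density, stringsAsFactors = FALSE)
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
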