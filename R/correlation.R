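#' Pairwise Spearman correlation with BH-FDR control
#'
#' Co-occurrence edges between features are scored by Spearman's rank
#' correlation (average ranks for ties). Two-sided p-values use the
#' t-distribution approximation t = rho * sqrt((n-2) / (1-rho^2)) on n-2
#' degrees of freedom; an exact permutation p-value is available for small n.
#' q-values are Benjamini-Hochberg adjusted over all pairs tested in one
#' call, which defines the FDR family (one group x rank analysis).
#'
#' @name correlation
NULL

# Column-wise average ranks.
rank_columns <- function(x) apply(x, 2L, rank, ties.method = "average")

# Two-sided p for Spearman rho at sample size n: t approximation, or exact
# permutation enumeration of rho under the null for small n (no ties only).
spearman_p <- function(rho, n, method = c("t", "permutation")) {
  method <- match.arg(method)
  if (method == "t") {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(rho) >= 1] <- 0
    return(pmin(p, 1))
  }
  vapply(rho, function(r) spearman_perm_p(r, n), 0)
}

# Exact permutation null for untied ranks: enumerate all n! rank orders.
spearman_perm_p <- function(rho, n) {
  if (is.na(rho)) return(NA_real_)
  perms <- permutations_of(seq_len(n))
  ref <- seq_len(n)
  null_rho <- apply(perms, 1L, function(p) stats::cor(ref, p))
  mean(abs(null_rho) >= abs(rho) - 1e-12)
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], permutations_of(v[-i]))
  }))
}

#' All-pairs Spearman correlation within a sample subset
#'
#' Computes one edge per unordered feature pair with rho, raw two-sided p,
#' and BH-adjusted q over all pairs in this call. Pairs involving a feature
#' that is constant across the samples have undefined rho; they are emitted
#' with `rho = NA` and excluded from the FDR family (their count is reported
#' in `attr(, "n_constant_pairs")`).
#'
#' @param m an `abundance_matrix`.
#' @param samples sample ids to use (default: all samples of `m`); at least 4.
#' @param p_method `"t"` (default) or `"permutation"` (exact, small n only).
#' @return a data frame of class `corr_edges` with columns `feature_a`,
#'   `feature_b` (canonically ordered `feature_a < feature_b`), `rho`, `p`,
#'   `q`.
#' @export
spearman_all_pairs <- function(m, samples = NULL, p_method = c("t", "permutation")) {
  stopifnot(inherits(m, "abundance_matrix"))
  p_method <- match.arg(p_method)
  if (!is.null(samples)) m <- subset_samples(m, samples)
  n <- nrow(m)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  if (ncol(m) < 2L) stop("need at least 2 features", call. = FALSE)
  feats <- sort(feature_ids(m))
  x <- unclass(m)[, feats, drop = FALSE]
  constant <- apply(x, 2L, function(col) length(unique(col)) == 1L)
  r <- rank_columns(x)
  rho_mat <- suppressWarnings(stats::cor(r))
  rho_mat[constant, ] <- NA_real_
  rho_mat[, constant] <- NA_real_
  idx <- which(upper.tri(rho_mat), arr.ind = TRUE)
  edges <- data.frame(feature_a = feats[idx[, 1]],
                      feature_b = feats[idx[, 2]],
                      rho = rho_mat[idx],
                      stringsAsFactors = FALSE)
  edges$p <- spearman_p(edges$rho, n, p_method)
  edges$q <- NA_real_
  ok <- !is.na(edges$p)
  edges$q[ok] <- stats::p.adjust(edges$p[ok], method = "BH")
  attr(edges, "n_samples") <- n
  attr(edges, "n_constant_pairs") <- sum(!ok)
  class(edges) <- c("corr_edges", "data.frame")
  edges
}

#' Threshold correlation edges into a co-occurrence network
#'
#' Retains edges with `|rho| > rho_min` and `q < q_max` (strict comparisons,
#' as printed). The rho threshold is applied to the magnitude with the sign
#' retained, so strong negative co-exclusions survive; set
#' `keep_negative = FALSE` to additionally require `rho > 0`.
#'
#' @param edges a `corr_edges` data frame from one [spearman_all_pairs] call
#'   (a shared FDR family).
#' @param rho_min correlation-magnitude threshold in `[0, 1)`; default 0.6.
#' @param q_max adjusted-p threshold in `(0, 1]`; default 0.05.
#' @param keep_negative keep negative-rho edges (default `TRUE`).
#' @param group group label annotation (e.g. `"CDT"`).
#' @param rank taxonomic rank annotation (e.g. `"family"`).
#' @return a `corr_network`: list with `edges`, `group`, `rank`,
#'   `thresholds`, `n_samples`, `n_tested`, `n_constant_pairs`.
#' @export
threshold_network <- function(edges, rho_min = 0.6, q_max = 0.05,
                              keep_negative = TRUE, group = NA_character_,
                              rank = NA_character_) {
  if (!is.numeric(rho_min) || rho_min < 0 || rho_min >= 1) {
    stop("rho_min must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(q_max) || q_max <= 0 || q_max > 1) {
    stop("q_max must lie in (0, 1]", call. = FALSE)
  }
  keep <- !is.na(edges$rho) & abs(edges$rho) > rho_min & edges$q < q_max
  if (!keep_negative) keep <- keep & edges$rho > 0
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  structure(list(edges = as.data.frame(kept), group = group, rank = rank,
                 thresholds = c(rho_min = rho_min, q_max = q_max),
                 n_samples = attr(edges, "n_samples"),
                 n_tested = sum(!is.na(edges$rho)),
                 n_constant_pairs = attr(edges, "n_constant_pairs") %||% 0L),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf(paste0("<corr_network> group=%s rank=%s: %d edges retained of ",
                     "%d pairs tested (|rho| > %.2f, q < %.2g)\n"),
              x$group, x$rank, nrow(x$edges), x$n_tested,
              x$thresholds["rho_min"], x$thresholds["q_max"]))
  invisible(x)
}

#' @export
summary.corr_network <- function(object, ...) {
  e <- object$edges
  cat(sprintf("Co-occurrence network (group %s, rank %s)\n",
              object$group, object$rank))
  cat(sprintf("  samples: %s; pairs tested: %d; constant-feature pairs: %d\n",
              object$n_samples %||% NA, object$n_tested,
              object$n_constant_pairs))
  cat(sprintf("  edges retained: %d (%d positive, %d negative)\n",
              nrow(e), sum(e$rho > 0), sum(e$rho < 0)))
  if (nrow(e)) {
    cat(sprintf("  |rho| range: %.3f .. %.3f\n",
                min(abs(e$rho)), max(abs(e$rho))))
  }
  invisible(object)
}

#' Network node set
#' @param net a `corr_network`.
#' @return character vector of feature labels appearing in retained edges.
#' @export
network_taxa <- function(net) {
  sort(unique(c(net$edges$feature_a, net$edges$feature_b)))
}

#' Write a correlation network edge list as TSV
#'
#' Columns: feature_a, feature_b, rho, p, q.
#'
#' @param net a `corr_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges[c("feature_a", "feature_b", "rho", "p", "q")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a correlation network edge list written by [write_network_tsv]
#' @param path TSV path.
#' @param group,rank annotations to attach.
#' @param rho_min,q_max thresholds to record (the file is assumed already
#'   thresholded).
#' @return a `corr_network`.
#' @export
read_network_tsv <- function(path, group = NA_character_,
                             rank = NA_character_,
                             rho_min = 0.6, q_max = 0.05) {
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  structure(list(edges = edges, group = group, rank = rank,
                 thresholds = c(rho_min = rho_min, q_max = q_max),
                 n_samples = NA_integer_, n_tested = nrow(edges),
                 n_constant_pairs = 0L),
            class = "corr_network")
}
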