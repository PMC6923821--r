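#' Shared-ancestor edge proportions and the pooled two-proportion z-test
#'
#' Do two groups differ in how phylogenetically clustered their
#' co-occurrence networks are? For a chosen ancestor rank, each network edge
#' whose endpoints both have that rank assigned contributes to the total n;
#' it contributes to x when the two endpoints carry the same taxon name at
#' that rank (a common ancestor). The group difference in the proportion
#' x/n is tested with the pooled two-proportion z statistic
#'
#'   z = (p1_hat - p2_hat) / sqrt(p_pooled (1 - p_pooled) (1/n1 + 1/n2)),
#'
#' with p_pooled = (x1 + x2)/(n1 + n2), no continuity correction, and a
#' two-sided normal p-value.
#'
#' @name lineage_stats
NULL

#' Count shared-ancestor edges in a network
#'
#' Edges with an endpoint lacking the requested rank (including the
#' `"unassigned"` aggregation sentinel) are excluded from both counts: an
#' unconfirmed lineage cannot witness a common ancestor.
#'
#' @param net a `corr_network`.
#' @param lineages named list of `lineage` objects (or lineage strings)
#'   covering the edge endpoints.
#' @param rank ancestor rank, one of [TAXONOMIC_RANKS].
#' @param include_unassigned if `TRUE`, endpoints named `"unassigned"` are
#'   looked up like any other (they then need a lineage entry).
#' @return integer vector `c(x = shared-ancestor edges, n = eligible
#'   edges)`.
#' @export
shared_ancestor_count <- function(net, lineages, rank,
                                  include_unassigned = FALSE) {
  stopifnot(inherits(net, "corr_network"))
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  if (is.character(lineages)) lineages <- parse_lineages(lineages)
  e <- net$edges
  if (!include_unassigned) {
    e <- e[e$feature_a != "unassigned" & e$feature_b != "unassigned", ,
           drop = FALSE]
  }
  ends <- unique(c(e$feature_a, e$feature_b))
  missing <- setdiff(ends, names(lineages))
  if (length(missing)) {
    stop("no lineage for edge endpoint(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  at_rank <- vapply(lineages, lineage_rank, "", rank = rank)
  a <- at_rank[e$feature_a]
  b <- at_rank[e$feature_b]
  eligible <- !is.na(a) & !is.na(b)
  c(x = sum(eligible & a == b, na.rm = TRUE), n = sum(eligible))
}

#' Pooled two-proportion z-test
#'
#' @param x1,n1 shared-ancestor edge count and eligible edge count, group 1.
#' @param x2,n2 same for group 2.
#' @return a one-row data frame of class `prop_test_result` with columns
#'   `x1`, `n1`, `x2`, `n2`, `p1_hat`, `p2_hat`, `p_pooled`, `z`, `p_value`,
#'   `degenerate`. When the pooled proportion is 0 or 1 the statistic is
#'   degenerate; z is reported as 0 with `degenerate = TRUE`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) {
    stop("two-proportion test undefined for empty group (n1, n2 must be > 0)",
         call. = FALSE)
  }
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stop("counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  degenerate <- pp <= 0 || pp >= 1
  if (degenerate || p1 == p2) {
    z <- 0
  } else {
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  }
  p_value <- if (z == 0) 1 else 2 * stats::pnorm(-abs(z))
  structure(data.frame(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                       p1_hat = p1, p2_hat = p2, p_pooled = pp,
                       z = z, p_value = p_value, degenerate = degenerate),
            class = c("prop_test_result", "data.frame"))
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf(paste0("Two-proportion z-test: p1 = %d/%d = %.3f vs ",
                     "p2 = %d/%d = %.3f\n  z = %.4f, two-sided p = %.4g%s\n"),
              x$x1, x$n1, x$p1_hat, x$x2, x$n2, x$p2_hat, x$z, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate pooled proportion)"
              else ""))
  invisible(x)
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Compare shared-ancestor edge proportions between two group networks
#'
#' For each requested ancestor rank, counts shared-ancestor edges in each
#' network and applies the pooled two-proportion z-test. Both networks must
#' come from the same taxonomic analysis rank and different groups.
#'
#' @param net1,net2 `corr_network` objects for the two groups.
#' @param lineages named list of `lineage` objects (or strings) covering all
#'   edge endpoints.
#' @param ranks ancestor ranks to test (default family, order, class,
#'   phylum).
#' @param include_unassigned passed to [shared_ancestor_count].
#' @return data frame of class `prop_test_table`, one row per rank, with
#'   the counts, z, p_value and a significance star annotation (no
#'   multiplicity correction across ranks).
#' @export
compare_groups <- function(net1, net2, lineages,
                           ranks = c("family", "order", "class", "phylum"),
                           include_unassigned = FALSE) {
  stopifnot(inherits(net1, "corr_network"), inherits(net2, "corr_network"))
  if (!is.na(net1$group) && !is.na(net2$group) &&
      net1$group == net2$group) {
    stop("the two networks carry the same group label: ", net1$group,
         call. = FALSE)
  }
  if (!is.na(net1$rank) && !is.na(net2$rank) && net1$rank != net2$rank) {
    stop("networks were built at different taxonomic ranks (",
         net1$rank, " vs ", net2$rank, ")", call. = FALSE)
  }
  rows <- lapply(ranks, function(rk) {
    c1 <- shared_ancestor_count(net1, lineages, rk, include_unassigned)
    c2 <- shared_ancestor_count(net2, lineages, rk, include_unassigned)
    res <- two_proportion_z(c1["x"], c1["n"], c2["x"], c2["n"])
    cbind(data.frame(rank = rk, stringsAsFactors = FALSE),
          as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  out$stars <- signif_stars(out$p_value)
  rownames(out) <- NULL
  structure(out, group1 = net1$group, group2 = net2$group,
            class = c("prop_test_table", "data.frame"))
}

#' Write a shared-ancestor comparison report as TSV
#'
#' Columns: rank, x1, n1, x2, n2, z, p_value, stars — the per-rank
#' p-values plus the underlying counts so runs are auditable.
#'
#' @param tab a `prop_test_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proptest_tsv <- function(tab, path) {
  utils::write.table(
    as.data.frame(tab)[c("rank", "x1", "n1", "x2", "n2", "z",
                         "p_value", "stars")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
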