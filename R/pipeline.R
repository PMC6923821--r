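#' Run the full split-graph pipeline for one sample group
#'
#' Convenience wrapper chaining the stages: taxon-taxon Spearman network
#' with BH-FDR thresholding, taxon-KO links, KO-density associations,
#' split-graph assembly, and maximal-clique extraction and ranking.
#'
#' @param taxa taxon `abundance_matrix`.
#' @param kos KO `abundance_matrix`.
#' @param map a `module_map`.
#' @param groups optional named vector (sample id -> group label); with
#'   `group`, restricts the analysis to one group's samples.
#' @param group group label to analyze (requires `groups`).
#' @param rank annotation for the taxonomic rank of the taxon features.
#' @param rho_min,q_max correlation thresholds (defaults 0.6, 0.05).
#' @param density_min,density_cmp cross-edge density threshold and boundary
#'   comparison (defaults 0.6, `"ge"`).
#' @param scheme clique weighting scheme, `"sum"` or `"mean"`.
#' @param top_k optional cap on ranked cliques.
#' @return list of class `splitgraph_run` with `network`, `links`,
#'   `densities`, `graph`, `cliques`.
#' @export
run_split_graph_pipeline <- function(taxa, kos, map, groups = NULL,
                                     group = NULL, rank = NA_character_,
                                     rho_min = 0.6, q_max = 0.05,
                                     density_min = 0.6,
                                     density_cmp = c("ge", "gt"),
                                     scheme = c("sum", "mean"),
                                     top_k = NULL) {
  density_cmp <- match.arg(density_cmp)
  scheme <- match.arg(scheme)
  samples <- sample_ids(taxa)
  if (!is.null(group)) {
    if (is.null(groups)) stop("group given without groups", call. = FALSE)
    samples <- names(groups)[groups == group]
    if (length(samples) == 0L) {
      stop("no samples in group ", group, call. = FALSE)
    }
  }
  edges <- spearman_all_pairs(taxa, samples)
  net <- threshold_network(edges, rho_min, q_max,
                           group = group %||% NA_character_, rank = rank)
  links <- taxon_ko_links(taxa, kos, samples, rho_min, q_max)
  dens <- all_densities(links, map, density_min, density_cmp)
  # module associations are scored only for taxa that already show strong
  # inter-taxon correlations, so restrict cross edges to network members
  dens <- dens[dens$taxon %in% network_taxa(net), , drop = FALSE]
  g <- build_split_graph(net, dens)
  cliques <- enumerate_maximal_cliques(g)
  cliques <- rank_cliques(cliques, g, scheme, top_k)
  structure(list(network = net, links = links, densities = dens,
                 graph = g, cliques = cliques),
            class = "splitgraph_run")
}

#' @export
print.splitgraph_run <- function(x, ...) {
  print(x$network)
  cat(sprintf("  taxon-KO links: %d; density associations: %d\n",
              nrow(x$links), nrow(x$densities)))
  print(x$graph)
  cat(sprintf("  maximal cliques (size >= 2): %d", nrow(x$cliques)))
  if (nrow(x$cliques)) {
    cat(sprintf("; top weight %.3f (%s)", x$cliques$weight[1],
                x$cliques$weight_scheme[1]))
  }
  cat("\n")
  invisible(x)
}
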