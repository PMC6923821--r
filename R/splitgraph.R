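#' Split graphs of taxa and functional modules
#'
#' A split graph partitions its vertices into a (potential) clique side and
#' an independent set. Here the clique side holds taxa, joined by clique
#' edges weighted by Spearman rho, and the independent side holds KEGG
#' modules, joined to taxa by cross edges weighted by KO density. No edge
#' ever joins two module nodes, so any clique of the mixed graph contains at
#' most one module node: a high-weighted maximal clique is a group of
#' mutually correlated taxa, possibly with the one functional module
#' associated with all of them.
#'
#' @name splitgraph
NULL

#' Assemble a split graph from a correlation network and density associations
#'
#' Taxon nodes are the union of network-edge endpoints and density-linked
#' taxa (a taxon isolated in the correlation network but carrying cross
#' edges is retained). Module-module edges are impossible by construction.
#'
#' @param net a `corr_network` of taxon-taxon edges.
#' @param dens a `density_associations` data frame (may be empty, in which
#'   case the graph reduces to the correlation network).
#' @param all_taxa optional universe of valid taxon labels; a density
#'   association naming a taxon outside it (and absent from the network) is
#'   a validation error.
#' @return a `split_graph`: list with `taxon_nodes`, `module_nodes`,
#'   `clique_edges` (taxon_a, taxon_b, weight = rho) and `cross_edges`
#'   (taxon, module, weight = density).
#' @export
build_split_graph <- function(net, dens = NULL, all_taxa = NULL) {
  stopifnot(inherits(net, "corr_network"))
  ce <- net$edges
  clique_edges <- data.frame(taxon_a = pmin(ce$feature_a, ce$feature_b),
                             taxon_b = pmax(ce$feature_a, ce$feature_b),
                             weight = ce$rho, stringsAsFactors = FALSE)
  if (is.null(dens) || nrow(dens) == 0L) {
    cross_edges <- data.frame(taxon = character(), module = character(),
                              weight = numeric(), stringsAsFactors = FALSE)
  } else {
    cross_edges <- data.frame(taxon = dens$taxon, module = dens$module,
                              weight = dens$density,
                              stringsAsFactors = FALSE)
  }
  if (!is.null(all_taxa)) {
    bad <- setdiff(cross_edges$taxon, union(all_taxa, network_taxa(net)))
    if (length(bad)) {
      stop("density association(s) name taxa absent from all inputs: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  taxon_nodes <- sort(unique(c(clique_edges$taxon_a, clique_edges$taxon_b,
                               cross_edges$taxon)))
  module_nodes <- sort(unique(cross_edges$module))
  clash <- intersect(taxon_nodes, module_nodes)
  if (length(clash)) {
    stop("labels used as both taxon and module: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  g <- structure(list(taxon_nodes = taxon_nodes,
                      module_nodes = module_nodes,
                      clique_edges = clique_edges,
                      cross_edges = cross_edges,
                      group = net$group, rank = net$rank),
                 class = "split_graph")
  validate_split_graph(g)
  g
}

#' Validate split-graph invariants
#'
#' Checks disjointness of the two node sets, that clique edges join taxa
#' only, that cross edges join a taxon to a module, and that the module side
#' is an independent set (zero module-module edges).
#'
#' @param g a `split_graph`.
#' @return `g` invisibly; errors on violation.
#' @export
validate_split_graph <- function(g) {
  stopifnot(inherits(g, "split_graph"))
  if (length(intersect(g$taxon_nodes, g$module_nodes))) {
    stop("taxon and module node sets are not disjoint", call. = FALSE)
  }
  ce <- g$clique_edges
  if (nrow(ce)) {
    if (!all(ce$taxon_a %in% g$taxon_nodes) ||
        !all(ce$taxon_b %in% g$taxon_nodes)) {
      stop("clique edge endpoint outside the taxon side", call. = FALSE)
    }
    if (any(ce$taxon_a == ce$taxon_b)) stop("self edge", call. = FALSE)
    if (anyDuplicated(paste(ce$taxon_a, ce$taxon_b))) {
      stop("parallel clique edges", call. = FALSE)
    }
  }
  xe <- g$cross_edges
  if (nrow(xe)) {
    if (!all(xe$taxon %in% g$taxon_nodes)) {
      stop("cross edge taxon endpoint outside the taxon side", call. = FALSE)
    }
    if (!all(xe$module %in% g$module_nodes)) {
      stop("cross edge module endpoint outside the module side",
           call. = FALSE)
    }
    if (anyDuplicated(paste(xe$taxon, xe$module))) {
      stop("parallel cross edges", call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.split_graph <- function(x, ...) {
  cat(sprintf(paste0("<split_graph> %d taxa, %d modules; %d clique edges, ",
                     "%d cross edges\n"),
              length(x$taxon_nodes), length(x$module_nodes),
              nrow(x$clique_edges), nrow(x$cross_edges)))
  invisible(x)
}

#' @export
summary.split_graph <- function(object, ...) {
  print(object)
  if (nrow(object$clique_edges)) {
    cat(sprintf("  clique-edge |rho|: %.3f .. %.3f (%d negative)\n",
                min(abs(object$clique_edges$weight)),
                max(abs(object$clique_edges$weight)),
                sum(object$clique_edges$weight < 0)))
  }
  if (nrow(object$cross_edges)) {
    cat(sprintf("  cross-edge density: %.3f .. %.3f\n",
                min(object$cross_edges$weight),
                max(object$cross_edges$weight)))
  }
  invisible(object)
}

#' Convert a split graph to an igraph object
#'
#' Nodes carry `node_class` (`"taxon"`/`"module"`); edges carry
#' `edge_class` (`"clique"`/`"cross"`), `weight` (|rho| or density) and
#' `rho_sign` (+1/-1 for clique edges, 0 for cross edges).
#'
#' @param g a `split_graph`.
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "split_graph"))
  nodes <- data.frame(name = c(g$taxon_nodes, g$module_nodes),
                      node_class = rep(c("taxon", "module"),
                                       c(length(g$taxon_nodes),
                                         length(g$module_nodes))),
                      stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(from = g$clique_edges$taxon_a, to = g$clique_edges$taxon_b,
               edge_class = rep("clique", nrow(g$clique_edges)),
               weight = abs(g$clique_edges$weight),
               rho_sign = sign(g$clique_edges$weight),
               stringsAsFactors = FALSE),
    data.frame(from = g$cross_edges$taxon, to = g$cross_edges$module,
               edge_class = rep("cross", nrow(g$cross_edges)),
               weight = g$cross_edges$weight,
               rho_sign = rep(0, nrow(g$cross_edges)),
               stringsAsFactors = FALSE))
  nodes$label <- nodes$name
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' @export
plot.split_graph <- function(x, ...) {
  ig <- as_igraph(x)
  cls <- igraph::V(ig)$node_class
  igraph::plot.igraph(
    ig,
    vertex.color = ifelse(cls == "taxon", "gold", "mediumpurple"),
    vertex.shape = ifelse(cls == "taxon", "circle", "square"),
    edge.lty = ifelse(igraph::E(ig)$edge_class == "clique", 1, 2),
    edge.width = 1 + 2 * igraph::E(ig)$weight, ...)
  invisible(x)
}

# Internal adjacency representation: node order = taxa then modules,
# logical symmetric matrix.
split_graph_adjacency <- function(g) {
  nodes <- c(g$taxon_nodes, g$module_nodes)
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(g$clique_edges)) {
    ia <- match(g$clique_edges$taxon_a, nodes)
    ib <- match(g$clique_edges$taxon_b, nodes)
    adj[cbind(ia, ib)] <- TRUE
    adj[cbind(ib, ia)] <- TRUE
  }
  if (nrow(g$cross_edges)) {
    it <- match(g$cross_edges$taxon, nodes)
    im <- match(g$cross_edges$module, nodes)
    adj[cbind(it, im)] <- TRUE
    adj[cbind(im, it)] <- TRUE
  }
  adj
}

# Pivoting Bron-Kerbosch over a logical adjacency matrix; returns a list of
# integer index vectors, one per maximal clique (including singletons).
bron_kerbosch <- function(adj) {
  n <- nrow(adj)
  out <- list()
  neigh <- lapply(seq_len(n), function(i) which(adj[i, ]))
  recurse <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    cand <- c(P, X)
    deg <- vapply(cand, function(u) length(intersect(neigh[[u]], P)), 0L)
    pivot <- cand[which.max(deg)]
    for (v in setdiff(P, neigh[[pivot]])) {
      recurse(c(R, v), intersect(P, neigh[[v]]), intersect(X, neigh[[v]]))
      P <- setdiff(P, v)
      X <- union(X, v)
    }
    invisible()
  }
  recurse(integer(), seq_len(n), integer())
  out
}

#' Enumerate maximal cliques of a split graph
#'
#' Runs pivoting Bron-Kerbosch on the full mixed graph. Module nodes need no
#' special casing: the independent-set property guarantees at most one per
#' clique. Each clique is reported with its taxon members and (optional)
#' module attachment. Size-1 cliques are suppressed by default.
#'
#' @param g a `split_graph`.
#' @param min_size minimum total clique size to report (default 2).
#' @param scope `"mixed"` (default) enumerates maximal cliques of the whole
#'   graph; `"taxa"` enumerates maximal cliques of the taxon-induced
#'   subgraph (a taxa clique can be maximal there yet extendable by a module
#'   node in the mixed graph).
#' @return data frame of class `clique_modules` with columns `clique_id`,
#'   `taxa` (list column), `module` (`NA` if none), `size`.
#' @export
enumerate_maximal_cliques <- function(g, min_size = 2L,
                                      scope = c("mixed", "taxa")) {
  stopifnot(inherits(g, "split_graph"))
  scope <- match.arg(scope)
  validate_split_graph(g)
  adj <- split_graph_adjacency(g)
  if (scope == "taxa") {
    adj <- adj[g$taxon_nodes, g$taxon_nodes, drop = FALSE]
  }
  nodes <- rownames(adj)
  cliques <- if (length(nodes)) bron_kerbosch(adj) else list()
  rows <- lapply(cliques, function(idx) {
    members <- nodes[idx]
    taxa <- sort(intersect(members, g$taxon_nodes))
    mods <- intersect(members, g$module_nodes)
    data.frame(module = if (length(mods)) mods[1] else NA_character_,
               size = length(members), stringsAsFactors = FALSE,
               taxa = I(list(taxa)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(), size = integer(),
               taxa = I(list()), stringsAsFactors = FALSE)
  out <- out[out$size >= min_size, , drop = FALSE]
  # deterministic order before ranking: by taxa labels then module
  key <- paste(vapply(out$taxa, paste, "", collapse = ";"), out$module)
  out <- out[order(key), , drop = FALSE]
  out$clique_id <- if (nrow(out)) sprintf("C%03d", seq_len(nrow(out))) else
    character()
  rownames(out) <- NULL
  structure(out[c("clique_id", "taxa", "module", "size")],
            scope = scope, class = c("clique_modules", "data.frame"))
}

# Aggregate weight of one clique: scheme-aggregate of |rho| over internal
# clique edges plus density over cross edges to the attached module.
clique_weight <- function(g, taxa, module, scheme = c("sum", "mean")) {
  scheme <- match.arg(scheme)
  ce <- g$clique_edges
  internal <- ce$taxon_a %in% taxa & ce$taxon_b %in% taxa
  w <- abs(ce$weight[internal])
  if (!is.na(module)) {
    xe <- g$cross_edges
    w <- c(w, xe$weight[xe$module == module & xe$taxon %in% taxa])
  }
  if (length(w) == 0L) return(0)
  if (scheme == "sum") sum(w) else mean(w)
}

#' Rank maximal cliques by aggregate weight
#'
#' The weight of a clique is the sum (default) or mean of |rho| over its
#' internal clique edges plus the densities of the cross edges joining the
#' attached module to each member taxon. Ties are broken by clique size
#' (descending) then lexicographically on the taxon labels, so ranking is
#' deterministic across runs.
#'
#' @param cliques a `clique_modules` data frame from
#'   [enumerate_maximal_cliques].
#' @param g the `split_graph` the cliques came from (source of edge
#'   weights).
#' @param scheme `"sum"` (default) or `"mean"`.
#' @param top_k keep only the k highest-weighted cliques (default: all).
#' @return the cliques with a `weight` and `weight_scheme` column, ordered
#'   by descending weight.
#' @export
rank_cliques <- function(cliques, g, scheme = c("sum", "mean"),
                         top_k = NULL) {
  stopifnot(inherits(g, "split_graph"))
  if (is.character(scheme) && !all(scheme %in% c("sum", "mean"))) {
    stop("unknown weighting scheme: ", scheme[1], call. = FALSE)
  }
  scheme <- match.arg(scheme)
  cliques$weight <- vapply(seq_len(nrow(cliques)), function(i) {
    clique_weight(g, cliques$taxa[[i]], cliques$module[i], scheme)
  }, 0)
  cliques$weight_scheme <- rep(scheme, length.out = nrow(cliques))
  key <- vapply(cliques$taxa, paste, "", collapse = ";")
  ord <- order(-cliques$weight, -cliques$size, key)
  out <- cliques[ord, , drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Verify reported cliques independently
#'
#' Re-checks, by direct adjacency inspection, that every reported clique
#' induces a complete subgraph and is maximal (no node of the graph can be
#' added while preserving completeness).
#'
#' @param cliques a `clique_modules` data frame (mixed scope).
#' @param g the `split_graph`.
#' @return `TRUE` if all pass; otherwise errors describing the first
#'   failure.
#' @export
check_cliques <- function(cliques, g) {
  adj <- split_graph_adjacency(g)
  nodes <- rownames(adj)
  for (i in seq_len(nrow(cliques))) {
    members <- c(cliques$taxa[[i]],
                 if (!is.na(cliques$module[i])) cliques$module[i])
    idx <- match(members, nodes)
    sub <- adj[idx, idx, drop = FALSE]
    diag(sub) <- TRUE
    if (!all(sub)) {
      stop("clique ", cliques$clique_id[i], " is not complete",
           call. = FALSE)
    }
    others <- setdiff(seq_along(nodes), idx)
    extendable <- others[vapply(others, function(v) all(adj[v, idx]),
                                TRUE)]
    if (length(extendable)) {
      stop("clique ", cliques$clique_id[i], " is not maximal (extendable by ",
           nodes[extendable[1]], ")", call. = FALSE)
    }
  }
  TRUE
}

#' Write a clique report as TSV
#'
#' Columns: clique_id, taxa (semicolon-joined), module, size, weight,
#' weight_scheme.
#'
#' @param cliques a ranked `clique_modules` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cliques_tsv <- function(cliques, path) {
  flat <- data.frame(clique_id = cliques$clique_id,
                     taxa = vapply(cliques$taxa, paste, "", collapse = ";"),
                     module = cliques$module, size = cliques$size,
                     stringsAsFactors = FALSE)
  if (!is.null(cliques$weight)) {
    flat$weight <- cliques$weight
    flat$weight_scheme <- cliques$weight_scheme
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a split graph (and optional clique annotation) as GraphML
#'
#' Writes a Cytoscape-importable GraphML file with node attributes
#' `node_class` and `label`, edge attributes `edge_class`, `weight` and
#' `rho_sign`, and, when cliques are supplied, a node attribute `cliques`
#' listing the ids of the reported cliques each node belongs to.
#'
#' @param g a `split_graph`.
#' @param path output path.
#' @param cliques optional `clique_modules` data frame (e.g. the top-k
#'   ranked cliques).
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path, cliques = NULL) {
  validate_split_graph(g)
  ig <- as_igraph(g)
  if (!is.null(cliques) && nrow(cliques)) {
    membership <- stats::setNames(rep("", igraph::vcount(ig)),
                                  igraph::V(ig)$name)
    for (i in seq_len(nrow(cliques))) {
      members <- c(cliques$taxa[[i]],
                   if (!is.na(cliques$module[i])) cliques$module[i])
      membership[members] <- ifelse(nzchar(membership[members]),
                                    paste(membership[members],
                                          cliques$clique_id[i], sep = ","),
                                    cliques$clique_id[i])
    }
    igraph::V(ig)$cliques <- unname(membership)
  }
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
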