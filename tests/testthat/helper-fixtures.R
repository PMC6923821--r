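# Fixture builders and independent oracles shared across the suite.

# Small abundance matrix with named samples/features.
make_abundance <- function(values, kind = "taxon",
                           samples = sprintf("S%d", seq_len(nrow(values))),
                           features = sprintf("F%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(samples, features)
  abundance_matrix(values, kind)
}

# Correlation network assembled directly from an edge data frame.
make_network <- function(feature_a, feature_b, rho,
                         group = NA_character_, rank = NA_character_) {
  edges <- data.frame(feature_a = feature_a, feature_b = feature_b,
                      rho = rho, p = rep(0, length(rho)),
                      q = rep(0, length(rho)), stringsAsFactors = FALSE)
  structure(list(edges = edges, group = group, rank = rank,
                 thresholds = c(rho_min = 0.6, q_max = 0.05),
                 n_samples = NA_integer_, n_tested = nrow(edges),
                 n_constant_pairs = 0L),
            class = "corr_network")
}

# Density-association table assembled directly.
make_densities <- function(taxon, module, density) {
  out <- data.frame(taxon = taxon, module = module,
                    n_correlated = NA_integer_, module_size = NA_integer_,
                    density = density, stringsAsFactors = FALSE)
  out$correlated_kos <- I(replicate(nrow(out), character(), FALSE))
  structure(out[c("taxon", "module", "correlated_kos", "n_correlated",
                  "module_size", "density")],
            class = c("density_associations", "data.frame"))
}

# The two-taxon / one-module configuration of the published stool split
# graph: Bacteroidaceae--Lachnospiraceae at rho 0.94, both linked to the
# V-type ATPase module M00159 (densities 0.89 and 0.67).
fig4_graph <- function() {
  net <- make_network("f__Bacteroidaceae", "f__Lachnospiraceae", 0.94,
                      group = "CDS", rank = "family")
  dens <- make_densities(c("f__Bacteroidaceae", "f__Lachnospiraceae"),
                         c("M00159", "M00159"), c(0.89, 0.67))
  build_split_graph(net, dens)
}

# Random split graph over n_taxa + n_modules nodes.
random_split_graph <- function(n_taxa, n_modules, p_clique = 0.4,
                               p_cross = 0.3) {
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  mods <- if (n_modules > 0) sprintf("m%02d", seq_len(n_modules)) else
    character()
  pairs <- if (n_taxa >= 2) t(combn(taxa, 2)) else
    matrix(character(), 0, 2)
  keep <- runif(nrow(pairs)) < p_clique
  ce <- data.frame(taxon_a = pairs[keep, 1], taxon_b = pairs[keep, 2],
                   weight = runif(sum(keep), -1, 1) ,
                   stringsAsFactors = FALSE)
  cross <- expand.grid(taxon = taxa, module = mods,
                       stringsAsFactors = FALSE)
  cross <- cross[runif(nrow(cross)) < p_cross, , drop = FALSE]
  xe <- data.frame(taxon = cross$taxon, module = cross$module,
                   weight = runif(nrow(cross)), stringsAsFactors = FALSE)
  g <- structure(list(taxon_nodes = taxa, module_nodes = mods,
                      clique_edges = ce, cross_edges = xe,
                      group = NA_character_, rank = NA_character_),
                 class = "split_graph")
  validate_split_graph(g)
  g
}

# Exhaustive subset enumeration of maximal cliques over a logical adjacency
# matrix; independent of the package's Bron-Kerbosch path.
brute_force_max_cliques <- function(adj) {
  n <- nrow(adj)
  bits <- 2^(seq_len(n) - 1)
  out <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bits) > 0)
    sub <- adj[idx, idx, drop = FALSE]
    diag(sub) <- TRUE
    if (!all(sub)) next
    others <- setdiff(seq_len(n), idx)
    extendable <- any(vapply(others, function(v) all(adj[v, idx]), TRUE))
    if (!extendable) out[[length(out) + 1L]] <- rownames(adj)[idx]
  }
  out
}

# Canonical string form of a clique set for set comparison.
clique_key_set <- function(cliques) {
  sort(vapply(cliques, function(m) paste(sort(m), collapse = "+"), ""))
}

# Membership sets of a clique_modules table (taxa plus module node).
clique_table_keys <- function(tab) {
  keys <- vapply(seq_len(nrow(tab)), function(i) {
    m <- c(tab$taxa[[i]], if (!is.na(tab$module[i])) tab$module[i])
    paste(sort(m), collapse = "+")
  }, "")
  sort(keys)
}

# Canonical unordered-pair keys for edge recall scoring.
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
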