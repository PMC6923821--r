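#' Synthetic microbiome data with planted structure
#'
#' Generates the four inputs of the pipeline — a taxon table, a KO table, a
#' KO-to-module map and a sample-to-group assignment, plus genus-level
#' lineages — with known planted structure: blocks of co-occurring taxa
#' loading on a shared latent factor, and taxon-to-module couplings in which
#' a stated fraction of a module's KOs is a monotone function of the driving
#' taxon's abundance. Abundance marginals are log-normal. The emitted ground
#' truth lists every planted within-block edge and every coupling, so
#' recovery can be scored without re-deriving it.
#'
#' @name synth
NULL

#' Synthetic-data configuration
#'
#' Defaults encode the generator's reference study conditions: 30 samples
#' in each of three groups (CDT, CDS, HCS), 20 genus-level taxa with two
#' planted blocks of three taxa at factor strength 0.95 and log-scale noise
#' 0.1, 60 KOs in 8 modules, and two planted couplings whose fraction times
#' module size is integral. The lineage plan gives the members of each
#' planted block a shared family; all other taxa get distinct families, with
#' families grouped pairwise into orders under one class and phylum.
#'
#' @param n_samples_per_group samples per group.
#' @param groups group labels.
#' @param n_taxa number of taxa (features `T01`, `T02`, ...).
#' @param planted_blocks list of `list(members = taxon ids, strength =
#'   factor loading in [0, 1])`.
#' @param noise_sd log-scale Gaussian noise SD for block members and driven
#'   KOs.
#' @param n_kos number of KOs (`K00001`, ...).
#' @param module_sizes integer sizes of consecutive KO modules (`M0001`,
#'   ...); must sum to at most `n_kos`.
#' @param planted_couplings list of `list(taxon, module, f)`; fraction `f`
#'   of the module's KOs is driven by the taxon. `f * size` must be
#'   integral.
#' @param link_slope log-log slope of driven-KO on driving-taxon abundance.
#' @param seed integer RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_samples_per_group = 30L,
                         groups = c("CDT", "CDS", "HCS"),
                         n_taxa = 20L,
                         planted_blocks = list(
                           list(members = c("T01", "T02", "T03"),
                                strength = 0.95),
                           list(members = c("T04", "T05", "T06"),
                                strength = 0.95)),
                         noise_sd = 0.1,
                         n_kos = 60L,
                         module_sizes = c(5L, 5L, 9L, 10L, 8L, 7L, 6L, 10L),
                         planted_couplings = list(
                           list(taxon = "T01", module = "M0001", f = 0.8),
                           list(taxon = "T04", module = "M0002", f = 0.6)),
                         link_slope = 1.0,
                         seed = 1L) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              groups = groups, n_taxa = as.integer(n_taxa),
              planted_blocks = planted_blocks, noise_sd = noise_sd,
              n_kos = as.integer(n_kos),
              module_sizes = as.integer(module_sizes),
              planted_couplings = planted_couplings,
              link_slope = link_slope, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_samples_per_group < 1L || cfg$n_taxa < 2L || cfg$n_kos < 1L) {
    stop("degenerate dimensions in synth config", call. = FALSE)
  }
  if (sum(cfg$module_sizes) > cfg$n_kos) {
    stop("module sizes exceed the number of KOs", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  taxa <- synth_taxon_ids(cfg$n_taxa)
  mods <- sprintf("M%04d", seq_along(cfg$module_sizes))
  for (b in cfg$planted_blocks) {
    if (b$strength < 0 || b$strength > 1) {
      stop("block strength must lie in [0, 1]", call. = FALSE)
    }
    if (!all(b$members %in% taxa)) {
      stop("planted block names unknown taxa: ",
           paste(setdiff(b$members, taxa), collapse = ", "), call. = FALSE)
    }
  }
  for (cp in cfg$planted_couplings) {
    if (!cp$module %in% mods) {
      stop("planted coupling names unknown module: ", cp$module,
           call. = FALSE)
    }
    if (!cp$taxon %in% taxa) {
      stop("planted coupling names unknown taxon: ", cp$taxon,
           call. = FALSE)
    }
    if (cp$f < 0 || cp$f > 1) {
      stop("coupling fraction must lie in [0, 1]", call. = FALSE)
    }
    size <- cfg$module_sizes[match(cp$module, mods)]
    k <- cp$f * size
    if (abs(k - round(k)) > 1e-8) {
      stop("coupling fraction ", cp$f, " on module ", cp$module,
           " of size ", size, " does not resolve to a whole number of KOs",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

synth_taxon_ids <- function(n) sprintf("T%02d", seq_len(n))
synth_ko_ids <- function(n) sprintf("K%05d", seq_len(n))

# Lineage plan: planted-block members share a family; every other taxon has
# its own family; families are grouped in pairs into orders; one class and
# phylum. Taxa are genus-level features.
synth_lineages <- function(cfg) {
  taxa <- synth_taxon_ids(cfg$n_taxa)
  fam <- stats::setNames(rep(NA_character_, cfg$n_taxa), taxa)
  for (bi in seq_along(cfg$planted_blocks)) {
    fam[cfg$planted_blocks[[bi]]$members] <- sprintf("BlockFam%02d", bi)
  }
  loose <- names(fam)[is.na(fam)]
  fam[loose] <- sprintf("Fam%02d", seq_along(loose))
  fam_levels <- unique(fam)
  ord <- stats::setNames(sprintf("Ord%02d",
                                 (match(fam, fam_levels) + 1L) %/% 2L),
                         taxa)
  strs <- sprintf("k__Bacteria; p__SynthPhylum; c__SynthClass; o__%s; f__%s; g__Gen%s",
                  ord, fam, sub("^T", "", taxa))
  parse_lineages(stats::setNames(strs, taxa))
}

#' Generate a synthetic dataset
#'
#' Taxon log-abundances of block members are `strength * F_block +
#' N(0, noise_sd)` with a fresh standard-normal factor per block, sample and
#' group; non-members are independent standard normals. Each driven KO's
#' log-abundance is `link_slope * (driving taxon's log-abundance) +
#' N(0, noise_sd)`; undriven KOs are independent. Abundances are
#' exponentiated (log-normal marginals). Output is bit-identical for a
#' given seed.
#'
#' @param cfg a `synth_config`.
#' @return list of class `synth_data` with elements `taxa` and `kos`
#'   (`abundance_matrix`), `module_map`, `lineages`, `groups` (named
#'   vector) and `ground_truth` (list with data frames `edges` and
#'   `couplings`).
#' @export
synth_generate <- function(cfg = synth_config()) {
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  taxa_ids <- synth_taxon_ids(cfg$n_taxa)
  ko_ids <- synth_ko_ids(cfg$n_kos)
  mod_ids <- sprintf("M%04d", seq_along(cfg$module_sizes))
  map <- module_map(stats::setNames(
    split(ko_ids[seq_len(sum(cfg$module_sizes))],
          rep(seq_along(cfg$module_sizes), cfg$module_sizes)),
    mod_ids))

  n_per <- cfg$n_samples_per_group
  n_tot <- n_per * length(cfg$groups)
  sample_ids <- sprintf("S%03d", seq_len(n_tot))
  groups <- stats::setNames(rep(cfg$groups, each = n_per), sample_ids)

  # taxon log-abundances
  z <- matrix(stats::rnorm(n_tot * cfg$n_taxa), n_tot, cfg$n_taxa,
              dimnames = list(sample_ids, taxa_ids))
  for (b in cfg$planted_blocks) {
    for (gname in cfg$groups) {
      rows <- which(groups == gname)
      f <- stats::rnorm(length(rows))
      for (t in b$members) {
        z[rows, t] <- b$strength * f +
          stats::rnorm(length(rows), sd = cfg$noise_sd)
      }
    }
  }

  # KO log-abundances: driven KOs follow their taxon, the rest independent
  y <- matrix(stats::rnorm(n_tot * cfg$n_kos), n_tot, cfg$n_kos,
              dimnames = list(sample_ids, ko_ids))
  couplings <- lapply(cfg$planted_couplings, function(cp) {
    size <- module_size(map, cp$module)
    k <- as.integer(round(cp$f * size))
    driven <- map[[cp$module]][seq_len(k)]
    for (ko in driven) {
      y[, ko] <<- cfg$link_slope * z[, cp$taxon] +
        stats::rnorm(n_tot, sd = cfg$noise_sd)
    }
    data.frame(taxon = cp$taxon, module = cp$module, f = cp$f,
               n_driven = k, module_size = size,
               driven_kos = paste(driven, collapse = ";"),
               stringsAsFactors = FALSE)
  })

  edges <- data.frame(taxon_a = character(), taxon_b = character(),
                      strength = numeric(), stringsAsFactors = FALSE)
  if (length(cfg$planted_blocks)) {
    edges <- do.call(rbind, lapply(cfg$planted_blocks, function(b) {
      pairs <- t(utils::combn(sort(b$members), 2L))
      data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2],
                 strength = b$strength, stringsAsFactors = FALSE)
    }))
    edges <- edges[!duplicated(edges[c("taxon_a", "taxon_b")]), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }

  structure(list(
    taxa = abundance_matrix(exp(z), "taxon"),
    kos = abundance_matrix(exp(y), "ko"),
    module_map = map,
    lineages = synth_lineages(cfg),
    groups = groups,
    ground_truth = list(edges = edges,
                        couplings = do.call(rbind, couplings)),
    config = cfg), class = "synth_data")
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf(paste0("<synth_data> %d samples (%s), %d taxa, %d KOs, ",
                     "%d modules; %d planted edges, %d couplings\n"),
              nrow(x$taxa), paste(unique(x$groups), collapse = "/"),
              ncol(x$taxa), ncol(x$kos), length(x$module_map),
              nrow(x$ground_truth$edges),
              if (is.null(x$ground_truth$couplings)) 0L
              else nrow(x$ground_truth$couplings)))
  invisible(x)
}

#' Write a synthetic dataset to a directory as TSV files
#'
#' Emits the same formats the readers consume: `taxa.tsv` and `kos.tsv`
#' (features as rows), `module_map.tsv`, `lineages.tsv`, `groups.tsv`, plus
#' `ground_truth_edges.tsv` and `ground_truth_couplings.tsv`.
#'
#' @param data a `synth_data` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_table(data$taxa, file.path(dir, "taxa.tsv"))
  write_abundance_table(data$kos, file.path(dir, "kos.tsv"))
  write_module_map(data$module_map, file.path(dir, "module_map.tsv"))
  write_lineage_table(data$lineages, file.path(dir, "lineages.tsv"))
  write_group_table(data$groups, file.path(dir, "groups.tsv"))
  utils::write.table(data$ground_truth$edges,
                     file.path(dir, "ground_truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$ground_truth$couplings,
                     file.path(dir, "ground_truth_couplings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
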