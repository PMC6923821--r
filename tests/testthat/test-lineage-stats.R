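shared_lineages <- function() {
  parse_lineages(c(
    gA = "k__B; p__P1; c__C1; o__O1; f__Lachnospiraceae; g__gA",
    gB = "k__B; p__P1; c__C1; o__O1; f__Lachnospiraceae; g__gB",
    gC = "k__B; p__P1; c__C1; o__O2; f__Ruminococcaceae; g__gC",
    gD = "k__B; p__P2; c__C2; o__O3; f__; g__gD"))
}

test_that("shared-ancestor counting honors rank presence and equality", {
  lins <- shared_lineages()
  net <- make_network(c("gA", "gA", "gC"), c("gB", "gC", "gD"),
                      c(0.9, 0.8, 0.7))
  fam <- shared_ancestor_count(net, lins, "family")
  # gC-gD excluded (gD family absent); gA-gB share Lachnospiraceae
  expect_equal(fam, c(x = 1L, n = 2L))
  ord <- shared_ancestor_count(net, lins, "order")
  expect_equal(ord, c(x = 1L, n = 3L))
  phy <- shared_ancestor_count(net, lins, "phylum")
  expect_equal(phy, c(x = 2L, n = 3L))
  expect_error(shared_ancestor_count(net, lins, "tribe"), "arg")
})

test_that("edges touching the unassigned sentinel are excluded by default", {
  lins <- shared_lineages()
  net <- make_network(c("gA", "unassigned"), c("gB", "gA"), c(0.9, 0.8))
  expect_equal(shared_ancestor_count(net, lins, "family"),
               c(x = 1L, n = 1L))
})

test_that("counts match a brute-force per-edge comparison on random fixtures", {
  set.seed(51)
  for (rep in 1:10) {
    n_taxa <- 10
    fams <- sprintf("F%d", sample(1:4, n_taxa, TRUE))
    fams[sample(n_taxa, 2)] <- NA
    ids <- sprintf("g%02d", 1:n_taxa)
    strs <- sprintf("k__B; f__%s", ifelse(is.na(fams), "", fams))
    lins <- parse_lineages(stats::setNames(strs, ids))
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.4
    net <- make_network(pairs[keep, 1], pairs[keep, 2],
                        runif(sum(keep), 0.6, 1))
    got <- shared_ancestor_count(net, lins, "family")
    x <- n <- 0L
    for (i in which(keep)) {
      fa <- fams[match(pairs[i, 1], ids)]
      fb <- fams[match(pairs[i, 2], ids)]
      if (!is.na(fa) && !is.na(fb)) {
        n <- n + 1L
        if (fa == fb) x <- x + 1L
      }
    }
    expect_equal(got, c(x = x, n = n))
  }
})

test_that("the pooled z-statistic matches its closed form", {
  r <- two_proportion_z(5, 10, 5, 10)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)

  r2 <- two_proportion_z(10, 20, 5, 20)
  expect_equal(r2$p_pooled, 0.375)
  expect_equal(r2$z, 0.25 / sqrt(0.375 * 0.625 * (1 / 20 + 1 / 20)),
               tolerance = 1e-12)
  expect_equal(r2$z, 1.6329932, tolerance = 1e-6)

  r3 <- two_proportion_z(5, 20, 10, 20)  # swapped groups
  expect_equal(r3$z, -r2$z)
  expect_equal(r3$p_value, r2$p_value)

  # agreement with the uncorrected chi-square test: X^2 = z^2
  pt <- suppressWarnings(prop.test(c(10, 5), c(20, 20), correct = FALSE))
  expect_equal(r2$z^2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(r2$p_value, pt$p.value, tolerance = 1e-9)
})

test_that("degenerate pools and empty groups are handled explicitly", {
  d0 <- two_proportion_z(0, 10, 0, 15)
  expect_equal(d0$z, 0)
  expect_true(d0$degenerate)
  d1 <- two_proportion_z(10, 10, 15, 15)
  expect_equal(d1$z, 0)
  expect_true(d1$degenerate)
  expect_error(two_proportion_z(0, 0, 1, 5), "undefined")
  expect_error(two_proportion_z(6, 5, 1, 5), "0 <= x <= n")
})

test_that("z is antisymmetric under complementing both groups", {
  set.seed(52)
  for (i in 1:50) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    r <- two_proportion_z(x1, n1, x2, n2)
    rc <- two_proportion_z(n1 - x1, n1, n2 - x2, n2)
    expect_equal(rc$z, -r$z, tolerance = 1e-12)
    expect_true(r$p_value > 0 && r$p_value <= 1)
  }
})

test_that("compare_groups reports one row per rank with star annotations", {
  lins <- shared_lineages()
  net1 <- make_network(c("gA", "gA"), c("gB", "gC"), c(0.9, 0.8),
                       group = "CDT", rank = "genus")
  net2 <- make_network("gA", "gC", 0.7, group = "CDS", rank = "genus")
  tab <- compare_groups(net1, net2, lins,
                        ranks = c("family", "order", "phylum"))
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$rank, c("family", "order", "phylum"))
  expect_true(all(tab$stars %in% c("***", "**", "*", "ns")))

  # identical edge sets give z = 0 at every rank
  net2b <- make_network(c("gA", "gA"), c("gB", "gC"), c(0.9, 0.8),
                        group = "CDS", rank = "genus")
  tab0 <- compare_groups(net1, net2b, lins)
  expect_true(all(tab0$z == 0))

  expect_error(compare_groups(net1, net1, lins), "same group")
  net_other_rank <- make_network("gA", "gB", 0.9, group = "CDS",
                                 rank = "family")
  expect_error(compare_groups(net1, net_other_rank, lins),
               "different taxonomic ranks")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_proptest_tsv(tab, path)
  back <- read.delim(path)
  expect_identical(names(back), c("rank", "x1", "n1", "x2", "n2", "z",
                                  "p_value", "stars"))
})

test_that("a family-clustered network separates from a dispersed one most at family rank", {
  # group 1: many same-family edges; group 2: none
  ids <- sprintf("g%02d", 1:12)
  fams <- rep(sprintf("F%d", 1:6), each = 2)
  lins <- parse_lineages(stats::setNames(sprintf("k__B; o__O1; f__%s", fams),
                                         ids))
  same_fam <- t(sapply(seq(1, 11, 2), function(i) ids[c(i, i + 1)]))
  net1 <- make_network(same_fam[, 1], same_fam[, 2], rep(0.9, 6),
                       group = "CDT")
  cross_fam <- cbind(ids[seq(1, 11, 2)], ids[c(4, 6, 8, 10, 12, 2)])
  net2 <- make_network(cross_fam[, 1], cross_fam[, 2], rep(0.9, 6),
                       group = "CDS")
  tab <- compare_groups(net1, net2, lins, ranks = c("family", "order"))
  expect_lt(tab$p_value[tab$rank == "family"],
            tab$p_value[tab$rank == "order"])
  expect_lt(tab$p_value[tab$rank == "family"], 0.05)
  expect_equal(tab$x1[tab$rank == "family"], 6)
  expect_equal(tab$x2[tab$rank == "family"], 0)
})
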