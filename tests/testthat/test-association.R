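test_that("a KO that is a monotone function of a taxon is linked at rho 1", {
  set.seed(21)
  tax <- matrix(rexp(8 * 2), nrow = 8)
  m_tax <- make_abundance(tax, "taxon", features = c("taxA", "taxB"))
  kos <- cbind(sqrt(tax[, 1]), rexp(8))
  m_ko <- make_abundance(kos, "ko", features = c("K00001", "K00002"))
  links <- taxon_ko_links(m_tax, m_ko)
  hit <- links[links$taxon == "taxA" & links$ko == "K00001", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$rho, 1)
})

test_that("links are invariant under permutation of sample order", {
  set.seed(22)
  m_tax <- make_abundance(matrix(rexp(12 * 3), nrow = 12), "taxon",
                          features = c("t1", "t2", "t3"))
  m_ko <- make_abundance(matrix(rexp(12 * 4), nrow = 12), "ko",
                         features = sprintf("K%05d", 1:4))
  l1 <- taxon_ko_links(m_tax, m_ko, rho_min = 0, q_max = 1)
  shuf <- sample(sample_ids(m_tax))
  l2 <- taxon_ko_links(subset_samples(m_tax, shuf), m_ko,
                       rho_min = 0, q_max = 1)
  expect_equal(as.data.frame(l1), as.data.frame(l2))
})

test_that("mismatched sample sets raise an alignment error naming them", {
  m_tax <- make_abundance(matrix(1:8, nrow = 4), "taxon",
                          samples = c("S1", "S2", "S3", "S4"))
  m_ko <- make_abundance(matrix(1:8, nrow = 4), "ko",
                         samples = c("S1", "S2", "S3", "S9"))
  expect_error(taxon_ko_links(m_tax, m_ko), "S4.*S9|S9.*S4")
})

test_that("module density is the exact fraction of linked module KOs", {
  map <- module_map(list(
    M00156 = sprintf("K%05d", 404:408),   # 5 KOs
    M00036 = sprintf("K%05d", 101:113),   # 13 KOs
    M00000 = sprintf("K%05d", 900:904)))  # 5 KOs, none linked
  links <- data.frame(
    taxon = "taxA",
    ko = c(sprintf("K%05d", 404:407), sprintf("K%05d", 101:108)),
    stringsAsFactors = FALSE)
  d1 <- module_density(links, map, "taxA", "M00156")
  expect_equal(d1$density, 4 / 5)
  expect_equal(d1$n_correlated, 4L)
  expect_equal(d1$module_size, 5L)

  d2 <- module_density(links, map, "taxA", "M00036")
  expect_equal(d2$density, 8 / 13)
  expect_equal(round(d2$density, 2), 0.62)

  d3 <- module_density(links, map, "taxA", "M00000")
  expect_equal(d3$density, 0)
  expect_identical(d3$correlated_kos[[1]], character())

  expect_error(module_density(links, map, "taxA", "M99999"),
               "unknown module")
})

test_that("density threshold boundary is configurable, defaulting to ge", {
  map <- module_map(list(M1 = sprintf("K%d", 1:5), M2 = sprintf("Q%d", 1:5)))
  links <- data.frame(taxon = "t",
                      ko = c("K1", "K2", "K3", "Q1", "Q2", "Q3", "Q4"),
                      stringsAsFactors = FALSE)
  ge <- all_densities(links, map, density_min = 0.6)
  expect_setequal(ge$module, c("M1", "M2"))  # 0.60 kept under ge
  gt <- all_densities(links, map, density_min = 0.6, cmp = "gt")
  expect_identical(gt$module, "M2")          # 0.60 dropped under gt
  all_of_them <- all_densities(links, map, density_min = 0)
  expect_equal(nrow(all_of_them), 2L)        # every pair with >= 1 linked KO
})

test_that("all_densities matches a brute-force taxon x module double loop", {
  set.seed(23)
  for (rep in 1:5) {
    kos <- sprintf("K%05d", 1:30)
    map <- module_map(split(kos, rep(sprintf("M%d", 1:5), each = 6)))
    links <- data.frame(
      taxon = sample(c("t1", "t2", "t3"), 25, replace = TRUE),
      ko = sample(kos, 25, replace = TRUE), stringsAsFactors = FALSE)
    got <- all_densities(links, map, density_min = 0.3)
    expected <- 0L
    for (t in unique(links$taxon)) {
      for (mod in names(map)) {
        dens <- length(intersect(unique(links$ko[links$taxon == t]),
                                 map[[mod]])) / length(map[[mod]])
        if (dens >= 0.3) {
          expected <- expected + 1L
          row <- got[got$taxon == t & got$module == mod, ]
          expect_equal(row$density, dens)
        }
      }
    }
    expect_equal(nrow(got), expected)
    expect_true(all(got$density >= 0 & got$density <= 1))
  }
})

test_that("density is monotone non-decreasing as links are added", {
  map <- module_map(list(M1 = sprintf("K%d", 1:8)))
  base <- data.frame(taxon = "t", ko = c("K1", "K2"),
                     stringsAsFactors = FALSE)
  d0 <- module_density(base, map, "t", "M1")$density
  more <- rbind(base, data.frame(taxon = "t", ko = "K3"))
  d1 <- module_density(more, map, "t", "M1")$density
  expect_true(d1 >= d0)
  full <- data.frame(taxon = "t", ko = sprintf("K%d", 1:8))
  expect_equal(module_density(full, map, "t", "M1")$density, 1)
})

test_that("density TSV serialization has the documented schema", {
  map <- module_map(list(M00159 = sprintf("K%05d", 2117:2124)))
  links <- data.frame(taxon = "f__Lachnospiraceae",
                      ko = sprintf("K%05d", 2117:2122))
  dens <- all_densities(links, map, density_min = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_densities_tsv(dens, path)
  back <- read.delim(path)
  expect_identical(names(back), c("taxon", "module", "correlated_kos",
                                  "module_size", "density"))
  expect_equal(back$density, 6 / 8)
  expect_equal(length(strsplit(back$correlated_kos, ";")[[1]]), 6L)
})
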