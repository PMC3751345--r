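two_maps <- function(names_a, acc_a, names_b, acc_b) {
  list(a = genome_map("A", markers(name = names_a, start = seq_along(names_a) * 10,
                                   accession = acc_a), extent = c(0, 1000)),
       b = genome_map("B", markers(name = names_b, start = seq_along(names_b) * 10,
                                   accession = acc_b), extent = c(0, 1000)))
}

test_that("identity links match shared accessions with all-pairs semantics", {
  m <- two_maps(c("x", "y"), c("ENSBTAG0007", NA), c("p"), c("ENSBTAG0007"))
  l <- identity_links(m$a, m$b)
  expect_equal(nrow(l), 1L)
  expect_equal(l$link_type, "identity")
  # duplicated accession on one side: all pairs
  m2 <- two_maps(c("x1", "x2"), c("AC1", "AC1"), c("y1"), c("AC1"))
  expect_equal(nrow(identity_links(m2$a, m2$b)), 2L)
  # case sensitivity
  m3 <- two_maps("x", "abc", "y", "ABC")
  expect_equal(nrow(identity_links(m3$a, m3$b)), 0L)
})

test_that("synonymy links match shared names, identity taking precedence", {
  m <- two_maps("BM1258", "AC_A", "BM1258", "AC_B")
  l <- synonymy_links(m$a, m$b)
  expect_equal(nrow(l), 1L)
  expect_equal(l$link_type, "synonymy")
  # same name AND same accession: suppressed by identity precedence
  m2 <- two_maps("BM1258", "AC1", "BM1258", "AC1")
  expect_equal(nrow(synonymy_links(m2$a, m2$b)), 0L)
  expect_equal(nrow(identity_links(m2$a, m2$b)), 1L)
})

test_that("homology links join table records across the two maps only", {
  m <- two_maps(c("gx", "gy"), c("g1", "g2"), c("hx"), c("h1"))
  tab <- homology_table(data.frame(
    gene_a = c("g1", "g1"), species_a = "cow",
    gene_b = c("h1", "g2"), species_b = c("human", "cow"),
    homology_type = c("ortholog_one2one", "paralog"),
    perc_identity = c(82.1, 50), perc_similarity = c(90.3, 60)))
  l <- homology_links(m$a, m$b, tab)
  expect_equal(nrow(l), 1L)                 # g1-g2 record is intra-map: dropped
  expect_equal(l$link_type, "ortholog_one2one")
  expect_equal(l$perc_identity, 82.1)
  expect_equal(l$perc_similarity, 90.3)
  # reversed column order matches too
  tab2 <- homology_table(data.frame(
    gene_a = "h1", species_a = "human", gene_b = "g1", species_b = "cow",
    homology_type = "possible_ortholog",
    perc_identity = NA_real_, perc_similarity = NA_real_))
  expect_equal(homology_links(m$a, m$b, tab2)$link_type, "possible_ortholog")
})

test_that("link discovery equals the brute-force double loop on random maps", {
  set.seed(31)
  names_pool <- sprintf("NM%03d", 1:60)
  acc_pool <- sprintf("AC%03d", 1:60)
  for (rep in 1:15) {
    a <- rand_map("A", n = sample(10:60, 1), name_pool = names_pool,
                  acc_pool = acc_pool)
    b <- rand_map("B", n = sample(10:60, 1), name_pool = names_pool,
                  acc_pool = acc_pool)
    tab <- rand_homology_table(acc_pool, acc_pool, n = 120)
    expect_identical(link_key(identity_links(a, b)), link_key(oracle_identity(a, b)))
    expect_identical(link_key(synonymy_links(a, b)), link_key(oracle_synonymy(a, b)))
    expect_identical(link_key(homology_links(a, b, tab)),
                     link_key(oracle_homology(a, b, tab)))
  }
})

test_that("link discovery is symmetric up to endpoint order", {
  set.seed(32)
  acc_pool <- sprintf("AC%03d", 1:30)
  a <- rand_map("A", n = 40, acc_pool = acc_pool)
  b <- rand_map("B", n = 40, acc_pool = acc_pool)
  tab <- rand_homology_table(acc_pool, acc_pool, n = 80)
  flip <- function(l) sort(sprintf("%d|%d|%s", l$idx_b, l$idx_a, l$link_type))
  keep <- function(l) sort(sprintf("%d|%d|%s", l$idx_a, l$idx_b, l$link_type))
  expect_identical(keep(identity_links(a, b)), flip(identity_links(b, a)))
  expect_identical(keep(synonymy_links(a, b)), flip(synonymy_links(b, a)))
  expect_identical(keep(homology_links(a, b, tab)), flip(homology_links(b, a, tab)))
  # identity and synonymy are disjoint by construction
  expect_length(intersect(sprintf("%d|%d", identity_links(a, b)$idx_a,
                                  identity_links(a, b)$idx_b),
                          sprintf("%d|%d", synonymy_links(a, b)$idx_a,
                                  synonymy_links(a, b)$idx_b)), 0L)
})

test_that("filter_links thresholds homology links only, conservatively", {
  links <- link_frame(map_a = "A", marker_a = c("m1", "m2", "m3", "m4"),
                      idx_a = 1:4, map_b = "B",
                      marker_b = c("n1", "n2", "n3", "n4"), idx_b = 1:4,
                      link_type = c("ortholog_one2one", "identity",
                                    "paralog", "ortholog_one2many"),
                      perc_identity = c(40, NA, 80, NA),
                      perc_similarity = c(55, NA, 92, NA))
  # m1 (score 40) removed; scoreless one2many also removed (conservative)
  expect_equal(nrow(filter_links(links, min_identity = 50)), 2L)
  # identity-type link survives even an impossible threshold
  f99 <- filter_links(links, min_identity = 99)
  expect_true("identity" %in% f99$link_type)
  # scoreless homology link fails an active threshold
  expect_false("ortholog_one2many" %in%
                 filter_links(links, min_similarity = 10)$link_type)
  # absent thresholds are the identity
  expect_equal(nrow(filter_links(links)), 4L)
  # (0, 0) with scores present keeps scored homology links
  expect_true(all(c("ortholog_one2one", "paralog") %in%
                    filter_links(links, 0, 0)$link_type))
  expect_error(filter_links(links, min_identity = 101),
               class = "synmapr_range_error")
})

test_that("filtered link counts are monotone in each threshold", {
  set.seed(33)
  acc_pool <- sprintf("AC%03d", 1:40)
  a <- rand_map("A", n = 60, acc_pool = acc_pool)
  b <- rand_map("B", n = 60, acc_pool = acc_pool)
  links <- all_links(a, b, rand_homology_table(acc_pool, acc_pool, n = 200))
  prev <- Inf
  for (t in seq(0, 100, by = 10)) {
    n <- nrow(filter_links(links, min_identity = t))
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (t in seq(0, 100, by = 10)) {
    n <- nrow(filter_links(links, min_similarity = t))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the default palette matches the published key and is injective", {
  expect_equal(link_color("ortholog_one2one"), "#000000")    # black
  expect_equal(link_color("paralog"), "#F0E442")             # yellow
  expect_equal(link_color("apparent_ortholog_one2one"), "#D55E00") # vermilion
  expect_equal(link_color("synonymy"), "#56B4E9")            # sky-blue
  all_cols <- vapply(c("identity", "synonymy", "ortholog_one2one",
                       "apparent_ortholog_one2one", "ortholog_one2many",
                       "ortholog_many2many", "possible_ortholog", "paralog"),
                     link_color, character(1))
  expect_equal(anyDuplicated(all_cols), 0L)
  expect_error(link_color("friendship"))
  # user palettes override
  expect_equal(link_color("identity", palette = c(identity = "#123456")),
               "#123456")
})
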