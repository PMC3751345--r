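gene_map <- function(id, acc, pos, chromosome = "chr1", species = "cow",
                     extent = c(1, max(pos) + 2e4)) {
  genome_map(id, markers(name = acc, start = pos, end = pos + 500,
                         kind = "gene", accession = acc),
             species = species, chromosome = chromosome, units = "bp",
             extent = extent)
}

test_that("conserved regions group target homologues by chromosome, ranked", {
  src <- gene_map("cow1", sprintf("g%d", 1:5), c(1, 3, 5, 7, 9) * 1e4)
  tgt2 <- gene_map("hum2", sprintf("h%d", 1:4), c(2, 4, 6, 8) * 1e4,
                   chromosome = "chr2", species = "human")
  tgt7 <- gene_map("hum7", "h5", 5e4, chromosome = "chr7", species = "human")
  tab <- homology_table(data.frame(
    gene_a = sprintf("g%d", 1:5), species_a = "cow",
    gene_b = sprintf("h%d", c(1, 2, 3, 4, 5)), species_b = "human",
    homology_type = "ortholog_one2one",
    perc_identity = 80, perc_similarity = 90))
  res <- find_conserved_regions(src, map_region("cow1", 1, 1e5), tab, "human",
                                list(tgt2, tgt7))
  expect_length(res$regions, 2L)
  expect_equal(res$regions[[1]]$target_chromosome, "chr2")
  expect_equal(res$regions[[1]]$source_gene_count, 4L)
  expect_equal(res$regions[[2]]$target_chromosome, "chr7")
  expect_equal(res$regions[[2]]$source_gene_count, 1L)
  # span covers every located target gene
  expect_equal(res$regions[[1]]$span_start, 2e4)
  expect_equal(res$regions[[1]]$span_end, 8e4 + 500)
  # one link per homology record used
  expect_equal(nrow(res$regions[[1]]$links), 4L)
  expect_length(res$skipped_genes, 0L)
})

test_that("regions restrict to the queried sub-region; empties are empty", {
  src <- gene_map("cow1", sprintf("g%d", 1:5), c(1, 3, 5, 7, 9) * 1e4)
  tgt <- gene_map("hum", sprintf("h%d", 1:5), (1:5) * 1e4,
                  chromosome = "chr2", species = "human")
  tab <- homology_table(data.frame(
    gene_a = sprintf("g%d", 1:5), species_a = "cow",
    gene_b = sprintf("h%d", 1:5), species_b = "human",
    homology_type = "ortholog_one2one", perc_identity = 80,
    perc_similarity = 90))
  res <- find_conserved_regions(src, map_region("cow1", 1, 35000), tab,
                                "human", tgt)
  expect_equal(res$regions[[1]]$source_gene_count, 2L)  # g1, g2 only
  # region with no gene markers
  empty_src <- genome_map("cow2", markers(name = "ms1", start = 100,
                                          kind = "microsatellite"),
                          units = "bp", extent = c(1, 1e4))
  res2 <- find_conserved_regions(empty_src, map_region("cow2", 1, 1e4), tab,
                                 "human", tgt)
  expect_length(res2$regions, 0L)
})

test_that("target genes on no target map land in the skipped report", {
  src <- gene_map("cow1", "g1", 1e4)
  tab <- homology_table(data.frame(
    gene_a = "g1", species_a = "cow", gene_b = "h_missing",
    species_b = "human", homology_type = "ortholog_one2one",
    perc_identity = 80, perc_similarity = 90))
  res <- find_conserved_regions(src, map_region("cow1", 1, 2e4), tab, "human",
                                list())
  expect_length(res$regions, 0L)
  expect_equal(res$skipped_genes, "h_missing")
})

test_that("an implanted orthologous block is recovered exactly", {
  sim <- simulate_genome_pair(sim_spec(
    n_genes = 20,
    blocks = list(list(length = 20, orientation = "preserved",
                       chromosome = "chrQ")), seed = 5))
  res <- find_conserved_regions(
    sim$source, map_region(sim$source$map_id, sim$source$extent_min,
                           sim$source$extent_max),
    sim$table, "human", sim$targets)
  expect_length(res$regions, 1L)
  r <- res$regions[[1]]
  expect_setequal(r$target_gene_accessions, sim$truth$blocks[[1]]$target_accessions)
  expect_equal(r$source_gene_count, 20L)
  expect_equal(c(r$span_start, r$span_end),
               as.numeric(sim$truth$blocks[[1]]$target_span))
})

test_that("source_gene_count sums to the brute-force (gene, chromosome) pair count", {
  set.seed(41)
  for (rep in 1:5) {
    sim <- simulate_genome_pair(sim_spec(
      n_genes = 30,
      blocks = list(list(length = 12, orientation = "preserved", chromosome = "c1"),
                    list(length = 9, orientation = "inverted", chromosome = "c2")),
      paralog_fraction = 0.3, seed = 100 + rep))
    res <- find_conserved_regions(
      sim$source, map_region(sim$source$map_id, sim$source$extent_min,
                             sim$source$extent_max),
      sim$table, "human", sim$targets)
    # brute force: distinct (source gene, target chromosome) pairs with >= 1
    # record whose target gene is located on that chromosome
    tgt_chr <- do.call(rbind, lapply(sim$targets, function(m)
      data.frame(acc = m$markers$accession, chr = m$chromosome)))
    r <- sim$table$records
    pairs <- unique(data.frame(g = r$gene_a,
                               chr = tgt_chr$chr[match(r$gene_b, tgt_chr$acc)]))
    pairs <- pairs[!is.na(pairs$chr), ]
    expect_equal(sum(vapply(res$regions, function(x) x$source_gene_count,
                            numeric(1))),
                 nrow(pairs))
  }
})

test_that("crossing_count matches parallel, inverted and random orders", {
  a <- gene_map("A", sprintf("a%d", 1:6), (1:6) * 1e4)
  b_same <- gene_map("B", sprintf("a%d", 1:6), (1:6) * 1e4 + 5,
                     chromosome = "chr2")
  links <- identity_links(a, b_same)
  expect_equal(crossing_count(links, a, b_same), 0L)
  # complete inversion: k(k-1)/2
  b_rev <- gene_map("B", sprintf("a%d", 6:1), (1:6) * 1e4, chromosome = "chr2")
  links_rev <- identity_links(a, b_rev)
  expect_equal(crossing_count(links_rev, a, b_rev), 15L)
  # random orders against the O(k^2) brute force
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:30, 1)
    perm <- sample(k)
    bb <- gene_map("B", sprintf("a%d", perm), (1:k) * 1e4, chromosome = "chr2")
    aa <- gene_map("A", sprintf("a%d", 1:k), (1:k) * 1e4)
    l <- identity_links(aa, bb)
    pos_a <- (aa$markers$start[l$idx_a] + aa$markers$end[l$idx_a]) / 2
    pos_b <- (bb$markers$start[l$idx_b] + bb$markers$end[l$idx_b]) / 2
    brute <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      if (sign(pos_a[i] - pos_a[j]) != sign(pos_b[i] - pos_b[j]))
        brute <- brute + 1L
    expect_equal(crossing_count(l, aa, bb), brute)
  }
})

test_that("transfer_markers copies in-extent markers between co-assembled maps", {
  src <- genome_map("epcr1", markers(name = c("e1", "e2", "e3"),
                                     start = c(1.2e6, 3.4e6, 5e6),
                                     kind = "sequence",
                                     accession = c("e1", "e2", "e3")),
                    units = "bp", extent = c(1, 6e6), assembly_tag = "asmV1")
  dest <- genome_map("asm1", markers(name = "g1", start = 2e6, end = 2.1e6,
                                     kind = "gene", accession = "G1"),
                     units = "bp", extent = c(1e6, 4e6), assembly_tag = "asmV1")
  out <- transfer_markers(src, dest)
  expect_equal(nrow(out$markers), 3L)          # e1, e2 transferred; e3 outside
  expect_setequal(out$markers$name, c("g1", "e1", "e2"))
  # accessions preserved: identity links back to the source count transfers
  il <- identity_links(out, src)
  expect_equal(nrow(il), 2L)
  # unit mismatch
  cm <- genome_map("lk", markers(name = "e1", start = 10), units = "cM",
                   extent = c(0, 100))
  expect_error(transfer_markers(cm, dest),
               class = "synmapr_incompatible_coordinates")
  # assembly mismatch
  dest2 <- genome_map("asm2", markers(name = "g1", start = 2e6, kind = "gene"),
                      units = "bp", extent = c(1e6, 4e6), assembly_tag = "asmV2")
  expect_error(transfer_markers(src, dest2),
               class = "synmapr_incompatible_coordinates")
})
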