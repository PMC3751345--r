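test_that("text dialect parses headers, point and range rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#map chr26 salmon cM", "mk1 0.0", "mk2 12.5", "mk3 40.1"), f)
  m <- read_map_text(f)
  expect_equal(m$units, "cM")
  expect_equal(m$species, "salmon")
  expect_equal(m$chromosome, "chr26")
  expect_equal(c(m$extent_min, m$extent_max), c(0, 40.1))
  expect_equal(nrow(m$markers), 3L)
  expect_true(all(m$markers$start == m$markers$end))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#map chr1 cow bp", "geneX 100 250 - gene ENSG0001"), f2)
  m2 <- read_map_text(f2)
  mk <- m2$markers
  expect_equal(c(mk$start, mk$end), c(100, 250))
  expect_equal(mk$strand, "reverse")
  expect_equal(mk$kind, "gene")
  expect_equal(mk$accession, "ENSG0001")
})

test_that("text dialect reports malformed lines and empty files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#map chr1 cow bp", "ok 10", "bad notanumber"), f)
  err <- tryCatch(read_map_text(f), error = function(e) e)
  expect_s3_class(err, "synmapr_parse_error")
  expect_match(conditionMessage(err), ":3:")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("#map chr1 cow bp", f2)
  expect_error(read_map_text(f2), class = "synmapr_empty_map")

  # an extent header alone is a legal empty map
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("#map chr1 cow bp", "#extent 0 100"), f3)
  expect_equal(nrow(read_map_text(f3)$markers), 0L)
})

test_that("text and XML round-trips are exact on random fixture maps", {
  set.seed(21)
  td <- withr::local_tempdir()
  for (i in 1:25) {
    units <- sample(c("bp", "cM", "arbitrary"), 1)
    m <- rand_map(sprintf("map%03d", i), n = sample(1:60, 1), units = units)
    ft <- file.path(td, "m.txt")
    write_map_text(m, ft)
    expect_true(maps_equal(read_map_text(ft), m))
    fx <- file.path(td, "m.xml")
    write_map_xml(m, fx)
    back <- read_map_xml(fx)
    expect_length(back, 1L)
    expect_true(maps_equal(back[[1]], m))
  }
  # multi-map XML document, mixed units
  ms <- list(rand_map("a", n = 10, units = "cM"),
             rand_map("b", n = 10, units = "bp", species = "other"))
  fx <- file.path(td, "multi.xml")
  write_map_xml(ms, fx)
  back <- read_map_xml(fx)
  expect_length(back, 2L)
  expect_true(maps_equal(back[[1]], ms[[1]]))
  expect_true(maps_equal(back[[2]], ms[[2]]))
})

test_that("writers are deterministic", {
  set.seed(22)
  m <- rand_map("det", n = 40)
  td <- withr::local_tempdir()
  f1 <- file.path(td, "a.txt"); f2 <- file.path(td, "b.txt")
  write_map_text(m, f1); write_map_text(m, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  x1 <- file.path(td, "a.xml"); x2 <- file.path(td, "b.xml")
  write_map_xml(m, x1); write_map_xml(m, x2)
  expect_identical(readBin(x1, "raw", file.size(x1)),
                   readBin(x2, "raw", file.size(x2)))
})

test_that("XML reader rejects documents missing required structure", {
  td <- withr::local_tempdir()
  f <- file.path(td, "bad.xml")
  writeLines(c('<mapset><species name="cow">',
               '<map id="m1" units="bp" chromosome="1" extent_min="0" extent_max="10">',
               '<marker start="1" end="2"/>', "</map></species></mapset>"), f)
  err <- tryCatch(read_map_xml(f), error = function(e) e)
  expect_s3_class(err, "synmapr_schema_error")
  expect_match(conditionMessage(err), "name")

  writeLines("<notamapset/>", f)
  expect_error(read_map_xml(f), class = "synmapr_schema_error")

  writeLines(c('<mapset><species name="cow">',
               '<map id="m1" units="parsec" chromosome="1" extent_min="0" extent_max="10"/>',
               "</species></mapset>"), f)
  expect_error(read_map_xml(f), class = "synmapr_schema_error")
})

gff_fixture <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr1 1 50000",
    paste("chr1", ".", "gene", "1000", "5000", ".", "-", ".",
          "ID=g1;Name=SHH", sep = "\t"),
    paste("chr1", ".", "mRNA", "1000", "5000", ".", "-", ".",
          "ID=t1;Parent=g1", sep = "\t"),
    paste("chr1", ".", "gene", "8000", "9500", ".", "+", ".",
          "ID=g2;Name=BMP4", sep = "\t"),
    paste("chr1", ".", "gene", "12000", "15000", ".", "+", ".", "ID=g3",
          sep = "\t"),
    paste("chr2", ".", "gene", "100", "900", ".", "+", ".",
          "ID=g4;Name=PAX6", sep = "\t")), path)
}

test_that("GFF3 gene import filters by type and landmark and maps attributes", {
  f <- withr::local_tempfile(fileext = ".gff3")
  gff_fixture(f)
  m <- read_gff3_genes(f, "chr1", species = "cow")
  expect_equal(nrow(m$markers), 3L)           # genes only, chr1 only
  expect_equal(c(m$extent_min, m$extent_max), c(1, 50000))  # sequence-region pragma
  shh <- m$markers[m$markers$name == "SHH", ]
  expect_equal(c(shh$start, shh$end), c(1000, 5000))
  expect_equal(shh$strand, "reverse")
  expect_equal(shh$accession, "g1")
  expect_equal(shh$kind, "gene")
  g3 <- m$markers[m$markers$accession == "g3", ]
  expect_equal(g3$name, "g3")                 # Name falls back to ID
  err <- tryCatch(read_gff3_genes(f, "chrZ"), error = function(e) e)
  expect_s3_class(err, "synmapr_not_found")
  expect_match(conditionMessage(err), "chr1")
  expect_match(conditionMessage(err), "chr2")
})

test_that("a GFF3 written from a known map is inverted by the reader", {
  set.seed(23)
  m <- rand_map("gffsrc", n = 25, p_range = 1, p_acc = 1)
  mk <- m$markers
  mk$kind <- "gene"
  mk$strand[mk$strand == "unstranded"] <- "forward"
  mk$description <- NA_character_            # the GFF route carries no description
  src <- genome_map("gffsrc", mk, species = m$species, chromosome = "chrT",
                    units = "bp", extent = c(m$extent_min, m$extent_max))
  f <- withr::local_tempfile(fileext = ".gff3")
  sym <- c(forward = "+", reverse = "-")
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region chrT %s %s", src$extent_min, src$extent_max),
               sprintf("chrT\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                       src$markers$start, src$markers$end,
                       sym[src$markers$strand], src$markers$accession,
                       src$markers$name)), f)
  back <- read_gff3_genes(f, "chrT", species = src$species, map_id = "gffsrc")
  expect_true(maps_equal(back, src))
})

test_that("BED import converts 0-based half-open to 1-based inclusive", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tfeatA\t0\t+", "chr1\t999\t2000\tfeatB\t0\t-"), f)
  m <- read_bed_markers(f, "chr1")
  a <- m$markers[m$markers$name == "featA", ]
  expect_equal(c(a$start, a$end), c(1, 100))
  b <- m$markers[m$markers$name == "featB", ]
  expect_equal(c(b$start, b$end), c(1000, 2000))
  expect_equal(b$strand, "reverse")
})

test_that("homology TSV reads, indexes symmetrically, and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("gene_a", "species_a", "gene_b", "species_b",
                     "homology_type", "perc_identity", "perc_similarity",
                     sep = "\t"),
               "g1\tcow\th1\thuman\tortholog_one2one\t82.1\t90.3"), f)
  tab <- read_homology_tsv(f)
  hit <- lookup_gene(tab, "h1")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$gene_a, "h1")              # normalised to queried column
  expect_equal(hit$gene_b, "g1")
  expect_equal(hit$perc_identity, 82.1)
  expect_equal(lookup_gene(tab, "g1")$gene_b, "h1")
  expect_equal(nrow(lookup_gene(tab, "nope")), 0L)

  # empty file with header only
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("gene_a", "species_a", "gene_b", "species_b",
                     "homology_type", "perc_identity", "perc_similarity"),
                   collapse = "\t"), f2)
  tab2 <- read_homology_tsv(f2)
  expect_equal(nrow(tab2$records), 0L)
  expect_equal(nrow(lookup_gene(tab2, "g1")), 0L)

  # similarity below identity is a validation error naming the row
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("gene_a", "species_a", "gene_b", "species_b",
                       "homology_type", "perc_identity", "perc_similarity"),
                     collapse = "\t"),
               "g1\tcow\th1\thuman\tortholog_one2one\t90\t80"), f3)
  err <- tryCatch(read_homology_tsv(f3), error = function(e) e)
  expect_s3_class(err, "synmapr_validation_error")
  expect_match(conditionMessage(err), "record 1")

  # unknown homology type
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("gene_a", "species_a", "gene_b", "species_b",
                       "homology_type", "perc_identity", "perc_similarity"),
                     collapse = "\t"),
               "g1\tcow\th1\thuman\tbest_friend\t80\t90"), f4)
  expect_error(read_homology_tsv(f4), class = "synmapr_validation_error")
})

test_that("homology lookup is symmetric and complete over random tables", {
  set.seed(24)
  pool_a <- sprintf("A%03d", 1:40)
  pool_b <- sprintf("B%03d", 1:40)
  tab <- rand_homology_table(pool_a, pool_b, n = 500)
  genes <- unique(c(tab$records$gene_a, tab$records$gene_b))
  total <- 0L
  for (g in genes) {
    hit <- lookup_gene(tab, g)
    expect_true(all(hit$gene_a == g))
    total <- total + nrow(hit)
  }
  # every record is returned exactly twice across all gene queries
  expect_equal(total, 2L * nrow(tab$records))
  # round trip through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_homology_tsv(tab, f)
  back <- read_homology_tsv(f)
  expect_equal(back$records[order(back$records$gene_a, back$records$gene_b,
                                  back$records$perc_identity), ],
               tab$records[order(tab$records$gene_a, tab$records$gene_b,
                                 tab$records$perc_identity), ],
               ignore_attr = TRUE)
})

test_that("readers reject corrupted fixtures (mutation check)", {
  set.seed(25)
  m <- rand_map("mut", n = 10)
  td <- withr::local_tempdir()
  ft <- file.path(td, "m.txt")
  write_map_text(m, ft)
  lines <- readLines(ft)
  # swap a start/end pair to violate start <= end
  i <- grep("^[^#]", lines)[1]
  parts <- strsplit(lines[i], "\t")[[1]]
  if (parts[2] == parts[3]) parts[3] <- as.character(as.numeric(parts[2]) - 5)
  else { tmp <- parts[2]; parts[2] <- parts[3]; parts[3] <- tmp }
  lines[i] <- paste(parts, collapse = "\t")
  writeLines(lines, ft)
  expect_error(read_map_text(ft))
  # truncate the XML
  fx <- file.path(td, "m.xml")
  write_map_xml(m, fx)
  x <- readLines(fx)
  writeLines(substr(paste(x, collapse = "\n"), 1, 80), fx)
  expect_error(read_map_xml(fx))
})
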