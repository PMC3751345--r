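# Test-side fixture builders and independent brute-force oracles.  These
# deliberately use naive algorithms (double loops, pairwise union-find,
# full position scans) so they stay independent of the package's indexed /
# merge-based implementations.

# --- random fixture maps -------------------------------------------------

# A random map with optional planted name/accession pools (collisions across
# maps arise by sampling from a shared pool).
rand_map <- function(id, n = 30, name_pool = NULL, acc_pool = NULL,
                     units = "bp", p_range = 0.3, p_acc = 0.7,
                     extent_max = 1e6, species = "spp", chromosome = "chr1") {
  start <- sort(round(runif(n, 1, extent_max * 0.95)))
  is_range <- runif(n) < p_range
  end <- ifelse(is_range, pmin(start + round(runif(n, 1, extent_max * 0.05)),
                               extent_max), start)
  nms <- if (is.null(name_pool)) sprintf("%s_mk%04d", id, seq_len(n)) else
    sample(name_pool, n, replace = TRUE)
  acc <- if (is.null(acc_pool)) sprintf("%s_AC%04d", id, seq_len(n)) else
    sample(acc_pool, n, replace = TRUE)
  acc[runif(n) > p_acc] <- NA_character_
  cm <- units == "cM"
  genome_map(id,
             markers(name = nms,
                     start = if (cm) round(start / 1e4, 2) else start,
                     end = if (cm) round(end / 1e4, 2) else end,
                     strand = sample(c("forward", "reverse", "unstranded"), n, TRUE),
                     kind = sample(c("gene", "variant", "microsatellite",
                                     "sequence", "generic"), n, TRUE),
                     accession = acc,
                     description = ifelse(runif(n) < 0.2, "a note here", NA)),
             species = species, chromosome = chromosome, units = units,
             extent = if (cm) c(0, extent_max / 1e4) else c(1, extent_max))
}

rand_homology_table <- function(acc_pool_a, acc_pool_b, n = 100,
                                species_a = "spp", species_b = "tgt") {
  types <- c("ortholog_one2one", "apparent_ortholog_one2one",
             "ortholog_one2many", "ortholog_many2many",
             "possible_ortholog", "paralog")
  id <- round(runif(n, 20, 95), 1)
  sim <- round(pmin(id + runif(n, 0, 10), 100), 1)
  miss <- runif(n) < 0.15
  id[miss] <- NA; sim[miss] <- NA
  homology_table(data.frame(
    gene_a = sample(acc_pool_a, n, replace = TRUE), species_a = species_a,
    gene_b = sample(acc_pool_b, n, replace = TRUE), species_b = species_b,
    homology_type = sample(types, n, replace = TRUE),
    perc_identity = id, perc_similarity = sim, stringsAsFactors = FALSE))
}

# --- brute-force link oracles -------------------------------------------

# Canonical comparable form of a link set: endpoint indices + type + scores.
link_key <- function(links) {
  if (!nrow(links)) return(character())
  sort(sprintf("%d|%d|%s|%s|%s", links$idx_a, links$idx_b, links$link_type,
               ifelse(is.na(links$perc_identity), "-", links$perc_identity),
               ifelse(is.na(links$perc_similarity), "-", links$perc_similarity)))
}

# Loop over every marker of map a (or every record), testing the matching
# rule against every marker of map b by direct comparison — no sorting,
# hashing or merging, so the oracle stays independent of the package's
# merge-based implementation.  (The innermost comparison is vectorised for
# speed; the all-pairs structure is unchanged.)
oracle_identity <- function(a, b) {
  ma <- a$markers; mb <- b$markers
  out <- list()
  for (i in seq_len(nrow(ma))) {
    if (is.na(ma$accession[i])) next
    js <- which(!is.na(mb$accession) & mb$accession == ma$accession[i])
    for (j in js)
      out[[length(out) + 1L]] <- data.frame(idx_a = i, idx_b = j,
                                            link_type = "identity",
                                            perc_identity = NA_real_,
                                            perc_similarity = NA_real_)
  }
  if (!length(out)) empty_df_links() else do.call(rbind, out)
}

oracle_synonymy <- function(a, b) {
  ma <- a$markers; mb <- b$markers
  out <- list()
  for (i in seq_len(nrow(ma))) {
    js <- which(mb$name == ma$name[i])
    for (j in js) {
      ident <- !is.na(ma$accession[i]) && !is.na(mb$accession[j]) &&
        ma$accession[i] == mb$accession[j]
      if (!ident)
        out[[length(out) + 1L]] <- data.frame(idx_a = i, idx_b = j,
                                              link_type = "synonymy",
                                              perc_identity = NA_real_,
                                              perc_similarity = NA_real_)
    }
  }
  if (!length(out)) empty_df_links() else do.call(rbind, out)
}

oracle_homology <- function(a, b, table) {
  ma <- a$markers; mb <- b$markers
  r <- table$records
  out <- list()
  for (k in seq_len(nrow(r))) {
    krows <- NULL
    for (dir in 1:2) {
      ga <- if (dir == 1) r$gene_a[k] else r$gene_b[k]
      gb <- if (dir == 1) r$gene_b[k] else r$gene_a[k]
      is <- which(!is.na(ma$accession) & ma$accession == ga)
      js <- which(!is.na(mb$accession) & mb$accession == gb)
      for (i in is) for (j in js)
        krows <- rbind(krows, data.frame(idx_a = i, idx_b = j,
                                         link_type = r$homology_type[k],
                                         perc_identity = r$perc_identity[k],
                                         perc_similarity = r$perc_similarity[k]))
    }
    # one link per record per endpoint pair (a self-record pairing a gene
    # with itself is found in both directions but reported once)
    if (!is.null(krows)) out[[length(out) + 1L]] <- unique(krows)
  }
  if (!length(out)) empty_df_links() else do.call(rbind, out)
}

empty_df_links <- function()
  data.frame(idx_a = integer(), idx_b = integer(), link_type = character(),
             perc_identity = numeric(), perc_similarity = numeric())

# --- union-find column oracle -------------------------------------------

# Connected components over pairwise closed-interval overlap, then ordered
# by minimum x.
oracle_columns <- function(cv) {
  ps <- Filter(function(p) p$visible, cv$placements)
  n <- length(ps)
  if (!n) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  x0 <- vapply(ps, function(p) p$x, numeric(1))
  x1 <- x0 + vapply(ps, function(p) p$width, numeric(1))
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j && x0[i] <= x1[j] && x0[j] <= x1[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  minx <- vapply(comps, function(ix) min(x0[ix]), numeric(1))
  comps <- comps[order(minx)]
  lapply(comps, function(ix)
    vapply(ps[ix], function(p) p$map_id, character(1)))
}

# set-of-sets comparison ignoring within-column order
columns_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  all(mapply(function(x, y) setequal(x, y), a, b))
}

# --- ePCR brute-force scan ----------------------------------------------

revcomp_chr <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Scan every start position on both orientations of one sequence.
oracle_epcr_hits <- function(seq_chr, fwd, rev, min_product, max_product) {
  n <- nchar(seq_chr)
  find_sites <- function(pat) {
    k <- nchar(pat)
    if (k > n) return(integer())
    which(substring(seq_chr, seq_len(n - k + 1), k:n) == pat)
  }
  hits <- NULL
  combos <- list(c(fwd, rev), c(rev, fwd))
  if (fwd == rev) combos <- combos[1]
  for (cmb in combos) {
    left <- cmb[1]; right <- cmb[2]
    ls <- find_sites(left)
    rs <- find_sites(revcomp_chr(right))
    for (s in ls) for (r in rs) {
      e <- r + nchar(right) - 1L
      len <- e - s + 1L
      if (r > s + nchar(left) - 1L && len >= min_product && len <= max_product)
        hits <- rbind(hits, data.frame(start = s, end = e))
    }
  }
  if (is.null(hits)) data.frame(start = integer(), end = integer()) else
    unique(hits[order(hits$start, hits$end), , drop = FALSE])
}

# --- misc ----------------------------------------------------------------

rand_canvas <- function(n = 6, max_x = 800) {
  ps <- lapply(seq_len(n), function(i)
    placement(sprintf("m%02d", i), x = round(runif(1, 0, max_x)),
              y = round(runif(1, 0, 200)), width = round(runif(1, 20, 150)),
              height = round(runif(1, 100, 500)), view_start = 0, view_end = 100,
              visible = runif(1) > 0.1))
  canvas(ps)
}

demo_dir <- function() system.file("extdata", "demo", package = "synmapr")

demo_map_files <- function() {
  truth <- jsonlite::read_json(file.path(demo_dir(), "truth.json"))
  file.path(demo_dir(), unlist(truth$files))
}
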