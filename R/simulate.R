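# Synthetic data with known ground truth.  The generators emulate the
# structures the comparative workflows assume — collinear and inverted
# orthologous blocks between two genomes, genetic linkage maps as noisy
# monotone transforms of physical maps, and genomes with implanted primer
# sites — so that synteny discovery, crossing counts, marker transfer and
# ePCR can all be tested offline against implanted truth.  Every generator
# is a pure function of (spec, seed).

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Specify a simulated genome pair
#'
#' @param n_genes total gene count on the source chromosome.
#' @param blocks list of syntenic blocks, each
#'   \code{list(length =, orientation = "preserved"|"inverted",
#'   chromosome =)}; lengths must sum to at most \code{n_genes}.  Blocks
#'   claim consecutive runs of source genes in positional order; genes
#'   outside any block have no orthologue.
#' @param identity_range,similarity_gap homology score model: percent
#'   identity ~ Uniform(range), percent similarity = identity +
#'   Uniform(0, gap), capped at 100.
#' @param paralog_fraction fraction of block genes receiving one extra
#'   within-target \code{paralog} record.
#' @param source_species,target_species species labels.
#' @param gene_length_range gene lengths drawn uniformly from this bp
#'   range, placed without overlap by rejection.
#' @param seed integer seed; the spec is infeasible if blocks exceed
#'   \code{n_genes}.
#' @return a \code{sim_spec} list.
#' @export
sim_spec <- function(n_genes = 40,
                     blocks = list(
                       list(length = 25, orientation = "preserved", chromosome = "chr1"),
                       list(length = 10, orientation = "inverted", chromosome = "chr2")),
                     identity_range = c(60, 95), similarity_gap = 5,
                     paralog_fraction = 0.1,
                     source_species = "cow", target_species = "human",
                     gene_length_range = c(1e3, 5e4), seed = 1L) {
  lens <- vapply(blocks, function(b) b$length, numeric(1))
  if (sum(lens) > n_genes)
    sm_abort("block lengths exceed n_genes", "synmapr_validation_error")
  sm_assert(all(vapply(blocks, function(b)
    b$orientation %in% c("preserved", "inverted"), logical(1))),
    "block orientation must be preserved or inverted", "synmapr_validation_error")
  sm_assert(paralog_fraction >= 0 && paralog_fraction <= 1,
            "paralog_fraction must be in [0, 1]", "synmapr_validation_error")
  structure(list(n_genes = n_genes, blocks = blocks,
                 identity_range = identity_range,
                 similarity_gap = similarity_gap,
                 paralog_fraction = paralog_fraction,
                 source_species = source_species,
                 target_species = target_species,
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

# n non-overlapping [start, end] intervals in [1, total], sorted; lengths
# uniform in len_range; placement by rejection.
place_genes <- function(n, len_range, total) {
  lens <- round(stats::runif(n, len_range[1], len_range[2]))
  starts <- numeric(0); ends <- numeric(0)
  for (l in lens) {
    repeat {
      s <- round(stats::runif(1, 1, total - l))
      if (!any(s <= ends + 1 & s + l >= starts - 1)) break
    }
    starts <- c(starts, s); ends <- c(ends, s + l - 1)
  }
  o <- order(starts)
  data.frame(start = starts[o], end = ends[o])
}

#' Simulate a genome pair with implanted syntenic blocks
#'
#' Generates a source map of \code{n_genes} gene markers at sorted random
#' bp positions; for each block, orthologous target genes on the named
#' target chromosome in preserved or reversed positional order; one2one
#' homology records with scores from the spec's distribution; and extra
#' \code{paralog}-typed records for a fraction of block genes.  The truth
#' record lists block memberships, orientations and target spans.
#'
#' @param spec a [sim_spec()].
#' @return list: \code{source} (\code{genome_map}), \code{targets} (list of
#'   \code{genome_map}, one per target chromosome), \code{table}
#'   (\code{homology_table}), \code{truth} (list; includes the seed).
#' @export
simulate_genome_pair <- function(spec = sim_spec()) {
  sm_assert(inherits(spec, "sim_spec"), "not a sim_spec")
  with_seed(spec$seed, {
    n <- spec$n_genes
    total <- max(2e5, n * 6e4)
    src_pos <- place_genes(n, spec$gene_length_range, total)
    src_acc <- sprintf("SRCG%04d", seq_len(n))
    src <- genome_map("source_chr1",
                      markers = markers(name = sprintf("sg%02d", seq_len(n)),
                                        start = src_pos$start, end = src_pos$end,
                                        strand = sample(c("forward", "reverse"), n, replace = TRUE),
                                        kind = "gene", accession = src_acc),
                      species = spec$source_species, chromosome = "chr1",
                      units = "bp", extent = c(1, total), assembly_tag = "srcAsm1")
    # consecutive runs of source genes claim the blocks
    cursor <- 0L
    targets <- list(); recs <- list(); truth_blocks <- list()
    tgt_counter <- 0L
    for (b in spec$blocks) {
      idx <- cursor + seq_len(b$length)
      cursor <- cursor + b$length
      t_total <- max(2e5, b$length * 6e4)
      t_pos <- place_genes(b$length, spec$gene_length_range, t_total)
      tgt_acc <- sprintf("TGTG%04d", tgt_counter + seq_len(b$length))
      tgt_counter <- tgt_counter + b$length
      # preserved: i-th source gene of the block pairs with i-th target
      # position; inverted: with the (length+1-i)-th
      pairing <- if (b$orientation == "preserved") seq_len(b$length)
                 else rev(seq_len(b$length))
      tmap <- genome_map(paste0("target_", b$chromosome),
                         markers = markers(
                           name = sprintf("tg%04d", tgt_counter - b$length + seq_len(b$length)),
                           start = t_pos$start, end = t_pos$end,
                           strand = sample(c("forward", "reverse"), b$length, replace = TRUE),
                           kind = "gene", accession = tgt_acc),
                         species = spec$target_species,
                         chromosome = b$chromosome, units = "bp",
                         extent = c(1, t_total), assembly_tag = "tgtAsm1")
      targets[[length(targets) + 1L]] <- tmap
      id <- stats::runif(b$length, spec$identity_range[1], spec$identity_range[2])
      sim <- pmin(id + stats::runif(b$length, 0, spec$similarity_gap), 100)
      recs[[length(recs) + 1L]] <- data.frame(
        gene_a = src_acc[idx], species_a = spec$source_species,
        gene_b = tgt_acc[pairing], species_b = spec$target_species,
        homology_type = "ortholog_one2one",
        perc_identity = round(id, 1), perc_similarity = round(sim, 1),
        stringsAsFactors = FALSE)
      n_par <- floor(spec$paralog_fraction * b$length)
      if (n_par >= 1 && b$length >= 2) {
        pi <- sample(seq_len(b$length), n_par)
        partner <- vapply(pi, function(i)
          sample(setdiff(seq_len(b$length), i), 1), numeric(1))
        pid <- stats::runif(n_par, spec$identity_range[1], spec$identity_range[2])
        recs[[length(recs) + 1L]] <- data.frame(
          gene_a = src_acc[idx[pi]], species_a = spec$source_species,
          gene_b = tgt_acc[partner], species_b = spec$target_species,
          homology_type = "paralog",
          perc_identity = round(pid, 1),
          perc_similarity = round(pmin(pid + stats::runif(n_par, 0, spec$similarity_gap), 100), 1),
          stringsAsFactors = FALSE)
      }
      truth_blocks[[length(truth_blocks) + 1L]] <- list(
        chromosome = b$chromosome, orientation = b$orientation,
        source_accessions = src_acc[idx],
        target_accessions = tgt_acc[pairing],
        target_span = c(min(t_pos$start), max(t_pos$end)))
    }
    table <- homology_table(do.call(rbind, recs))
    list(source = src, targets = targets, table = table,
         truth = list(seed = spec$seed, n_genes = n, blocks = truth_blocks))
  })
}

#' Simulate a genetic linkage map from a physical map
#'
#' Emulates linkage-versus-physical alignment: a cM map sharing names and
#' accessions with the physical (bp) map, with positions equal to the
#' scaled physical position plus Gaussian jitter, clamped monotone
#' non-decreasing (recombination distance cannot run backwards).
#'
#' @param physical a \code{genome_map} in bp units.
#' @param cm_per_unit cM per bp (default \code{1e-6}: the classical ~1
#'   cM/Mb).
#' @param jitter_sd standard deviation of the cM jitter (default 0.5 cM).
#' @param seed integer seed.
#' @return a \code{genome_map} in cM with point markers.
#' @export
simulate_linkage_map <- function(physical, cm_per_unit = 1e-6, jitter_sd = 0.5,
                                 seed = 1L) {
  sm_assert(is_genome_map(physical) && physical$units == "bp",
            "physical map must be in bp")
  with_seed(seed, {
    mk <- physical$markers
    mid <- (mk$start + mk$end) / 2
    cm <- mid * cm_per_unit
    if (jitter_sd > 0) cm <- cm + stats::rnorm(nrow(mk), 0, jitter_sd)
    # clamp monotone non-decreasing along the physical (midpoint) order —
    # recombination distance cannot run backwards
    o <- order(mid)
    cm[o] <- cummax(pmax(cm[o], 0))
    cm <- round(cm, 6)
    genome_map(paste0(physical$map_id, "_linkage"),
               markers = markers(name = mk$name, start = cm, end = cm,
                                 strand = "unstranded", kind = mk$kind,
                                 accession = mk$accession),
               species = physical$species, chromosome = physical$chromosome,
               units = "cM",
               title = paste0(physical$title, " (linkage)"),
               extent = c(0, max(cm) + 1))
  })
}

#' Build a primer pair record
#'
#' @param name pair name.
#' @param forward,reverse primer sequences over ACGT.
#' @param min_product,max_product product size bounds in bp.
#' @return one-row primer \code{data.frame}.
#' @export
primer_pair <- function(name, forward, reverse, min_product = 100,
                        max_product = 1000) {
  validate_primers(data.frame(name = name, forward = forward, reverse = reverse,
                              min_product = min_product,
                              max_product = max_product,
                              stringsAsFactors = FALSE))
}

random_dna <- function(n) paste(sample(DNA_ALPHABET, n, replace = TRUE),
                                collapse = "")

#' Simulate a genome with implanted primer sites
#'
#' Uniform-random ACGT background with amplicon sites implanted at stated
#' positions; each site is the forward primer, random filler, then the
#' reverse-complement of the reverse primer, with total length midway
#' between the pair's product bounds.  Implants must not overlap.  The
#' truth lists the expected amplicon interval of every copy and the
#' expected discard reason for multi-copy pairs (\code{multiple_hits}).
#'
#' @param length background length in bp.
#' @param implants list of \code{list(pair = <one-row primer data.frame>,
#'   positions = <numeric vector of implant starts>)}; \code{copies =
#'   length(positions)}.
#' @param seed integer seed.
#' @param sequence_name FASTA record name (default \code{"chr1"}).
#' @return list: \code{sequence} (character), \code{fasta_lines},
#'   \code{truth} (\code{data.frame} pair/start/end/copies/expected).
#' @export
simulate_genome_fasta <- function(length, implants = list(), seed = 1L,
                                  sequence_name = "chr1") {
  with_seed(seed, {
    seq <- strsplit(random_dna(length), "")[[1]]
    truth <- list()
    occupied <- data.frame(start = numeric(), end = numeric())
    for (imp in implants) {
      p <- validate_primers(imp$pair)
      amp_len <- floor((p$min_product + p$max_product) / 2)
      site <- paste0(p$forward, random_dna(amp_len - nchar(p$forward) -
                                             nchar(p$reverse)),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(p$reverse))))
      for (pos in imp$positions) {
        s <- as.integer(pos); e <- s + amp_len - 1L
        if (s < 1 || e > length)
          sm_abort("implant outside the genome", "synmapr_validation_error")
        if (any(s <= occupied$end & e >= occupied$start))
          sm_abort("implants overlap", "synmapr_validation_error")
        occupied <- rbind(occupied, data.frame(start = s, end = e))
        seq[s:e] <- strsplit(site, "")[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          pair = p$name, start = s, end = e,
          copies = base::length(imp$positions),
          expected = if (base::length(imp$positions) >= 2) "multiple_hits" else "unique",
          stringsAsFactors = FALSE)
      }
    }
    sequence <- paste(seq, collapse = "")
    truth <- if (base::length(truth)) do.call(rbind, truth) else
      data.frame(pair = character(), start = integer(), end = integer(),
                 copies = integer(), expected = character())
    list(sequence = sequence, sequence_name = sequence_name,
         fasta_lines = c(paste0(">", sequence_name),
                         substring(sequence, seq(1, nchar(sequence), 70),
                                   pmin(seq(1, nchar(sequence), 70) + 69,
                                        nchar(sequence)))),
         truth = truth, seed = seed)
  })
}

#' Draw a random primer pair
#'
#' Convenience for tests and demos: two random 20-mers with the default
#' product window.
#'
#' @param name pair name.
#' @param primer_length primer length in bp.
#' @param min_product,max_product product bounds.
#' @return one-row primer \code{data.frame}.
#' @export
random_primer_pair <- function(name, primer_length = 20, min_product = 100,
                               max_product = 1000) {
  primer_pair(name, random_dna(primer_length), random_dna(primer_length),
              min_product, max_product)
}

#' Write the bundled six-map demonstration recipe
#'
#' Emits a synthetic analogue of a typical cross-species integration: a
#' private QTL linkage map and a published-style linkage map of one salmon
#' chromosome (cM), two bridge maps carrying sequence hits of the salmon
#' markers on stickleback and medaka chromosomes (bp), and the two
#' gene-annotated assemblies with the bridge markers transferred onto them
#' (bp).  The layout places the maps in four virtual columns —
#' \code{{private}, {published}, {bridge pair}, {assembly pair}} — so
#' identity links join the linkage maps and each bridge to its assembly,
#' and synonymy links join the published map to the bridges.  Files:
#' \code{map1_private.txt \ldots map6_medaka_asm.txt}, \code{layout.json},
#' \code{truth.json}.
#'
#' @param dir output directory.
#' @param seed integer seed (recorded in the truth file).
#' @return invisibly, the directory.
#' @export
write_demo_recipe <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    n_snp <- 12
    snp_names <- sprintf("SSA26_%03d", seq_len(n_snp))
    snp_acc <- sprintf("ARKSNP%04d", seq_len(n_snp))
    cm <- round(sort(stats::runif(n_snp, 0, 60)), 1)

    map2 <- genome_map("salmon_chr26_published",
                       markers = markers(name = snp_names, start = cm,
                                         kind = "variant", accession = snp_acc),
                       species = "salmon", chromosome = "chr26", units = "cM",
                       title = "published salmon linkage map chr26",
                       extent = c(0, max(cm) + 2))
    # private map: half of the markers, jittered order-preserving, plus a QTL
    priv_idx <- sort(sample(seq_len(n_snp), 6))
    priv_cm <- round(cummax(cm[priv_idx] + stats::rnorm(6, 0, 0.4)), 1)
    map1 <- genome_map("salmon_qtl_private",
                       markers = markers(
                         name = c(snp_names[priv_idx], "QTL1"),
                         start = c(priv_cm, round(mean(priv_cm), 1)),
                         kind = c(rep("variant", 6), "generic"),
                         accession = c(snp_acc[priv_idx], NA)),
                       species = "salmon", chromosome = "chr26", units = "cM",
                       title = "private salmon QTL map",
                       extent = c(0, max(c(priv_cm, cm)) + 2))
    bridge <- function(idx, map_id, species, chromosome, asm, acc_prefix) {
      pos <- sort(round(stats::runif(length(idx), 2e5, 3.8e6)))
      genome_map(map_id,
                 markers = markers(name = snp_names[idx], start = pos,
                                   kind = "sequence",
                                   accession = sprintf("%s%03d", acc_prefix, idx)),
                 species = species, chromosome = chromosome, units = "bp",
                 title = paste0(species, " ", chromosome, " sequence hits"),
                 extent = c(1, 4e6), assembly_tag = asm)
    }
    stick_idx <- seq(1, n_snp, by = 2)
    med_idx <- seq(2, n_snp, by = 2)
    map3 <- bridge(stick_idx, "stickleback_grpIV_hits", "stickleback",
                   "groupIV", "gacAsm1", "GACHIT")
    map4 <- bridge(med_idx, "medaka_chr12_hits", "medaka", "chr12",
                   "olaAsm1", "OLAHIT")
    assembly <- function(bridge_map, map_id, acc_prefix, n_genes) {
      pos <- place_genes(n_genes, c(5e3, 6e4), 4e6)
      g <- genome_map(map_id,
                      markers = markers(
                        name = sprintf("%s_g%02d", bridge_map$species, seq_len(n_genes)),
                        start = pos$start, end = pos$end,
                        strand = sample(c("forward", "reverse"), n_genes, TRUE),
                        kind = "gene",
                        accession = sprintf("%sG%04d", acc_prefix, seq_len(n_genes))),
                      species = bridge_map$species,
                      chromosome = bridge_map$chromosome, units = "bp",
                      title = paste0(bridge_map$species, " annotated assembly"),
                      extent = c(1, 4e6), assembly_tag = bridge_map$assembly_tag)
      transfer_markers(bridge_map, g)
    }
    map5 <- assembly(map3, "stickleback_grpIV_asm", "ENSGAC", 15)
    map6 <- assembly(map4, "medaka_chr12_asm", "ENSORL", 15)

    maps <- list(map1, map2, map3, map4, map5, map6)
    files <- c("map1_private.txt", "map2_published.txt", "map3_stickleback_hits.txt",
               "map4_medaka_hits.txt", "map5_stickleback_asm.txt",
               "map6_medaka_asm.txt")
    for (i in seq_along(maps))
      write_map_text(maps[[i]], file.path(dir, files[i]))
    layout <- list(maps = list(
      list(map_id = map1$map_id, x = 0, y = 40, width = 120, height = 420),
      list(map_id = map2$map_id, x = 200, y = 20, width = 120, height = 460),
      list(map_id = map3$map_id, x = 400, y = 10, width = 120, height = 220),
      list(map_id = map4$map_id, x = 460, y = 260, width = 120, height = 220),
      list(map_id = map5$map_id, x = 660, y = 10, width = 130, height = 220,
           label_mode = "linked_only"),
      list(map_id = map6$map_id, x = 700, y = 260, width = 130, height = 220,
           label_mode = "linked_only")))
    jsonlite::write_json(layout, file.path(dir, "layout.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    truth <- list(seed = seed,
                  files = as.list(stats::setNames(files, vapply(maps, function(m) m$map_id, character(1)))),
                  columns = list(map1$map_id, map2$map_id,
                                 c(map3$map_id, map4$map_id),
                                 c(map5$map_id, map6$map_id)),
                  identity_pairs = list(c(map1$map_id, map2$map_id),
                                        c(map3$map_id, map5$map_id),
                                        c(map4$map_id, map6$map_id)),
                  synonymy_pairs = list(c(map2$map_id, map3$map_id),
                                        c(map2$map_id, map4$map_id)),
                  n_private_shared = 6L,
                  n_bridge = c(length(stick_idx), length(med_idx)))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(dir)
}
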