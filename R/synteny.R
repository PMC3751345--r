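# Conserved-synteny discovery: walk the gene markers of a source region,
# collect asserted homologues in a target species from a homology table,
# and group the located target genes by target chromosome.  No rules are
# imposed on what constitutes a "block" of conserved synteny: every target
# chromosome hit by at least one homologue is reported, ranked by how many
# source genes support it, and callers may threshold on that count.

#' Find regions of conserved synteny for a source map region
#'
#' For each gene marker (kind \code{gene}, accession present) inside
#' \code{region} on \code{source}, homology records towards
#' \code{target_species} are collected from \code{table}; matched target
#' genes are located on the supplied target maps and grouped by target
#' chromosome.  One \code{conserved_region} is emitted per hit chromosome
#' with a span covering every located target gene, the number of distinct
#' contributing source genes, and one link per homology record used.
#' Regions are sorted by descending \code{source_gene_count} (chromosome
#' label breaks ties deterministically).  Target genes asserted in the
#' table but present on no target map are collected into a skipped-genes
#' report rather than raising an error.
#'
#' @param source a \code{genome_map} carrying gene markers.
#' @param region a [map_region()] on \code{source}.
#' @param table a \code{homology_table}.
#' @param target_species species label to search towards (must match the
#'   table's species columns).
#' @param target_maps list of \code{genome_map}s providing coordinates for
#'   target gene accessions.
#' @return a list of class \code{conserved_region_set}: \code{regions} (list
#'   of \code{conserved_region}), \code{skipped_genes} (character vector of
#'   unlocatable target accessions).
#' @export
find_conserved_regions <- function(source, region, table, target_species,
                                   target_maps) {
  sm_assert(is_genome_map(source), "source must be a genome_map")
  sm_assert(inherits(region, "map_region") && region$map_id == source$map_id,
            "region must reference the source map")
  sm_assert(inherits(table, "homology_table"), "not a homology_table")
  if (is_genome_map(target_maps)) target_maps <- list(target_maps)
  sub <- subregion(source, region, paste0(source$map_id, "_query"))
  mk <- sub$markers
  genes <- mk[mk$kind == "gene" & !is.na(mk$accession), , drop = FALSE]
  empty <- structure(list(regions = list(), skipped_genes = character()),
                     class = "conserved_region_set")
  if (!nrow(genes)) return(empty)

  # index target gene accessions across the target maps
  tgt_index <- do.call(rbind, lapply(target_maps, function(m) {
    t <- m$markers
    keep <- !is.na(t$accession)
    if (!any(keep)) return(NULL)
    data.frame(accession = t$accession[keep], map_id = m$map_id,
               chromosome = m$chromosome, name = t$name[keep],
               start = t$start[keep], end = t$end[keep],
               idx = which(keep), stringsAsFactors = FALSE)
  }))

  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(genes))) {
    recs <- lookup_gene(table, genes$accession[i])
    recs <- recs[recs$species_b == target_species, , drop = FALSE]
    for (j in seq_len(nrow(recs))) {
      tg <- recs$gene_b[j]
      loc <- if (is.null(tgt_index)) NULL else
        tgt_index[tgt_index$accession == tg, , drop = FALSE]
      if (is.null(loc) || !nrow(loc)) {
        skipped <- c(skipped, tg)
        next
      }
      for (k in seq_len(nrow(loc)))
        rows[[length(rows) + 1L]] <- data.frame(
          src_gene = genes$accession[i], src_name = genes$name[i],
          src_idx = which(source$markers$accession == genes$accession[i] &
                            source$markers$name == genes$name[i])[1],
          tgt_gene = tg, tgt_map = loc$map_id[k], tgt_chr = loc$chromosome[k],
          tgt_name = loc$name[k], tgt_idx = loc$idx[k],
          tgt_start = loc$start[k], tgt_end = loc$end[k],
          homology_type = recs$homology_type[j],
          perc_identity = recs$perc_identity[j],
          perc_similarity = recs$perc_similarity[j],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(structure(list(regions = list(), skipped_genes = unique(skipped)),
                     class = "conserved_region_set"))
  hits <- do.call(rbind, rows)
  regions <- lapply(split(hits, hits$tgt_chr), function(h) {
    links <- order_links(link_frame(
      map_a = source$map_id, marker_a = h$src_name, idx_a = h$src_idx,
      map_b = h$tgt_map, marker_b = h$tgt_name, idx_b = h$tgt_idx,
      link_type = h$homology_type, perc_identity = h$perc_identity,
      perc_similarity = h$perc_similarity))
    structure(list(target_species = target_species,
                   target_chromosome = h$tgt_chr[1],
                   target_map_id = h$tgt_map[1],
                   span_start = min(h$tgt_start),
                   span_end = max(h$tgt_end),
                   target_gene_accessions = sort(unique(h$tgt_gene)),
                   source_gene_count = length(unique(h$src_gene)),
                   links = links),
              class = "conserved_region")
  })
  counts <- vapply(regions, function(r) r$source_gene_count, numeric(1))
  chrs <- vapply(regions, function(r) r$target_chromosome, character(1))
  regions <- regions[order(-counts, chrs, method = "radix")]
  names(regions) <- NULL
  structure(list(regions = regions, skipped_genes = unique(skipped)),
            class = "conserved_region_set")
}

#' @export
print.conserved_region_set <- function(x, ...) {
  cat(sprintf("<conserved_region_set> %d region(s), %d unlocatable target gene(s)\n",
              length(x$regions), length(x$skipped_genes)))
  for (r in x$regions)
    cat(sprintf("  %s %s [%s, %s]  %d source gene(s), %d target gene(s)\n",
                r$target_species, r$target_chromosome, fmt_num(r$span_start),
                fmt_num(r$span_end), r$source_gene_count,
                length(r$target_gene_accessions)))
  invisible(x)
}

#' Count discordantly ordered link pairs between two maps
#'
#' The crossing count is the number of unordered link pairs whose endpoint
#' orders differ between the two maps (pair \code{(i, j)} crosses iff
#' \code{sign(a_i - a_j) != sign(b_i - b_j)}, positions taken as interval
#' midpoints).  Parallel one-to-one links in conserved order give 0; a
#' complete inversion of \code{k} linked genes gives \code{k(k-1)/2} — the
#' quantitative counterpart of the visually crossing lines that reveal an
#' inversion between two aligned maps.
#'
#' @param links a link \code{data.frame}; every link must connect \code{a}
#'   and \code{b} (in either endpoint order).
#' @param a,b the two \code{genome_map}s.
#' @return integer crossing count.
#' @export
crossing_count <- function(links, a, b) {
  sm_assert(is_genome_map(a) && is_genome_map(b), "need two genome_maps")
  if (!nrow(links)) return(0L)
  fwd <- links$map_a == a$map_id & links$map_b == b$map_id
  rev <- links$map_a == b$map_id & links$map_b == a$map_id
  sm_assert(all(fwd | rev), "all links must connect the two given maps")
  pos_a <- ifelse(fwd,
                  (a$markers$start[links$idx_a] + a$markers$end[links$idx_a]) / 2,
                  (a$markers$start[links$idx_b] + a$markers$end[links$idx_b]) / 2)
  pos_b <- ifelse(fwd,
                  (b$markers$start[links$idx_b] + b$markers$end[links$idx_b]) / 2,
                  (b$markers$start[links$idx_a] + b$markers$end[links$idx_a]) / 2)
  k <- length(pos_a)
  if (k < 2) return(0L)
  da <- sign(outer(pos_a, pos_a, "-"))
  db <- sign(outer(pos_b, pos_b, "-"))
  sum((da != db)[upper.tri(da)])
}

#' Transfer markers between co-assembled maps
#'
#' Copies every source marker whose interval lies within the destination
#' extent onto the destination map, preserving name, accession, strand and
#' kind.  The two maps must share units and assembly tag (same coordinate
#' system) — this is how ePCR bridge markers are projected onto a cognate
#' gene-annotated assembly.
#'
#' @param source,dest \code{genome_map}s sharing units and
#'   \code{assembly_tag}.
#' @return a new \code{genome_map}: \code{dest} plus the transferred
#'   markers.
#' @export
transfer_markers <- function(source, dest) {
  sm_assert(is_genome_map(source) && is_genome_map(dest), "need two genome_maps")
  same_tag <- (is.na(source$assembly_tag) && is.na(dest$assembly_tag)) ||
    (!is.na(source$assembly_tag) && !is.na(dest$assembly_tag) &&
       source$assembly_tag == dest$assembly_tag)
  if (source$units != dest$units || !same_tag)
    sm_abort(sprintf(
      "incompatible coordinates: source is %s/%s, dest is %s/%s",
      source$units, source$assembly_tag, dest$units, dest$assembly_tag),
      "synmapr_incompatible_coordinates")
  mk <- source$markers
  keep <- mk$start >= dest$extent_min & mk$end <= dest$extent_max
  out <- dest
  out$markers <- canonicalise_markers(rbind(dest$markers, mk[keep, , drop = FALSE]))
  out
}
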