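# Assembly-annotation inputs: GFF3 gene tracks and BED intervals, read via
# rtracklayer (GFF3/BED grammar, coordinate conventions and attribute
# unescaping are delegated to it; BED's 0-based half-open intervals come
# back 1-based inclusive).

gr_strand_to_model <- function(s)
  c("+" = "forward", "-" = "reverse", "*" = "unstranded")[as.character(s)]

#' Build an assembly map from the gene features of a GFF3 file
#'
#' One marker per feature of type \code{gene} on the requested landmark;
#' the marker name is the \code{Name} attribute, falling back to \code{ID};
#' the accession is the \code{ID}.  The map extent comes from the
#' \code{##sequence-region} pragma when present, else from the features.
#'
#' @param path GFF3 file.
#' @param chromosome landmark (seqid) to extract.
#' @param species species label for the map.
#' @param assembly_tag optional assembly/release label.
#' @param map_id id for the new map; default \code{"<species>_<chromosome>"}.
#' @return a \code{genome_map} in bp units.
#' @export
read_gff3_genes <- function(path, chromosome, species = "unknown",
                            assembly_tag = NULL,
                            map_id = paste0(species, "_", chromosome)) {
  sm_assert(file.exists(path), paste0("no such file: ", path), "synmapr_io_error")
  gr <- rtracklayer::import(path, format = "gff3")
  seqs <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (!chromosome %in% seqs)
    sm_abort(sprintf("chromosome '%s' not found; available landmarks: %s",
                     chromosome, paste(sort(seqs), collapse = ", ")),
             "synmapr_not_found")
  keep <- as.character(gr$type) == "gene" &
    as.character(GenomicRanges::seqnames(gr)) == chromosome
  genes <- gr[keep]
  id <- as.character(genes$ID)
  nm <- if (is.null(genes$Name)) rep(NA_character_, length(genes)) else
    as.character(genes$Name)
  nm[is.na(nm) | !nzchar(nm)] <- id[is.na(nm) | !nzchar(nm)]
  mk <- markers(name = nm,
                start = GenomicRanges::start(genes),
                end = GenomicRanges::end(genes),
                strand = gr_strand_to_model(GenomicRanges::strand(genes)),
                kind = "gene", accession = id)
  extent <- gff3_sequence_region(path, chromosome)
  if (is.null(extent) && nrow(mk) > 0L) extent <- c(min(mk$start), max(mk$end))
  genome_map(map_id, markers = mk, species = species, chromosome = chromosome,
             units = "bp", extent = extent, assembly_tag = assembly_tag)
}

# Extract the ##sequence-region pragma for one landmark (rtracklayer does
# not surface pragmas; a direct scan is robust and cheap).
gff3_sequence_region <- function(path, chromosome) {
  for (ln in grep("^##sequence-region", readLines(path, warn = FALSE), value = TRUE)) {
    toks <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(toks) >= 4 && toks[2] == chromosome)
      return(as.numeric(toks[3:4]))
  }
  NULL
}

#' Build a map from a BED file
#'
#' BED intervals (0-based, half-open) are converted to the model's 1-based
#' inclusive convention on read.  All records on the requested chromosome
#' become markers of the given kind.
#'
#' @param path BED file.
#' @param chromosome landmark to extract.
#' @param species,assembly_tag,map_id as in [read_gff3_genes()].
#' @param kind marker kind for all records (default \code{"generic"}).
#' @return a \code{genome_map} in bp units.
#' @export
read_bed_markers <- function(path, chromosome, species = "unknown",
                             assembly_tag = NULL, kind = "generic",
                             map_id = paste0(species, "_", chromosome)) {
  sm_assert(file.exists(path), paste0("no such file: ", path), "synmapr_io_error")
  gr <- rtracklayer::import(path, format = "bed")
  seqs <- unique(as.character(GenomicRanges::seqnames(gr)))
  if (!chromosome %in% seqs)
    sm_abort(sprintf("chromosome '%s' not found; available landmarks: %s",
                     chromosome, paste(sort(seqs), collapse = ", ")),
             "synmapr_not_found")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chromosome]
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    paste0("bed_", seq_along(gr))
  mk <- markers(name = nm, start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr),
                strand = gr_strand_to_model(GenomicRanges::strand(gr)),
                kind = kind)
  genome_map(map_id, markers = mk, species = species, chromosome = chromosome,
             units = "bp", assembly_tag = assembly_tag)
}
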