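# In-silico PCR (ePCR): locate a primer pair's amplification product in
# genome sequence computationally.  Panels of primer pairs from linkage
# analyses, mapped against a sequence assembly, yield "bridge" maps joining
# genetic linkage maps to assemblies.  Matching is exact (no mismatches) on
# both strands; only pairs amplifying exactly one product anywhere in the
# assembly are kept, and hits on non-assembled fragments (scaffolds,
# contigs, unplaced sequence, recognised by name pattern) are discarded —
# the remaining unique positions form the ePCR sequence maps.

#' Read a primer panel from TSV
#'
#' Columns: \code{name, forward, reverse, min_product, max_product}.
#' Primer sequences must be over \code{A, C, G, T} (case-insensitive) and
#' \code{0 < min_product <= max_product}.
#'
#' @param path TSV file.
#' @return a \code{data.frame} of validated primer pairs.
#' @export
read_primers_tsv <- function(path) {
  sm_assert(file.exists(path), paste0("no such file: ", path), "synmapr_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(name = "character",
                                         forward = "character",
                                         reverse = "character"))
  validate_primers(df)
}

validate_primers <- function(df) {
  cols <- c("name", "forward", "reverse", "min_product", "max_product")
  sm_assert(all(cols %in% names(df)),
            paste0("primer table needs columns: ", paste(cols, collapse = ", ")))
  df$forward <- toupper(df$forward); df$reverse <- toupper(df$reverse)
  bad <- grepl("[^ACGT]", df$forward) | grepl("[^ACGT]", df$reverse)
  if (any(bad))
    sm_abort(sprintf("primer pair '%s' contains non-ACGT characters",
                     df$name[which(bad)[1]]), "synmapr_validation_error")
  badp <- !(df$min_product > 0 & df$min_product <= df$max_product)
  if (any(badp))
    sm_abort(sprintf("primer pair '%s': need 0 < min_product <= max_product",
                     df$name[which(badp)[1]]), "synmapr_validation_error")
  df[, cols]
}

# All amplicons of one primer pair on one sequence (both orientations).
# A hit is an exact match of the forward primer with the reverse primer's
# reverse-complement matching downstream on the same strand, product length
# (1-based inclusive, first base of the forward match to last base of the
# reverse-complement match) within [min_product, max_product].
epcr_hits_on_seq <- function(subject, fwd, rev, min_product, max_product) {
  hit1 <- amplicons(subject, fwd, rev, min_product, max_product)
  hit2 <- if (fwd == rev) NULL else
    amplicons(subject, rev, fwd, min_product, max_product)  # pair annealing the other way round
  out <- rbind(hit1, hit2)
  if (is.null(out)) data.frame(start = integer(), end = integer()) else
    unique(out)
}

amplicons <- function(subject, left, right, min_product, max_product) {
  starts <- Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString(left), subject))
  if (!length(starts)) return(NULL)
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(right))
  ends <- Biostrings::end(Biostrings::matchPattern(rc, subject))
  if (!length(ends)) return(NULL)
  grid <- expand.grid(start = starts, end = ends)
  len <- grid$end - grid$start + 1L
  # the reverse-complement site must lie strictly downstream of the forward
  # site (primers do not overlap), and the product length within bounds
  rc_start <- grid$end - nchar(right) + 1L
  left_end <- grid$start + nchar(left) - 1L
  grid <- grid[rc_start > left_end & len >= min_product & len <= max_product,
               , drop = FALSE]
  if (!nrow(grid)) return(NULL)
  grid
}

#' Map a primer panel against a genome by in-silico PCR
#'
#' Scans every sequence of the FASTA genome for exact amplicons of each
#' primer pair (both orientations).  Pairs with exactly one hit across the
#' whole genome, on a placed sequence, become range markers (the amplicon
#' interval, kind \code{sequence}, accession = pair name) on that
#' sequence's map.  Pairs with no hit, multiple hits, or a unique hit on a
#' sequence matching \code{unplaced_pattern} are discarded and reported
#' with the reason (\code{no_hit}, \code{multiple_hits}, \code{unplaced}).
#'
#' @param pairs primer pairs as from [read_primers_tsv()].
#' @param genome path to a FASTA file, or a named
#'   \code{Biostrings::DNAStringSet}.
#' @param species,assembly_tag labels applied to the produced maps.
#' @param unplaced_pattern regular expression flagging non-assembled
#'   fragment names (default matches \code{scaffold}, \code{contig},
#'   \code{random}, \code{Un}).
#' @return a list of class \code{epcr_result}: \code{maps} (one
#'   \code{genome_map} per placed sequence, bp units) and \code{discards}
#'   (\code{data.frame} with \code{pair, reason, hit_count}).
#' @export
epcr_map <- function(pairs, genome, species = "unknown", assembly_tag = NULL,
                     unplaced_pattern = "scaffold|contig|random|Un") {
  pairs <- validate_primers(pairs)
  seqs <- if (inherits(genome, "DNAStringSet")) genome else {
    sm_assert(file.exists(genome), paste0("no such file: ", genome),
              "synmapr_io_error")
    Biostrings::readDNAStringSet(genome)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))  # FASTA id = first word
  unplaced <- grepl(unplaced_pattern, names(seqs))

  hit_rows <- list()
  discards <- list()
  for (i in seq_len(nrow(pairs))) {
    hits <- NULL
    for (s in seq_along(seqs)) {
      h <- epcr_hits_on_seq(seqs[[s]], pairs$forward[i], pairs$reverse[i],
                            pairs$min_product[i], pairs$max_product[i])
      if (nrow(h)) {
        h$seq <- names(seqs)[s]
        hits <- rbind(hits, h)
      }
    }
    n <- if (is.null(hits)) 0L else nrow(hits)
    if (n == 0L)
      discards[[length(discards) + 1L]] <-
        data.frame(pair = pairs$name[i], reason = "no_hit", hit_count = 0L)
    else if (n >= 2L)
      discards[[length(discards) + 1L]] <-
        data.frame(pair = pairs$name[i], reason = "multiple_hits", hit_count = n)
    else if (unplaced[match(hits$seq, names(seqs))])
      discards[[length(discards) + 1L]] <-
        data.frame(pair = pairs$name[i], reason = "unplaced", hit_count = 1L)
    else {
      hits$pair <- pairs$name[i]
      hit_rows[[length(hit_rows) + 1L]] <- hits
    }
  }
  kept <- if (length(hit_rows)) do.call(rbind, hit_rows) else NULL
  maps <- list()
  for (s in names(seqs)[!unplaced]) {
    sh <- if (is.null(kept)) NULL else kept[kept$seq == s, , drop = FALSE]
    mk <- if (is.null(sh) || !nrow(sh)) empty_markers() else
      markers(name = sh$pair, start = sh$start, end = sh$end,
              strand = "unstranded", kind = "sequence", accession = sh$pair)
    maps[[s]] <- genome_map(paste0("epcr_", s), markers = mk, species = species,
                            chromosome = s, units = "bp",
                            title = paste0("ePCR map of ", s),
                            extent = c(1, length(seqs[[s]])),
                            assembly_tag = assembly_tag)
  }
  discards <- if (length(discards)) do.call(rbind, discards) else
    data.frame(pair = character(), reason = character(), hit_count = integer())
  structure(list(maps = maps, discards = discards), class = "epcr_result")
}

#' Write an ePCR discard report as TSV
#'
#' @param result an \code{epcr_result}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_discard_tsv <- function(result, path) {
  sm_assert(inherits(result, "epcr_result"), "not an epcr_result")
  utils::write.table(result$discards, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
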