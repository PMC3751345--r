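# Homology tables: asserted orthology/paralogy between gene pairs across
# species, consumed from precomputed Compara-style exports, never computed
# from sequence here.

#' Construct a homology table
#'
#' A symmetric lookup of gene-pair homology records.  A record is unordered:
#' \code{(gene_a, gene_b)} and \code{(gene_b, gene_a)} denote the same
#' record, and [lookup_gene()] finds a record regardless of which column
#' carries the queried accession.  Percent amino-acid identity/similarity
#' scores are optional (\code{NA} = absent) and, when both present, must
#' satisfy \code{perc_similarity >= perc_identity}.
#'
#' @param records \code{data.frame} with columns \code{gene_a, species_a,
#'   gene_b, species_b, homology_type, perc_identity, perc_similarity}.
#' @return an object of class \code{homology_table}.
#' @export
homology_table <- function(records = NULL) {
  cols <- c("gene_a", "species_a", "gene_b", "species_b", "homology_type",
            "perc_identity", "perc_similarity")
  if (is.null(records))
    records <- data.frame(gene_a = character(), species_a = character(),
                          gene_b = character(), species_b = character(),
                          homology_type = character(),
                          perc_identity = numeric(), perc_similarity = numeric(),
                          stringsAsFactors = FALSE)
  sm_assert(all(cols %in% names(records)),
            paste0("homology records need columns: ", paste(cols, collapse = ", ")))
  records <- records[, cols, drop = FALSE]
  records$perc_identity <- as.numeric(records$perc_identity)
  records$perc_similarity <- as.numeric(records$perc_similarity)
  bad_type <- !records$homology_type %in% HOMOLOGY_TYPES
  if (any(bad_type))
    sm_abort(sprintf("unknown homology_type '%s'",
                     records$homology_type[which(bad_type)[1]]),
             "synmapr_validation_error")
  both <- !is.na(records$perc_identity) & !is.na(records$perc_similarity)
  bad_score <- both & records$perc_similarity < records$perc_identity
  if (any(bad_score))
    sm_abort(sprintf("record %d: perc_similarity < perc_identity",
                     which(bad_score)[1]),
             "synmapr_validation_error")
  rownames(records) <- NULL
  structure(list(records = records), class = "homology_table")
}

#' @export
print.homology_table <- function(x, ...) {
  cat(sprintf("<homology_table> %d records, %d genes\n", nrow(x$records),
              length(unique(c(x$records$gene_a, x$records$gene_b)))))
  invisible(x)
}

#' Look up every homology record mentioning a gene
#'
#' Symmetric: the queried accession may sit in either column.  Matched
#' records are returned normalised so that \code{gene_a} is the queried
#' gene (columns swapped where needed), which simplifies downstream joins.
#'
#' @param table a \code{homology_table}.
#' @param accession gene stable identifier.
#' @return a record \code{data.frame} (possibly empty) with \code{gene_a ==
#'   accession} on every row.
#' @export
lookup_gene <- function(table, accession) {
  sm_assert(inherits(table, "homology_table"), "not a homology_table")
  r <- table$records
  ia <- r$gene_a == accession
  ib <- r$gene_b == accession & !ia
  out_a <- r[ia, , drop = FALSE]
  out_b <- r[ib, , drop = FALSE]
  if (nrow(out_b)) {
    out_b <- data.frame(gene_a = out_b$gene_b, species_a = out_b$species_b,
                        gene_b = out_b$gene_a, species_b = out_b$species_a,
                        homology_type = out_b$homology_type,
                        perc_identity = out_b$perc_identity,
                        perc_similarity = out_b$perc_similarity,
                        stringsAsFactors = FALSE)
  }
  out <- rbind(out_a, out_b)
  rownames(out) <- NULL
  out
}

#' Read a homology table from TSV
#'
#' The file must carry a header row naming the seven fixed columns
#' \code{gene_a, species_a, gene_b, species_b, homology_type,
#' perc_identity, perc_similarity} (mirroring Compara homology exports).
#' Percent columns may be empty.  A row with \code{perc_similarity <
#' perc_identity} or an unknown homology type is a validation error naming
#' the row.
#'
#' @param path TSV file.
#' @return a \code{homology_table}.
#' @export
read_homology_tsv <- function(path) {
  sm_assert(file.exists(path), paste0("no such file: ", path), "synmapr_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(gene_a = "character",
                                         species_a = "character",
                                         gene_b = "character",
                                         species_b = "character",
                                         homology_type = "character"),
                          na.strings = c("", "NA"))
  tryCatch(homology_table(df), synmapr_validation_error = function(e)
    sm_abort(sprintf("%s: %s", path, conditionMessage(e)),
             "synmapr_validation_error"))
}

#' Write a homology table to TSV
#'
#' @param table a \code{homology_table}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_homology_tsv <- function(table, path) {
  sm_assert(inherits(table, "homology_table"), "not a homology_table")
  r <- table$records
  r$perc_identity <- ifelse(is.na(r$perc_identity), "", fmt_num(r$perc_identity))
  r$perc_similarity <- ifelse(is.na(r$perc_similarity), "", fmt_num(r$perc_similarity))
  utils::write.table(r, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
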