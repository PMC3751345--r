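# Typed inter-map marker relationships.
#
# Links are kept in a flat data.frame (one row per link) with the endpoint
# maps, endpoint marker names, the relationship type and optional percent
# identity/similarity scores.  Marker endpoints are referenced by row index
# into the canonical marker table plus name, so renderers can recover
# coordinates without ambiguity when names repeat.

#' Construct a link table
#'
#' Links are plain \code{data.frame}s, one row per typed inter-map edge.
#' \code{idx_a}/\code{idx_b} are row indices into the canonical marker
#' tables of the endpoint maps (names alone can repeat).
#'
#' @param map_a,map_b endpoint map ids.
#' @param marker_a,marker_b endpoint marker names.
#' @param idx_a,idx_b endpoint marker row indices.
#' @param link_type one of the link-type vocabulary.
#' @param perc_identity,perc_similarity optional scores (NA = absent).
#' @return a link \code{data.frame}.
#' @export
link_frame <- function(map_a = character(), marker_a = character(),
                       idx_a = integer(), map_b = character(),
                       marker_b = character(), idx_b = integer(),
                       link_type = character(),
                       perc_identity = numeric(), perc_similarity = numeric()) {
  data.frame(map_a = map_a, marker_a = marker_a, idx_a = as.integer(idx_a),
             map_b = map_b, marker_b = marker_b, idx_b = as.integer(idx_b),
             link_type = link_type,
             perc_identity = as.numeric(perc_identity),
             perc_similarity = as.numeric(perc_similarity),
             stringsAsFactors = FALSE)
}

#' @rdname link_frame
#' @export
empty_links <- function() link_frame()

order_links <- function(links) {
  links <- links[order(links$link_type, links$marker_a, links$marker_b,
                       links$idx_a, links$idx_b, method = "radix"), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Identity links: markers sharing a database accession
#'
#' One link of type \code{identity} per marker pair (one marker from each
#' map) carrying the same non-absent accession.  Matching is exact and
#' case-sensitive (accessions are case-significant); markers without an
#' accession never match.  All pairs are reported when an accession repeats
#' on a map.
#'
#' @param a,b distinct \code{genome_map}s.
#' @return a link \code{data.frame}.
#' @export
identity_links <- function(a, b) {
  sm_assert(is_genome_map(a) && is_genome_map(b) && a$map_id != b$map_id,
            "identity_links needs two distinct maps")
  ma <- a$markers; mb <- b$markers
  ia <- which(!is.na(ma$accession))
  ib <- which(!is.na(mb$accession))
  if (!length(ia) || !length(ib)) return(empty_links())
  hits <- merge(data.frame(idx_a = ia, key = ma$accession[ia]),
                data.frame(idx_b = ib, key = mb$accession[ib]))
  if (!nrow(hits)) return(empty_links())
  order_links(link_frame(map_a = a$map_id, marker_a = ma$name[hits$idx_a],
                         idx_a = hits$idx_a, map_b = b$map_id,
                         marker_b = mb$name[hits$idx_b], idx_b = hits$idx_b,
                         link_type = "identity",
                         perc_identity = NA_real_, perc_similarity = NA_real_))
}

#' Synonymy links: markers sharing a name
#'
#' One link of type \code{synonymy} per marker pair with exactly equal
#' (case-sensitive) names, excluding pairs already related by identity:
#' sharing an accession is stronger evidence than sharing a name, so the
#' identity link takes precedence and the pair is not double-reported.
#'
#' @param a,b distinct \code{genome_map}s.
#' @return a link \code{data.frame}.
#' @export
synonymy_links <- function(a, b) {
  sm_assert(is_genome_map(a) && is_genome_map(b) && a$map_id != b$map_id,
            "synonymy_links needs two distinct maps")
  ma <- a$markers; mb <- b$markers
  if (!nrow(ma) || !nrow(mb)) return(empty_links())
  hits <- merge(data.frame(idx_a = seq_len(nrow(ma)), key = ma$name),
                data.frame(idx_b = seq_len(nrow(mb)), key = mb$name))
  if (!nrow(hits)) return(empty_links())
  ident <- !is.na(ma$accession[hits$idx_a]) & !is.na(mb$accession[hits$idx_b]) &
    ma$accession[hits$idx_a] == mb$accession[hits$idx_b]
  hits <- hits[!ident, , drop = FALSE]
  if (!nrow(hits)) return(empty_links())
  order_links(link_frame(map_a = a$map_id, marker_a = ma$name[hits$idx_a],
                         idx_a = hits$idx_a, map_b = b$map_id,
                         marker_b = mb$name[hits$idx_b], idx_b = hits$idx_b,
                         link_type = "synonymy",
                         perc_identity = NA_real_, perc_similarity = NA_real_))
}

#' Homology links: marker pairs asserted homologous in a table
#'
#' One link per homology record whose two gene accessions occur on the two
#' maps respectively (either orientation).  The link carries the record's
#' homology type and percent identity/similarity scores.  Records joining
#' two genes on the same map yield nothing (links are inter-map);
#' markers without an accession never match.
#'
#' @param a,b distinct \code{genome_map}s.
#' @param table a \code{homology_table}.
#' @return a link \code{data.frame}.
#' @export
homology_links <- function(a, b, table) {
  sm_assert(is_genome_map(a) && is_genome_map(b) && a$map_id != b$map_id,
            "homology_links needs two distinct maps")
  sm_assert(inherits(table, "homology_table"), "not a homology_table")
  ma <- a$markers; mb <- b$markers
  r <- table$records
  if (!nrow(r)) return(empty_links())
  acc_a <- data.frame(idx_a = which(!is.na(ma$accession)))
  acc_a$key <- ma$accession[acc_a$idx_a]
  acc_b <- data.frame(idx_b = which(!is.na(mb$accession)))
  acc_b$key <- mb$accession[acc_b$idx_b]
  if (!nrow(acc_a) || !nrow(acc_b)) return(empty_links())
  join_dir <- function(ga, gb) {
    rec <- data.frame(rec = seq_len(nrow(r)), key = ga)
    h1 <- merge(rec, acc_a)              # gene in column ga found on map a
    if (!nrow(h1)) return(NULL)
    h1$key <- gb[h1$rec]
    h2 <- merge(h1, acc_b)               # partner gene found on map b
    if (!nrow(h2)) return(NULL)
    h2
  }
  hits <- rbind(join_dir(r$gene_a, r$gene_b), join_dir(r$gene_b, r$gene_a))
  if (is.null(hits) || !nrow(hits)) return(empty_links())
  # A self-record (gene_a == gene_b) would be picked up by both directions;
  # keep unique (record, endpoints) combinations.
  hits <- hits[!duplicated(hits[, c("rec", "idx_a", "idx_b")]), , drop = FALSE]
  order_links(link_frame(map_a = a$map_id, marker_a = ma$name[hits$idx_a],
                         idx_a = hits$idx_a, map_b = b$map_id,
                         marker_b = mb$name[hits$idx_b], idx_b = hits$idx_b,
                         link_type = r$homology_type[hits$rec],
                         perc_identity = r$perc_identity[hits$rec],
                         perc_similarity = r$perc_similarity[hits$rec]))
}

#' Discover all links between two maps
#'
#' Convenience wrapper running identity, synonymy and (when a table is
#' supplied) homology link discovery.
#'
#' @param a,b distinct \code{genome_map}s.
#' @param table optional \code{homology_table}.
#' @return a link \code{data.frame}.
#' @export
all_links <- function(a, b, table = NULL) {
  out <- rbind(identity_links(a, b), synonymy_links(a, b),
               if (!is.null(table)) homology_links(a, b, table) else empty_links())
  order_links(out)
}

#' Filter homology links by score thresholds
#'
#' Raises reporting stringency: a homology link is retained iff its percent
#' identity/similarity scores meet every active threshold; a link lacking a
#' score fails any threshold applied to that score (conservative).
#' Identity and synonymy links are never score-filtered and pass through
#' unconditionally.
#'
#' @param links a link \code{data.frame}.
#' @param min_identity,min_similarity thresholds in \code{[0, 100]}, or
#'   \code{NULL} (absent) to leave that score unconstrained.
#' @return the filtered link \code{data.frame}.
#' @export
filter_links <- function(links, min_identity = NULL, min_similarity = NULL) {
  chk <- function(t, nm) {
    if (!is.null(t) && (!is_num(t) || t < 0 || t > 100))
      sm_abort(sprintf("%s must be in [0, 100]", nm), "synmapr_range_error")
  }
  chk(min_identity, "min_identity"); chk(min_similarity, "min_similarity")
  if (!nrow(links)) return(links)
  hom <- links$link_type %in% HOMOLOGY_TYPES
  keep <- rep(TRUE, nrow(links))
  if (!is.null(min_identity))
    keep <- keep & (!hom | (!is.na(links$perc_identity) &
                              links$perc_identity >= min_identity))
  if (!is.null(min_similarity))
    keep <- keep & (!hom | (!is.na(links$perc_similarity) &
                              links$perc_similarity >= min_similarity))
  out <- links[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Okabe-Ito colour-universal-design palette, resolvable by colour-blind
# readers; identity reuses the reddish-purple slot.
DEFAULT_PALETTE <- c(identity = "#CC79A7",                  # purple
                     synonymy = "#56B4E9",                  # sky-blue
                     ortholog_one2one = "#000000",          # black
                     apparent_ortholog_one2one = "#D55E00", # vermilion
                     ortholog_one2many = "#E69F00",         # orange
                     ortholog_many2many = "#009E73",        # blue-green
                     possible_ortholog = "#0072B2",         # blue
                     paralog = "#F0E442")                   # yellow

#' Colour for a link type
#'
#' The default palette maps each relationship type to a distinct
#' colour-universal-design (Okabe-Ito) colour: identity purple, synonymy
#' sky-blue, one-to-one orthology black, apparent one-to-one orthology
#' vermilion, one-to-many orthology orange, many-to-many orthology
#' blue-green, possible orthology blue, paralogy yellow.
#'
#' @param link_type one of the link-type vocabulary.
#' @param palette named colour vector overriding defaults per type.
#' @return a hex colour string.
#' @export
link_color <- function(link_type, palette = NULL) {
  sm_assert(is_string(link_type) && link_type %in% LINK_TYPES,
            sprintf("unknown link type '%s'", link_type))
  if (!is.null(palette) && link_type %in% names(palette))
    return(unname(palette[[link_type]]))
  unname(DEFAULT_PALETTE[[link_type]])
}

#' Write links as TSV
#'
#' Columns: \code{map_a, marker_a, map_b, marker_b, type, perc_identity,
#' perc_similarity}; deterministic ordering.
#'
#' @param links a link \code{data.frame}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_links_tsv <- function(links, path) {
  links <- order_links(links)
  out <- data.frame(map_a = links$map_a, marker_a = links$marker_a,
                    map_b = links$map_b, marker_b = links$marker_b,
                    type = links$link_type,
                    perc_identity = ifelse(is.na(links$perc_identity), "",
                                           fmt_num(links$perc_identity)),
                    perc_similarity = ifelse(is.na(links$perc_similarity), "",
                                             fmt_num(links$perc_similarity)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
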