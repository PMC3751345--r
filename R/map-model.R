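#' Construct a marker table
#'
#' Markers are stored as a plain \code{data.frame} with one row per marker.
#' A point marker has \code{start == end}; a range marker spans
#' \code{[start, end]} inclusively in the units of its map.  Strand and kind
#' use the fixed vocabularies of the model (\code{forward}/\code{reverse}/
#' \code{unstranded}; \code{gene}, \code{variant}, \code{microsatellite},
#' \code{sequence}, \code{assembly_exception}, \code{generic}).
#'
#' @param name character vector of non-empty marker names.
#' @param start,end numeric positions in map units; \code{end} defaults to
#'   \code{start} (point markers).  Rows with \code{start > end} are invalid.
#' @param strand character, recycled; one of the strand vocabulary.
#' @param kind character, recycled; one of the marker-kind vocabulary.
#' @param accession optional stable identifiers (\code{NA} = absent).
#' @param description optional free-text descriptions.
#' @return a \code{data.frame} with columns \code{name, accession, start,
#'   end, strand, kind, description}, canonically ordered by
#'   \code{(start, end, name)}.
#' @export
markers <- function(name = character(), start = numeric(), end = start,
                    strand = "unstranded", kind = "generic",
                    accession = NA_character_,
                    description = NA_character_) {
  n <- length(name)
  df <- data.frame(name = as.character(name),
                   accession = rep_len(as.character(accession), n),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   kind = rep_len(as.character(kind), n),
                   description = rep_len(as.character(description), n),
                   stringsAsFactors = FALSE)
  canonicalise_markers(df)
}

# Canonical (start, end, name) ordering makes writers deterministic and
# outputs diffable.
canonicalise_markers <- function(df) {
  df <- df[order(df$start, df$end, df$name, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_markers <- function() markers()

#' Construct a genome map
#'
#' A \code{genome_map} is a self-contained one-dimensional coordinate system
#' for a single chromosome or linkage group of one species, holding an
#' ordered collection of markers.  Each map is free to use its own units
#' (\code{bp}, \code{cM} or \code{arbitrary}), so physical assemblies,
#' genetic linkage maps and ad hoc marker lists share one representation.
#'
#' @param map_id unique string identifying the map within a session/canvas.
#' @param markers a marker \code{data.frame} as built by [markers()].
#' @param species,chromosome,title descriptive strings; \code{title}
#'   defaults to \code{map_id}.
#' @param units one of \code{"bp"}, \code{"cM"}, \code{"arbitrary"}.
#' @param extent numeric length-2 \code{c(min, max)} coordinate extent;
#'   defaults to the span of the markers.
#' @param assembly_tag optional build/release label (e.g. \code{"asmV1"});
#'   maps sharing units and tag are considered co-assembled.
#' @return an object of class \code{genome_map}.
#' @export
genome_map <- function(map_id, markers = empty_markers(), species = "unknown",
                       chromosome = "unknown", units = "bp",
                       title = map_id, extent = NULL, assembly_tag = NULL) {
  sm_assert(is_string(map_id) && nzchar(map_id), "map_id must be a non-empty string")
  sm_assert(is_string(units) && units %in% MAP_UNITS,
            sprintf("units must be one of %s", paste(MAP_UNITS, collapse = ", ")))
  if (is.null(extent)) {
    sm_assert(nrow(markers) > 0L,
              "a map with no markers needs an explicit extent",
              "synmapr_empty_map")
    extent <- c(min(markers$start), max(markers$end))
  }
  sm_assert(is.numeric(extent) && length(extent) == 2L && all(is.finite(extent)),
            "extent must be numeric c(min, max)")
  if (extent[1] == extent[2]) extent[2] <- extent[1] + 1  # degenerate single-point map
  sm_assert(extent[1] < extent[2], "extent_min must be < extent_max")
  m <- structure(list(map_id = map_id,
                      title = title,
                      species = species,
                      chromosome = chromosome,
                      units = units,
                      assembly_tag = if (is.null(assembly_tag) || is.na(assembly_tag)) NA_character_ else as.character(assembly_tag),
                      extent_min = as.numeric(extent[1]),
                      extent_max = as.numeric(extent[2]),
                      markers = canonicalise_markers(markers)),
                 class = "genome_map")
  viol <- validate_map(m)
  sm_assert(length(viol) == 0L,
            paste0("invalid map '", map_id, "': ", paste(viol, collapse = "; ")))
  m
}

#' @export
print.genome_map <- function(x, ...) {
  cat(sprintf("<genome_map> %s  (%s %s, %s)\n", x$map_id, x$species,
              x$chromosome, x$units))
  cat(sprintf("  extent [%s, %s]%s; %d markers\n",
              fmt_num(x$extent_min), fmt_num(x$extent_max),
              if (!is.na(x$assembly_tag)) paste0(" assembly ", x$assembly_tag) else "",
              nrow(x$markers)))
  invisible(x)
}

is_genome_map <- function(x) inherits(x, "genome_map")

#' Validate a genome map against the model invariants
#'
#' Diagnostic: returns a character vector of human-readable violation
#' descriptions (empty when the map is well formed).  Checked rules:
#' marker \code{start <= end}, markers within the map extent, non-empty
#' names, non-empty accessions when present, valid strand/kind vocabulary,
#' and \code{extent_min < extent_max}.
#'
#' @param map a \code{genome_map} (or a structurally similar list).
#' @return character vector of violations, possibly empty.
#' @export
validate_map <- function(map) {
  v <- character()
  if (!(is_num(map$extent_min) && is_num(map$extent_max) &&
        map$extent_min < map$extent_max))
    v <- c(v, "extent_min must be < extent_max")
  mk <- map$markers
  if (is.null(mk) || nrow(mk) == 0L) return(v)
  bad <- function(which, rule)
    if (any(which)) sprintf("marker '%s': %s", mk$name[which], rule) else character()
  noname <- is.na(mk$name) | !nzchar(mk$name)
  if (any(noname)) v <- c(v, sprintf("marker #%d: empty name", which(noname)))
  swapped <- is.na(mk$start) | is.na(mk$end) | mk$start > mk$end
  v <- c(v, bad(swapped, "start must be <= end"))
  # a marker must intersect the extent; full containment is NOT required,
  # because zooming retains markers that straddle the region boundary with
  # their original coordinates (the renderer clips visually)
  if (is_num(map$extent_min))
    v <- c(v, bad(!swapped & (mk$end < map$extent_min | mk$start > map$extent_max),
                  "marker lies outside the map extent"))
  v <- c(v, bad(!is.na(mk$accession) & !nzchar(mk$accession),
                "accession, when present, must be non-empty"))
  v <- c(v, bad(!mk$strand %in% STRANDS, "invalid strand"))
  v <- c(v, bad(!mk$kind %in% MARKER_KINDS, "invalid kind"))
  v
}

#' Reference a sub-interval of a map
#'
#' @param map_id id of the referenced map.
#' @param start,end interval bounds in map units, \code{start < end}.
#' @return an object of class \code{map_region}.
#' @export
map_region <- function(map_id, start, end) {
  sm_assert(is_string(map_id), "map_id must be a string")
  sm_assert(is_num(start) && is_num(end) && start < end,
            "region start must be < end", "synmapr_range_error")
  structure(list(map_id = map_id, start = as.numeric(start),
                 end = as.numeric(end)), class = "map_region")
}

#' Zoom/project a region of a map into a new map
#'
#' Returns a new self-contained map whose extent is the selected region and
#' which contains exactly those source markers whose interval intersects the
#' region.  Coordinates are unchanged (same coordinate system), so markers
#' partially overlapping the region keep their full ranges; the renderer
#' clips visually.  The source map is not modified.
#'
#' @param map source \code{genome_map}.
#' @param region a [map_region()] on \code{map} (the \code{map_id}s must
#'   agree), lying within the map extent.
#' @param new_id map_id for the derived map.
#' @return a new \code{genome_map} with extent \code{[region$start,
#'   region$end]}.
#' @export
subregion <- function(map, region, new_id) {
  sm_assert(is_genome_map(map), "map must be a genome_map")
  sm_assert(inherits(region, "map_region") && region$map_id == map$map_id,
            "region must reference the given map")
  if (region$start < map$extent_min || region$end > map$extent_max)
    sm_abort(sprintf("region [%s, %s] outside map extent [%s, %s]",
                     fmt_num(region$start), fmt_num(region$end),
                     fmt_num(map$extent_min), fmt_num(map$extent_max)),
             "synmapr_range_error")
  mk <- map$markers
  keep <- mk$end >= region$start & mk$start <= region$end
  genome_map(new_id, markers = mk[keep, , drop = FALSE],
             species = map$species, chromosome = map$chromosome,
             units = map$units, title = map$title,
             extent = c(region$start, region$end),
             assembly_tag = map$assembly_tag)
}

#' Reverse the orientation of a map
#'
#' Reflects every marker about the extent midpoint
#' (\code{c -> extent_min + extent_max - c}, endpoints swapped so that
#' \code{start <= end} still holds) and flips strands
#' (\code{forward <-> reverse}; \code{unstranded} unchanged).  The extent is
#' unchanged and \code{reorient(reorient(m))} reproduces \code{m}.
#'
#' @param map a \code{genome_map}.
#' @return the reoriented \code{genome_map}.
#' @export
reorient <- function(map) {
  sm_assert(is_genome_map(map), "map must be a genome_map")
  mk <- map$markers
  s <- map$extent_min + map$extent_max
  new_start <- s - mk$end
  new_end <- s - mk$start
  mk$start <- new_start
  mk$end <- new_end
  mk$strand <- ifelse(mk$strand == "forward", "reverse",
                      ifelse(mk$strand == "reverse", "forward", "unstranded"))
  out <- map
  out$markers <- canonicalise_markers(mk)
  out
}

#' Test two maps for equality of content
#'
#' Field-by-field comparison of metadata, extent and the full marker table
#' (used by the round-trip tests of the I/O layer).
#'
#' @param a,b \code{genome_map} objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
maps_equal <- function(a, b) {
  meta <- c("map_id", "title", "species", "chromosome", "units")
  for (f in meta) if (!identical(a[[f]], b[[f]])) return(FALSE)
  if (!identical(is.na(a$assembly_tag), is.na(b$assembly_tag))) return(FALSE)
  if (!is.na(a$assembly_tag) && a$assembly_tag != b$assembly_tag) return(FALSE)
  if (a$extent_min != b$extent_min || a$extent_max != b$extent_max) return(FALSE)
  ma <- a$markers; mb <- b$markers
  if (nrow(ma) != nrow(mb)) return(FALSE)
  if (nrow(ma) == 0L) return(TRUE)
  same_chr <- function(x, y) all(ifelse(is.na(x), is.na(y), !is.na(y) & x == y))
  all(ma$start == mb$start) && all(ma$end == mb$end) &&
    all(ma$name == mb$name) && same_chr(ma$accession, mb$accession) &&
    all(ma$strand == mb$strand) && all(ma$kind == mb$kind) &&
    same_chr(ma$description, mb$description)
}
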