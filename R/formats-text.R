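# Plain-text map dialect
#
# Maps in their most basic form are simple lists of mappable objects on an
# arbitrary coordinate system, so the text dialect is a whitespace/tab
# separated table with "#"-prefixed header lines for map metadata:
#
#   #map <chromosome> <species> <units>
#   #id <map_id>                  (optional; default "<species>_<chromosome>")
#   #title <free text>            (optional)
#   #extent <min> <max>           (optional; default marker span)
#   #assembly <tag>               (optional)
#   name start [end] [strand] [kind] [accession] [description...]
#
# `end` is recognised by being numeric; a missing end makes a point marker.
# `strand` is one of "+", "-", "."; `kind` one of the marker-kind
# vocabulary; any remaining tokens join into the description.

strand_from_symbol <- function(s)
  c("+" = "forward", "-" = "reverse", "." = "unstranded")[[s]]

strand_to_symbol <- function(s)
  c(forward = "+", reverse = "-", unstranded = ".")[[s]]

parse_err <- function(path, lineno, msg)
  sm_abort(sprintf("%s:%d: %s", path, lineno, msg), "synmapr_parse_error")

is_numeric_token <- function(tok) !is.na(suppressWarnings(as.numeric(tok)))

#' Read a map from the plain-text dialect
#'
#' See the package vignette for the dialect grammar.  The extent defaults to
#' \code{[min start, max end]} of the markers when no \code{#extent} header
#' is given; a file with neither markers nor an extent header is an error.
#'
#' @param path file to read.
#' @return a validated \code{genome_map}.
#' @export
read_map_text <- function(path) {
  sm_assert(file.exists(path), paste0("no such file: ", path), "synmapr_io_error")
  lines <- readLines(path, warn = FALSE)
  meta <- list(chromosome = "unknown", species = "unknown", units = "arbitrary",
               map_id = NULL, title = NULL, extent = NULL, assembly = NULL)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      toks <- strsplit(sub("^#", "", ln), "[ \t]+")[[1]]
      key <- toks[1]
      val <- toks[-1]
      if (key == "map") {
        if (length(val) < 3) parse_err(path, i, "'#map' needs chromosome, species, units")
        if (!val[3] %in% MAP_UNITS)
          parse_err(path, i, sprintf("unknown units '%s'", val[3]))
        meta$chromosome <- val[1]; meta$species <- val[2]; meta$units <- val[3]
      } else if (key == "id") meta$map_id <- val[1]
      else if (key == "title") meta$title <- paste(val, collapse = " ")
      else if (key == "assembly") meta$assembly <- val[1]
      else if (key == "extent") {
        if (length(val) < 2 || !all(vapply(val[1:2], is_numeric_token, logical(1))))
          parse_err(path, i, "'#extent' needs two numbers")
        meta$extent <- as.numeric(val[1:2])
      }
      next
    }
    toks <- strsplit(ln, "[ \t]+")[[1]]
    if (length(toks) < 2) parse_err(path, i, "marker row needs at least name and start")
    if (!is_numeric_token(toks[2]))
      parse_err(path, i, sprintf("start '%s' is not numeric", toks[2]))
    row <- list(name = toks[1], start = as.numeric(toks[2]), end = NA_real_,
                strand = "unstranded", kind = "generic",
                accession = NA_character_, description = NA_character_)
    rest <- toks[-(1:2)]
    if (length(rest) && is_numeric_token(rest[1])) {
      row$end <- as.numeric(rest[1]); rest <- rest[-1]
    } else row$end <- row$start
    if (length(rest) && rest[1] %in% c("+", "-", ".")) {
      row$strand <- strand_from_symbol(rest[1]); rest <- rest[-1]
    }
    if (length(rest) && rest[1] %in% MARKER_KINDS) {
      row$kind <- rest[1]; rest <- rest[-1]
    }
    if (length(rest)) {  # "." denotes an absent accession (placeholder column)
      row$accession <- if (rest[1] == ".") NA_character_ else rest[1]
      rest <- rest[-1]
    }
    if (length(rest)) row$description <- paste(rest, collapse = " ")
    if (row$start > row$end)
      parse_err(path, i, sprintf("marker '%s' has start > end", row$name))
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L && is.null(meta$extent))
    sm_abort(sprintf("%s: no markers and no #extent header", path),
             "synmapr_empty_map")
  mk <- if (length(rows) == 0L) empty_markers() else
    canonicalise_markers(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
  map_id <- meta$map_id %||% paste0(meta$species, "_", meta$chromosome)
  genome_map(map_id, markers = mk, species = meta$species,
             chromosome = meta$chromosome, units = meta$units,
             title = meta$title %||% map_id, extent = meta$extent,
             assembly_tag = meta$assembly)
}

#' Write a map in the plain-text dialect
#'
#' Deterministic: identical maps produce byte-identical files (markers are
#' canonically ordered, numbers formatted with a fixed rule).
#'
#' @param map a \code{genome_map}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_map_text <- function(map, path) {
  sm_assert(is_genome_map(map), "map must be a genome_map")
  out <- c(sprintf("#map %s %s %s", map$chromosome, map$species, map$units),
           sprintf("#id %s", map$map_id),
           sprintf("#title %s", map$title),
           sprintf("#extent %s %s", fmt_num(map$extent_min), fmt_num(map$extent_max)))
  if (!is.na(map$assembly_tag))
    out <- c(out, sprintf("#assembly %s", map$assembly_tag))
  mk <- map$markers
  for (i in seq_len(nrow(mk))) {
    fields <- c(mk$name[i], fmt_num(mk$start[i]), fmt_num(mk$end[i]),
                strand_to_symbol(mk$strand[i]), mk$kind[i],
                if (!is.na(mk$accession[i])) mk$accession[i]
                else if (!is.na(mk$description[i])) "." else NULL,
                if (!is.na(mk$description[i])) mk$description[i] else NULL)
    out <- c(out, paste(fields, collapse = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}
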