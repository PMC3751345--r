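# Map-interchange XML dialect ("GMD-like").
#
# The authentic GenomicMappingData schema is not public in printable form,
# so the package defines a minimal compatible dialect playing the same role
# (nested species -> map -> marker), documented here and in the vignette:
#
#   <mapset>
#     <species name="...">
#       <map id="..." title="..." units="bp|cM|arbitrary" chromosome="..."
#            extent_min="..." extent_max="..." [assembly="..."]>
#         <marker name="..." start="..." end="..." strand="forward|reverse|unstranded"
#                 kind="..." [accession="..."] [description="..."]/>
#       </map>
#     </species>
#   </mapset>

schema_err <- function(msg) sm_abort(msg, "synmapr_schema_error")

req_attr <- function(node, attr, what) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) schema_err(sprintf("<%s> element missing required attribute '%s' (%s)",
                                   xml2::xml_name(node), attr, what))
  v
}

#' Read maps from the XML interchange dialect
#'
#' @param path XML file.
#' @return a list of \code{genome_map} objects, in document order.
#' @export
read_map_xml <- function(path) {
  sm_assert(file.exists(path), paste0("no such file: ", path), "synmapr_io_error")
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "mapset")
    schema_err(sprintf("root element must be <mapset>, found <%s>", xml2::xml_name(doc)))
  maps <- list()
  for (sp in xml2::xml_find_all(doc, "./species")) {
    species <- req_attr(sp, "name", "species name")
    for (mapel in xml2::xml_find_all(sp, "./map")) {
      map_id <- req_attr(mapel, "id", "map id")
      units <- req_attr(mapel, "units", "map units")
      if (!units %in% MAP_UNITS)
        schema_err(sprintf("<map id='%s'> has unknown units '%s'", map_id, units))
      mnodes <- xml2::xml_find_all(mapel, "./marker")
      rows <- lapply(mnodes, function(mn) {
        strand <- xml2::xml_attr(mn, "strand")
        if (is.na(strand)) strand <- "unstranded"
        if (!strand %in% STRANDS)
          schema_err(sprintf("<marker> in map '%s' has unknown strand '%s'", map_id, strand))
        kind <- xml2::xml_attr(mn, "kind")
        if (is.na(kind)) kind <- "generic"
        if (!kind %in% MARKER_KINDS)
          schema_err(sprintf("<marker> in map '%s' has unknown kind '%s'", map_id, kind))
        data.frame(name = req_attr(mn, "name", paste0("marker in map ", map_id)),
                   accession = xml2::xml_attr(mn, "accession"),
                   start = as.numeric(req_attr(mn, "start", "marker start")),
                   end = as.numeric(req_attr(mn, "end", "marker end")),
                   strand = strand, kind = kind,
                   description = xml2::xml_attr(mn, "description"),
                   stringsAsFactors = FALSE)
      })
      mk <- if (length(rows)) do.call(rbind, rows) else empty_markers()
      asm <- xml2::xml_attr(mapel, "assembly")
      maps[[length(maps) + 1L]] <-
        genome_map(map_id, markers = mk, species = species,
                   chromosome = xml2::xml_attr(mapel, "chromosome") %|na|% "unknown",
                   units = units,
                   title = xml2::xml_attr(mapel, "title") %|na|% map_id,
                   extent = as.numeric(c(req_attr(mapel, "extent_min", "map extent"),
                                         req_attr(mapel, "extent_max", "map extent"))),
                   assembly_tag = if (is.na(asm)) NULL else asm)
    }
  }
  maps
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

#' Write maps to the XML interchange dialect
#'
#' Maps are grouped by species; output is deterministic (document order
#' follows the input list; markers are canonically ordered).
#'
#' @param maps a \code{genome_map} or list of them.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_map_xml <- function(maps, path) {
  if (is_genome_map(maps)) maps <- list(maps)
  sm_assert(all(vapply(maps, is_genome_map, logical(1))),
            "maps must be genome_map objects")
  doc <- xml2::xml_new_root("mapset")
  species_nodes <- list()
  for (map in maps) {
    sp <- species_nodes[[map$species]]
    if (is.null(sp)) {
      sp <- xml2::xml_add_child(doc, "species", name = map$species)
      species_nodes[[map$species]] <- sp
    }
    attrs <- list(id = map$map_id, title = map$title, units = map$units,
                  chromosome = map$chromosome,
                  extent_min = fmt_num(map$extent_min),
                  extent_max = fmt_num(map$extent_max))
    if (!is.na(map$assembly_tag)) attrs$assembly <- map$assembly_tag
    mapel <- do.call(xml2::xml_add_child, c(list(sp, "map"), attrs))
    mk <- map$markers
    for (i in seq_len(nrow(mk))) {
      mattrs <- list(name = mk$name[i], start = fmt_num(mk$start[i]),
                     end = fmt_num(mk$end[i]), strand = mk$strand[i],
                     kind = mk$kind[i])
      if (!is.na(mk$accession[i])) mattrs$accession <- mk$accession[i]
      if (!is.na(mk$description[i])) mattrs$description <- mk$description[i]
      do.call(xml2::xml_add_child, c(list(mapel, "marker"), mattrs))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
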