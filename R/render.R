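# Deterministic SVG rendering.  Maps are drawn vertically as a scaled red
# axis with labelled markers as points (ticks) or ranges (side bars) and
# orientation glyphs (up/down triangles for forward/reverse transcribed
# genes); typed relationship lines join markers on maps in adjacent
# columns.  The renderer is split in two: build_scene() turns model objects
# into a flat list of drawable primitives, each carrying the identifier of
# the model object it came from; render_svg() serialises a scene with a
# fixed element order and number format, so identical scenes produce
# byte-identical files.

# Largest 1/2/5 x 10^k step giving between 4 and 10 ticks across the view.
axis_tick_step <- function(span) {
  sm_assert(is_num(span) && span > 0, "span must be positive")
  raw <- span / 4                        # coarsest candidate
  k <- floor(log10(raw))
  for (step in c(5, 2, 1) * 10^k) {      # descending; first with <= 10 ticks wins
    if (floor(span / step) + 1 >= 4 && floor(span / step) + 1 <= 10) return(step)
  }
  10^k                                    # fallback: 1 x 10^k
}

axis_ticks <- function(view_start, view_end) {
  step <- axis_tick_step(view_end - view_start)
  first <- ceiling(view_start / step) * step
  ticks <- seq(first, view_end, by = step)
  ticks[ticks >= view_start & ticks <= view_end]
}

#' Build a drawable scene from a canvas, maps and links
#'
#' Produces the flat primitive tables the SVG writer consumes: one red axis
#' per visible map, round-number tick labels over the view window, a glyph
#' per in-view marker (tick for points, side bar for ranges, a triangle
#' where strand is known), horizontal marker labels (subject to the
#' placement's \code{label_mode} and the no-overlap sweep), one straight
#' coloured line per link whose two endpoints are in view, and a legend
#' listing only the link types present.  Links must connect maps in
#' adjacent virtual columns; a link between non-adjacent (or same-column)
#' maps is a contract violation.
#'
#' @param cv a [canvas()].
#' @param maps list of \code{genome_map}s covering every placed map.
#' @param links a link \code{data.frame} (possibly empty).
#' @return a \code{scene} object (list of primitive data.frames:
#'   \code{axes, ticks, glyphs, labels, link_lines, legend}).
#' @export
build_scene <- function(cv, maps, links = empty_links()) {
  sm_assert(inherits(cv, "canvas"), "not a canvas")
  if (is_genome_map(maps)) maps <- list(maps)
  byid <- stats::setNames(maps, vapply(maps, function(m) m$map_id, character(1)))
  for (p in cv$placements)
    if (is.null(byid[[p$map_id]]))
      sm_abort(sprintf("no map supplied for placement '%s'", p$map_id),
               "synmapr_not_found")
  cv <- canvas(cv$placements, maps = maps, style = cv$style)  # resolve views
  columns <- compute_columns(cv)
  pairs <- adjacent_pairs(cv, columns)
  pmap <- stats::setNames(cv$placements,
                          vapply(cv$placements, function(p) p$map_id, character(1)))
  style <- cv$style

  col_order <- unlist(columns, use.names = FALSE)
  axes <- list(); ticks <- list(); glyphs <- list(); labels <- list()

  linked_names <- function(id) unique(c(links$marker_a[links$map_a == id],
                                        links$marker_b[links$map_b == id]))
  for (id in col_order) {
    p <- pmap[[id]]
    m <- byid[[id]]
    ax_x <- p$x + p$width * 0.25         # axis line sits left; labels to the right
    axes[[length(axes) + 1L]] <- data.frame(
      map_id = id, x = ax_x, y0 = p$y, y1 = p$y + p$height,
      title = m$title, stringsAsFactors = FALSE)
    tk <- axis_ticks(p$view_start, p$view_end)
    if (length(tk))
      ticks[[length(ticks) + 1L]] <- data.frame(
        map_id = id, value = tk, x = ax_x, y = to_canvas_y(p, tk),
        text = fmt_num(tk), stringsAsFactors = FALSE)
    mk <- m$markers
    if (nrow(mk)) {
      mid <- (mk$start + mk$end) / 2
      inview <- mk$end >= p$view_start & mk$start <= p$view_end
      mkv <- mk[inview, , drop = FALSE]
      if (nrow(mkv)) {
        y0 <- to_canvas_y(p, pmin(pmax(mkv$start, p$view_start), p$view_end))
        y1 <- to_canvas_y(p, pmin(pmax(mkv$end, p$view_start), p$view_end))
        ymid <- (y0 + y1) / 2
        glyphs[[length(glyphs) + 1L]] <- data.frame(
          map_id = id, marker = mkv$name, kind = mkv$kind, strand = mkv$strand,
          shape = ifelse(mkv$start == mkv$end, "tick", "bar"),
          x = ax_x, y0 = pmin(y0, y1), y1 = pmax(y0, y1), ymid = ymid,
          stringsAsFactors = FALSE)
        lab_names <- switch(p$label_mode,
                            all = mkv$name,
                            linked_only = intersect(mkv$name, linked_names(id)),
                            none = character())
        if (length(lab_names)) {
          sel <- mkv$name %in% lab_names
          lb <- place_labels(p, ymid[sel], mkv$name[sel],
                             label_height = style$label_height)
          if (nrow(lb))
            labels[[length(labels) + 1L]] <- data.frame(
              map_id = id, marker = lb$label, x = ax_x + 8, y = lb$y,
              stringsAsFactors = FALSE)
        }
      }
    }
  }

  link_lines <- list()
  if (nrow(links)) {
    ok_pair <- paste(pairs$map_a, pairs$map_b)
    for (i in seq_len(nrow(links))) {
      la <- links$map_a[i]; lb <- links$map_b[i]
      fwd <- paste(la, lb) %in% ok_pair
      rev <- paste(lb, la) %in% ok_pair
      if (!fwd && !rev) {
        if (!la %in% col_order || !lb %in% col_order) next  # hidden map: clip
        sm_abort(sprintf(
          "link %s/%s -- %s/%s joins maps not in adjacent columns",
          la, links$marker_a[i], lb, links$marker_b[i]),
          "synmapr_contract_violation")
      }
      pa <- pmap[[la]]; pb <- pmap[[lb]]
      ma <- byid[[la]]$markers; mb <- byid[[lb]]$markers
      ya <- to_canvas_y(pa, (ma$start[links$idx_a[i]] + ma$end[links$idx_a[i]]) / 2)
      yb <- to_canvas_y(pb, (mb$start[links$idx_b[i]] + mb$end[links$idx_b[i]]) / 2)
      if (is.na(ya) || is.na(yb)) next   # out-of-view endpoint: clip
      xa <- pa$x + pa$width * 0.25
      xb <- pb$x + pb$width * 0.25
      link_lines[[length(link_lines) + 1L]] <- data.frame(
        map_a = la, marker_a = links$marker_a[i], map_b = lb,
        marker_b = links$marker_b[i], link_type = links$link_type[i],
        x0 = xa, y0 = ya, x1 = xb, y1 = yb,
        color = link_color(links$link_type[i], style$palette),
        stringsAsFactors = FALSE)
    }
  }
  bindf <- function(l, empty) if (length(l)) do.call(rbind, l) else empty
  link_df <- bindf(link_lines, data.frame(
    map_a = character(), marker_a = character(), map_b = character(),
    marker_b = character(), link_type = character(), x0 = numeric(),
    y0 = numeric(), x1 = numeric(), y1 = numeric(), color = character(),
    stringsAsFactors = FALSE))
  link_df <- link_df[order(link_df$link_type, link_df$map_a, link_df$marker_a,
                           link_df$map_b, link_df$marker_b, method = "radix"),
                     , drop = FALSE]
  rownames(link_df) <- NULL
  present <- sort(unique(link_df$link_type))
  legend <- data.frame(link_type = present,
                       color = vapply(present, link_color,
                                      character(1), palette = style$palette),
                       stringsAsFactors = FALSE)
  structure(list(axes = bindf(axes, data.frame()),
                 ticks = bindf(ticks, data.frame()),
                 glyphs = bindf(glyphs, data.frame()),
                 labels = bindf(labels, data.frame()),
                 link_lines = link_df, legend = legend,
                 style = style, columns = columns),
            class = "scene")
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Serialise a scene to an SVG 1.1 file
#'
#' Output is bit-stable: element order is fixed (axes in column order, then
#' ticks, marker glyphs, link lines sorted by type and endpoints, labels,
#' legend), numbers use a fixed decimal format, and every primitive carries
#' its source identifier in \code{data-*} attributes so the document can be
#' parsed back and tallied against the model.
#'
#' @param scene a [build_scene()] result.
#' @param path output file.
#' @param width,height document dimensions; defaults grow to fit content.
#' @return invisibly, \code{path}.
#' @export
render_svg <- function(scene, path, width = NULL, height = NULL) {
  sm_assert(inherits(scene, "scene"), "not a scene")
  st <- scene$style
  all_x <- c(scene$axes$x, scene$link_lines$x0, scene$link_lines$x1,
             if (nrow(scene$labels)) scene$labels$x + 90)
  all_y <- c(scene$axes$y0, scene$axes$y1)
  width <- width %||% (if (length(all_x)) max(all_x) + 120 else 200)
  height <- height %||% (if (length(all_y)) max(all_y) + 80 else 200)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%s" height="%s" font-family="%s" font-size="%s">'),
            fmt_px(width), fmt_px(height), st$font_family, fmt_px(st$font_size)),
    sprintf('<rect data-kind="background" x="0" y="0" width="%s" height="%s" fill="%s"/>',
            fmt_px(width), fmt_px(height), st$background))
  emit <- function(...) out <<- c(out, sprintf(...))
  ax <- scene$axes
  for (i in seq_len(nrow(ax))) {
    emit('<line data-kind="axis" data-map="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
         svg_escape(ax$map_id[i]), fmt_px(ax$x[i]), fmt_px(ax$y0[i]),
         fmt_px(ax$x[i]), fmt_px(ax$y1[i]), st$axis_color,
         fmt_px(st$stroke_width * 2))
    emit('<text data-kind="title" data-map="%s" x="%s" y="%s" fill="#000000">%s</text>',
         svg_escape(ax$map_id[i]), fmt_px(ax$x[i] - 10), fmt_px(ax$y0[i] - 8),
         svg_escape(ax$title[i]))
  }
  tk <- scene$ticks
  for (i in seq_len(nrow(tk))) {
    emit('<line data-kind="axis-tick" data-map="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
         svg_escape(tk$map_id[i]), fmt_px(tk$x[i] - 4), fmt_px(tk$y[i]),
         fmt_px(tk$x[i]), fmt_px(tk$y[i]), st$axis_color, fmt_px(st$stroke_width))
    emit('<text data-kind="tick-label" data-map="%s" x="%s" y="%s" text-anchor="end" fill="#000000">%s</text>',
         svg_escape(tk$map_id[i]), fmt_px(tk$x[i] - 6), fmt_px(tk$y[i] + 3),
         svg_escape(tk$text[i]))
  }
  gl <- scene$glyphs
  for (i in seq_len(nrow(gl))) {
    if (gl$shape[i] == "tick")
      emit('<line data-kind="marker" data-map="%s" data-marker="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000" stroke-width="%s"/>',
           svg_escape(gl$map_id[i]), svg_escape(gl$marker[i]),
           fmt_px(gl$x[i]), fmt_px(gl$ymid[i]), fmt_px(gl$x[i] + 5),
           fmt_px(gl$ymid[i]), fmt_px(st$stroke_width))
    else
      emit('<rect data-kind="marker" data-map="%s" data-marker="%s" x="%s" y="%s" width="3" height="%s" fill="#555555"/>',
           svg_escape(gl$map_id[i]), svg_escape(gl$marker[i]),
           fmt_px(gl$x[i] + 2), fmt_px(gl$y0[i]),
           fmt_px(max(gl$y1[i] - gl$y0[i], 0.5)))
    if (gl$strand[i] != "unstranded") {
      # orientation glyph: triangle pointing up = forward, down = reverse
      xg <- gl$x[i] - 6; yg <- gl$ymid[i]
      pts <- if (gl$strand[i] == "forward")
        sprintf("%s,%s %s,%s %s,%s", fmt_px(xg - 3), fmt_px(yg + 3),
                fmt_px(xg + 3), fmt_px(yg + 3), fmt_px(xg), fmt_px(yg - 3))
      else
        sprintf("%s,%s %s,%s %s,%s", fmt_px(xg - 3), fmt_px(yg - 3),
                fmt_px(xg + 3), fmt_px(yg - 3), fmt_px(xg), fmt_px(yg + 3))
      emit('<polygon data-kind="strand" data-map="%s" data-marker="%s" data-strand="%s" points="%s" fill="#000000"/>',
           svg_escape(gl$map_id[i]), svg_escape(gl$marker[i]), gl$strand[i], pts)
    }
  }
  ll <- scene$link_lines
  for (i in seq_len(nrow(ll)))
    emit('<line data-kind="link" data-link-type="%s" data-map-a="%s" data-marker-a="%s" data-map-b="%s" data-marker-b="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
         ll$link_type[i], svg_escape(ll$map_a[i]), svg_escape(ll$marker_a[i]),
         svg_escape(ll$map_b[i]), svg_escape(ll$marker_b[i]),
         fmt_px(ll$x0[i]), fmt_px(ll$y0[i]), fmt_px(ll$x1[i]), fmt_px(ll$y1[i]),
         ll$color[i], fmt_px(st$stroke_width))
  lb <- scene$labels
  for (i in seq_len(nrow(lb)))
    emit('<text data-kind="label" data-map="%s" data-marker="%s" x="%s" y="%s" fill="#000000">%s</text>',
         svg_escape(lb$map_id[i]), svg_escape(lb$marker[i]),
         fmt_px(lb$x[i]), fmt_px(lb$y[i] + 3), svg_escape(lb$marker[i]))
  lg <- scene$legend
  for (i in seq_len(nrow(lg))) {
    y <- 16 + 14 * (i - 1)
    emit('<line data-kind="legend" data-link-type="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2"/>',
         lg$link_type[i], fmt_px(width - 170), fmt_px(y), fmt_px(width - 150),
         fmt_px(y), lg$color[i])
    emit('<text data-kind="legend-label" data-link-type="%s" x="%s" y="%s" fill="#000000">%s</text>',
         lg$link_type[i], fmt_px(width - 144), fmt_px(y + 3),
         svg_escape(gsub("_", " ", lg$link_type[i])))
  }
  out <- c(out, "</svg>")
  con <- file(path, open = "wb")               # fixed newline convention
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

#' Tally the primitives of a rendered SVG document
#'
#' Parses an SVG produced by [render_svg()] and counts elements by their
#' \code{data-kind} source attribute — the parse-back oracle used by the
#' rendering tests.
#'
#' @param path SVG file.
#' @return named list: \code{axes}, \code{links} (rows with type/endpoint
#'   attributes), \code{labels}, \code{glyphs}, \code{legend}.
#' @export
svg_tally <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(svg = "http://www.w3.org/2000/svg")
  grab <- function(kind)
    xml2::xml_find_all(doc, sprintf(".//svg:*[@data-kind='%s']", kind), ns)
  links <- grab("link")
  list(axes = vapply(grab("axis"), function(n) xml2::xml_attr(n, "data-map"),
                     character(1)),
       links = data.frame(
         link_type = vapply(links, function(n) xml2::xml_attr(n, "data-link-type"), character(1)),
         map_a = vapply(links, function(n) xml2::xml_attr(n, "data-map-a"), character(1)),
         map_b = vapply(links, function(n) xml2::xml_attr(n, "data-map-b"), character(1)),
         stroke = vapply(links, function(n) xml2::xml_attr(n, "stroke"), character(1)),
         stringsAsFactors = FALSE),
       labels = length(grab("label")),
       glyphs = length(grab("marker")),
       legend = vapply(grab("legend"), function(n) xml2::xml_attr(n, "data-link-type"),
                       character(1)))
}
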