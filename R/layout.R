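# Canvas layout: maps are placed freely in 2-D; "virtual columns" are
# derived automatically from the horizontal positions — maps whose width
# intervals overlap (closed intervals, so touching counts) fall in one
# column, transitively.  Relationship links are only drawn between maps in
# adjacent columns, which is how a user controls what is visible.

#' Construct a placement of one map on the canvas
#'
#' @param map_id id of the placed map.
#' @param x,y top-left canvas coordinates.
#' @param width,height positive box dimensions (the vertical axis spans
#'   \code{height}).
#' @param view_start,view_end visible window in map units
#'   (\code{view_start < view_end}); defaults taken from the map when
#'   assembled into a canvas.
#' @param flipped draw the axis with coordinates increasing upward?
#' @param visible hidden maps belong to no column and are not drawn.
#' @param label_mode \code{"all"}, \code{"linked_only"} (only markers with
#'   at least one link get labels) or \code{"none"}.
#' @return a \code{placement} object.
#' @export
placement <- function(map_id, x = 0, y = 0, width = 120, height = 400,
                      view_start = NA_real_, view_end = NA_real_,
                      flipped = FALSE, visible = TRUE, label_mode = "all") {
  sm_assert(is_string(map_id), "map_id must be a string")
  sm_assert(is_num(x) && is_num(y) && is_num(width) && is_num(height) &&
              width > 0 && height > 0, "width and height must be positive")
  sm_assert(label_mode %in% c("all", "linked_only", "none"),
            "label_mode must be all, linked_only or none")
  if (!is.na(view_start) && !is.na(view_end))
    sm_assert(view_start < view_end, "view_start must be < view_end")
  structure(list(map_id = map_id, x = as.numeric(x), y = as.numeric(y),
                 width = as.numeric(width), height = as.numeric(height),
                 view_start = as.numeric(view_start),
                 view_end = as.numeric(view_end),
                 flipped = isTRUE(flipped), visible = isTRUE(visible),
                 label_mode = label_mode),
            class = "placement")
}

#' Assemble placements into a canvas
#'
#' @param placements list of [placement()]s with unique \code{map_id}s.
#'   Placements with missing view windows are completed from \code{maps}.
#' @param maps optional list of \code{genome_map}s used to default view
#'   windows to full map extents.
#' @param style named list of style settings (palette overrides, fonts,
#'   stroke widths) merged over the defaults.
#' @return a \code{canvas} object.
#' @export
canvas <- function(placements, maps = NULL, style = list()) {
  if (inherits(placements, "placement")) placements <- list(placements)
  ids <- vapply(placements, function(p) p$map_id, character(1))
  sm_assert(!anyDuplicated(ids), "placement map_ids must be unique")
  if (!is.null(maps)) {
    byid <- stats::setNames(maps, vapply(maps, function(m) m$map_id, character(1)))
    placements <- lapply(placements, function(p) {
      m <- byid[[p$map_id]]
      if (!is.null(m)) {
        if (is.na(p$view_start)) p$view_start <- m$extent_min
        if (is.na(p$view_end)) p$view_end <- m$extent_max
      }
      p
    })
  }
  default_style <- list(palette = as.list(DEFAULT_PALETTE), axis_color = "#CC0000",
                        font_family = "Helvetica", font_size = 9,
                        stroke_width = 1, label_height = 11, background = "#FFFFFF")
  structure(list(placements = placements,
                 style = utils::modifyList(default_style, style)),
            class = "canvas")
}

#' Derive the virtual columns of a canvas
#'
#' Columns are the connected components of the overlap graph on visible
#' placements, with an edge when the horizontal intervals
#' \code{[x, x + width]} intersect as closed intervals (a shared boundary
#' counts).  Components are ordered left-to-right by their minimum
#' \code{x}; hidden maps belong to no column.  Vertical position plays no
#' role.
#'
#' @param cv a \code{canvas}.
#' @return ordered list of character vectors of \code{map_id}s.
#' @export
compute_columns <- function(cv) {
  sm_assert(inherits(cv, "canvas"), "not a canvas")
  ps <- Filter(function(p) p$visible, cv$placements)
  if (!length(ps)) return(list())
  x0 <- vapply(ps, function(p) p$x, numeric(1))
  x1 <- x0 + vapply(ps, function(p) p$width, numeric(1))
  ids <- vapply(ps, function(p) p$map_id, character(1))
  o <- order(x0, x1, ids, method = "radix")
  cols <- list()
  cur <- character(); cur_max <- -Inf
  for (i in o) {
    if (length(cur) && x0[i] > cur_max) {      # gap: start a new column
      cols[[length(cols) + 1L]] <- cur
      cur <- character(); cur_max <- -Inf
    }
    cur <- c(cur, ids[i])
    cur_max <- max(cur_max, x1[i])
  }
  cols[[length(cols) + 1L]] <- cur
  cols
}

#' Enumerate the map pairs allowed to show links
#'
#' All cross-column pairs between consecutive virtual columns; pairs within
#' one column are excluded.  Link rendering consumes only these pairs.
#'
#' @param cv a \code{canvas}.
#' @param columns optionally, precomputed [compute_columns()] output.
#' @return \code{data.frame} with columns \code{map_a, map_b}.
#' @export
adjacent_pairs <- function(cv, columns = compute_columns(cv)) {
  out <- list()
  if (length(columns) >= 2) {
    for (i in seq_len(length(columns) - 1L)) {
      grid <- expand.grid(map_a = columns[[i]], map_b = columns[[i + 1L]],
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      out[[length(out) + 1L]] <- grid
    }
  }
  if (!length(out))
    return(data.frame(map_a = character(), map_b = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map coordinate to canvas y
#'
#' Linear interpolation of a map coordinate into the vertical span of a
#' placement: \code{view_start} maps to the axis top (\code{y}) and
#' \code{view_end} to the bottom (\code{y + height}); a flipped axis
#' reverses the direction.  Coordinates outside the view window return
#' \code{NA} (the out-of-view signal; callers clip).
#'
#' @param p a [placement()] with a resolved view window.
#' @param c numeric vector of map coordinates.
#' @return numeric vector of canvas y values (NA where out of view).
#' @export
to_canvas_y <- function(p, c) {
  sm_assert(inherits(p, "placement"), "not a placement")
  sm_assert(!is.na(p$view_start) && !is.na(p$view_end), "view window unresolved")
  f <- (c - p$view_start) / (p$view_end - p$view_start)
  if (p$flipped) f <- 1 - f
  y <- p$y + p$height * f
  y[c < p$view_start | c > p$view_end] <- NA_real_
  y
}

#' Canvas y back to map coordinate (inverse of [to_canvas_y()])
#'
#' @param p a [placement()].
#' @param y numeric vector of canvas y values within the placement's
#'   vertical span.
#' @return numeric vector of map coordinates (NA where outside the axis).
#' @export
from_canvas_y <- function(p, y) {
  sm_assert(inherits(p, "placement"), "not a placement")
  f <- (y - p$y) / p$height
  if (p$flipped) f <- 1 - f
  c <- p$view_start + f * (p$view_end - p$view_start)
  c[y < p$y | y > p$y + p$height] <- NA_real_
  c
}

#' Place horizontal marker labels without overlap
#'
#' Greedy top-down sweep: labels are anchored at their marker's canvas y,
#' in increasing y order, and nudged downward just enough that boxes on one
#' side of one axis never overlap.  Labels pushed past the bottom of the
#' placement are dropped and counted.
#'
#' @param p a [placement()].
#' @param marker_y numeric vector of desired anchor y positions (already on
#'   canvas scale, NA = out of view).
#' @param labels character vector of label texts (parallel to
#'   \code{marker_y}).
#' @param label_height box height in canvas units.
#' @return \code{data.frame} with \code{label, y} rows for emitted labels;
#'   attribute \code{dropped} counts the labels that did not fit.
#' @export
place_labels <- function(p, marker_y, labels, label_height = 11) {
  keep <- !is.na(marker_y)
  marker_y <- marker_y[keep]; labels <- labels[keep]
  o <- order(marker_y, labels, method = "radix")
  marker_y <- marker_y[o]; labels <- labels[o]
  out_y <- numeric(0); out_l <- character(0); dropped <- 0L
  bottom <- -Inf
  limit <- p$y + p$height
  for (i in seq_along(marker_y)) {
    y <- max(marker_y[i], bottom)
    if (y + label_height > limit + label_height) { # completely out of axis span
      dropped <- dropped + 1L
      next
    }
    out_y <- c(out_y, y); out_l <- c(out_l, labels[i])
    bottom <- y + label_height
  }
  res <- data.frame(label = out_l, y = out_y, stringsAsFactors = FALSE)
  attr(res, "dropped") <- dropped
  res
}

#' Read a canvas layout description from JSON
#'
#' The layout file is a JSON object with a \code{maps} array (one object
#' per placement, fields as in [placement()]; omitted fields default, and
#' maps with no \code{x} are auto-tiled left-to-right in file order) and an
#' optional \code{style} object.
#'
#' @param path JSON file.
#' @param maps optional list of \code{genome_map}s to resolve view windows.
#' @return a \code{canvas}.
#' @export
read_layout_json <- function(path, maps = NULL) {
  sm_assert(file.exists(path), paste0("no such file: ", path), "synmapr_io_error")
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  sm_assert(!is.null(spec$maps), "layout JSON needs a 'maps' array")
  tile_x <- 0
  ps <- lapply(spec$maps, function(m) {
    sm_assert(!is.null(m$map_id), "layout map entry needs a map_id")
    w <- m$width %||% 120
    x <- m$x
    if (is.null(x)) { x <- tile_x; tile_x <<- tile_x + w + 60 }
    else tile_x <<- max(tile_x, x + w + 60)
    placement(m$map_id, x = x, y = m$y %||% 0, width = w,
              height = m$height %||% 400,
              view_start = m$view_start %||% NA_real_,
              view_end = m$view_end %||% NA_real_,
              flipped = m$flipped %||% FALSE,
              visible = m$visible %||% TRUE,
              label_mode = m$label_mode %||% "all")
  })
  canvas(ps, maps = maps, style = lapply(spec$style %||% list(), function(x) x))
}
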