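# ---- drawing primitives -----------------------------------------------------
# Every glyph is a display list of primitives; the SVG writer and the PNG
# rasteriser both replay the same list, so the SVG is byte-deterministic
# and the raster matches it at any DPI.

fmt_num <- function(x) sprintf("%.6g", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

prim_rect <- function(x, y, w, h, fill = "#FFFFFF", stroke = "#999999",
                      stroke_width = 0.5) {
  list(type = "rect", x = x, y = y, w = w, h = h, fill = fill,
       stroke = stroke, stroke_width = stroke_width)
}

prim_polyline <- function(xs, ys, stroke = "#333333", stroke_width = 1) {
  list(type = "polyline", xs = xs, ys = ys, stroke = stroke,
       stroke_width = stroke_width)
}

prim_circle <- function(cx, cy, r, fill = "#333333") {
  list(type = "circle", cx = cx, cy = cy, r = r, fill = fill)
}

prim_text <- function(x, y, text, size = 10, anchor = "middle",
                      fill = "#000000", bold = FALSE) {
  list(type = "text", x = x, y = y, text = text, size = size,
       anchor = anchor, fill = fill, bold = bold)
}

prim_to_svg <- function(p) {
  switch(
    p$type,
    rect = sprintf(
      '<rect x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
      fmt_num(p$x), fmt_num(p$y), fmt_num(p$w), fmt_num(p$h), p$fill,
      p$stroke, fmt_num(p$stroke_width)),
    polyline = sprintf(
      '<polyline points="%s" fill="none" stroke="%s" stroke-width="%s"/>',
      paste(fmt_num(p$xs), fmt_num(p$ys), sep = ",", collapse = " "),
      p$stroke, fmt_num(p$stroke_width)),
    circle = sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s"/>',
      fmt_num(p$cx), fmt_num(p$cy), fmt_num(p$r), p$fill),
    text = sprintf(
      '<text x="%s" y="%s" font-family="sans-serif" font-size="%s"%s text-anchor="%s" fill="%s">%s</text>',
      fmt_num(p$x), fmt_num(p$y), fmt_num(p$size),
      if (isTRUE(p$bold)) ' font-weight="bold"' else "",
      p$anchor, p$fill, xml_escape(p$text)),
    abort(paste0("unknown primitive type: ", p$type))
  )
}

svg_document <- function(prims, width, height) {
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            fmt_num(width), fmt_num(height), fmt_num(width), fmt_num(height)),
    paste(vapply(prims, prim_to_svg, character(1)), collapse = "\n"),
    "\n</svg>\n")
}

render_png_file <- function(prims, width, height, file, dpi = 96) {
  scale <- dpi / 96
  grDevices::png(file, width = round(width * scale),
                 height = round(height * scale), res = dpi)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, width), ylim = c(height, 0))
  for (p in prims) {
    switch(
      p$type,
      rect = graphics::rect(
        p$x, p$y + p$h, p$x + p$w, p$y,
        col = if (identical(p$fill, "none")) NA else p$fill,
        border = if (identical(p$stroke, "none") || p$stroke_width == 0) NA
                 else p$stroke,
        lwd = max(p$stroke_width, 0.2)),
      polyline = graphics::lines(p$xs, p$ys, col = p$stroke,
                                 lwd = p$stroke_width),
      circle = graphics::symbols(p$cx, p$cy, circles = p$r, inches = FALSE,
                                 add = TRUE, bg = p$fill, fg = NA),
      text = graphics::text(p$x, p$y, labels = p$text, cex = p$size / 12,
                            col = p$fill,
                            adj = switch(p$anchor, middle = c(0.5, 0),
                                         start = c(0, 0), end = c(1, 0)))
    )
  }
  invisible(file)
}

# ---- style registry ---------------------------------------------------------

gn_styles <- new.env(parent = emptyenv())

#' Register a glyph drawing style
#'
#' A drawer is a function `function(values, headers, scale, cells)`
#' returning a list of drawing primitives; `cells` is the tibble of cell
#' geometries (one row per data column for array datasets) assigned to
#' the dataset by the layout. Built-in styles: heatmap, bar, line,
#' timeseries, scatter.
#'
#' @param name style name (must not be taken).
#' @param drawer the drawing function.
#' @return the style name, invisibly.
#' @export
register_style <- function(name, drawer) {
  if (name %in% ls(gn_styles)) {
    abort(paste0("style '", name, "' is already registered"))
  }
  if (!is.function(drawer)) abort("drawer must be a function")
  assign(name, drawer, envir = gn_styles)
  invisible(name)
}

#' @rdname register_style
#' @export
unregister_style <- function(name) {
  if (name %in% c("heatmap", "bar", "line", "timeseries", "scatter")) {
    abort("built-in styles cannot be unregistered")
  }
  if (name %in% ls(gn_styles)) rm(list = name, envir = gn_styles)
  invisible(name)
}

#' @rdname register_style
#' @export
registered_styles <- function() sort(ls(gn_styles))

style_drawer <- function(name) {
  if (!name %in% ls(gn_styles)) {
    abort(paste0("no glyph style named '", name,
                 "' is registered (available: ",
                 paste(registered_styles(), collapse = ", "), ")"))
  }
  get(name, envir = gn_styles)
}

cell_blanks <- function(cells, missing_color = "#FFFFFF") {
  lapply(seq_len(nrow(cells)), function(i) {
    prim_rect(cells$x[[i]], cells$y[[i]], cells$w[[i]], cells$h[[i]],
              fill = missing_color, stroke = "#CCCCCC")
  })
}

draw_heatmap <- function(values, headers, scale, cells) {
  cols <- scale_color_of(scale, values)
  lapply(seq_len(nrow(cells)), function(i) {
    prim_rect(cells$x[[i]], cells$y[[i]], cells$w[[i]], cells$h[[i]],
              fill = cols[[i]], stroke = "#CCCCCC")
  })
}

draw_bar <- function(values, headers, scale, cells) {
  lo <- scale$domain[[1]]; hi <- scale$domain[[length(scale$domain)]]
  frac <- pmin(pmax((values - lo) / (hi - lo), 0), 1)
  out <- cell_blanks(cells)
  for (i in seq_len(nrow(cells))) {
    if (is.na(values[[i]])) next
    bh <- cells$h[[i]] * frac[[i]]
    out <- c(out, list(prim_rect(
      cells$x[[i]] + 1, cells$y[[i]] + cells$h[[i]] - bh,
      cells$w[[i]] - 2, bh, fill = "#4477AA", stroke = "#4477AA",
      stroke_width = 0)))
  }
  out
}

draw_series <- function(values, headers, scale, cells, points, line) {
  lo <- scale$domain[[1]]; hi <- scale$domain[[length(scale$domain)]]
  frac <- pmin(pmax((values - lo) / (hi - lo), 0), 1)
  x0 <- min(cells$x); x1 <- max(cells$x + cells$w)
  y0 <- min(cells$y); h <- max(cells$h)
  out <- list(prim_rect(x0, y0, x1 - x0, h, fill = "#FFFFFF",
                        stroke = "#CCCCCC"))
  cx <- cells$x + cells$w / 2
  cy <- y0 + h * (1 - frac)
  ok <- !is.na(values)
  if (line) {
    # split polyline at missing values
    runs <- split(seq_along(ok)[ok], cumsum(!ok)[ok])
    for (r in runs) {
      if (length(r) >= 2) {
        out <- c(out, list(prim_polyline(cx[r], cy[r], stroke = "#225588",
                                         stroke_width = 1)))
      }
    }
  }
  if (points) {
    for (i in which(ok)) {
      out <- c(out, list(prim_circle(cx[[i]], cy[[i]], r = 1.6,
                                     fill = "#225588")))
    }
  }
  out
}

draw_line <- function(values, headers, scale, cells) {
  draw_series(values, headers, scale, cells, points = FALSE, line = TRUE)
}

draw_timeseries <- function(values, headers, scale, cells) {
  draw_series(values, headers, scale, cells, points = TRUE, line = TRUE)
}

draw_scatter <- function(values, headers, scale, cells) {
  draw_series(values, headers, scale, cells, points = TRUE, line = FALSE)
}

register_builtin_styles <- function() {
  for (nm in c("heatmap", "bar", "line", "timeseries", "scatter")) {
    if (!nm %in% ls(gn_styles)) {
      assign(nm, switch(nm, heatmap = draw_heatmap, bar = draw_bar,
                        line = draw_line, timeseries = draw_timeseries,
                        scatter = draw_scatter), envir = gn_styles)
    }
  }
}

# ---- layout -----------------------------------------------------------------

#' Automatic glyph layout for a node type
#'
#' Array datasets each get a full-width row (in dataset order, one cell
#' per column); single-value datasets are packed left-to-right into
#' shared rows of up to four cells. A label band sits on top. The canvas
#' width is fixed by the widest row (single rows count their packed
#' slots); narrower rows stretch their cells to keep the total width
#' uniform. All nodes of one node type share the layout, so their images
#' have identical dimensions.
#'
#' @param signature a `gn_signature` from [derive_node_types()].
#' @param datasets list of all `gn_dataset` objects (superset of the
#'   signature is fine).
#' @param cell_w,cell_h base cell size in px.
#' @param label_band height of the label band in px.
#' @param max_singles_per_row packing width for single-value datasets.
#' @return a `gn_layout` with `cells` (tibble: dataset_id, column,
#'   col_index, row, x, y, w, h), `width`, `height`, `label_band`.
#' @export
auto_layout <- function(signature, datasets, cell_w = 40, cell_h = 20,
                        label_band = 14, max_singles_per_row = 4) {
  ds_map <- stats::setNames(datasets,
                            vapply(datasets, function(d) d$id, character(1)))
  miss <- setdiff(signature$dataset_ids, names(ds_map))
  if (length(miss)) {
    abort(paste0("signature references unknown dataset(s): ",
                 paste(miss, collapse = ", ")))
  }
  rows <- list()   # each: tibble(dataset_id, column, col_index)
  buf <- NULL
  flush <- function() {
    if (!is.null(buf) && nrow(buf)) rows[[length(rows) + 1L]] <<- buf
    buf <<- NULL
  }
  for (did in signature$dataset_ids) {
    ds <- ds_map[[did]]
    if (ds$kind == "array") {
      flush()
      rows[[length(rows) + 1L]] <- tibble(
        dataset_id = did, column = ds$headers,
        col_index = seq_along(ds$headers))
    } else {
      cell <- tibble(dataset_id = did, column = ds$headers[[1]],
                     col_index = 1L)
      buf <- if (is.null(buf)) cell else dplyr::bind_rows(buf, cell)
      if (nrow(buf) == max_singles_per_row) flush()
    }
  }
  flush()
  n_cells <- vapply(rows, nrow, integer(1))
  width <- cell_w * max(n_cells)
  cells <- dplyr::bind_rows(lapply(seq_along(rows), function(r) {
    row <- rows[[r]]
    cw <- width / nrow(row)
    row$row <- r
    row$x <- (seq_len(nrow(row)) - 1L) * cw
    row$y <- label_band + (r - 1L) * cell_h
    row$w <- cw
    row$h <- cell_h
    row
  }))
  structure(list(cells = cells, width = width,
                 height = label_band + length(rows) * cell_h,
                 label_band = label_band, cell_w = cell_w, cell_h = cell_h),
            class = "gn_layout")
}

#' Read a manual layout override
#'
#' Accepts a JSON file mirroring the `gn_layout` structure (`width`,
#' `height`, `label_band` and a `cells` array with dataset_id, column,
#' col_index, row, x, y, w, h) and validates it against a signature:
#' every dataset of the signature must occupy at least one cell.
#'
#' @param path JSON file.
#' @param signature the `gn_signature` the layout is for.
#' @return a `gn_layout`.
#' @export
read_layout <- function(path, signature) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("width", "height", "label_band", "cells")
  miss <- setdiff(need, names(spec))
  if (length(miss)) {
    abort(paste0("layout file missing field(s): ",
                 paste(miss, collapse = ", ")), class = "gn_io_error")
  }
  cells <- as_tibble(spec$cells)
  uncovered <- setdiff(signature$dataset_ids, cells$dataset_id)
  if (length(uncovered)) {
    abort(paste0("layout does not cover dataset(s): ",
                 paste(uncovered, collapse = ", ")),
          class = "gn_validation_error")
  }
  structure(list(cells = cells, width = spec$width, height = spec$height,
                 label_band = spec$label_band,
                 cell_w = spec$cell_w %||% 40, cell_h = spec$cell_h %||% 20),
            class = "gn_layout")
}

# ---- node and legend rendering ----------------------------------------------

#' Render the glyph image of one node
#'
#' Draws a label band (node label, falling back to the id) and one glyph
#' per layout cell using each dataset's style. Values the node lacks —
#' a missing cell, or a whole dataset absent for this node — render as
#' blank cells. Output is deterministic: identical inputs give
#' byte-identical SVG.
#'
#' @param net the `gn_network` (for labels and replicate data_id lookup).
#' @param node_id id of a node in `signature$members`.
#' @param signature a `gn_signature`.
#' @param datasets list of `gn_dataset`.
#' @param layout a `gn_layout` for the signature (default: [auto_layout()]).
#' @return a `gn_image`: node_id, signature_id, label, width, height,
#'   the SVG document string and the primitive display list.
#' @export
render_node <- function(net, node_id, signature, datasets,
                        layout = auto_layout(signature, datasets)) {
  if (!node_id %in% signature$members) {
    abort(paste0("node ", node_id, " is not a member of node type ",
                 signature$id))
  }
  ds_map <- stats::setNames(datasets,
                            vapply(datasets, function(d) d$id, character(1)))
  idx <- match(node_id, net$nodes$id)
  label <- if (!is.na(idx)) net$nodes$label[[idx]] else node_id
  prims <- list(
    prim_rect(0, 0, layout$width, layout$height, fill = "#FFFFFF",
              stroke = "#333333", stroke_width = 1),
    prim_text(layout$width / 2, layout$label_band - 4, label, size = 9,
              bold = TRUE)
  )
  for (did in signature$dataset_ids) {
    ds <- ds_map[[did]]
    cells <- layout$cells[layout$cells$dataset_id == did, ]
    cells <- cells[order(cells$col_index), ]
    values <- dataset_values_for(ds, net, node_id)
    if (is.null(values)) values <- rep(NA_real_, length(ds$headers))
    if (all(is.na(values))) {
      prims <- c(prims, cell_blanks(cells, ds$scale$missing_color))
    } else {
      drawer <- style_drawer(ds$style)
      prims <- c(prims, drawer(values, ds$headers, ds$scale, cells))
    }
  }
  structure(list(node_id = node_id, signature_id = signature$id,
                 label = label, width = layout$width,
                 height = layout$height, prims = prims,
                 svg = svg_document(prims, layout$width, layout$height)),
            class = "gn_image")
}

#' @export
print.gn_image <- function(x, ...) {
  cat(sprintf("<gn_image> %s (%sx%s px, node type %s)\n", x$node_id,
              fmt_num(x$width), fmt_num(x$height), x$signature_id))
  invisible(x)
}

#' Render the legend of a node type
#'
#' One entry per dataset of the signature, in registration order: name,
#' description, style, and the colour scale (a labelled colour bar for
#' heatmap/bar styles, the value range for point/line styles).
#'
#' @param signature a `gn_signature`.
#' @param datasets list of `gn_dataset`.
#' @param width legend width in px.
#' @return a `gn_legend` with `entries` tibble, prims and SVG string.
#' @export
render_legend <- function(signature, datasets, width = 260) {
  ds_map <- stats::setNames(datasets,
                            vapply(datasets, function(d) d$id, character(1)))
  entry_h <- 44
  height <- 18 + entry_h * length(signature$dataset_ids)
  prims <- list(
    prim_rect(0, 0, width, height, fill = "#FFFFFF", stroke = "#333333",
              stroke_width = 1),
    prim_text(width / 2, 12, paste0("Node type: ", signature$id), size = 9,
              bold = TRUE)
  )
  entries <- list()
  for (k in seq_along(signature$dataset_ids)) {
    ds <- ds_map[[signature$dataset_ids[[k]]]]
    y0 <- 18 + (k - 1) * entry_h
    prims <- c(prims, list(
      prim_text(6, y0 + 11, ds$name, size = 8, anchor = "start",
                bold = TRUE),
      prim_text(6, y0 + 21, paste0(ds$description,
                                   if (nzchar(ds$description)) " " else "",
                                   "[", ds$style, "]"),
                size = 7, anchor = "start", fill = "#444444")
    ))
    lo <- ds$scale$domain[[1]]
    hi <- ds$scale$domain[[length(ds$scale$domain)]]
    if (ds$style %in% c("heatmap", "bar")) {
      bar_x <- 6; bar_w <- 120; bar_h <- 8; n_slice <- 32
      sx <- bar_x + (seq_len(n_slice) - 1) * bar_w / n_slice
      cols <- scale_color_of(ds$scale,
                             lo + (seq_len(n_slice) - 0.5) / n_slice * (hi - lo))
      for (i in seq_len(n_slice)) {
        prims <- c(prims, list(prim_rect(sx[[i]], y0 + 26, bar_w / n_slice,
                                         bar_h, fill = cols[[i]],
                                         stroke = cols[[i]],
                                         stroke_width = 0)))
      }
      prims <- c(prims, list(
        prim_rect(bar_x, y0 + 26, bar_w, bar_h, fill = "none",
                  stroke = "#333333", stroke_width = 0.5),
        prim_text(bar_x, y0 + 42, fmt_num(lo), size = 7, anchor = "start"),
        prim_text(bar_x + bar_w, y0 + 42, fmt_num(hi), size = 7,
                  anchor = "end")
      ))
    } else {
      prims <- c(prims, list(
        prim_text(6, y0 + 34, paste0("value range: ", fmt_num(lo), " to ",
                                     fmt_num(hi)), size = 7,
                  anchor = "start")
      ))
    }
    entries[[k]] <- tibble(dataset_id = ds$id, name = ds$name,
                           description = ds$description, style = ds$style)
  }
  structure(list(signature_id = signature$id,
                 entries = dplyr::bind_rows(entries),
                 width = width, height = height, prims = prims,
                 svg = svg_document(prims, width, height)),
            class = "gn_legend")
}

#' @export
print.gn_legend <- function(x, ...) {
  cat(sprintf("<gn_legend> node type %s: %d entr%s\n", x$signature_id,
              nrow(x$entries), if (nrow(x$entries) == 1) "y" else "ies"))
  invisible(x)
}

#' Render glyphs for every data-bearing node of a network
#'
#' Derives node types from data availability, lays each type out, and
#' renders one image per member node plus one legend per node type.
#'
#' @param net a `gn_network`.
#' @param datasets list of `gn_dataset`.
#' @param mode passed to [derive_node_types()].
#' @param cell_w,cell_h,label_band passed to [auto_layout()].
#' @return a `gn_render` list: `images` (named by node id), `legends`
#'   (named by signature id), `signatures`, and `manifest` (tibble
#'   node_id / signature_id — the node-legend mapping).
#' @export
render_metanodes <- function(net, datasets, mode = "uniform", cell_w = 40,
                             cell_h = 20, label_band = 14) {
  sigs <- derive_node_types(datasets, net, mode = mode)
  images <- list()
  legends <- list()
  manifest <- list()
  for (sig in sigs) {
    layout <- auto_layout(sig, datasets, cell_w = cell_w, cell_h = cell_h,
                          label_band = label_band)
    legends[[sig$id]] <- render_legend(sig, datasets)
    for (nid in sig$members) {
      images[[nid]] <- render_node(net, nid, sig, datasets, layout)
    }
    manifest[[sig$id]] <- tibble(node_id = sig$members,
                                 signature_id = sig$id)
  }
  structure(list(images = images, legends = legends, signatures = sigs,
                 manifest = dplyr::bind_rows(manifest)),
            class = "gn_render")
}

#' @export
print.gn_render <- function(x, ...) {
  cat(sprintf("<gn_render> %d image(s), %d node type(s)\n",
              length(x$images), length(x$legends)))
  invisible(x)
}

safe_filename <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Export rendered images and legends
#'
#' Writes one file per node image (`node_<id>.<ext>`) and per legend
#' (`legend_<signature>.<ext>`) plus a `manifest.json` mapping node ids
#' to their files and node types to legends. SVG is the source of truth;
#' PNG is rasterised from the same primitive list at the given DPI. I/O
#' failures are reported per file and do not stop the export.
#'
#' @param render a `gn_render` (or list with `images` and `legends`).
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("svg", "png")`.
#' @param dpi raster resolution; the PNG pixel size is the SVG canvas
#'   scaled by `dpi/96`.
#' @return the manifest, invisibly: list with `nodes` and `legends`
#'   tibbles and the path of the JSON file.
#' @export
export_images <- function(render, out_dir, formats = "svg", dpi = 96) {
  bad <- setdiff(formats, c("svg", "png"))
  if (length(bad)) {
    abort(paste0("unknown format(s): ", paste(bad, collapse = ", ")),
          class = "gn_io_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failures <- character()
  write_one <- function(obj, stem) {
    files <- character()
    if ("svg" %in% formats) {
      f <- file.path(out_dir, paste0(stem, ".svg"))
      ok <- tryCatch({ writeLines(obj$svg, f, sep = ""); TRUE },
                     error = function(e) {
                       failures <<- c(failures, paste0(f, ": ",
                                                       conditionMessage(e)))
                       FALSE
                     })
      if (ok) files[["svg"]] <- f
    }
    if ("png" %in% formats) {
      f <- file.path(out_dir, paste0(stem, ".png"))
      ok <- tryCatch({
        render_png_file(obj$prims, obj$width, obj$height, f, dpi = dpi)
        TRUE
      }, error = function(e) {
        failures <<- c(failures, paste0(f, ": ", conditionMessage(e)))
        FALSE
      })
      if (ok) files[["png"]] <- f
    }
    files
  }
  node_rows <- lapply(render$images, function(img) {
    files <- write_one(img, paste0("node_", safe_filename(img$node_id)))
    tibble(node_id = img$node_id, signature_id = img$signature_id,
           svg = if ("svg" %in% names(files)) files[["svg"]] else NA_character_,
           png = if ("png" %in% names(files)) files[["png"]] else NA_character_)
  })
  legend_rows <- lapply(render$legends, function(lg) {
    files <- write_one(lg, paste0("legend_", safe_filename(lg$signature_id)))
    tibble(signature_id = lg$signature_id,
           svg = if ("svg" %in% names(files)) files[["svg"]] else NA_character_,
           png = if ("png" %in% names(files)) files[["png"]] else NA_character_)
  })
  manifest <- list(nodes = dplyr::bind_rows(node_rows),
                   legends = dplyr::bind_rows(legend_rows))
  if (length(failures)) {
    warn(paste0("export failures:\n", paste0("  ", failures,
                                             collapse = "\n")))
  }
  json_path <- file.path(out_dir, "manifest.json")
  # the JSON manifest stores paths relative to out_dir so identical runs
  # produce identical bytes wherever the directory lives
  relativize <- function(tb) {
    for (col in intersect(c("svg", "png"), names(tb))) {
      tb[[col]] <- ifelse(is.na(tb[[col]]), NA_character_,
                          basename(tb[[col]]))
    }
    tb
  }
  jsonlite::write_json(
    list(nodes = relativize(manifest$nodes),
         legends = relativize(manifest$legends)),
    json_path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE,
    na = "null")
  manifest$json <- json_path
  manifest$relative <- list(nodes = relativize(manifest$nodes),
                            legends = relativize(manifest$legends))
  invisible(manifest)
}
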