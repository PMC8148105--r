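#' Read an omics data table keyed by node identifier
#'
#' Accepts CSV (RFC 4180), TSV, or XLSX (first sheet unless `sheet` is
#' given; needs the readxl package). The table must have a header row and
#' an id column; all other columns must be numeric or empty (empty cells
#' become missing values, rendered blank on glyphs). Decimal separator is
#' `"."`; thousands separators are rejected.
#'
#' @param path input file.
#' @param id name or description shown in legends (defaults to the file
#'   base name).
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"xlsx"`.
#' @param id_column name of the identifier column (default: first column).
#' @param kind `"auto"` (single if exactly one value column), `"single"`
#'   or `"array"`.
#' @param style visualisation style: one of the registered styles
#'   (built-ins: heatmap, bar, line, timeseries, scatter). Line, scatter
#'   and timeseries require `kind = "array"`.
#' @param name,description shown in the legend.
#' @param sheet optional xlsx sheet name.
#' @return a `gn_dataset`: fields `id`, `name`, `description`, `kind`,
#'   `headers`, `values` (tibble with an `id` column plus one numeric
#'   column per header) and `style`, plus a default [color_scale()].
#' @export
read_omics_table <- function(path, id = NULL,
                             format = c("auto", "csv", "tsv", "xlsx"),
                             id_column = NULL, kind = c("auto", "single", "array"),
                             style = "heatmap", name = NULL,
                             description = "", sheet = NULL) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(paste0("data file not found: ", path), class = "gn_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx",
                     abort(paste0("cannot infer format from extension: ",
                                  ext), class = "gn_io_error"))
  }
  raw <- switch(
    format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("xlsx input needs the readxl package", class = "gn_io_error")
      }
      df <- readxl::read_excel(path, sheet = sheet %||% 1,
                               col_types = "text")
      as_tibble(df)
    }
  )
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort("data table needs at least one row and one value column",
          class = "gn_io_error")
  }
  id_column <- id_column %||% names(raw)[[1]]
  if (!id_column %in% names(raw)) {
    abort(paste0("id column '", id_column, "' not found (columns: ",
                 paste(names(raw), collapse = ", "), ")"),
          class = "gn_io_error")
  }
  ids <- as.character(raw[[id_column]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate node id(s) in ", path, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "gn_validation_error")
  }
  headers <- setdiff(names(raw), id_column)
  vals <- raw[headers]
  for (h in headers) {
    x <- trimws(vals[[h]])
    x[!nzchar(x)] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                    x[bad[[1]]], bad[[1]], h, path),
            class = "gn_validation_error")
    }
    vals[[h]] <- num
  }
  if (!any(!is.na(as.matrix(vals)))) {
    abort(paste0("dataset has no non-missing values: ", path),
          class = "gn_validation_error")
  }
  new_dataset(
    id = id %||% tools::file_path_sans_ext(basename(path)),
    values = dplyr::bind_cols(tibble(id = ids), vals),
    kind = kind, style = style, name = name, description = description)
}

#' Construct a dataset from an in-memory table
#'
#' @param id dataset identifier (unique among registered datasets).
#' @param values tibble with an `id` column and numeric value columns.
#' @param kind,style,name,description see [read_omics_table()].
#' @param scale optional [color_scale()]; computed from the values when
#'   absent.
#' @return a `gn_dataset`.
#' @export
new_dataset <- function(id, values, kind = "auto", style = "heatmap",
                        name = NULL, description = "", scale = NULL) {
  values <- as_tibble(values)
  headers <- setdiff(names(values), "id")
  if (!length(headers)) abort("dataset needs at least one value column")
  if (kind == "auto") kind <- if (length(headers) == 1) "single" else "array"
  if (kind == "single" && length(headers) != 1) {
    abort("kind 'single' requires exactly one value column")
  }
  if (style %in% c("line", "scatter", "timeseries") && kind != "array") {
    abort(paste0("style '", style, "' requires an array dataset"),
          class = "gn_validation_error")
  }
  vals <- as.matrix(values[headers])
  structure(list(
    id = id, name = name %||% id, description = description,
    kind = kind, headers = headers, values = values, style = style,
    scale = scale %||% color_scale(vals)
  ), class = "gn_dataset")
}

#' @export
print.gn_dataset <- function(x, ...) {
  cat(sprintf("<gn_dataset> %s [%s/%s]: %d node(s) x %d column(s)\n",
              x$id, x$kind, x$style, nrow(x$values), length(x$headers)))
  invisible(x)
}

#' Long-format view of a dataset
#'
#' @param x a `gn_dataset`.
#' @param ... unused.
#' @return a tibble with `id`, `column`, `value`.
#' @export
tidy.gn_dataset <- function(x, ...) {
  tidyr::pivot_longer(x$values, -"id", names_to = "column",
                      values_to = "value")
}

#' @export
glance.gn_dataset <- function(x, ...) {
  v <- as.matrix(x$values[x$headers])
  tibble(id = x$id, kind = x$kind, style = x$style,
         n_nodes = nrow(x$values), n_columns = length(x$headers),
         missing_rate = mean(is.na(v)))
}

#' Heatmap view of a dataset
#'
#' @param object a `gn_dataset`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gn_dataset <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = factor(.data$column,
                                          levels = object$headers),
                               y = .data$id, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#FFFFFF",
                                  high = "#B2182B", na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, title = object$name)
}

#' Colour scale for glyph rendering
#'
#' Diverging (blue-white-red, symmetric around 0) when the data carry
#' both signs, sequential (white to red) otherwise; 256 quantised steps,
#' linear interpolation in RGB. Missing values always render blank
#' (white).
#'
#' @param values numeric vector/matrix used to fix the domain, or NULL if
#'   `domain` is given.
#' @param mode `"auto"`, `"sequential"` or `"diverging"`.
#' @param domain optional `(min, max)` or `(min, mid, max)`.
#' @return a `gn_color_scale` with `mode`, `domain`, a 256-colour
#'   `palette` and `missing_color = "#FFFFFF"`.
#' @export
color_scale <- function(values = NULL,
                        mode = c("auto", "sequential", "diverging"),
                        domain = NULL) {
  mode <- match.arg(mode)
  if (is.null(domain)) {
    v <- values[is.finite(values)]
    if (!length(v)) v <- c(0, 1)
    lo <- min(v); hi <- max(v)
    if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
    if (mode == "auto") {
      mode <- if (lo < 0 && hi > 0) "diverging" else "sequential"
    }
    if (mode == "diverging") {
      a <- max(abs(lo), abs(hi))
      domain <- c(-a, 0, a)
    } else {
      domain <- c(lo, hi)
    }
  } else {
    if (mode == "auto") {
      mode <- if (length(domain) == 3) "diverging" else "sequential"
    }
  }
  if (mode == "diverging") {
    if (length(domain) == 2) domain <- c(domain[1], mean(domain), domain[2])
    if (!(domain[1] < domain[2] && domain[2] < domain[3])) {
      abort("diverging scale needs min < mid < max")
    }
    pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(256)
  } else {
    if (length(domain) != 2 || domain[1] >= domain[2]) {
      abort("sequential scale needs domain (min, max) with min < max")
    }
    pal <- grDevices::colorRampPalette(c("#FFFFFF", "#B2182B"))(256)
  }
  structure(list(mode = mode, domain = domain, palette = pal,
                 missing_color = "#FFFFFF"), class = "gn_color_scale")
}

#' Map values to scale colours
#'
#' @param scale a `gn_color_scale`.
#' @param values numeric vector.
#' @return character vector of hex colours; missing values get the
#'   scale's missing colour.
#' @export
scale_color_of <- function(scale, values) {
  lo <- scale$domain[[1]]
  hi <- scale$domain[[length(scale$domain)]]
  f <- (values - lo) / (hi - lo)
  f <- pmin(pmax(f, 0), 1)
  idx <- pmin(255L, as.integer(floor(f * 256))) + 1L
  out <- scale$palette[idx]
  out[is.na(values)] <- scale$missing_color
  out
}

data_key <- function(net, ids) {
  did <- node_attribute(net, ids, "data_id")
  ifelse(is.na(did), ids, did)
}

#' Match a dataset against a network
#'
#' Matching is by node id with a fallback to the `data_id` attribute
#' carried by duplication replicates, so data mapped under an original
#' id reaches every replicate.
#'
#' @param ds a `gn_dataset`.
#' @param net a `gn_network`.
#' @return a `gn_coverage` list with matched node ids, dataset ids
#'   missing from the network (`unmatched_dataset`), network nodes with
#'   no data (`dataless_network`), and the corresponding counts.
#' @export
match_nodes <- function(ds, net) {
  assert_network(net)
  keys <- data_key(net, net$nodes$id)
  hit <- keys %in% ds$values$id
  matched <- net$nodes$id[hit]
  structure(list(
    dataset = ds$id,
    matched = matched,
    unmatched_dataset = sort(setdiff(ds$values$id, keys)),
    dataless_network = net$nodes$id[!hit],
    n_matched = length(matched),
    n_unmatched_dataset = length(setdiff(ds$values$id, keys)),
    n_dataless_network = sum(!hit)
  ), class = "gn_coverage")
}

#' @export
print.gn_coverage <- function(x, ...) {
  cat(sprintf("<gn_coverage> %s: %d matched, %d dataset id(s) unmatched, %d network node(s) without data\n",
              x$dataset, x$n_matched, x$n_unmatched_dataset,
              x$n_dataless_network))
  invisible(x)
}

# values of `ds` for one network node (via data_id fallback); NULL if absent
dataset_values_for <- function(ds, net, node_id) {
  key <- data_key(net, node_id)
  i <- match(key, ds$values$id)
  if (is.na(i)) return(NULL)
  as.numeric(ds$values[i, ds$headers])
}

#' Derive node-type signatures from data availability
#'
#' A node type is the set of datasets available for a node; it determines
#' the node's glyph layout and legend. In `uniform` mode every node with
#' any data gets the same node type containing all datasets (unknown
#' information renders blank); in `per_subset` mode one node type is
#' created per distinct non-empty data-presence pattern. Nodes with no
#' data in any dataset appear in no signature and get no image.
#'
#' @param datasets list of `gn_dataset` (registration order fixes glyph
#'   and legend order).
#' @param net a `gn_network`.
#' @param mode `"uniform"` or `"per_subset"`.
#' @return a list of `gn_signature` objects (`id`, `dataset_ids`,
#'   `members` sorted), ordered by first dataset appearance.
#' @export
derive_node_types <- function(datasets, net, mode = c("uniform", "per_subset")) {
  mode <- match.arg(mode)
  if (!length(datasets)) abort("need at least one dataset")
  ds_ids <- vapply(datasets, function(d) d$id, character(1))
  if (anyDuplicated(ds_ids)) abort("dataset ids must be unique")
  keys <- data_key(net, net$nodes$id)
  presence <- vapply(datasets, function(d) {
    nonmiss <- d$values$id[rowSums(!is.na(d$values[d$headers])) > 0]
    keys %in% nonmiss
  }, logical(nrow(net$nodes)))
  presence <- matrix(presence, nrow = nrow(net$nodes),
                     dimnames = list(net$nodes$id, ds_ids))
  any_data <- rowSums(presence) > 0
  if (mode == "uniform") {
    sigs <- list(new_signature(ds_ids, sort(net$nodes$id[any_data])))
  } else {
    pat <- apply(presence, 1, function(r) paste(ds_ids[r], collapse = "\r"))
    pat <- pat[any_data]
    ids <- net$nodes$id[any_data]
    # order patterns by dataset registration order of their first dataset,
    # then by pattern string for determinism
    upat <- unique(pat)
    key <- vapply(strsplit(upat, "\r", fixed = TRUE), function(p) {
      sprintf("%04d|%s", min(match(p, ds_ids)), paste(p, collapse = "+"))
    }, character(1))
    upat <- upat[order(key)]
    sigs <- lapply(upat, function(p) {
      new_signature(strsplit(p, "\r", fixed = TRUE)[[1]],
                    sort(ids[pat == p]))
    })
  }
  sigs
}

new_signature <- function(dataset_ids, members) {
  structure(list(
    id = paste(dataset_ids, collapse = "+"),
    dataset_ids = dataset_ids,
    members = members
  ), class = "gn_signature")
}

#' @export
print.gn_signature <- function(x, ...) {
  cat(sprintf("<gn_signature> %s: %d member node(s)\n", x$id,
              length(x$members)))
  invisible(x)
}
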