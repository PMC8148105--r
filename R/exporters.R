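# Flat formats join multi-valued subsystems with ";"; ";" inside a
# subsystem name is escaped to "," so the join stays reversible.
subsys_join <- function(x) {
  paste(gsub(";", ",", x, fixed = TRUE), collapse = ";")
}

subsys_split <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Write a network to GraphML
#'
#' Node class, label, compartment, SBO term, duplication group,
#' subsystems (joined with `";"`) and every entry of the free-form
#' attribute map get their own typed GraphML key, as do edge role,
#' direction and edge attributes; [read_graphml()] restores them exactly.
#'
#' @param net a `gn_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  assert_network(net)
  n_attr <- sort(unique(unlist(lapply(net$nodes$attributes, names))))
  e_attr <- sort(unique(unlist(lapply(net$edges$attributes, names))))
  esc <- xml_escape
  key_line <- function(id, dom, name) {
    sprintf('  <key id="%s" for="%s" attr.name="%s" attr.type="string"/>',
            esc(id), dom, esc(name))
  }
  keys <- c(
    key_line("label", "node", "label"),
    key_line("node_class", "node", "node_class"),
    key_line("compartment", "node", "compartment"),
    key_line("sbo_term", "node", "sbo_term"),
    key_line("duplication_group", "node", "duplication_group"),
    key_line("subsystems", "node", "subsystems"),
    vapply(n_attr, function(a) key_line(paste0("na_", a), "node", a),
           character(1)),
    key_line("role", "edge", "role"),
    key_line("directed", "edge", "directed"),
    vapply(e_attr, function(a) key_line(paste0("ea_", a), "edge", a),
           character(1))
  )
  dat <- function(key, val) {
    sprintf('      <data key="%s">%s</data>', esc(key), esc(val))
  }
  node_xml <- vapply(seq_len(nrow(net$nodes)), function(i) {
    nd <- net$nodes[i, ]
    lines <- c(
      sprintf('    <node id="%s">', esc(nd$id)),
      dat("label", nd$label),
      dat("node_class", nd$node_class),
      if (!is.na(nd$compartment)) dat("compartment", nd$compartment),
      if (!is.na(nd$sbo_term)) dat("sbo_term", nd$sbo_term),
      if (!is.na(nd$duplication_group))
        dat("duplication_group", nd$duplication_group),
      if (length(nd$subsystems[[1]]))
        dat("subsystems", subsys_join(nd$subsystems[[1]])),
      vapply(names(nd$attributes[[1]]), function(a) {
        dat(paste0("na_", a), nd$attributes[[1]][[a]])
      }, character(1)),
      "    </node>")
    paste(lines, collapse = "\n")
  }, character(1))
  edge_xml <- vapply(seq_len(nrow(net$edges)), function(i) {
    ed <- net$edges[i, ]
    lines <- c(
      sprintf('    <edge source="%s" target="%s">', esc(ed$source),
              esc(ed$target)),
      dat("role", ed$role),
      dat("directed", if (ed$directed) "true" else "false"),
      vapply(names(ed$attributes[[1]]), function(a) {
        dat(paste0("ea_", a), ed$attributes[[1]][[a]])
      }, character(1)),
      "    </edge>")
    paste(lines, collapse = "\n")
  }, character(1))
  doc <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keys,
    sprintf('  <graph id="%s" edgedefault="directed">', esc(net$name)),
    node_xml, edge_xml,
    "  </graph>", "</graphml>", ""), collapse = "\n")
  writeLines(doc, path, sep = "")
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path a GraphML file.
#' @return a `gn_network`.
#' @export
read_graphml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("malformed GraphML: ", conditionMessage(e)),
          class = "gn_io_error")
  })
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_name <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
  graph <- xml2::xml_find_first(doc, ".//graph")
  net <- network(xml2::xml_attr(graph, "id") %||% "network")
  data_map <- function(el) {
    ds <- xml2::xml_find_all(el, "./data")
    stats::setNames(xml2::xml_text(ds), xml2::xml_attr(ds, "key"))
  }
  nodes_xml <- xml2::xml_find_all(graph, "./node")
  if (length(nodes_xml)) {
    rows <- lapply(nodes_xml, function(el) {
      d <- data_map(el)
      extra <- d[startsWith(names(d), "na_")]
      tibble(
        id = xml2::xml_attr(el, "id"),
        label = if ("label" %in% names(d)) d[["label"]] else NA_character_,
        node_class = if ("node_class" %in% names(d)) d[["node_class"]]
                     else "other",
        compartment = if ("compartment" %in% names(d)) d[["compartment"]]
                      else NA_character_,
        sbo_term = if ("sbo_term" %in% names(d)) d[["sbo_term"]]
                   else NA_character_,
        duplication_group = if ("duplication_group" %in% names(d))
          d[["duplication_group"]] else NA_character_,
        subsystems = list(if ("subsystems" %in% names(d))
          subsys_split(d[["subsystems"]]) else character()),
        attributes = list(stats::setNames(unname(extra),
                                          substring(names(extra), 4)))
      )
    })
    net <- add_nodes(net, dplyr::bind_rows(rows))
  }
  edges_xml <- xml2::xml_find_all(graph, "./edge")
  if (length(edges_xml)) {
    rows <- lapply(edges_xml, function(el) {
      d <- data_map(el)
      extra <- d[startsWith(names(d), "ea_")]
      tibble(
        source = xml2::xml_attr(el, "source"),
        target = xml2::xml_attr(el, "target"),
        role = if ("role" %in% names(d)) d[["role"]] else "link",
        directed = !identical(d[["directed"]], "false"),
        attributes = list(stats::setNames(unname(extra),
                                          substring(names(extra), 4)))
      )
    })
    net <- add_edges(net, dplyr::bind_rows(rows))
  }
  net
}

#' Write a network as Cytoscape.js JSON
#'
#' Produces the `elements.nodes` / `elements.edges` structure importable
#' by Cytoscape 3.x. All node and edge fields, subsystems and the
#' attribute maps are kept in the `data` objects; an optional image
#' manifest adds a `data.image` path per node.
#'
#' @param net a `gn_network`.
#' @param path output file.
#' @param image_manifest optional `nodes` tibble from [export_images()]
#'   (columns node_id and svg/png) used to attach image paths.
#' @return `path`, invisibly.
#' @export
write_cyjs <- function(net, path, image_manifest = NULL) {
  assert_network(net)
  img <- character()
  if (!is.null(image_manifest) && nrow(image_manifest)) {
    pick <- dplyr::coalesce(image_manifest$svg,
                            if ("png" %in% names(image_manifest))
                              image_manifest$png else NA_character_)
    img <- stats::setNames(pick, image_manifest$node_id)
  }
  nodes <- lapply(seq_len(nrow(net$nodes)), function(i) {
    nd <- net$nodes[i, ]
    d <- list(id = nd$id, label = nd$label, node_class = nd$node_class)
    if (!is.na(nd$compartment)) d$compartment <- nd$compartment
    if (!is.na(nd$sbo_term)) d$sbo_term <- nd$sbo_term
    if (!is.na(nd$duplication_group)) {
      d$duplication_group <- nd$duplication_group
    }
    if (length(nd$subsystems[[1]])) d$subsystems <- as.list(nd$subsystems[[1]])
    a <- nd$attributes[[1]]
    if (length(a)) d$attributes <- as.list(a)
    if (nd$id %in% names(img) && !is.na(img[[nd$id]])) {
      d$image <- img[[nd$id]]
    }
    list(data = d)
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(i) {
    ed <- net$edges[i, ]
    d <- list(id = paste0("e", i), source = ed$source, target = ed$target,
              role = ed$role, directed = ed$directed)
    a <- ed$attributes[[1]]
    if (length(a)) d$attributes <- as.list(a)
    list(data = d)
  })
  jsonlite::write_json(
    list(format_version = "1.0", generated_by = "glyphnet",
         data = list(name = net$name),
         elements = list(nodes = nodes, edges = edges)),
    path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a Cytoscape.js JSON file written by [write_cyjs()]
#'
#' @param path a .cyjs file.
#' @return a `gn_network`.
#' @export
read_cyjs <- function(path) {
  js <- tryCatch(jsonlite::read_json(path), error = function(e) {
    abort(paste0("malformed CYJS: ", conditionMessage(e)),
          class = "gn_io_error")
  })
  net <- network(js$data$name %||% "network")
  nodes <- js$elements$nodes
  if (length(nodes)) {
    rows <- lapply(nodes, function(el) {
      d <- el$data
      tibble(
        id = d$id, label = d$label %||% d$id,
        node_class = d$node_class %||% "other",
        compartment = d$compartment %||% NA_character_,
        sbo_term = d$sbo_term %||% NA_character_,
        duplication_group = d$duplication_group %||% NA_character_,
        subsystems = list(unlist(d$subsystems) %||% character()),
        attributes = list(stats::setNames(
          as.character(unlist(d$attributes) %||% character()),
          names(d$attributes)))
      )
    })
    net <- add_nodes(net, dplyr::bind_rows(rows))
  }
  edges <- js$elements$edges
  if (length(edges)) {
    rows <- lapply(edges, function(el) {
      d <- el$data
      tibble(source = d$source, target = d$target,
             role = d$role %||% "link",
             directed = isTRUE(d$directed),
             attributes = list(stats::setNames(
               as.character(unlist(d$attributes) %||% character()),
               names(d$attributes))))
    })
    net <- add_edges(net, dplyr::bind_rows(rows))
  }
  net
}

#' Write a network in SIF format
#'
#' One line per edge, `source<TAB>role<TAB>target`; isolated nodes are
#' listed alone on their own line.
#'
#' @param net a `gn_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  assert_network(net)
  ids <- c(net$nodes$id, net$edges$source, net$edges$target)
  if (any(grepl("\t", ids, fixed = TRUE))) {
    abort("node ids containing tabs cannot be written to SIF",
          class = "gn_io_error")
  }
  lines <- character()
  if (nrow(net$edges)) {
    lines <- sprintf("%s\t%s\t%s", net$edges$source, net$edges$role,
                     net$edges$target)
  }
  isolated <- setdiff(net$nodes$id, c(net$edges$source, net$edges$target))
  lines <- c(lines, isolated)
  writeLines(lines, path)
  invisible(path)
}

#' Export a subnetwork decomposition
#'
#' Writes one file per subnetwork plus the navigation map from
#' [subnetwork_graph()]. When `qualify_bridges` is set, bridge-class
#' node copies get `"<id>@<group>"` ids in the written files while the
#' `data_id` attribute keeps the original id for data mapping.
#'
#' @param subs result of [split_network()].
#' @param out_dir output directory.
#' @param format `"graphml"`, `"cyjs"` or `"sif"`.
#' @param qualify_bridges suffix bridge/linker-adjacent node copies with
#'   their group.
#' @return tibble of written files, invisibly.
#' @export
export_subnetworks <- function(subs, out_dir, format = c("graphml", "cyjs",
                                                         "sif"),
                               qualify_bridges = FALSE) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- attr(subs, "config")
  writer <- switch(format, graphml = write_graphml, cyjs = write_cyjs,
                   sif = write_sif)
  ext <- switch(format, graphml = "graphml", cyjs = "cyjs", sif = "sif")
  rows <- lapply(subs, function(s) {
    net <- s$net
    if (qualify_bridges && !is.null(config)) {
      bridge <- net$nodes$id[net$nodes$node_class ==
                               config$bipartition$bridge_class]
      if (length(bridge)) {
        net <- set_node_attributes(net, bridge, attrs = character())
        for (b in bridge) {
          a <- net$nodes$attributes[[match(b, net$nodes$id)]]
          if (!"data_id" %in% names(a)) {
            net <- set_node_attributes(net, b, attrs = c(data_id = b))
          }
        }
        new_ids <- stats::setNames(paste0(bridge, "@", s$group), bridge)
        net$nodes$id <- dplyr::recode(net$nodes$id, !!!as.list(new_ids))
        net$edges$source <- dplyr::recode(net$edges$source,
                                          !!!as.list(new_ids))
        net$edges$target <- dplyr::recode(net$edges$target,
                                          !!!as.list(new_ids))
      }
    }
    f <- file.path(out_dir, paste0("subnetwork_", safe_filename(s$group),
                                   ".", ext))
    writer(net, f)
    tibble(group = s$group, file = f)
  })
  meta <- subnetwork_graph(subs)
  meta_file <- file.path(out_dir, paste0("subnetwork_map.", ext))
  writer(meta, meta_file)
  out <- dplyr::bind_rows(c(rows, list(tibble(group = "(map)",
                                              file = meta_file))))
  invisible(out)
}
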