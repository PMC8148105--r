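#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

NODE_CLASSES <- c("species", "reaction", "gene", "protein", "linker", "other")
EDGE_ROLES <- c("substrate", "product", "modifier", "catalyzes", "encodes",
                "gpr", "link")

empty_node_tbl <- function() {
  tibble(
    id = character(), label = character(), node_class = character(),
    compartment = character(), sbo_term = character(),
    duplication_group = character(),
    subsystems = list(), attributes = list()
  )
}

empty_edge_tbl <- function() {
  tibble(source = character(), target = character(), role = character(),
         directed = logical(), attributes = list())
}

#' Create an empty typed network
#'
#' A glyphnet network is a typed multi-partite graph holding species,
#' reaction, gene, protein and linker nodes as a node tibble and an edge
#' tibble. Edges carry a role (substrate, product, modifier, catalyzes,
#' encodes, gpr, link); direction is stored but degree and subnetwork
#' logic treat the graph as undirected.
#'
#' @param name network name.
#' @return An object of class `gn_network` with components `name`,
#'   `nodes` (tibble), `edges` (tibble) and `duplications` (named list of
#'   duplication records, see [duplicate_node()]).
#' @export
#' @examples
#' net <- network("toy") |>
#'   add_node("A", node_class = "species") |>
#'   add_node("R1", node_class = "reaction") |>
#'   add_edge("A", "R1", role = "substrate")
#' net
network <- function(name = "network") {
  structure(
    list(name = name, nodes = empty_node_tbl(), edges = empty_edge_tbl(),
         duplications = list()),
    class = "gn_network"
  )
}

#' Build a network from node and edge tibbles
#'
#' @param nodes a data frame with at least an `id` column; `label`,
#'   `node_class`, `compartment`, `sbo_term`, `duplication_group`,
#'   `subsystems` (list of character) and `attributes` (list of named
#'   character) are filled with defaults when absent.
#' @param edges a data frame with `source`, `target` and `role` columns;
#'   `directed` defaults to `TRUE`.
#' @param name network name.
#' @return a `gn_network`.
#' @export
as_network <- function(nodes, edges = NULL, name = "network") {
  net <- network(name)
  net <- add_nodes(net, nodes)
  if (!is.null(edges) && nrow(edges) > 0) net <- add_edges(net, edges)
  net
}

is_network <- function(x) inherits(x, "gn_network")

assert_network <- function(net) {
  if (!is_network(net)) abort("expected a gn_network object")
  invisible(net)
}

normalise_nodes <- function(nodes) {
  nodes <- as_tibble(nodes)
  if (!"id" %in% names(nodes)) abort("node table needs an `id` column")
  n <- nrow(nodes)
  nodes$id <- as.character(nodes$id)
  if (any(!nzchar(nodes$id)) || anyNA(nodes$id)) {
    abort("node ids must be non-empty strings")
  }
  if (!"label" %in% names(nodes)) nodes$label <- nodes$id
  nodes$label <- dplyr::coalesce(as.character(nodes$label), nodes$id)
  if (!"node_class" %in% names(nodes)) nodes$node_class <- "other"
  nodes$node_class <- dplyr::coalesce(as.character(nodes$node_class), "other")
  bad <- setdiff(unique(nodes$node_class), NODE_CLASSES)
  if (length(bad)) abort(paste0("unknown node_class: ", paste(bad, collapse = ", ")))
  for (col in c("compartment", "sbo_term", "duplication_group")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
    nodes[[col]] <- as.character(nodes[[col]])
  }
  if (!"subsystems" %in% names(nodes)) {
    nodes$subsystems <- rep(list(character()), n)
  }
  nodes$subsystems <- lapply(nodes$subsystems, function(s) {
    if (is.null(s) || all(is.na(s))) character() else as.character(s)
  })
  if (!"attributes" %in% names(nodes)) {
    nodes$attributes <- rep(list(character()), n)
  }
  nodes$attributes <- lapply(nodes$attributes, function(a) {
    if (is.null(a) || length(a) == 0) {
      stats::setNames(character(), character())
    } else {
      stats::setNames(as.character(a), names(a))
    }
  })
  nodes[, names(empty_node_tbl())]
}

#' Add nodes to a network
#'
#' @param net a `gn_network`.
#' @param nodes data frame of nodes (see [as_network()] for columns).
#' @return the updated network.
#' @export
add_nodes <- function(net, nodes) {
  assert_network(net)
  nodes <- normalise_nodes(nodes)
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    abort(paste0("duplicate node id(s): ", paste(dup, collapse = ", ")))
  }
  clash <- intersect(nodes$id, net$nodes$id)
  if (length(clash)) {
    abort(paste0("node id(s) already present: ", paste(clash, collapse = ", ")))
  }
  net$nodes <- dplyr::bind_rows(net$nodes, nodes)
  net
}

#' Add a single node
#'
#' @inheritParams add_nodes
#' @param id,label,node_class,compartment,sbo_term node fields.
#' @param subsystems character vector of pathway memberships.
#' @param attributes named character vector of free-form attributes.
#' @return the updated network.
#' @export
add_node <- function(net, id, label = id, node_class = "other",
                     compartment = NA_character_, sbo_term = NA_character_,
                     subsystems = character(), attributes = character()) {
  add_nodes(net, tibble(
    id = id, label = label, node_class = node_class,
    compartment = compartment, sbo_term = sbo_term,
    subsystems = list(subsystems), attributes = list(attributes)
  ))
}

normalise_edges <- function(edges) {
  edges <- as_tibble(edges)
  for (col in c("source", "target", "role")) {
    if (!col %in% names(edges)) abort(paste0("edge table needs a `", col, "` column"))
    edges[[col]] <- as.character(edges[[col]])
  }
  bad <- setdiff(unique(edges$role), EDGE_ROLES)
  if (length(bad)) abort(paste0("unknown edge role: ", paste(bad, collapse = ", ")))
  if (!"directed" %in% names(edges)) edges$directed <- TRUE
  edges$directed <- as.logical(edges$directed)
  if (!"attributes" %in% names(edges)) {
    edges$attributes <- rep(list(character()), nrow(edges))
  }
  edges$attributes <- lapply(edges$attributes, function(a) {
    if (is.null(a) || length(a) == 0) {
      stats::setNames(character(), character())
    } else {
      stats::setNames(as.character(a), names(a))
    }
  })
  edges[, names(empty_edge_tbl())]
}

#' Add edges to a network
#'
#' Identical (source, target, role) triples are collapsed to one edge;
#' parallel edges with distinct roles are kept (a metabolite may be both
#' substrate and product of one reaction). Self-loops are rejected.
#'
#' @param net a `gn_network`.
#' @param edges data frame with `source`, `target`, `role` and optionally
#'   `directed` and `attributes`.
#' @return the updated network.
#' @export
add_edges <- function(net, edges) {
  assert_network(net)
  edges <- normalise_edges(edges)
  loops <- edges$source == edges$target
  if (any(loops)) {
    abort(paste0("self-loops are not allowed: ",
                 paste(unique(edges$source[loops]), collapse = ", ")))
  }
  known <- net$nodes$id
  miss <- setdiff(unique(c(edges$source, edges$target)), known)
  if (length(miss)) {
    abort(paste0("edge endpoint(s) not in network: ", paste(miss, collapse = ", ")))
  }
  net$edges <- dplyr::bind_rows(net$edges, edges) |>
    dplyr::distinct(.data$source, .data$target, .data$role, .keep_all = TRUE)
  net
}

#' @rdname add_edges
#' @param source,target node ids.
#' @param role edge role.
#' @param directed logical.
#' @param attributes named character vector.
#' @export
add_edge <- function(net, source, target, role, directed = TRUE,
                     attributes = character()) {
  add_edges(net, tibble(source = source, target = target, role = role,
                        directed = directed, attributes = list(attributes)))
}

#' Remove nodes (and their incident edges)
#'
#' @param net a `gn_network`.
#' @param ids node ids to drop.
#' @return the updated network.
#' @export
remove_nodes <- function(net, ids) {
  assert_network(net)
  net$nodes <- dplyr::filter(net$nodes, !.data$id %in% ids)
  net$edges <- dplyr::filter(net$edges,
                             !.data$source %in% ids & !.data$target %in% ids)
  net
}

#' Node and edge accessors
#'
#' @param net a `gn_network`.
#' @return a tibble of nodes or edges.
#' @export
network_nodes <- function(net) {
  assert_network(net)
  net$nodes
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  assert_network(net)
  net$edges
}

#' Degree of a node
#'
#' Counts incident edges once each, regardless of direction; matches the
#' undirected connectivity used by the subnetwork decomposition.
#'
#' @param net a `gn_network`.
#' @param node_id a single node id.
#' @return an integer.
#' @export
node_degree <- function(net, node_id) {
  assert_network(net)
  if (!node_id %in% net$nodes$id) abort(paste0("unknown node: ", node_id))
  sum(net$edges$source == node_id | net$edges$target == node_id)
}

#' Degrees of all nodes
#'
#' @param net a `gn_network`.
#' @return a tibble with `id` and `degree`, one row per node.
#' @export
degree_table <- function(net) {
  assert_network(net)
  inc <- c(net$edges$source, net$edges$target)
  counts <- table(factor(inc, levels = net$nodes$id))
  tibble(id = net$nodes$id, degree = as.integer(counts))
}

#' Neighbors of a node
#'
#' @param net a `gn_network`.
#' @param node_id a single node id.
#' @param roles optional character vector of edge roles to restrict to.
#' @return a character vector of adjacent node ids (no duplicates, sorted).
#' @export
node_neighbors <- function(net, node_id, roles = NULL) {
  assert_network(net)
  if (!node_id %in% net$nodes$id) abort(paste0("unknown node: ", node_id))
  e <- net$edges
  if (!is.null(roles)) e <- e[e$role %in% roles, , drop = FALSE]
  nb <- c(e$target[e$source == node_id], e$source[e$target == node_id])
  sort(unique(nb))
}

#' Check network invariants
#'
#' Full-scan validation of referential integrity, id uniqueness, absence
#' of self-loops and role typing (link edges touch a linker, gpr edges
#' join gene and reaction, encodes edges join gene and protein).
#'
#' @param net a `gn_network`.
#' @return a character vector of violations; empty when the network is
#'   consistent.
#' @export
validate_network <- function(net) {
  assert_network(net)
  out <- character()
  if (anyDuplicated(net$nodes$id)) out <- c(out, "duplicate node ids")
  known <- net$nodes$id
  e <- net$edges
  if (nrow(e)) {
    if (!all(e$source %in% known) || !all(e$target %in% known)) {
      out <- c(out, "edge endpoint not in node set")
    }
    if (any(e$source == e$target)) out <- c(out, "self-loop present")
    cls <- stats::setNames(net$nodes$node_class, net$nodes$id)
    sc <- cls[e$source]; tc <- cls[e$target]
    # link edges join a linker to its anchor, or two subnetwork-map nodes
    link <- e$role == "link"
    if (any(link & sc != "linker" & tc != "linker" &
              !(sc == "other" & tc == "other"), na.rm = TRUE)) {
      out <- c(out, "link edge not incident to a linker node")
    }
    gpr <- e$role == "gpr"
    if (any(gpr & !((sc == "gene" & tc == "reaction") |
                    (sc == "reaction" & tc == "gene")), na.rm = TRUE)) {
      out <- c(out, "gpr edge does not connect gene and reaction")
    }
    enc <- e$role == "encodes"
    if (any(enc & !((sc == "gene" & tc == "protein") |
                    (sc == "protein" & tc == "gene")), na.rm = TRUE)) {
      out <- c(out, "encodes edge does not connect gene and protein")
    }
  }
  out
}

#' Set or update node attributes
#'
#' @param net a `gn_network`.
#' @param ids node ids to update.
#' @param attrs named character vector merged into each node's attribute map.
#' @param label optional new label applied to all `ids`.
#' @return the updated network.
#' @export
set_node_attributes <- function(net, ids, attrs = character(), label = NULL) {
  assert_network(net)
  miss <- setdiff(ids, net$nodes$id)
  if (length(miss)) abort(paste0("unknown node: ", paste(miss, collapse = ", ")))
  idx <- match(ids, net$nodes$id)
  if (length(attrs)) {
    net$nodes$attributes[idx] <- lapply(net$nodes$attributes[idx], function(a) {
      a[names(attrs)] <- unname(attrs)
      a
    })
  }
  if (!is.null(label)) net$nodes$label[idx] <- label
  net
}

node_attribute <- function(net, ids, name) {
  idx <- match(ids, net$nodes$id)
  vapply(net$nodes$attributes[idx], function(a) {
    if (name %in% names(a)) a[[name]] else NA_character_
  }, character(1))
}

#' @export
print.gn_network <- function(x, ...) {
  cat(sprintf("<gn_network> %s: %d nodes, %d edges\n",
              x$name, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$node_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a network into its node table
#'
#' @param x a `gn_network`.
#' @param what `"nodes"` (default) or `"edges"`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gn_network <- function(x, what = c("nodes", "edges"), ...) {
  what <- match.arg(what)
  if (what == "nodes") x$nodes else x$edges
}

#' One-row network summary
#'
#' @param x a `gn_network`.
#' @param ... unused.
#' @return a one-row tibble with node/edge counts per class.
#' @export
glance.gn_network <- function(x, ...) {
  tibble(
    name = x$name,
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_species = sum(x$nodes$node_class == "species"),
    n_reactions = sum(x$nodes$node_class == "reaction"),
    n_genes = sum(x$nodes$node_class == "gene"),
    n_proteins = sum(x$nodes$node_class == "protein"),
    n_linkers = sum(x$nodes$node_class == "linker")
  )
}

as_igraph <- function(net, roles = NULL) {
  e <- net$edges
  if (!is.null(roles)) e <- e[e$role %in% roles, , drop = FALSE]
  igraph::graph_from_data_frame(
    d = e[, c("source", "target")],
    directed = FALSE,
    vertices = net$nodes["id"]
  )
}

#' Plot a network
#'
#' Quick-look ggplot of the graph using a deterministic
#' Fruchterman-Reingold layout, colored by node class.
#'
#' @param object a `gn_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gn_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  pts <- tibble(id = object$nodes$id, x = xy[, 1], y = xy[, 2],
                node_class = object$nodes$node_class)
  seg <- object$edges |>
    dplyr::left_join(pts, by = c(source = "id")) |>
    dplyr::left_join(pts, by = c(target = "id"), suffix = c("", "_t"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_t, yend = .data$y_t),
      color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$node_class),
      size = 2) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "class", title = object$name)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
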