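#' Replicate a highly connected node
#'
#' Highly connected co-factors (ATP, water, ...) induce hairball layouts.
#' Linked replication replaces such a node by one replicate per incident
#' edge (`per_edge`, default) or per distinct neighbor (`per_neighbor`).
#' Replicates share a `duplication_group` and carry the original id in
#' the `data_id` attribute so omics glyphs render identically on every
#' replicate without dataset changes. Replicates are treated as
#' non-branching by [split_network()]: a duplicated bridge node never
#' generates linkers. The duplication record needed by [remerge()] is
#' stored on the network (`net$duplications`).
#'
#' @param net a `gn_network`.
#' @param node_id id of the node to replicate (not a linker, not already
#'   a replicate).
#' @param mode `"per_edge"` or `"per_neighbor"`.
#' @return the updated network.
#' @export
#' @examples
#' net <- network() |>
#'   add_node("h2o", node_class = "species") |>
#'   add_node("R1", node_class = "reaction") |>
#'   add_node("R2", node_class = "reaction") |>
#'   add_edge("h2o", "R1", "substrate") |>
#'   add_edge("R2", "h2o", "product")
#' dup <- duplicate_node(net, "h2o")
#' network_nodes(dup)$id
#' network_nodes(remerge(dup, "h2o"))$id
duplicate_node <- function(net, node_id, mode = c("per_edge", "per_neighbor")) {
  assert_network(net)
  mode <- match.arg(mode)
  idx <- match(node_id, net$nodes$id)
  if (is.na(idx)) abort(paste0("unknown node: ", node_id))
  if (net$nodes$node_class[[idx]] == "linker") {
    abort("linker nodes cannot be duplicated")
  }
  if (!is.na(net$nodes$duplication_group[[idx]])) {
    abort(paste0("node ", node_id, " is already a replicate"))
  }
  if (node_id %in% names(net$duplications)) {
    abort(paste0("node ", node_id, " is already duplicated"))
  }
  orig_node <- net$nodes[idx, ]
  inc <- net$edges$source == node_id | net$edges$target == node_id
  orig_edges <- net$edges[inc, ]
  # deterministic edge order
  ord <- order(orig_edges$source, orig_edges$target, orig_edges$role)
  orig_edges <- orig_edges[ord, ]
  n_e <- nrow(orig_edges)
  if (mode == "per_edge") {
    part <- as.list(seq_len(max(n_e, 1L)))
    if (n_e == 0) part <- list(integer())
  } else {
    other <- ifelse(orig_edges$source == node_id,
                    orig_edges$target, orig_edges$source)
    part <- unname(split(seq_len(n_e), factor(other, levels = sort(unique(other)))))
    if (!length(part)) part <- list(integer())
  }
  group_id <- node_id
  rep_ids <- paste0(node_id, "#", seq_along(part))

  net <- remove_nodes(net, node_id)
  reps <- orig_node[rep(1L, length(rep_ids)), ]
  reps$id <- rep_ids
  reps$duplication_group <- group_id
  reps$attributes <- lapply(reps$attributes, function(a) {
    a[["data_id"]] <- node_id
    a
  })
  net <- add_nodes(net, reps)
  assignment <- list()
  for (k in seq_along(part)) {
    es <- orig_edges[part[[k]], ]
    assignment[[rep_ids[[k]]]] <- es
    if (nrow(es)) {
      es$source[es$source == node_id] <- rep_ids[[k]]
      es$target[es$target == node_id] <- rep_ids[[k]]
      net <- add_edges(net, es)
    }
  }
  net$duplications[[group_id]] <- list(
    group_id = group_id, original_id = node_id, replicate_ids = rep_ids,
    edge_assignment = assignment, node = orig_node, edges = orig_edges,
    mode = mode)
  net
}

#' Retrieve a duplication record
#'
#' @param net a `gn_network`.
#' @param group_id the duplication group (= the original node id).
#' @return the record stored by [duplicate_node()]: `group_id`,
#'   `original_id`, `replicate_ids`, `edge_assignment` (replicate id ->
#'   edge tibble) and mode.
#' @export
duplication_record <- function(net, group_id) {
  assert_network(net)
  rec <- net$duplications[[group_id]]
  if (is.null(rec)) abort(paste0("unknown duplication group: ", group_id))
  rec
}

#' Remerge a duplicated node
#'
#' Collapses the replicates of one duplication group back into a single
#' node with the original id, restoring the original incident edge set.
#' Attribute updates applied to the replicates (see
#' [propagate_attributes()]) survive the merge.
#'
#' @param net a `gn_network`.
#' @param group_id duplication group to collapse.
#' @return the updated network.
#' @export
remerge <- function(net, group_id) {
  rec <- duplication_record(net, group_id)
  merged <- rec$node
  first_rep <- sort(rec$replicate_ids)[[1]]
  ridx <- match(first_rep, net$nodes$id)
  if (!is.na(ridx)) {
    merged$label <- net$nodes$label[[ridx]]
    a <- net$nodes$attributes[[ridx]]
    a <- a[setdiff(names(a), "data_id")]
    merged$attributes <- list(a)
  }
  net <- remove_nodes(net, rec$replicate_ids)
  net <- add_nodes(net, merged)
  if (nrow(rec$edges)) net <- add_edges(net, rec$edges)
  net$duplications[[group_id]] <- NULL
  net
}

#' Propagate attributes across replicates of a duplication group
#'
#' Updating one replicate updates all of them: the given attributes (and
#' optional label) are applied to every replicate in the group.
#'
#' @param net a `gn_network`.
#' @param group_id duplication group.
#' @param attrs named character vector merged into each replicate's
#'   attribute map (may be empty).
#' @param label optional new display label for all replicates.
#' @return the updated network.
#' @export
propagate_attributes <- function(net, group_id, attrs = character(),
                                 label = NULL) {
  rec <- duplication_record(net, group_id)
  set_node_attributes(net, rec$replicate_ids, attrs = attrs, label = label)
}
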