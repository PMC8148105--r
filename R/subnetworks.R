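#' Define the bipartition of a network
#'
#' A bipartite decomposition needs one node class whose nodes carry the
#' grouping property and belong to subnetworks (the member class, e.g.
#' reactions grouped by pathway) and one class allowed to span
#' subnetworks (the bridge class, e.g. metabolites).
#'
#' @param member_class,bridge_class node classes, each `"species"` or
#'   `"reaction"`, and different from each other.
#' @param group_attribute where member nodes hold their group value(s):
#'   `"subsystems"` (list field), `"compartment"`, or the name of an
#'   entry in the node attribute map (split on `";"`).
#' @return a `gn_bipartition`.
#' @export
bipartition <- function(member_class = "reaction", bridge_class = "species",
                        group_attribute = "subsystems") {
  allowed <- c("species", "reaction")
  if (!member_class %in% allowed || !bridge_class %in% allowed) {
    abort("member_class and bridge_class must be 'species' or 'reaction'")
  }
  if (member_class == bridge_class) {
    abort("member_class and bridge_class must differ")
  }
  structure(list(member_class = member_class, bridge_class = bridge_class,
                 group_attribute = group_attribute),
            class = "gn_bipartition")
}

#' Configure a subnetwork split
#'
#' @param bipartition a [bipartition()].
#' @param removed_ids bridge-class node ids excluded from every
#'   subnetwork (abundant metabolites such as water or protons).
#' @param nonlink_ids bridge-class node ids kept inside subnetworks but
#'   never used to link between them (less abundant co-factors such as
#'   Coenzyme A).
#' @param include_companions should gene/protein nodes follow their
#'   adjacent member/bridge nodes into the subnetworks?
#' @param one_linker_per_group collapse linkers so each subnetwork holds
#'   at most one linker per foreign group (default keeps one linker per
#'   anchor/group pair, preserving where the connection leaves the
#'   pathway).
#' @return a `gn_split_config`.
#' @export
split_config <- function(bipartition = glyphnet::bipartition(),
                         removed_ids = character(),
                         nonlink_ids = character(),
                         include_companions = TRUE,
                         one_linker_per_group = FALSE) {
  if (!inherits(bipartition, "gn_bipartition")) {
    abort("bipartition must be created with bipartition()")
  }
  removed_ids <- unique(as.character(removed_ids))
  nonlink_ids <- unique(as.character(nonlink_ids))
  both <- intersect(removed_ids, nonlink_ids)
  if (length(both)) {
    abort(paste0("ids cannot be both removed and non-linking: ",
                 paste(both, collapse = ", ")), class = "gn_validation_error")
  }
  structure(list(bipartition = bipartition, removed_ids = removed_ids,
                 nonlink_ids = nonlink_ids,
                 include_companions = isTRUE(include_companions),
                 one_linker_per_group = isTRUE(one_linker_per_group)),
            class = "gn_split_config")
}

UNASSIGNED <- "(unassigned)"

# (member_id, group) pairs; members with no group value map to UNASSIGNED
member_groups <- function(net, bp) {
  members <- net$nodes[net$nodes$node_class == bp$member_class, ]
  vals <- switch(
    bp$group_attribute,
    subsystems = members$subsystems,
    compartment = lapply(members$compartment,
                         function(x) if (is.na(x)) character() else x),
    {
      a <- node_attribute(net, members$id, bp$group_attribute)
      lapply(a, function(x) {
        if (is.na(x)) character() else {
          v <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
          v[nzchar(v)]
        }
      })
    }
  )
  n <- lengths(vals)
  tibble(
    id = rep(members$id, pmax(n, 1L)),
    group = unlist(lapply(vals, function(v) if (length(v)) v else UNASSIGNED))
  )
}

# member-bridge edge view: one row per qualifying edge
member_bridge_edges <- function(net, bp) {
  cls <- stats::setNames(net$nodes$node_class, net$nodes$id)
  e <- net$edges
  sc <- unname(cls[e$source]); tc <- unname(cls[e$target])
  fwd <- sc == bp$member_class & tc == bp$bridge_class
  rev <- sc == bp$bridge_class & tc == bp$member_class
  tibble(
    member = c(e$source[fwd], e$target[rev]),
    bridge = c(e$target[fwd], e$source[rev])
  )
}

#' Suggest removed and non-linking node sets from connectivity
#'
#' Highly connected bridge-class nodes (abundant metabolites) are
#' candidates for removal; moderately connected ones for non-linking
#' status. Thresholds default to `max(30, 98th percentile)` and
#' `max(8, 90th percentile)` of the bridge-class degree distribution.
#'
#' @param net a `gn_network`.
#' @param bipartition a [bipartition()].
#' @param remove_threshold,nonlink_threshold optional integer overrides.
#' @return a `gn_suggestions` list with `removal_candidates` and
#'   `nonlink_candidates` tibbles (id, degree; sorted by descending
#'   degree) and the `thresholds` used.
#' @export
suggest_exclusions <- function(net, bipartition = glyphnet::bipartition(),
                               remove_threshold = NULL,
                               nonlink_threshold = NULL) {
  assert_network(net)
  bp <- bipartition
  deg <- degree_table(net)
  bridge <- net$nodes$id[net$nodes$node_class == bp$bridge_class]
  if (!length(bridge)) {
    abort(paste0("no nodes of bridge class '", bp$bridge_class,
                 "' in the network"), class = "gn_validation_error")
  }
  deg <- deg[deg$id %in% bridge, ]
  if (is.null(remove_threshold)) {
    remove_threshold <- max(30, stats::quantile(deg$degree, 0.98, names = FALSE))
  }
  if (is.null(nonlink_threshold)) {
    nonlink_threshold <- max(8, stats::quantile(deg$degree, 0.90, names = FALSE))
  }
  ord <- deg |> dplyr::arrange(dplyr::desc(.data$degree), .data$id)
  structure(list(
    removal_candidates = dplyr::filter(ord, .data$degree >= remove_threshold),
    nonlink_candidates = dplyr::filter(ord, .data$degree >= nonlink_threshold,
                                       .data$degree < remove_threshold),
    thresholds = c(remove_threshold = unname(remove_threshold),
                   nonlink_threshold = unname(nonlink_threshold))
  ), class = "gn_suggestions")
}

#' @export
print.gn_suggestions <- function(x, ...) {
  cat(sprintf("<gn_suggestions> remove >= %.6g (%d node(s)), non-link >= %.6g (%d node(s))\n",
              x$thresholds[["remove_threshold"]], nrow(x$removal_candidates),
              x$thresholds[["nonlink_threshold"]], nrow(x$nonlink_candidates)))
  invisible(x)
}

#' Decompose a bipartite network into linked subnetworks
#'
#' Each distinct group value of the member class yields one subnetwork
#' containing: the member nodes of that group; every non-removed
#' bridge-class node adjacent to them, with the connecting edges;
#' companion gene/protein nodes adjacent to included nodes (when
#' configured); and linker nodes. A linker is created for every included
#' bridge node that is neither non-linking nor a duplication replicate
#' and that is adjacent (in the full network) to members of another
#' group: one linker per (bridge, foreign group) pair, labelled with the
#' foreign group's name and joined to its anchor bridge by a link edge.
#' Members without any group value are pooled into `"(unassigned)"`.
#' Removed nodes and their edges appear in no subnetwork.
#'
#' @param net a `gn_network`.
#' @param config a [split_config()].
#' @return a named list of `gn_subnetwork` objects (sorted by group),
#'   each with fields `group`, `net` (a `gn_network`) and `linkers`
#'   (tibble: id, label, home_group, target_group, anchor_id).
#' @export
split_network <- function(net, config = split_config()) {
  assert_network(net)
  if (!inherits(config, "gn_split_config")) {
    abort("config must be created with split_config()")
  }
  bp <- config$bipartition
  bridge_ids <- net$nodes$id[net$nodes$node_class == bp$bridge_class]
  bad <- setdiff(c(config$removed_ids, config$nonlink_ids), bridge_ids)
  if (length(bad)) {
    abort(paste0("removed/nonlink ids must be existing nodes of the bridge ",
                 "class: ", paste(bad, collapse = ", ")),
          class = "gn_validation_error")
  }
  mg <- member_groups(net, bp)
  if (nrow(mg) == 0 || all(mg$group == UNASSIGNED)) {
    abort(paste0("no group values found on ", bp$member_class,
                 " nodes; run extract_subsystems() or choose another ",
                 "group_attribute"), class = "gn_validation_error")
  }
  emb <- member_bridge_edges(net, bp)
  emb <- emb[!emb$bridge %in% config$removed_ids, , drop = FALSE]
  bridge_grp <- emb |>
    dplyr::inner_join(mg, by = c(member = "id"), relationship = "many-to-many") |>
    dplyr::distinct(.data$bridge, .data$group)
  dup_grp <- stats::setNames(net$nodes$duplication_group, net$nodes$id)
  gp_ids <- net$nodes$id[net$nodes$node_class %in% c("gene", "protein")]
  groups <- sort(unique(mg$group))

  subs <- lapply(groups, function(v) {
    members_v <- mg$id[mg$group == v]
    e_v <- emb[emb$member %in% members_v, , drop = FALSE]
    bridges_v <- sort(unique(e_v$bridge))
    included <- c(members_v, bridges_v)
    if (config$include_companions && length(gp_ids)) {
      repeat {
        nb <- net$edges[net$edges$source %in% included |
                          net$edges$target %in% included, ]
        cand <- intersect(unique(c(nb$source, nb$target)), gp_ids)
        new <- setdiff(cand, included)
        if (!length(new)) break
        included <- c(included, new)
      }
    }
    sub <- network(paste0(net$name, "::", v))
    sub <- add_nodes(sub, net$nodes[net$nodes$id %in% included, ])
    keep <- net$edges$source %in% included & net$edges$target %in% included
    if (any(keep)) sub <- add_edges(sub, net$edges[keep, ])

    # linkers: bridges adjacent to foreign groups, unless non-linking or
    # duplication replicates (replicates are non-branching by design)
    anchors <- setdiff(bridges_v, config$nonlink_ids)
    anchors <- anchors[is.na(dup_grp[anchors])]
    lk <- bridge_grp |>
      dplyr::filter(.data$bridge %in% anchors, .data$group != v) |>
      dplyr::arrange(.data$bridge, .data$group)
    if (nrow(lk)) {
      if (config$one_linker_per_group) {
        lk$linker_id <- paste0("linker:", lk$group)
      } else {
        lk$linker_id <- paste0("linker:", lk$bridge, "|", lk$group)
      }
      linker_nodes <- lk |>
        dplyr::group_by(.data$linker_id, .data$group) |>
        dplyr::summarise(anchor = paste(sort(.data$bridge), collapse = ";"),
                         .groups = "drop")
      sub <- add_nodes(sub, tibble(
        id = linker_nodes$linker_id,
        label = linker_nodes$group,
        node_class = "linker",
        attributes = lapply(seq_len(nrow(linker_nodes)), function(i) {
          c(home_group = v, target_group = linker_nodes$group[[i]],
            anchor = linker_nodes$anchor[[i]])
        })
      ))
      sub <- add_edges(sub, tibble(
        source = lk$bridge, target = lk$linker_id, role = "link",
        directed = FALSE))
    }
    structure(list(
      group = v, net = sub,
      linkers = tibble(id = if (nrow(lk)) lk$linker_id else character(),
                       label = if (nrow(lk)) lk$group else character(),
                       home_group = rep(v, nrow(lk)),
                       target_group = if (nrow(lk)) lk$group else character(),
                       anchor_id = if (nrow(lk)) lk$bridge else character())
    ), class = "gn_subnetwork")
  })
  names(subs) <- groups
  attr(subs, "config") <- config
  subs
}

#' @export
print.gn_subnetwork <- function(x, ...) {
  cat(sprintf("<gn_subnetwork> %s: %d nodes, %d edges, %d linker record(s)\n",
              x$group, nrow(x$net$nodes), nrow(x$net$edges), nrow(x$linkers)))
  invisible(x)
}

#' Tidy a subnetwork into its node table
#'
#' @param x a `gn_subnetwork`.
#' @param ... passed to [tidy.gn_network()].
#' @return a tibble.
#' @export
tidy.gn_subnetwork <- function(x, ...) tidy(x$net, ...)

#' Build the navigation map between subnetworks
#'
#' One node per subnetwork; an undirected edge joins two groups whenever
#' any linker connects them, with the anchor ids recorded on the edge.
#'
#' @param subs the list returned by [split_network()].
#' @return a `gn_network` whose nodes are subnetwork groups.
#' @export
subnetwork_graph <- function(subs) {
  groups <- vapply(subs, function(s) s$group, character(1))
  meta <- network("subnetwork map")
  meta <- add_nodes(meta, tibble(
    id = unname(groups), node_class = "other",
    attributes = rep(list(c(kind = "subnetwork")), length(groups))))
  lks <- dplyr::bind_rows(lapply(subs, function(s) s$linkers))
  if (nrow(lks)) {
    pairs <- lks |>
      dplyr::mutate(a = pmin(.data$home_group, .data$target_group),
                    b = pmax(.data$home_group, .data$target_group)) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(
        anchors = paste(sort(unique(.data$anchor_id)), collapse = ";"),
        .groups = "drop")
    meta <- add_edges(meta, tibble(
      source = pairs$a, target = pairs$b, role = "link", directed = FALSE,
      attributes = lapply(pairs$anchors, function(a) c(anchors = a))))
  }
  meta
}

#' Validate a subnetwork decomposition
#'
#' Re-checks the decomposition contract against the original network:
#' removed nodes absent everywhere; every member node present in exactly
#' the subnetworks of its groups; every surviving member-bridge edge in
#' exactly the subnetworks of its member endpoint; linker symmetry
#' (a linker home v / target w / anchor b implies its mirror) and linker
#' completeness (every qualifying bridge/foreign-group adjacency has its
#' linker); linker labels never name the home group; anchors present and
#' not non-linking.
#'
#' @param net the original `gn_network`.
#' @param config the [split_config()] used.
#' @param subs the result of [split_network()].
#' @return a `gn_split_report` list with `ok` (logical) and `violations`
#'   (character vector).
#' @export
validate_split <- function(net, config, subs) {
  bp <- config$bipartition
  v <- character()
  groups <- vapply(subs, function(s) s$group, character(1))
  mg <- member_groups(net, bp)
  # removed nodes absent
  for (s in subs) {
    bad <- intersect(config$removed_ids, s$net$nodes$id)
    if (length(bad)) {
      v <- c(v, sprintf("removed node(s) %s present in subnetwork %s",
                        paste(bad, collapse = ","), s$group))
    }
  }
  # member coverage
  where <- dplyr::bind_rows(lapply(subs, function(s) {
    tibble(group = s$group,
           id = s$net$nodes$id[s$net$nodes$node_class == bp$member_class])
  }))
  expected <- mg |> dplyr::arrange(.data$id, .data$group)
  actual <- where |>
    dplyr::filter(.data$id %in% mg$id) |>
    dplyr::select("id", "group") |> dplyr::arrange(.data$id, .data$group)
  if (!identical(as.data.frame(expected[, c("id", "group")]),
                 as.data.frame(actual))) {
    v <- c(v, "member coverage differs from group assignment")
  }
  # member-class nodes must belong to their subnetwork's group
  for (s in subs) {
    ms <- s$net$nodes$id[s$net$nodes$node_class == bp$member_class]
    ok_ids <- mg$id[mg$group == s$group]
    bad <- setdiff(ms, ok_ids)
    if (length(bad)) {
      v <- c(v, sprintf("member(s) %s in subnetwork %s lack group %s",
                        paste(bad, collapse = ","), s$group, s$group))
    }
  }
  # edge conservation
  emb <- member_bridge_edges(net, bp)
  emb <- emb[!emb$bridge %in% config$removed_ids, , drop = FALSE]
  if (nrow(emb)) {
    emb_g <- emb |>
      dplyr::inner_join(mg, by = c(member = "id"),
                        relationship = "many-to-many")
    want_e <- unique(paste(emb_g$group, emb_g$member, emb_g$bridge,
                           sep = "\r"))
    have_e <- unlist(lapply(subs, function(s) {
      se <- member_bridge_edges(s$net, bp)
      if (nrow(se)) paste(s$group, se$member, se$bridge, sep = "\r")
      else character()
    }))
    have_e <- unique(have_e)
    if (length(setdiff(want_e, have_e))) {
      v <- c(v, sprintf("%d member-bridge edge placement(s) missing",
                        length(setdiff(want_e, have_e))))
    }
    if (length(setdiff(have_e, want_e))) {
      v <- c(v, sprintf("%d member-bridge edge(s) in a foreign subnetwork",
                        length(setdiff(have_e, want_e))))
    }
  }
  # linkers: symmetry and completeness
  lks <- dplyr::bind_rows(lapply(subs, function(s) s$linkers))
  have <- if (nrow(lks)) {
    paste(lks$home_group, lks$target_group, lks$anchor_id, sep = "\r")
  } else character()
  mirror <- if (nrow(lks)) {
    paste(lks$target_group, lks$home_group, lks$anchor_id, sep = "\r")
  } else character()
  miss <- setdiff(mirror, have)
  if (length(miss)) {
    v <- c(v, sprintf("linker symmetry violated for %d linker(s)",
                      length(miss)))
  }
  dup_grp <- stats::setNames(net$nodes$duplication_group, net$nodes$id)
  bridge_grp <- emb |>
    dplyr::inner_join(mg, by = c(member = "id"),
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$bridge, .data$group)
  qual <- bridge_grp |>
    dplyr::filter(!.data$bridge %in% config$nonlink_ids,
                  is.na(dup_grp[.data$bridge]))
  expected_lk <- qual |>
    dplyr::inner_join(qual, by = "bridge", relationship = "many-to-many") |>
    dplyr::filter(.data$group.x != .data$group.y)
  if (nrow(expected_lk)) {
    want <- paste(expected_lk$group.x, expected_lk$group.y,
                  expected_lk$bridge, sep = "\r")
    miss2 <- setdiff(want, have)
    if (length(miss2)) {
      v <- c(v, sprintf("%d expected linker(s) missing", length(miss2)))
    }
    extra <- setdiff(have, want)
    if (length(extra)) {
      v <- c(v, sprintf("%d unexpected linker(s) present", length(extra)))
    }
  } else if (nrow(lks)) {
    v <- c(v, "linkers present although none expected")
  }
  if (nrow(lks)) {
    if (any(lks$home_group == lks$target_group)) {
      v <- c(v, "linker targets its own home group")
    }
    if (any(lks$anchor_id %in% config$nonlink_ids)) {
      v <- c(v, "linker anchored at a non-linking node")
    }
    for (s in subs) {
      if (nrow(s$linkers) &&
            !all(s$linkers$anchor_id %in% s$net$nodes$id)) {
        v <- c(v, sprintf("anchor missing from subnetwork %s", s$group))
      }
    }
  }
  structure(list(ok = length(v) == 0, violations = v),
            class = "gn_split_report")
}

#' @export
print.gn_split_report <- function(x, ...) {
  if (x$ok) {
    cat("<gn_split_report> OK\n")
  } else {
    cat("<gn_split_report>", length(x$violations), "violation(s):\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  invisible(x)
}
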