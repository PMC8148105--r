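# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (plain loops over the raw node/edge tables) so they
# never share code paths with the implementation they check.

canonical_graph <- function(net) {
  nodes <- network_nodes(net)
  nodes <- nodes[order(nodes$id), ]
  nodes$attributes <- lapply(nodes$attributes, function(a) {
    a[order(names(a))]
  })
  edges <- network_edges(net)
  edges <- edges[order(edges$source, edges$target, edges$role), ]
  edges$attributes <- lapply(edges$attributes, function(a) {
    a[order(names(a))]
  })
  list(nodes = as.data.frame(nodes, stringsAsFactors = FALSE),
       edges = as.data.frame(edges, stringsAsFactors = FALSE))
}

# naive incidence count by scanning the edge list
degree_oracle <- function(net, id) {
  e <- network_edges(net)
  n <- 0L
  for (i in seq_len(nrow(e))) {
    if (e$source[[i]] == id || e$target[[i]] == id) n <- n + 1L
  }
  n
}

neighbors_oracle <- function(net, id, roles = NULL) {
  e <- network_edges(net)
  out <- character()
  for (i in seq_len(nrow(e))) {
    if (!is.null(roles) && !e$role[[i]] %in% roles) next
    if (e$source[[i]] == id) out <- c(out, e$target[[i]])
    if (e$target[[i]] == id) out <- c(out, e$source[[i]])
  }
  sort(unique(out))
}

# random GPR tree generator (structure first, then serialised):
# the round-trip oracle compares parsed trees against these structures
random_gpr_tree <- function(depth, genes = sprintf("gene%02d", 1:12)) {
  if (depth == 0 || runif(1) < 0.3) {
    return(list(gene = sample(genes, 1)))
  }
  n_args <- sample(2:3, 1)
  list(op = sample(c("and", "or"), 1),
       args = lapply(seq_len(n_args), function(i) {
         random_gpr_tree(depth - 1, genes)
       }))
}

# trees are nested lists; normalise class for comparison
strip_gpr_class <- function(x) {
  x <- unclass(x)
  if (!is.null(x$args)) x$args <- lapply(x$args, strip_gpr_class)
  x
}

# exhaustive per-definition split oracle
split_oracle <- function(net, config) {
  bp <- config$bipartition
  nodes <- network_nodes(net)
  edges <- network_edges(net)
  cls <- stats::setNames(nodes$node_class, nodes$id)
  groups_of <- function(id) {
    s <- nodes$subsystems[[match(id, nodes$id)]]
    if (length(s)) s else "(unassigned)"
  }
  mb <- list()
  for (i in seq_len(nrow(edges))) {
    s <- edges$source[[i]]; t <- edges$target[[i]]
    if (cls[[s]] == bp$member_class && cls[[t]] == bp$bridge_class) {
      mb[[length(mb) + 1L]] <- c(member = s, bridge = t)
    } else if (cls[[t]] == bp$member_class && cls[[s]] == bp$bridge_class) {
      mb[[length(mb) + 1L]] <- c(member = t, bridge = s)
    }
  }
  members <- nodes$id[nodes$node_class == bp$member_class]
  dupg <- stats::setNames(nodes$duplication_group, nodes$id)
  all_groups <- sort(unique(unlist(lapply(members, groups_of))))
  membership <- list(); bridges <- list(); linkers <- list()
  placements <- list()
  for (v in all_groups) {
    mv <- members[vapply(members, function(m) v %in% groups_of(m),
                         logical(1))]
    bv <- character()
    for (p in mb) {
      if (p[["member"]] %in% mv && !p[["bridge"]] %in% config$removed_ids) {
        bv <- c(bv, p[["bridge"]])
        placements[[length(placements) + 1L]] <-
          c(group = v, member = p[["member"]], bridge = p[["bridge"]])
      }
    }
    bv <- sort(unique(bv))
    membership[[v]] <- sort(mv)
    bridges[[v]] <- bv
    for (b in bv) {
      if (b %in% config$nonlink_ids) next
      if (!is.na(dupg[[b]])) next
      foreign <- character()
      for (p in mb) {
        if (p[["bridge"]] == b) {
          foreign <- c(foreign, groups_of(p[["member"]]))
        }
      }
      for (w in setdiff(sort(unique(foreign)), v)) {
        linkers[[length(linkers) + 1L]] <-
          c(home = v, target = w, anchor = b)
      }
    }
  }
  list(groups = all_groups, membership = membership, bridges = bridges,
       linkers = if (length(linkers)) {
         unique(do.call(rbind, linkers))
       } else {
         matrix(character(), ncol = 3,
                dimnames = list(NULL, c("home", "target", "anchor")))
       },
       placements = unique(vapply(placements, paste, character(1),
                                  collapse = "\r")))
}

# presence-pattern grouping by hashing rows of the presence matrix
node_type_oracle <- function(datasets, net) {
  nodes <- network_nodes(net)
  keys <- vapply(seq_len(nrow(nodes)), function(i) {
    a <- nodes$attributes[[i]]
    if ("data_id" %in% names(a)) a[["data_id"]] else nodes$id[[i]]
  }, character(1))
  pats <- list()
  for (i in seq_len(nrow(nodes))) {
    present <- character()
    for (ds in datasets) {
      row <- match(keys[[i]], ds$values$id)
      if (!is.na(row) && any(!is.na(as.numeric(ds$values[row, ds$headers])))) {
        present <- c(present, ds$id)
      }
    }
    if (length(present)) {
      key <- paste(present, collapse = "+")
      pats[[key]] <- c(pats[[key]], nodes$id[[i]])
    }
  }
  lapply(pats, sort)
}

make_toy_net <- function() {
  network("toy") |>
    add_node("A", node_class = "species") |>
    add_node("B", node_class = "species") |>
    add_node("R1", node_class = "reaction") |>
    add_node("g1", node_class = "gene") |>
    add_edge("A", "R1", "substrate") |>
    add_edge("R1", "B", "product") |>
    add_edge("g1", "R1", "gpr", directed = FALSE)
}

# two pathway groups sharing one bridge metabolite
make_two_group_net <- function(nonlink = character(),
                               removed = character()) {
  net <- network("two groups") |>
    add_nodes(tibble::tibble(
      id = c("r1", "r2"), node_class = "reaction",
      subsystems = list("A", "B"))) |>
    add_nodes(tibble::tibble(
      id = c("m1", "m", "m2"), node_class = "species")) |>
    add_edge("m1", "r1", "substrate") |>
    add_edge("r1", "m", "product") |>
    add_edge("m", "r2", "substrate") |>
    add_edge("r2", "m2", "product")
  list(net = net,
       config = split_config(bipartition(), removed_ids = removed,
                             nonlink_ids = nonlink))
}
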