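test_that("two groups sharing one bridge metabolite produce symmetric linkers", {
  tg <- make_two_group_net()
  subs <- split_network(tg$net, tg$config)
  expect_named(subs, c("A", "B"))
  expect_equal(subs$A$linkers$label, "B")
  expect_equal(subs$A$linkers$anchor_id, "m")
  expect_equal(subs$B$linkers$label, "A")
  # linker node present, connected to its anchor by a link edge
  a <- subs$A$net
  lid <- subs$A$linkers$id
  expect_true(lid %in% network_nodes(a)$id)
  e <- network_edges(a)
  expect_true(any(e$role == "link" & e$source == "m" & e$target == lid))
  expect_length(validate_network(a), 0)
})

test_that("single-group networks yield one subnetwork and no linkers", {
  net <- network() |>
    add_nodes(tibble::tibble(id = c("r1", "r2"), node_class = "reaction",
                             subsystems = list("Only", "Only"))) |>
    add_node("m", node_class = "species") |>
    add_edge("m", "r1", "substrate") |>
    add_edge("m", "r2", "substrate")
  subs <- split_network(net, split_config())
  expect_length(subs, 1)
  expect_equal(nrow(subs$Only$linkers), 0)
  meta <- subnetwork_graph(subs)
  expect_equal(nrow(network_nodes(meta)), 1)
  expect_equal(nrow(network_edges(meta)), 0)
})

test_that("non-linking bridges appear in every adjacent subnetwork but never link", {
  tg <- make_two_group_net(nonlink = "m")
  subs <- split_network(tg$net, tg$config)
  expect_true("m" %in% network_nodes(subs$A$net)$id)
  expect_true("m" %in% network_nodes(subs$B$net)$id)
  expect_equal(nrow(subs$A$linkers), 0)
  expect_equal(nrow(subs$B$linkers), 0)
})

test_that("removed bridges and their edges appear in no subnetwork", {
  tg <- make_two_group_net(removed = "m")
  subs <- split_network(tg$net, tg$config)
  for (s in subs) {
    expect_false("m" %in% network_nodes(s$net)$id)
    e <- network_edges(s$net)
    expect_false(any(e$source == "m" | e$target == "m"))
  }
})

test_that("group-less members pool into the unassigned subnetwork", {
  net <- network() |>
    add_nodes(tibble::tibble(id = c("r1", "r2"), node_class = "reaction",
                             subsystems = list("A", character()))) |>
    add_node("m", node_class = "species") |>
    add_edge("m", "r1", "substrate") |>
    add_edge("m", "r2", "substrate")
  subs <- split_network(net, split_config())
  expect_setequal(names(subs), c("A", "(unassigned)"))
  expect_true("r2" %in% network_nodes(subs$`(unassigned)`$net)$id)
})

test_that("split errors are informative", {
  net <- network() |>
    add_node("r1", node_class = "reaction") |>
    add_node("m", node_class = "species") |>
    add_edge("m", "r1", "substrate")
  expect_error(split_network(net, split_config()),
               "extract_subsystems|group_attribute",
               class = "gn_validation_error")
  expect_error(split_config(removed_ids = "x", nonlink_ids = "x"),
               class = "gn_validation_error")
  tg <- make_two_group_net()
  expect_error(
    split_network(tg$net, split_config(removed_ids = "r1")),
    "bridge", class = "gn_validation_error")
})

test_that("companion gene/protein nodes follow their reactions into subnetworks", {
  gen <- generate_toy_sbml(toy_model_spec(n_enzymes = 2, seed = 21),
                           tempfile(fileext = ".xml"))
  net <- annotate_sbml(gen$path)
  subs <- split_network(net, split_config())
  for (s in subs) {
    nd <- network_nodes(s$net)
    genes <- nd$id[nd$node_class == "gene"]
    expect_gt(length(genes), 0)
    # every included reaction's GPR genes are present
    for (rid in nd$id[nd$node_class == "reaction"]) {
      want <- gen$truth$gene_map$gene[gen$truth$gene_map$reaction == rid]
      expect_true(all(paste0("gene:", want) %in% genes))
    }
  }
  # no companions when disabled
  subs2 <- split_network(net, split_config(include_companions = FALSE))
  cls <- unlist(lapply(subs2, function(s) network_nodes(s$net)$node_class))
  expect_false(any(cls %in% c("gene", "protein")))
})

test_that("split matches the exhaustive per-definition oracle on random networks", {
  for (seed in 1:20) {
    net <- generate_random_bipartite(
      n_members = sample(30:200, 1), n_bridges = sample(15:60, 1),
      n_groups = sample(2:4, 1), p_unassigned = 0.05, seed = seed)
    bridges <- network_nodes(net)$id[network_nodes(net)$node_class == "species"]
    deg <- degree_table(net)
    hubs <- deg$id[deg$id %in% bridges & deg$degree >= 12]
    nonlink <- setdiff(deg$id[deg$id %in% bridges & deg$degree >= 9], hubs)
    config <- split_config(removed_ids = hubs, nonlink_ids = nonlink)
    subs <- split_network(net, config)
    oracle <- split_oracle(net, config)
    expect_equal(names(subs), oracle$groups)
    for (v in oracle$groups) {
      nd <- network_nodes(subs[[v]]$net)
      expect_equal(sort(nd$id[nd$node_class == "reaction"]),
                   oracle$membership[[v]])
      expect_equal(sort(nd$id[nd$node_class == "species"]),
                   oracle$bridges[[v]])
    }
    lks <- dplyr::bind_rows(lapply(subs, function(s) s$linkers))
    got <- sort(paste(lks$home_group, lks$target_group, lks$anchor_id))
    want <- sort(paste(oracle$linkers[, "home"], oracle$linkers[, "target"],
                       oracle$linkers[, "anchor"]))
    expect_equal(got, want)
    # linker symmetry
    expect_setequal(paste(lks$home_group, lks$target_group, lks$anchor_id),
                    paste(lks$target_group, lks$home_group, lks$anchor_id))
    # edge conservation per oracle placements
    have <- unlist(lapply(subs, function(s) {
      e <- network_edges(s$net)
      cls <- stats::setNames(network_nodes(s$net)$node_class,
                             network_nodes(s$net)$id)
      mb <- e[cls[e$source] != cls[e$target] &
                cls[e$source] %in% c("species", "reaction") &
                cls[e$target] %in% c("species", "reaction") &
                e$role != "link", ]
      if (nrow(mb) == 0) return(character(0))
      m <- ifelse(cls[mb$source] == "reaction", mb$source, mb$target)
      b <- ifelse(cls[mb$source] == "reaction", mb$target, mb$source)
      paste(s$group, m, b, sep = "\r")
    }))
    expect_setequal(unique(have), oracle$placements)
    # validator agrees
    expect_true(validate_split(net, config, subs)$ok)
  }
})

test_that("determinism: same input and config give identical decompositions", {
  net <- generate_random_bipartite(seed = 77)
  config <- split_config()
  s1 <- split_network(net, config)
  s2 <- split_network(net, config)
  expect_identical(lapply(s1, function(s) canonical_graph(s$net)),
                   lapply(s2, function(s) canonical_graph(s$net)))
  # linker ids follow sorted (anchor, target group) order
  for (s in s1) {
    lk <- s$linkers
    expect_false(is.unsorted(paste(lk$anchor_id, lk$target_group)))
  }
})

test_that("one_linker_per_group collapses linkers but keeps anchors on edges", {
  net <- generate_random_bipartite(n_members = 40, n_bridges = 10,
                                   n_groups = 3, seed = 9)
  subs <- split_network(net, split_config(one_linker_per_group = TRUE))
  for (s in subs) {
    nd <- network_nodes(s$net)
    linkers <- nd$id[nd$node_class == "linker"]
    expect_lte(length(linkers), 2)  # at most one per foreign group
    expect_equal(anyDuplicated(nd$label[nd$node_class == "linker"]), 0L)
  }
})

test_that("subnetwork_graph mirrors groups sharing a linking bridge", {
  for (seed in c(101, 202, 303)) {
    net <- generate_random_bipartite(n_members = 60, n_bridges = 25,
                                     n_groups = 4, seed = seed)
    config <- split_config()
    subs <- split_network(net, config)
    meta <- subnetwork_graph(subs)
    oracle <- split_oracle(net, config)
    want_pairs <- unique(apply(oracle$linkers, 1, function(r) {
      paste(min(r[["home"]], r[["target"]]),
            max(r[["home"]], r[["target"]]))
    }))
    e <- network_edges(meta)
    got_pairs <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
    expect_setequal(got_pairs, want_pairs)
    expect_length(validate_network(meta), 0)
  }
})

test_that("validate_split detects injected corruption", {
  tg <- make_two_group_net()
  subs <- split_network(tg$net, tg$config)
  expect_true(validate_split(tg$net, tg$config, subs)$ok)
  # inject a removed node
  cfg_rm <- split_config(bipartition(), removed_ids = "m")
  bad <- validate_split(tg$net, cfg_rm, subs)
  expect_false(bad$ok)
  expect_match(bad$violations, "removed", all = FALSE)
  # delete a linker -> symmetry/completeness violation
  subs2 <- split_network(tg$net, tg$config)
  subs2$A$linkers <- subs2$A$linkers[0, ]
  bad2 <- validate_split(tg$net, tg$config, subs2)
  expect_false(bad2$ok)
  expect_match(bad2$violations, "linker|symmetry", all = FALSE)
})

test_that("suggest_exclusions applies thresholds and percentile defaults", {
  # one hub of degree 40, others low
  net <- network() |> add_node("hub", node_class = "species")
  for (i in 1:40) {
    net <- net |> add_node(paste0("r", i), node_class = "reaction") |>
      add_edge("hub", paste0("r", i), "substrate")
  }
  for (i in 1:10) {
    net <- net |> add_node(paste0("m", i), node_class = "species") |>
      add_edge(paste0("m", i), paste0("r", i), "product")
  }
  sug <- suggest_exclusions(net, remove_threshold = 30, nonlink_threshold = 8)
  expect_equal(sug$removal_candidates$id, "hub")
  expect_equal(nrow(sug$nonlink_candidates), 0)

  # uniform degree 2: both lists empty under (30, 8)
  net2 <- make_two_group_net()$net
  sug2 <- suggest_exclusions(net2, remove_threshold = 30,
                             nonlink_threshold = 8)
  expect_equal(nrow(sug2$removal_candidates), 0)
  expect_equal(nrow(sug2$nonlink_candidates), 0)

  # skewed degrees vs a sort-and-filter oracle with default thresholds
  net3 <- generate_random_bipartite(n_members = 150, n_bridges = 40,
                                    seed = 13)
  sug3 <- suggest_exclusions(net3)
  deg <- degree_table(net3)
  bridge <- network_nodes(net3)$id[network_nodes(net3)$node_class == "species"]
  bd <- deg[deg$id %in% bridge, ]
  rt <- max(30, stats::quantile(bd$degree, 0.98, names = FALSE))
  nt <- max(8, stats::quantile(bd$degree, 0.90, names = FALSE))
  expect_setequal(sug3$removal_candidates$id, bd$id[bd$degree >= rt])
  expect_setequal(sug3$nonlink_candidates$id,
                  bd$id[bd$degree >= nt & bd$degree < rt])
  expect_equal(length(intersect(sug3$removal_candidates$id,
                                sug3$nonlink_candidates$id)), 0L)
  # sorted by descending degree
  expect_false(is.unsorted(rev(sug3$removal_candidates$degree)))
  # no bridge nodes -> error
  only_members <- network() |> add_node("r", node_class = "reaction")
  expect_error(suggest_exclusions(only_members), "bridge")
})

test_that("navigability: connected members stay connected across the subnetwork map", {
  for (seed in 1:20) {
    net <- generate_random_bipartite(
      n_members = sample(30:120, 1), n_bridges = sample(15:50, 1),
      n_groups = sample(2:4, 1), seed = seed)
    nodes <- network_nodes(net)
    bridges <- nodes$id[nodes$node_class == "species"]
    deg <- degree_table(net)
    removed <- deg$id[deg$id %in% bridges & deg$degree >= 14]
    nonlink <- setdiff(deg$id[deg$id %in% bridges & deg$degree >= 10],
                       removed)
    config <- split_config(removed_ids = removed, nonlink_ids = nonlink)
    subs <- split_network(net, config)
    meta <- subnetwork_graph(subs)

    # oracle: components of the original graph restricted to members plus
    # allowed bridges
    keep <- c(nodes$id[nodes$node_class == "reaction"],
              setdiff(bridges, c(removed, nonlink)))
    e <- network_edges(net)
    e <- e[e$source %in% keep & e$target %in% keep, ]
    g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                       directed = FALSE,
                                       vertices = data.frame(name = keep))
    comp <- igraph::components(g)$membership
    gm <- igraph::graph_from_data_frame(
      network_edges(meta)[, c("source", "target")], directed = FALSE,
      vertices = data.frame(name = network_nodes(meta)$id))
    mcomp <- igraph::components(gm)$membership
    mg <- tidyr::unnest(
      dplyr::mutate(nodes[nodes$node_class == "reaction",
                          c("id", "subsystems")],
                    subsystems = lapply(subsystems, function(s) {
                      if (length(s)) s else "(unassigned)"
                    })),
      "subsystems")
    members <- mg$id
    grp <- split(mg$subsystems, mg$id)
    for (trial in 1:40) {
      pair <- sample(members, 2)
      if (comp[[pair[[1]]]] == comp[[pair[[2]]]]) {
        g1 <- grp[[pair[[1]]]]; g2 <- grp[[pair[[2]]]]
        connected <- any(outer(mcomp[g1], mcomp[g2], "=="))
        expect_true(connected)
      }
    }
  }
})
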