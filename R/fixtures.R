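# Synthetic model/data generators: every module is testable without
# downloads, and the generator bookkeeping doubles as the ground-truth
# oracle in tests.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic toy metabolic model
#'
#' The generated model mimics the structure of a small bacterial core
#' network: each pathway is a linear reaction chain over its own
#' metabolites, pathway pairs share connecting metabolites (one reaction
#' of each pathway produces/consumes them), and a few high-degree
#' co-factor metabolites attach to a fraction of all reactions. Every
#' reaction carries COBRA notes (`SUBSYSTEM`, `GENE_ASSOCIATION` with a
#' random and/or tree over a pathway-level gene pool). Optionally,
#' enzyme species are added as reaction modifiers, alternating between
#' an SBO enzyme term and an `isEncodedBy` qualifier annotation.
#'
#' @param n_pathways number of pathways.
#' @param reactions_per_pathway chain length per pathway.
#' @param shared_metabolites_per_pathway_pair connecting metabolites per
#'   unordered pathway pair.
#' @param n_cofactors number of high-degree co-factor metabolites.
#' @param cofactor_fraction fraction of all reactions each co-factor
#'   attaches to.
#' @param genes_per_reaction `(min, max)` genes per GPR.
#' @param gene_pool_factor pathway gene-pool size relative to its
#'   reaction count (controls gene reuse).
#' @param n_enzymes number of enzyme species (0 disables).
#' @param seed fixes all randomness.
#' @return a `gn_toy_spec` list.
#' @export
toy_model_spec <- function(n_pathways = 3, reactions_per_pathway = 5,
                           shared_metabolites_per_pathway_pair = 1,
                           n_cofactors = 2, cofactor_fraction = 0.5,
                           genes_per_reaction = c(1, 3),
                           gene_pool_factor = 1.2, n_enzymes = 0,
                           seed = 42) {
  stopifnot(n_pathways >= 1, reactions_per_pathway >= 1,
            shared_metabolites_per_pathway_pair >= 0, n_cofactors >= 0,
            cofactor_fraction >= 0, cofactor_fraction <= 1,
            length(genes_per_reaction) == 2,
            genes_per_reaction[1] >= 1,
            genes_per_reaction[2] >= genes_per_reaction[1])
  structure(as.list(environment()), class = "gn_toy_spec")
}

random_gpr_string <- function(genes) {
  build <- function(g) {
    if (length(g) == 1) return(g)
    cut <- sample.int(length(g) - 1, 1)
    op <- sample(c("and", "or"), 1)
    left <- build(g[seq_len(cut)])
    right <- build(g[-seq_len(cut)])
    wrap <- function(s) if (grepl(" ", s, fixed = TRUE)) paste0("(", s, ")")
                        else s
    paste(wrap(left), op, wrap(right))
  }
  build(genes)
}

#' Generate a toy SBML model with known ground truth
#'
#' @param spec a [toy_model_spec()].
#' @param path output SBML file.
#' @return a list with `path` and `truth`: tibbles `reactions`
#'   (id, pathway), `gene_map` (reaction, gene), `edges` (species,
#'   reaction, role), plus `species_ids`, `cofactor_ids`, `enzyme_ids`,
#'   `gene_ids` (unique gene tokens) and the counts `n_species`,
#'   `n_reactions`.
#' @export
generate_toy_sbml <- function(spec, path) {
  stopifnot(inherits(spec, "gn_toy_spec"))
  with_seed(spec$seed, {
    P <- spec$n_pathways
    K <- spec$reactions_per_pathway
    pw <- sprintf("PW%02d", seq_len(P))
    species <- character()
    reactions <- list()  # id -> list(subs, prods, mods, pathway, gpr)
    truth_edges <- list()
    gene_map <- list()

    add_sp <- function(id) species <<- c(species, id)
    pool <- lapply(seq_len(P), function(p) {
      sprintf("g%02d_%03d", p,
              seq_len(max(2, ceiling(K * spec$gene_pool_factor))))
    })

    for (p in seq_len(P)) {
      mets <- sprintf("M_p%02d_%03d", p, 0:K)
      for (m in mets) add_sp(m)
      for (i in seq_len(K)) {
        rid <- sprintf("R_p%02d_%03d", p, i)
        n_g <- sample(seq(spec$genes_per_reaction[1],
                          spec$genes_per_reaction[2]), 1)
        genes <- sample(pool[[p]], min(n_g, length(pool[[p]])))
        gpr <- random_gpr_string(genes)
        reactions[[rid]] <- list(
          subs = mets[[i]], prods = mets[[i + 1]], mods = character(),
          pathway = pw[[p]], gpr = gpr)
        gene_map[[rid]] <- tibble(reaction = rid, gene = sort(genes))
      }
    }
    rxn_ids <- names(reactions)
    rxn_pw <- vapply(reactions, function(r) r$pathway, character(1))

    if (P >= 2 && spec$shared_metabolites_per_pathway_pair > 0) {
      for (p in seq_len(P - 1)) {
        for (q in seq(p + 1, P)) {
          for (j in seq_len(spec$shared_metabolites_per_pathway_pair)) {
            sid <- sprintf("S_p%02d_p%02d_%02d", p, q, j)
            add_sp(sid)
            rp <- sample(rxn_ids[rxn_pw == pw[[p]]], 1)
            rq <- sample(rxn_ids[rxn_pw == pw[[q]]], 1)
            reactions[[rp]]$prods <- c(reactions[[rp]]$prods, sid)
            reactions[[rq]]$subs <- c(reactions[[rq]]$subs, sid)
          }
        }
      }
    }

    cof_ids <- character()
    if (spec$n_cofactors > 0) {
      n_att <- max(1, ceiling(spec$cofactor_fraction * length(rxn_ids)))
      for (k in seq_len(spec$n_cofactors)) {
        cid <- sprintf("C_%02d", k)
        add_sp(cid)
        cof_ids <- c(cof_ids, cid)
        att <- sample(rxn_ids, min(n_att, length(rxn_ids)))
        for (i in seq_along(att)) {
          if (i %% 2 == 1) {
            reactions[[att[[i]]]]$subs <- c(reactions[[att[[i]]]]$subs, cid)
          } else {
            reactions[[att[[i]]]]$prods <- c(reactions[[att[[i]]]]$prods, cid)
          }
        }
      }
    }

    enz_ids <- character()
    enz_genes <- stats::setNames(character(), character())
    enz_xml <- stats::setNames(character(), character())
    if (spec$n_enzymes > 0) {
      for (k in seq_len(spec$n_enzymes)) {
        eid <- sprintf("E_%02d", k)
        add_sp(eid)
        enz_ids <- c(enz_ids, eid)
        host <- sample(rxn_ids, 1)
        reactions[[host]]$mods <- c(reactions[[host]]$mods, eid)
        p <- match(rxn_pw[[host]], pw)
        gene <- sample(pool[[p]], 1)
        if (k %% 2 == 0) enz_genes[[eid]] <- gene
        if (k %% 2 == 1) {
          enz_xml[[eid]] <- sprintf(' sboTerm="SBO:0000014"')
        } else {
          enz_xml[[eid]] <- sprintf(
            '>%s', paste0(
              '<annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" ',
              'xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
              sprintf('<rdf:Description rdf:about="#%s">', eid),
              '<bqbiol:isEncodedBy><rdf:Bag>',
              sprintf('<rdf:li rdf:resource="http://identifiers.org/ncbigene/%s"/>',
                      gene),
              '</rdf:Bag></bqbiol:isEncodedBy>',
              '</rdf:Description></rdf:RDF></annotation>'))
        }
      }
    }

    sp_lines <- vapply(species, function(s) {
      extra <- if (s %in% names(enz_xml)) enz_xml[[s]] else ""
      if (startsWith(extra, ">")) {
        sprintf('      <species id="%s" name="%s" compartment="c"%s</species>',
                s, s, extra)
      } else {
        sprintf('      <species id="%s" name="%s" compartment="c"%s/>',
                s, s, extra)
      }
    }, character(1))

    rx_lines <- vapply(names(reactions), function(rid) {
      r <- reactions[[rid]]
      sref <- function(ids) {
        paste(sprintf('          <speciesReference species="%s" stoichiometry="1"/>',
                      ids), collapse = "\n")
      }
      mref <- function(ids) {
        paste(sprintf('          <modifierSpeciesReference species="%s"/>',
                      ids), collapse = "\n")
      }
      paste(c(
        sprintf('      <reaction id="%s" name="%s" reversible="false">',
                rid, rid),
        "        <notes>",
        '          <body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf("            <p>GENE_ASSOCIATION: %s</p>", r$gpr),
        sprintf("            <p>SUBSYSTEM: %s</p>", r$pathway),
        "          </body>",
        "        </notes>",
        "        <listOfReactants>", sref(r$subs), "        </listOfReactants>",
        "        <listOfProducts>", sref(r$prods), "        </listOfProducts>",
        if (length(r$mods)) c("        <listOfModifiers>", mref(r$mods),
                              "        </listOfModifiers>"),
        "      </reaction>"), collapse = "\n")
    }, character(1))

    doc <- paste(c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
      '  <model id="toy_model" name="toy_model">',
      "    <listOfCompartments>",
      '      <compartment id="c" name="cytosol"/>',
      "    </listOfCompartments>",
      "    <listOfSpecies>",
      sp_lines,
      "    </listOfSpecies>",
      "    <listOfReactions>",
      rx_lines,
      "    </listOfReactions>",
      "  </model>",
      "</sbml>", ""), collapse = "\n")
    writeLines(doc, path, sep = "")

    for (rid in names(reactions)) {
      r <- reactions[[rid]]
      truth_edges[[rid]] <- dplyr::bind_rows(
        tibble(species = unique(r$subs), reaction = rid, role = "substrate"),
        tibble(species = unique(r$prods), reaction = rid, role = "product"),
        if (length(r$mods)) tibble(species = unique(r$mods), reaction = rid,
                                   role = "modifier"))
    }
    gm <- dplyr::bind_rows(gene_map)
    truth <- list(
      reactions = tibble(id = names(reactions), pathway = unname(rxn_pw)),
      gene_map = gm,
      edges = dplyr::bind_rows(truth_edges),
      species_ids = species,
      cofactor_ids = cof_ids,
      enzyme_ids = enz_ids,
      enzyme_gene_map = tibble(enzyme = names(enz_genes),
                               gene = unname(enz_genes)),
      gene_ids = sort(unique(c(gm$gene, unname(enz_genes)))),
      n_species = length(species),
      n_reactions = length(reactions)
    )
    list(path = path, truth = truth)
  })
}

#' Generate omics data tables with known ground truth
#'
#' Writes `n_datasets` CSV tables of Gaussian values over a seeded random
#' subset of network nodes, with missing cells injected at a fixed rate.
#'
#' @param net a `gn_network` (rows are keyed by its node ids).
#' @param out_dir directory for the CSV files.
#' @param n_datasets number of tables.
#' @param coverage_fraction fraction of nodes covered by each dataset
#'   (each dataset draws its own subset).
#' @param n_columns integer vector (recycled) of value columns per
#'   dataset; 1 gives a single-value dataset.
#' @param missing_rate fraction of cells set missing.
#' @param styles styles assigned to the datasets (recycled; styles that
#'   need arrays are only valid where `n_columns > 1`).
#' @param node_pool optional vector of node ids to draw rows from
#'   (default: all nodes); caps the union of data-bearing nodes.
#' @param seed fixes all randomness.
#' @return a list with `files` (tibble: id, file, style, kind) and
#'   `matrices` (named list of ground-truth value tibbles, identical to
#'   what [read_omics_table()] should recover).
#' @export
generate_omics_tables <- function(net, out_dir, n_datasets = 4,
                                  coverage_fraction = 0.5,
                                  n_columns = c(1, 6, 4, 5),
                                  missing_rate = 0.05,
                                  styles = c("heatmap", "timeseries",
                                             "line", "bar"),
                                  node_pool = NULL, seed = 1) {
  assert_network(net)
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_columns <- rep_len(n_columns, n_datasets)
  styles <- rep_len(styles, n_datasets)
  ids <- node_pool %||% net$nodes$id
  with_seed(seed, {
    files <- list()
    matrices <- list()
    for (d in seq_len(n_datasets)) {
      did <- sprintf("dataset_%02d", d)
      n_rows <- max(1, floor(coverage_fraction * length(ids)))
      rows <- sort(sample(ids, n_rows))
      k <- n_columns[[d]]
      m <- matrix(round(stats::rnorm(n_rows * k), 4), nrow = n_rows)
      if (missing_rate > 0) {
        drop <- which(stats::runif(length(m)) < missing_rate)
        m[drop] <- NA_real_
      }
      # no all-missing table
      if (all(is.na(m))) m[1] <- 0
      colnames(m) <- paste0("t", seq_len(k) - 1)
      tab <- dplyr::bind_cols(tibble(id = rows), as_tibble(m))
      f <- file.path(out_dir, paste0(did, ".csv"))
      readr::write_csv(tab, f, na = "")
      files[[d]] <- tibble(id = did, file = f, style = styles[[d]],
                           kind = if (k == 1) "single" else "array")
      matrices[[did]] <- tab
    }
    list(files = dplyr::bind_rows(files), matrices = matrices)
  })
}

#' Generate a random bipartite member/bridge network
#'
#' Test fixture: `n_members` member-class nodes (reactions) assigned to
#' `n_groups` groups (a small fraction belong to two groups, some may be
#' left unassigned), `n_bridges` bridge-class nodes (species), and random
#' member-bridge edges.
#'
#' @param n_members,n_bridges,n_groups sizes.
#' @param edges_per_member average bridge connections per member.
#' @param p_multi_group probability a member carries two groups.
#' @param p_unassigned probability a member carries no group.
#' @param seed fixes all randomness.
#' @return a `gn_network` with member subsystems populated.
#' @export
generate_random_bipartite <- function(n_members = 50, n_bridges = 30,
                                      n_groups = 4, edges_per_member = 3,
                                      p_multi_group = 0.15,
                                      p_unassigned = 0, seed = 1) {
  with_seed(seed, {
    groups <- sprintf("G%02d", seq_len(n_groups))
    m_ids <- sprintf("rxn%03d", seq_len(n_members))
    b_ids <- sprintf("met%03d", seq_len(n_bridges))
    subsystems <- lapply(seq_len(n_members), function(i) {
      u <- stats::runif(1)
      if (u < p_unassigned) return(character())
      if (u < p_unassigned + p_multi_group && n_groups >= 2) {
        sort(sample(groups, 2))
      } else {
        sample(groups, 1)
      }
    })
    net <- network(sprintf("random_bipartite_%d", seed))
    net <- add_nodes(net, tibble(id = m_ids, node_class = "reaction",
                                 subsystems = subsystems))
    net <- add_nodes(net, tibble(id = b_ids, node_class = "species"))
    edges <- lapply(seq_len(n_members), function(i) {
      k <- max(1, stats::rpois(1, edges_per_member))
      nb <- sample(b_ids, min(k, n_bridges))
      role <- ifelse(seq_along(nb) %% 2 == 1, "substrate", "product")
      tibble(source = ifelse(role == "substrate", nb, m_ids[[i]]),
             target = ifelse(role == "substrate", m_ids[[i]], nb),
             role = role, directed = TRUE)
    })
    add_edges(net, dplyr::bind_rows(edges))
  })
}
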