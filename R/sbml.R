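ln <- function(name) sprintf("*[local-name()='%s']", name)

#' Read an SBML metabolic model into a typed network
#'
#' Supports SBML Level 2 (COBRA notes dialect) and Level 3 (with the fbc
#' package). Each SBML species becomes a species node, each reaction a
#' reaction node; speciesReferences become substrate/product/modifier
#' edges with the stoichiometry kept as an edge attribute string. COBRA
#' notes (`GENE_ASSOCIATION`, `SUBSYSTEM`, ...) and fbc
#' geneProductAssociations are captured into node attributes for
#' [attach_genes()] and [extract_subsystems()]; SBO terms and
#' `isEncodedBy` qualifier annotations are captured for
#' [classify_species()].
#'
#' @param path path to an SBML file.
#' @return a `gn_network`.
#' @export
#' @seealso [annotate_sbml()] for the full annotation pipeline.
read_sbml <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("SBML file not found: ", path), class = "gn_io_error")
  }
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(paste0("malformed SBML XML: ",
                                     conditionMessage(e)),
                              class = "gn_io_error")
  )
  if (xml2::xml_name(doc) != "sbml") {
    abort("not an SBML document (root element is not <sbml>)",
          class = "gn_io_error")
  }
  level <- xml2::xml_attr(doc, "level")
  if (!level %in% c("2", "3")) {
    abort(paste0("unsupported SBML level: ", level %||% "missing",
                 " (levels 2 and 3 are supported)"), class = "gn_io_error")
  }
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, paste0("./", ln("model")))
  if (is.na(xml2::xml_name(model, ns = character()))) {
    abort("SBML document has no <model> element", class = "gn_io_error")
  }
  name <- xml2::xml_attr(model, "name")
  if (is.na(name)) name <- xml2::xml_attr(model, "id") %||% "model"
  net <- network(name %||% "model")

  # fbc gene products: id -> label (label preferred as gene token)
  gp <- xml2::xml_find_all(model, paste0(".//", ln("listOfGeneProducts"),
                                         "/", ln("geneProduct")))
  gp_map <- character()
  if (length(gp)) {
    gp_id <- xml2::xml_attr(gp, "id")
    gp_label <- xml2::xml_attr(gp, "label")
    gp_map <- stats::setNames(ifelse(is.na(gp_label), gp_id, gp_label), gp_id)
  }

  ## species
  sp <- xml2::xml_find_all(model, paste0(".//", ln("listOfSpecies"),
                                         "/", ln("species")))
  if (length(sp)) {
    sp_id <- xml2::xml_attr(sp, "id")
    sp_name <- xml2::xml_attr(sp, "name")
    sp_comp <- xml2::xml_attr(sp, "compartment")
    sp_sbo <- xml2::xml_attr(sp, "sboTerm")
    nodes <- tibble(
      id = sp_id,
      label = ifelse(is.na(sp_name), sp_id, sp_name),
      node_class = "species",
      compartment = sp_comp,
      sbo_term = sp_sbo
    )
    net <- add_nodes(net, nodes)
  }

  # isEncodedBy biological qualifiers (one global scan)
  enc <- xml2::xml_find_all(
    doc, paste0(".//", ln("species"), "/", ln("annotation"),
                "//", ln("isEncodedBy"), "//", ln("li")))
  if (length(enc)) {
    res <- xml2::xml_attr(enc, "resource")
    host <- xml2::xml_find_first(enc, paste0("./ancestor::", ln("species")))
    host_id <- xml2::xml_attr(host, "id")
    gene_tok <- basename(res)
    by_sp <- split(gene_tok, host_id)
    for (sid in names(by_sp)) {
      net <- set_node_attributes(
        net, sid,
        attrs = c(encoded_by = paste(sort(unique(by_sp[[sid]])),
                                     collapse = ";")))
    }
  }

  ## reactions
  rx <- xml2::xml_find_all(model, paste0(".//", ln("listOfReactions"),
                                         "/", ln("reaction")))
  if (length(rx)) {
    rx_id <- xml2::xml_attr(rx, "id")
    rx_name <- xml2::xml_attr(rx, "name")
    notes_txt <- vapply(seq_along(rx), function(i) {
      ps <- xml2::xml_find_all(rx[[i]], paste0("./", ln("notes"),
                                               "//", ln("p")))
      if (length(ps)) {
        paste(xml2::xml_text(ps), collapse = "\n")
      } else {
        nt <- xml2::xml_find_first(rx[[i]], paste0("./", ln("notes")))
        if (is.na(nt)) "" else trimws(xml2::xml_text(nt))
      }
    }, character(1))
    attrs <- lapply(seq_along(rx), function(i) {
      a <- character()
      if (nzchar(notes_txt[[i]])) {
        cn <- extract_cobra_notes(notes_txt[[i]])
        if (!is.null(cn$gene_association)) {
          a[["gene_association"]] <- cn$gene_association
        }
        if (!is.null(cn$subsystem)) {
          a[["subsystem"]] <- paste(cn$subsystem, collapse = ";")
        }
        if (length(cn$other)) {
          a[paste0("note_", names(cn$other))] <- unname(cn$other)
        }
      }
      gpa <- xml2::xml_find_first(
        rx[[i]], paste0("./", ln("geneProductAssociation")))
      if (!is.na(gpa) && !"gene_association" %in% names(a)) {
        tree <- fbc_to_gpr(xml2::xml_children(gpa)[[1]], gp_map)
        a[["gene_association"]] <- format_gpr(structure(tree,
                                                        class = "gn_gpr"))
      }
      a
    })
    net <- add_nodes(net, tibble(
      id = rx_id,
      label = ifelse(is.na(rx_name), rx_id, rx_name),
      node_class = "reaction",
      attributes = attrs
    ))

    sref_edges <- function(list_name, role) {
      refs <- xml2::xml_find_all(
        model, paste0(".//", ln(list_name), "/*"))
      if (!length(refs)) return(empty_edge_tbl())
      rid <- xml2::xml_attr(xml2::xml_find_first(refs, "./../.."), "id")
      sid <- xml2::xml_attr(refs, "species")
      stoich <- xml2::xml_attr(refs, "stoichiometry")
      stoich[is.na(stoich)] <- "1"
      if (role == "product") {
        tibble(source = rid, target = sid, role = role, directed = TRUE,
               attributes = lapply(stoich, function(s) c(stoichiometry = s)))
      } else {
        tibble(source = sid, target = rid, role = role, directed = TRUE,
               attributes = lapply(stoich, function(s) c(stoichiometry = s)))
      }
    }
    edges <- dplyr::bind_rows(
      sref_edges("listOfReactants", "substrate"),
      sref_edges("listOfProducts", "product"),
      sref_edges("listOfModifiers", "modifier")
    )
    if (nrow(edges)) net <- add_edges(net, edges)
  }
  net
}

fbc_to_gpr <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    tok <- if (ref %in% names(gp_map)) gp_map[[ref]] else ref
    return(list(gene = tok))
  }
  if (nm %in% c("and", "or")) {
    kids <- xml2::xml_children(node)
    return(list(op = nm, args = lapply(kids, fbc_to_gpr, gp_map = gp_map)))
  }
  abort(paste0("unsupported fbc association element: ", nm))
}

#' Parse COBRA-style notes text
#'
#' COBRA tools store reaction annotations as `TAG: value` lines inside the
#' SBML notes element. `GENE_ASSOCIATION` (also accepted as
#' `GENE ASSOCIATION`, case-insensitively) holds the raw boolean gene
#' expression; `SUBSYSTEM` holds pathway name(s), split on `";"`. The
#' first matching line wins for each tag; remaining tags land in `other`
#' keyed by their upper-cased name. Unparseable lines are ignored.
#'
#' @param notes_text body text of an SBML notes element, one note per line.
#' @return a list with `gene_association` (string or NULL), `subsystem`
#'   (character vector or NULL) and `other` (named character vector).
#' @export
#' @examples
#' extract_cobra_notes("GENE_ASSOCIATION: (b0001 and b0002) or b0003
#' SUBSYSTEM: Citric Acid Cycle")
extract_cobra_notes <- function(notes_text) {
  out <- list(gene_association = NULL, subsystem = NULL,
              other = stats::setNames(character(), character()))
  if (is.null(notes_text) || is.na(notes_text) || !nzchar(notes_text)) {
    return(out)
  }
  lines <- strsplit(notes_text, "\n", fixed = TRUE)[[1]]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z_][A-Za-z0-9 _-]*?)\\s*:\\s*(.*?)\\s*$",
                                 lines))
  for (hit in m) {
    if (length(hit) != 3) next
    tag <- gsub("[ -]", "_", toupper(hit[[2]]))
    val <- hit[[3]]
    if (!nzchar(val)) next
    if (tag == "GENE_ASSOCIATION") {
      if (is.null(out$gene_association)) out$gene_association <- val
    } else if (tag == "SUBSYSTEM") {
      if (is.null(out$subsystem)) {
        out$subsystem <- trimws(strsplit(val, ";", fixed = TRUE)[[1]])
        out$subsystem <- out$subsystem[nzchar(out$subsystem)]
      }
    } else if (!tag %in% names(out$other)) {
      out$other[[tag]] <- val
    }
  }
  out
}

#' Classify enzyme/polypeptide species as protein nodes
#'
#' Species whose SBO term marks them as an enzyme (SBO:0000014) or
#' polypeptide chain (SBO:0000252), or that carry an `isEncodedBy`
#' biological qualifier annotation, are retyped as protein nodes.
#' Modifier edges from a protein to a reaction become catalyzes edges.
#' Reaction and gene nodes are never touched. SBO matching compares the
#' 7-digit numeric part, so `"SBO:0000014"` and bare `"0000014"` both
#' match.
#'
#' @param net a network from [read_sbml()].
#' @param protein_sbo_terms SBO terms that mark a protein.
#' @param encoded_by_attribute attribute name holding the `isEncodedBy`
#'   gene references.
#' @return the updated network.
#' @export
classify_species <- function(net,
                             protein_sbo_terms = c("SBO:0000014",
                                                   "SBO:0000252"),
                             encoded_by_attribute = "encoded_by") {
  assert_network(net)
  want <- sbo_digits(protein_sbo_terms)
  is_sp <- net$nodes$node_class == "species"
  sbo <- sbo_digits(net$nodes$sbo_term)
  has_enc <- !is.na(node_attribute(net, net$nodes$id, encoded_by_attribute))
  hit <- is_sp & ((!is.na(sbo) & sbo %in% want) | has_enc)
  net$nodes$node_class[hit] <- "protein"
  prot <- net$nodes$id[net$nodes$node_class == "protein"]
  rxn <- net$nodes$id[net$nodes$node_class == "reaction"]
  mod <- net$edges$role == "modifier" &
    net$edges$source %in% prot & net$edges$target %in% rxn
  net$edges$role[mod] <- "catalyzes"
  net
}

sbo_digits <- function(x) {
  d <- sub("^\\s*SBO:\\s*", "", x)
  ifelse(grepl("^[0-9]{7}$", d), d, NA_character_)
}

#' Materialise gene nodes from GPR annotations
#'
#' Creates one gene node per unique gene token across all reaction GPRs
#' (ids are prefixed `gene:` to avoid collisions with species sharing the
#' token; labels are the bare token), links each leaf gene of a
#' reaction's GPR to that reaction with a gpr edge, and links genes
#' referenced by a protein's `isEncodedBy` annotation to the protein with
#' encodes edges. Reactions gain a `gpr` attribute holding the serialised
#' expression. Idempotent: applying it twice yields the same network.
#' Reactions whose GPR fails to parse are skipped with a warning; the
#' number of failures is stored in `net$gpr_errors`.
#'
#' @param net a network, typically after [classify_species()].
#' @return the updated network.
#' @export
attach_genes <- function(net) {
  assert_network(net)
  rxn <- net$nodes$id[net$nodes$node_class == "reaction"]
  gpr_raw <- node_attribute(net, rxn, "gene_association")
  genes <- character()
  gpr_edges <- list()
  n_err <- 0L
  rxn_gpr <- character()
  for (i in seq_along(rxn)) {
    if (is.na(gpr_raw[[i]])) next
    tree <- tryCatch(parse_gpr(gpr_raw[[i]]), error = function(e) e)
    if (inherits(tree, "error")) {
      warn(sprintf("skipping reaction %s: %s", rxn[[i]],
                   conditionMessage(tree)))
      n_err <- n_err + 1L
      next
    }
    leaves <- gpr_genes(tree)
    genes <- c(genes, leaves)
    gpr_edges[[length(gpr_edges) + 1L]] <- tibble(
      source = paste0("gene:", leaves), target = rxn[[i]], role = "gpr",
      directed = FALSE)
    rxn_gpr[[rxn[[i]]]] <- format_gpr(tree)
  }
  prot <- net$nodes$id[net$nodes$node_class == "protein"]
  enc_raw <- node_attribute(net, prot, "encoded_by")
  enc_edges <- list()
  for (i in seq_along(prot)) {
    if (is.na(enc_raw[[i]])) next
    toks <- trimws(strsplit(enc_raw[[i]], ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    genes <- c(genes, toks)
    enc_edges[[length(enc_edges) + 1L]] <- tibble(
      source = paste0("gene:", toks), target = prot[[i]], role = "encodes",
      directed = FALSE)
  }
  genes <- sort(unique(genes))
  new_ids <- setdiff(paste0("gene:", genes), net$nodes$id)
  if (length(new_ids)) {
    net <- add_nodes(net, tibble(
      id = new_ids, label = sub("^gene:", "", new_ids), node_class = "gene"))
  }
  all_edges <- dplyr::bind_rows(c(gpr_edges, enc_edges))
  if (!is.null(all_edges) && nrow(all_edges)) net <- add_edges(net, all_edges)
  if (length(rxn_gpr)) {
    for (rid in names(rxn_gpr)) {
      net <- set_node_attributes(net, rid, attrs = c(gpr = rxn_gpr[[rid]]))
    }
  }
  net$gpr_errors <- n_err
  net
}

#' Populate reaction subsystems from COBRA notes
#'
#' Moves the `SUBSYSTEM` note (captured by [read_sbml()] into the
#' `subsystem` attribute, `";"`-separated) into the `subsystems` field of
#' each reaction node. Reactions without the note keep an empty list.
#'
#' @param net a network from [read_sbml()].
#' @return the updated network.
#' @export
extract_subsystems <- function(net) {
  assert_network(net)
  is_rxn <- net$nodes$node_class == "reaction"
  subsys <- node_attribute(net, net$nodes$id, "subsystem")
  net$nodes$subsystems[is_rxn] <- lapply(subsys[is_rxn], function(s) {
    if (is.na(s)) character() else {
      v <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
      v[nzchar(v)]
    }
  })
  net
}

#' Full SBML annotation pipeline
#'
#' Convenience wrapper: [read_sbml()], then [classify_species()],
#' [attach_genes()] and [extract_subsystems()].
#'
#' @param path path to an SBML file.
#' @param protein_sbo_terms passed to [classify_species()].
#' @return an annotated `gn_network` with gene/protein nodes and
#'   reaction subsystems populated.
#' @export
annotate_sbml <- function(path, protein_sbo_terms = c("SBO:0000014",
                                                      "SBO:0000252")) {
  read_sbml(path) |>
    classify_species(protein_sbo_terms = protein_sbo_terms) |>
    attach_genes() |>
    extract_subsystems()
}
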