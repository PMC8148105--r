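# inline Level-2 COBRA-dialect fixture: 2 reactions, enzyme species with
# SBO term, one with isEncodedBy, one plain chemical control
L2_SBML <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="mini" name="mini">
    <listOfCompartments><compartment id="c"/></listOfCompartments>
    <listOfSpecies>
      <species id="glc" name="glucose" compartment="c" sboTerm="SBO:0000247"/>
      <species id="g6p" name="glucose-6P" compartment="c"/>
      <species id="pyr" name="pyruvate" compartment="c"/>
      <species id="enz1" name="hexokinase" compartment="c" sboTerm="SBO:0000014"/>
      <species id="pep1" name="peptide" compartment="c" sboTerm="0000252"/>
      <species id="enc1" name="encoded protein" compartment="c"><annotation>
        <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
                 xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
          <rdf:Description rdf:about="#enc1">
            <bqbiol:isEncodedBy><rdf:Bag>
              <rdf:li rdf:resource="http://identifiers.org/ncbigene/b0002"/>
            </rdf:Bag></bqbiol:isEncodedBy>
          </rdf:Description>
        </rdf:RDF></annotation>
      </species>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="HEX" name="hexokinase rxn">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE_ASSOCIATION: (b0001 and b0002) or b0003</p>
          <p>SUBSYSTEM: Glycolysis</p>
          <p>EC Number: 2.7.1.1</p>
        </body></notes>
        <listOfReactants><speciesReference species="glc" stoichiometry="1"/></listOfReactants>
        <listOfProducts><speciesReference species="g6p"/></listOfProducts>
        <listOfModifiers><modifierSpeciesReference species="enz1"/></listOfModifiers>
      </reaction>
      <reaction id="PYK">
        <notes><body xmlns="http://www.w3.org/1999/xhtml">
          <p>GENE ASSOCIATION: b0003</p>
          <p>SUBSYSTEM: Glycolysis; Fermentation</p>
        </body></notes>
        <listOfReactants><speciesReference species="g6p"/></listOfReactants>
        <listOfProducts><speciesReference species="pyr"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'

L3_FBC_SBML <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="fbcmini" fbc:strict="false">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="a" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="b" compartment="c" constant="false" boundaryCondition="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_x1" fbc:label="x1"/>
      <fbc:geneProduct fbc:id="G_x2" fbc:label="x2"/>
      <fbc:geneProduct fbc:id="G_x3" fbc:label="x3"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R1" reversible="false" fast="false">
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:and>
              <fbc:geneProductRef fbc:geneProduct="G_x1"/>
              <fbc:geneProductRef fbc:geneProduct="G_x2"/>
            </fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_x3"/>
          </fbc:or>
        </fbc:geneProductAssociation>
        <listOfReactants><speciesReference species="a" stoichiometry="1" constant="true"/></listOfReactants>
        <listOfProducts><speciesReference species="b" stoichiometry="1" constant="true"/></listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'

write_fixture <- function(text) {
  f <- tempfile(fileext = ".xml")
  writeLines(text, f)
  f
}

test_that("read_sbml builds species/reaction nodes and role-typed edges", {
  net <- read_sbml(write_fixture(L2_SBML))
  nd <- network_nodes(net)
  expect_equal(sum(nd$node_class == "species"), 6)
  expect_equal(sum(nd$node_class == "reaction"), 2)
  expect_equal(nd$compartment[nd$id == "glc"], "c")
  expect_equal(nd$label[nd$id == "glc"], "glucose")
  e <- network_edges(net)
  expect_equal(nrow(e), 5)
  expect_setequal(e$role[e$source == "glc" | e$target == "glc"], "substrate")
  # default stoichiometry is 1
  stoich <- e$attributes[[which(e$source == "HEX" & e$target == "g6p")]]
  expect_equal(unname(stoich["stoichiometry"]), "1")
})

test_that("read_sbml rejects missing files, malformed XML, and foreign levels", {
  expect_error(read_sbml(tempfile()), class = "gn_io_error")
  bad <- write_fixture("<sbml><model></sbml>")
  expect_error(read_sbml(bad), class = "gn_io_error")
  l1 <- write_fixture(paste0('<sbml xmlns="http://www.sbml.org/sbml/level1" ',
                             'level="1" version="2"><model/></sbml>'))
  expect_error(read_sbml(l1), "unsupported SBML level")
})

test_that("COBRA notes parsing handles both dialects, multi-subsystems and empties", {
  cn <- extract_cobra_notes(
    "GENE_ASSOCIATION: (b0001 and b0002) or b0003\nSUBSYSTEM: Citric Acid Cycle")
  expect_equal(cn$gene_association, "(b0001 and b0002) or b0003")
  expect_equal(cn$subsystem, "Citric Acid Cycle")

  cn2 <- extract_cobra_notes(
    "gene association: b1\nSUBSYSTEM: A; B\nEC Number: 1.1.1.1\nnot a note line")
  expect_equal(cn2$gene_association, "b1")
  expect_equal(cn2$subsystem, c("A", "B"))
  expect_equal(unname(cn2$other["EC_NUMBER"]), "1.1.1.1")

  empty <- extract_cobra_notes("")
  expect_null(empty$gene_association)
  expect_null(empty$subsystem)
  expect_length(empty$other, 0)
})

test_that("classify_species retypes SBO and isEncodedBy species only", {
  net <- classify_species(read_sbml(write_fixture(L2_SBML)))
  nd <- network_nodes(net)
  cls <- stats::setNames(nd$node_class, nd$id)
  expect_equal(unname(cls[c("enz1", "pep1", "enc1")]),
               rep("protein", 3))
  expect_equal(unname(cls[c("glc", "g6p", "pyr")]), rep("species", 3))
  expect_equal(unname(cls[c("HEX", "PYK")]), rep("reaction", 2))
  # modifier edge from the enzyme became catalyzes
  e <- network_edges(net)
  expect_equal(e$role[e$source == "enz1"], "catalyzes")
})

test_that("attach_genes creates unique gene nodes, gpr and encodes edges, and is idempotent", {
  net <- annotate_sbml(write_fixture(L2_SBML))
  nd <- network_nodes(net)
  genes <- nd$id[nd$node_class == "gene"]
  expect_setequal(genes, c("gene:b0001", "gene:b0002", "gene:b0003"))
  e <- network_edges(net)
  # b0003 appears in both GPRs: one node, gpr edges to both reactions
  expect_setequal(e$target[e$source == "gene:b0003" & e$role == "gpr"],
                  c("HEX", "PYK"))
  expect_equal(sum(e$role == "gpr"), 4)
  expect_equal(e$source[e$role == "encodes"], "gene:b0002")
  expect_equal(e$target[e$role == "encodes"], "enc1")
  # reaction carries the serialised expression
  hex_attrs <- nd$attributes[[which(nd$id == "HEX")]]
  expect_equal(unname(hex_attrs["gpr"]), "(b0001 and b0002) or b0003")
  # idempotent
  again <- extract_subsystems(attach_genes(net))
  expect_identical(canonical_graph(again), canonical_graph(net))
  expect_length(validate_network(net), 0)
})

test_that("extract_subsystems fills reaction subsystems and leaves others empty", {
  net <- annotate_sbml(write_fixture(L2_SBML))
  nd <- network_nodes(net)
  expect_equal(nd$subsystems[[which(nd$id == "HEX")]], "Glycolysis")
  expect_equal(nd$subsystems[[which(nd$id == "PYK")]],
               c("Glycolysis", "Fermentation"))
  expect_equal(nd$subsystems[[which(nd$id == "glc")]], character(0))
})

test_that("fbc geneProductAssociations translate to the same GPR dialect", {
  net <- annotate_sbml(write_fixture(L3_FBC_SBML))
  nd <- network_nodes(net)
  expect_setequal(nd$id[nd$node_class == "gene"],
                  c("gene:x1", "gene:x2", "gene:x3"))
  r1 <- nd$attributes[[which(nd$id == "R1")]]
  g <- parse_gpr(unname(r1["gpr"]))
  expect_equal(g$op, "or")
  expect_equal(gpr_genes(g), c("x1", "x2", "x3"))
})

test_that("generated fixture model reproduces generator ground truth", {
  spec <- toy_model_spec(n_pathways = 4, reactions_per_pathway = 6,
                         shared_metabolites_per_pathway_pair = 2,
                         n_cofactors = 3, n_enzymes = 4, seed = 123)
  gen <- generate_toy_sbml(spec, tempfile(fileext = ".xml"))
  net <- annotate_sbml(gen$path)
  nd <- network_nodes(net)
  expect_equal(sum(nd$node_class %in% c("species", "protein")),
               gen$truth$n_species)
  expect_equal(sum(nd$node_class == "reaction"), gen$truth$n_reactions)
  expect_setequal(nd$id[nd$node_class == "gene"],
                  paste0("gene:", gen$truth$gene_ids))
  expect_setequal(nd$id[nd$node_class == "protein"], gen$truth$enzyme_ids)
  # subsystem assignment equals the generator pathway map
  pw <- stats::setNames(gen$truth$reactions$pathway, gen$truth$reactions$id)
  for (rid in gen$truth$reactions$id) {
    expect_equal(nd$subsystems[[which(nd$id == rid)]], unname(pw[[rid]]))
  }
  # gene->reaction edge set equals the generator gene map
  e <- network_edges(net)
  gpr_e <- e[e$role == "gpr", ]
  got <- sort(paste(sub("^gene:", "", gpr_e$source), gpr_e$target))
  want <- sort(paste(gen$truth$gene_map$gene, gen$truth$gene_map$reaction))
  expect_equal(got, want)
  # species-reaction edges equal the generator edge bookkeeping
  sr <- e[e$role %in% c("substrate", "product", "modifier", "catalyzes"), ]
  sp_end <- ifelse(sr$role == "product", sr$target, sr$source)
  rx_end <- ifelse(sr$role == "product", sr$source, sr$target)
  role <- ifelse(sr$role == "catalyzes", "modifier", sr$role)
  got_e <- sort(paste(sp_end, rx_end, role))
  want_e <- sort(paste(gen$truth$edges$species, gen$truth$edges$reaction,
                       gen$truth$edges$role))
  expect_equal(got_e, want_e)
})

test_that("same seed gives byte-identical SBML; different seed differs", {
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  generate_toy_sbml(toy_model_spec(seed = 5), f1)
  generate_toy_sbml(toy_model_spec(seed = 5), f2)
  generate_toy_sbml(toy_model_spec(seed = 6), f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
})
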