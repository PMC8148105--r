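# glyphnet

Visual integration of multi-omics data on genome-scale metabolic networks.

Genome-scale metabolic reconstructions reach thousands of reactions, and two
problems make their visual inspection hard. First, mapping several omics
datasets (expression, proteomics, metabolite time courses, flux predictions)
onto one network view requires composing a small multi-panel figure — a
*metanode glyph* — for every node, plus a legend explaining what each panel
shows. Second, abundant metabolites (water, protons, ATP) connect to hundreds
of reactions and collapse any layout into an untraceable hairball, so the
network must be decomposed into pathway views without losing the connections
between pathways.

glyphnet is an R toolkit for both tasks. It is aimed at systems biologists who
work with SBML/COBRA models and want reproducible, scriptable figures rather
than interactive sessions.

## What it does

* **SBML annotation.** `read_sbml()` parses SBML Level 2 (COBRA notes
  dialect) and Level 3 (+fbc) into a typed multi-partite graph of species,
  reaction, gene and protein nodes. `classify_species()` retypes species
  carrying the SBO terms for *enzyme* (SBO:0000014) or *polypeptide chain*
  (SBO:0000252), or an `isEncodedBy` qualifier annotation, as proteins.
  `attach_genes()` parses gene–protein–reaction (GPR) boolean rules — e.g.
  `(b0001 and b0002) or b0003` — into AND/OR trees and materialises one gene
  node per unique gene, linked to its reactions and proteins.
  `extract_subsystems()` pulls pathway membership from `SUBSYSTEM` notes.

* **Subnetwork decomposition.** A bipartite network has a *member* class
  that carries the grouping property (e.g. reactions grouped by pathway) and
  a *bridge* class that spans groups (metabolites). `split_network()` builds
  one self-contained subnetwork per group value: its member nodes, their
  adjacent bridge nodes, companion gene/protein nodes, and *linker nodes* —
  placeholders labelled with the name of every other pathway a bridge
  metabolite leads to, anchored where the connection leaves the current
  view. Abundant metabolites can be *removed* entirely; co-factors can be
  declared *non-linking* (kept locally, never bridging).
  `suggest_exclusions()` proposes both sets from the bridge-class degree
  distribution, and `subnetwork_graph()` summarises the decomposition as a
  navigable pathway map. `validate_split()` re-checks the whole contract
  (coverage, edge conservation, linker symmetry).

* **Hub duplication.** `duplicate_node()` replaces a highly connected node
  by linked replicates (one per edge or per neighbor) that share a
  duplication group: `propagate_attributes()` updates all replicates at
  once, `remerge()` restores the original exactly, and replicates never
  generate linkers during splitting. Replicates keep the original id in a
  `data_id` attribute, so data mapped to the original reaches every copy.

* **Metanode rendering.** `read_omics_table()` loads CSV/TSV/XLSX tables
  keyed by node id; `derive_node_types()` assigns each data-bearing node a
  *node type* (the set of datasets available for it — one shared type in
  `uniform` mode, one per presence pattern in `per_subset` mode).
  `auto_layout()` arranges datasets on a grid (arrays one full row, single
  values packed four per row under a label band) and `render_node()` /
  `render_legend()` draw deterministic SVG glyphs — heatmap, bar, line,
  time-series and scatter styles, missing values left blank — with one
  legend per node type. `export_images()` writes SVG/PNG plus a JSON
  manifest with the node-to-legend mapping; `register_style()` accepts
  user-defined drawing styles.

* **Interchange.** GraphML, Cytoscape.js JSON and SIF writers (round-trip
  readers for the first two), preserving classes, subsystems, linker
  metadata and image paths.

* **Fixtures.** `generate_toy_sbml()` and `generate_omics_tables()` build
  seeded synthetic models (linear pathway chains, shared metabolites,
  co-factor hubs, random GPR trees) and data tables with full ground truth,
  up to genome scale (~10,000 nodes, ~25,000 edges).

## Worked example

```r
library(glyphnet)

gen <- generate_toy_sbml(toy_model_spec(n_enzymes = 2, seed = 42), "model.xml")
net <- annotate_sbml("model.xml")
net
#> <gn_network> toy_model: 55 nodes, 81 edges
#>   classes: gene=15, protein=2, reaction=15, species=23

sug <- suggest_exclusions(net, remove_threshold = 6, nonlink_threshold = 5)
sug
#> <gn_suggestions> remove >= 6 (2 node(s)), non-link >= 5 (0 node(s))

subs <- split_network(net, split_config(removed_ids = sug$removal_candidates$id))
subs[[1]]
#> <gn_subnetwork> PW01: 23 nodes, 27 edges, 2 linker record(s)

subnetwork_graph(subs)
#> <gn_network> subnetwork map: 3 nodes, 3 edges
#>   classes: other=3

validate_split(net, split_config(removed_ids = sug$removal_candidates$id), subs)
#> <gn_split_report> OK
```

The annotated toy model has three five-reaction pathways (`PW01`–`PW03`),
15 gene nodes created from the COBRA `GENE_ASSOCIATION` notes and two
enzyme species retyped as proteins. The two co-factor metabolites exceed
the removal threshold and are excluded, leaving each pathway view with two
linker records pointing at the other two pathways; the subnetwork map shows
all three pathways pairwise connected, and the validator confirms the
decomposition contract. Adding omics tables and rendering is one more step:

```r
tabs <- generate_omics_tables(net, "data", seed = 42)
res  <- run_render(net, tabs$files, "images", formats = "svg")
length(res$render$images)   # one glyph per data-bearing node
```

A command-line wrapper over the same functions ships in
`inst/cli/glyphnet.R` with `annotate`, `split`, `render` and `demo`
subcommands (exit codes: 0 success, 1 validation failure, 2 I/O/usage).

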