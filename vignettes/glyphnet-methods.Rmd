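---
title: "Methods: typed metabolic graphs, pathway decomposition and glyph rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: typed metabolic graphs, pathway decomposition and glyph rendering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyphnet)
```

This vignette documents the models and procedures behind glyphnet, the
choices that were genuinely open when it was designed, and what the test
suite does and does not establish about real data.

## The typed graph model

A network is a pair of tibbles. Nodes carry an id (case-sensitive, matched
exactly — silent identifier normalisation is a classic source of wrong data
mappings in omics work, so none is performed), a display label, a class
(`species`, `reaction`, `gene`, `protein`, `linker`, `other`), optional
compartment and SBO term, a list of subsystem (pathway) memberships, and a
free-form string attribute map. Edges carry a role (`substrate`, `product`,
`modifier`, `catalyzes`, `encodes`, `gpr`, `link`) and a direction flag.
Direction is stored for fidelity with the SBML source but all connectivity
logic (degree, neighbor sets, decomposition) treats the graph as
undirected: navigating a pathway drawing does not care which way an arrow
points.

Two representational decisions matter downstream. Parallel edges with
distinct roles are kept — a metabolite can legitimately be both substrate
and product of one reaction — while identical `(source, target, role)`
triples collapse to one edge, because SBML lists the same species reference
only once per role. And `subsystems` is a list: most models tag a reaction
with a single pathway, but nothing forbids multiplicity, and group logic
treats every listed value independently (a reaction in two pathways appears
in both pathway views — the only behaviour that keeps each view
self-contained). Stoichiometric coefficients are retained as an edge
attribute string but never computed on; flux semantics are out of scope.

## SBML annotation

`read_sbml()` accepts Level 2 with COBRA-style notes and Level 3 with the
fbc package. Notes lines of the form `TAG: value` are parsed
case-insensitively, with both `GENE_ASSOCIATION` and `GENE ASSOCIATION`
accepted and the first matching line winning — real model files are
inconsistent about the tag spelling. `SUBSYSTEM` values split on `";"`.
fbc `geneProductAssociation` trees are translated into the same AND/OR
expression dialect (using the gene product's label when present), so
downstream code has a single GPR representation regardless of input
dialect.

The GPR grammar is parentheses > AND > OR with case-insensitive keywords
and `&&`/`||` synonyms; gene tokens preserve their original case. Syntax
errors report the character position. The boolean semantics (isoenzymes vs
complexes) are recorded but never evaluated — visualisation needs the gene
set and the gene-reaction edges, not a truth value.

Protein classification follows the SBO terms for enzyme (`SBO:0000014`)
and polypeptide chain (`SBO:0000252`), matching on the 7-digit numeric part
so bare `0000014` also works, plus the `isEncodedBy` biological qualifier.
Gene node ids are namespaced `gene:<token>` to avoid colliding with species
that share the token; the label stays bare. `attach_genes()` is idempotent
and skips (with a warning and a count in `net$gpr_errors`) reactions whose
GPR fails to parse rather than aborting a whole model import.

## Subnetwork decomposition

The decomposition takes a bipartition: the *member* class owns the grouping
attribute and populates subnetworks; the *bridge* class spans them. For
each group value `v`, the subnetwork contains (i) every member with `v`
among its groups, (ii) every non-removed bridge node adjacent to one of
them with the connecting edges, (iii) companion gene/protein nodes adjacent
to included nodes (a closure, so gene–protein chains follow), and (iv)
linker nodes: for each included bridge `b` that is neither non-linking nor
a duplication replicate and is adjacent to members of a foreign group `w`,
one linker labelled `w` anchored at `b`.

Open choices and how they were settled:

* **One linker per (anchor, group), not per group.** Keeping one linker per
  anchor preserves *where* the connection leaves a pathway, which is the
  information a reader needs to follow flux out of the view. Collapsing to
  one linker per foreign group is available as `one_linker_per_group`.
* **Bridge nodes are replicated per subnetwork.** Each pathway view must be
  self-contained; exports can qualify copies as `<id>@<group>` while a
  `data_id` attribute keeps the original id for data mapping.
* **Unassigned members are pooled** into a reserved `"(unassigned)"` group
  rather than dropped — dropping would silently violate edge conservation.
* **Degenerate configurations are legal**: removing every bridge yields
  disconnected pathway islands with zero linkers.

The decomposition guarantees, enforced by `validate_split()` and the test
oracles: a member with *k* group values appears in exactly *k* subnetworks;
every member–bridge edge whose bridge survives appears in exactly the
subnetworks of its member endpoint; linkers are symmetric (home *v*,
target *w*, anchor *b* implies the mirror); and groups connected in the
original network through allowed bridges stay connected in the subnetwork
map. Linker ids are assigned in sorted (anchor, target) order so identical
inputs produce identical output, byte for byte in the exports.

`suggest_exclusions()` ranks bridge nodes by degree and proposes removal
candidates above `max(30, 98th percentile)` and non-linking candidates
between `max(8, 90th percentile)` and the removal threshold. The exact
heuristic behind such suggestions is not standardised anywhere; this
percentile-with-floor rule is this package's own documented choice, picked
so that small models (where the 98th percentile is a handful of edges)
never flag ordinary chain metabolites. Both thresholds can be overridden.

## Hub duplication

`duplicate_node()` offers `per_edge` granularity (default — it removes
hairball structure maximally) and `per_neighbor` (parallel substrate and
modifier edges to the same reaction stay together). Replicate ids are
`<original>#k` in sorted-edge order for determinism. The duplication record
is stored on the network, so `remerge()` restores the exact original node
and edge set; attribute updates propagated across replicates survive the
merge. Replicates are non-branching for decomposition purposes: a
duplicated co-factor never spawns linkers, matching its purpose of being
visually local.

## Omics data and node types

Tables must have a header row and an id column; all other cells are numeric
or empty (missing). The numeric locale is fixed to `"."` decimals and
thousands separators are rejected — silently misreading European CSVs is
worse than an error. A dataset is `single` (one value column) or `array`
(several, e.g. time points); line, time-series and scatter styles require
arrays.

A node's *node type* is the set of datasets that have at least one
non-missing value for it (matching by node id with a `data_id` fallback for
replicates). `uniform` mode gives every data-bearing node the same type
over all datasets, rendering unknown panels blank — one consistent glyph
shape across the figure. `per_subset` mode creates one type per distinct
presence pattern, giving smaller glyphs at the cost of several legends.
Which behaviour is preferable depends on the figure, so both are provided;
`uniform` is the default. Nodes with no data anywhere get no image.

## Layout, rendering and colour

The automatic layout gives each array dataset a full-width row (one cell
per column, dataset registration order top to bottom) and packs single
value datasets left-to-right into shared rows of up to four cells, under a
label band. Default cell size is 40×20 px, the label band 14 px. The canvas
width is set by the widest row and narrower rows stretch their cells, so
every image of a node type has identical dimensions — a layout invariant
the tests assert.

Rendering goes through a primitive display list (rectangles, polylines,
circles, text). SVG is the source of truth: numbers are formatted with a
fixed `%.6g`, there are no timestamps or generated ids, and fonts are named
as generic `sans-serif` with text metrics approximated by fixed character
width, so identical inputs give byte-identical SVG on any platform. PNG is
rasterised by replaying the same display list on a `grDevices::png()`
device; its pixel size is the SVG canvas scaled by `dpi/96` (raster bytes
are device-dependent and not asserted).

Colour scales quantise to 256 steps with linear RGB interpolation: a
diverging blue–white–red ramp symmetric around zero when the data carry
both signs, a sequential white–red ramp over `[min, max]` otherwise.
Missing values always render as blank (white) cells, visually distinct from
any in-range value except an exact white midpoint — a known ambiguity of
diverging ramps, mitigated by the light cell border drawn on blanks.
Legends show, per dataset: name, description, style, and either a labelled
colour bar (heatmap/bar) or the value range (point/line styles).

## The synthetic generator

`generate_toy_sbml()` emulates the structure that matters for these
algorithms: linear reaction chains per pathway (so pathway views are
connected), shared metabolites between pathway pairs (so linkers arise),
co-factor metabolites attached to a configurable fraction of all reactions
(so hairball hubs and the exclusion heuristics have something to act on),
random AND/OR gene rules drawn from a pathway-level gene pool (so gene
reuse across reactions occurs, as in real operons), and optional enzyme
species alternating between SBO-term and `isEncodedBy` annotation. Defaults
(3 pathways × 5 reactions, 1 shared metabolite per pair, 2 co-factors on
half the reactions, 1–3 genes per reaction) mirror a small bacterial core
model. The genome-scale configuration used by the acceptance script
(50 pathways × 80 reactions, co-factor fraction 0.15, gene pool factor
0.25) was chosen to land at roughly 10,000 nodes and 25,000 edges with
glyphs for 3,400 data-bearing nodes — the scale a genome-scale bacterial
reconstruction with partial omics coverage presents.

What the generator does *not* emulate: realistic stoichiometry, reversible
reactions, compartments beyond a single cytosol, mass balance, or the
heavy-tailed degree distributions of real metabolism beyond the injected
co-factor hubs. Passing tests therefore demonstrate the correctness of the
graph transformations and rendering contracts on networks with the right
shape, not biological validity of any particular decomposition of a real
model; on real models the quality of the pathway views depends mainly on
the curation of the `SUBSYSTEM` annotations.

Data tables are Gaussian values over seeded node subsets with a 5% missing
rate by default — enough to exercise blank-cell rendering and presence
patterns, with no correlation structure.

## Numerical and degenerate-input choices

* Empty GPR strings are an error; unparseable GPRs skip their reaction with
  a warning and a counted error.
* A dataset with no non-missing value at all is rejected at read time.
* Constant-valued datasets widen their scale domain by ±0.5 to avoid a
  zero-length colour domain.
* Values outside a scale domain clamp to the endpoints.
* Duplicate dataset row ids, non-numeric cells and missing id columns are
  errors with row/column context.
* Problem sizes in the test suite (random networks up to 200 members,
  20-network property loops, one genome-scale run) were chosen as the
  smallest sizes at which the properties are non-trivial.

## Known limitations

* SBML writing is not supported; the annotator only reads.
* MIRIAM annotations other than `isEncodedBy` are captured only as opaque
  note attributes.
* No automatic graph layout is computed for subnetworks — layout is
  delegated to the consumer of the GraphML/CYJS exports.
* XLSX input reads one sheet at a time and requires readxl.
* The `";"` join for multi-valued subsystems in flat exports escapes `";"`
  in names to `","`; names containing `";"` therefore do not round-trip
  verbatim (the CYJS writer, which stores arrays natively, does not have
  this limitation).
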