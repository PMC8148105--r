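# Pipeline entry points mirroring the tool's subcommands. Each step can
# emit a structured JSON log line so runs are machine-checkable.

log_step <- function(verbose, step, ...) {
  if (!isTRUE(verbose)) return(invisible())
  payload <- list(step = step, ...)
  message(jsonlite::toJSON(payload, auto_unbox = TRUE))
  invisible()
}

#' Annotate an SBML model and export the typed network
#'
#' Reads the SBML file, classifies protein species, materialises gene
#' nodes from GPR annotations, populates reaction subsystems, and writes
#' the annotated network.
#'
#' @param sbml path to an SBML file.
#' @param out output file; its extension (or `format`) picks the writer.
#' @param format `"graphml"`, `"cyjs"` or `"sif"`.
#' @param verbose emit JSON log lines.
#' @return the annotated `gn_network`, invisibly.
#' @export
run_annotate <- function(sbml, out = NULL, format = NULL, verbose = FALSE) {
  net <- annotate_sbml(sbml)
  log_step(verbose, "annotate", sbml = sbml, nodes = nrow(net$nodes),
           edges = nrow(net$edges), gpr_errors = net$gpr_errors %||% 0L)
  if (!is.null(out)) {
    format <- format %||% tolower(tools::file_ext(out))
    writer <- switch(format, graphml = write_graphml, cyjs = write_cyjs,
                     sif = write_sif,
                     abort(paste0("unknown output format: ", format),
                           class = "gn_io_error"))
    writer(net, out)
    log_step(verbose, "export", file = out)
  }
  invisible(net)
}

#' Split a network into linked subnetworks and export them
#'
#' Runs [split_network()], validates the result, writes one file per
#' subnetwork plus the navigation map. A failed validation raises a
#' `gn_validation_error`.
#'
#' @param net a `gn_network` or the path of a GraphML/CYJS file.
#' @param out_dir output directory.
#' @param config a [split_config()].
#' @param format export format.
#' @param verbose emit JSON log lines.
#' @return list with `subnetworks`, `map` (the meta network), `report`
#'   and `files`, invisibly.
#' @export
run_split <- function(net, out_dir, config = split_config(),
                      format = "graphml", verbose = FALSE) {
  if (is.character(net)) {
    ext <- tolower(tools::file_ext(net))
    net <- switch(ext, graphml = read_graphml(net), cyjs = read_cyjs(net),
                  abort(paste0("cannot read network from .", ext, " file"),
                        class = "gn_io_error"))
  }
  subs <- split_network(net, config)
  report <- validate_split(net, config, subs)
  log_step(verbose, "split", groups = length(subs),
           linkers = sum(vapply(subs, function(s) nrow(s$linkers),
                                integer(1))),
           valid = report$ok)
  if (!report$ok) {
    abort(paste0("subnetwork validation failed: ",
                 paste(report$violations, collapse = "; ")),
          class = "gn_validation_error")
  }
  files <- export_subnetworks(subs, out_dir, format = format)
  log_step(verbose, "export", files = nrow(files))
  invisible(list(subnetworks = subs, map = subnetwork_graph(subs),
                 report = report, files = files))
}

#' Render multi-omics glyphs for a network and export them
#'
#' Reads the data tables, derives node types, renders node images and
#' legends, writes them with a manifest, and exports the network as CYJS
#' with image paths attached.
#'
#' @param net a `gn_network` or network file path (GraphML/CYJS).
#' @param data a tibble with columns `file` (path) and optionally `id`,
#'   `style`, `kind` — or a character vector of paths.
#' @param out_dir output directory.
#' @param mode `"uniform"` or `"per_subset"` node-type derivation.
#' @param formats image formats, subset of `c("svg", "png")`.
#' @param verbose emit JSON log lines.
#' @return list with `render` (a `gn_render`), `manifest` and the `cyjs`
#'   path, invisibly.
#' @export
run_render <- function(net, data, out_dir, mode = "uniform",
                       formats = "svg", verbose = FALSE) {
  if (is.character(net)) {
    ext <- tolower(tools::file_ext(net))
    net <- switch(ext, graphml = read_graphml(net), cyjs = read_cyjs(net),
                  abort(paste0("cannot read network from .", ext, " file"),
                        class = "gn_io_error"))
  }
  if (is.character(data)) data <- tibble(file = data)
  if (!nrow(data)) {
    abort("no data tables supplied: nothing to render",
          class = "gn_validation_error")
  }
  if (!"id" %in% names(data)) data$id <- NA_character_
  if (!"style" %in% names(data)) data$style <- "heatmap"
  if (!"kind" %in% names(data)) data$kind <- "auto"
  datasets <- lapply(seq_len(nrow(data)), function(i) {
    ds <- read_omics_table(
      data$file[[i]],
      id = if (is.na(data$id[[i]])) NULL else data$id[[i]],
      kind = data$kind[[i]], style = data$style[[i]])
    cov <- match_nodes(ds, net)
    log_step(verbose, "dataset", id = ds$id, matched = cov$n_matched,
             unmatched = cov$n_unmatched_dataset)
    ds
  })
  render <- render_metanodes(net, datasets, mode = mode)
  if (!length(render$images)) {
    abort("no network node carries any data: nothing to render",
          class = "gn_validation_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- export_images(render, out_dir, formats = formats)
  cyjs <- file.path(out_dir, "network.cyjs")
  # image paths relative to out_dir keep the cyjs portable and seed-stable
  write_cyjs(net, cyjs, image_manifest = manifest$relative$nodes)
  log_step(verbose, "render", images = length(render$images),
           legends = length(render$legends))
  invisible(list(render = render, manifest = manifest, cyjs = cyjs))
}

#' End-to-end demo on generated fixtures
#'
#' Generates a toy SBML model and omics tables, then runs annotate,
#' split (with suggested exclusions) and render into `out_dir`. The same
#' seed reproduces the output byte for byte (PNG excepted).
#'
#' @param out_dir output directory.
#' @param seed generator seed.
#' @param spec a [toy_model_spec()]; its seed is overridden by `seed`.
#' @param formats image formats.
#' @param verbose emit JSON log lines.
#' @return list with the annotated network, subnetworks, render result
#'   and file manifests, invisibly.
#' @export
run_demo <- function(out_dir, seed = 42,
                     spec = toy_model_spec(n_enzymes = 2), formats = "svg",
                     verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec$seed <- seed
  gen <- generate_toy_sbml(spec, file.path(out_dir, "model.xml"))
  net <- run_annotate(gen$path,
                      out = file.path(out_dir, "network.graphml"),
                      verbose = verbose)
  sug <- suggest_exclusions(net, bipartition(),
                            remove_threshold = 30, nonlink_threshold = 8)
  cfg <- split_config(bipartition(),
                      removed_ids = sug$removal_candidates$id,
                      nonlink_ids = sug$nonlink_candidates$id)
  split <- run_split(net, file.path(out_dir, "subnetworks"), cfg,
                     verbose = verbose)
  tabs <- generate_omics_tables(net, file.path(out_dir, "data"),
                                seed = seed)
  rendered <- run_render(net, tabs$files, file.path(out_dir, "images"),
                         formats = formats, verbose = verbose)
  invisible(list(network = net, truth = gen$truth, split = split,
                 tables = tabs, rendered = rendered))
}
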