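#' Configure an end-to-end pipeline run
#'
#' Bundles the file paths, filtering settings, change criterion and network
#' thresholds of a full analysis: load and validate -> filter probes ->
#' (optionally) collapse duplicate probes -> call directional change sets ->
#' per-phase association networks -> four-dimensional network -> reports.
#' The effective configuration is echoed into the run manifest, so a run is
#' reproducible from its output directory alone.
#'
#' @param matrix_path,annotation_path input TSVs (see [load_expression()])
#' @param out_dir output directory, created by [run_pipeline()]
#' @param detection_path optional detection-call TSV
#' @param gene_map_path optional probe-to-gene TSV (columns `probe`, `gene`)
#'   triggering duplicate-probe collapse
#' @param scale scale of the stored values, `"log2"` or `"linear"`
#' @param criterion a [change_criterion()] of kind `"fold_change"` or
#'   `"z_test"` (the composite and consensus criteria need per-comparison
#'   tables or a second dataset; use the function interface for those)
#' @param max_missing_fraction probe filter level, see
#'   [filter_missing_probes()]
#' @param association_threshold per-phase edge significance level (strict)
#' @param fourd_threshold four-dimensional edge significance level (strict)
#' @param universe `"filtered"` (default: genes surviving the probe filter
#'   form the hypergeometric universe) or `"input"` (all probes of the input
#'   matrix, for sensitivity checks)
#' @param unit age unit used in phase labels
#' @param seed optional integer seed recorded in the manifest and applied
#'   before the run (the standard pipeline is deterministic; the seed
#'   matters when a criterion or downstream step draws random numbers)
#' @return an object of class `PipelineConfig`
#' @export
pipeline_config <- function(matrix_path, annotation_path, out_dir,
                            detection_path = NULL, gene_map_path = NULL,
                            scale = c("log2", "linear"),
                            criterion = change_criterion("fold_change"),
                            max_missing_fraction = 0.80,
                            association_threshold = 0.005,
                            fourd_threshold = 1e-4,
                            universe = c("filtered", "input"),
                            unit = "M", seed = NULL) {
  scale <- match.arg(scale)
  universe <- match.arg(universe)
  stopifnot(inherits(criterion, "ChangeCriterion"),
            association_threshold > 0, association_threshold < 1,
            fourd_threshold > 0, fourd_threshold < 1)
  if (!criterion$kind %in% c("fold_change", "z_test"))
    stop("run_pipeline supports criterion kinds 'fold_change' and 'z_test'; ",
         "use detect_mas5_composite()/detect_consensus() directly for the others")
  structure(list(matrix_path = matrix_path,
                 annotation_path = annotation_path, out_dir = out_dir,
                 detection_path = detection_path,
                 gene_map_path = gene_map_path, scale = scale,
                 criterion = criterion,
                 max_missing_fraction = max_missing_fraction,
                 association_threshold = association_threshold,
                 fourd_threshold = fourd_threshold, universe = universe,
                 unit = unit, seed = seed),
            class = "PipelineConfig")
}

#' Run the full spatio-temporal association pipeline
#'
#' Validates inputs before writing anything (a bad path fails with no
#' partial outputs), then executes every stage and writes to `out_dir`:
#' `change_sets.tsv` (node table), `gene_memberships.tsv` (node/gene pairs),
#' one `edges_phase_<label>.tsv` and `network_phase_<label>.graphml` per age
#' phase, `edges_4d.tsv` / `network_4d.graphml`, `node_categories.tsv`,
#' `summary.txt` and a machine-readable `manifest.json` holding the package
#' version, the effective configuration, input checksums and headline
#' counts. Given identical inputs, configuration and seed the outputs are
#' byte-identical.
#'
#' @param cfg a [pipeline_config()]
#' @return invisibly, the run report: list with `dataset`, `sets`,
#'   `phase_networks`, `fourd`, `summary` (data.frame), `files`, `config`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  inputs <- c(matrix = cfg$matrix_path, annotations = cfg$annotation_path)
  if (!is.null(cfg$detection_path))
    inputs <- c(inputs, detection = cfg$detection_path)
  if (!is.null(cfg$gene_map_path))
    inputs <- c(inputs, gene_map = cfg$gene_map_path)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent))
    stop("pipeline input file(s) not found: ",
         paste(sprintf("%s (%s)", absent, names(absent)), collapse = ", "))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  ds <- tryCatch(
    load_expression(cfg$matrix_path, cfg$annotation_path, scale = cfg$scale,
                    detection_path = cfg$detection_path),
    error = function(e) stop("stage load_expression: ", conditionMessage(e)))
  n_input <- nrow(ds$values)
  ds <- filter_missing_probes(ds, cfg$max_missing_fraction)
  if (!is.null(cfg$gene_map_path)) {
    gene_map <- utils::read.delim(cfg$gene_map_path, stringsAsFactors = FALSE)
    ds <- tryCatch(collapse_duplicate_probes(ds, gene_map),
                   error = function(e)
                     stop("stage collapse_duplicate_probes: ",
                          conditionMessage(e)))
  }
  N <- if (cfg$universe == "filtered") nrow(ds$values) else n_input

  sets <- tryCatch(build_change_sets(ds, cfg$criterion, unit = cfg$unit),
                   error = function(e)
                     stop("stage build_change_sets: ", conditionMessage(e)))

  phase_labels <- unique(vapply(sets, function(s) s$phase$label, ""))
  phase_networks <- lapply(phase_labels, function(lbl) {
    in_phase <- Filter(function(s) s$phase$label == lbl, sets)
    build_phase_network(in_phase, N = N,
                        threshold = cfg$association_threshold)
  })
  names(phase_networks) <- phase_labels
  fourd <- build_4d_network(sets, N = N, threshold = cfg$fourd_threshold)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wt <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files[[name]] <<- path
    path
  }

  node_tab <- do.call(rbind, lapply(sets, function(s) data.frame(
    node_name = s$node_name, tissue = s$phase$tissue,
    phase = s$phase$label, direction = s$direction,
    n_genes = length(s$genes), stringsAsFactors = FALSE)))
  rownames(node_tab) <- NULL
  wt(node_tab, "change_sets.tsv")

  memb <- do.call(rbind, lapply(sets, function(s)
    if (length(s$genes))
      data.frame(node_name = s$node_name, gene = s$genes,
                 stringsAsFactors = FALSE)))
  if (is.null(memb))
    memb <- data.frame(node_name = character(), gene = character())
  rownames(memb) <- NULL
  wt(memb, "gene_memberships.tsv")

  for (lbl in phase_labels) {
    net <- phase_networks[[lbl]]
    write_edge_list(net, wt_path <- file.path(
      cfg$out_dir, sprintf("edges_phase_%s.tsv", lbl)))
    files[[basename(wt_path)]] <- wt_path
    gml <- file.path(cfg$out_dir, sprintf("network_phase_%s.graphml", lbl))
    write_graphml(net, gml)
    files[[basename(gml)]] <- gml
  }
  write_edge_list(fourd, f4 <- file.path(cfg$out_dir, "edges_4d.tsv"))
  files[["edges_4d.tsv"]] <- f4
  write_graphml(fourd, g4 <- file.path(cfg$out_dir, "network_4d.graphml"))
  files[["network_4d.graphml"]] <- g4
  wt(classify_4d_nodes(fourd), "node_categories.tsv")

  summary_df <- do.call(rbind, c(lapply(phase_networks, summarize_network),
                                 list(summarize_network(fourd))))
  rownames(summary_df) <- NULL
  report <- list(dataset = ds, sets = sets,
                 phase_networks = phase_networks, fourd = fourd,
                 summary = summary_df, files = files, config = cfg)
  class(report) <- "agesync_run"

  sum_path <- file.path(cfg$out_dir, "summary.txt")
  writeLines(render_summary(report), sum_path)
  files[["summary.txt"]] <- sum_path

  manifest <- list(
    package = "agesync",
    version = as.character(utils::packageVersion("agesync")),
    config = list(
      scale = cfg$scale, criterion = unclass(cfg$criterion),
      max_missing_fraction = cfg$max_missing_fraction,
      association_threshold = cfg$association_threshold,
      fourd_threshold = cfg$fourd_threshold, universe = cfg$universe,
      universe_N = N, unit = cfg$unit, seed = cfg$seed),
    inputs = lapply(seq_along(inputs), function(i) list(
      role = names(inputs)[i], path = unname(inputs[i]),
      md5 = unname(tools::md5sum(inputs[i])))),
    counts = list(genes_input = n_input, genes_analyzed = nrow(ds$values),
                  change_sets = length(sets),
                  phase_networks = length(phase_networks),
                  fourd_edges = nrow(fourd$edges)))
  man_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files[["manifest.json"]] <- man_path
  report$files <- files
  invisible(report)
}

#' Render a run's per-phase summary as a text table
#'
#' One row per age phase (plus the four-dimensional map): synchronous
#' edges, asynchronous edges, connected and stochastic node counts, with the
#' significance threshold and universe size stated in the header.
#'
#' @param report an `agesync_run` from [run_pipeline()], or a list of
#'   `AssociationNetwork`s
#' @return character vector of table lines (invisible when printed via
#'   `writeLines`)
#' @export
render_summary <- function(report) {
  nets <- if (inherits(report, "agesync_run"))
    c(report$phase_networks, list(report$fourd))
  else if (inherits(report, "AssociationNetwork")) list(report)
  else report
  stopifnot(all(vapply(nets, inherits, TRUE, "AssociationNetwork")))
  s <- do.call(rbind, lapply(nets, summarize_network))
  header <- sprintf("scope: N=%d genes; thresholds: %s",
                    s$N[1],
                    paste(sprintf("%s p<%g", s$phase_scope, s$threshold),
                          collapse = ", "))
  fmt <- "%-10s %10s %11s %9s %10s"
  lines <- c(header,
             sprintf(fmt, "phase", "sync_edges", "async_edges", "connected",
                     "stochastic"),
             sprintf(fmt, s$phase_scope, s$sync_edges, s$async_edges,
                     s$connected_nodes, s$stochastic_nodes))
  lines
}

#' @export
print.agesync_run <- function(x, ...) {
  cat(sprintf("agesync pipeline run: %d change sets, %d phase networks\n",
              length(x$sets), length(x$phase_networks)))
  writeLines(render_summary(x))
  invisible(x)
}
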