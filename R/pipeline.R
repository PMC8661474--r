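#' Assemble a pipeline run configuration
#'
#' Exactly one of `input` (paths to `features`, `metadata`, `catalog` TSVs)
#' or `simulate` (arguments for [make_ground_truth()] / [simulate_cohort()])
#' must be given.  Every default is echoed into the run manifest so the
#' effective parameter set is never ambiguous.
#'
#' @param input named list with `features`, `metadata`, `catalog` paths, or
#'   `NULL`.
#' @param simulate named list of synthetic-cohort parameters, or `NULL`.
#' @param nrr named list overriding [nrr_config()] arguments.
#' @param nrr_threshold NRR retention threshold (inclusive), default 0.1.
#' @param rho_threshold strong-candidate threshold on `|rho|`, default 0.5.
#' @param group_scale scale for group tests, `"log2"` or `"concentration"`.
#' @param sd_method autoscaling SD convention, see [log2_autoscale()].
#' @param seed master seed for simulation and NRR substreams.
#' @param output_dir where all stage outputs are written.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, simulate = NULL, nrr = list(),
                       nrr_threshold = 0.1, rho_threshold = 0.5,
                       group_scale = "log2", sd_method = "sample",
                       seed = 1L, output_dir = "lipidnrr_run") {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' or 'simulate' must be given")
  stopifnot(nrr_threshold >= 0, nrr_threshold <= 1,
            rho_threshold >= 0, rho_threshold <= 1)
  if (!is.null(input)) {
    miss <- setdiff(c("features", "metadata", "catalog"), names(input))
    if (length(miss)) stop("input lacks: ", paste(miss, collapse = ", "))
  }
  structure(list(input = input, simulate = simulate, nrr = nrr,
                 nrr_threshold = nrr_threshold,
                 rho_threshold = rho_threshold,
                 group_scale = group_scale, sd_method = sd_method,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

#' Run the full pipeline
#'
#' Executes: simulate (or read) -> clean -> half-minimum impute -> log2 +
#' autoscale -> matched-pair fold change -> Spearman matrix -> NRR matrix ->
#' NRR histogram -> NRR filter -> lipid-lipid pruning -> network assembly ->
#' strong candidates -> per-feature group tests -> confounder scan.  Every
#' stage output is written to `output_dir` and listed, together with the
#' echoed parameters, dropped features and stage timings, in
#' `manifest.json`.
#'
#' Output depends only on (inputs, config, seed): re-running with the same
#' configuration reproduces all TSV/GraphML outputs byte for byte.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  outputs <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[lipidnrr] stage: ", name)
    v <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }
  emit <- function(name, writer) {
    outputs[[name]] <<- file.path(out_dir, name)
    writer(outputs[[name]])
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    truth_args <- sim[intersect(names(sim), names(formals(make_ground_truth)))]
    if (is.null(truth_args$seed)) truth_args$seed <- config$seed
    truth <- stage("make_ground_truth", do.call(make_ground_truth, truth_args))
    cohort_args <- sim[intersect(names(sim), names(formals(simulate_cohort)))]
    cohort_args$truth <- truth
    if (is.null(cohort_args$seed)) cohort_args$seed <- config$seed
    cohort <- stage("simulate_cohort", do.call(simulate_cohort, cohort_args))
    stage("write_cohort", write_cohort(cohort, file.path(out_dir, "cohort")))
    table <- cohort$table
    metadata <- cohort$metadata
    catalog <- cohort$catalog
  } else {
    table <- stage("read_feature_table",
                   read_feature_table(config$input$features))
    metadata <- stage("read_metadata", read_metadata(config$input$metadata))
    catalog <- stage("read_catalog", read_catalog(config$input$catalog))
  }

  pre <- stage("preprocess",
               preprocess_cohort(table, metadata, sd_method = config$sd_method))
  fc <- pre$fold_change
  emit("fold_change.tsv", function(p) write_feature_table(fc, p))

  rho <- stage("spearman_matrix", spearman_matrix(fc))
  nrr_args <- config$nrr
  if (is.null(nrr_args$seed)) nrr_args$seed <- config$seed
  ncfg <- do.call(nrr_config, nrr_args)
  nrr <- stage("nrr_matrix", nrr_matrix(fc, ncfg))
  emit("nrr_matrix.tsv", function(p) write_records(
    data.frame(feature_id = rownames(nrr), nrr, check.names = FALSE), p))
  hist_df <- stage("nrr_histogram", nrr_histogram(nrr))
  emit("nrr_histogram.tsv", function(p) write_records(hist_df, p))

  edges <- stage("filter_nonspurious",
                 filter_nonspurious(rho, nrr, catalog, config$nrr_threshold))
  pruned <- stage("prune_lipid_lipid", prune_lipid_lipid(edges, catalog))
  emit("edges.tsv", function(p) write_edge_list(pruned, p, catalog))
  if (nrow(pruned) > 0L) {
    net <- stage("build_network", build_network(pruned, catalog))
    emit("network.graphml", function(p) write_graphml(net, p))
  }
  cands <- stage("strong_candidates",
                 strong_candidates(pruned, catalog, config$rho_threshold))
  emit("candidates.tsv", function(p) write_candidates(cands, p, catalog))

  gt <- stage("per_feature_group_test",
              per_feature_group_test(table, metadata,
                                     scale = config$group_scale))
  emit("group_tests.tsv", function(p) write_records(gt, p))
  conf <- if (sum(metadata$antipsychotic_flag) > 0 &&
              any(!metadata$antipsychotic_flag[metadata$group == "patient"])) {
    stage("confounder_scan",
          confounder_scan(table, metadata, scale = config$group_scale))
  } else NULL
  if (!is.null(conf))
    emit("confounder_scan.tsv", function(p) write_records(conf, p))

  manifest <- list(
    parameters = list(
      nrr = unclass(ncfg), nrr_threshold = config$nrr_threshold,
      rho_threshold = config$rho_threshold, group_scale = config$group_scale,
      sd_method = config$sd_method, seed = config$seed,
      simulate = config$simulate, input = config$input),
    dropped_features = pre$dropped_features,
    n_pairs = nrow(fc), n_features = ncol(fc),
    n_edges = nrow(pruned), n_candidates = nrow(cands),
    outputs = as.list(outputs), timings = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
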