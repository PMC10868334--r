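#' Run an end-to-end pipeline step from a configuration list
#'
#' Executes one subcommand — `test-global`, `test-cluster`, `simulate`,
#' `evaluate` or `benchmark` — writing its artifacts plus the configuration
#' that produced them (`config.json`) and a log file into the output
#' directory. Runs are reproducible from the stored config and inputs;
#' simulation subcommands require an explicit seed. On failure, files
#' created by the run are removed.
#'
#' Config fields by subcommand (all paths relative to the working
#' directory):
#' * `test-global` / `test-cluster`: `counts`, `meta`, optional `format`,
#'   `mode` (cluster test), `fdr`, filter/normalization settings;
#' * `simulate`: simulator parameters of [simulate_synthetic()] plus
#'   mandatory `seed`;
#' * `evaluate`: `results`, `truth`, optional `thresholds`;
#' * `benchmark`: `patterns`, `seeds` (mandatory), simulator parameters —
#'   runs simulate/test/evaluate per pattern and seed and aggregates.
#'
#' @param config Named list with at least `subcommand` and `outdir`.
#' @return Invisibly, a list of artifact paths (and, for in-memory use, the
#'   main result object).
#' @export
run_pipeline <- function(config) {
  if (is.null(config[["subcommand"]]))
    stop("config must name a subcommand")
  sub <- match.arg(config[["subcommand"]],
                   c("test-global", "test-cluster", "simulate", "evaluate",
                     "benchmark"))
  if (is.null(config[["outdir"]])) stop("config must name an output directory")
  outdir <- config[["outdir"]]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  created <- character(0)
  note <- function(p) { created <<- c(created, p); p }
  logfile <- note(file.path(outdir, "run.log"))
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  res <- tryCatch({
    jsonlite::write_json(config, note(file.path(outdir, "config.json")),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    logmsg("subcommand: ", sub)
    switch(sub,
      `test-global` = ,
      `test-cluster` = .run_test(sub, config, outdir, note, logmsg),
      simulate = .run_simulate(config, outdir, note, logmsg),
      evaluate = .run_evaluate(config, outdir, note, logmsg),
      benchmark = .run_benchmark(config, outdir, note, logmsg))
  }, error = function(e) {
    suppressWarnings(file.remove(created[file.exists(created)]))
    stop("pipeline '", sub, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

.read_inputs <- function(config) {
  if (is.null(config[["counts"]]) || is.null(config[["meta"]]))
    stop("missing required input path(s): need 'counts' and 'meta'")
  cm <- read_count_matrix(config[["counts"]],
                          format = config[["format"]] %||% "auto")
  spots <- read_spot_table(config[["meta"]])
  list(cm = cm, spots = spots)
}

.run_test <- function(sub, config, outdir, note, logmsg) {
  inp <- .read_inputs(config)
  logmsg("loaded ", nrow(inp$cm$counts), " spots x ",
         ncol(inp$cm$counts), " genes")
  args <- list(cm = inp$cm, spots = inp$spots,
               model = config[["model"]] %||% "auto",
               filter = config[["filter"]] %||% TRUE,
               min_gene_count = config[["min_gene_count"]] %||% 20,
               min_gene_spots = config[["min_gene_spots"]] %||% 10,
               min_spot_count = config[["min_spot_count"]] %||% 10,
               normalize = if (isFALSE(config[["tmm"]])) "libsize" else "tmm",
               prior_df = config[["prior_df"]] %||% 10)
  res <- if (sub == "test-global") do.call(test_global, args)
  else do.call(test_cluster, c(args, list(mode = config[["mode"]] %||% "fast")))
  out <- note(file.path(outdir, config[["out"]] %||% "results.tsv"))
  write_results(res, out)
  q <- config[["fdr"]] %||% 0.05
  logmsg(sum(!is.na(res$fdr) & res$fdr <= q), " rows at FDR <= ", q)
  invisible(list(results = res, path = out))
}

.run_simulate <- function(config, outdir, note, logmsg) {
  if (is.null(config[["seed"]])) stop("simulation requires an explicit seed")
  sim <- simulate_synthetic(
    n_spots = config[["n_spots"]] %||% 1000L,
    n_genes = config[["n_genes"]] %||% 1000L,
    n_clusters = config[["n_clusters"]] %||% 5L,
    cluster_props = config[["cluster_props"]],
    prop_svg = config[["prop_svg"]] %||% 0.5,
    phi = config[["phi"]] %||% 0.4,
    pattern = config[["pattern"]] %||% "mixture",
    n_samples = config[["n_samples"]] %||% 1L,
    seed = config[["seed"]])
  mtx <- write_count_matrix_mtx(sim$counts, outdir)
  note(mtx)
  note(file.path(outdir, c("barcodes.tsv", "features.tsv")))
  meta <- note(file.path(outdir, "meta.tsv"))
  utils::write.table(as.data.frame(sim$spots), meta, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- note(file.path(outdir, "truth.tsv"))
  utils::write.table(sim$truth, tr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logmsg("simulated ", nrow(sim$counts$counts), " spots x ",
         ncol(sim$counts$counts), " genes (", config[["pattern"]] %||% "mixture",
         ")")
  invisible(list(sim = sim, counts = mtx, meta = meta, truth = tr))
}

.run_evaluate <- function(config, outdir, note, logmsg) {
  if (is.null(config[["results"]]) || is.null(config[["truth"]]))
    stop("evaluate requires 'results' and 'truth' paths")
  res <- read_results(config[["results"]])
  truth <- utils::read.table(config[["truth"]], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  thresholds <- config[["thresholds"]] %||% c(0.01, 0.05, 0.1, 0.2)
  curve <- tpr_fdr(res, truth, thresholds)
  nulls <- res$pvalue[match(truth$gene_id[!truth$is_svg], res$gene_id)]
  report <- list(tpr_fdr = curve)
  if (sum(!is.na(nulls)) >= 20)
    report$null_uniformity <- null_uniformity(nulls)
  path <- note(file.path(outdir, config[["report"]] %||% "report.json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  logmsg("evaluation report written to ", path)
  invisible(list(report = report, path = path))
}

.run_benchmark <- function(config, outdir, note, logmsg) {
  if (is.null(config[["seeds"]])) stop("benchmark requires explicit seeds")
  patterns <- config[["patterns"]] %||% "mixture"
  runs <- list()
  for (pat in patterns) for (seed in config[["seeds"]]) {
    tag <- paste0(pat, "_seed", seed)
    logmsg("run ", tag)
    sim <- simulate_synthetic(
      n_spots = config[["n_spots"]] %||% 500L,
      n_genes = config[["n_genes"]] %||% 300L,
      n_clusters = config[["n_clusters"]] %||% 4L,
      prop_svg = config[["prop_svg"]] %||% 0.5,
      phi = config[["phi"]] %||% 0.4,
      pattern = pat, seed = seed)
    res <- test_global(sim$counts, sim$spots,
                       min_gene_count = 1, min_gene_spots = 1,
                       min_spot_count = 1)
    curve <- tpr_fdr(res, sim$truth)
    rp <- note(file.path(outdir, paste0("results_", tag, ".tsv")))
    write_results(res, rp)
    runs[[tag]] <- list(pattern = pat, seed = seed, tpr_fdr = curve)
  }
  agg <- do.call(rbind, lapply(names(runs), function(tag) {
    cbind(run = tag, pattern = runs[[tag]]$pattern, runs[[tag]]$tpr_fdr)
  }))
  report <- list(runs = agg)
  path <- note(file.path(outdir, "benchmark_report.json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  logmsg("benchmark report written to ", path)
  invisible(list(report = report, path = path, runs = runs))
}
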