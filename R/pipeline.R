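# Single-config orchestration of the full analysis: load or synthesize a
# cohort, evaluate the model suite across seeds, run the coalition
# domain-importance analysis, and write SHAP summaries, plus a
# reproducibility manifest.

#' Build a run configuration
#'
#' @param config named list (typically from [read_run_config()]) with:
#'   exactly one of `cohort` (list: `csv`, `domain_map` paths) or
#'   `synthesis` (arguments for [cohort_spec()], or one of the named
#'   presets `"recovery"` / `"ushape"`); optional `split`
#'   (`train_fraction`, `stratified`), `models` (character vector of
#'   model names; default the boosted tree + logistic + benchmark),
#'   `seeds` (default 1:10), `domain_metric` (default `"pr_auc"`),
#'   `domain_weighting`, `coalition_model`, `shap`
#'   (`breaks`, `threshold`), and `output_dir`.
#' @return Validated `run_config` object.
#' @export
run_config <- function(config) {
  has_cohort <- !is.null(config$cohort)
  has_synth <- !is.null(config$synthesis)
  if (has_cohort == has_synth) {
    stop("config must declare exactly one of `cohort` and `synthesis`",
         call. = FALSE)
  }
  seeds <- as.integer(unlist(config$seeds %||% 1:10))
  if (length(seeds) == 0L) stop("`seeds` must be non-empty", call. = FALSE)
  cfg <- list(
    cohort = config$cohort,
    synthesis = config$synthesis,
    split = list(
      train_fraction = config$split$train_fraction %||% 0.7,
      stratified = config$split$stratified %||% TRUE),
    models = unlist(config$models %||% c("gbm_leafwise", "logistic")),
    seeds = seeds,
    domain_metric = config$domain_metric %||% "pr_auc",
    domain_weighting = config$domain_weighting %||% "unweighted_mean",
    coalition_model = config$coalition_model %||% "gbm_leafwise",
    shap = list(breaks = unlist(config$shap$breaks) %||%
                  c(seq(50, 80, by = 5), 110),
                threshold = config$shap$threshold %||% 0.1),
    output_dir = config$output_dir %||% "mortdomains_output")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) run_config(read_config(path))

resolve_synthesis_spec <- function(synthesis, seed) {
  if (is.character(synthesis) && length(synthesis) == 1L) {
    return(switch(synthesis,
                  recovery = recovery_spec(seed = seed),
                  ushape = ushape_spec(seed = seed),
                  stop("unknown synthesis preset: ", synthesis,
                       call. = FALSE)))
  }
  args <- synthesis
  if (!is.null(args$domain_sizes)) {
    args$domain_sizes <- unlist(args$domain_sizes)
  }
  if (!is.null(args$domain_betas)) {
    args$domain_betas <- lapply(args$domain_betas, unlist)
  }
  args$seed <- args$seed %||% seed
  do.call(cohort_spec, args)
}

load_or_generate <- function(cfg) {
  if (!is.null(cfg$cohort)) {
    load_cohort(cfg$cohort$csv, cfg$cohort$domain_map)
  } else {
    gen <- generate_cohort(resolve_synthesis_spec(cfg$synthesis,
                                                  cfg$seeds[1L]))
    gen[c("table", "map")]
  }
}

log_msg <- function(level, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or synthesize the cohort; (2) evaluate the configured
#' model suite plus the demographic benchmark across seeds (metric report
#' CSV/JSON); (3) leave-one-domain-out coalition analysis (importance CSV
#' and ledger JSON); (4) SHAP attribution of the coalition model fitted
#' on the first seed's training split, summarized over the full cohort
#' overall and by age bin (CSVs); (5) a reproducibility manifest.
#'
#' @param config a `run_config` (or plain list accepted by
#'   [run_config()]).
#' @param quiet suppress progress logging.
#' @return Invisibly, a list with the in-memory results and the output
#'   file paths.
#' @export
run_all <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  t0 <- Sys.time()
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) log_msg("INFO", ...)

  say("stage 1/4: cohort")
  data <- load_or_generate(cfg)
  validate_domain_map(data$table, data$map)

  say("stage 2/4: model suite (", length(cfg$models), " models x ",
      length(cfg$seeds), " seeds)")
  specs <- lapply(cfg$models, model_spec)
  names(specs) <- cfg$models
  split <- split_spec(cfg$split$train_fraction,
                      stratified = cfg$split$stratified)
  report <- evaluate_suite(specs, data$table, split, cfg$seeds)
  write_report(report,
               csv_path = file.path(cfg$output_dir, "metric_report.csv"),
               json_path = file.path(cfg$output_dir, "metric_report.json"))

  say("stage 3/4: domain coalition analysis (",
      2^length(data$map$domains) - 1, " coalitions per seed)")
  dom <- run_domain_analysis(data$table, data$map,
                             spec = model_spec(cfg$coalition_model),
                             split = split, seeds = cfg$seeds,
                             metric_name = cfg$domain_metric,
                             weighting = cfg$domain_weighting)
  utils::write.csv(dom$importance,
                   file.path(cfg$output_dir, "domain_importance.csv"),
                   row.names = FALSE)
  write_ledger(dom$ledger,
               file.path(cfg$output_dir, "coalition_ledger.json"))

  say("stage 4/4: SHAP summaries")
  split$seed <- cfg$seeds[1L]
  parts <- split_cohort(data$table, split)
  shap_model <- fit_model(model_spec(cfg$coalition_model,
                                     seed = child_seed(cfg$seeds[1L],
                                                       "shap_fit")),
                          parts$train)
  shap <- compute_shap(shap_model, data$table)
  overall <- mean_abs_shap(shap, threshold = cfg$shap$threshold)
  overall$domain <- unname(data$map$assignment[overall$feature])
  by_age <- age_stratified_shap(shap, data$table, breaks = cfg$shap$breaks)
  utils::write.csv(overall, file.path(cfg$output_dir, "shap_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(by_age),
                   file.path(cfg$output_dir, "shap_by_age.csv"),
                   row.names = FALSE)

  manifest <- list(
    config = unclass(cfg),
    versions = list(
      r = as.character(getRversion()),
      mortdomains = as.character(utils::packageVersion("mortdomains")),
      xgboost = as.character(utils::packageVersion("xgboost")),
      ranger = as.character(utils::packageVersion("ranger"))),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done in ", sprintf("%.1f", manifest$wall_clock_sec), " s")
  invisible(list(report = report, domain = dom, shap_summary = overall,
                 shap_by_age = by_age, output_dir = cfg$output_dir))
}

#' Command-line entry point
#'
#' Subcommands: `generate` (write a synthetic cohort bundle), `evaluate`
#' (model suite only), `domains` (coalition analysis only), `shap`
#' (attribution summaries only), `all` (full pipeline). All subcommands
#' require `--config <file>`. Logs go to stderr; results to files under
#' the configured output directory.
#'
#' @param argv character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code: 0 on success, 1 on a stage error, 2 on a
#'   usage error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mortdomains <generate|evaluate|domains|shap|all>",
    "--config <file> [--quiet]")
  if (length(argv) < 1L || !argv[1L] %in%
      c("generate", "evaluate", "domains", "shap", "all")) {
    message(usage)
    return(2L)
  }
  sub <- argv[1L]
  cfg_idx <- which(argv == "--config")
  if (length(cfg_idx) != 1L || cfg_idx + 1L > length(argv)) {
    message("--config <file> is required\n", usage)
    return(2L)
  }
  cfg_path <- argv[cfg_idx + 1L]
  quiet <- "--quiet" %in% argv
  if (!file.exists(cfg_path)) {
    message("config file not found: ", cfg_path)
    return(1L)
  }
  res <- tryCatch({
    cfg <- read_run_config(cfg_path)
    if (sub == "generate") {
      if (is.null(cfg$synthesis)) {
        stop("`generate` needs a synthesis block", call. = FALSE)
      }
      spec <- resolve_synthesis_spec(cfg$synthesis, cfg$seeds[1L])
      write_synthetic_bundle(spec, cfg$output_dir)
    } else if (sub == "all") {
      run_all(cfg, quiet = quiet)
    } else {
      # stage subcommands reuse the same config; run the single stage by
      # narrowing the pipeline
      run_stage(cfg, sub, quiet)
    }
    0L
  }, error = function(e) {
    message("error [", sub, "]: ", conditionMessage(e))
    1L
  })
  res
}

run_stage <- function(cfg, stage, quiet = FALSE) {
  data <- load_or_generate(cfg)
  validate_domain_map(data$table, data$map)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  split <- split_spec(cfg$split$train_fraction,
                      stratified = cfg$split$stratified)
  if (stage == "evaluate") {
    specs <- lapply(cfg$models, model_spec)
    names(specs) <- cfg$models
    report <- evaluate_suite(specs, data$table, split, cfg$seeds)
    write_report(report,
                 csv_path = file.path(cfg$output_dir, "metric_report.csv"),
                 json_path = file.path(cfg$output_dir, "metric_report.json"))
    return(invisible(report))
  }
  if (stage == "domains") {
    dom <- run_domain_analysis(data$table, data$map,
                               spec = model_spec(cfg$coalition_model),
                               split = split, seeds = cfg$seeds,
                               metric_name = cfg$domain_metric,
                               weighting = cfg$domain_weighting)
    utils::write.csv(dom$importance,
                     file.path(cfg$output_dir, "domain_importance.csv"),
                     row.names = FALSE)
    write_ledger(dom$ledger,
                 file.path(cfg$output_dir, "coalition_ledger.json"))
    return(invisible(dom))
  }
  if (stage == "shap") {
    split$seed <- cfg$seeds[1L]
    parts <- split_cohort(data$table, split)
    model <- fit_model(model_spec(cfg$coalition_model,
                                  seed = child_seed(cfg$seeds[1L],
                                                    "shap_fit")),
                       parts$train)
    shap <- compute_shap(model, data$table)
    overall <- mean_abs_shap(shap, threshold = cfg$shap$threshold)
    by_age <- age_stratified_shap(shap, data$table,
                                  breaks = cfg$shap$breaks)
    utils::write.csv(overall, file.path(cfg$output_dir, "shap_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(by_age),
                     file.path(cfg$output_dir, "shap_by_age.csv"),
                     row.names = FALSE)
    return(invisible(list(overall = overall, by_age = by_age)))
  }
  stop("unknown stage: ", stage, call. = FALSE)
}
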