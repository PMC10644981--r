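#' Pipeline configuration files
#'
#' One YAML file drives all pipeline stages. Recognized keys (with
#' defaults) — simulation: `n_nodes` (84), `n_per_group` ([20, 28]),
#' `intra_hemisphere_density`, `inter_hemisphere_density`,
#' `base_weight_log_mean`, `base_weight_log_sd`, `subject_noise_sd`,
#' `n_planted`, `n_cross_hemisphere_planted`, `effect_size`, `seed`;
#' experiment: `k_folds` (5), `n_seeds` (1000), `epochs` (100),
#' `learning_rate` (1e-3), `split_seed` (0), `hidden` ([1024, 256, 64]),
#' `refold_per_seed` (false); analysis: `normalize` (true),
#' `saliency_mode` ("probability"), `k_top_nodes` (20), `k_top_edges`
#' (20). Unknown keys are an error, reported with their key path.
#'
#' @param path YAML file path (for `read_pipeline_config`).
#' @param config A named list of overrides (for `pipeline_config`).
#' @return Named list of class `pipeline_config` with all keys filled.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    n_nodes = 84L, n_per_group = c(20L, 28L),
    intra_hemisphere_density = 0.35, inter_hemisphere_density = 0.15,
    base_weight_log_mean = 3, base_weight_log_sd = 1,
    subject_noise_sd = 0.3, n_planted = 20L,
    n_cross_hemisphere_planted = 2L, effect_size = 2, seed = 1L,
    k_folds = 5L, n_seeds = 1000L, epochs = 100L, learning_rate = 1e-3,
    split_seed = 0L, hidden = c(1024L, 256L, 64L),
    refold_per_seed = FALSE, normalize = TRUE,
    saliency_mode = "probability", k_top_nodes = 20L, k_top_edges = 20L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, config)
  structure(out, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

config_sim <- function(cfg) {
  sim_config(n_nodes = cfg$n_nodes, n_per_group = cfg$n_per_group,
             intra_hemisphere_density = cfg$intra_hemisphere_density,
             inter_hemisphere_density = cfg$inter_hemisphere_density,
             base_weight_log_mean = cfg$base_weight_log_mean,
             base_weight_log_sd = cfg$base_weight_log_sd,
             subject_noise_sd = cfg$subject_noise_sd,
             n_planted = cfg$n_planted,
             n_cross_hemisphere_planted = cfg$n_cross_hemisphere_planted,
             effect_size = cfg$effect_size, seed = cfg$seed)
}

# Run manifest: config snapshot, seeds, input hashes, version, timestamps
# and every artifact emitted, so a run can be reproduced and audited.
write_run_manifest <- function(dir, cfg, stage, artifacts,
                               inputs = character(0), warnings = character(0)) {
  manifest <- list(
    tool = "connectomlp",
    version = as.character(utils::packageVersion("connectomlp")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    input_hashes = if (length(inputs))
      as.list(tools::md5sum(inputs)) else NULL,
    artifacts = as.list(artifacts),
    warnings = as.list(warnings))
  path <- file.path(dir, paste0("run_manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort from the simulation keys of a pipeline
#' config and writes matrix files, the participant manifest, the
#' ground-truth JSON and a run manifest.
#'
#' @param config A [pipeline_config()], config YAML path, or named list.
#' @param out_dir Output directory.
#' @return Invisibly, the manifest TSV path.
#' @export
simulate_to_dir <- function(config = pipeline_config(), out_dir) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else pipeline_config(as.list(unclass(config)))
  cohort <- generate_cohort(config_sim(cfg))
  manifest_path <- write_cohort(cohort, out_dir)
  artifacts <- c(manifest_path, file.path(out_dir, "ground_truth.json"),
                 vapply(cohort$connectomes, function(m)
                   file.path(out_dir, paste0(m$participant_id,
                                             "_connectome.txt")),
                   character(1)))
  write_run_manifest(out_dir, cfg, "simulate", artifacts)
  invisible(manifest_path)
}

#' Run the full classification and saliency pipeline
#'
#' Loads a cohort from a participant manifest, normalizes and vectorizes
#' each connectome, runs repeated-seed stratified k-fold cross-validation,
#' aggregates input gradients into per-class edge/node scores, and writes
#' a JSON run summary, score TSVs, a plain-text report and a run
#' manifest. Any validation warnings raised while loading (zeroed
#' diagonals, symmetrized inputs) are surfaced in the report.
#'
#' @param manifest_path Participant manifest TSV
#'   (`participant_id  path  label`).
#' @param config A [pipeline_config()], config YAML path, or named list.
#' @param out_dir Output directory for reports.
#' @param node_table Node table; defaults to the shipped DK-84 table for
#'   84-node cohorts, or generic two-block tables otherwise.
#' @param progress Print per-seed progress.
#' @return Invisibly, a list with the `repeated_run`, the
#'   `saliency_result` and the report paths.
#' @export
run_pipeline <- function(manifest_path, config = pipeline_config(),
                         out_dir, node_table = NULL, progress = FALSE) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else pipeline_config(as.list(unclass(config)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- read_manifest(manifest_path)
  if (is.null(node_table)) {
    probe <- length(readLines(manifest$path[1], warn = FALSE))
    node_table <- if (probe == 84L) dk_node_table() else
      sim_config(n_nodes = probe, n_per_group = c(1L, 1L))$node_table
  }
  load_warnings <- character(0)
  cohort <- withCallingHandlers(
    load_cohort(manifest, node_table),
    warning = function(w) {
      load_warnings <<- c(load_warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  design <- cohort_design(cohort, normalize = cfg$normalize)
  folds <- make_folds(design$y, k = cfg$k_folds,
                      split_seed = cfg$split_seed,
                      ids = manifest$participant_id)
  run <- run_repeated(design$X, design$y, folds, n_seeds = cfg$n_seeds,
                      config = train_config(epochs = cfg$epochs,
                                            learning_rate = cfg$learning_rate),
                      hidden = cfg$hidden, gradients = TRUE,
                      gradient_mode = cfg$saliency_mode,
                      refold_per_seed = cfg$refold_per_seed,
                      progress = progress)
  n_nodes <- nrow(node_table)
  sal <- compute_saliency(run$gradient_samples, node_table,
                          k_nodes = min(cfg$k_top_nodes, n_nodes),
                          k_edges = min(cfg$k_top_edges,
                                        n_nodes * (n_nodes - 1L) / 2L))
  paths <- write_saliency_tables(sal, out_dir)
  summary_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(list(
    n_participants = length(design$y),
    class_sizes = as.vector(table(factor(design$y, levels = 0:1))),
    k_folds = cfg$k_folds,
    fold_assignment = stats::setNames(as.list(folds$fold),
                                      manifest$participant_id),
    n_seeds = length(run$seeds),
    per_seed_accuracy = stats::setNames(as.list(run$accuracies),
                                        paste0("seed", run$seeds)),
    best_seed = run$best_seed,
    best_accuracy = run$best_accuracy,
    mean_accuracy = mean(run$accuracies),
    gradient_mode = sal$mode,
    gradient_samples_per_class = as.list(stats::setNames(sal$count,
                                                         c("class0", "class1"))),
    top_nodes = sal$top_nodes, top_edges = sal$top_edges,
    cross_hemisphere_in_top_edges = as.list(sal$cross_hemisphere),
    load_warnings = as.list(load_warnings)),
    summary_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  report_path <- file.path(out_dir, "report.txt")
  writeLines(text_report(run, sal, design, load_warnings), report_path)
  artifacts <- c(summary_path, report_path, paths)
  write_run_manifest(out_dir, cfg, "run", artifacts,
                     inputs = c(manifest_path, manifest$path),
                     warnings = load_warnings)
  invisible(list(run = run, saliency = sal,
                 summary_path = summary_path, report_path = report_path))
}

text_report <- function(run, sal, design, load_warnings = character(0)) {
  fmt_list <- function(df) {
    sprintf("  %2d. %-45s %+.4g", df$rank, df$item, df$score)
  }
  c(sprintf("connectomlp run report"),
    sprintf("Participants: %d (%d class 0 / %d class 1)",
            length(design$y), sum(design$y == 0), sum(design$y == 1)),
    sprintf("Experiments: %d init seeds x %d-fold CV",
            length(run$seeds), run$folds$k),
    sprintf("Best pooled accuracy: %.2f%% (seed %d); mean %.2f%%",
            100 * run$best_accuracy, run$best_seed,
            100 * mean(run$accuracies)),
    sprintf("Gradient samples: %d class-0, %d class-1 (%s mode)",
            sal$count[1], sal$count[2], sal$mode),
    "", sprintf("Top %d class-0 nodes:", nrow(sal$top_nodes$class0)),
    fmt_list(sal$top_nodes$class0),
    "", sprintf("Top %d class-1 nodes:", nrow(sal$top_nodes$class1)),
    fmt_list(sal$top_nodes$class1),
    "", sprintf("Top %d class-0 edges (%d cross-hemisphere):",
                nrow(sal$top_edges$class0), sal$cross_hemisphere[["class0"]]),
    fmt_list(sal$top_edges$class0),
    "", sprintf("Top %d class-1 edges (%d cross-hemisphere):",
                nrow(sal$top_edges$class1), sal$cross_hemisphere[["class1"]]),
    fmt_list(sal$top_edges$class1),
    if (length(load_warnings)) c("", "Input warnings:",
                                 paste0("  - ", load_warnings)) else character(0))
}
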