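#' Configuration for a full pipeline run
#'
#' @param seed integer master seed; every stage derives its RNG state from
#'   it, so a run is a deterministic function of the configuration.
#' @param styles stimulus styles to generate (subset of `"D1"`..`"D5"`).
#' @param n_participants simulated participants per dataset.
#' @param weber_median median Weber fraction of the simulated panel.
#' @param weber_sdlog between-participant log-SD of the Weber fraction.
#' @param geometry a [geometry_config()].
#' @param paper_mode fixed Bonferroni families 75/80/75 (see
#'   [run_validation()]).
#' @param outlier_fraction fraction of participants slowed down before
#'   preprocessing, to exercise the exclusion rule.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, styles = paste0("D", 1:5),
                       n_participants = 200L, weber_median = 0.25,
                       weber_sdlog = 0.3, geometry = geometry_config(),
                       paper_mode = TRUE, outlier_fraction = 0.02) {
  structure(list(seed = as.integer(seed), styles = styles,
                 n_participants = as.integer(n_participants),
                 weber_median = weber_median, weber_sdlog = weber_sdlog,
                 geometry = geometry, paper_mode = paper_mode,
                 outlier_fraction = outlier_fraction),
            class = "run_config")
}

# per-stage sub-seed, kept within 32-bit integer range
.stage_seed <- function(seed, stage, k = 0L) {
  (as.integer(seed) * 1009L + match(stage, c("generate", "simulate")) *
     101L + k) %% .Machine$integer.max
}

#' Run the full pipeline: generate, simulate, prepare, extract, analyze
#'
#' One-command driver. Output tree: `stimuli/<style>/` (images + stimulus
#' list), `trials/`, `behavior/` (per-stimulus aggregates + exclusion logs),
#' `features/`, `results/` (correlation, R-squared and incremental
#' R-squared tables, heatmaps, run log), and a `MANIFEST.json` with the
#' configuration, seed, package version and per-file content hashes.
#'
#' @param config a [run_config()].
#' @param out_dir output root directory.
#' @return The [run_validation()] report, invisibly; side effect: the
#'   directory tree.
#' @export
pipeline_run <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("stimuli", "trials", "behavior", "features", "results"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  features <- list(); behavior <- list()
  for (i in seq_along(config$styles)) {
    style <- config$styles[i]
    message("[", style, "] generating stimuli")
    sdir <- file.path(out_dir, "stimuli", style)
    gen <- generate_dataset(style, .stage_seed(config$seed, "generate", i),
                            out_dir = sdir, geometry = config$geometry)
    message("[", style, "] simulating behavior")
    set.seed(.stage_seed(config$seed, "simulate", i))
    panel <- participant_panel(config$n_participants,
                               weber_median = config$weber_median,
                               weber_sdlog = config$weber_sdlog)
    trials <- simulate_trials(gen$stimlist, panel)
    if (config$outlier_fraction > 0)
      trials <- inject_outliers(trials, config$outlier_fraction)
    write_trials(trials, file.path(out_dir, "trials",
                                   sprintf("alltrial_%s.csv", style)))
    message("[", style, "] preparing behavior")
    excl <- exclude_outliers(trials)
    beh <- aggregate_behavior(excl$kept)
    utils::write.csv(beh, file.path(out_dir, "behavior",
                                    sprintf("behavior_%s.csv", style)),
                     row.names = FALSE)
    utils::write.csv(excl$excluded,
                     file.path(out_dir, "behavior",
                               sprintf("excluded_%s.csv", style)),
                     row.names = FALSE)
    message("[", style, "] extracting features")
    feats <- extract_dataset(gen$stimlist, sdir)
    write_features(feats, file.path(out_dir, "features",
                                    sprintf("features_%s.csv", style)))
    features[[style]] <- feats
    behavior[[style]] <- beh
  }
  message("[analyze] running validation")
  report <- run_validation(features, behavior,
                           out_dir = file.path(out_dir, "results"),
                           paper_mode = config$paper_mode)
  .write_manifest(config, out_dir)
  invisible(report)
}

.write_manifest <- function(config, out_dir) {
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "MANIFEST.json")
  hashes <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    package = "numerosity",
    version = as.character(utils::packageVersion("numerosity")),
    seed = config$seed,
    config = config[setdiff(names(config), "geometry")],
    geometry = unclass(config$geometry),
    files = stats::setNames(as.list(hashes), files))
  jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
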