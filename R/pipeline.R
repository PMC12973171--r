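#' Default run configuration
#'
#' Returns the full configuration tree with the method's canonical
#' defaults (51-250 bp analysis range, 1-Mb bins, 1e6-fragment
#' subsample floor, 5/3 subsample policy, 64/32/16 network, stopping
#' thresholds 0.1 and 15%, 400-epoch cap, 0.25 test fraction, 20 splits
#' x 20 retrains, 10 CV folds). Any subset can be overridden by the
#' `config` list read from YAML.
#'
#' @param overrides Named list (possibly nested) of overrides.
#' @return Nested configuration list.
#' @export
default_run_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    size_range = c(51L, 250L),
    bin_size = 1e6,
    ingest = list(min_mapq = 20, size_window = c(1L, 1000L)),
    augment = list(min_fragments = 1e6, cancer_target = 5L,
                   healthy_choices = c(3L, 5L)),
    dwt = list(wavelet = "db4", level = "max", boundary = "symmetric"),
    model = list(kind = "dnn", features = "dwt",
                 hidden_sizes = c(64L, 32L, 16L), leaky_slope = 0.01,
                 dropout_rate = 0.2, learning_rate = 1e-3,
                 max_epochs = 400L, stopping = "rule1"),
    evaluation = list(n_splits = 20L, n_retrains = 20L,
                      test_fraction = 0.25, cv_folds = 10L),
    simulate = list(enabled = TRUE, n_healthy = 40L, n_cancer = 40L,
                    bins_per_sample = 50L, fragments_per_bin = 4000,
                    dispersion = 8, n_flowcells = 2L,
                    tumor_fraction = 0.3, short_shift_mass = 0.15),
    inputs = list(fragment_table = NULL, counts_table = NULL),
    out_dir = "fragwave_run"
  )
  modifyList(cfg, overrides)
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys override [default_run_config()].
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    fw_stop(sprintf("config file not found: %s", path),
            "fragwave_input_error")
  }
  default_run_config(yaml::read_yaml(path))
}

cohort_from_config <- function(config) {
  if (!is.null(config$inputs$counts_table) ||
      !is.null(config$inputs$fragment_table)) {
    path <- config$inputs$counts_table %||% config$inputs$fragment_table
    if (!file.exists(path)) {
      fw_stop(sprintf("input not found: %s", path), "fragwave_input_error")
    }
    meta_path <- config$inputs$metadata
    if (is.null(meta_path) || !file.exists(meta_path)) {
      fw_stop("a metadata table (patient_id, sample_id, class[, flowcell]) is required with external inputs",
              "fragwave_input_error")
    }
    md <- as.data.frame(data.table::fread(meta_path))
    bins <- if (!is.null(config$inputs$bins_bed)) {
      read_bins_bed(config$inputs$bins_bed)
    } else {
      build_bins(hg19_autosome_lengths(), config$bin_size)
    }
    counts <- if (!is.null(config$inputs$counts_table)) {
      read_binned_counts(path, bins,
                         size_window = config$ingest$size_window)
    } else {
      ingest_table(path, bins, size_window = config$ingest$size_window)
    }
    structure(list(counts = counts, metadata = md, bins = bins,
                   spec = NULL), class = "fragment_cohort")
  } else if (isTRUE(config$simulate$enabled)) {
    sim <- config$simulate
    spec <- cohort_spec(sim$n_healthy, sim$n_cancer,
                        bins_per_sample = sim$bins_per_sample,
                        fragments_per_bin = sim$fragments_per_bin,
                        dispersion = sim$dispersion,
                        n_flowcells = sim$n_flowcells,
                        bin_size = config$bin_size,
                        size_range = config$size_range,
                        seed = config$seed)
    generate_cohort(spec,
                    cancer_params = profile_model_params(
                      tumor_fraction = sim$tumor_fraction,
                      short_shift_mass = sim$short_shift_mass))
  } else {
    fw_stop("no inputs configured and simulation disabled",
            "fragwave_input_error")
  }
}

#' Run the full workflow from a configuration
#'
#' Executes the end-to-end pipeline: obtain binned fragment counts
#' (simulate, or load a fragment/counts table), subsample-augment,
#' compute PMFs, featurize, train, and assess under all three methods
#' over the configured split grid. All artifacts (config, manifest,
#' per-run metrics, summary) are written to `config$out_dir`, and the
#' run is fully reproducible from the config and seed.
#'
#' @param config Nested list from [read_run_config()] /
#'   [default_run_config()].
#' @return The `experiment_report` (invisibly also written to disk).
#' @export
run_pipeline <- function(config) {
  cohort <- cohort_from_config(config)
  report <- run_experiment(
    cohort,
    model = config$model$kind, features = config$model$features,
    n_splits = config$evaluation$n_splits,
    n_retrains = config$evaluation$n_retrains,
    test_fraction = config$evaluation$test_fraction,
    min_fragments = config$augment$min_fragments,
    cancer_target = config$augment$cancer_target,
    healthy_choices = config$augment$healthy_choices,
    size_range = config$size_range,
    dwt = dwt_config(config$dwt$wavelet, config$dwt$level,
                     config$dwt$boundary),
    dnn = dnn_spec(config$model$hidden_sizes, config$model$leaky_slope,
                   config$model$dropout_rate,
                   config$model$learning_rate,
                   config$model$max_epochs),
    stopping = config$model$stopping,
    base_seed = config$seed)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = config$seed,
                   package_version = as.character(packageVersion("fragwave")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  data.table::fwrite(report$runs, file.path(config$out_dir, "runs.tsv"),
                     sep = "\t")
  data.table::fwrite(report$summary,
                     file.path(config$out_dir, "summary.tsv"), sep = "\t")
  jsonlite::write_json(
    list(summary = report$summary, config = report$config,
         timing = report$timing),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
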