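#' Read and write feature tables
#'
#' The feature CSV is the interchange format between the spectral and
#' classification halves of the pipeline: columns `fly_id`, `genotype`, then
#' the 64 canonical amplitude columns (`sf0.014_tf1`, ..., `sf1.76_tf36`).
#' Amplitudes are written with 15 significant digits so a write/read
#' round-trip is lossless to numerical precision. The reader validates the
#' schema strictly: missing, extra or reordered columns and non-finite
#' amplitudes are errors.
#'
#' @param table Data frame as produced by [feature_matrix()].
#' @param path File path.
#' @return `read_features_csv()` returns the validated data frame.
#' @export
write_features_csv <- function(table, path) {
  want <- c("fly_id", "genotype", feature_names())
  if (!identical(names(table), want))
    stop("schema error: feature table must have columns fly_id, genotype, ",
         "then the 64 canonical amplitude columns")
  out <- table
  for (j in 3:ncol(out)) out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  want <- c("fly_id", "genotype", feature_names())
  extra <- setdiff(names(tab), want)
  if (length(extra))
    stop("schema error: unexpected column(s): ", paste(extra, collapse = ", "))
  missing_cols <- setdiff(want, names(tab))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  tab <- tab[, want]
  amp <- as.matrix(tab[, feature_names()])
  if (!is.numeric(amp))
    stop("validation error: non-numeric amplitude value")
  bad <- which(!is.finite(amp), arr.ind = TRUE)
  if (nrow(bad))
    stop("validation error: non-finite amplitude at row ", bad[1, 1],
         ", column '", feature_names()[bad[1, 2]], "'")
  if (any(amp < 0))
    stop("validation error: negative amplitude")
  tab
}

#' Run configuration
#'
#' A flat, schema-versioned YAML configuration driving [run_end_to_end()].
#' Unknown keys are rejected (silent key typos are the dominant failure mode
#' of config-driven pipelines) and the seed is mandatory; all randomness in a
#' run flows from it through per-stage derived streams.
#'
#' @param seed Integer root seed (mandatory).
#' @param genotypes Character vector of preset names to simulate (>= 2), or
#'   `NULL` with `genotype_presets` pointing at a JSON preset file whose
#'   entries are all used.
#' @param genotype_presets Optional path to a JSON preset file.
#' @param n_flies,n_reps,fs_hz,bin_s,discard_lead_bins Simulation and binning
#'   parameters.
#' @param gamma_grid,n_delta,k_folds,n_iter Classifier settings.
#' @param metric Distance metric for the similarity stage.
#' @param output_dir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, genotypes = c("ctrl_w1118", "pd_DJ1a"),
                       genotype_presets = NULL, n_flies = 20, n_reps = 10,
                       fs_hz = 1000, bin_s = 1, discard_lead_bins = 1,
                       gamma_grid = seq(0, 1, by = 0.1), n_delta = 10,
                       k_folds = 10, n_iter = 1000,
                       metric = "euclidean", output_dir = "ssvep_run") {
  if (missing(seed) || is.null(seed)) stop("validation error: seed is mandatory")
  cfg <- list(schema_version = 1L, seed = as.integer(seed),
              genotypes = genotypes, genotype_presets = genotype_presets,
              n_flies = n_flies, n_reps = n_reps, fs_hz = fs_hz, bin_s = bin_s,
              discard_lead_bins = discard_lead_bins,
              gamma_grid = gamma_grid, n_delta = n_delta, k_folds = k_folds,
              n_iter = n_iter, metric = metric, output_dir = output_dir)
  .validate_config(cfg)
  structure(cfg, class = "run_config")
}

.config_keys <- c("schema_version", "seed", "genotypes", "genotype_presets",
                  "n_flies", "n_reps", "fs_hz", "bin_s", "discard_lead_bins",
                  "gamma_grid", "n_delta", "k_folds", "n_iter", "metric",
                  "output_dir")

.validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("validation error: unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("validation error: seed is mandatory")
  if (!identical(as.integer(cfg$schema_version), 1L))
    stop("validation error: unsupported schema_version")
  for (k in c("n_flies", "n_reps", "fs_hz", "bin_s", "n_delta", "k_folds", "n_iter")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("validation error: '", k, "' must be a positive number")
  }
  if (cfg$discard_lead_bins < 0)
    stop("validation error: discard_lead_bins must be >= 0")
  if (!cfg$metric %in% c("euclidean", "correlation"))
    stop("validation error: metric must be euclidean or correlation")
  invisible(cfg)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  .validate_config(cfg)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
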