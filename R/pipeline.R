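run_config_defaults <- function() {
  list(
    seed = 7L,
    out_dir = "sonoqc_run",
    features = list(t_corr = 0.7, t_comp = 20, wiener_window = c(5L, 5L)),
    phantom = unclass(phantom_config()),
    admittance = list(mass = 5.625, stiffness = 50, damping = NULL),
    policy = list(delta_F = 0.25, f_min = 1, f_max = 20),
    svm = list(kernel = "radial", cost = 1, gamma = NULL),
    dataset = list(n_per_class = 500L, train_frac = 0.8),
    scan = list(rate = 30, max_ticks = 600L)
  )
}

merge_validated <- function(defaults, given, path) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown) > 0L)
    stop_sonoqc(sprintf("unknown config key(s) under '%s': %s", path,
                        paste(unknown, collapse = ", ")),
                "sonoqc_config_error")
  for (k in names(given)) defaults[[k]] <- given[[k]]
  defaults
}

#' Build and validate a run configuration
#'
#' Merges a YAML file (and/or an override list) over the package defaults.
#' Sections: `features`, `phantom`, `admittance`, `policy`, `svm`, `dataset`,
#' `scan`, plus top-level `seed` and `out_dir`. Unknown keys are rejected, and
#' every section is validated against its module's invariants before any
#' computation.
#'
#' @param path optional YAML file.
#' @param overrides optional named list merged over the file.
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- run_config_defaults()
  apply_layer <- function(cfg, layer) {
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown) > 0L)
      stop_sonoqc(sprintf("unknown top-level config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "sonoqc_config_error")
    for (k in names(layer)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && k != "phantom")
        merge_validated(cfg[[k]], layer[[k]], k)
      else if (k == "phantom") merge_validated(cfg[[k]], layer[[k]], k)
      else layer[[k]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_sonoqc(sprintf("config file not found: %s", path), "sonoqc_io_error")
    cfg <- apply_layer(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- apply_layer(cfg, overrides)
  # validate by constructing every component object
  cfg$features <- do.call(feature_config, cfg$features)
  cfg$phantom <- do.call(phantom_config, cfg$phantom)
  do.call(admittance_params, cfg$admittance)
  do.call(force_policy, cfg$policy)
  if (cfg$dataset$n_per_class < 1L || cfg$dataset$train_frac <= 0 ||
      cfg$dataset$train_frac >= 1)
    stop_sonoqc("dataset: n_per_class >= 1 and 0 < train_frac < 1 required",
                "sonoqc_config_error")
  if (cfg$scan$rate <= 0 || cfg$scan$max_ticks < 1L)
    stop_sonoqc("scan: rate > 0 and max_ticks >= 1 required",
                "sonoqc_config_error")
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  flat <- rapply(unclass(cfg), function(x) x, how = "replace")
  flat$out_dir <- NULL  # hash the scientific configuration, not the destination
  yaml::write_yaml(flat, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline end to end
#'
#' Generates a labeled synthetic dataset, splits it, trains the gated SVM,
#' evaluates it on the held-out frames, runs the force-adaptive scan loop, and
#' writes all artifacts (dataset + manifest, model, evaluation report, scan
#' trace, run manifest with seeds and a config hash) under the configured
#' output directory.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the trained `model`, the `evaluation`, the
#'   scan `trace`, and the artifact `paths`.
#' @export
run_end_to_end <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config"))
    stop_sonoqc("config must be a run_config object", "sonoqc_config_error")
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  say("[1/4] generating synthetic dataset (%d frames/class)",
      config$dataset$n_per_class)
  phantom <- virtual_phantom(config$phantom)
  ds_dir <- file.path(out, "dataset")
  ds <- generate_dataset(phantom, config$dataset$n_per_class, dir = ds_dir,
                         seed = derive_seed(seed, 1L))
  write_frame(phantom$reference, file.path(out, "reference.png"))

  say("[2/4] training gated SVM")
  parts <- split_frame_set(ds, config$dataset$train_frac,
                           seed = derive_seed(seed, 2L))
  model <- train_quality_model(parts$train, phantom$reference,
                               config = config$features,
                               seed = derive_seed(seed, 3L),
                               kernel = config$svm$kernel,
                               cost = config$svm$cost, gamma = config$svm$gamma)
  model_path <- file.path(out, "model.rds")
  save_quality_model(model, model_path)

  say("[3/4] evaluating on held-out frames")
  ev <- evaluate_quality_model(model, parts$test, phantom$reference)
  eval_path <- file.path(out, "evaluation.csv")
  write.csv(data.frame(metric = c("accuracy", "TP", "TN", "FP", "FN",
                                  "precision_high", "precision_low",
                                  "recall_high", "recall_low", "n_test"),
                       value = c(ev$accuracy, ev$confusion, ev$precision,
                                 ev$recall, ev$n)),
            eval_path, row.names = FALSE)

  say("[4/4] simulating force-adaptive scan")
  trace <- simulate_scan(model, phantom,
                         params = do.call(admittance_params, config$admittance),
                         policy = do.call(force_policy, config$policy),
                         rate = config$scan$rate,
                         max_ticks = config$scan$max_ticks,
                         seed = derive_seed(seed, 4L))
  trace_path <- file.path(out, "scan_trace.csv")
  write_scan_trace(trace, trace_path)

  manifest <- list(seed = seed,
                   derived_seeds = list(dataset = derive_seed(seed, 1L),
                                        split = derive_seed(seed, 2L),
                                        training = derive_seed(seed, 3L),
                                        scan = derive_seed(seed, 4L)),
                   config_hash = config_hash(config),
                   accuracy = ev$accuracy,
                   scan_converged = isTRUE(attr(trace, "converged")),
                   final_force_N = trace$force_N[nrow(trace)])
  yaml::write_yaml(manifest, file.path(out, "run_manifest.yaml"))
  say("done: accuracy %.3f; scan %s at %.2f N", ev$accuracy,
      if (manifest$scan_converged) "converged" else "did not converge",
      manifest$final_force_N)
  invisible(list(model = model, evaluation = ev, trace = trace,
                 paths = list(dataset = ds_dir, model = model_path,
                              evaluation = eval_path, trace = trace_path,
                              manifest = file.path(out, "run_manifest.yaml"))))
}
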