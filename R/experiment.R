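#' Run a full experiment from a configuration
#'
#' Drives the whole pipeline — lexicon generation (or loading), staged
#' training, optional lesioning, and analysis — from one configuration,
#' writing every artefact and a run manifest to `out_dir`.  All
#' randomness is derived from the single master seed, so re-running the
#' same configuration reproduces every output byte-identically.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' keys:
#' \preformatted{
#' protocol: sim1            # sim1..sim7 or custom
#' seed: 42                  # master seed
#' lexicon:                  # lexicon_config() fields, or `path:` to a CSV
#'   group_sizes: {"1": 20, "2": 20}
#'   mapping_mode: quasi_regular
#'   inconsistency_rate: 0.2
#' overrides:                # build_protocol() overrides
#'   epochs: [50, 50]
#'   eval_every: 10
#' lesion:                   # optional; triggers the lesion experiment
#'   severities: [0.05, 0.1, 0.2]
#'   methods: [zero_weights, add_noise]
#'   n_samples: 20
#'   noise_sd: 0.5
#' }
#'
#' Outputs: `lexicon.csv`, `network.json` (trained weights),
#' `trajectory.csv`, `unit_stats.csv`, `item_results.csv`,
#' `group_summary.csv`, `lesion_results.csv` / `lesion_summary.csv`
#' (when lesioning is configured), and `manifest.json`.
#'
#' @param config Path to a YAML config file, or a named list.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional master-seed override of the config's `seed`.
#' @return The run manifest, invisibly: resolved config, derived stream
#'   seeds, package version, input digest, and output file list.
#' @export
run_experiment <- function(config, out_dir, seed = NULL) {
  digest <- NULL
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    digest <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  cfg <- .validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seeds <- list(master = cfg$seed,
                lexicon = derive_seed(cfg$seed, 101L),
                protocol = derive_seed(cfg$seed, 202L),
                lesion = derive_seed(cfg$seed, 303L))

  # --- lexicon ---
  if (!is.null(cfg$lexicon$path)) {
    lex <- read_lexicon(cfg$lexicon$path)
  } else {
    args <- cfg$lexicon
    if (!is.null(args$group_sizes))
      args$group_sizes <- unlist(args$group_sizes)
    args$seed <- seeds$lexicon
    lex <- generate_lexicon(do.call(lexicon_config, args))
  }
  outputs <- character(0)
  p <- file.path(out_dir, "lexicon.csv"); write_lexicon(lex, p)
  outputs <- c(outputs, p)

  # --- training ---
  training <- run_sim(lex, cfg$protocol, seed = seeds$protocol,
                      overrides = cfg$overrides)
  p <- file.path(out_dir, "network.json"); save_network(training$net, p)
  outputs <- c(outputs, p)
  p <- file.path(out_dir, "trajectory.csv")
  utils::write.csv(training$trajectory, p, row.names = FALSE)
  outputs <- c(outputs, p)
  p <- file.path(out_dir, "unit_stats.csv")
  utils::write.csv(training$unit_stats, p, row.names = FALSE)
  outputs <- c(outputs, p)

  res <- final_results(training)
  p <- file.path(out_dir, "item_results.csv")
  utils::write.csv(res, p, row.names = FALSE)
  outputs <- c(outputs, p)
  p <- file.path(out_dir, "group_summary.csv")
  utils::write.csv(group_summary(res), p, row.names = FALSE)
  outputs <- c(outputs, p)

  gap <- if (length(training$protocol$early_ids) &&
             length(training$protocol$late_ids))
    aoa_gap(res, training$protocol$early_ids, training$protocol$late_ids)
  else NA_real_

  # --- lesioning ---
  if (!is.null(cfg$lesion)) {
    lr <- run_lesion_experiment(
      training$net, training$protocol$lexicon,
      early_ids = training$protocol$early_ids,
      late_ids = training$protocol$late_ids,
      severities = cfg$lesion$severities %||% c(0.05, 0.10, 0.20),
      methods = cfg$lesion$methods %||% c("zero_weights", "add_noise"),
      n_samples = cfg$lesion$n_samples %||% 20L,
      noise_sd = cfg$lesion$noise_sd %||% 0.5,
      seed = seeds$lesion)
    p <- file.path(out_dir, "lesion_results.csv")
    utils::write.csv(lr$results, p, row.names = FALSE)
    outputs <- c(outputs, p)
    p <- file.path(out_dir, "lesion_summary.csv")
    utils::write.csv(lr$summary, p, row.names = FALSE)
    outputs <- c(outputs, p)
  }

  manifest <- list(
    package = "aoanet",
    version = as.character(utils::packageVersion("aoanet")),
    config = cfg,
    seeds = seeds,
    config_digest = digest,
    aoa_gap = gap,
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("protocol", "seed", "lexicon", "overrides", "lesion")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(config$protocol))
    stop("config key 'protocol' is required")
  if (!config$protocol %in% c(paste0("sim", 1:7), "custom"))
    stop("config key 'protocol' must be one of sim1..sim7 or custom")
  config$seed <- as.integer(config$seed %||% 1L)
  config$lexicon <- config$lexicon %||% list()
  config$overrides <- config$overrides %||% list()
  if (!is.null(config$lesion)) {
    sev <- config$lesion$severities
    if (!is.null(sev) && any(sev < 0 | sev > 1))
      stop("config key 'lesion.severities': severity must lie in [0, 1]")
    m <- config$lesion$methods
    if (!is.null(m) && !all(m %in% c("zero_weights", "add_noise")))
      stop("config key 'lesion.methods': unknown method")
  }
  if (!is.null(config$overrides$epochs))
    config$overrides$epochs <- as.integer(config$overrides$epochs)
  config
}
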