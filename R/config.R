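# Run configuration (YAML/JSON), command-level entry points and
# reproducibility manifests. The `sprachbund` script in exec/ is a thin
# wrapper around cmd_simulate(), cmd_run() and cmd_scan_k().

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("sb_config_error", "error")))
}

#' Read and validate a run configuration
#'
#' @param path YAML (or JSON) configuration file. Schema violations are
#'   reported with their field paths as errors of class `sb_config_error`.
#' @return A validated configuration list of class `sb_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_run_config(cfg, dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from YAML).
#' @param dir directory against which relative data paths are resolved.
#' @export
validate_run_config <- function(cfg, dir = ".") {
  if (!is.list(cfg)) config_error("config must be a mapping")
  need_num <- function(x, path, lo = -Inf, hi = Inf) {
    if (is.null(x)) return(NULL)
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi) {
      config_error(path, " must be a number in [", lo, ", ", hi, "]")
    }
    x
  }
  cfg$seed <- need_num(cfg$seed %||% 1, "seed")
  cfg$output <- cfg$output %||% "output"

  if (!is.null(cfg$data)) {
    for (field in c("features", "locations")) {
      p <- cfg$data[[field]]
      if (is.null(p)) config_error("data.", field, " is required")
      if (!file.exists(p) && !file.exists(file.path(dir, p))) {
        config_error("data.", field, ": file not found: ", p)
      }
      if (!file.exists(p)) cfg$data[[field]] <- file.path(dir, p)
    }
    for (field in c("states", "cost_matrix")) {
      p <- cfg$data[[field]]
      if (!is.null(p) && !file.exists(p)) {
        if (file.exists(file.path(dir, p))) {
          cfg$data[[field]] <- file.path(dir, p)
        } else {
          config_error("data.", field, ": file not found: ", p)
        }
      }
    }
    cfg$data$missing_token <- cfg$data$missing_token %||% "?"
    cfg$data$coord <- cfg$data$coord %||% "auto"
    if (!cfg$data$coord %in% c("auto", "planar", "spherical")) {
      config_error("data.coord must be auto, planar or spherical")
    }
  }

  cfg$model <- cfg$model %||% list()
  cfg$model$confounders <- cfg$model$confounders %||% "family"
  if (!cfg$model$confounders %in% c("family", "none")) {
    config_error("model.confounders must be 'family' or 'none'")
  }
  if (!is.null(cfg$model$k)) need_num(cfg$model$k, "model.k", lo = 0)
  if (!is.null(cfg$model$k_list)) {
    kl <- cfg$model$k_list
    if (!is.numeric(kl) || !length(kl) || is.unsorted(kl, strictly = TRUE)) {
      config_error("model.k_list must be a strictly ascending numeric list")
    }
  }

  pr <- cfg$priors %||% list()
  geo <- pr$geo %||% list()
  geo$type <- geo$type %||% "uniform"
  if (!geo$type %in% c("uniform", "cost_based")) {
    config_error("priors.geo.type must be 'uniform' or 'cost_based'")
  }
  geo$lambda <- need_num(geo$lambda %||% 0, "priors.geo.lambda", lo = 0)
  geo$linkage <- geo$linkage %||% "mst"
  if (!geo$linkage %in% c("mst", "delaunay", "complete")) {
    config_error("priors.geo.linkage must be mst, delaunay or complete")
  }
  pr$geo <- geo
  if (!is.null(pr$size)) {
    need_num(pr$size$min, "priors.size.min", lo = 2)
    need_num(pr$size$max, "priors.size.max", lo = 2)
  }
  for (block in c("alpha", "beta", "gamma")) {
    b <- pr[[block]]
    if (!is.null(b) && !is.null(b$type) &&
        !b$type %in% c("uniform", "pseudocounts", "empirical")) {
      config_error("priors.", block,
                   ".type must be uniform, pseudocounts or empirical")
    }
    if (!is.null(b$file) && !file.exists(b$file)) {
      if (file.exists(file.path(dir, b$file))) {
        pr[[block]]$file <- file.path(dir, b$file)
      } else {
        config_error("priors.", block, ".file: file not found: ", b$file)
      }
    }
  }
  cfg$priors <- pr

  mc <- cfg$mcmc %||% list()
  mc$steps <- need_num(mc$steps %||% 100000, "mcmc.steps", lo = 1)
  mc$burn_in <- need_num(mc$burn_in %||% 0.2, "mcmc.burn_in", 0, 1)
  mc$retained <- need_num(mc$retained %||% 1000, "mcmc.retained", lo = 1)
  mc$kappa <- need_num(mc$kappa %||% 30, "mcmc.kappa", lo = 1e-8)
  mc$log_every <- need_num(mc$log_every %||% 0, "mcmc.log_every", lo = 0)
  mc$g <- need_num(mc$g %||% 10, "mcmc.g", lo = 1)
  cfg$mcmc <- mc
  structure(cfg, class = c("sb_run_config", "list"))
}

# Assemble dataset + priors from a validated config.
build_from_config <- function(cfg) {
  if (is.null(cfg$data)) config_error("config has no data block")
  feats <- read_feature_table(cfg$data$features,
                              missing_token = cfg$data$missing_token,
                              states = cfg$data$states)
  loc <- read_locations(cfg$data$locations)
  dataset <- sb_dataset(feats, loc, coord = cfg$data$coord)
  if (cfg$model$confounders == "none") {
    dataset$entities$family <- NA_character_
    dataset$families <- character()
  }
  cost <- if (!is.null(cfg$data$cost_matrix)) {
    read_cost_matrix(cfg$data$cost_matrix, ids = dataset$entities$id)
  } else {
    build_cost_matrix(dataset)
  }

  prior_block <- function(block, default = 1) {
    b <- cfg$priors[[block]]
    if (is.null(b) || is.null(b$type) || b$type == "uniform") return(default)
    counts_or_psi <- if (grepl("\\.json$", b$file, ignore.case = TRUE)) {
      jsonlite::read_json(b$file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(b$file)
    }
    if (b$type == "pseudocounts") {
      lapply(counts_or_psi, as.numeric)
    } else {
      empirical_prior_from_sample(lapply(counts_or_psi, as.numeric),
                                  rho = b$precision %||% 10)
    }
  }
  geo <- geo_prior_spec(cfg$priors$geo$type, cfg$priors$geo$lambda,
                        cfg$priors$geo$linkage, cost = cost)
  priors <- prior_spec(dataset,
                       psi_alpha = prior_block("alpha"),
                       psi_beta = prior_block("beta"),
                       psi_gamma = prior_block("gamma"),
                       geo = geo,
                       m_min = cfg$priors$size$min %||% 3L,
                       m_max = cfg$priors$size$max %||%
                         min(50L, nrow(dataset$X) - 1L))
  list(dataset = dataset, priors = priors, cost = cost)
}

config_to_sampler <- function(cfg) {
  ow <- cfg$mcmc$operator_weights
  base <- c(area = 0.4, weights = 0.2, alpha = 0.1, beta = 0.15,
            gamma = 0.15)
  if (!is.null(ow)) base[names(ow)] <- as.numeric(ow)
  sampler_config(n_steps = cfg$mcmc$steps, burn_in = cfg$mcmc$burn_in,
                 n_retained = cfg$mcmc$retained, kappa = cfg$mcmc$kappa,
                 g = cfg$mcmc$g, op_weights = base, seed = cfg$seed,
                 log_every = cfg$mcmc$log_every)
}

write_manifest <- function(cfg, dir, extra = list()) {
  manifest <- c(list(config = unclass(cfg),
                     seed = cfg$seed,
                     package = "sprachbund",
                     package_version = as.character(
                       utils::packageVersion("sprachbund")),
                     r_version = as.character(getRversion())),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Generate a synthetic dataset from a configuration
#'
#' Needs a `simulate` block with `experiment` (exp1--exp4) and optional
#' `scale`; writes the dataset files, the ground truth and a manifest to the
#' configured output directory.
#'
#' @param cfg an `sb_run_config` (or a path to one).
#' @return The output directory, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  sim <- cfg$simulate %||% config_error("config has no simulate block")
  if (is.null(sim$experiment) ||
      !sim$experiment %in% c("exp1", "exp2", "exp3", "exp4")) {
    config_error("simulate.experiment must be one of exp1, exp2, exp3, exp4")
  }
  synth <- make_experiment(sim$experiment, scale = sim$scale %||% 1,
                           seed = cfg$seed)
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  write_synth(synth, cfg$output)
  write_manifest(cfg, cfg$output)
  invisible(cfg$output)
}

#' Run a single-K posterior sampling analysis
#'
#' Reads the data, builds the priors, runs one chain at `model.k` areas, and
#' writes the trace files, the posterior area summary, diagnostics
#' (per-operator acceptance rates, effective sample sizes of the
#' log-likelihood and deviance) and a reproducibility manifest.
#'
#' @param cfg an `sb_run_config` (or a path to one).
#' @return The `sb_trace`, invisibly.
#' @export
cmd_run <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  k <- cfg$model$k %||% config_error("model.k is required for a run")
  parts <- build_from_config(cfg)
  sc <- config_to_sampler(cfg)
  trace <- run_chain(parts$dataset, parts$priors, K = k, config = sc,
                     cost = parts$cost)
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  write_trace(trace, cfg$output)
  diag <- list(
    ess_log_likelihood = ess(trace$ll),
    ess_deviance = ess(trace$deviance),
    acceptance = setNames(as.list(ifelse(trace$accept$proposed > 0,
                                         trace$accept$accepted /
                                           trace$accept$proposed, NA)),
                          trace$accept$op))
  jsonlite::write_json(diag, file.path(cfg$output, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (k >= 1) {
    summ <- area_summary(trace, parts$dataset)
    write_area_summary(summ, parts$dataset, cfg$output)
  }
  write_manifest(cfg, cfg$output)
  invisible(trace)
}

#' Scan the number of areas from a configuration
#'
#' Runs [scan_k()] over `model.k_list`, writes the DIC table, the selected
#' K, per-K trace files and a manifest.
#'
#' @param cfg an `sb_run_config` (or a path to one).
#' @return The `sb_scan`, invisibly.
#' @export
cmd_scan_k <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  kl <- cfg$model$k_list %||%
    config_error("model.k_list is required for a scan")
  parts <- build_from_config(cfg)
  sc <- config_to_sampler(cfg)
  scan <- scan_k(parts$dataset, parts$priors, K_list = kl, config = sc,
                 tau = cfg$model$tau %||% 0.02)
  dir.create(cfg$output, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(table = scan$table, selected_k = scan$selected_k,
                            tau = scan$tau),
                       file.path(cfg$output, "dic_scan.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(kl)) {
    write_trace(scan$traces[[i]], file.path(cfg$output,
                                            sprintf("k%d", kl[i])))
  }
  write_manifest(cfg, cfg$output)
  invisible(scan)
}
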