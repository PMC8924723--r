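# Run configuration: YAML schema, validation, serialization, pipeline.

.config_keys <- c("synthetic", "use_case", "label", "seed", "n_psa",
                  "n_individuals", "discount", "fee", "wtp_max", "wtp_step",
                  "sweeps", "params", "distributions")

.config_defaults <- list(seed = 1, n_psa = 1000, n_individuals = 1000,
                         discount = 0.03, wtp_max = 1e5, wtp_step = 1000)

#' Load and validate a run configuration
#'
#' Reads a YAML run config, rejects unknown keys, fills in and records
#' documented defaults (seed 1, 1000 PSA replicates x 1000 individuals,
#' 3% discount, WTP grid 0-100,000 by 1,000), checks that probability-like
#' parameters lie in \[0, 1\], and compiles the `distributions` block into
#' validated [param_dist()] objects.
#'
#' @param path Path to a YAML file (as written by [write_config()] or
#'   [generate_default_params()]).
#' @return A list of class `run_config`; `$defaults_applied` names the keys
#'   that were filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$use_case))
    stop("config key 'use_case' is required", call. = FALSE)
  if (!raw$use_case %in% c("dermatology", "dentistry", "ophthalmology"))
    stop("config key 'use_case': must be dermatology, dentistry or ",
         "ophthalmology", call. = FALSE)
  applied <- setdiff(names(.config_defaults), names(raw))
  raw <- utils::modifyList(.config_defaults, raw)
  if (is.null(raw$params) || !is.list(raw$params) ||
      is.null(names(raw$params)))
    stop("config key 'params': must be a named mapping", call. = FALSE)
  raw$params$life_table <- unlist(raw$params$life_table)
  raw$params$discount <- raw$discount
  if (!is.null(raw$fee)) raw$params$fee <- raw$fee

  problike <- grepl("^(p_|u_|sens_|spec_|prev_)", names(raw$params))
  for (nm in names(raw$params)[problike]) {
    v <- raw$params[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("config parameter '", nm, "': probability must lie in [0, 1]",
           call. = FALSE)
  }
  if (!is.null(raw$discount) && (raw$discount < 0 || raw$discount > 1))
    stop("config key 'discount': must lie in [0, 1]", call. = FALSE)

  raw$distributions <- lapply(raw$distributions, function(d) {
    if (inherits(d, "param_dist")) return(d)
    param_dist(d$name, d$family, mean = d$mean,
               ci = if (!is.null(d$ci)) unlist(d$ci),
               bounds = if (!is.null(d$bounds)) unlist(d$bounds))
  })
  raw$defaults_applied <- applied
  structure(raw, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' The inverse of [load_config()]; `param_dist` objects are flattened to
#' their defining fields. Writing then reading recovers the configuration
#' (up to floating-point serialization precision).
#'
#' @param config A `run_config` (or compatible named list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$defaults_applied <- NULL
  out$distributions <- lapply(out$distributions, function(d) {
    d <- unclass(d)
    d$fit <- NULL
    if (!is.null(d$bounds) && any(!is.finite(d$bounds))) d$bounds <- NULL
    d <- d[!vapply(d, is.null, logical(1))]
    lapply(d, function(x) if (is.numeric(x)) unname(x) else x)
  })
  out <- out[intersect(.config_keys, names(out))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates one end-to-end run: probabilistic sensitivity analysis over
#' the configured use-case model, the acceptability curve over the WTP
#' grid, any requested one-way sweeps (`sweeps: [fee, discount]`), and a
#' reproduction manifest. Results are returned and, if `out_dir` is given,
#' written as CSV (UTF-8, period decimal separator) plus `manifest.json`.
#'
#' @param config A `run_config` from [load_config()] (or
#'   [as_run_config()]).
#' @param out_dir Optional output directory, created if missing.
#' @return Invisibly, a list with `psa` ([run_psa()] result), `ceac`,
#'   `sweeps` (named list of sweep tables), `thresholds`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  model <- use_case_model(config$use_case, config$params)
  message(sprintf(
    "run_pipeline: use_case=%s seed=%d n_psa=%d n_individuals=%d horizon=age %s",
    config$use_case, config$seed, config$n_psa, config$n_individuals,
    config$params$max_age))
  psa <- run_psa(model, config$distributions, n_psa = config$n_psa,
                 n_individuals = config$n_individuals, seed = config$seed,
                 discount_rate = config$discount)
  wtp_grid <- seq(0, config$wtp_max, by = config$wtp_step)
  curve <- ceac(psa$draws, wtp_grid)

  sweeps <- list(); thresholds <- list()
  for (sw in config$sweeps %||% character()) {
    grid <- switch(sw,
                   discount = seq(0, 0.10, by = 0.01),
                   fee = seq(0, 4 * (config$params$fee %||% 8), length.out = 9),
                   stop("unknown sweep '", sw, "'", call. = FALSE))
    tbl <- one_way_sweep(model, sw, grid, n = config$n_individuals,
                         seed = config$seed)
    sweeps[[sw]] <- tbl
    thresholds[[sw]] <- find_threshold(tbl)
  }

  manifest <- run_manifest(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(as.data.frame(x),
                                          file.path(out_dir, f),
                                          row.names = FALSE,
                                          fileEncoding = "UTF-8")
    wr(psa$draws, "ce_draws.csv")
    wr(psa$summary, "summary.csv")
    wr(curve, "ceac.csv")
    for (sw in names(sweeps)) wr(sweeps[[sw]], paste0("sweep_", sw, ".csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(psa = psa, ceac = curve, sweeps = sweeps,
                 thresholds = thresholds, manifest = manifest))
}

#' Reproduction manifest for a run
#'
#' Everything needed to reproduce a run bit-identically: the configuration
#' hash, master seed, replication counts, discount rate and package
#' version. The timestamp is informational and excluded from the hash.
#'
#' @param config A `run_config`.
#' @return A named list.
#' @export
run_manifest <- function(config) {
  hashable <- unclass(config)
  hashable$defaults_applied <- NULL
  hashable$distributions <- lapply(hashable$distributions, function(d)
    unclass(d)[c("name", "family", "mean", "ci", "bounds")])
  list(config_hash = rlang::hash(hashable),
       seed = config$seed,
       n_psa = config$n_psa,
       n_individuals = config$n_individuals,
       discount = config$discount,
       package_version =
         as.character(utils::packageVersion("markovscreen")),
       timestamp = format(Sys.time(), tz = "UTC",
                          format = "%Y-%m-%dT%H:%M:%SZ"))
}
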