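# Configuration loading, result serialization and run manifests.

config_defaults <- function() {
  list(
    constants = cell_constants(),
    simulation = list(duration = 10000, alpha = 0.3, noise_sd = 0.005,
                      seed = 1, rel_tol = 1e-8, abs_tol = 1e-8,
                      record_dt = 1, init = "random"),
    deletions = character(0),
    sweep = list(n_steps = 1000, alpha_min = 0, alpha_max = 1.05,
                 per_step = 10000, directions = c("up", "down"),
                 aux_runs = TRUE, jump_tol = 0.05, sd_tol = 0.001),
    noise = list(alphas = c(0.3, 0.6, 0.75), noise_sd = 1.75,
                 duration = 1e6, settle = 10000),
    transition = list(alpha_before = 0.02, alpha_after = 0.4,
                      settle = 10000, run = 10000),
    robustness = list(sigma_p = c(0.01, 0.02, 0.05, 0.10), n_models = 100)
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON configuration file, validates it against the known
#' schema (unknown keys are rejected, naming the offender), resolves any
#' deletion selectors against the intact network, and fills every missing
#' entry with the canonical default. An empty file yields the full default
#' configuration.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`); `NULL` for
#'   pure defaults.
#' @return nested configuration list (sections `constants`, `simulation`,
#'   `deletions`, `sweep`, `noise`, `transition`, `robustness`).
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      user <- jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      user <- yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (sec == "deletions") {
      defaults$deletions <- as.character(user$deletions)
      next
    }
    bad_keys <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad_keys))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad_keys, collapse = ", "))
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  if (length(defaults$deletions))
    resolve_selector(build_intact_network(), defaults$deletions)
  defaults
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run manifest
#'
#' Builds a provenance record for a set of result files: configuration hash,
#' seeds, package version, timestamp and output paths. Written alongside
#' results so any run can be reproduced exactly.
#'
#' @param config configuration list (see [load_config()]).
#' @param seeds named list/vector of seeds used.
#' @param outputs named character vector of result file paths.
#' @return manifest list.
#' @export
run_manifest <- function(config, seeds, outputs) {
  list(config_hash = config_hash(config),
       seeds = seeds,
       package_version = as.character(utils::packageVersion("quadgait")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       outputs = as.list(outputs))
}

#' Write experiment results with a manifest
#'
#' Tabular artifacts (data frames, including the `steps` table of a
#' bifurcation sweep) are written as CSV with a fixed column order; lists
#' (inventories, reports) as JSON. A `manifest.json` embedding the
#' configuration hash and seeds is written next to them.
#'
#' @param artifacts named list of data frames / lists / `cpg_bifurcation`
#'   objects.
#' @param dir output directory (created if needed).
#' @param config configuration list used for the run.
#' @param seeds seeds used.
#' @return named vector of written file paths, invisibly.
#' @export
write_results <- function(artifacts, dir, config = load_config(),
                          seeds = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(artifacts)) {
    x <- artifacts[[nm]]
    if (inherits(x, "cpg_bifurcation")) x <- x$steps
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, digits = NA, auto_unbox = TRUE,
                           force = TRUE)
    }
    paths[nm] <- p
  }
  man <- run_manifest(config, seeds, paths)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE)
  invisible(paths)
}
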