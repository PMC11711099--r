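#' Default run configuration
#'
#' The full parameter tree with the reference-protocol defaults: GA
#' population 500, 30 generations, 80% retention; 3 predictor candidates
#' per masked position; 5 CV folds; 100 ps snapshot spacing and a 20 ns
#' analysis window.
#'
#' @return Nested named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = ".",
    log_level = "info",
    ga = list(population_size = 500L, generations = 30L,
              retain_fraction = 0.8, crossover_rate = 0.5,
              crossover_type = "single_point", stop_on_score = NA_real_),
    strategy = list(strategy = "basic", max_mutations = 5L,
                    region = NA_integer_, candidates_per_position = 3L,
                    candidate_mode = "sample"),
    models = list(folds = 5L, ntree = 100L, nrounds = 300L,
                  holdout = 0.2, log_base = 10, embed_dim = 8L),
    md = list(snapshot_ps = 100, window_ns = 20, variant = "printed"))
}

# merge user values into defaults, rejecting unknown keys; `path` tracks
# the field position for error messages
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config field ", path, " must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(path, ".", k))
    } else {
      v <- user[[k]]
      if (is.null(v)) v <- defaults[[k]][NA][1L]  # typed NA
      defaults[[k]] <- v
    }
  }
  defaults
}

.validate_config <- function(cfg) {
  ga <- cfg$ga
  if (ga$population_size < 2) stop("ga.population_size must be >= 2")
  if (ga$generations < 1) stop("ga.generations must be >= 1")
  if (!(ga$retain_fraction > 0 && ga$retain_fraction <= 1))
    stop("ga.retain_fraction must lie in (0, 1]")
  if (ga$crossover_rate < 0 || ga$crossover_rate > 1)
    stop("ga.crossover_rate must lie in [0, 1]")
  if (!ga$crossover_type %in% c("single_point", "uniform"))
    stop("ga.crossover_type must be 'single_point' or 'uniform'")
  st <- cfg$strategy
  if (!st$strategy %in% c("llm", "smart", "basic"))
    stop("strategy.strategy must be one of 'llm', 'smart', 'basic'")
  if (st$max_mutations < 1) stop("strategy.max_mutations must be >= 1")
  if (st$candidates_per_position < 1)
    stop("strategy.candidates_per_position must be >= 1")
  if (!st$candidate_mode %in% c("sample", "argmax"))
    stop("strategy.candidate_mode must be 'sample' or 'argmax'")
  if (cfg$models$folds < 2) stop("models.folds must be >= 2")
  if (!cfg$md$variant %in% c("printed", "time-matched"))
    stop("md.variant must be 'printed' or 'time-matched'")
  cfg
}

# normalize scalar types so load/echo round-trips are exact
.normalize_config <- function(cfg) {
  ints <- function(x, keys) {
    for (k in keys) x[[k]] <- as.integer(x[[k]])
    x
  }
  nums <- function(x, keys) {
    for (k in keys) x[[k]] <- as.numeric(x[[k]])
    x
  }
  cfg <- ints(cfg, "seed")
  cfg$ga <- ints(cfg$ga, c("population_size", "generations"))
  cfg$ga <- nums(cfg$ga, c("retain_fraction", "crossover_rate",
                           "stop_on_score"))
  cfg$strategy <- ints(cfg$strategy,
                       c("max_mutations", "candidates_per_position"))
  cfg$strategy$region <- as.integer(cfg$strategy$region)
  cfg$models <- ints(cfg$models, c("folds", "ntree", "nrounds",
                                   "embed_dim"))
  cfg$models <- nums(cfg$models, c("holdout", "log_base"))
  cfg$md <- nums(cfg$md, c("snapshot_ps", "window_ns"))
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Reads the file (format by extension), fills every omitted field from
#' [defaultConfig()], rejects unknown keys with a path-to-field message,
#' and validates ranges. An empty or missing file yields the full default
#' tree.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`), or `NULL` for pure
#'   defaults.
#' @param overrides named list merged on top of the file's values.
#' @return The validated, fully populated configuration list.
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
    else yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- .merge_config(defaultConfig(), user)
  cfg <- .merge_config(cfg, overrides)
  .validate_config(.normalize_config(cfg))
}

#' Echo a configuration to JSON
#'
#' Writes the fully populated configuration as pretty JSON; reloading the
#' echo with [loadConfig()] reproduces the configuration exactly, so any
#' run can be replayed from its echo.
#'
#' @param cfg configuration list (as from [loadConfig()]).
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
echoConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}

#' Convert a configuration tree into package parameter objects
#'
#' @param cfg configuration list.
#' @return List with `gaConfig` ([GAConfig-class]) and the models/md
#'   sublists.
#' @export
configToObjects <- function(cfg) {
  st <- cfg$strategy
  scfg <- StrategyConfig(st$strategy, st$max_mutations,
                         region = if (all(is.na(st$region))) NA else
                           st$region,
                         candidatesPerPosition =
                           st$candidates_per_position,
                         candidateMode = st$candidate_mode)
  ga <- cfg$ga
  list(gaConfig = GAConfig(ga$population_size, ga$generations,
                           ga$retain_fraction, ga$crossover_rate,
                           ga$crossover_type, scfg, cfg$seed,
                           ga$stop_on_score),
       models = cfg$models, md = cfg$md)
}
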