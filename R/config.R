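# Run configuration: a YAML (or list) of options for the whole pipeline.
# Unknown keys are rejected so typos fail loudly instead of silently using
# defaults.

default_run_config <- function() {
  list(
    seed = 1L,
    paths = list(input_dir = "input", output_dir = "output"),
    hemocytometer = list(counted_volume_ml = 1e-4, stain_volume_ul = 0),
    community = list(threshold_reads = 1000, permutations = 999,
                     use_percent = TRUE, n_per_category = 12,
                     fixed_ids = NULL),
    bootstrap = list(iterations = 1000, ci_level = 0.95,
                     scheme = "resample-means"),
    active_hours = 8,
    simulate = list(n_per_guild = 12, n_genus_per_guild = 14,
                    n_follows = 40, n_transects = 4)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    here <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(base))
      stop_invalid("unknown config key: '%s'", here)
    if (is.list(base[[key]]) && !is.null(base[[key]]) && is.list(user[[key]]))
      base[[key]] <- merge_config(base[[key]], user[[key]], here)
    else
      base[[key]] <- user[[key]]
  }
  base
}

#' Load and validate a run configuration
#'
#' @param config Path to a YAML file, a named list of overrides, or NULL for
#'   all defaults. Unknown keys are rejected; numeric options are checked
#'   against their operations' preconditions.
#' @return Validated config list.
#' @export
read_run_config <- function(config = NULL) {
  user <- if (is.null(config)) list()
  else if (is.character(config)) yaml::read_yaml(config)
  else if (is.list(config)) config
  else stop_invalid("config must be a path, a list, or NULL")
  cfg <- merge_config(default_run_config(), user)
  check_number(cfg$seed, "seed", integer = TRUE)
  check_number(cfg$hemocytometer$counted_volume_ml, "counted_volume_ml")
  if (cfg$hemocytometer$counted_volume_ml <= 0)
    stop_invalid("counted_volume_ml must be > 0")
  check_number(cfg$hemocytometer$stain_volume_ul, "stain_volume_ul", lower = 0)
  check_number(cfg$community$threshold_reads, "threshold_reads", lower = 0)
  check_number(cfg$community$permutations, "permutations", lower = 1, integer = TRUE)
  check_number(cfg$community$n_per_category, "n_per_category", lower = 1, integer = TRUE)
  check_number(cfg$bootstrap$iterations, "iterations", lower = 1, integer = TRUE)
  check_number(cfg$bootstrap$ci_level, "ci_level", lower = 0, upper = 1)
  if (!cfg$bootstrap$scheme %in% c("resample-means", "single-draw"))
    stop_invalid("unknown bootstrap scheme '%s'", cfg$bootstrap$scheme)
  check_number(cfg$active_hours, "active_hours", lower = 0)
  cfg
}
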