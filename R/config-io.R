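# Serialization of classifier configuration as YAML or JSON documents.
# Format is chosen by file extension (.json -> JSON, otherwise YAML).

read_config_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config_file <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

ctp_config_to_list <- function(config) {
  list(
    initiation_cutoff_weeks = config$initiation_cutoff_weeks,
    lower_range = as.list(config$lower_range),
    upper_range = as.list(config$upper_range),
    trimester_minima = lapply(config$trimester_minima, as.list),
    boundaries = config$boundaries
  )
}

#' Read / write a CTP configuration file
#'
#' CTP configuration round-trips through a YAML or JSON document with
#' keys `initiation_cutoff_weeks`, `lower_range`, `upper_range`,
#' `trimester_minima` (maps keyed by US/BP/BS) and `boundaries`
#' (`t1_end`, `t2_end`). Missing keys fall back to the [ctp_config()]
#' defaults; all invariants are re-validated on read.
#'
#' @param path file to read or write (`.json` for JSON, else YAML).
#' @return `read_ctp_config()` returns a `ctp_config`;
#'   `write_ctp_config()` returns `path` invisibly.
#' @export
read_ctp_config <- function(path) {
  raw <- read_config_file(path)
  defaults <- ctp_config()
  get <- function(key, fallback) if (!is.null(raw[[key]])) raw[[key]] else fallback
  ctp_config(
    initiation_cutoff_weeks = get("initiation_cutoff_weeks", defaults$initiation_cutoff_weeks),
    lower_range = unlist(get("lower_range", as.list(defaults$lower_range))),
    upper_range = unlist(get("upper_range", as.list(defaults$upper_range))),
    trimester_minima = lapply(get("trimester_minima",
                                  lapply(defaults$trimester_minima, as.list)), unlist),
    boundaries = do.call(trimester_boundaries, get("boundaries", defaults$boundaries))
  )
}

#' @rdname read_ctp_config
#' @param config a [ctp_config()].
#' @export
write_ctp_config <- function(config, path) {
  write_config_file(ctp_config_to_list(config), path)
}

#' Read / write an APNCU schedule file
#'
#' Schedules round-trip through `{name, visit_weeks,
#' initiation_month_cutoff, initiation_week_cutoff, expected_basis}`.
#'
#' @param path file to read or write (`.json` for JSON, else YAML).
#' @return `read_apncu_schedule()` returns an `apncu_schedule`;
#'   `write_apncu_schedule()` returns `path` invisibly.
#' @export
read_apncu_schedule <- function(path) {
  raw <- read_config_file(path)
  apncu_schedule(
    name = if (!is.null(raw$name)) raw$name else "custom",
    visit_weeks = unlist(raw$visit_weeks),
    initiation_month_cutoff = if (!is.null(raw$initiation_month_cutoff)) raw$initiation_month_cutoff else 4,
    initiation_week_cutoff = raw$initiation_week_cutoff,
    expected_basis = if (!is.null(raw$expected_basis)) raw$expected_basis else "week"
  )
}

#' @rdname read_apncu_schedule
#' @param schedule an [apncu_schedule()].
#' @export
write_apncu_schedule <- function(schedule, path) {
  write_config_file(unclass(schedule), path)
}

# resolve a --schedule argument: shipped name or a file path
resolve_schedule <- function(arg) {
  if (arg %in% c("acog", "belgian")) return(apncu_schedule(arg))
  read_apncu_schedule(arg)
}
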