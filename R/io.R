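#' Read a model configuration file
#'
#' Accepts YAML or JSON with three sections:
#'
#' ```yaml
#' causes:
#'   - {id: diarrhea, name: Diarrhea, baseline_deaths: 10000}
#' interventions:
#'   - id: vaccine
#'     name: New rotavirus vaccine
#'     category: preventive
#'     stage: childhood
#'     effectiveness: {diarrhea: 0.5}
#' demography:
#'   base_year: 2010
#'   base_births: 100000
#'   growth_rate: 0.0
#' ```
#'
#' `demography` may instead carry a `births:` mapping of year to live
#' births. The file is fully validated; all violations are reported at once.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return An [lst_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- tryCatch({
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = FALSE)
    } else {
      yaml::read_yaml(path)
    }
  }, error = function(e) {
    abort(paste0("cannot parse ", path, ": ", conditionMessage(e)),
          class = "lst_parse_error")
  })
  if (!is.list(raw) || is.null(raw$causes) || is.null(raw$interventions) ||
      is.null(raw$demography)) {
    abort(paste0("config must have sections causes, interventions, demography: ",
                 path),
          class = "lst_parse_error")
  }

  causes <- purrr::map_dfr(raw$causes, function(x) {
    tibble(cause_id = as.character(x$id),
           name = as.character(x$name %||% x$id),
           baseline_deaths = as.numeric(x$baseline_deaths))
  })
  interventions <- purrr::map_dfr(raw$interventions, function(x) {
    tibble(intervention_id = as.character(x$id),
           name = as.character(x$name %||% x$id),
           category = as.character(x$category),
           stage = as.character(x$stage))
  })
  effectiveness <- purrr::map_dfr(raw$interventions, function(x) {
    eff <- x$effectiveness
    tibble(intervention_id = as.character(x$id),
           cause_id = names(eff),
           effectiveness = as.numeric(unlist(eff)))
  })

  d <- raw$demography
  dem <- if (!is.null(d$births)) {
    demography(d$base_year,
               births = tibble(year = as.integer(names(d$births)),
                               births = as.numeric(unlist(d$births))))
  } else {
    demography(d$base_year, base_births = d$base_births,
               growth_rate = d$growth_rate %||% 0)
  }
  lst_config(causes, interventions, effectiveness, dem)
}

#' Read a coverage CSV
#'
#' Schema: header `intervention,year,channel,coverage`, coverage as a
#' fraction in \[0, 1\]. Percent-looking values (> 1) are rejected with a
#' hint, as are duplicate (intervention, year, channel) keys and unknown
#' channels.
#'
#' @param path Path to the CSV.
#' @return Coverage tibble (`intervention_id`, `year`, `channel`,
#'   `coverage`).
#' @export
read_coverage_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("intervention", "year", "channel", "coverage")
  if (!all(needed %in% names(df))) {
    abort(paste0("coverage CSV must have header: ",
                 paste(needed, collapse = ",")),
          class = "lst_parse_error")
  }
  df <- df |>
    rename(intervention_id = "intervention") |>
    mutate(year = as.integer(.data$year),
           coverage = as.numeric(.data$coverage))
  if (any(df$coverage > 1, na.rm = TRUE)) {
    bad <- df[df$coverage > 1, ]
    abort(sprintf(paste0("coverage value %.4g for (%s, %d, %s) exceeds 1 -- ",
                         "use fractions, not percent"),
                  bad$coverage[1], bad$intervention_id[1], bad$year[1],
                  bad$channel[1]))
  }
  if (any(df$coverage < 0, na.rm = TRUE) || anyNA(df$coverage)) {
    abort("coverage values must be fractions in [0, 1]")
  }
  if (any(!df$channel %in% CHANNELS)) {
    abort(paste0("unknown channel(s): ",
                 paste(setdiff(df$channel, CHANNELS), collapse = ", "),
                 " -- map extra survey categories to 'other'"))
  }
  key <- paste(df$intervention_id, df$year, df$channel, sep = "/")
  if (anyDuplicated(key)) {
    abort(paste0("duplicate coverage record(s): ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  df |> select("intervention_id", "year", "channel", "coverage")
}

#' Write a coverage tibble back to the CSV schema
#'
#' Inverse of [read_coverage_csv()]; rows are sorted so reruns are
#' byte-identical.
#'
#' @param coverage Coverage tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_coverage_csv <- function(coverage, path) {
  as_tibble(coverage) |>
    arrange(.data$intervention_id, .data$year, .data$channel) |>
    rename(intervention = "intervention_id") |>
    readr::write_csv(path)
  invisible(path)
}

#' Write projection (and optional comparison) outputs
#'
#' Emits tidy CSVs, a JSON summary and a run-metadata record into `dir`.
#' Content ordering is deterministic: rerunning on identical inputs gives
#' identical bytes apart from the timestamp inside the metadata file.
#'
#' Files written: `deaths.csv` (scenario,year,cause,deaths),
#' `attribution.csv` (intervention,cause,year,lives_saved), `summary.json`
#' (totals, lives saved, percent reductions at one decimal),
#' `comparison.csv` + per-year difference series inside `summary.json` when
#' a comparison is supplied, and `run_metadata.json`.
#'
#' @param projection An `lst_projection`.
#' @param dir Output directory (created if needed).
#' @param comparison Optional `lst_comparison`.
#' @param seed Optional seed to record in the metadata.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(projection, dir, comparison = NULL, seed = NULL) {
  stopifnot(inherits(projection, "lst_projection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  deaths <- projection$deaths |>
    mutate(scenario = projection$scenario_name, .before = 1) |>
    rename(cause = "cause_id") |>
    arrange(.data$year, .data$cause)
  readr::write_csv(deaths, file.path(dir, "deaths.csv"))

  attribution <- projection$attribution |>
    rename(intervention = "intervention_id", cause = "cause_id") |>
    arrange(.data$year, .data$cause, .data$intervention)
  readr::write_csv(attribution, file.path(dir, "attribution.csv"))

  summary <- list(
    scenario = projection$scenario_name,
    total_deaths = projection$total_deaths,
    lives_saved = projection$lives_saved,
    percent_reduction = projection$percent_reduction |>
      mutate(percent_reduction = round(.data$percent_reduction, 1)),
    assumptions = projection$meta)
  if (!is.null(comparison)) {
    readr::write_csv(comparison$difference, file.path(dir, "comparison.csv"))
    summary$comparison <- list(
      scenario_a = comparison$scenario_a,
      scenario_b = comparison$scenario_b,
      difference = comparison$difference,
      cumulative_difference = comparison$cumulative_difference)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  meta <- list(
    tool = "listlite",
    version = as.character(utils::packageVersion("listlite")),
    interpolation = projection$meta$interpolation,
    effectiveness_channel_invariant =
      projection$meta$effectiveness_channel_invariant,
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
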