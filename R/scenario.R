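#' Define a projection scenario
#'
#' A scenario bundles a name, a demography, a channel-disaggregated coverage
#' trajectory and an inclusive year horizon starting at the demography's base
#' year. Base-year coverage is the scenario's baseline: all mortality impact
#' is measured against it.
#'
#' @param name Scenario label used in outputs.
#' @param demography A [demography()] object; its `base_year` anchors the
#'   horizon.
#' @param coverage Coverage tibble (`intervention_id`, `year`, `channel`,
#'   `coverage`), fractions in \[0, 1\]. Years between records are linearly
#'   interpolated; outside records, held constant (see [coverage_at()]).
#' @param horizon Length-2 integer vector `c(from, to)`; `from` must equal
#'   the demography base year.
#' @return An object of class `lst_scenario`.
#' @export
scenario <- function(name, demography, coverage, horizon) {
  stopifnot(inherits(demography, "lst_demography"), length(horizon) == 2)
  horizon <- as.integer(horizon)
  if (horizon[1] != demography$base_year) {
    abort("horizon must start at the demography base year")
  }
  if (horizon[2] < horizon[1]) abort("horizon end precedes its start")
  coverage <- as_tibble(coverage)
  needed <- c("intervention_id", "year", "channel", "coverage")
  if (!all(needed %in% names(coverage))) {
    abort(paste0("coverage must have columns: ", paste(needed, collapse = ", ")))
  }
  structure(
    list(name = name, demography = demography, coverage = coverage,
         horizon = horizon),
    class = "lst_scenario")
}

#' @export
print.lst_scenario <- function(x, ...) {
  cat(sprintf("<scenario> \"%s\": %d-%d, %d intervention(s)\n",
              x$name, x$horizon[1], x$horizon[2],
              length(unique(x$coverage$intervention_id))))
  invisible(x)
}

#' Years covered by a scenario horizon
#' @param x An `lst_scenario`.
#' @return Integer vector of years.
#' @export
horizon_years <- function(x) {
  stopifnot(inherits(x, "lst_scenario"))
  seq.int(x$horizon[1], x$horizon[2])
}
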