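#' Total coverage of an intervention in a year
#'
#' Sums coverage over delivery channels for one intervention-year. A channel
#' with no record counts as zero, so the result is invariant to record order
#' and to which channels happen to be present.
#'
#' @param coverage Coverage tibble (`intervention_id`, `year`, `channel`,
#'   `coverage`), fractions in \[0, 1\].
#' @param intervention Intervention id.
#' @param year Calendar year.
#' @return Total coverage as a fraction.
#' @examples
#' cov <- tibble::tibble(
#'   intervention_id = "orszinc", year = 2010,
#'   channel = c("community", "facility"), coverage = c(0.02, 0.38))
#' total_coverage(cov, "orszinc", 2010) # 0.40
#' @export
total_coverage <- function(coverage, intervention, year) {
  coverage <- as_tibble(coverage)
  if (!intervention %in% coverage$intervention_id) {
    abort(paste0("unknown intervention id: ", intervention))
  }
  rows <- coverage[coverage$intervention_id == intervention &
                     coverage$year == year, ]
  sum(rows$coverage)
}

#' Interpolate channel coverage onto a set of years
#'
#' Coverage surveys give sparse points (often just a before and an after
#' year). Between recorded years each (intervention, channel) series is
#' interpolated piecewise-linearly; beyond the first/last record it is held
#' constant. A channel never recorded for an intervention is zero throughout.
#'
#' @param coverage Coverage tibble (`intervention_id`, `year`, `channel`,
#'   `coverage`).
#' @param years Integer vector of years to evaluate at.
#' @return Tibble `intervention_id`, `year`, `channel`, `coverage` with one
#'   row per intervention x year x recorded channel, plus a `total` column
#'   obtainable via [coverage_totals()].
#' @export
coverage_at <- function(coverage, years) {
  coverage <- as_tibble(coverage)
  years <- sort(unique(as.integer(years)))
  series <- coverage |>
    group_by(.data$intervention_id, .data$channel) |>
    arrange(.data$year, .by_group = TRUE) |>
    summarise(
      coverage = list(interp_series(.data$year, .data$coverage, .env$years)),
      .groups = "drop")
  series |>
    mutate(year = list(years)) |>
    tidyr::unnest(c("year", "coverage")) |>
    select("intervention_id", "year", "channel", "coverage")
}

# linear interpolation with constant extrapolation; a single record is a
# constant series
interp_series <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  stats::approx(x, y, xout = xout, method = "linear", rule = 2)$y
}

#' Total (channel-summed) coverage per intervention-year
#'
#' @param coverage Coverage tibble.
#' @return Tibble `intervention_id`, `year`, `total`.
#' @export
coverage_totals <- function(coverage) {
  as_tibble(coverage) |>
    group_by(.data$intervention_id, .data$year) |>
    summarise(total = sum(.data$coverage), .groups = "drop")
}
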