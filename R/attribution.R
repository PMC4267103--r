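#' Attribute lives saved among interventions for one cause
#'
#' Implements the two-block attribution rule. Lives saved are first computed
#' for the preventive block alone (its coverage changes applied to baseline
#' deaths); that block total is split among preventive interventions in
#' proportion to `increase in coverage x effectiveness`. The curative block
#' then receives only the *additional* deaths averted when its coverage
#' changes are applied to the preventive residual, split by the same weight
#' formula. The shares sum exactly to the cause's total lives saved, so no
#' impact is double counted: a curative intervention is worth less when a
#' preventive one on the same cause is scaled up alongside it.
#'
#' Negative coverage changes are allowed; the corresponding attribution
#' entries are negative ("lives lost") and additivity is preserved.
#'
#' @param baseline_deaths Deaths of the cause at baseline (scaled for growth
#'   if applicable).
#' @param steps Tibble in cascade order (see [order_interventions()]) with
#'   columns `intervention_id`, `category`, `effectiveness`, `cov_now`,
#'   `cov_base`.
#' @return Tibble `intervention_id`, `lives_saved`; zero rows if no
#'   intervention acts on the cause.
#' @export
attribute_cause <- function(baseline_deaths, steps) {
  steps <- as_tibble(steps) |> filter(.data$effectiveness > 0)
  if (nrow(steps) == 0) {
    return(tibble(intervention_id = character(), lives_saved = numeric()))
  }
  steps <- steps |>
    mutate(r = apply_intervention(1, .data$effectiveness, .data$cov_now,
                                  .data$cov_base),
           w = (.data$cov_now - .data$cov_base) * .data$effectiveness)
  prev <- steps[steps$category == "preventive", ]
  cur <- steps[steps$category == "curative", ]
  R_prev <- prod(prev$r)
  L_prev <- baseline_deaths * (1 - R_prev)
  L_cur <- baseline_deaths * R_prev * (1 - prod(cur$r))
  bind_rows(
    split_block(prev, L_prev, baseline_deaths),
    split_block(cur, L_cur, baseline_deaths))
}

# proportional split of a block total by weight delta-coverage x effectiveness
split_block <- function(rows, block_total, scale_ref) {
  if (nrow(rows) == 0) return(NULL)
  W <- sum(rows$w)
  if (W == 0) {
    # zero weights can only coexist with a (numerically) zero block impact
    if (abs(block_total) > 1e-9 * max(scale_ref, 1)) {
      abort("internal error: degenerate attribution weights for nonzero impact")
    }
    return(tibble(intervention_id = rows$intervention_id,
                  lives_saved = 0))
  }
  tibble(intervention_id = rows$intervention_id,
         lives_saved = block_total * rows$w / W)
}

#' Attribution table for a scenario
#'
#' Applies [attribute_cause()] to every cause and year of a scenario,
#' yielding the per-(intervention, cause, year) decomposition of lives saved
#' relative to the scenario's no-change baseline. Summing over interventions
#' and causes recovers the projection's total lives saved exactly.
#'
#' @inheritParams project
#' @return Tibble `intervention_id`, `cause_id`, `year`, `lives_saved`.
#' @export
attribute_lives_saved <- function(scn, config) {
  stopifnot(inherits(scn, "lst_scenario"), inherits(config, "lst_config"))
  years <- horizon_years(scn)
  ordered <- order_interventions(config$interventions)

  tot <- coverage_totals(coverage_at(scn$coverage, years))
  base_tot <- tot |>
    filter(.data$year == scn$horizon[1]) |>
    select("intervention_id", cov_base = "total")
  cov <- tot |>
    left_join(base_tot, by = "intervention_id") |>
    rename(cov_now = "total")

  births <- births_for(scn$demography, years)
  growth <- tibble(year = years, growth = births / births[1])

  steps_all <- ordered |>
    mutate(.order = row_number()) |>
    select("intervention_id", "category", ".order") |>
    inner_join(config$effectiveness, by = "intervention_id") |>
    filter(.data$effectiveness > 0) |>
    inner_join(cov, by = "intervention_id", relationship = "many-to-many") |>
    arrange(.data$cause_id, .data$year, .data$.order)

  shares <- steps_all |>
    inner_join(select(config$causes, "cause_id", "baseline_deaths"),
               by = "cause_id") |>
    inner_join(growth, by = "year") |>
    group_by(.data$cause_id, .data$year) |>
    dplyr::group_modify(function(g, key) {
      out <- attribute_cause(g$baseline_deaths[1] * g$growth[1],
                             g[, c("intervention_id", "category",
                                   "effectiveness", "cov_now", "cov_base")])
      out
    }) |>
    ungroup()

  shares |>
    select("intervention_id", "cause_id", "year", "lives_saved") |>
    arrange(.data$year, .data$cause_id, .data$intervention_id)
}

#' Per-intervention percent mortality reduction
#'
#' Expresses each intervention's cumulative attributed lives saved as a
#' percent of the baseline-scenario total deaths over the same span. Values
#' are kept at full precision; round only for display (one decimal is the
#' reporting convention) so that additivity is never destroyed by rounding
#' in intermediate steps.
#'
#' @param attribution Attribution tibble from [attribute_lives_saved()].
#' @param baseline Tibble `year`, `baseline_scaled`: no-change total deaths
#'   per year (baseline cause structure scaled by births).
#' @param years Optional subset of years to report over; defaults to all
#'   years present in `attribution`. In a before-after design, passing just
#'   the endline year(s) reports the endline mortality reduction.
#' @return Tibble `intervention_id`, `lives_saved` (cumulative over `years`),
#'   `percent_reduction` (full precision). If baseline deaths over the span
#'   are zero, percent is `NA` (undefined), not `NaN`.
#' @export
percent_reduction_table <- function(attribution, baseline, years = NULL) {
  attribution <- as_tibble(attribution)
  baseline <- as_tibble(baseline)
  if (is.null(years)) years <- unique(attribution$year)
  denom <- sum(baseline$baseline_scaled[baseline$year %in% years])
  out <- attribution |>
    filter(.data$year %in% .env$years) |>
    group_by(.data$intervention_id) |>
    summarise(lives_saved = sum(.data$lives_saved), .groups = "drop")
  if (denom <= 0) {
    warn("baseline deaths are zero over the requested span; percent undefined")
    out$percent_reduction <- NA_real_
  } else {
    out$percent_reduction <- 100 * out$lives_saved / denom
  }
  out
}
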