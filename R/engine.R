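#' Apply one intervention to residual cause-specific deaths
#'
#' The elementary step of the residual cascade. With baseline coverage zero
#' this is the textbook calculation `deaths * (1 - effectiveness * coverage)`:
#' e.g. 10 000 diarrhea deaths with a 50%-effective intervention reaching 50%
#' coverage leave 7 500. For a nonzero starting coverage the step generalises
#' to the ratio form
#' `deaths * (1 - e * cov_now) / (1 - e * cov_base)`,
#' which reduces exactly to the simple form when `cov_base = 0` and leaves
#' deaths unchanged when coverage does not change.
#'
#' @param deaths_residual Deaths of the cause remaining after earlier
#'   interventions in the cascade.
#' @param effectiveness Fraction in \[0, 1\].
#' @param cov_now,cov_base Current and baseline total coverage, fractions.
#' @return Residual deaths after this intervention. Vectorised.
#' @examples
#' apply_intervention(10000, 0.5, 0.5, 0) # 7500
#' @export
apply_intervention <- function(deaths_residual, effectiveness, cov_now,
                               cov_base = 0) {
  stopifnot(all(effectiveness >= 0 & effectiveness <= 1),
            all(cov_now >= 0 & cov_now <= 1),
            all(cov_base >= 0 & cov_base <= 1))
  denom <- 1 - effectiveness * cov_base
  if (any(denom <= 0)) {
    abort(paste0("configuration error: effectiveness * baseline coverage = 1 ",
                 "already eliminates the cause entirely"))
  }
  deaths_residual * (1 - effectiveness * cov_now) / denom
}

#' Order interventions for cascade and attribution
#'
#' Preventive interventions come first, sequenced along the continuum of care
#' (periconceptual, pregnancy, delivery, postnatal, childhood); curative
#' interventions follow. Ties keep declared configuration order, then id. The
#' sort is stable and deterministic. Within a single cause the cascade product
#' commutes, so engine results do not depend on this order — but attribution
#' does, which is why the order is fixed here once for both.
#'
#' @param interventions Intervention tibble (`intervention_id`, `category`,
#'   `stage`, ...).
#' @return The same tibble, reordered.
#' @export
order_interventions <- function(interventions) {
  interventions <- as_tibble(interventions)
  if (nrow(interventions) == 0) return(interventions)
  interventions |>
    mutate(.declared = row_number()) |>
    arrange(match(.data$category, CATEGORIES),
            match(.data$stage, STAGES),
            .data$.declared,
            .data$intervention_id) |>
    select(-".declared")
}

#' Cascade all interventions over one cause
#'
#' Folds [apply_intervention()] over the interventions that act on the cause
#' (effectiveness > 0), each step consuming the residual deaths left by the
#' previous one — the device that prevents double counting. Returns the final
#' death count and a step ledger for audit.
#'
#' @param baseline_deaths Deaths of the cause at baseline (already scaled for
#'   population growth if applicable).
#' @param steps Tibble with one row per intervention acting on the cause, in
#'   cascade order: `intervention_id`, `effectiveness`, `cov_now`, `cov_base`.
#' @return List with `deaths` (final residual) and `steps` (ledger tibble
#'   with `deaths_before`, `deaths_after`, `deaths_averted_at_step`).
#' @export
cascade_cause <- function(baseline_deaths, steps) {
  steps <- as_tibble(steps)
  active <- steps[steps$effectiveness > 0, ]
  n <- nrow(active)
  before <- after <- numeric(n)
  residual <- baseline_deaths
  for (i in seq_len(n)) {
    before[i] <- residual
    residual <- apply_intervention(residual, active$effectiveness[i],
                                   active$cov_now[i], active$cov_base[i])
    after[i] <- residual
  }
  ledger <- active |>
    mutate(deaths_before = before, deaths_after = after,
           deaths_averted_at_step = before - after)
  list(deaths = residual, steps = ledger)
}

#' Project a scenario into deaths by cause and year
#'
#' The deterministic core of the model: cause-specific mortality changes only
#' in response to coverage changes. For every year in the horizon, each
#' cause's baseline deaths are scaled by the residual cascade of all
#' interventions (total coverage in that year vs. base-year total coverage)
#' and by population growth (`births_t / births_base`). Total mortality is
#' the plain sum over causes; lives saved are measured against the no-change
#' baseline (baseline cause structure scaled only by births). Effectiveness
#' is channel-invariant: community- and facility-delivered care avert deaths
#' identically.
#'
#' @param scn An [scenario()] object.
#' @param config An [lst_config()] object (its demography is ignored in
#'   favour of the scenario's).
#' @return An `lst_projection` object: a list with tibbles `deaths`
#'   (`year`, `cause_id`, `deaths`), `total_deaths` (`year`, `deaths`),
#'   `lives_saved` (`year`, `lives_saved`), `attribution` (`intervention_id`,
#'   `cause_id`, `year`, `lives_saved`), `percent_reduction` (per
#'   intervention, over the full horizon), plus `scenario_name` and
#'   `meta` (assumptions in force). Use [tidy()] / [glance()] /
#'   `autoplot()` on it.
#' @export
project <- function(scn, config) {
  stopifnot(inherits(scn, "lst_scenario"), inherits(config, "lst_config"))
  years <- horizon_years(scn)
  report <- validate_config(config$causes, config$interventions,
                            config$effectiveness, coverage = scn$coverage)
  if (nrow(report) > 0) {
    abort(c("invalid scenario inputs",
            stats::setNames(paste0(report$locus, ": ", report$message),
                            rep("x", nrow(report)))))
  }

  tot <- coverage_totals(coverage_at(scn$coverage, years))
  base_tot <- tot |>
    filter(.data$year == scn$horizon[1]) |>
    select("intervention_id", cov_base = "total")
  cov <- tot |>
    left_join(base_tot, by = "intervention_id") |>
    rename(cov_now = "total")

  births <- births_for(scn$demography, years)
  growth <- tibble(year = years,
                   growth = births / births[1])

  # residual-cascade factor per (intervention, cause, year); the product over
  # interventions gives the cause's survival-of-baseline factor
  fac <- config$effectiveness |>
    filter(.data$effectiveness > 0) |>
    inner_join(cov, by = "intervention_id",
               relationship = "many-to-many") |>
    mutate(factor = apply_intervention(1, .data$effectiveness,
                                       .data$cov_now, .data$cov_base))

  cause_factor <- fac |>
    group_by(.data$cause_id, .data$year) |>
    summarise(factor = prod(.data$factor), .groups = "drop")

  deaths <- tidyr::expand_grid(cause_id = config$causes$cause_id,
                               year = years) |>
    left_join(cause_factor, by = c("cause_id", "year")) |>
    mutate(factor = tidyr::replace_na(.data$factor, 1)) |>
    left_join(select(config$causes, "cause_id", "baseline_deaths"),
              by = "cause_id") |>
    left_join(growth, by = "year") |>
    mutate(deaths = .data$baseline_deaths * .data$factor * .data$growth,
           baseline_scaled = .data$baseline_deaths * .data$growth) |>
    select("year", "cause_id", "deaths", "baseline_scaled") |>
    arrange(.data$year, .data$cause_id)

  total_deaths <- deaths |>
    group_by(.data$year) |>
    summarise(deaths = sum(.data$deaths),
              baseline_scaled = sum(.data$baseline_scaled),
              .groups = "drop")

  lives_saved <- total_deaths |>
    mutate(lives_saved = .data$baseline_scaled - .data$deaths) |>
    select("year", "lives_saved")

  attribution <- attribute_lives_saved(scn, config)
  pct <- percent_reduction_table(attribution, total_deaths |>
                                   select("year", "baseline_scaled"))

  structure(
    list(scenario_name = scn$name,
         deaths = select(deaths, "year", "cause_id", "deaths"),
         total_deaths = select(total_deaths, "year", "deaths"),
         baseline_deaths = select(total_deaths, "year", "baseline_scaled"),
         lives_saved = lives_saved,
         attribution = attribution,
         percent_reduction = pct,
         horizon = scn$horizon,
         meta = list(
           interpolation = "piecewise-linear between records, constant beyond",
           effectiveness_channel_invariant = TRUE)),
    class = "lst_projection")
}

#' @export
print.lst_projection <- function(x, ...) {
  yrs <- range(x$deaths$year)
  cat(sprintf("<projection> scenario \"%s\", %d-%d\n", x$scenario_name,
              yrs[1], yrs[2]))
  last <- x$total_deaths[x$total_deaths$year == yrs[2], ]
  cat(sprintf("  final-year deaths: %.0f; cumulative lives saved: %.0f\n",
              last$deaths, sum(x$lives_saved$lives_saved)))
  invisible(x)
}

#' @rdname project
#' @param x An `lst_projection`.
#' @param ... Unused.
#' @export
tidy.lst_projection <- function(x, ...) {
  x$deaths |> mutate(scenario = x$scenario_name, .before = 1)
}

#' @rdname project
#' @export
glance.lst_projection <- function(x, ...) {
  yrs <- range(x$deaths$year)
  tibble(
    scenario = x$scenario_name,
    from = yrs[1], to = yrs[2],
    n_causes = length(unique(x$deaths$cause_id)),
    total_deaths = sum(x$total_deaths$deaths),
    lives_saved = sum(x$lives_saved$lives_saved),
    percent_reduction = sum(x$percent_reduction$percent_reduction))
}
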