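#' Build the facility-only counterfactual of an observed scenario
#'
#' Returns a scenario identical to the observed one except that every
#' intervention's community-channel coverage is frozen at its base-year
#' value for all years; facility and other channels are untouched. The
#' counterfactual's total coverage in year t is therefore
#' `community_base + facility_t + other_t`. Differencing the counterfactual
#' against the observed scenario isolates the community (iCCM) program's
#' impact: facility-side shifts (stockouts, task shifting, strikes) are
#' treated as background in both scenarios. Construction guarantees that
#' base-year total coverage matches the observed scenario, so
#' [check_baseline_equality()] passes by construction. The operation is
#' idempotent.
#'
#' @param observed An [scenario()] object with channel-disaggregated
#'   coverage.
#' @param freeze_other Also freeze the `"other"` channel (pharmacies etc.) at
#'   baseline. Default `FALSE`: only community delivery is the program under
#'   evaluation.
#' @param name Name for the counterfactual scenario.
#' @return An `lst_scenario`.
#' @export
build_facility_only_counterfactual <- function(observed,
                                               freeze_other = FALSE,
                                               name = paste0(observed$name,
                                                             " (facility-only)")) {
  stopifnot(inherits(observed, "lst_scenario"))
  frozen <- if (freeze_other) c("community", "other") else "community"
  base_year <- observed$horizon[1]
  cov <- as_tibble(observed$coverage)

  # base-year value per (intervention, frozen channel); a channel with no
  # record at all stays absent (i.e. zero), matching the observed scenario
  base_vals <- coverage_at(cov, base_year) |>
    filter(.data$channel %in% frozen) |>
    select("intervention_id", "channel", base_cov = "coverage")

  kept <- cov |> filter(!.data$channel %in% frozen)
  frozen_rows <- cov |>
    filter(.data$channel %in% frozen) |>
    distinct(.data$intervention_id, .data$year, .data$channel) |>
    inner_join(base_vals, by = c("intervention_id", "channel")) |>
    mutate(coverage = .data$base_cov) |>
    select("intervention_id", "year", "channel", "coverage")

  scenario(name, observed$demography,
           bind_rows(kept, frozen_rows) |>
             arrange(.data$intervention_id, .data$year, .data$channel),
           observed$horizon)
}

#' Check that two scenarios share baseline coverage
#'
#' A valid program comparison requires the base-year total coverage of every
#' intervention to be identical in the two scenarios; otherwise the
#' difference between them mixes program impact with a baseline artefact.
#'
#' @param a,b [scenario()] objects sharing a base year.
#' @param tol Equality tolerance on total coverage.
#' @return Violation tibble (`locus`, `message`); zero rows when the
#'   baselines agree.
#' @export
check_baseline_equality <- function(a, b, tol = 1e-9) {
  stopifnot(inherits(a, "lst_scenario"), inherits(b, "lst_scenario"))
  if (a$horizon[1] != b$horizon[1]) {
    abort("scenarios have different base years")
  }
  base_year <- a$horizon[1]
  tot_a <- coverage_totals(coverage_at(a$coverage, base_year)) |>
    select("intervention_id", a = "total")
  tot_b <- coverage_totals(coverage_at(b$coverage, base_year)) |>
    select("intervention_id", b = "total")
  joined <- dplyr::full_join(tot_a, tot_b, by = "intervention_id") |>
    mutate(across(c("a", "b"), ~ tidyr::replace_na(.x, 0))) |>
    filter(abs(.data$a - .data$b) > tol)
  if (nrow(joined) == 0) {
    return(tibble(locus = character(), message = character()))
  }
  tibble(
    locus = paste0("coverage/", joined$intervention_id),
    message = sprintf("baseline total coverage differs: %.6f vs %.6f",
                      joined$a, joined$b))
}

#' Compare two scenarios and isolate program impact
#'
#' Projects both scenarios under the same configuration and differences the
#' total death series. The sign convention is `b - a` (counterfactual minus
#' observed when `a` is the observed scenario), so a beneficial program is
#' positive even when deaths rise in both scenarios — for instance when total
#' coverage falls and the population grows, the program still saved lives if
#' the no-community counterfactual's deaths rise faster.
#'
#' @param a Observed scenario.
#' @param b Comparison (counterfactual) scenario.
#' @param config An [lst_config()].
#' @return An `lst_comparison`: list with both projections, a `difference`
#'   tibble (`year`, `deaths_a`, `deaths_b`, `difference`) and
#'   `cumulative_difference` (program-attributable deaths averted over the
#'   horizon).
#' @export
compare_scenarios <- function(a, b, config) {
  violations <- check_baseline_equality(a, b)
  if (nrow(violations) > 0) {
    abort(c("baseline coverage differs between scenarios",
            stats::setNames(paste0(violations$locus, ": ", violations$message),
                            rep("x", nrow(violations)))))
  }
  pa <- project(a, config)
  pb <- project(b, config)
  diff <- pa$total_deaths |>
    rename(deaths_a = "deaths") |>
    inner_join(rename(pb$total_deaths, deaths_b = "deaths"), by = "year") |>
    mutate(difference = .data$deaths_b - .data$deaths_a)
  structure(
    list(scenario_a = a$name, scenario_b = b$name,
         projection_a = pa, projection_b = pb,
         difference = diff,
         cumulative_difference = sum(diff$difference)),
    class = "lst_comparison")
}

#' @export
print.lst_comparison <- function(x, ...) {
  cat(sprintf("<comparison> \"%s\" vs \"%s\"\n", x$scenario_a, x$scenario_b))
  cat(sprintf("  cumulative program-attributable deaths averted: %.1f\n",
              x$cumulative_difference))
  invisible(x)
}

#' @rdname compare_scenarios
#' @param x An `lst_comparison`.
#' @param ... Unused.
#' @export
tidy.lst_comparison <- function(x, ...) {
  x$difference |>
    mutate(scenario_a = x$scenario_a, scenario_b = x$scenario_b, .before = 1)
}

#' @rdname compare_scenarios
#' @export
glance.lst_comparison <- function(x, ...) {
  tibble(scenario_a = x$scenario_a, scenario_b = x$scenario_b,
         cumulative_difference = x$cumulative_difference,
         years = nrow(x$difference))
}

#' Decompose mortality reduction across concurrent programs
#'
#' When several programs scale up interventions simultaneously (e.g. an iCCM
#' program delivering antimalarials, pneumonia case management and ORS+zinc
#' while a bednet campaign distributes ITNs), the joint scenario's attributed
#' percent reductions can be summed within program labels to say which
#' portion of the decline each program is likely responsible for. Totals are
#' invariant to how interventions are partitioned into programs.
#'
#' @inheritParams project
#' @param programs Tibble `intervention_id`, `program` labelling each
#'   intervention with exactly one program. Every intervention whose coverage
#'   changes must be labelled.
#' @param years Optional year subset passed to [percent_reduction_table()].
#' @return Tibble `program`, `lives_saved`, `percent_reduction`, with one
#'   extra attribute-free total row obtainable by summing.
#' @export
decompose_concurrent_programs <- function(scn, config, programs,
                                          years = NULL) {
  programs <- as_tibble(programs)
  stopifnot(all(c("intervention_id", "program") %in% names(programs)))
  proj <- project(scn, config)
  pct <- percent_reduction_table(proj$attribution, proj$baseline_deaths,
                                 years = years)
  changed <- pct$intervention_id[abs(pct$lives_saved) > 1e-9]
  unlabelled <- setdiff(changed, programs$intervention_id)
  if (length(unlabelled) > 0) {
    abort(paste0("interventions with changed coverage lack a program label: ",
                 paste(unlabelled, collapse = ", ")))
  }
  pct |>
    inner_join(programs, by = "intervention_id") |>
    group_by(.data$program) |>
    summarise(lives_saved = sum(.data$lives_saved),
              percent_reduction = sum(.data$percent_reduction),
              .groups = "drop")
}
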