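#' Specification for a synthetic fixture
#'
#' Describes a reproducible synthetic world: a cause-of-death structure, an
#' intervention catalogue and a survey-style coverage trajectory following
#' one of four channel-shift regimes observed around community case
#' management programs:
#'
#' * `"ideal"` — facility coverage stays flat while community delivery grows:
#'   the program reaches children not already accessing care.
#' * `"task_shifting"` — users move from facility to community care; total
#'   coverage roughly flat.
#' * `"stockout"` — facility coverage drops (stockouts, strikes) while
#'   community coverage grows but only partially compensates, so total
#'   coverage declines even though the program helps.
#' * `"concurrent_itn"` — a stockout-shaped curative trajectory plus a
#'   simultaneously scaled-up preventive malaria intervention (bednets).
#'
#' Same seed and spec give byte-identical fixtures; generation never touches
#' the global random state.
#'
#' @param seed Integer RNG seed.
#' @param n_causes Number of causes (>= 1); the first few take the canonical
#'   names pneumonia, diarrhea, malaria, other.
#' @param n_interventions Number of interventions (>= 1).
#' @param horizon_length Years in the projection horizon (inclusive span).
#' @param regime One of the four regimes above.
#' @param effect_range Range for nonzero effectiveness values.
#' @param delta_range Range for community coverage increases.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_causes = 4, n_interventions = 4,
                         horizon_length = 6, regime = "ideal",
                         effect_range = c(0.2, 0.8),
                         delta_range = c(0.05, 0.25)) {
  regimes <- c("ideal", "task_shifting", "stockout", "concurrent_itn")
  if (!regime %in% regimes) {
    abort(paste0("unknown regime; must be one of: ",
                 paste(regimes, collapse = ", ")))
  }
  if (n_causes < 1) abort("infeasible spec: need at least one cause")
  if (n_interventions < 1) abort("infeasible spec: need at least one intervention")
  structure(
    list(seed = as.integer(seed), n_causes = n_causes,
         n_interventions = n_interventions, horizon_length = horizon_length,
         regime = regime, effect_range = effect_range,
         delta_range = delta_range),
    class = "fixture_spec")
}

#' Generate a synthetic configuration
#'
#' Produces a valid [lst_config()]: causes with baseline death counts, a mix
#' of preventive and curative interventions (at least one of each when
#' `n_interventions >= 2`) each acting on at least one cause, and a
#' demography with a base cohort of live births and a small growth rate.
#' Magnitudes are survey-plausible, not calibrated to any country.
#'
#' @param spec A [fixture_spec()].
#' @return An `lst_config`.
#' @export
generate_config <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    canonical <- c("pneumonia", "diarrhea", "malaria", "other")
    ids <- if (spec$n_causes <= length(canonical)) {
      canonical[seq_len(spec$n_causes)]
    } else {
      c(canonical, paste0("cause", seq_len(spec$n_causes - length(canonical))))
    }
    causes <- tibble(
      cause_id = ids,
      name = tools::toTitleCase(ids),
      baseline_deaths = round(stats::runif(spec$n_causes, 5000, 40000)))

    n <- spec$n_interventions
    category <- if (n == 1) {
      sample(CATEGORIES, 1)
    } else {
      # guarantee both categories are represented
      c("preventive", "curative",
        sample(CATEGORIES, n - 2, replace = TRUE))[seq_len(n)]
    }
    stage <- ifelse(category == "curative", "childhood",
                    sample(STAGES, n, replace = TRUE))
    interventions <- tibble(
      intervention_id = paste0("int", seq_len(n)),
      name = paste("Intervention", seq_len(n)),
      category = category, stage = stage)

    # each intervention acts on one primary cause; occasionally on a second
    primary <- sample(causes$cause_id, n, replace = TRUE)
    eff <- tibble(
      intervention_id = interventions$intervention_id,
      cause_id = primary,
      effectiveness = stats::runif(n, spec$effect_range[1],
                                   spec$effect_range[2]))
    extra <- which(stats::runif(n) < 0.3 & spec$n_causes > 1)
    if (length(extra) > 0) {
      second <- vapply(extra, function(i) {
        sample(setdiff(causes$cause_id, primary[i]), 1)
      }, character(1))
      eff <- bind_rows(eff, tibble(
        intervention_id = interventions$intervention_id[extra],
        cause_id = second,
        effectiveness = stats::runif(length(extra), spec$effect_range[1],
                                     spec$effect_range[2])))
    }

    dem <- demography(2008,
                      base_births = round(stats::runif(1, 50000, 500000)),
                      growth_rate = stats::runif(1, 0, 0.03))
    lst_config(causes, interventions, eff, dem)
  })
}

#' Generate a survey-style coverage table
#'
#' Builds before/after channel-disaggregated coverage records for every
#' intervention of a configuration, following the spec's regime (see
#' [fixture_spec()]). Records are written at the first and last horizon year
#' only, mimicking a before-after survey design; intermediate years are
#' produced by the model's interpolation. All rows respect the channel-sum
#' constraint by construction.
#'
#' @param spec A [fixture_spec()].
#' @param config The [lst_config()] generated from the same spec.
#' @return Coverage tibble (`intervention_id`, `year`, `channel`,
#'   `coverage`).
#' @export
generate_coverage <- function(spec, config) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(config, "lst_config"))
  withr::with_seed(spec$seed + 1L, {
    y0 <- config$demography$base_year
    y1 <- y0 + spec$horizon_length - 1L
    ivs <- config$interventions

    one <- function(id, is_preventive) {
      fac0 <- stats::runif(1, 0.25, 0.5)
      com0 <- stats::runif(1, 0, 0.1)
      d <- stats::runif(1, spec$delta_range[1], spec$delta_range[2])
      if (spec$regime == "ideal") {
        fac1 <- fac0
        com1 <- min(com0 + d, 1 - fac1)
      } else if (spec$regime == "task_shifting") {
        shift <- min(d, fac0)
        fac1 <- fac0 - shift
        com1 <- com0 + shift
      } else { # stockout, concurrent_itn
        # facility drop must exceed the community gain (total declines) but
        # cannot exceed the facility level itself
        hi <- min(d * 2.5, fac0)
        drop <- stats::runif(1, min(d * 1.2, (d + hi) / 2), hi)
        fac1 <- fac0 - drop
        com1 <- com0 + d
      }
      if (spec$regime == "concurrent_itn" && is_preventive) {
        # preventive campaign (e.g. bednets): facility-style scale-up
        fac1 <- min(fac0 + d, 1)
        com1 <- com0
      }
      tibble(intervention_id = id,
             year = rep(c(y0, y1), each = 2),
             channel = rep(c("community", "facility"), 2),
             coverage = c(com0, fac0, com1, fac1))
    }

    purrr::map2(ivs$intervention_id, ivs$category == "preventive", one) |>
      bind_rows()
  })
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper: config + coverage + scenario, all from one spec.
#'
#' @param spec A [fixture_spec()].
#' @return List with `config` (an `lst_config`) and `scenario` (an
#'   `lst_scenario` named after the regime).
#' @export
generate_scenario <- function(spec) {
  config <- generate_config(spec)
  coverage <- generate_coverage(spec, config)
  y0 <- config$demography$base_year
  list(config = config,
       scenario = scenario(paste0("synthetic-", spec$regime),
                           config$demography, coverage,
                           c(y0, y0 + spec$horizon_length - 1L)))
}
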