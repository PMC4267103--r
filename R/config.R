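#' Assemble a model configuration
#'
#' Bundles the cause-of-death structure, the intervention catalogue, the
#' per-cause effectiveness values and the demography into a single validated
#' object. Effectiveness is the proportional reduction in a cause's mortality
#' when the intervention reaches 100% coverage.
#'
#' @param causes Tibble with columns `cause_id`, `name`, `baseline_deaths`
#'   (under-five deaths at the base year attributable to each cause).
#' @param interventions Tibble with columns `intervention_id`, `name`,
#'   `category` (`"preventive"` or `"curative"`) and `stage` (one of
#'   `"periconceptual"`, `"pregnancy"`, `"delivery"`, `"postnatal"`,
#'   `"childhood"`).
#' @param effectiveness Tibble with columns `intervention_id`, `cause_id`,
#'   `effectiveness` (fraction in \[0, 1\]).
#' @param demography A [demography()] object.
#'
#' @return An object of class `lst_config`.
#' @seealso [validate_config()] for the full rule list.
#' @export
lst_config <- function(causes, interventions, effectiveness, demography) {
  causes <- as_tibble(causes)
  interventions <- as_tibble(interventions)
  effectiveness <- as_tibble(effectiveness)
  cfg <- structure(
    list(causes = causes, interventions = interventions,
         effectiveness = effectiveness, demography = demography),
    class = "lst_config")
  report <- validate_config(causes, interventions, effectiveness,
                            demography = demography)
  if (nrow(report) > 0) {
    abort(c("invalid configuration",
            stats::setNames(paste0(report$locus, ": ", report$message),
                            rep("x", nrow(report)))))
  }
  cfg
}

#' @export
print.lst_config <- function(x, ...) {
  cat(sprintf("<lst_config> %d cause(s), %d intervention(s)\n",
              nrow(x$causes), nrow(x$interventions)))
  print(x$demography)
  invisible(x)
}

#' Validate a raw configuration
#'
#' Checks every structural rule of the model inputs and returns all
#' violations at once; it never repairs anything. An empty report means the
#' configuration is valid. The function is side-effect free and idempotent.
#'
#' Rules enforced:
#' * cause and intervention ids unique; `baseline_deaths >= 0`;
#' * `category` and `stage` drawn from their fixed vocabularies;
#' * every effectiveness value in \[0, 1\] and every referenced cause id
#'   known; each intervention has at least one cause with effectiveness > 0;
#' * coverage (if supplied) in \[0, 1\], channels from
#'   community/facility/other, no duplicate (intervention, year, channel)
#'   record, per-(intervention, year) channel sum at most 1, and every
#'   intervention id known.
#'
#' @inheritParams lst_config
#' @param coverage Optional coverage tibble with columns `intervention_id`,
#'   `year`, `channel`, `coverage` (fractions, not percent).
#' @param demography Optional [demography()] object.
#' @return A tibble with columns `locus` (where the problem is) and
#'   `message`; zero rows when valid.
#' @export
validate_config <- function(causes, interventions, effectiveness,
                            coverage = NULL, demography = NULL) {
  v <- list()
  add <- function(locus, message) {
    v[[length(v) + 1]] <<- tibble(locus = locus, message = message)
  }

  causes <- as_tibble(causes)
  interventions <- as_tibble(interventions)
  effectiveness <- as_tibble(effectiveness)

  dup <- unique(causes$cause_id[duplicated(causes$cause_id)])
  for (id in dup) add(paste0("causes/", id), "duplicate cause id")
  bad <- causes$cause_id[!is.finite(causes$baseline_deaths) |
                           causes$baseline_deaths < 0]
  for (id in bad) add(paste0("causes/", id), "baseline_deaths must be >= 0")

  dup <- unique(interventions$intervention_id[
    duplicated(interventions$intervention_id)])
  for (id in dup) add(paste0("interventions/", id), "duplicate intervention id")
  bad <- interventions$intervention_id[!interventions$category %in% CATEGORIES]
  for (id in bad) {
    add(paste0("interventions/", id),
        paste0("category must be one of: ", paste(CATEGORIES, collapse = ", ")))
  }
  bad <- interventions$intervention_id[!interventions$stage %in% STAGES]
  for (id in bad) {
    add(paste0("interventions/", id),
        paste0("stage must be one of: ", paste(STAGES, collapse = ", ")))
  }

  bad <- effectiveness[!is.finite(effectiveness$effectiveness) |
                         effectiveness$effectiveness < 0 |
                         effectiveness$effectiveness > 1, ]
  for (i in seq_len(nrow(bad))) {
    add(paste0("effectiveness/", bad$intervention_id[i], "/", bad$cause_id[i]),
        "effectiveness out of range [0, 1]")
  }
  unknown <- setdiff(effectiveness$cause_id, causes$cause_id)
  for (id in unknown) {
    add(paste0("effectiveness/", id), "unknown cause id referenced")
  }
  unknown <- setdiff(effectiveness$intervention_id,
                     interventions$intervention_id)
  for (id in unknown) {
    add(paste0("effectiveness/", id), "unknown intervention id referenced")
  }
  has_effect <- unique(
    effectiveness$intervention_id[effectiveness$effectiveness > 0])
  for (id in setdiff(interventions$intervention_id, has_effect)) {
    add(paste0("interventions/", id),
        "intervention has no cause with effectiveness > 0")
  }

  if (!is.null(coverage)) {
    coverage <- as_tibble(coverage)
    bad <- coverage[!coverage$channel %in% CHANNELS, ]
    for (i in seq_len(nrow(bad))) {
      add(sprintf("coverage/%s/%s/%s", bad$intervention_id[i], bad$year[i],
                  bad$channel[i]),
          paste0("unknown channel; must be one of: ",
                 paste(CHANNELS, collapse = ", ")))
    }
    bad <- coverage[!is.finite(coverage$coverage) | coverage$coverage < 0 |
                      coverage$coverage > 1, ]
    for (i in seq_len(nrow(bad))) {
      add(sprintf("coverage/%s/%s/%s", bad$intervention_id[i], bad$year[i],
                  bad$channel[i]),
          "coverage out of range [0, 1] (use fractions, not percent)")
    }
    key <- paste(coverage$intervention_id, coverage$year, coverage$channel)
    for (k in unique(key[duplicated(key)])) {
      add(paste0("coverage/", gsub(" ", "/", k)),
          "duplicate (intervention, year, channel) record")
    }
    sums <- coverage |>
      group_by(.data$intervention_id, .data$year) |>
      summarise(total = sum(.data$coverage), .groups = "drop") |>
      filter(.data$total > 1 + 1e-9)
    for (i in seq_len(nrow(sums))) {
      add(sprintf("coverage/%s/%s", sums$intervention_id[i], sums$year[i]),
          sprintf("channel sum exceeds 1 (%.4f)", sums$total[i]))
    }
    unknown <- setdiff(coverage$intervention_id,
                       interventions$intervention_id)
    for (id in unknown) {
      add(paste0("coverage/", id), "unknown intervention id")
    }
  }

  if (!is.null(demography) && !inherits(demography, "lst_demography")) {
    add("demography", "not an lst_demography object")
  }

  if (length(v) == 0) {
    tibble(locus = character(), message = character())
  } else {
    bind_rows(v)
  }
}
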