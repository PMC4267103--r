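# Fixtures built in code, shared across test files.

# one cause, one 50%-effective intervention: the classic textbook world
worked_config <- function(category = "preventive") {
  lst_config(
    causes = tibble::tibble(cause_id = "diarrhea", name = "Diarrhea",
                            baseline_deaths = 10000),
    interventions = tibble::tibble(
      intervention_id = "vaccine", name = "Vaccine",
      category = category, stage = "childhood"),
    effectiveness = tibble::tibble(
      intervention_id = "vaccine", cause_id = "diarrhea",
      effectiveness = 0.5),
    demography = demography(2010, base_births = 100000))
}

worked_scenario <- function(cfg, cov_after = 0.5) {
  cov <- tibble::tibble(
    intervention_id = "vaccine", year = c(2010L, 2011L),
    channel = "facility", coverage = c(0, cov_after))
  scenario("worked", cfg$demography, cov, c(2010, 2011))
}

# a valid 4-cause / 4-intervention configuration used for validation tests
four_by_four_config <- function() {
  causes <- tibble::tibble(
    cause_id = c("pneumonia", "diarrhea", "malaria", "other"),
    name = c("Pneumonia", "Diarrhea", "Malaria", "Other"),
    baseline_deaths = c(30000, 25000, 15000, 30000))
  interventions <- tibble::tibble(
    intervention_id = c("itn", "antimalarials", "pneumorx", "orszinc"),
    name = c("ITNs", "Antimalarials", "Pneumonia case mgmt", "ORS+zinc"),
    category = c("preventive", "curative", "curative", "curative"),
    stage = c("childhood", "childhood", "childhood", "childhood"))
  eff <- tibble::tibble(
    intervention_id = c("itn", "antimalarials", "pneumorx", "orszinc"),
    cause_id = c("malaria", "malaria", "pneumonia", "diarrhea"),
    effectiveness = c(0.55, 0.4, 0.3, 0.5))
  lst_config(causes, interventions, eff,
             demography(2008, base_births = 200000, growth_rate = 0.01))
}

# the declining-total-coverage survey pattern: community 5->15%,
# facility 47->33% over 2008-2013
declining_coverage <- function() {
  tibble::tibble(
    intervention_id = "treatment",
    year = rep(c(2008L, 2013L), each = 2),
    channel = rep(c("community", "facility"), 2),
    coverage = c(0.05, 0.47, 0.15, 0.33))
}

declining_scenario <- function(growth_rate = 0.02) {
  cfg <- lst_config(
    causes = tibble::tibble(cause_id = "diarrhea", name = "Diarrhea",
                            baseline_deaths = 10000),
    interventions = tibble::tibble(
      intervention_id = "treatment", name = "Treatment",
      category = "curative", stage = "childhood"),
    effectiveness = tibble::tibble(
      intervention_id = "treatment", cause_id = "diarrhea",
      effectiveness = 0.6),
    demography = demography(2008, base_births = 100000,
                            growth_rate = growth_rate))
  list(config = cfg,
       scenario = scenario("observed", cfg$demography, declining_coverage(),
                           c(2008, 2013)))
}

# random single-cause attribution problem with a preventive and curative mix
random_steps <- function(n, allow_negative = FALSE) {
  category <- sample(c("preventive", "curative"), n, replace = TRUE)
  cov_base <- round(runif(n, 0, 0.4), 3)
  delta <- round(runif(n, 0.05, 0.5), 3)
  if (allow_negative) {
    sign <- sample(c(-1, 1), n, replace = TRUE)
    cov_now <- pmin(pmax(cov_base + sign * delta, 0), 1)
  } else {
    cov_now <- pmin(cov_base + delta, 1)
  }
  tibble::tibble(
    intervention_id = paste0("i", seq_len(n)),
    category = category,
    effectiveness = round(runif(n, 0.1, 0.9), 3),
    cov_now = cov_now, cov_base = cov_base)
}

# order a raw steps tibble the way the engine would (preventive block first,
# stable within blocks -- all same stage here)
order_steps <- function(steps) {
  steps[order(match(steps$category, c("preventive", "curative"))), ]
}
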