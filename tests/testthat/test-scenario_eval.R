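test_that("freezing community coverage reproduces the survey counterfactuals", {
  # declining-total pattern: community 5 -> 15%, facility 47 -> 33%
  dem <- demography(2008, base_births = 100000)
  obs <- scenario("observed", dem, declining_coverage(), c(2008, 2013))
  cf <- build_facility_only_counterfactual(obs)
  tot <- coverage_totals(coverage_at(cf$coverage, c(2008, 2013)))
  expect_equal(tot$total[tot$year == 2008], 0.52)
  expect_equal(tot$total[tot$year == 2013], 0.38) # 5% + 33%

  # ideal pattern: community 0 -> 10%, facility flat at 30%
  ideal_cov <- tibble::tibble(
    intervention_id = "treatment",
    year = rep(c(2008L, 2013L), each = 2),
    channel = rep(c("community", "facility"), 2),
    coverage = c(0, 0.30, 0.10, 0.30))
  ideal <- scenario("ideal", dem, ideal_cov, c(2008, 2013))
  cf2 <- build_facility_only_counterfactual(ideal)
  tot2 <- coverage_totals(coverage_at(cf2$coverage, 2013))
  expect_equal(tot2$total, 0.30)
})

test_that("counterfactual construction is idempotent and a no-op when community is flat", {
  dem <- demography(2008, base_births = 100000)
  obs <- scenario("observed", dem, declining_coverage(), c(2008, 2013))
  cf1 <- build_facility_only_counterfactual(obs)
  cf2 <- build_facility_only_counterfactual(cf1)
  norm <- function(s) dplyr::arrange(s$coverage, intervention_id, year, channel)
  expect_equal(norm(cf2), norm(cf1))

  flat <- obs
  flat$coverage$coverage[flat$coverage$channel == "community"] <- 0.05
  cf3 <- build_facility_only_counterfactual(flat)
  expect_equal(norm(cf3), norm(flat))
})

test_that("the freeze_other flag also pins the pharmacy channel", {
  dem <- demography(2008, base_births = 100000)
  cov <- dplyr::bind_rows(
    declining_coverage(),
    tibble::tibble(intervention_id = "treatment",
                   year = c(2008L, 2013L), channel = "other",
                   coverage = c(0.02, 0.08)))
  obs <- scenario("observed", dem, cov, c(2008, 2013))
  cf <- build_facility_only_counterfactual(obs, freeze_other = TRUE)
  oth <- cf$coverage[cf$coverage$channel == "other", ]
  expect_equal(unique(oth$coverage), 0.02)
  # default keeps "other" as observed
  cf2 <- build_facility_only_counterfactual(obs)
  expect_equal(sort(cf2$coverage$coverage[cf2$coverage$channel == "other"]),
               c(0.02, 0.08))
})

test_that("baseline equality holds by construction and flags real mismatches", {
  dem <- demography(2008, base_births = 100000)
  obs <- scenario("observed", dem, declining_coverage(), c(2008, 2013))
  cf <- build_facility_only_counterfactual(obs)
  expect_equal(nrow(check_baseline_equality(obs, cf)), 0)

  other <- obs
  other$coverage$coverage[other$coverage$year == 2008 &
                            other$coverage$channel == "facility"] <- 0.50
  report <- check_baseline_equality(obs, other)
  expect_equal(nrow(report), 1)
  expect_match(report$message, "baseline total coverage differs")

  dem2 <- demography(2009, base_births = 100000)
  shifted <- scenario("shifted", dem2,
                      dplyr::mutate(declining_coverage(),
                                    year = year + 1L), c(2009, 2014))
  expect_error(check_baseline_equality(obs, shifted), "different base years")
})

test_that("comparing a scenario with itself gives zero everywhere", {
  world <- declining_scenario()
  cmp <- compare_scenarios(world$scenario, world$scenario, world$config)
  expect_equal(cmp$difference$difference, rep(0, 6))
  expect_equal(cmp$cumulative_difference, 0)
})

test_that("comparison is antisymmetric in its difference series", {
  world <- declining_scenario()
  cf <- build_facility_only_counterfactual(world$scenario)
  ab <- compare_scenarios(world$scenario, cf, world$config)
  ba <- compare_scenarios(cf, world$scenario, world$config)
  expect_equal(ab$difference$difference, -ba$difference$difference)
})

test_that("a community program shows positive impact even as total coverage falls", {
  # total coverage drops 52% -> 48%, population grows: deaths rise in BOTH
  # scenarios, but the no-community-change counterfactual rises faster
  world <- declining_scenario(growth_rate = 0.02)
  cf <- build_facility_only_counterfactual(world$scenario)
  cmp <- compare_scenarios(world$scenario, cf, world$config)
  expect_gt(cmp$cumulative_difference, 0)
  final_a <- cmp$difference$deaths_a[cmp$difference$year == 2013]
  base_a <- cmp$difference$deaths_a[cmp$difference$year == 2008]
  expect_gt(final_a, base_a) # observed deaths still rising
})

test_that("identical coverage under growth differences to zero each year", {
  world <- declining_scenario(growth_rate = 0.02)
  flat_cov <- world$scenario$coverage |>
    dplyr::group_by(intervention_id, channel) |>
    dplyr::mutate(coverage = coverage[year == min(year)]) |>
    dplyr::ungroup()
  a <- scenario("a", world$config$demography, flat_cov, c(2008, 2013))
  b <- scenario("b", world$config$demography, flat_cov, c(2008, 2013))
  cmp <- compare_scenarios(a, b, world$config)
  expect_equal(cmp$difference$difference, rep(0, 6))
  expect_gt(cmp$difference$deaths_a[6], cmp$difference$deaths_a[1])
})

test_that("comparison aborts when baselines differ", {
  world <- declining_scenario()
  other <- world$scenario
  other$coverage$coverage[other$coverage$year == 2008 &
                            other$coverage$channel == "facility"] <- 0.30
  expect_error(compare_scenarios(world$scenario, other, world$config),
               "baseline coverage differs")
})

test_that("program decomposition sums to the overall reduction, any partition", {
  cfg <- read_config(system.file("extdata/iccm_itn_synthetic.yaml",
                                 package = "listlite"))
  cov <- read_coverage_csv(system.file("extdata/iccm_itn_synthetic_coverage.csv",
                                       package = "listlite"))
  scn <- scenario("joint", cfg$demography, cov, c(2010, 2011))
  labels <- tibble::tibble(
    intervention_id = c("itn", "antimalarials", "pneumo_cm", "ors_zinc"),
    program = c("itn-campaign", "iccm", "iccm", "iccm"))
  dec <- decompose_concurrent_programs(scn, cfg, labels, years = 2011)
  p <- project(scn, cfg)
  total <- sum(percent_reduction_table(p$attribution, p$baseline_deaths,
                                       years = 2011)$percent_reduction)
  expect_equal(sum(dec$percent_reduction), total, tolerance = 1e-9)

  # invariant to how interventions are partitioned
  labels2 <- dplyr::mutate(labels, program = intervention_id)
  dec2 <- decompose_concurrent_programs(scn, cfg, labels2, years = 2011)
  expect_equal(sum(dec2$percent_reduction), total, tolerance = 1e-9)

  # a program whose interventions never change coverage contributes zero
  cov0 <- cov |> dplyr::mutate(coverage = ifelse(intervention_id == "itn",
                                                 0, coverage))
  scn0 <- scenario("no-itn", cfg$demography, cov0, c(2010, 2011))
  dec0 <- decompose_concurrent_programs(scn0, cfg, labels, years = 2011)
  expect_equal(dec0$percent_reduction[dec0$program == "itn-campaign"], 0)
})

test_that("an unlabelled intervention with changed coverage is an error", {
  cfg <- read_config(system.file("extdata/iccm_itn_synthetic.yaml",
                                 package = "listlite"))
  cov <- read_coverage_csv(system.file("extdata/iccm_itn_synthetic_coverage.csv",
                                       package = "listlite"))
  scn <- scenario("joint", cfg$demography, cov, c(2010, 2011))
  labels <- tibble::tibble(intervention_id = c("itn", "antimalarials"),
                           program = c("itn-campaign", "iccm"))
  expect_error(decompose_concurrent_programs(scn, cfg, labels, years = 2011),
               "lack a program label")
})

test_that("a curative intervention is worth less beside a scaled-up preventive", {
  cfg <- read_config(system.file("extdata/iccm_itn_synthetic.yaml",
                                 package = "listlite"))
  cov <- read_coverage_csv(system.file("extdata/iccm_itn_synthetic_coverage.csv",
                                       package = "listlite"))
  joint <- scenario("joint", cfg$demography, cov, c(2010, 2011))
  alone_cov <- cov |> dplyr::mutate(coverage = ifelse(intervention_id == "itn",
                                                      0, coverage))
  alone <- scenario("iccm-alone", cfg$demography, alone_cov, c(2010, 2011))
  pj <- project(joint, cfg)
  pa <- project(alone, cfg)
  am <- function(p) {
    pct <- percent_reduction_table(p$attribution, p$baseline_deaths,
                                   years = 2011)
    pct$percent_reduction[pct$intervention_id == "antimalarials"]
  }
  expect_lt(am(pj), am(pa))
  expect_equal(round(am(pa), 1), 2.9)
  expect_equal(round(am(pj), 1), 2.1)
})
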