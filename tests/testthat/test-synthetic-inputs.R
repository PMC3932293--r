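test_that("Gompertz life tables behave across their parameter space", {
  # degenerate slope: constant six-month probability at every age
  flat <- make_life_table(gompertz_a = 0.01, gompertz_b = 0)
  expect_equal(length(unique(flat$q6[-nrow(flat)])), 1L)

  lt <- default_life_table
  expect_lt(lt$q6[lt$age == 65], lt$q6[lt$age == 85])
  expect_true(all(diff(lt$q6[lt$age >= 60]) >= 0))
  expect_equal(lt$q6[lt$age == 110], 1)

  # parameters whose probability saturates before age 100 are rejected
  expect_error(make_life_table(gompertz_a = 0.5, gompertz_b = 0.1),
               class = "osteohta_calibration_error")
})

test_that("life expectancy matches a continuous-survival integration oracle", {
  a <- attr(default_life_table, "gompertz_a")
  b <- attr(default_life_table, "gompertz_b")
  # independent oracle: numerical integration of the continuous Gompertz
  # survival function S(t) = exp(-(a/b) (e^{b(65+t)} - e^{65b}))
  oracle <- stats::integrate(function(t) {
    exp(-(a / b) * (exp(b * (65 + t)) - exp(b * 65)))
  }, 0, Inf)$value
  expect_equal(life_expectancy(default_life_table, 65), oracle, tolerance = 0.1 / oracle)
})

test_that("hazard calibration is deterministic and scales linearly", {
  exposure <- tibble::tibble(
    product = c("denosumab", "risedronate"),
    patients = c(50000, 150000)
  )
  targets <- c(hip = 3000, vertebral = 5000, other = 4000)
  h1 <- make_baseline_hazards(targets, exposure, default_params$treatments)
  h2 <- make_baseline_hazards(targets, exposure, default_params$treatments)
  expect_identical(h1, h2)

  # expectation oracle: expected counts = sum over products of
  # patients * p_annual * (1 - rrr * compliance), computed by hand
  p <- attr(h1, "annual_reference")
  tr <- default_params$treatments
  for (tp in c("hip", "vertebral", "other")) {
    eff <- tr[[paste0("rrr_", tp)]][match(exposure$product, tr$product)] *
      tr$compliance[match(exposure$product, tr$product)]
    expect_equal(sum(exposure$patients * p[[tp]] * (1 - eff)), targets[[tp]])
  }

  half <- make_baseline_hazards(targets / 2, exposure, default_params$treatments)
  expect_equal(attr(half, "annual_reference"),
               attr(h1, "annual_reference") / 2, tolerance = 1e-12)

  zero <- make_baseline_hazards(c(hip = 0, vertebral = 0, other = 0),
                                exposure, default_params$treatments)
  expect_true(all(zero$hip == 0 & zero$vertebral == 0 & zero$other == 0))

  expect_error(
    make_baseline_hazards(c(hip = 1e9, vertebral = 0, other = 0),
                          exposure, default_params$treatments),
    class = "osteohta_calibration_error"
  )
})

test_that("hip hazard rises with age below the mortality-crowding region", {
  bg <- cea_background(life_table = default_life_table)
  hz <- bg$hazards
  young <- hz[hz$age <= 100, ]
  expect_true(all(diff(young$hip) >= 0))
  # joint feasibility everywhere, including extreme ages
  q_eff <- pmin(1, osteohta:::death_probability(default_life_table, hz$age) *
                  attr(hz, "excess_mortality_hip"))
  expect_true(all(hz$hip + hz$vertebral + hz$other + q_eff <= 1 + 1e-12))
})

test_that("calibrated hazards are recovered from simulated fracture counts", {
  exposure <- tibble::tibble(product = "denosumab", patients = 2e5)
  targets <- c(hip = 4000, vertebral = 9000, other = 7000)
  hz <- make_baseline_hazards(targets, exposure, default_params$treatments)
  p <- attr(hz, "annual_reference")
  eff <- 1 - 0.85 * c(hip = 0.40, vertebral = 0.68, other = 0.20)
  set.seed(101)
  for (tp in names(p)) {
    n <- 2e5
    events <- rbinom(1, n, p[[tp]] * eff[[tp]])
    p_hat <- events / (n * eff[[tp]])
    mc_sd <- sqrt(p[[tp]] * (1 - p[[tp]]) / (n * eff[[tp]]))
    expect_lt(abs(p_hat - p[[tp]]), 4 * mc_sd)
  }
})

test_that("population projections follow the geometric closed form", {
  const <- make_population_projection(annual_growth = 0)
  expect_equal(length(unique(population_totals(const)$women)), 1L)

  grown <- make_population_projection(base_counts = c(all = 1e6),
                                      annual_growth = 0.01,
                                      years = 2010:2013)
  expect_equal(population_totals(grown)$women[4], 1e6 * 1.01^3)

  # year-on-year change stays within the demographic +/-5% bound
  tot <- population_totals(make_population_projection())$women
  expect_true(all(abs(diff(tot) / tot[-length(tot)]) <= 0.05))

  expect_error(make_population_projection(annual_growth = -1.5),
               class = "osteohta_validation_error")
  expect_error(make_population_projection(annual_growth = 0.2),
               class = "osteohta_validation_error")
  expect_error(make_population_projection(base_counts = c(a = -5)),
               class = "osteohta_validation_error")
})

test_that("back-solved population reproduces the published hip discharge rate", {
  # 4,653 hip/femur admissions against 27.2 million women aged 45+
  proj <- make_population_projection(base_counts = c(total = 27200000),
                                     annual_growth = 0, years = 2010)
  women <- population_totals(proj)$women
  expect_equal(discharge_rate(4653, women), 17.11)
})

test_that("background bundles round-trip through CSV", {
  dir <- withr::local_tempdir()
  bg <- cea_background(life_table = default_life_table)
  write_backgrounds(list(life_table = default_life_table, hazards = bg$hazards,
                         projection = make_population_projection()), dir)
  lt2 <- readr::read_csv(file.path(dir, "life_table.csv"), show_col_types = FALSE)
  expect_equal(lt2$q6, default_life_table$q6)
  hz2 <- readr::read_csv(file.path(dir, "baseline_hazards.csv"), show_col_types = FALSE)
  expect_equal(hz2$hip, bg$hazards$hip)
})
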