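# Shared fixtures: everything is built in code at test time.

default_params <- load_parameters()
default_life_table <- make_life_table()

cea_comparators <- c("risedronate", "alendronate_generic", "alendronate_branded",
                     "ibandronate", "strontium_ranelate")

# Hand-built hazard tables with constant age profiles, for mechanistic tests.
test_hazards <- function(hip = 0, vertebral = 0, other = 0, ages = 45:110,
                         excess_mortality_hip = 1, annual_reference = NULL) {
  structure(
    tibble::tibble(age = as.integer(ages), hip = hip, vertebral = vertebral,
                   other = other),
    class = c("osteo_hazards", class(tibble::tibble())),
    annual_reference = annual_reference %||%
      c(hip = 1 - (1 - hip)^2, vertebral = 1 - (1 - vertebral)^2,
        other = 1 - (1 - other)^2),
    reference_age = 65,
    age_slopes = c(hip = 0, vertebral = 0, other = 0),
    excess_mortality_hip = excess_mortality_hip
  )
}

# Constant-mortality life table (q6 at every age; no terminal forcing so the
# engine's max-age truncation is what ends the run).
test_life_table <- function(q6 = 0, ages = 45:110) {
  structure(
    tibble::tibble(age = as.integer(ages), q6 = q6),
    class = c("osteo_life_table", class(tibble::tibble()))
  )
}

# Minimal single-arm trajectory wrapper around an internal occupancy matrix.
fake_trajectory <- function(occ, on_drug = rep(FALSE, nrow(occ) - 1)) {
  colnames(occ) <- osteohta:::internal_states
  structure(
    tibble::tibble(cycle = 0:(nrow(occ) - 1)),
    class = c("cohort_trajectory", class(tibble::tibble())),
    arms = list(list(weight = 1, arm = "compliant", occ = occ,
                     on_drug = on_drug,
                     efficacy_weight = rep(1, nrow(occ) - 1))),
    profile = list(name = "test", annual_cost = 0), start_age = 65,
    cycle_length = 0.5
  )
}

zero_cost_profile <- function(name = "test", rrr = c(hip = 0, vertebral = 0, other = 0),
                              compliance = 1, annual_cost = 0, duration = 5,
                              offset = 1) {
  list(name = name, rrr = rrr, compliance = compliance,
       annual_cost = annual_cost, duration = duration, offset = offset)
}

scenario_costs_from_deltas <- function(deltas, baseline_keur = 1e5) {
  # Builds a pair of scenario cost tables whose difference equals the given
  # per-category deltas (thousand EUR).
  without <- deltas |>
    dplyr::mutate(cost_eur = baseline_keur * 1000) |>
    dplyr::select(year, category, cost_eur)
  with <- deltas |>
    dplyr::mutate(cost_eur = baseline_keur * 1000 + delta_thousand_eur * 1000) |>
    dplyr::select(year, category, cost_eur)
  list(with = with, without = without)
}

printed_budget_deltas <- function() {
  readr::read_csv(system.file("extdata", "budget_impact_deltas.csv",
                              package = "osteohta"),
                  show_col_types = FALSE, progress = FALSE)
}

printed_scenario_fractures <- function() {
  readr::read_csv(system.file("extdata", "scenario_fractures.csv",
                              package = "osteohta"),
                  show_col_types = FALSE, progress = FALSE)
}
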