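#' Generate an all-cause female life table
#'
#' Builds a deterministic life table on a Gompertz mortality law: the hazard
#' at age \eqn{x} is \eqn{a e^{bx}}, so the six-month death probability for
#' the year of age \eqn{x} is \eqn{1 - \exp(-0.5\, a e^{b(x + 1/2)})} — the
#' hazard is evaluated at mid-year so the piecewise-constant table
#' integrates the continuous law (the summed survival curve then matches
#' the continuous Gompertz life expectancy to well under 0.1 years). The
#' default parameters are calibrated to an elderly-female mortality schedule
#' with a remaining life expectancy at age 65 of roughly 21 years. The
#' terminal age carries probability 1.
#'
#' @param gompertz_a Baseline hazard level (`> 0`).
#' @param gompertz_b Exponential age slope of the hazard (`>= 0`).
#' @param ages Integer ages covered by the table.
#' @param seed Ignored: the generator is fully deterministic; the argument is
#'   kept so every background generator shares the same interface.
#' @return A tibble of class `osteo_life_table` with columns `age` and `q6`
#'   (six-month death probability).
#' @examples
#' lt <- make_life_table()
#' life_expectancy(lt, at_age = 65)
#' @export
make_life_table <- function(gompertz_a = 4e-6, gompertz_b = 0.115,
                            ages = 45:110, seed = NULL) {
  if (gompertz_a <= 0 || gompertz_b < 0) {
    abort("Gompertz parameters must satisfy a > 0, b >= 0",
          class = "osteohta_validation_error")
  }
  q6 <- 1 - exp(-0.5 * gompertz_a * exp(gompertz_b * (ages + 0.5)))
  if (any(q6[ages < 100] >= 1)) {
    abort("calibration error: six-month death probability reaches 1 before age 100",
          class = "osteohta_calibration_error")
  }
  q6[length(q6)] <- 1
  structure(
    tibble(age = as.integer(ages), q6 = q6),
    class = c("osteo_life_table", class(tibble())),
    gompertz_a = gompertz_a, gompertz_b = gompertz_b
  )
}

#' Remaining life expectancy from a life table
#'
#' Brute-force summation of the six-month survival curve implied by the life
#' table (midpoint rule: each half-year lived contributes 0.5 years weighted
#' by the average of the survival probabilities at its endpoints).
#'
#' @param life_table A life table from [make_life_table()].
#' @param at_age Age at which to evaluate remaining life expectancy.
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(life_table, at_age) {
  steps <- seq(at_age, max(life_table$age) - 0.5, by = 0.5)
  q <- death_probability(life_table, steps)
  surv <- cumprod(1 - q)
  # trapezoid: each half-year interval contributes 0.5 * mean endpoint survival
  sum(0.25 * (c(1, surv[-length(surv)]) + surv))
}

death_probability <- function(life_table, age) {
  idx <- pmin(pmax(floor(age), min(life_table$age)), max(life_table$age)) -
    min(life_table$age) + 1
  life_table$q6[idx]
}

#' Baseline fracture hazards for an untreated reference population
#'
#' Low-level constructor: takes annual first-fracture probabilities at a
#' reference age and expands them into age-specific six-month probabilities
#' with exponential age gradients (steepest for hip, shallow for vertebral
#' and other sites). These hazards are synthetic: the source publication
#' never prints baseline incidence, so the level is either supplied directly
#' (cost-effectiveness cohort) or calibrated to national fracture counts via
#' [make_baseline_hazards()].
#'
#' @param annual_reference Named vector `c(hip=, vertebral=, other=)` of
#'   annual first-fracture probabilities at `reference_age`.
#' @param reference_age Age anchoring the probability level.
#' @param ages Ages covered.
#' @param age_slopes Named vector of log-linear age gradients per year.
#' @param excess_mortality_hip Multiplier (`>= 1`) applied to background
#'   mortality during the first year after a hip fracture.
#' @param life_table Optional life table used to verify that fracture and
#'   death probabilities never sum above 1 at any age.
#' @return A tibble of class `osteo_hazards` with columns `age`, `hip`,
#'   `vertebral`, `other` (six-month probabilities) and attributes
#'   `annual_reference`, `reference_age`, `excess_mortality_hip`.
#' @export
baseline_hazards <- function(annual_reference, reference_age = 70,
                             ages = 45:110,
                             age_slopes = c(hip = 0.06, vertebral = 0.02, other = 0.01),
                             excess_mortality_hip = 2,
                             life_table = NULL) {
  types <- c("hip", "vertebral", "other")
  if (!all(types %in% names(annual_reference))) {
    abort("annual_reference must name hip, vertebral and other probabilities",
          class = "osteohta_schema_error")
  }
  if (any(annual_reference < 0 | annual_reference >= 1)) {
    abort("calibration error: annual fracture probabilities must lie in [0, 1)",
          class = "osteohta_calibration_error")
  }
  if (excess_mortality_hip < 1) {
    abort("excess_mortality_hip must be >= 1", class = "osteohta_validation_error")
  }
  p6_ref <- 1 - (1 - annual_reference[types])^0.5
  curves <- vapply(types, function(tp) {
    pmin(p6_ref[[tp]] * exp(age_slopes[[tp]] * (ages - reference_age)), 0.5)
  }, numeric(length(ages)))
  hz <- tibble(age = as.integer(ages), hip = curves[, "hip"],
               vertebral = curves[, "vertebral"], other = curves[, "other"])
  total <- hz$hip + hz$vertebral + hz$other
  if (!is.null(life_table)) {
    # At extreme ages mortality crowds out the fracture hazards: scale the
    # three curves down together so every transition row stays stochastic
    # (fractures + death <= 1), reaching zero where death is certain.
    q_eff <- pmin(1, death_probability(life_table, ages) * excess_mortality_hip)
    room <- pmax(0, 1 - q_eff)
    factor <- ifelse(total > 0, pmin(1, room / total), 1)
    hz$hip <- hz$hip * factor
    hz$vertebral <- hz$vertebral * factor
    hz$other <- hz$other * factor
  } else if (any(total > 1)) {
    abort("calibration error: fracture probabilities sum above 1",
          class = "osteohta_calibration_error")
  }
  structure(hz, class = c("osteo_hazards", class(tibble())),
            annual_reference = annual_reference[types],
            reference_age = reference_age,
            age_slopes = age_slopes,
            excess_mortality_hip = excess_mortality_hip)
}

#' Calibrate baseline hazards to national fracture counts
#'
#' Back-solves annual first-fracture probabilities so that the treated
#' population, under each product's compliance-weighted efficacy, experiences
#' the target number of fractures per year. The identifiable quantity is the
#' product of hazard and exposed-population size: with `exposure` fixed, the
#' annual probability per type is
#' `target / sum(patients * (1 - rrr * compliance))`.
#'
#' @param targets Named vector `c(hip=, vertebral=, other=)` of target annual
#'   fracture counts. A zero target yields an all-zero hazard for that type.
#' @param exposure Tibble `product, patients` for the calibration year.
#' @param treatments Treatments tibble (see [load_parameters()]).
#' @param seed Ignored (deterministic); kept for interface symmetry.
#' @inheritParams baseline_hazards
#' @return An `osteo_hazards` object (see [baseline_hazards()]).
#' @examples
#' params <- load_parameters()
#' exposure <- tibble::tibble(product = "denosumab", patients = 1e6)
#' make_baseline_hazards(c(hip = 5000, vertebral = 8000, other = 6000),
#'                       exposure, params$treatments)
#' @export
make_baseline_hazards <- function(targets, exposure, treatments,
                                  reference_age = 70, ages = 45:110,
                                  age_slopes = c(hip = 0.06, vertebral = 0.02, other = 0.01),
                                  excess_mortality_hip = 2,
                                  life_table = NULL, seed = NULL) {
  types <- c("hip", "vertebral", "other")
  if (!all(types %in% names(targets))) {
    abort("targets must name hip, vertebral and other counts",
          class = "osteohta_schema_error")
  }
  if (any(targets < 0)) {
    abort("targets must be >= 0", class = "osteohta_validation_error")
  }
  joined <- exposure |>
    left_join(as_tibble(treatments), by = "product")
  if (any(is.na(joined$compliance))) {
    abort(paste0("no treatment profile for product(s): ",
                 paste(joined$product[is.na(joined$compliance)], collapse = ", ")),
          class = "osteohta_validation_error")
  }
  eff_exposure <- vapply(types, function(tp) {
    rrr <- joined[[paste0("rrr_", tp)]]
    sum(joined$patients * (1 - rrr * joined$compliance))
  }, numeric(1))
  p_annual <- ifelse(targets[types] == 0, 0, targets[types] / eff_exposure)
  if (any(p_annual >= 1)) {
    abort("calibration error: targets require an annual fracture probability >= 1",
          class = "osteohta_calibration_error")
  }
  baseline_hazards(setNames(p_annual, types), reference_age = reference_age,
                   ages = ages, age_slopes = age_slopes,
                   excess_mortality_hip = excess_mortality_hip,
                   life_table = life_table)
}

#' Project the female population aged 45+
#'
#' Deterministic geometric projection per age band, standing in for the
#' demographic component of the budget-impact model. The default base counts
#' are synthetic: the total (28.72 million women aged 45+) is back-solved
#' from the published total discharge rate of 35.60 per 100,000 against
#' 10,225 admissions, split across bands with a plausible Italian age
#' structure.
#'
#' @param base_counts Named vector of women per age band in the base year.
#' @param annual_growth Annual growth rate per band (scalar or named vector);
#'   must be `> -1`, and within +/-5% to keep the projection demographic.
#' @param years Projection years; the first is the base year.
#' @return A tibble of class `osteo_population` with columns `year`,
#'   `age_band`, `women`.
#' @examples
#' make_population_projection()
#' @export
make_population_projection <- function(base_counts = c("45-64" = 15797100,
                                                       "65-74" = 6318840,
                                                       "75+" = 6606060),
                                       annual_growth = 0.01,
                                       years = 2010:2013) {
  if (any(base_counts <= 0)) {
    abort("base_counts must be > 0", class = "osteohta_validation_error")
  }
  if (any(annual_growth <= -1)) {
    abort("annual_growth must be > -1", class = "osteohta_validation_error")
  }
  if (any(abs(annual_growth) > 0.05)) {
    abort("annual_growth outside +/-5% is not a demographic projection",
          class = "osteohta_validation_error")
  }
  growth <- if (length(annual_growth) == 1) {
    setNames(rep(annual_growth, length(base_counts)), names(base_counts))
  } else {
    annual_growth[names(base_counts)]
  }
  out <- tidyr::expand_grid(year = years, age_band = names(base_counts)) |>
    mutate(women = base_counts[.data$age_band] *
             (1 + growth[.data$age_band])^(.data$year - years[1]))
  structure(as_tibble(out), class = c("osteo_population", class(tibble())))
}

#' Total women aged 45+ per projection year
#'
#' @param projection An `osteo_population` tibble.
#' @return Tibble `year, women`.
#' @export
population_totals <- function(projection) {
  projection |>
    summarise(women = sum(.data$women), .by = "year")
}

#' Write background inputs to a directory of CSV files
#'
#' @param backgrounds List with elements `life_table`, `hazards`,
#'   `projection` (any may be omitted).
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_backgrounds <- function(backgrounds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(backgrounds$life_table)) {
    p <- file.path(dir, "life_table.csv")
    readr::write_csv(backgrounds$life_table, p)
    paths <- c(paths, p)
  }
  if (!is.null(backgrounds$hazards)) {
    p <- file.path(dir, "baseline_hazards.csv")
    hz <- backgrounds$hazards
    readr::write_csv(as_tibble(hz), p)
    meta <- file.path(dir, "baseline_hazards_meta.yaml")
    yaml::write_yaml(list(
      annual_reference = as.list(attr(hz, "annual_reference")),
      reference_age = attr(hz, "reference_age"),
      excess_mortality_hip = attr(hz, "excess_mortality_hip")
    ), meta)
    paths <- c(paths, p, meta)
  }
  if (!is.null(backgrounds$projection)) {
    p <- file.path(dir, "population_projection.csv")
    readr::write_csv(backgrounds$projection, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
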