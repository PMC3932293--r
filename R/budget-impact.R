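#' Treated patients per year
#'
#' Disease component of the budget-impact model: the treated population is
#' the deterministic product of the projected female population, the
#' osteoporosis prevalence and the treatment rate, per year.
#'
#' @param projection An `osteo_population` projection
#'   ([make_population_projection()]).
#' @param prevalence Osteoporosis prevalence among women 45+ (fraction;
#'   scalar or named per-year vector).
#' @param treatment_rate Fraction of prevalent patients on drug therapy
#'   (scalar or named per-year vector).
#' @return A tibble of class `treated_population` with columns `year`,
#'   `treated`.
#' @examples
#' proj <- make_population_projection()
#' project_treated(proj, prevalence = 0.30, treatment_rate = 0.30)
#' @export
project_treated <- function(projection, prevalence, treatment_rate) {
  rates <- c(prevalence, treatment_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("prevalence and treatment_rate must lie in [0, 1]",
          class = "osteohta_validation_error")
  }
  totals <- population_totals(projection)
  per_year <- function(x) {
    if (length(x) == 1 && is.null(names(x))) rep(x, nrow(totals))
    else as.numeric(x[as.character(totals$year)])
  }
  out <- totals |>
    mutate(treated = .data$women * per_year(prevalence) * per_year(treatment_rate)) |>
    select("year", "treated")
  structure(out, class = c("treated_population", class(tibble())))
}

#' Uptake rates hitting published denosumab patient counts
#'
#' The published forecast counts 60,000 denosumab patients in its first
#' market year and 150,000 in the third; combined with the fixed market
#' shares this pins the total treated population in those years
#' (`count / share`). This helper back-solves per-year treatment rates from
#' such anchors, interpolating geometrically for years in between and
#' holding the first anchor's total for earlier years.
#'
#' @param projection An `osteo_population` projection.
#' @param shares Market-share table (`params$shares`).
#' @param anchors Named vector of denosumab patient counts by year.
#' @param prevalence Assumed prevalence (fraction), default 0.30.
#' @return List with `prevalence` and per-year `treatment_rate` suitable for
#'   [project_treated()].
#' @export
calibrated_uptake <- function(projection, shares,
                              anchors = c("2011" = 60000, "2013" = 150000),
                              prevalence = 0.30) {
  totals <- population_totals(projection)
  yrs <- totals$year
  deno <- shares |> filter(.data$product == "denosumab")
  target <- setNames(rep(NA_real_, length(yrs)), yrs)
  for (ay in names(anchors)) {
    sh <- deno$share[deno$year == as.numeric(ay)]
    if (length(sh) != 1 || sh == 0) {
      abort(paste0("no nonzero denosumab share for anchor year ", ay),
            class = "osteohta_validation_error")
    }
    target[[ay]] <- anchors[[ay]] / sh
  }
  known <- which(!is.na(target))
  for (i in seq_along(target)) {
    if (!is.na(target[i])) next
    lo <- known[known < i]; hi <- known[known > i]
    target[i] <- if (length(lo) == 0) {
      target[min(hi)]
    } else if (length(hi) == 0) {
      target[max(lo)]
    } else { # geometric interpolation between surrounding anchors
      a <- max(lo); b <- min(hi)
      target[a] * (target[b] / target[a])^((i - a) / (b - a))
    }
  }
  rate <- target / (totals$women * prevalence)
  if (any(rate > 1)) {
    abort("calibrated treatment rate exceeds 1; raise prevalence or population",
          class = "osteohta_validation_error")
  }
  list(prevalence = prevalence, treatment_rate = setNames(rate, yrs))
}

#' Split the treated population over products by market share
#'
#' Technology-prediction component: per-product patient counts are the total
#' treated population times each product's market share. In the
#' `"without"` (counterfactual) scenario denosumab's share is redistributed
#' over the products it displaces, in fixed proportions derived from the
#' published per-product spend erosion (strontium ranelate absorbs most,
#' then oral ibandronate, then the alendronate/cholecalciferol combination).
#'
#' @param treated A `treated_population` tibble.
#' @param shares Market-share table (`year, product, share`).
#' @param scenario `"with"` or `"without"` denosumab.
#' @param redistribution Named nonnegative weights (summing to 1) giving the
#'   share of denosumab's market that each displaced product absorbs in the
#'   counterfactual.
#' @return Tibble `year, product, patients` of class `treated_by_product`.
#' @export
apply_market_shares <- function(treated, shares,
                                scenario = c("with", "without"),
                                redistribution = c(strontium_ranelate = 0.66,
                                                   ibandronate = 0.31,
                                                   alendronate_cholecalciferol = 0.03)) {
  scenario <- match.arg(scenario)
  missing_years <- setdiff(treated$year, unique(shares$year))
  if (length(missing_years) > 0) {
    abort(paste0("market shares missing for year(s): ",
                 paste(missing_years, collapse = ", ")),
          class = "osteohta_validation_error")
  }
  sh <- shares |> filter(.data$year %in% treated$year)
  if (scenario == "without") {
    if (any(redistribution < 0) || abs(sum(redistribution) - 1) > 1e-9) {
      abort("redistribution weights must be nonnegative and sum to 1",
            class = "osteohta_validation_error")
    }
    absorb <- tibble(product = names(redistribution), w = unname(redistribution))
    sh <- sh |>
      left_join(absorb, by = "product") |>
      mutate(deno = sum(.data$share[.data$product == "denosumab"]), .by = "year") |>
      mutate(share = ifelse(.data$product == "denosumab", 0,
                            .data$share + dplyr::coalesce(.data$w, 0) * .data$deno)) |>
      select("year", "product", "share")
  }
  out <- sh |>
    inner_join(treated, by = "year") |>
    mutate(patients = .data$treated * .data$share) |>
    select("year", "product", "patients") |>
    arrange(.data$year, .data$product)
  structure(out, class = c("treated_by_product", class(tibble())),
            scenario = scenario)
}

#' Expected annual fracture counts
#'
#' Per year and fracture type, the expected count is the sum over products
#' of patients times the baseline annual first-fracture probability times
#' the compliance-weighted efficacy factor `1 - rrr * compliance`.
#' Deterministic (expectation-based); see `sample_fractures` for a sampled
#' uncertainty mode.
#'
#' @param treated_products `treated_by_product` tibble
#'   ([apply_market_shares()]).
#' @param treatments Treatments tibble.
#' @param hazards `osteo_hazards` whose `annual_reference` attribute holds
#'   the population-level annual fracture probabilities.
#' @return Tibble `year, type, fractures` of class `scenario_fractures`.
#' @export
expected_fractures <- function(treated_products, treatments, hazards) {
  p_annual <- attr(hazards, "annual_reference")
  if (is.null(p_annual)) {
    abort("hazards carry no annual_reference attribute",
          class = "osteohta_validation_error")
  }
  joined <- treated_products |>
    left_join(as_tibble(treatments), by = "product")
  if (any(is.na(joined$compliance))) {
    abort(paste0("no treatment profile for product(s): ",
                 paste(unique(joined$product[is.na(joined$compliance)]), collapse = ", ")),
          class = "osteohta_validation_error")
  }
  rows <- map(c("hip", "vertebral", "other"), function(tp) {
    joined |>
      mutate(expected = .data$patients * p_annual[[tp]] *
               (1 - .data[[paste0("rrr_", tp)]] * .data$compliance)) |>
      summarise(fractures = sum(.data$expected), .by = "year") |>
      mutate(type = tp, .after = "year")
  })
  structure(list_rbind(rows) |> arrange(.data$year, .data$type),
            class = c("scenario_fractures", class(tibble())),
            scenario = attr(treated_products, "scenario"))
}

#' Sampled annual fracture counts
#'
#' Binomial sampling counterpart of [expected_fractures()] for uncertainty
#' runs: each product-year contributes
#' `Binomial(patients, p * (1 - rrr * compliance))` events per type.
#'
#' @inheritParams expected_fractures
#' @param seed Integer seed.
#' @return Tibble `year, type, fractures`.
#' @export
sample_fractures <- function(treated_products, treatments, hazards, seed) {
  set.seed(seed)
  p_annual <- attr(hazards, "annual_reference")
  joined <- treated_products |>
    left_join(as_tibble(treatments), by = "product")
  rows <- map(c("hip", "vertebral", "other"), function(tp) {
    joined |>
      mutate(fractures = rbinom(dplyr::n(), size = as.integer(round(.data$patients)),
                                prob = p_annual[[tp]] *
                                  (1 - .data[[paste0("rrr_", tp)]] * .data$compliance))) |>
      summarise(fractures = sum(.data$fractures), .by = "year") |>
      mutate(type = tp, .after = "year")
  })
  list_rbind(rows) |> arrange(.data$year, .data$type)
}

#' Per-category scenario costs
#'
#' Costs a scenario's drug consumption and fracture burden into the four
#' payer categories: medications (patients times annual price, with
#' noncompliant patients paying for six months), inpatient care (acute
#' DRG-tariff cost at the event), outpatient care (per-event follow-up in
#' the event year), and community care (per-event follow-on in the year
#' after the event — hence empty in the first modelled year).
#'
#' @param treated_products `treated_by_product` tibble.
#' @param fractures `scenario_fractures` tibble.
#' @param treatments Treatments tibble.
#' @param cost_model List with named per-type unit costs `inpatient_unit`,
#'   `outpatient_unit`, `community_unit` (EUR per fracture).
#' @return Tibble `year, category, cost_eur` of class `scenario_costs`.
#' @export
scenario_costs <- function(treated_products, fractures, treatments,
                           cost_model = default_cost_model()) {
  meds <- treated_products |>
    left_join(as_tibble(treatments), by = "product") |>
    mutate(cost_eur = .data$patients * .data$annual_cost_eur *
             (.data$compliance + (1 - .data$compliance) * 0.5)) |>
    summarise(cost_eur = sum(.data$cost_eur), .by = "year") |>
    mutate(category = "medications", .after = "year")
  frac_cost <- function(unit, lag) {
    fractures |>
      mutate(year = .data$year + lag,
             cost_eur = .data$fractures * unit[.data$type]) |>
      filter(.data$year %in% treated_products$year) |>
      summarise(cost_eur = sum(.data$cost_eur), .by = "year")
  }
  inpat <- frac_cost(cost_model$inpatient_unit, 0) |>
    mutate(category = "inpatient", .after = "year")
  outpat <- frac_cost(cost_model$outpatient_unit, 0) |>
    mutate(category = "outpatient", .after = "year")
  comm <- frac_cost(cost_model$community_unit, 1) |>
    complete(year = unique(treated_products$year), fill = list(cost_eur = 0)) |>
    mutate(category = "community", .after = "year")
  out <- bind_rows(meds, inpat, outpat, comm) |> arrange(.data$year, .data$category)
  structure(out, class = c("scenario_costs", class(tibble())),
            scenario = attr(treated_products, "scenario"))
}

#' Default per-fracture category unit costs
#'
#' Acute inpatient costs are the published DRG-based unit costs; outpatient
#' and lagged community follow-on costs are synthetic configuration values
#' (the published budget split is printed but its generating unit costs are
#' not), sized so hip fractures dominate community care.
#'
#' @param catalogue Optional cost/utility catalogue supplying acute costs.
#' @return List with `inpatient_unit`, `outpatient_unit`, `community_unit`.
#' @export
default_cost_model <- function(catalogue = NULL) {
  acute <- if (is.null(catalogue)) {
    c(hip = 8206, vertebral = 2476, other = 3686.3)
  } else {
    c(hip = unname(catalogue$unit_cost[["hip"]]),
      vertebral = unname(catalogue$unit_cost[["vertebral"]]),
      other = unname(catalogue$unit_cost[["other"]]))
  }
  list(inpatient_unit = acute,
       outpatient_unit = c(hip = 900, vertebral = 600, other = 700),
       community_unit = c(hip = 6000, vertebral = 500, other = 300))
}

#' Fractures avoided by the new treatment
#'
#' Per year and type, `without - with`.
#'
#' @param with_s,without_s `scenario_fractures` tibbles (columns `year`,
#'   `type`, `fractures`) for the two market scenarios.
#' @return Tibble `year, type, avoided`.
#' @examples
#' with_s <- tibble::tibble(year = 2013, type = "hip", fractures = 38382)
#' without_s <- tibble::tibble(year = 2013, type = "hip", fractures = 38657)
#' fractures_avoided(with_s, without_s)
#' @export
fractures_avoided <- function(with_s, without_s) {
  if (!setequal(paste(with_s$year, with_s$type),
                paste(without_s$year, without_s$type))) {
    abort("scenario year/type mismatch", class = "osteohta_validation_error")
  }
  inner_join(without_s |> rename(without = "fractures"),
             with_s |> rename(with = "fractures"),
             by = c("year", "type")) |>
    mutate(avoided = .data$without - .data$with) |>
    select("year", "type", "avoided")
}

#' Budget impact of the with-denosumab scenario
#'
#' Per year and cost category, the delta `with - without` (negative values
#' are savings for the payer), in EUR and in thousands of EUR rounded
#' half-away-from-zero; the per-year total equals the category sum to the
#' rounding unit.
#'
#' @param with_s,without_s `scenario_costs` tibbles (columns `year`,
#'   `category`, `cost_eur`).
#' @return Tibble of class `budget_impact`: `year, category, delta_eur,
#'   delta_keur`.
#' @export
compute_budget_impact <- function(with_s, without_s) {
  cats <- c("medications", "inpatient", "outpatient", "community")
  for (s in list(with_s, without_s)) {
    miss <- setdiff(cats, unique(s$category))
    if (length(miss) > 0) {
      abort(paste0("scenario is missing cost category(ies): ",
                   paste(miss, collapse = ", ")),
            class = "osteohta_validation_error")
    }
  }
  out <- inner_join(with_s |> rename(with = "cost_eur"),
                    without_s |> rename(without = "cost_eur"),
                    by = c("year", "category")) |>
    mutate(delta_eur = .data$with - .data$without,
           delta_keur = round_half_away(.data$delta_eur / 1000),
           category = factor(.data$category, levels = cats)) |>
    select("year", "category", "delta_eur", "delta_keur") |>
    arrange(.data$year, .data$category)
  structure(out, class = c("budget_impact", class(tibble())))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-year budget impact totals
#'
#' @param impact A `budget_impact` tibble.
#' @return Tibble `year, total_eur, total_keur`; the thousands total is the
#'   rounded sum of the exact per-category deltas.
#' @export
budget_impact_total <- function(impact) {
  impact |>
    summarise(total_eur = sum(.data$delta_eur),
              total_keur = round_half_away(sum(.data$delta_eur) / 1000),
              .by = "year")
}

#' Inpatient share of avoided-fracture costs
#'
#' Among the fracture-related categories (inpatient, outpatient, community —
#' medications excluded), the percentage of a year's avoided costs
#' attributable to inpatient care.
#'
#' @param impact A `budget_impact` tibble.
#' @param year Year to evaluate.
#' @return Percentage (0-100).
#' @export
inpatient_share <- function(impact, year) {
  yr <- impact |> filter(.data$year == !!year, .data$category != "medications")
  tot <- sum(abs(yr$delta_eur))
  if (tot == 0) abort("no fracture-related impact in that year",
                      class = "osteohta_validation_error")
  100 * abs(yr$delta_eur[yr$category == "inpatient"]) / tot
}

#' @export
tidy.budget_impact <- function(x, ...) as_tibble(x)

#' @export
autoplot.budget_impact <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$year), y = .data$delta_keur,
                                       fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Year", y = "Budget impact (thousand EUR)",
                  fill = "Category") +
    ggplot2::theme_minimal()
}

#' Run the full budget-impact pipeline
#'
#' Chains the three model components for both scenarios: population
#' projection x uptake -> treated patients -> market-share split ->
#' expected fractures and per-category costs -> deltas.
#'
#' @param params An `osteo_parameters` object.
#' @param projection `osteo_population` projection; default
#'   [make_population_projection()].
#' @param uptake List with `prevalence` and `treatment_rate`; default
#'   calibrated to the published denosumab patient counts via
#'   [calibrated_uptake()].
#' @param hazard_targets Named annual fracture-count targets for the
#'   calibration year (first projection year).
#' @param cost_model See [scenario_costs()].
#' @param redistribution See [apply_market_shares()].
#' @return List with `treated`, `hazards`, `fractures` (per scenario),
#'   `avoided`, `costs` (per scenario), `impact`, `totals`.
#' @export
run_budget_impact <- function(params,
                              projection = make_population_projection(),
                              uptake = NULL,
                              hazard_targets = c(hip = 36343, vertebral = 21487,
                                                 other = 30000),
                              cost_model = default_cost_model(params$catalogue),
                              redistribution = c(strontium_ranelate = 0.66,
                                                 ibandronate = 0.31,
                                                 alendronate_cholecalciferol = 0.03)) {
  uptake <- uptake %||% calibrated_uptake(projection, params$shares)
  treated <- project_treated(projection, uptake$prevalence, uptake$treatment_rate)
  with_p <- apply_market_shares(treated, params$shares, "with",
                                redistribution = redistribution)
  without_p <- apply_market_shares(treated, params$shares, "without",
                                   redistribution = redistribution)
  base_year <- min(treated$year)
  hazards <- make_baseline_hazards(
    hazard_targets,
    exposure = with_p |> filter(.data$year == base_year) |>
      select("product", "patients"),
    treatments = params$treatments
  )
  f_with <- expected_fractures(with_p, params$treatments, hazards)
  f_without <- expected_fractures(without_p, params$treatments, hazards)
  c_with <- scenario_costs(with_p, f_with, params$treatments, cost_model)
  c_without <- scenario_costs(without_p, f_without, params$treatments, cost_model)
  impact <- compute_budget_impact(c_with, c_without)
  list(treated = treated, hazards = hazards,
       fractures = list(with = f_with, without = f_without),
       avoided = fractures_avoided(f_with, f_without),
       costs = list(with = c_with, without = c_without),
       impact = impact, totals = budget_impact_total(impact))
}
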