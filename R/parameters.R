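#' Load the model parameter set
#'
#' Reads the treatment profiles (fracture-specific efficacy, compliance,
#' annual drug cost, treatment duration and offset time), the cost/utility
#' catalogue, the market-share table and the discounting settings from a
#' parameter directory and validates them. With `path = NULL` the packaged
#' default parameter set is loaded; it encodes the published Italian inputs:
#' per-drug relative risk reductions and compliance, acute fracture costs
#' (hip 8,206 EUR, vertebral 2,476 EUR, a weighted pool for other sites),
#' health-state utilities, and per-product market shares for 2010-2013.
#' Annual drug prices are not published as unit prices; the packaged price
#' vector is synthetic, calibrated to the order of magnitude of national
#' drug spend, and fully overridable.
#'
#' A parameter directory holds three files:
#' `treatments.csv` (one row per product), `market_shares.csv`
#' (`product,year,share`, shares as fractions) and `economics.yaml`
#' (unit costs, utilities, discounting, cohort settings). All monetary
#' values are EUR; all percentages are stored as fractions.
#'
#' @param path Directory containing `treatments.csv`, `market_shares.csv`
#'   and `economics.yaml`, or `NULL` for the packaged defaults.
#' @return An object of class `osteo_parameters`: a list with elements
#'   `treatments` (tibble), `catalogue` (cost/utility catalogue),
#'   `shares` (tibble `year, product, share`, normalized to sum to 1 per
#'   year), `discount` (list `annual_rate`, `cycle_length`) and `cohort`
#'   (list `start_age`, `max_age`).
#' @examples
#' params <- load_parameters()
#' params$treatments
#' @export
load_parameters <- function(path = NULL) {
  path <- path %||% system.file("extdata", package = "osteohta")
  files <- file.path(path, c("treatments.csv", "market_shares.csv", "economics.yaml"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    abort(paste0("Parameter file(s) not found: ", paste(missing, collapse = ", ")),
          class = "osteohta_schema_error")
  }
  treatments <- readr::read_csv(files[1], show_col_types = FALSE, progress = FALSE)
  shares_raw <- readr::read_csv(files[2], show_col_types = FALSE, progress = FALSE)
  econ <- yaml::read_yaml(files[3])

  treatments <- validate_treatments(treatments)
  shares <- validate_market_shares(shares_raw)
  catalogue <- validate_catalogue(econ)
  discount <- discount_spec(
    annual_rate = econ$discount$annual_rate %||% 0.03,
    cycle_length = econ$discount$cycle_length_years %||% 0.5
  )
  cohort <- list(
    start_age = econ$cohort$start_age %||% 65,
    max_age = econ$cohort$max_age %||% 110
  )

  structure(
    list(treatments = treatments, catalogue = catalogue, shares = shares,
         discount = discount, cohort = cohort),
    class = "osteo_parameters"
  )
}

#' @export
print.osteo_parameters <- function(x, ...) {
  cat("<osteo_parameters>\n")
  cat("  treatments: ", nrow(x$treatments), " products\n", sep = "")
  cat("  market shares: years ", paste(sort(unique(x$shares$year)), collapse = ", "), "\n", sep = "")
  cat("  discount: ", x$discount$annual_rate * 100, "% per year, cycle ",
      x$discount$cycle_length, " years\n", sep = "")
  cat("  cohort: start age ", x$cohort$start_age, ", max age ", x$cohort$max_age, "\n", sep = "")
  invisible(x)
}

required_treatment_fields <- c(
  "product", "rrr_hip", "rrr_vertebral", "rrr_other", "compliance",
  "annual_cost_eur", "duration_years", "offset_years"
)

validate_treatments <- function(treatments) {
  miss <- setdiff(required_treatment_fields, names(treatments))
  if (length(miss) > 0) {
    abort(paste0("treatments table is missing field(s): ", paste(miss, collapse = ", ")),
          class = "osteohta_schema_error")
  }
  fracs <- c("rrr_hip", "rrr_vertebral", "rrr_other", "compliance")
  for (f in fracs) {
    v <- treatments[[f]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      abort(paste0("treatments$", f, " must be a fraction in [0, 1]"),
            class = "osteohta_validation_error")
    }
  }
  if (any(treatments$annual_cost_eur < 0)) {
    abort("treatments$annual_cost_eur must be >= 0", class = "osteohta_validation_error")
  }
  if (any(treatments$duration_years <= 0)) {
    abort("treatments$duration_years must be > 0", class = "osteohta_validation_error")
  }
  if (any(treatments$offset_years < 0)) {
    abort("treatments$offset_years must be >= 0", class = "osteohta_validation_error")
  }
  if (anyDuplicated(treatments$product)) {
    abort("duplicate product ids in treatments table", class = "osteohta_validation_error")
  }
  as_tibble(treatments)
}

#' @rdname load_parameters
#' @param shares A tibble with columns `product`, `year`, `share` (fractions).
#' @param tolerance Largest allowed deviation of a year's raw share sum from 1
#'   before normalization. Printed share tables rounded to 0.1 percentage
#'   points can sum to 99.9 or 100.1 percent; larger gaps indicate a broken
#'   table and raise a validation error.
#' @export
validate_market_shares <- function(shares, tolerance = 0.01) {
  miss <- setdiff(c("product", "year", "share"), names(shares))
  if (length(miss) > 0) {
    abort(paste0("market share table is missing field(s): ", paste(miss, collapse = ", ")),
          class = "osteohta_schema_error")
  }
  if (any(shares$share < 0)) {
    abort("market shares must be >= 0", class = "osteohta_validation_error")
  }
  sums <- shares |>
    summarise(total = sum(.data$share), .by = "year")
  bad <- sums |> filter(abs(.data$total - 1) > tolerance)
  if (nrow(bad) > 0) {
    abort(
      paste0("market shares for year(s) ", paste(bad$year, collapse = ", "),
             " sum to ", paste(signif(bad$total, 6), collapse = ", "),
             " (must be 1 within ", tolerance, ")"),
      class = "osteohta_validation_error"
    )
  }
  shares |>
    mutate(share = .data$share / sum(.data$share), .by = "year") |>
    as_tibble()
}

validate_catalogue <- function(econ) {
  uc <- econ$unit_costs_eur
  ut <- econ$utilities
  if (is.null(uc) || is.null(ut)) {
    abort("economics.yaml must contain unit_costs_eur and utilities",
          class = "osteohta_schema_error")
  }
  for (f in c("hip", "vertebral", "other")) {
    if (is.null(uc[[f]])) {
      abort(paste0("unit_costs_eur is missing field: ", f), class = "osteohta_schema_error")
    }
  }
  other_costs <- unlist(uc$other)
  mix <- unlist(econ$other_mix %||% setNames(rep(1 / length(other_costs), length(other_costs)),
                                             names(other_costs)))
  mix <- mix[names(other_costs)]
  if (any(is.na(mix))) {
    abort("other_mix must provide a weight for every other-fracture site",
          class = "osteohta_schema_error")
  }
  mix <- mix / sum(mix)
  unit_cost <- c(hip = as.numeric(uc$hip), vertebral = as.numeric(uc$vertebral),
                 other = as.numeric(sum(mix * other_costs)))
  if (any(unit_cost < 0) || any(other_costs < 0)) {
    abort("unit costs must be >= 0", class = "osteohta_validation_error")
  }

  need <- list(healthy = "healthy", hip = c("first_year", "subsequent"),
               vertebral = c("first_year", "subsequent"), other = "first_year")
  for (st in names(need)) {
    if (is.null(ut[[st]])) {
      abort(paste0("utilities is missing state: ", st), class = "osteohta_schema_error")
    }
  }
  u_first <- c(hip = as.numeric(ut$hip$first_year),
               vertebral = as.numeric(ut$vertebral$first_year),
               other = as.numeric(ut$other$first_year))
  u_sub <- c(hip = as.numeric(ut$hip$subsequent),
             vertebral = as.numeric(ut$vertebral$subsequent))
  u_healthy <- as.numeric(ut$healthy)
  all_u <- c(u_first, u_sub, u_healthy)
  if (any(!is.finite(all_u)) || any(all_u < 0 | all_u > 1)) {
    abort("utilities must lie in [0, 1]", class = "osteohta_validation_error")
  }
  structure(
    list(unit_cost = unit_cost, other_site_costs = other_costs, other_mix = mix,
         utility_first_year = u_first, utility_subsequent = u_sub,
         utility_healthy = u_healthy),
    class = "osteo_catalogue"
  )
}

#' Discounting settings
#'
#' Costs and health benefits are discounted at a constant annual rate; the
#' model cycle is fixed at six months (0.5 years).
#'
#' @param annual_rate Annual discount rate as a fraction (default 0.03).
#' @param cycle_length Cycle length in years; must be 0.5.
#' @return A list of class `osteo_discount`.
#' @export
discount_spec <- function(annual_rate = 0.03, cycle_length = 0.5) {
  if (annual_rate < 0) {
    abort("annual discount rate must be >= 0", class = "osteohta_validation_error")
  }
  if (!isTRUE(all.equal(cycle_length, 0.5))) {
    abort("cycle_length must be 0.5 years (six-month cycles)",
          class = "osteohta_validation_error")
  }
  structure(list(annual_rate = annual_rate, cycle_length = cycle_length),
            class = "osteo_discount")
}

#' Extract one treatment profile
#'
#' @param params An `osteo_parameters` object (or a treatments tibble).
#' @param product Product id, e.g. `"denosumab"`.
#' @return A list with elements `name`, `rrr` (named vector hip/vertebral/
#'   other), `compliance`, `annual_cost`, `duration`, `offset`.
#' @examples
#' treatment_profile(load_parameters(), "denosumab")$rrr
#' @export
treatment_profile <- function(params, product) {
  treatments <- if (inherits(params, "osteo_parameters")) params$treatments else params
  row <- treatments[treatments$product == product, ]
  if (nrow(row) != 1) {
    abort(paste0("unknown product: ", product), class = "osteohta_validation_error")
  }
  list(
    name = row$product,
    rrr = c(hip = row$rrr_hip, vertebral = row$rrr_vertebral, other = row$rrr_other),
    compliance = row$compliance,
    annual_cost = row$annual_cost_eur,
    duration = row$duration_years,
    offset = row$offset_years
  )
}

#' Write a parameter set back to disk
#'
#' Inverse of [load_parameters()]: writes `treatments.csv`,
#' `market_shares.csv` and `economics.yaml` so that reloading reproduces the
#' parameter set value-for-value.
#'
#' @param params An `osteo_parameters` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(params, dir) {
  stopifnot(inherits(params, "osteo_parameters"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(params$treatments, file.path(dir, "treatments.csv"))
  readr::write_csv(params$shares, file.path(dir, "market_shares.csv"))
  cat <- params$catalogue
  econ <- list(
    discount = list(annual_rate = params$discount$annual_rate,
                    cycle_length_years = params$discount$cycle_length),
    cohort = params$cohort,
    unit_costs_eur = list(
      hip = unname(cat$unit_cost[["hip"]]),
      vertebral = unname(cat$unit_cost[["vertebral"]]),
      other = as.list(cat$other_site_costs)
    ),
    other_mix = as.list(cat$other_mix),
    utilities = list(
      healthy = cat$utility_healthy,
      hip = list(first_year = unname(cat$utility_first_year[["hip"]]),
                 subsequent = unname(cat$utility_subsequent[["hip"]])),
      vertebral = list(first_year = unname(cat$utility_first_year[["vertebral"]]),
                       subsequent = unname(cat$utility_subsequent[["vertebral"]])),
      other = list(first_year = unname(cat$utility_first_year[["other"]]))
    )
  )
  yaml::write_yaml(econ, file.path(dir, "economics.yaml"))
  invisible(dir)
}

#' Risk ratio from cumulative incidences
#'
#' Computes the risk ratio of an intervention arm versus a control arm from
#' their cumulative incidences, e.g. the pivotal denosumab trial's new
#' vertebral fractures: 2.3% versus 7.2% under placebo gives RR 0.32.
#'
#' @param ci_treated,ci_control Cumulative incidences as fractions in
#'   \[0, 1\]; `ci_control` must be positive.
#' @return The risk ratio `ci_treated / ci_control`.
#' @examples
#' rr_from_cumulative_incidence(0.023, 0.072)
#' @export
rr_from_cumulative_incidence <- function(ci_treated, ci_control) {
  if (any(ci_treated < 0 | ci_treated > 1) || any(ci_control < 0 | ci_control > 1)) {
    abort("cumulative incidences must lie in [0, 1]", class = "osteohta_validation_error")
  }
  if (any(ci_control == 0)) {
    abort("risk ratio undefined: control cumulative incidence is 0",
          class = "osteohta_validation_error")
  }
  ci_treated / ci_control
}

#' Relative risk reduction from a risk ratio
#'
#' `1 - rr`, floored at 0. A risk ratio above 1 denotes a harmful effect;
#' the reduction is reported as 0 and the result carries a `harmful`
#' attribute (with a warning) so callers can detect the floor.
#'
#' @param rr Risk ratio(s), `>= 0`.
#' @return Relative risk reduction(s) in \[0, 1\], with a logical `harmful`
#'   attribute marking floored entries.
#' @examples
#' rrr_from_rr(0.32)  # 0.68
#' @export
rrr_from_rr <- function(rr) {
  if (any(rr < 0)) {
    abort("risk ratio must be >= 0", class = "osteohta_validation_error")
  }
  harmful <- rr > 1
  if (any(harmful)) {
    warn("risk ratio > 1 (harmful effect); relative risk reduction floored at 0")
  }
  structure(pmax(0, 1 - rr), harmful = harmful)
}
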