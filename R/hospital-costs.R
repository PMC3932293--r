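#' Aggregate hospital admission records by fracture type
#'
#' Burden-of-illness calculator: sums DRG-tariff remunerations and admission
#' counts per fracture type. Monetary accumulation is exact to the cent —
#' tariffs are converted to integer cents before summation, so totals
#' reproduce national aggregates bit-for-bit regardless of record order.
#'
#' @param records Data frame of admission records with columns
#'   `fracture_type` (one of `hip_femur`, `vertebral`, `other`) and
#'   `tariff_eur` (`>= 0`); an optional `age_band` column is carried by the
#'   record schema but not aggregated.
#' @return A tibble of class `admission_table` with one row per fracture
#'   type (`fracture_type`, `admissions`, `total_cost_eur`), plus
#'   attributes `total_admissions` and `total_cost_eur`.
#' @examples
#' recs <- tibble::tibble(fracture_type = c("hip_femur", "vertebral"),
#'                        tariff_eur = c(8206, 2476))
#' aggregate_admissions(recs)
#' @export
aggregate_admissions <- function(records) {
  types <- c("hip_femur", "vertebral", "other")
  if (!all(c("fracture_type", "tariff_eur") %in% names(records))) {
    abort("records need columns fracture_type and tariff_eur",
          class = "osteohta_schema_error")
  }
  unknown <- setdiff(unique(records$fracture_type), types)
  if (length(unknown) > 0) {
    abort(paste0("unknown fracture type label(s): ", paste(unknown, collapse = ", ")),
          class = "osteohta_validation_error")
  }
  if (any(records$tariff_eur < 0)) {
    abort("tariffs must be >= 0", class = "osteohta_validation_error")
  }
  cents <- round(records$tariff_eur * 100)
  out <- tibble(fracture_type = factor(records$fracture_type, levels = types),
                cents = cents) |>
    summarise(admissions = dplyr::n(), cents = sum(.data$cents),
              .by = "fracture_type") |>
    complete(fracture_type = factor(types, levels = types),
             fill = list(admissions = 0L, cents = 0)) |>
    mutate(fracture_type = as.character(.data$fracture_type),
           total_cost_eur = .data$cents / 100) |>
    select("fracture_type", "admissions", "total_cost_eur")
  structure(out, class = c("admission_table", class(tibble())),
            total_admissions = sum(out$admissions),
            total_cost_eur = sum(round(out$total_cost_eur * 100)) / 100)
}

#' Mean hospitalization cost per admission
#'
#' Grand total cost divided by grand total admissions, reported to the cent.
#'
#' @param table An `admission_table` from [aggregate_admissions()].
#' @return Mean cost per admission (EUR, rounded to cents).
#' @export
mean_cost_per_admission <- function(table) {
  n <- attr(table, "total_admissions") %||% sum(table$admissions)
  if (n == 0) abort("mean cost undefined: zero admissions",
                    class = "osteohta_validation_error")
  total <- attr(table, "total_cost_eur") %||% sum(table$total_cost_eur)
  round(total / n, 2)
}

#' Hospital discharge rate per 100,000
#'
#' @param admissions Number of admissions (`>= 0`).
#' @param population Population denominator (`> 0`).
#' @return Discharges per 100,000, rounded to two decimals.
#' @examples
#' discharge_rate(10225, 28722000)
#' @export
discharge_rate <- function(admissions, population) {
  if (any(population <= 0)) {
    abort("population must be > 0", class = "osteohta_validation_error")
  }
  if (any(admissions < 0)) {
    abort("admissions must be >= 0", class = "osteohta_validation_error")
  }
  round(admissions / population * 1e5, 2)
}

#' Synthesize admission records matching published marginals
#'
#' Generates one record per admission such that per-type counts match the
#' marginal table exactly and per-type cost totals match to the cent:
#' tariffs are drawn from a Gamma distribution around the type mean, scaled
#' to the cost marginal, rounded to cents, and the rounding residual is
#' added to the largest record. Age bands are assigned with fixed synthetic
#' weights (45-64, 65-74, 75+). The default marginal table is the packaged
#' national 2009 admission table.
#'
#' @param marginals Tibble `fracture_type, admissions, total_cost_eur`;
#'   `NULL` loads the packaged table.
#' @param seed Integer seed.
#' @param cv Coefficient of variation of the simulated tariffs.
#' @return Tibble of records `age_band, fracture_type, tariff_eur`.
#' @export
synthesize_admissions <- function(marginals = NULL, seed = 1, cv = 0.3) {
  marginals <- marginals %||% readr::read_csv(
    system.file("extdata", "admissions_2009.csv", package = "osteohta"),
    show_col_types = FALSE, progress = FALSE
  )
  set.seed(seed)
  rows <- map(seq_len(nrow(marginals)), function(i) {
    n <- marginals$admissions[i]
    target_cents <- round(marginals$total_cost_eur[i] * 100)
    if (n == 0) return(NULL)
    mu <- marginals$total_cost_eur[i] / n
    shape <- 1 / cv^2
    draw <- rgamma(n, shape = shape, rate = shape / mu)
    cents <- round(draw * (target_cents / 100) / sum(draw) * 100)
    resid <- target_cents - sum(cents)
    j <- which.max(cents)
    cents[j] <- cents[j] + resid
    if (cents[j] < 0) abort("synthesis failed: negative tariff after residual fix",
                            class = "osteohta_validation_error")
    tibble(age_band = sample(c("45-64", "65-74", "75+"), n, replace = TRUE,
                             prob = c(0.2, 0.3, 0.5)),
           fracture_type = marginals$fracture_type[i],
           tariff_eur = cents / 100)
  })
  list_rbind(rows)
}
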