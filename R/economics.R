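#' Discounted costs and QALYs for a cohort trajectory
#'
#' Accumulates, cycle by cycle and per compliance arm: drug acquisition cost
#' (half the annual cost per on-treatment cycle, paid by the fraction alive
#' at the cycle start; the noncompliant arm pays for a single cycle), acute
#' fracture costs (occupancy of a fracture state equals the fraction
#' fracturing that cycle, so occupancy times the unit cost prices the
#' events), and quality-adjusted time (occupancy times state utility times
#' half a year). First-year utilities apply during the fracture cycle and
#' the recent post-fracture phase; subsequent-year utilities in the
#' established phase. Everything accruing in cycle k is discounted by
#' `(1 + rate)^(-k/2)`.
#'
#' @param traj A [run_cohort()] trajectory.
#' @param catalogue Cost/utility catalogue (`params$catalogue`).
#' @param profile Treatment profile used for drug cost.
#' @param discount A [discount_spec()].
#' @param half_cycle If `TRUE`, apply a half-cycle correction to the QALY
#'   stream (average adjacent occupancies, mid-cycle discounting). Off by
#'   default.
#' @return A one-row tibble of class `economic_result` with columns
#'   `strategy`, `total_cost`, `total_qalys`; attributes `life_years`
#'   (undiscounted) and `components` (drug vs fracture cost).
#' @examples
#' params <- load_parameters()
#' lt <- make_life_table()
#' hz <- baseline_hazards(c(hip = 0.02, vertebral = 0.05, other = 0.04),
#'                        reference_age = 65, life_table = lt)
#' prof <- treatment_profile(params, "denosumab")
#' traj <- run_cohort(prof, hz, lt)
#' accumulate_outcomes(traj, params$catalogue, prof, params$discount)
#' @export
accumulate_outcomes <- function(traj, catalogue, profile, discount,
                                half_cycle = FALSE) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  u <- internal_utilities(catalogue)
  costs <- c(hip_fracture = unname(catalogue$unit_cost[["hip"]]),
             vertebral_fracture = unname(catalogue$unit_cost[["vertebral"]]),
             other_fracture = unname(catalogue$unit_cost[["other"]]))
  r <- discount$annual_rate
  total_cost <- 0; total_qalys <- 0; life_years <- 0
  drug_cost <- 0; fracture_cost <- 0
  for (ar in attr(traj, "arms")) {
    occ <- ar$occ
    K <- nrow(occ) - 1
    if (K == 0) next
    k <- seq_len(K)
    disc <- (1 + r)^(-(k * 0.5))
    alive_start <- 1 - occ[k, "dead"]
    frac_k <- occ[k + 1, "hip_fracture"] * costs[["hip_fracture"]] +
      occ[k + 1, "vertebral_fracture"] * costs[["vertebral_fracture"]] +
      occ[k + 1, "other_fracture"] * costs[["other_fracture"]]
    drug_k <- as.numeric(ar$on_drug) * 0.5 * profile$annual_cost * alive_start
    occ_u <- occ[k + 1, , drop = FALSE] %*% u
    if (half_cycle) {
      occ_u <- (occ[k, , drop = FALSE] %*% u + occ_u) / 2
      disc_q <- (1 + r)^(-((k - 0.5) * 0.5))
    } else {
      disc_q <- disc
    }
    qaly_k <- 0.5 * as.numeric(occ_u)
    total_cost <- total_cost + ar$weight * sum(disc * (frac_k + drug_k))
    drug_cost <- drug_cost + ar$weight * sum(disc * drug_k)
    fracture_cost <- fracture_cost + ar$weight * sum(disc * frac_k)
    total_qalys <- total_qalys + ar$weight * sum(disc_q * qaly_k)
    life_years <- life_years + ar$weight * sum(0.5 * (1 - occ[k + 1, "dead"]))
  }
  structure(
    tibble(strategy = profile$name, total_cost = total_cost,
           total_qalys = total_qalys),
    class = c("economic_result", class(tibble())),
    life_years = life_years,
    components = c(drug = drug_cost, fracture = fracture_cost)
  )
}

internal_utilities <- function(catalogue) {
  uf <- catalogue$utility_first_year
  us <- catalogue$utility_subsequent
  need <- c("hip", "vertebral", "other")
  if (any(is.na(uf[need])) || any(is.na(us[c("hip", "vertebral")]))) {
    abort("catalogue error: missing utility for a modelled fracture state",
          class = "osteohta_catalogue_error")
  }
  c(healthy = catalogue$utility_healthy,
    hip_fracture = unname(uf[["hip"]]), post_hip_recent = unname(uf[["hip"]]),
    post_hip = unname(us[["hip"]]),
    vertebral_fracture = unname(uf[["vertebral"]]),
    post_vertebral_recent = unname(uf[["vertebral"]]),
    post_vertebral = unname(us[["vertebral"]]),
    other_fracture = unname(uf[["other"]]), dead = 0)[internal_states]
}

#' Run one treatment strategy end to end
#'
#' Convenience wrapper: [run_cohort()] followed by [accumulate_outcomes()].
#'
#' @param params An `osteo_parameters` object.
#' @param product Product id.
#' @param backgrounds List with `hazards` and `life_table`.
#' @param ... Passed to [run_cohort()] / [accumulate_outcomes()]
#'   (`half_cycle`, `dead_tol`, ...).
#' @return An `economic_result` tibble.
#' @export
run_strategy <- function(params, product, backgrounds, ...) {
  dots <- list(...)
  profile <- if (is.list(product) && !is.null(product$rrr)) product else
    treatment_profile(params, product)
  traj <- run_cohort(profile, backgrounds$hazards, backgrounds$life_table,
                     start_age = params$cohort$start_age,
                     max_age = params$cohort$max_age,
                     dead_tol = dots$dead_tol %||% 1e-9)
  accumulate_outcomes(traj, params$catalogue, profile, params$discount,
                      half_cycle = isTRUE(dots$half_cycle))
}

#' Economic result from known totals
#'
#' Constructs an `economic_result` directly from total discounted cost and
#' QALYs — useful for incremental arithmetic on published strategy totals.
#'
#' @param strategy Strategy label.
#' @param total_cost Discounted total cost (EUR), `>= 0`.
#' @param total_qalys Discounted total QALYs, `>= 0`.
#' @return An `economic_result` tibble.
#' @examples
#' economic_result("denosumab", 22399, 10.46)
#' @export
economic_result <- function(strategy, total_cost, total_qalys) {
  if (total_cost < 0 || total_qalys < 0) {
    abort("total_cost and total_qalys must be >= 0",
          class = "osteohta_validation_error")
  }
  structure(tibble(strategy = strategy, total_cost = total_cost,
                   total_qalys = total_qalys),
            class = c("economic_result", class(tibble())))
}

#' Incremental cost-effectiveness ratio
#'
#' `ICER = (cost_int - cost_comp) / (qalys_int - qalys_comp)`. A strategy
#' that costs no more and yields no fewer QALYs (not both equal) is
#' `dominant`; the reverse is `dominated`. Equal QALYs with a cost
#' difference give an infinite ICER (`status = "infinite"`), and identical
#' results are `indifferent`; neither raises an error.
#'
#' @param intervention,comparator `economic_result` objects (or one-row data
#'   frames with `strategy`, `total_cost`, `total_qalys`).
#' @return A one-row tibble of class `icer_result`: `intervention`,
#'   `comparator`, `delta_cost`, `delta_qalys`, `icer`, `status`.
#' @examples
#' compute_icer(economic_result("denosumab", 22399, 10.46),
#'              economic_result("generic alendronate", 21621, 10.41))
#' @export
compute_icer <- function(intervention, comparator) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  if (dq == 0 && dc == 0) {
    status <- "indifferent"; icer <- NA_real_
  } else if (dq == 0) {
    status <- "infinite"; icer <- sign(dc) * Inf
  } else if (dc <= 0 && dq >= 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (dc >= 0 && dq <= 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "ratio"; icer <- dc / dq
  }
  structure(
    tibble(intervention = intervention$strategy, comparator = comparator$strategy,
           delta_cost = dc, delta_qalys = dq, icer = icer, status = status),
    class = c("icer_result", class(tibble()))
  )
}

#' @export
tidy.icer_result <- function(x, ...) as_tibble(x)

#' Deterministic cost-effectiveness comparison table
#'
#' Runs the intervention and every comparator through the cohort model and
#' lays the results out as a comparison table (total costs and QALYs for
#' both strategies, differences, ICER or dominance status per comparator).
#'
#' @param params An `osteo_parameters` object.
#' @param backgrounds List with `hazards` and `life_table`.
#' @param intervention Product id of the intervention (default denosumab).
#' @param comparators Character vector of comparator product ids.
#' @param ... Passed on to [run_strategy()].
#' @return A tibble of class `cea_table` with one row per comparator.
#' @export
cea_table <- function(params, backgrounds, intervention = "denosumab",
                      comparators, ...) {
  res_int <- run_strategy(params, intervention, backgrounds, ...)
  rows <- map(comparators, function(cp) {
    res_cp <- run_strategy(params, cp, backgrounds, ...)
    ic <- compute_icer(res_int, res_cp)
    tibble(comparator = cp,
           cost_intervention = res_int$total_cost,
           cost_comparator = res_cp$total_cost,
           qalys_intervention = res_int$total_qalys,
           qalys_comparator = res_cp$total_qalys,
           delta_cost = ic$delta_cost, delta_qalys = ic$delta_qalys,
           icer = ic$icer, status = ic$status)
  })
  structure(list_rbind(rows), class = c("cea_table", class(tibble())),
            intervention = intervention)
}
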