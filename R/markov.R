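#' Markov health states
#'
#' The cohort model distinguishes seven health states: no fracture, the
#' six-month cycle in which a hip/femoral fracture occurs, the period after
#' a hip fracture, the cycle of a vertebral fracture, the period after a
#' vertebral fracture, a one-cycle state for other (non-hip non-vertebral)
#' fractures, and death. Internally the two post-fracture states are split
#' into a "recent" phase (months 6-12 after the event, carrying first-year
#' utility and, for hip, excess mortality) and an "established" phase, so
#' first-year and subsequent-year parameters act through tunnel states.
#'
#' @format Character vectors of state names.
#' @export
markov_states <- c("healthy", "hip_fracture", "post_hip",
                   "vertebral_fracture", "post_vertebral",
                   "other_fracture", "dead")

internal_states <- c("healthy", "hip_fracture", "post_hip_recent", "post_hip",
                     "vertebral_fracture", "post_vertebral_recent", "post_vertebral",
                     "other_fracture", "dead")

# Fast path used by the engine: returns the 9x9 internal matrix for given
# six-month probabilities. ph/pv/po are treated fracture entry probabilities,
# q the background death probability, m the first-post-hip-year mortality
# multiplier. Rows are validated, never renormalized.
transition_matrix_internal <- function(ph, pv, po, q, m) {
  n <- length(internal_states)
  M <- matrix(0, n, n, dimnames = list(internal_states, internal_states))
  qh <- min(1, q * m) # excess mortality saturates at certainty
  M["healthy", ] <- c(1 - ph - pv - po - q, ph, 0, 0, pv, 0, 0, po, q)
  M["hip_fracture", c("post_hip_recent", "dead")] <- c(1 - qh, qh)
  M["post_hip_recent", c("hip_fracture", "vertebral_fracture", "other_fracture",
                         "post_hip", "dead")] <-
    c(ph, pv, po, 1 - ph - pv - po - qh, qh)
  M["post_hip", c("hip_fracture", "vertebral_fracture", "other_fracture",
                  "post_hip", "dead")] <-
    c(ph, pv, po, 1 - ph - pv - po - q, q)
  M["vertebral_fracture", c("post_vertebral_recent", "dead")] <- c(1 - q, q)
  M["post_vertebral_recent", c("hip_fracture", "vertebral_fracture", "other_fracture",
                               "post_vertebral", "dead")] <-
    c(ph, pv, po, 1 - ph - pv - po - q, q)
  M["post_vertebral", c("hip_fracture", "vertebral_fracture", "other_fracture",
                        "post_vertebral", "dead")] <-
    c(ph, pv, po, 1 - ph - pv - po - q, q)
  M["other_fracture", c("healthy", "dead")] <- c(1 - q, q)
  M["dead", "dead"] <- 1

  # residual stay probabilities can round to tiny negatives when a row is
  # exactly saturated; clamp those, error on anything genuinely negative
  M[M < 0 & M > -1e-12] <- 0
  if (any(M < 0)) {
    bad <- internal_states[which(rowSums(M < 0) > 0)[1]]
    abort(paste0("transition matrix construction error: negative probability in row '",
                 bad, "' (fracture and death probabilities sum above 1)"),
          class = "osteohta_construction_error")
  }
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-12)) {
    bad <- internal_states[which.max(abs(rs - 1))]
    abort(paste0("transition matrix construction error: row '", bad,
                 "' sums to ", format(rs[which.max(abs(rs - 1))], digits = 17)),
          class = "osteohta_construction_error")
  }
  M
}

#' Build the six-month transition matrix at a given age
#'
#' Fracture entry probabilities are the baseline six-month hazards scaled by
#' `1 - rrr * efficacy_weight` per fracture type; death is reachable from
#' every state at the life-table probability, multiplied by the excess-
#' mortality factor during the first year after a hip fracture (the hip
#' cycle and the recent post-hip cycle). A hip fracture flows to the
#' post-hip state on the next cycle, a vertebral fracture to the
#' post-vertebral state; other fractures return to the no-fracture state
#' after one cycle; post-fracture states permit re-fracture at the treated
#' baseline risk. Rows that fail to sum to 1 raise a construction error —
#' the function never silently renormalizes.
#'
#' @param age Age (years) at the start of the cycle.
#' @param profile Treatment profile (see [treatment_profile()]).
#' @param hazards Baseline hazards from [baseline_hazards()] or
#'   [make_baseline_hazards()].
#' @param life_table Life table from [make_life_table()].
#' @param efficacy_weight Fraction of the full relative risk reduction in
#'   force this cycle: 1 on treatment, decaying linearly to 0 over the
#'   offset time after discontinuation, 0 thereafter.
#' @param expanded If `TRUE`, return the 9-state internal matrix in which
#'   the post-hip and post-vertebral states are split into recent and
#'   established phases; otherwise the 7-state matrix (the merged post
#'   states use the established-phase rows).
#' @return A row-stochastic matrix with dimnames in state order.
#' @examples
#' lt <- make_life_table()
#' hz <- baseline_hazards(c(hip = 0.02, vertebral = 0.05, other = 0.04),
#'                        reference_age = 65, life_table = lt)
#' profile <- treatment_profile(load_parameters(), "denosumab")
#' M <- build_transition_matrix(70, profile, hz, lt)
#' rowSums(M)
#' @export
build_transition_matrix <- function(age, profile, hazards, life_table,
                                    efficacy_weight = 1, expanded = FALSE) {
  if (efficacy_weight < 0 || efficacy_weight > 1) {
    abort("efficacy_weight must lie in [0, 1]", class = "osteohta_validation_error")
  }
  base <- hazard_at(hazards, age)
  ph <- base[["hip"]] * (1 - profile$rrr[["hip"]] * efficacy_weight)
  pv <- base[["vertebral"]] * (1 - profile$rrr[["vertebral"]] * efficacy_weight)
  po <- base[["other"]] * (1 - profile$rrr[["other"]] * efficacy_weight)
  q <- death_probability(life_table, age)
  m <- attr(hazards, "excess_mortality_hip") %||% 1
  M <- transition_matrix_internal(ph, pv, po, q, m)
  if (expanded) return(M)
  collapse_matrix(M)
}

# 9-state -> 7-state view: merged post states adopt the established-phase row.
collapse_matrix <- function(M) {
  n <- length(markov_states)
  out <- matrix(0, n, n, dimnames = list(markov_states, markov_states))
  dest <- c(healthy = "healthy", hip_fracture = "hip_fracture",
            post_hip_recent = "post_hip", post_hip = "post_hip",
            vertebral_fracture = "vertebral_fracture",
            post_vertebral_recent = "post_vertebral", post_vertebral = "post_vertebral",
            other_fracture = "other_fracture", dead = "dead")
  src <- c(healthy = "healthy", hip_fracture = "hip_fracture",
           post_hip = "post_hip", vertebral_fracture = "vertebral_fracture",
           post_vertebral = "post_vertebral", other_fracture = "other_fracture",
           dead = "dead")
  for (s in markov_states) {
    row <- M[src[[s]], ]
    for (j in internal_states) {
      out[s, dest[[j]]] <- out[s, dest[[j]]] + row[[j]]
    }
  }
  out
}

hazard_at <- function(hazards, age) {
  idx <- pmin(pmax(floor(age), min(hazards$age)), max(hazards$age)) -
    min(hazards$age) + 1
  c(hip = hazards$hip[idx], vertebral = hazards$vertebral[idx],
    other = hazards$other[idx])
}

# Efficacy weight at time t0 (years since treatment start) for an arm that
# receives the drug for `duration` years (compliant) or one cycle
# (noncompliant), with linear offset decay afterwards.
efficacy_weight_at <- function(t0, duration, offset) {
  if (t0 < duration) return(1)
  if (offset <= 0) return(0)
  max(0, 1 - (t0 - duration) / offset)
}

#' Run the Markov cohort to a lifetime horizon
#'
#' Propagates a cohort that starts in the no-fracture state through the
#' age-dependent transition matrices in six-month cycles until (practically)
#' everyone has died or the maximum age is reached. The cohort splits at
#' baseline into a compliant fraction — full efficacy and drug cost for the
#' treatment duration, then linear offset decay — and a noncompliant
#' fraction that receives drug cost and efficacy for a single cycle before
#' its own offset decay. Occupancy is conserved at every cycle to 1e-12.
#'
#' @param profile Treatment profile (see [treatment_profile()]).
#' @param hazards Baseline hazards ([baseline_hazards()]).
#' @param life_table Life table ([make_life_table()]).
#' @param start_age Cohort age at baseline (years).
#' @param max_age Oldest modelled age.
#' @param dead_tol Cohort is considered extinct when the dead fraction
#'   exceeds `1 - dead_tol`.
#' @param compliance_split If `FALSE`, run a single fully-compliant arm
#'   (useful for mechanistic checks).
#' @return A tibble of class `cohort_trajectory`: columns `cycle`, `age`,
#'   `time_years` and the seven state occupancies. Attributes `arms`
#'   (per-arm weight, internal 9-state occupancy matrix, per-cycle drug and
#'   efficacy schedules), `profile`, `start_age`.
#' @examples
#' lt <- make_life_table()
#' hz <- baseline_hazards(c(hip = 0.02, vertebral = 0.05, other = 0.04),
#'                        reference_age = 65, life_table = lt)
#' traj <- run_cohort(treatment_profile(load_parameters(), "denosumab"), hz, lt)
#' head(tidy(traj))
#' @export
run_cohort <- function(profile, hazards, life_table, start_age = 65,
                       max_age = 110, dead_tol = 1e-9,
                       compliance_split = TRUE) {
  arms <- if (compliance_split && profile$compliance < 1) {
    list(compliant = profile$compliance, noncompliant = 1 - profile$compliance)
  } else {
    list(compliant = 1)
  }
  arm_runs <- imap(arms, function(weight, arm) {
    run_arm(profile, hazards, life_table, start_age, max_age, dead_tol,
            arm = arm, weight = weight)
  })
  k_max <- max(map_dbl(arm_runs, ~ nrow(.x$occ) - 1))
  mix <- matrix(0, k_max + 1, length(internal_states),
                dimnames = list(NULL, internal_states))
  for (ar in arm_runs) {
    occ <- ar$occ
    if (nrow(occ) < k_max + 1) { # extinct arm: freeze its terminal distribution
      occ <- rbind(occ, matrix(rep(occ[nrow(occ), ], k_max + 1 - nrow(occ)),
                               ncol = ncol(occ), byrow = TRUE))
    }
    mix <- mix + ar$weight * occ
  }
  cycles <- 0:k_max
  out <- tibble(
    cycle = cycles,
    age = start_age + cycles * 0.5,
    time_years = cycles * 0.5,
    healthy = mix[, "healthy"],
    hip_fracture = mix[, "hip_fracture"],
    post_hip = mix[, "post_hip_recent"] + mix[, "post_hip"],
    vertebral_fracture = mix[, "vertebral_fracture"],
    post_vertebral = mix[, "post_vertebral_recent"] + mix[, "post_vertebral"],
    other_fracture = mix[, "other_fracture"],
    dead = mix[, "dead"]
  )
  structure(out, class = c("cohort_trajectory", class(tibble())),
            arms = arm_runs, profile = profile, start_age = start_age,
            cycle_length = 0.5)
}

run_arm <- function(profile, hazards, life_table, start_age, max_age,
                    dead_tol, arm, weight) {
  k_max <- ceiling((max_age - start_age) * 2)
  occ <- matrix(0, k_max + 1, length(internal_states),
                dimnames = list(NULL, internal_states))
  occ[1, "healthy"] <- 1
  on_drug <- logical(k_max)
  w_eff <- numeric(k_max)
  drug_years <- if (arm == "noncompliant") 0.5 else profile$duration
  v <- occ[1, ]
  k_used <- 0
  for (k in seq_len(k_max)) {
    t0 <- (k - 1) * 0.5
    w <- efficacy_weight_at(t0, drug_years, profile$offset)
    base <- hazard_at(hazards, start_age + t0)
    M <- transition_matrix_internal(
      base[["hip"]] * (1 - profile$rrr[["hip"]] * w),
      base[["vertebral"]] * (1 - profile$rrr[["vertebral"]] * w),
      base[["other"]] * (1 - profile$rrr[["other"]] * w),
      death_probability(life_table, start_age + t0),
      attr(hazards, "excess_mortality_hip") %||% 1
    )
    v <- drop(v %*% M)
    if (abs(sum(v) - 1) > 1e-12) {
      abort(paste0("occupancy conservation violated at cycle ", k,
                   ": total = ", format(sum(v), digits = 17)),
            class = "osteohta_conservation_error")
    }
    occ[k + 1, ] <- v
    on_drug[k] <- t0 < drug_years
    w_eff[k] <- w
    k_used <- k
    if (v[["dead"]] >= 1 - dead_tol) break
  }
  list(weight = weight, arm = arm,
       occ = occ[seq_len(k_used + 1), , drop = FALSE],
       on_drug = on_drug[seq_len(k_used)], efficacy_weight = w_eff[seq_len(k_used)])
}

#' @export
tidy.cohort_trajectory <- function(x, ...) {
  as_tibble(x) |>
    pivot_longer(all_of(markov_states), names_to = "state", values_to = "occupancy") |>
    mutate(state = factor(.data$state, levels = markov_states))
}

#' @export
autoplot.cohort_trajectory <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_years, y = .data$occupancy,
                                 fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Years since model start", y = "State occupancy",
                  fill = "Health state",
                  title = paste0("Cohort trajectory: ",
                                 attr(object, "profile")$name)) +
    ggplot2::theme_minimal()
}
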