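test_that("cycle accruals discount at (1 + r)^(-years)", {
  # one unit in the other-fracture state exactly one year (two cycles) in:
  # a 100 EUR event cost then discounts to 100 / 1.03 = 97.0874
  occ <- matrix(0, 3, 9)
  occ[, 1] <- 1
  occ[3, ] <- c(0, 0, 0, 0, 0, 0, 0, 1, 0) # other_fracture at cycle 2
  traj <- fake_trajectory(occ)
  cat <- default_params$catalogue
  cat$unit_cost[["other"]] <- 100
  cat$utility_healthy <- 0
  res <- accumulate_outcomes(traj, cat, zero_cost_profile(), discount_spec(0.03))
  expect_equal(res$total_cost, 100 / 1.03, tolerance = 1e-12)
  expect_equal(round(res$total_cost, 4), 97.0874)
})

test_that("permanent full-health occupancy accrues exactly one QALY per year", {
  occ <- matrix(0, 21, 9)
  occ[, 1] <- 1 # healthy for 20 cycles = 10 years
  res <- accumulate_outcomes(fake_trajectory(occ), default_params$catalogue,
                             zero_cost_profile(), discount_spec(0))
  expect_equal(res$total_qalys, 10)
  expect_equal(res$total_cost, 0)
})

test_that("a vertebral fracture cycle is costed and utility-weighted as printed", {
  hz <- test_hazards(vertebral = 1) # certain fracture in the first cycle
  lt <- test_life_table(0)
  prof <- zero_cost_profile()
  traj <- run_cohort(prof, hz, lt, start_age = 65, max_age = 66)
  res <- accumulate_outcomes(traj, default_params$catalogue, prof, discount_spec(0))
  # cycle 1: vertebral event (2,476 EUR, utility 0.590); cycle 2: recent
  # post-vertebral phase still at first-year utility
  expect_equal(res$total_cost, 2476)
  expect_equal(res$total_qalys, 0.5 * 0.590 + 0.5 * 0.590)

  res_d <- accumulate_outcomes(traj, default_params$catalogue, prof,
                               discount_spec(0.03))
  expect_equal(res_d$total_cost, 2476 * 1.03^-0.5, tolerance = 1e-12)
})

test_that("zero discounting reproduces undiscounted sums exactly", {
  bg <- cea_background(life_table = default_life_table)
  prof <- treatment_profile(default_params, "denosumab")
  traj <- run_cohort(prof, bg$hazards, default_life_table)
  r0 <- accumulate_outcomes(traj, default_params$catalogue, prof, discount_spec(0))
  # hand-accumulated undiscounted totals from the same trajectory
  u <- osteohta:::internal_utilities(default_params$catalogue)
  cost_hand <- 0; qaly_hand <- 0
  for (ar in attr(traj, "arms")) {
    occ <- ar$occ; K <- nrow(occ) - 1; k <- seq_len(K)
    cost_hand <- cost_hand + ar$weight * sum(
      occ[k + 1, "hip_fracture"] * 8206 + occ[k + 1, "vertebral_fracture"] * 2476 +
        occ[k + 1, "other_fracture"] * default_params$catalogue$unit_cost[["other"]] +
        as.numeric(ar$on_drug) * 0.5 * prof$annual_cost * (1 - occ[k, "dead"]))
    qaly_hand <- qaly_hand + ar$weight * sum(0.5 * occ[k + 1, , drop = FALSE] %*% u)
  }
  expect_equal(r0$total_cost, cost_hand)
  expect_equal(r0$total_qalys, qaly_hand)
  # discounting can only shrink totals, and QALYs never exceed life years
  r3 <- accumulate_outcomes(traj, default_params$catalogue, prof, discount_spec(0.03))
  expect_lt(r3$total_cost, r0$total_cost)
  expect_lt(r3$total_qalys, r0$total_qalys)
  expect_lte(r3$total_qalys, attr(r3, "life_years"))
})

test_that("ICER arithmetic handles ratios, dominance and degenerate deltas", {
  ic <- compute_icer(economic_result("denosumab", 22399, 10.46),
                     economic_result("generic alendronate", 21621, 10.41))
  expect_equal(ic$delta_cost, 778)
  expect_equal(ic$icer, 778 / (10.46 - 10.41), tolerance = 1e-9)
  expect_equal(round(ic$icer), 15560)

  ic2 <- compute_icer(economic_result("a", 105, 1.07), economic_result("b", 100, 1.00))
  expect_equal(round(ic2$icer, 1), 71.4)

  dom <- compute_icer(economic_result("a", 99, 1.01), economic_result("b", 100, 1.00))
  expect_equal(dom$status, "dominant")
  expect_true(is.na(dom$icer))

  sub <- compute_icer(economic_result("a", 101, 0.99), economic_result("b", 100, 1.00))
  expect_equal(sub$status, "dominated")

  inf <- compute_icer(economic_result("a", 105, 1.00), economic_result("b", 100, 1.00))
  expect_equal(inf$status, "infinite")
  expect_equal(inf$icer, Inf)

  same <- compute_icer(economic_result("a", 100, 1.00), economic_result("b", 100, 1.00))
  expect_equal(same$status, "indifferent")
})

test_that("zero-efficacy equal-cost strategies are economically identical", {
  bg <- cea_background(life_table = default_life_table)
  p1 <- zero_cost_profile("a", annual_cost = 150)
  p2 <- zero_cost_profile("b", annual_cost = 150)
  r1 <- accumulate_outcomes(run_cohort(p1, bg$hazards, default_life_table),
                            default_params$catalogue, p1, default_params$discount)
  r2 <- accumulate_outcomes(run_cohort(p2, bg$hazards, default_life_table),
                            default_params$catalogue, p2, default_params$discount)
  ic <- compute_icer(r1, r2)
  expect_equal(ic$delta_cost, 0)
  expect_equal(ic$delta_qalys, 0)
  expect_equal(ic$status, "indifferent")
})

test_that("raising efficacy never lowers QALYs nor raises fracture costs", {
  bg <- cea_background(life_table = default_life_table)
  grid <- seq(0, 0.8, by = 0.2)
  res <- lapply(grid, function(rrr_hip) {
    prof <- zero_cost_profile(rrr = c(hip = rrr_hip, vertebral = 0.3, other = 0.1),
                              annual_cost = 300, compliance = 0.85)
    accumulate_outcomes(run_cohort(prof, bg$hazards, default_life_table),
                        default_params$catalogue, prof, default_params$discount)
  })
  qalys <- vapply(res, function(r) r$total_qalys, numeric(1))
  frac_cost <- vapply(res, function(r) attr(r, "components")[["fracture"]], numeric(1))
  expect_true(all(diff(qalys) >= 0))
  expect_true(all(diff(frac_cost) <= 0))
})

test_that("compliance splits the cohort into arms with distinct drug exposure", {
  bg <- cea_background(life_table = default_life_table)
  prof <- treatment_profile(default_params, "denosumab")
  traj <- run_cohort(prof, bg$hazards, default_life_table)
  arms <- attr(traj, "arms")
  expect_named(arms, c("compliant", "noncompliant"))
  expect_equal(arms$compliant$weight, 0.85)
  expect_equal(sum(arms$compliant$on_drug), 10)     # 5 years of six-month cycles
  expect_equal(sum(arms$noncompliant$on_drug), 1)   # a single cycle
  # offset decay: efficacy fades linearly to zero after discontinuation
  w <- arms$compliant$efficacy_weight
  expect_equal(w[10], 1)
  expect_equal(w[11], 1)        # decay starts after the cycle beginning at 5y
  expect_equal(w[12], 0.5)
  expect_equal(w[13], 0)
})

test_that("the half-cycle correction flag changes only the QALY stream", {
  bg <- cea_background(life_table = default_life_table)
  prof <- treatment_profile(default_params, "risedronate")
  traj <- run_cohort(prof, bg$hazards, default_life_table)
  plain <- accumulate_outcomes(traj, default_params$catalogue, prof,
                               default_params$discount)
  hc <- accumulate_outcomes(traj, default_params$catalogue, prof,
                            default_params$discount, half_cycle = TRUE)
  expect_equal(hc$total_cost, plain$total_cost)
  expect_false(isTRUE(all.equal(hc$total_qalys, plain$total_qalys)))
})
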