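test_that("treated patients are the product of population and uptake rates", {
  proj <- make_population_projection(base_counts = c(a = 1e6, b = 2e6),
                                     annual_growth = 0, years = 2010:2011)
  tr <- project_treated(proj, prevalence = 0.3, treatment_rate = 0.5)
  expect_equal(tr$treated, rep(3e6 * 0.3 * 0.5, 2))

  expect_equal(project_treated(proj, 0.3, 0)$treated, c(0, 0))

  proj2 <- make_population_projection(base_counts = c(a = 2e6, b = 4e6),
                                      annual_growth = 0, years = 2010:2011)
  expect_equal(project_treated(proj2, 0.3, 0.5)$treated, 2 * tr$treated)

  expect_error(project_treated(proj, 1.2, 0.5), class = "osteohta_validation_error")
})

test_that("uptake calibration reproduces the published denosumab patient counts", {
  proj <- make_population_projection()
  uptake <- calibrated_uptake(proj, default_params$shares)
  treated <- project_treated(proj, uptake$prevalence, uptake$treatment_rate)
  deno <- apply_market_shares(treated, default_params$shares, "with") |>
    dplyr::filter(product == "denosumab")
  expect_equal(deno$patients[deno$year == 2011], 60000)
  expect_equal(deno$patients[deno$year == 2013], 150000)
})

test_that("market-share splits respect shares and the counterfactual", {
  treated <- structure(tibble::tibble(year = 2010:2013, treated = 2e6),
                       class = c("treated_population", class(tibble::tibble())))
  with_p <- apply_market_shares(treated, default_params$shares, "with")
  # 2013: denosumab holds 8.0% of the market
  deno13 <- with_p$patients[with_p$product == "denosumab" & with_p$year == 2013]
  sh13 <- default_params$shares |>
    dplyr::filter(year == 2013, product == "denosumab")
  expect_equal(deno13, 2e6 * sh13$share)
  expect_equal(round(deno13), 160000)

  without_p <- apply_market_shares(treated, default_params$shares, "without")
  expect_true(all(without_p$patients[without_p$product == "denosumab"] == 0))
  # patients are conserved within each year
  expect_equal(
    dplyr::summarise(without_p, p = sum(patients), .by = year)$p,
    dplyr::summarise(with_p, p = sum(patients), .by = year)$p
  )
  # the launch year (zero share) is identical in both scenarios
  expect_equal(
    with_p |> dplyr::filter(year == 2010) |> dplyr::arrange(product),
    without_p |> dplyr::filter(year == 2010) |> dplyr::arrange(product),
    ignore_attr = TRUE
  )

  # uniform shares split the market evenly
  sh_u <- tibble::tibble(product = c("a", "b", "c", "d"), year = 2010, share = 0.25)
  tr1 <- structure(tibble::tibble(year = 2010, treated = 1000),
                   class = c("treated_population", class(tibble::tibble())))
  even <- apply_market_shares(tr1, sh_u, "with")
  expect_equal(even$patients, rep(250, 4))

  expect_error(apply_market_shares(tr1, default_params$shares |>
                                     dplyr::filter(year != 2010), "with"),
               class = "osteohta_validation_error")
})

test_that("expected fracture counts follow the compliance-weighted efficacy", {
  tp <- structure(tibble::tibble(year = 2010, product = "denosumab",
                                 patients = 1000),
                  class = c("treated_by_product", class(tibble::tibble())))
  hz <- test_hazards(annual_reference = c(hip = 0.01, vertebral = 0, other = 0))
  profile_full <- default_params$treatments |>
    dplyr::mutate(compliance = ifelse(product == "denosumab", 1, compliance))
  out <- expected_fractures(tp, profile_full, hz)
  expect_equal(out$fractures[out$type == "hip"], 1000 * 0.01 * (1 - 0.40))
  expect_equal(out$fractures[out$type == "hip"], 6)

  # zero efficacy everywhere makes the two scenarios indistinguishable
  no_eff <- default_params$treatments |>
    dplyr::mutate(rrr_hip = 0, rrr_vertebral = 0, rrr_other = 0)
  treated <- structure(tibble::tibble(year = 2010:2013, treated = 1e6),
                       class = c("treated_population", class(tibble::tibble())))
  hz2 <- test_hazards(annual_reference = c(hip = 0.01, vertebral = 0.02, other = 0.015))
  f_with <- expected_fractures(
    apply_market_shares(treated, default_params$shares, "with"), no_eff, hz2)
  f_without <- expected_fractures(
    apply_market_shares(treated, default_params$shares, "without"), no_eff, hz2)
  expect_equal(f_with$fractures, f_without$fractures)

  expect_error(expected_fractures(tp, profile_full, test_life_table(0)),
               class = "osteohta_validation_error")
})

test_that("scenario subtraction gives avoided fractures, zero for identical runs", {
  printed <- printed_scenario_fractures()
  avoided <- fractures_avoided(
    printed |> dplyr::select(year, type, fractures = with_denosumab),
    printed |> dplyr::select(year, type, fractures = without_denosumab)
  )
  expect_equal(avoided$avoided[avoided$type == "hip" & avoided$year == 2013], 275)
  expect_equal(avoided$avoided[avoided$type == "vertebral" & avoided$year == 2012], 225)

  same <- printed |> dplyr::select(year, type, fractures = with_denosumab)
  expect_true(all(fractures_avoided(same, same)$avoided == 0))

  expect_error(
    fractures_avoided(same, same |> dplyr::filter(year != 2010)),
    class = "osteohta_validation_error"
  )
})

test_that("budget impact deltas add up per year to the rounding unit", {
  sc <- scenario_costs_from_deltas(printed_budget_deltas())
  impact <- compute_budget_impact(sc$with, sc$without)
  totals <- budget_impact_total(impact)
  expect_equal(totals$total_keur[totals$year == 2011], -5190)
  # additivity: totals equal the category sums exactly
  by_hand <- impact |>
    dplyr::summarise(s = sum(delta_keur), .by = year)
  expect_equal(totals$total_keur, by_hand$s)

  zero <- sc$with
  expect_true(all(compute_budget_impact(zero, zero)$delta_eur == 0))

  expect_error(compute_budget_impact(sc$with |>
                                       dplyr::filter(category != "community"),
                                     sc$without),
               class = "osteohta_validation_error")
})

test_that("a denosumab identical to the mix it displaces has zero budget impact", {
  params <- default_params
  # make every product identical in price, efficacy and compliance
  params$treatments <- params$treatments |>
    dplyr::mutate(rrr_hip = 0.3, rrr_vertebral = 0.4, rrr_other = 0.2,
                  compliance = 0.7, annual_cost_eur = 200)
  bim <- run_budget_impact(params)
  expect_true(all(abs(bim$impact$delta_eur) < 1e-6))
  expect_true(all(abs(bim$avoided$avoided) < 1e-9))
})

test_that("raising the denosumab price never decreases the medications impact", {
  impacts <- vapply(c(300, 427, 600), function(price) {
    params <- default_params
    params$treatments$annual_cost_eur[params$treatments$product == "denosumab"] <- price
    bim <- run_budget_impact(params)
    sum(bim$impact$delta_eur[bim$impact$category == "medications"])
  }, numeric(1))
  expect_true(all(diff(impacts) >= 0))
})

test_that("avoided counts are nonnegative when denosumab dominates on efficacy", {
  bim <- run_budget_impact(default_params)
  # denosumab's compliance-weighted efficacy exceeds every displaced product's
  expect_true(all(bim$avoided$avoided >= 0))
  # community-care savings lag the avoided fractures by one year
  comm <- bim$impact |> dplyr::filter(category == "community")
  expect_equal(comm$delta_eur[comm$year == min(comm$year) + 1], 0)
})

test_that("sampled fracture counts agree with the expectation in large samples", {
  treated <- structure(tibble::tibble(year = 2010, treated = 1e6),
                       class = c("treated_population", class(tibble::tibble())))
  tp <- apply_market_shares(treated, default_params$shares, "with")
  hz <- test_hazards(annual_reference = c(hip = 0.01, vertebral = 0.02, other = 0.015))
  exp_f <- expected_fractures(tp, default_params$treatments, hz)
  samp <- sample_fractures(tp, default_params$treatments, hz, seed = 21)
  joined <- dplyr::inner_join(exp_f, samp, by = c("year", "type"),
                              suffix = c("_e", "_s"))
  expect_true(all(abs(joined$fractures_s - joined$fractures_e) /
                    joined$fractures_e < 0.05))
})
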