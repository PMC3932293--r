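#' Probabilistic sensitivity analysis distributions
#'
#' Constructors for the parameter distributions used by [run_psa()]. Beta
#' distributions (moment-matched to a mean and standard deviation) are used
#' for utilities, probabilities and compliance; Gamma for unit costs;
#' log-normal for relative risks and multiplicative factors; uniform for
#' offset time and treatment duration; `psa_fixed()` is a point mass that
#' degenerates the PSA to the deterministic analysis.
#'
#' @param mean,sd Target mean and standard deviation (`psa_beta`,
#'   `psa_gamma`). `sd = 0` gives a point mass.
#' @param median,sdlog Median and log-scale standard deviation
#'   (`psa_lognormal`).
#' @param min,max Bounds (`psa_uniform`).
#' @param value Fixed value (`psa_fixed`).
#' @return An object of class `osteo_psa_dist` with elements `sample`
#'   (function of `n`) and `base`.
#' @name psa_distributions
NULL

new_psa_dist <- function(sample, base, label) {
  structure(list(sample = sample, base = base, label = label),
            class = "osteo_psa_dist")
}

#' @rdname psa_distributions
#' @export
psa_beta <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) {
    abort("psa_beta requires mean in (0, 1)", class = "osteohta_validation_error")
  }
  if (sd == 0) return(psa_fixed(mean))
  if (sd^2 >= mean * (1 - mean)) {
    abort("psa_beta: sd too large for the given mean",
          class = "osteohta_validation_error")
  }
  k <- mean * (1 - mean) / sd^2 - 1
  new_psa_dist(function(n) rbeta(n, mean * k, (1 - mean) * k), mean, "beta")
}

#' @rdname psa_distributions
#' @export
psa_gamma <- function(mean, sd) {
  if (mean <= 0) abort("psa_gamma requires mean > 0", class = "osteohta_validation_error")
  if (sd == 0) return(psa_fixed(mean))
  shape <- mean^2 / sd^2
  new_psa_dist(function(n) rgamma(n, shape = shape, rate = shape / mean), mean, "gamma")
}

#' @rdname psa_distributions
#' @export
psa_lognormal <- function(median, sdlog) {
  if (median <= 0) abort("psa_lognormal requires median > 0",
                         class = "osteohta_validation_error")
  if (sdlog == 0) return(psa_fixed(median))
  new_psa_dist(function(n) rlnorm(n, log(median), sdlog), median, "lognormal")
}

#' @rdname psa_distributions
#' @export
psa_uniform <- function(min, max) {
  if (max < min) abort("psa_uniform requires max >= min",
                       class = "osteohta_validation_error")
  new_psa_dist(function(n) runif(n, min, max), (min + max) / 2, "uniform")
}

#' @rdname psa_distributions
#' @export
psa_fixed <- function(value) {
  new_psa_dist(function(n) rep(value, n), value, "fixed")
}

#' Default PSA specification
#'
#' Assigns a distribution to every varied quantity: acute unit costs
#' (Gamma, 20% coefficient of variation), state utilities (Beta, sd 0.05),
#' per-product compliance (Beta, sd 0.05), per-product relative risks
#' (log-normal on the risk-ratio scale, sdlog 0.15), a common multiplicative
#' fracture-risk factor (log-normal, sdlog 0.10), the first-year post-hip
#' mortality multiplier (log-normal around its base value, sdlog 0.15,
#' truncated to `>= 1` by rejection), offset time (uniform 0.5-1.5 years,
#' centred on the base case) and treatment duration (uniform 3-7 years).
#'
#' @param params An `osteo_parameters` object.
#' @param strategies Product ids whose compliance and efficacy are varied.
#' @param backgrounds List with `hazards` (for the mortality multiplier base).
#' @return Named list of `osteo_psa_dist` objects.
#' @export
default_psa_spec <- function(params, strategies, backgrounds) {
  cat <- params$catalogue
  spec <- list(
    unit_cost_hip = psa_gamma(cat$unit_cost[["hip"]], 0.2 * cat$unit_cost[["hip"]]),
    unit_cost_vertebral = psa_gamma(cat$unit_cost[["vertebral"]],
                                    0.2 * cat$unit_cost[["vertebral"]]),
    unit_cost_other = psa_gamma(cat$unit_cost[["other"]], 0.2 * cat$unit_cost[["other"]]),
    utility_hip_first = psa_beta(cat$utility_first_year[["hip"]], 0.05),
    utility_hip_subsequent = psa_beta(cat$utility_subsequent[["hip"]], 0.05),
    utility_vertebral_first = psa_beta(cat$utility_first_year[["vertebral"]], 0.05),
    utility_vertebral_subsequent = psa_beta(cat$utility_subsequent[["vertebral"]], 0.03),
    utility_other_first = psa_beta(cat$utility_first_year[["other"]], 0.03),
    fracture_risk_multiplier = psa_lognormal(1, 0.10),
    excess_mortality_hip = psa_lognormal(
      attr(backgrounds$hazards, "excess_mortality_hip") %||% 2, 0.15),
    offset_years = psa_uniform(0.5, 1.5),
    duration_years = psa_uniform(3, 7)
  )
  for (st in strategies) {
    prof <- treatment_profile(params, st)
    spec[[paste0("compliance_", st)]] <- psa_beta(min(max(prof$compliance, 1e-6), 1 - 1e-6), 0.05)
    for (tp in c("hip", "vertebral", "other")) {
      rr <- 1 - prof$rrr[[tp]]
      spec[[paste0("rr_", tp, "_", st)]] <-
        if (rr <= 0) psa_fixed(0) else psa_lognormal(rr, 0.15)
    }
  }
  spec
}

draw_psa_values <- function(spec) {
  map_dbl(spec, function(d) d$sample(1))
}

# Apply one draw to parameters and backgrounds; returns NULL when the draw
# is out of domain (utility/probability above 1, multiplier below 1, or
# hazards that no longer fit below 1 with death probabilities).
apply_psa_draw <- function(vals, params, backgrounds, strategies) {
  cat <- params$catalogue
  cat$unit_cost[c("hip", "vertebral", "other")] <-
    c(vals[["unit_cost_hip"]], vals[["unit_cost_vertebral"]], vals[["unit_cost_other"]])
  cat$utility_first_year[c("hip", "vertebral", "other")] <-
    c(vals[["utility_hip_first"]], vals[["utility_vertebral_first"]],
      vals[["utility_other_first"]])
  cat$utility_subsequent[c("hip", "vertebral")] <-
    c(vals[["utility_hip_subsequent"]], vals[["utility_vertebral_subsequent"]])
  if (any(c(cat$utility_first_year, cat$utility_subsequent) > 1)) return(NULL)
  if (vals[["excess_mortality_hip"]] < 1) return(NULL)

  hz0 <- backgrounds$hazards
  ref <- attr(hz0, "annual_reference") * vals[["fracture_risk_multiplier"]]
  if (any(ref >= 1)) return(NULL)
  hz <- tryCatch(
    baseline_hazards(ref, reference_age = attr(hz0, "reference_age"),
                     ages = hz0$age, age_slopes = attr(hz0, "age_slopes"),
                     excess_mortality_hip = vals[["excess_mortality_hip"]],
                     life_table = backgrounds$life_table),
    osteohta_calibration_error = function(e) NULL
  )
  if (is.null(hz)) return(NULL)

  treatments <- params$treatments
  for (st in strategies) {
    i <- which(treatments$product == st)
    cmp <- vals[[paste0("compliance_", st)]]
    if (cmp < 0 || cmp > 1) return(NULL)
    treatments$compliance[i] <- cmp
    for (tp in c("hip", "vertebral", "other")) {
      rr <- vals[[paste0("rr_", tp, "_", st)]]
      treatments[[paste0("rrr_", tp)]][i] <-
        suppressWarnings(as.numeric(rrr_from_rr(rr)))
    }
    treatments$offset_years[i] <- vals[["offset_years"]]
    treatments$duration_years[i] <- vals[["duration_years"]]
  }
  params$treatments <- treatments
  params$catalogue <- cat
  list(params = params, backgrounds = list(hazards = hz,
                                           life_table = backgrounds$life_table))
}

#' Probabilistic sensitivity analysis
#'
#' Jointly redraws the varied parameters (unit costs, utilities, fracture
#' risk, compliance, relative risks, offset time, treatment duration,
#' post-hip mortality) and reruns the full cohort model for every strategy
#' on each draw. Out-of-domain draws (a utility or probability above 1, a
#' mortality multiplier below 1, hazards that no longer fit) are rejected
#' and resampled; the count is reported in the `n_rejected` attribute.
#'
#' @param params An `osteo_parameters` object.
#' @param backgrounds List with `hazards` and `life_table`.
#' @param strategies Product ids to evaluate on every draw.
#' @param n_draws Number of accepted draws (`>= 1`).
#' @param seed Integer seed; fixed seeds give identical draws.
#' @param spec Named list of `osteo_psa_dist`, as from [default_psa_spec()].
#' @param max_attempts Safety cap on total sampling attempts.
#' @return A tibble of class `psa_draws`: columns `draw`, `strategy`,
#'   `total_cost`, `total_qalys`; attributes `seed`, `n_rejected`.
#' @export
run_psa <- function(params, backgrounds, strategies, n_draws, seed,
                    spec = default_psa_spec(params, strategies, backgrounds),
                    max_attempts = 50 * n_draws + 100) {
  if (n_draws < 1) abort("n_draws must be >= 1", class = "osteohta_validation_error")
  set.seed(seed)
  out <- vector("list", n_draws)
  accepted <- 0L; rejected <- 0L; attempts <- 0L
  while (accepted < n_draws) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort("PSA rejection rate too high: check the distribution specification",
            class = "osteohta_validation_error")
    }
    vals <- draw_psa_values(spec)
    drawn <- apply_psa_draw(vals, params, backgrounds, strategies)
    if (is.null(drawn)) { rejected <- rejected + 1L; next }
    accepted <- accepted + 1L
    res <- map(strategies, function(st) {
      run_strategy(drawn$params, st, drawn$backgrounds)
    })
    out[[accepted]] <- list_rbind(map(res, as_tibble)) |>
      mutate(draw = accepted, .before = 1)
  }
  structure(list_rbind(out), class = c("psa_draws", class(tibble())),
            seed = seed, n_rejected = rejected, strategies = strategies)
}

psa_increments <- function(draws, comparator, intervention) {
  wide <- as_tibble(draws) |>
    filter(.data$strategy %in% c(comparator, intervention))
  int <- wide |> filter(.data$strategy == intervention)
  cmp <- wide |> filter(.data$strategy == comparator)
  if (nrow(int) == 0 || nrow(cmp) == 0) {
    abort(paste0("strategy not present in draws: ",
                 if (nrow(int) == 0) intervention else comparator),
          class = "osteohta_validation_error")
  }
  tibble(draw = int$draw,
         delta_cost = int$total_cost - cmp$total_cost[match(int$draw, cmp$draw)],
         delta_qalys = int$total_qalys - cmp$total_qalys[match(int$draw, cmp$draw)])
}

#' Probability of cost-effectiveness at a willingness-to-pay threshold
#'
#' Fraction of PSA draws in which the intervention's net monetary benefit
#' against the comparator, `threshold * delta_QALYs - delta_cost`, is
#' strictly positive (an exactly zero benefit counts as not cost-effective).
#'
#' @param draws A [run_psa()] result.
#' @param threshold Willingness to pay (EUR per QALY).
#' @param comparator Comparator strategy label present in `draws`.
#' @param intervention Intervention strategy label (default denosumab).
#' @return A fraction in \[0, 1\].
#' @export
probability_cost_effective <- function(draws, threshold, comparator,
                                       intervention = "denosumab") {
  if (nrow(draws) == 0) abort("empty draws", class = "osteohta_validation_error")
  inc <- psa_increments(draws, comparator, intervention)
  mean(threshold * inc$delta_qalys - inc$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @inheritParams probability_cost_effective
#' @param thresholds Vector of willingness-to-pay thresholds (EUR/QALY).
#' @return A tibble of class `osteo_ceac` with columns `threshold` and
#'   `probability`.
#' @export
ceac <- function(draws, thresholds = seq(0, 100000, by = 1000), comparator,
                 intervention = "denosumab") {
  inc <- psa_increments(draws, comparator, intervention)
  probs <- vapply(thresholds, function(th) {
    mean(th * inc$delta_qalys - inc$delta_cost > 0)
  }, numeric(1))
  structure(tibble(threshold = thresholds, probability = probs),
            class = c("osteo_ceac", class(tibble())),
            comparator = comparator, intervention = intervention)
}

#' @export
glance.psa_draws <- function(x, ...) {
  as_tibble(x) |>
    summarise(mean_cost = mean(.data$total_cost),
              mean_qalys = mean(.data$total_qalys),
              sd_cost = sd(.data$total_cost),
              sd_qalys = sd(.data$total_qalys),
              n_draws = dplyr::n_distinct(.data$draw),
              .by = "strategy")
}

#' @export
tidy.psa_draws <- function(x, ...) as_tibble(x)

#' @export
autoplot.psa_draws <- function(object, comparator = NULL,
                               intervention = "denosumab", ...) {
  if (is.null(comparator)) {
    return(
      as_tibble(object) |>
        ggplot2::ggplot(ggplot2::aes(x = .data$total_qalys, y = .data$total_cost,
                                     colour = .data$strategy)) +
        ggplot2::geom_point(alpha = 0.4, size = 0.8) +
        ggplot2::labs(x = "QALYs (discounted)", y = "Cost (EUR, discounted)") +
        ggplot2::theme_minimal()
    )
  }
  inc <- psa_increments(object, comparator, intervention)
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$delta_qalys, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Delta ~ "QALYs"), y = expression(Delta ~ "cost (EUR)"),
                  title = paste(intervention, "vs", comparator)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.osteo_ceac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "Probability cost-effective",
                  title = paste(attr(object, "intervention"), "vs",
                                attr(object, "comparator"))) +
    ggplot2::theme_minimal()
}
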