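fmt_thousands <- function(x, digits = 0) {
  format(round(x, digits), big.mark = ",", scientific = FALSE, trim = TRUE,
         nsmall = digits)
}

#' Render a result as a publication-style delimited table
#'
#' Deterministic tab-separated text renderings mirroring the layouts of the
#' published tables: `"table2"` (admissions and hospitalization costs by
#' fracture type, with a total row), `"table3"` (per-year fracture counts by
#' scenario with avoided counts), `"table5"` (per-category budget impact in
#' thousand EUR with a total row), `"table6"` (cost-effectiveness comparison
#' rows) and `"ceac"` (threshold/probability pairs). Identical inputs
#' render to identical bytes.
#'
#' @param result The object to render: an `admission_table`, a list with
#'   `with`/`without` `scenario_fractures`, a `budget_impact`, a
#'   `cea_table`, or an `osteo_ceac`.
#' @param layout One of `"table2"`, `"table3"`, `"table5"`, `"table6"`,
#'   `"ceac"`.
#' @return A character vector of lines (invisibly writable with
#'   [writeLines()]).
#' @export
render_table <- function(result, layout = c("table2", "table3", "table5",
                                            "table6", "ceac")) {
  layout <- match.arg(layout)
  switch(layout,
         table2 = render_table2(result),
         table3 = render_table3(result),
         table5 = render_table5(result),
         table6 = render_table6(result),
         ceac = render_ceac(result))
}

check_layout <- function(result, class, layout) {
  if (!inherits(result, class)) {
    abort(paste0("layout '", layout, "' needs a ", class, " object"),
          class = "osteohta_validation_error")
  }
}

render_table2 <- function(result) {
  check_layout(result, "admission_table", "table2")
  header <- "Fractures type\tNumber of admissions\tTotal mean direct costs (EUR)"
  if (nrow(result) == 0) return(header)
  labels <- c(hip_femur = "Hip and femur", vertebral = "Vertebral", other = "Other")
  body <- paste(labels[result$fracture_type],
                fmt_thousands(result$admissions),
                fmt_thousands(result$total_cost_eur, 2), sep = "\t")
  total <- paste("Total",
                 fmt_thousands(attr(result, "total_admissions")),
                 fmt_thousands(attr(result, "total_cost_eur"), 2), sep = "\t")
  c(header, body, total)
}

render_table3 <- function(result) {
  if (!is.list(result) || is.null(result$with) || is.null(result$without)) {
    abort("layout 'table3' needs a list with 'with' and 'without' scenario fractures",
          class = "osteohta_validation_error")
  }
  years <- sort(unique(result$with$year))
  header <- paste(c("", years), collapse = "\t")
  avoided <- fractures_avoided(result$with, result$without)
  lines <- header
  for (tp in unique(result$with$type)) {
    wo <- result$without |> filter(.data$type == tp) |> arrange(.data$year)
    wi <- result$with |> filter(.data$type == tp) |> arrange(.data$year)
    av <- avoided |> filter(.data$type == tp) |> arrange(.data$year)
    lines <- c(
      lines,
      paste(c(paste0(tp, " fractures (alternatives)"),
              fmt_thousands(wo$fractures)), collapse = "\t"),
      paste(c(paste0(tp, " fractures (denosumab)"),
              fmt_thousands(wi$fractures)), collapse = "\t"),
      paste(c(paste0(tp, " fractures avoided with denosumab"),
              fmt_thousands(av$avoided)), collapse = "\t")
    )
  }
  lines
}

render_table5 <- function(result) {
  check_layout(result, "budget_impact", "table5")
  years <- sort(unique(result$year))
  header <- paste(c("", years), collapse = "\t")
  if (nrow(result) == 0) return(header)
  labels <- c(medications = "Medications", inpatient = "Inpatient care",
              outpatient = "Outpatient care", community = "Community care")
  wide <- result |>
    select("year", "category", "delta_keur") |>
    pivot_wider(names_from = "year", values_from = "delta_keur")
  body <- vapply(seq_len(nrow(wide)), function(i) {
    paste(c(labels[as.character(wide$category[i])],
            fmt_thousands(as.numeric(wide[i, -1]))), collapse = "\t")
  }, character(1))
  totals <- budget_impact_total(result) |> arrange(.data$year)
  total <- paste(c("Total", fmt_thousands(totals$total_keur)), collapse = "\t")
  c(header, body, total)
}

render_table6 <- function(result) {
  check_layout(result, "cea_table", "table6")
  header <- paste(c("Comparator", "Total costs (intervention)",
                    "Total costs (alternative)", "QALYs (intervention)",
                    "QALYs (alternative)", "Difference", "ICER (EUR/QALY)"),
                  collapse = "\t")
  if (nrow(result) == 0) return(header)
  icer_lab <- ifelse(result$status == "ratio",
                     fmt_thousands(result$icer), result$status)
  body <- paste(result$comparator,
                fmt_thousands(result$cost_intervention),
                fmt_thousands(result$cost_comparator),
                format(round(result$qalys_intervention, 2), nsmall = 2),
                format(round(result$qalys_comparator, 2), nsmall = 2),
                fmt_thousands(result$delta_cost),
                icer_lab, sep = "\t")
  c(header, body)
}

render_ceac <- function(result) {
  check_layout(result, "osteo_ceac", "ceac")
  header <- "threshold_eur_per_qaly\tprobability_cost_effective"
  if (nrow(result) == 0) return(header)
  c(header, paste(fmt_thousands(result$threshold),
                  format(round(result$probability, 4), nsmall = 4), sep = "\t"))
}

#' Run a configured analysis end to end
#'
#' Programmatic pipeline entry point: takes a configuration (a YAML file
#' path or an equivalent named list), runs the requested analyses on the
#' packaged or configured parameter set, and writes CSV artifacts to the
#' output directory. Steps: `"synth"` (write the background inputs),
#' `"burden"` (hospitalization table), `"bim"` (budget impact),
#' `"cea"` (deterministic comparison table), `"psa"` (PSA draws and CEAC).
#' All randomness flows from the single `seed` entry.
#'
#' @param config Path to a YAML configuration or a named list. Recognized
#'   fields: `steps` (character vector as above), `out_dir`, `seed`,
#'   `params_dir` (parameter directory for [load_parameters()]),
#'   `comparators`, `n_draws`, `thresholds` (`list(from, to, by)`),
#'   `population` (denominator for the discharge rate).
#' @return Named character vector of written file paths, invisibly.
#' @export
run_hta <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("config file not found: ", config), class = "osteohta_schema_error")
    }
    config <- yaml::read_yaml(config)
  }
  steps <- config$steps %||% c("synth", "burden", "bim", "cea")
  out_dir <- config$out_dir %||% "."
  seed <- config$seed %||% 1
  if (!is.numeric(seed) || seed < 0) {
    abort("seed must be a nonnegative integer", class = "osteohta_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- load_parameters(config$params_dir)
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    written[[name]] <<- p
    written <<- written
  }

  life_table <- make_life_table()
  if ("synth" %in% steps) {
    bg_dir <- file.path(out_dir, "backgrounds")
    bim0 <- run_budget_impact(params)
    write_backgrounds(list(life_table = life_table, hazards = bim0$hazards,
                           projection = make_population_projection()), bg_dir)
    written[["backgrounds"]] <- bg_dir
  }
  if ("burden" %in% steps) {
    recs <- synthesize_admissions(seed = seed)
    tab <- aggregate_admissions(recs)
    emit(as_tibble(tab), "burden_table.csv")
    emit(tibble(
      mean_cost_per_admission_eur = mean_cost_per_admission(tab),
      discharge_rate_per_100k = discharge_rate(
        attr(tab, "total_admissions"), config$population %||% 28722000)
    ), "burden_summary.csv")
  }
  if ("bim" %in% steps) {
    bim <- run_budget_impact(params)
    emit(as_tibble(bim$impact), "budget_impact.csv")
    emit(bim$totals, "budget_impact_totals.csv")
    emit(bim$avoided, "fractures_avoided.csv")
  }
  comparators <- config$comparators %||%
    c("risedronate", "alendronate_generic", "alendronate_branded",
      "ibandronate", "strontium_ranelate")
  if ("cea" %in% steps || "psa" %in% steps) {
    backgrounds <- cea_background(life_table = life_table)
  }
  if ("cea" %in% steps) {
    tab6 <- cea_table(params, backgrounds, comparators = comparators)
    emit(as_tibble(tab6), "cea_results.csv")
  }
  if ("psa" %in% steps) {
    strategies <- c("denosumab", comparators)
    draws <- run_psa(params, backgrounds, strategies,
                     n_draws = config$n_draws %||% 200, seed = seed)
    emit(as_tibble(draws), "psa_draws.csv")
    th <- config$thresholds %||% list(from = 0, to = 100000, by = 1000)
    for (cp in comparators) {
      cv <- ceac(draws, seq(th$from, th$to, by = th$by), comparator = cp)
      emit(as_tibble(cv), paste0("ceac_", cp, ".csv"))
    }
  }
  invisible(written)
}
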