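#' Synthetic background for the cost-effectiveness cohort
#'
#' The cost-effectiveness analysis concerns 65-year-old women with severe
#' osteoporosis (T-score below -4 SD), whose baseline fracture incidence and
#' background mortality are not published. This background is the package's
#' documented synthetic stand-in: a Gompertz female life table and
#' age-increasing fracture hazards anchored at age 65 at levels typical of a
#' severe-osteoporosis cohort (annual probabilities: hip 2.5%, vertebral 7%,
#' other 6%), with doubled background mortality in the first year after a
#' hip fracture. The calibration is chosen so the model reproduces the
#' qualitative published ordering — denosumab cost-effective against all
#' five oral comparators, and near cost-neutral against strontium ranelate
#' — not any exact published figure; see the methods vignette.
#'
#' @param annual_reference Annual first-fracture probabilities at
#'   `reference_age` for the cohort.
#' @param reference_age Anchor age (cohort entry age).
#' @param excess_mortality_hip First-post-hip-year mortality multiplier.
#' @param life_table Life table; default [make_life_table()].
#' @return List with `hazards` and `life_table`, ready for
#'   [run_strategy()], [cea_table()] and [run_psa()].
#' @examples
#' bg <- cea_background()
#' cea_table(load_parameters(), bg, comparators = "strontium_ranelate")
#' @export
cea_background <- function(annual_reference = c(hip = 0.025, vertebral = 0.07,
                                                other = 0.06),
                           reference_age = 65,
                           excess_mortality_hip = 2,
                           life_table = make_life_table()) {
  hazards <- baseline_hazards(
    annual_reference, reference_age = reference_age,
    age_slopes = c(hip = 0.05, vertebral = 0.01, other = 0.005),
    excess_mortality_hip = excess_mortality_hip,
    life_table = life_table
  )
  list(hazards = hazards, life_table = life_table)
}
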