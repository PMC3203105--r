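# Intervention cost build-up, attrition-adjusted drug use, disease cost
# offsets and unrelated health-care costs in added years of life.

#' Year-equivalent of drug use per starting participant
#'
#' Completers contribute a full treatment-year; the half of attrition
#' occurring in the first month contributes no drug use on this metric;
#' the late half (month 6 on average) contributes half a year.
#' (For costing, early dropouts do incur one month of drug cost; see
#' [intervention_cost_per_starter()].)
#'
#' @param spec An [attrition_spec()].
#' @param digits Rounding for reporting (2 dp as published); use
#'   `digits = Inf` for full precision.
#' @return Expected treatment-years per starter.
#' @export
#' @examples
#' year_equivalent(attrition_spec("sibutramine"))  # 0.64
#' year_equivalent(attrition_spec("orlistat"))     # 0.75
year_equivalent <- function(spec, digits = 2) {
  a <- spec$attrition
  if (a < 0 || a > 1) abort("attrition must lie in [0, 1]")
  early <- spec$early_share * a
  late <- (1 - spec$early_share) * a
  ye <- (1 - a) * 1 + early * 0 + late * 0.5
  if (is.finite(digits)) round(ye, digits) else ye
}

#' Recruitment fraction via opportunistic GP screening
#'
#' The product of the proportion of the target group seen by a GP in a
#' year and the proportion willing to try a weight-reducing drug.
#'
#' @param gp_contact Proportion seen by a GP in one year (default 0.835).
#' @param willingness Proportion willing to participate (default 0.5).
#' @param report If `"percent"`, return the nearest whole percent as
#'   published; `"proportion"` returns full precision.
#' @return Recruitment as a proportion or whole percent.
#' @export
#' @examples
#' recruitment_fraction()                       # 0.4175
#' recruitment_fraction(report = "percent")     # 42
recruitment_fraction <- function(gp_contact = 0.835, willingness = 0.5,
                                 report = c("proportion", "percent")) {
  report <- match.arg(report)
  if (any(c(gp_contact, willingness) < 0 | c(gp_contact, willingness) > 1)) {
    abort("gp_contact and willingness must lie in [0, 1]")
  }
  p <- gp_contact * willingness
  if (report == "percent") round(100 * p) else p
}

#' Intervention cost per starting participant
#'
#' Drug cost for up to one year (completers a full year, early dropouts
#' one month, late dropouts six months), GP time for the initial
#' prescribing appointment at the hourly rate, and medication-related
#' follow-up visits at the standard consultation fee.  Patient time and
#' travel (waiting, travel and consultation minutes valued at the patient
#' hourly rate, plus per-trip travel cost, for the initial and each
#' follow-up visit) are added when `include_patient_costs` is `TRUE` and
#' returned separately in the breakdown.
#'
#' @param costs Cost parameter list as [default_cost_params()], augmented
#'   with `drug_year_cost` and `followup_visits` (or pass `drug` to fill
#'   them from [drug_params()]).  Triangular components may be length-3
#'   `c(min, mode, max)` (the mode is used) or scalars (e.g. PSA draws).
#' @param spec An [attrition_spec()].
#' @param include_patient_costs Include patient time and travel?
#' @param drug Optional drug name supplying `drug_year_cost`,
#'   `followup_visits` and attrition defaults.
#' @return A list: `total`, `health_sector`, `drug`, `gp_initial`,
#'   `gp_followup`, `patient`.
#' @export
#' @examples
#' intervention_cost_per_starter(drug = "sibutramine")$drug  # 968.22
intervention_cost_per_starter <- function(costs = default_cost_params(),
                                          spec = NULL,
                                          include_patient_costs = TRUE,
                                          drug = NULL) {
  if (!is.null(drug)) {
    dp <- drug_params(drug)
    costs$drug_year_cost <- costs$drug_year_cost %||% dp$drug_year_cost
    costs$followup_visits <- costs$followup_visits %||% dp$followup_visits
    if (is.null(spec)) spec <- attrition_spec(dp$attrition)
  }
  if (is.null(spec)) abort("an attrition spec is required")
  if (is.null(costs$drug_year_cost) || is.null(costs$followup_visits)) {
    abort("`costs` must include drug_year_cost and followup_visits")
  }
  a <- spec$attrition
  early <- spec$early_share * a
  late <- (1 - spec$early_share) * a
  exposure <- (1 - a) + early * (spec$early_month / 12) +
    late * (spec$late_month / 12)
  drug_cost <- costs$drug_year_cost * exposure
  min_init <- tri_mode(costs$minutes_initial)
  min_fu <- tri_mode(costs$minutes_followup)
  min_travel <- tri_mode(costs$travel_minutes)
  gp_initial <- min_init / 60 * costs$gp_hour
  gp_followup <- costs$followup_visits * costs$gp_consult
  components <- c(drug_cost, gp_initial, gp_followup)
  if (any(components < 0)) abort("cost components must be >= 0")
  trip_fixed <- costs$travel_per_trip +
    (costs$wait_minutes + min_travel) / 60 * costs$patient_hour
  patient <- (1 + costs$followup_visits) * trip_fixed +
    (min_init + costs$followup_visits * min_fu) / 60 * costs$patient_hour
  health <- drug_cost + gp_initial + gp_followup
  list(
    total = health + if (include_patient_costs) patient else 0,
    health_sector = health,
    drug = drug_cost,
    gp_initial = gp_initial,
    gp_followup = gp_followup,
    patient = patient
  )
}

# cost-table band lookup: bands start at 20 (i.e. <55), 55, 65, 75, 85
cost_band_lo <- function(age) {
  c(20, 55, 65, 75, 85)[findInterval(age, c(20, 55, 65, 75, 85))]
}

#' Discounted disease-treatment cost offsets
#'
#' Future health-care expenditure averted by prevention: cancers are
#' credited per incident case averted, the chronic diseases per prevalent
#' case-year averted.  Savings carry a negative sign.
#'
#' @param deltas Tibble with columns `disease`, `sex`, `age`, `t` (years
#'   since intervention start), `incident_cases_averted`,
#'   `prevalent_case_years_averted` (reference minus intervention; may be
#'   negative when survivors accrue disease later).
#' @param cost_table Disease cost tibble as [default_disease_costs()].
#' @param discount_rate Annual discount rate.
#' @return Total discounted offset in AUD (<= 0 when cases are averted).
#' @export
cost_offsets <- function(deltas, cost_table, discount_rate = 0.03) {
  if (!nrow(deltas)) return(0)
  ct <- cost_table %>% filter(.data$disease != "all_other")
  joined <- deltas %>%
    mutate(age_lo = cost_band_lo(.data$age)) %>%
    left_join(ct, by = c("disease", "sex", "age_lo"))
  if (anyNA(joined$cost)) {
    abort("cost table is missing entries for some disease/sex/age combinations")
  }
  averted <- with(joined, ifelse(
    basis == "per_incident_case", incident_cases_averted,
    ifelse(basis == "per_prevalent_case_year", prevalent_case_years_averted,
           NA_real_)))
  if (anyNA(averted)) abort("unexpected cost basis in cost table")
  -sum(averted * joined$cost * (1 + discount_rate)^(-joined$t))
}

#' Unrelated health-care costs in added years of life
#'
#' Annual all-other health-care cost per person applied to the extra
#' (discounted) person-years lived in the intervention arm.  Reported
#' separately; included in the ICER only under the widest costing
#' perspective.
#'
#' @param py_deltas Tibble with columns `sex`, `age`, `t`,
#'   `person_years_added` (intervention minus reference).
#' @param cost_table Disease cost tibble including `all_other` rows.
#' @param discount_rate Annual discount rate.
#' @return Total discounted unrelated cost in AUD (>= 0 when life is
#'   extended).
#' @export
unrelated_costs_in_added_years <- function(py_deltas, cost_table,
                                           discount_rate = 0.03) {
  if (!nrow(py_deltas)) return(0)
  ct <- cost_table %>% filter(.data$disease == "all_other")
  joined <- py_deltas %>%
    mutate(age_lo = cost_band_lo(.data$age)) %>%
    left_join(ct, by = c("sex", "age_lo"))
  if (anyNA(joined$cost)) abort("cost table is missing all_other entries")
  sum(joined$person_years_added * joined$cost *
        (1 + discount_rate)^(-joined$t))
}
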