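# Published model inputs: drug effectiveness and cost parameters, relative
# risks per BMI unit, disability weights, and per-case disease costs
# (2003 Australian dollars).

#' The nine obesity-related diseases in the model
#'
#' Canonical disease identifiers used throughout the package: ischemic heart
#' disease, stroke, hypertensive heart disease, type II diabetes,
#' osteoarthritis, colon cancer, post-menopausal breast cancer, endometrial
#' cancer and kidney cancer.  Breast and endometrial cancer are restricted
#' to women.
#'
#' @return Character vector of nine disease identifiers.
#' @export
#' @examples
#' pmslt_diseases()
pmslt_diseases <- function() {
  c("ihd", "stroke", "hhd", "diabetes", "osteoarthritis",
    "colon_cancer", "breast_cancer", "endometrial_cancer", "kidney_cancer")
}

#' Diseases that occur in one sex only
#' @return Named character vector: disease id -> sex in which it occurs.
#' @export
sex_specific_diseases <- function() {
  c(breast_cancer = "female", endometrial_cancer = "female")
}

#' Relative risks of disease per 1-unit increase in BMI
#'
#' Log-linear relative risks per +1 kg/m^2 of BMI by disease and age band,
#' with 95% confidence intervals, as used in comparative-risk-assessment
#' modelling of high body mass.  Risk below `min_rr_age` (default 35) is
#' treated as unrelated to BMI (RR = 1); entries printed for younger ages
#' for endometrial cancer, kidney cancer and osteoarthritis are clamped
#' accordingly, consistent with the model producing zero benefit in the
#' 20-29 age group.
#'
#' @param min_rr_age Age (years) below which all RRs are set to 1.
#' @return A tibble with columns `disease`, `sex` (`"all"`), `age_lo`,
#'   `age_hi` (half-open band `[age_lo, age_hi)`), `rr`, `lo95`, `hi95`.
#' @export
#' @examples
#' default_rr_table() |> dplyr::filter(disease == "diabetes")
default_rr_table <- function(min_rr_age = 35) {
  tb <- tribble(
    ~disease,             ~age_lo, ~age_hi, ~rr,  ~lo95, ~hi95,
    "colon_cancer",            20,      35, 1.00, 1.00,  1.00,
    "colon_cancer",            35,     100, 1.03, 1.01,  1.05,
    "breast_cancer",           20,      35, 1.00, 1.00,  1.00,
    "breast_cancer",           35,     100, 1.03, 1.02,  1.04,
    "endometrial_cancer",      20,      35, 1.10, 1.07,  1.14,
    "endometrial_cancer",      35,     100, 1.10, 1.07,  1.14,
    "kidney_cancer",           20,      35, 1.06, 1.03,  1.08,
    "kidney_cancer",           35,     100, 1.06, 1.03,  1.08,
    "osteoarthritis",          20,      35, 1.04, 1.03,  1.06,
    "osteoarthritis",          35,     100, 1.04, 1.03,  1.06,
    "ihd",                     20,      35, 1.00, 1.00,  1.00,
    "ihd",                     35,      45, 1.12, 1.05,  1.19,
    "ihd",                     45,      60, 1.10, 1.08,  1.14,
    "ihd",                     60,      70, 1.06, 1.03,  1.08,
    "ihd",                     70,      80, 1.04, 1.02,  1.06,
    "ihd",                     80,     100, 1.02, 1.00,  1.05,
    "hhd",                     20,      45, 1.00, 1.00,  1.00,
    "hhd",                     45,      60, 1.09, 1.03,  1.14,
    "hhd",                     60,      70, 1.16, 1.05,  1.27,
    "hhd",                     70,      80, 1.12, 1.04,  1.21,
    "hhd",                     80,     100, 1.06, 1.02,  1.11,
    "stroke",                  20,      35, 1.00, 1.00,  1.00,
    "stroke",                  35,      45, 1.14, 1.05,  1.23,
    "stroke",                  45,      60, 1.10, 1.03,  1.16,
    "stroke",                  60,      70, 1.08, 1.03,  1.13,
    "stroke",                  70,      80, 1.05, 1.02,  1.09,
    "stroke",                  80,     100, 1.03, 1.01,  1.05,
    "diabetes",                20,      35, 1.00, 1.00,  1.00,
    "diabetes",                35,      45, 1.19, 1.06,  1.32,
    "diabetes",                45,      70, 1.14, 1.05,  1.23,
    "diabetes",                70,     100, 1.10, 1.03,  1.16
  )
  tb <- tb %>%
    mutate(
      rr   = ifelse(.data$age_hi <= min_rr_age, 1, .data$rr),
      lo95 = ifelse(.data$age_hi <= min_rr_age, 1, .data$lo95),
      hi95 = ifelse(.data$age_hi <= min_rr_age, 1, .data$hi95),
      sex  = "all"
    ) %>%
    select("disease", "sex", "age_lo", "age_hi", "rr", "lo95", "hi95")
  tb
}

#' Disability weights for prevalent disease, by sex
#'
#' Population-average disability weights (0 = full health, 1 = death
#' equivalent) attached to time lived with each prevalent disease.
#'
#' @return A tibble with columns `disease`, `sex`, `weight`.  Female-only
#'   cancers have rows for females only.
#' @export
default_disability_weights <- function() {
  tribble(
    ~disease,             ~sex,     ~weight,
    "colon_cancer",       "male",   0.12,
    "colon_cancer",       "female", 0.11,
    "breast_cancer",      "female", 0.12,
    "endometrial_cancer", "female", 0.03,
    "kidney_cancer",      "male",   0.06,
    "kidney_cancer",      "female", 0.06,
    "ihd",                "male",   0.04,
    "ihd",                "female", 0.06,
    "stroke",             "male",   0.31,
    "stroke",             "female", 0.31,
    "hhd",                "male",   0.09,
    "hhd",                "female", 0.07,
    "diabetes",           "male",   0.08,
    "diabetes",           "female", 0.08,
    "osteoarthritis",     "male",   0.05,
    "osteoarthritis",     "female", 0.06
  )
}

#' Average health-care costs per prevalent or incident case of disease
#'
#' 2003 Australian-dollar treatment costs by disease, sex and age band.
#' Cancers are costed once per incident case; the chronic diseases are
#' costed annually per prevalent case; the `all_other` rows are annual
#' health-care costs per person (used for unrelated costs in added years
#' of life).
#'
#' @return A tibble with columns `disease`, `sex`, `age_lo` (band lower
#'   bound: 20, 55, 65, 75, 85), `cost` (AUD) and `basis` (one of
#'   `per_incident_case`, `per_prevalent_case_year`, `per_person_year`).
#' @export
default_disease_costs <- function() {
  male <- tribble(
    ~age_lo, ~colon_cancer, ~kidney_cancer, ~ihd, ~stroke,  ~hhd, ~diabetes, ~osteoarthritis, ~all_other,
    20,      17490,         16298,          2962, 2228,    13103, 504,       4431,            1555,
    55,      17657,         16751,          1988, 4942,    24408, 660,       4431,            2828,
    65,      18164,         14748,          1664, 9529,    15048, 763,       4431,            4731,
    75,      18037,         14526,          1512, 12856,    8167, 639,       4431,            7945,
    85,      19288,          7372,          1394, 16301,    1723, 594,       4431,           13061
  )
  female <- tribble(
    ~age_lo, ~colon_cancer, ~breast_cancer, ~endometrial_cancer, ~kidney_cancer, ~ihd, ~stroke,  ~hhd, ~diabetes, ~osteoarthritis, ~all_other,
    20,      17136,         12424,          10665,               15505,          1832, 1161,    22097, 506,       4431,            2009,
    55,      16349,         10493,           9902,               16363,          1520, 2090,    32044, 759,       4431,            3225,
    65,      17238,         11609,          14419,               17133,          1595, 5106,    20357, 839,       4431,            4829,
    75,      17360,         12706,          10497,               17198,          1564, 13137,    9624, 745,       4431,            8197,
    85,      16545,         12520,          13402,               12192,          1670, 19679,    1695, 429,       4431,           15078
  )
  long <- bind_rows(
    male %>% mutate(sex = "male"),
    female %>% mutate(sex = "female")
  ) %>%
    pivot_longer(-c("age_lo", "sex"), names_to = "disease",
                 values_to = "cost") %>%
    filter(!is.na(.data$cost))  # female-only cancers have no male rows
  cancers <- c("colon_cancer", "breast_cancer", "endometrial_cancer",
               "kidney_cancer")
  long %>%
    mutate(basis = dplyr::case_when(
      .data$disease %in% cancers   ~ "per_incident_case",
      .data$disease == "all_other" ~ "per_person_year",
      TRUE                         ~ "per_prevalent_case_year"
    )) %>%
    select("disease", "sex", "age_lo", "cost", "basis") %>%
    arrange(.data$disease, .data$sex, .data$age_lo)
}

#' Drug-specific effectiveness and cost inputs
#'
#' Mean 12-month weight loss (kg, with the SE used as the PSA standard
#' deviation), attrition, medication-related GP follow-up visits per
#' starter, and the subsidised annual medication price (no uncertainty
#' distribution: the price is centrally determined).
#'
#' @param drug `"sibutramine"` or `"orlistat"`.
#' @return Named list with elements `drug`, `loss_kg`, `loss_se`,
#'   `attrition`, `followup_visits`, `drug_year_cost`.
#' @export
#' @examples
#' drug_params("sibutramine")$loss_kg  # 4.45
drug_params <- function(drug = c("sibutramine", "orlistat")) {
  drug <- match.arg(drug)
  switch(drug,
    sibutramine = list(drug = "sibutramine", loss_kg = 4.45, loss_se = 0.426,
                       attrition = 0.48, followup_visits = 1.3,
                       drug_year_cost = 1467),
    orlistat    = list(drug = "orlistat", loss_kg = 2.89, loss_se = 0.316,
                       attrition = 0.33, followup_visits = 1.6,
                       drug_year_cost = 1486)
  )
}

#' Unit costs and time inputs for the intervention cost build-up
#'
#' GP consultation and hourly rates, appointment/waiting/travel minutes
#' (triangular most-likely/min/max where a distribution is used in the
#' PSA), patient time valued at 25% of the wage rate, and travel cost per
#' trip.  All in 2003 AUD.
#'
#' @return Named list of cost components.  Triangular components are
#'   length-3 numeric vectors `c(min, mode, max)`.
#' @export
default_cost_params <- function() {
  list(
    gp_consult       = 30.20,
    gp_hour          = 109.36,
    minutes_initial  = c(9, 10, 11),
    minutes_followup = c(20, 25, 30),
    wait_minutes     = 30,
    travel_minutes   = c(24, 30, 36),
    patient_hour     = 17.44,
    travel_per_trip  = 7.45
  )
}

#' Attrition specification for a one-year drug course
#'
#' The proportion of starters who discontinue, with half of all attrition
#' occurring in the first month and the remainder at six months on
#' average.
#'
#' @param attrition Proportion of starters discontinuing within the year,
#'   or a drug name (`"sibutramine"` = 0.48, `"orlistat"` = 0.33).
#' @param early_share Share of attrition occurring in the first month.
#' @return Named list `attrition`, `early_share`, `early_month`,
#'   `late_month`.
#' @export
attrition_spec <- function(attrition = 0.48, early_share = 0.5) {
  if (is.character(attrition)) {
    attrition <- drug_params(attrition)$attrition
  }
  if (!is.numeric(attrition) || attrition < 0 || attrition > 1) {
    abort("`attrition` must be a proportion in [0, 1].")
  }
  list(attrition = attrition, early_share = early_share,
       early_month = 1, late_month = 6)
}

# internal: triangular cost components drawn in the PSA keep c(min,mode,max);
# deterministic evaluation uses the mode.
tri_mode <- function(x) if (length(x) == 3L) x[2L] else x
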