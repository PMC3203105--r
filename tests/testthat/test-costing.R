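test_that("attrition converts to year-equivalents of drug use", {
  expect_equal(year_equivalent(attrition_spec("sibutramine")), 0.64)
  expect_equal(year_equivalent(attrition_spec("orlistat")), 0.75)
  expect_equal(year_equivalent(attrition_spec(0.33), digits = Inf), 0.7525)
  expect_equal(year_equivalent(attrition_spec(0)), 1.0)
  expect_error(attrition_spec(1.2), "\\[0, 1\\]")
})

test_that("opportunistic GP recruitment multiplies through", {
  expect_equal(recruitment_fraction(), 0.835 * 0.5)
  expect_equal(recruitment_fraction(report = "percent"), 42)
  expect_equal(recruitment_fraction(willingness = 0), 0)
  expect_equal(recruitment_fraction(1, 1), 1)
  expect_error(recruitment_fraction(1.5, 0.5), "\\[0, 1\\]")
})

test_that("intervention cost per starter builds up from its components", {
  res <- intervention_cost_per_starter(drug = "sibutramine")
  # early dropouts incur one month of drug cost, late ones six months
  expect_equal(res$drug, 1467 * (0.52 + 0.24 / 12 + 0.24 * 0.5))  # 968.22
  expect_equal(res$drug, 968.22)
  expect_equal(res$gp_initial, 10 / 60 * 109.36)
  expect_equal(res$gp_followup, 1.3 * 30.20)
  expect_equal(res$health_sector, res$drug + res$gp_initial + res$gp_followup)
  # degenerate case: full adherence, no follow-up visits
  cp <- default_cost_params()
  cp$drug_year_cost <- 1467
  cp$followup_visits <- 0
  res0 <- intervention_cost_per_starter(cp, attrition_spec(0),
                                        include_patient_costs = FALSE)
  expect_equal(res0$total, 1467 + 10 / 60 * 109.36)
})

test_that("patient time and travel enter as an exact component", {
  res_on <- intervention_cost_per_starter(drug = "orlistat",
                                          include_patient_costs = TRUE)
  res_off <- intervention_cost_per_starter(drug = "orlistat",
                                           include_patient_costs = FALSE)
  trips <- 1 + 1.6
  expected <- trips * (7.45 + (30 + 30) / 60 * 17.44) +
    (10 + 1.6 * 25) / 60 * 17.44
  expect_equal(res_on$total - res_off$total, expected)
  expect_equal(res_on$patient, expected)
})

test_that("disease cost offsets follow the per-case bases", {
  ct <- default_disease_costs()
  expect_equal(cost_offsets(tibble::tibble(
    disease = character(), sex = character(), age = integer(),
    t = integer(), incident_cases_averted = numeric(),
    prevalent_case_years_averted = numeric()), ct), 0)
  # one prevalent diabetes case-year averted, male < 55, undiscounted
  d1 <- tibble::tibble(disease = "diabetes", sex = "male", age = 50, t = 0,
                       incident_cases_averted = 99,  # ignored for chronic
                       prevalent_case_years_averted = 1)
  expect_equal(cost_offsets(d1, ct, 0), -504)
  # one incident male colon cancer averted, < 55
  d2 <- tibble::tibble(disease = "colon_cancer", sex = "male", age = 45,
                       t = 0, incident_cases_averted = 1,
                       prevalent_case_years_averted = 99)
  expect_equal(cost_offsets(d2, ct, 0), -17490)
  # discounting applies per event year
  d3 <- d2
  d3$t <- 10
  expect_equal(cost_offsets(d3, ct, 0.03), -17490 * 1.03^-10)
})

test_that("unrelated costs price out added person-years", {
  ct <- default_disease_costs()
  empty <- tibble::tibble(sex = character(), age = integer(), t = integer(),
                          person_years_added = numeric())
  expect_equal(unrelated_costs_in_added_years(empty, ct), 0)
  py <- tibble::tibble(sex = "male", age = 90, t = 0, person_years_added = 1)
  expect_equal(unrelated_costs_in_added_years(py, ct, 0), 13061)
})

test_that("pipeline cost streams agree with the tidy costing functions", {
  run <- run_pipeline(tw, scenario_config("sibutramine"), detail = TRUE)
  expect_equal(
    cost_offsets(run$streams$disease_deltas, default_disease_costs(), 0.03),
    run$costs$cost_offsets)
  expect_equal(
    unrelated_costs_in_added_years(run$streams$py_deltas,
                                   default_disease_costs(), 0.03),
    run$costs$cost_unrelated)
  # offsets are savings whenever weight falls and all RRs >= 1
  expect_lt(run$costs$cost_offsets, 0)
})
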