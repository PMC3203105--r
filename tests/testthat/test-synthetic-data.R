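test_that("population generator emits 16 bands x 2 sexes with monotone Gompertz mortality", {
  pop <- generate_population(1)
  expect_equal(nrow(pop), 32)
  expect_setequal(unique(pop$sex), c("male", "female"))
  expect_equal(sort(unique(pop$age_lo)), seq(20, 95, 5))
  for (sx in c("male", "female")) {
    m <- pop$mortality_rate[pop$sex == sx][order(pop$age_lo[pop$sex == sx])]
    expect_true(all(diff(m) > 0))
    expect_true(all(m > 0 & m < 1))
  }
  # zero Gompertz slope gives constant mortality across ages
  flat <- generator_config(gompertz = list(male = c(alpha = 0.01, beta = 0),
                                           female = c(alpha = 0.005, beta = 0)))
  pf <- generate_population(1, flat)
  expect_equal(unique(pf$mortality_rate[pf$sex == "male"]), 0.01)
  expect_error(generator_config(count_20_24 = -5), "positive")
})

test_that("disease epidemiology covers the nine diseases with sex restrictions", {
  epi <- generate_disease_epi(1)
  expect_setequal(unique(epi$disease), pmslt_diseases())
  for (d in names(sex_specific_diseases())) {
    expect_equal(epi$incidence[epi$disease == d & epi$sex == "male"],
                 rep(0, 16))
  }
  expect_true(all(epi$incidence >= 0 & epi$case_fatality >= 0))
  expect_equal(unique(epi$remission), 0)
  expect_error(generate_disease_epi(1, diseases = c("ihd", "gout")),
               "unknown disease")
})

test_that("generators are bit-identical under a fixed seed", {
  expect_identical(generate_population(7), generate_population(7))
  expect_identical(generate_disease_epi(7), generate_disease_epi(7))
  expect_identical(generate_bmi_params(7), generate_bmi_params(7))
  # different seeds perturb the jittered incidence
  expect_false(identical(generate_disease_epi(1), generate_disease_epi(2)))
})

test_that("BMI parameters hit the target obesity prevalence", {
  b <- generate_bmi_params(1)
  for (sx in c("male", "female")) {
    row <- b[b$sex == sx, ][1, ]
    implied <- pnorm(30, row$mean_bmi, row$sd_bmi, lower.tail = FALSE)
    target <- c(male = 0.21, female = 0.23)[[sx]]
    expect_lt(abs(implied - target), 0.001)
  }
  # a 50% target puts the mean exactly at the threshold
  half <- generate_bmi_params(1, generator_config(
    obesity_target = c(male = 0.5, female = 0.5)))
  expect_equal(unique(half$mean_bmi), 30)
  expect_error(
    generate_bmi_params(1, generator_config(
      obesity_target = c(male = 1.2, female = 0.23))),
    "strictly in"
  )
})

test_that("zero remission gives non-decreasing prevalence under constant incidence", {
  # chronic-disease convention: with r = 0 and constant rates the disease
  # model's prevalence path is monotone non-decreasing
  path <- simulate_disease_path(0, rep(0.01, 100), rep(0.02, 100), 0)
  expect_true(all(diff(path$prevalence) >= 0))
  expect_true(all(path$prevalence >= 0 & path$prevalence <= 1))
})

test_that("synthetic steady-state prevalence stays within [0, 1] for all diseases", {
  epi <- tw$disease_epi
  for (d in pmslt_diseases()) {
    for (sx in c("male", "female")) {
      ed <- epi[epi$disease == d & epi$sex == sx, ]
      ed <- ed[order(ed$age_lo), ]
      band <- pmin(findInterval(20:99, ed$age_lo), nrow(ed))
      path <- simulate_disease_path(0, ed$incidence[band],
                                    ed$case_fatality[band],
                                    ed$remission[band])
      expect_true(all(path$prevalence >= 0 & path$prevalence <= 1))
    }
  }
})
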