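test_that("disease step does the single-cycle bookkeeping", {
  # absorbing-free null: nothing moves
  s0 <- step_disease(list(prevalence = 0.2), 0, 0, 0)
  expect_equal(s0$prevalence, 0.2)
  expect_equal(s0$disease_mortality, 0)
  # all-well cohort, incidence 0.1, one step
  s1 <- step_disease(list(prevalence = 0), 0.1, 0, 0)
  expect_equal(s1$prevalence, 0.1)
  # case fatality removes prevalent cases and reports disease deaths
  s2 <- step_disease(list(prevalence = 0.5), 0, 0.2, 0)
  expect_equal(s2$prevalence, 0.4)
  expect_equal(s2$disease_mortality, 0.1)
  expect_error(step_disease(list(prevalence = 0.1), -0.01, 0, 0), ">= 0")
  expect_error(step_disease(list(prevalence = 0.1), 0.1, 0, 0, dt = 0.5),
               "annual")
})

test_that("constant rates converge to the i/(i+f) steady state", {
  p <- 0
  for (k in 1:500) {
    p <- step_disease(list(prevalence = p), 0.01, 0.02, 0)$prevalence
  }
  expect_equal(p, 0.01 / 0.03, tolerance = 1e-6 / (0.01 / 0.03))
  expect_lt(abs(p - 1 / 3), 1e-6)
})

test_that("PIF scales incidence multiplicatively", {
  expect_equal(apply_pif_to_incidence(0.02, 0), 0.02)
  expect_equal(apply_pif_to_incidence(0.02, 1), 0)
  expect_equal(apply_pif_to_incidence(0.02, 0.0909), 0.02 * (1 - 0.0909))
  expect_equal(apply_pif_to_incidence(0.02, 0.0909091), 0.0181818,
               tolerance = 1e-6)
  expect_error(apply_pif_to_incidence(0.02, 1.5), "<= 1")
})

test_that("obese baseline prevalence derivation respects the risk gradient", {
  bmi <- tw$bmi
  rr1 <- tibble::tibble(disease = "osteoarthritis", sex = "all",
                        age_lo = 20, age_hi = 100, rr = 1,
                        lo95 = 1, hi95 = 1)
  epi <- tw$disease_epi[tw$disease_epi$disease == "osteoarthritis", ]
  out1 <- derive_obese_baseline(epi, bmi, rr1)
  expect_equal(out1$prevalence_obese, out1$prevalence_population)
  rr2 <- rr1
  rr2$rr <- 1.04
  out2 <- derive_obese_baseline(epi, bmi, rr2)
  ages_on <- out2$age >= 25  # incidence starts at the onset age
  expect_true(all(out2$incidence_ratio > 1))
  expect_true(all(out2$prevalence_obese[ages_on] >=
                    out2$prevalence_population[ages_on]))
})

test_that("obese baseline pipeline equals hand-iterated difference equations", {
  # tiny two-band fixture: i = 0.01 / 0.02, f = 0.02, RR = 1.10, male only
  epi <- tibble::tibble(
    disease = "diabetes", sex = "male", age_lo = c(20, 60),
    incidence = c(0.01, 0.02), case_fatality = 0.02, remission = 0)
  bmi <- tibble::tibble(sex = "male", age_lo = 20, mean_bmi = 26,
                        sd_bmi = 4, mean_height = 1.78)
  rr <- tibble::tibble(disease = "diabetes", sex = "all", age_lo = 20,
                       age_hi = 100, rr = 1.10, lo95 = 1.0, hi95 = 1.2)
  out <- derive_obese_baseline(epi, bmi, rr, ages = 20:99)
  # oracle: incidence-rate ratio by direct integration, then explicit loop
  lr <- log(1.10)
  p_ob <- pnorm(30, 26, 4, lower.tail = FALSE)
  e_pop <- integrate(function(x) dnorm(x, 26, 4) * exp(lr * (x - 21)),
                     10, 60, rel.tol = 1e-10)$value
  e_ob <- integrate(function(x) dnorm(x, 26, 4) * exp(lr * (x - 21)) *
                      (x >= 30), 10, 60, rel.tol = 1e-10)$value / p_ob
  ir <- e_ob / e_pop
  i_by_age <- ifelse(20:99 < 60, 0.01, 0.02) * ir
  p <- numeric(80)
  cur <- 0
  for (k in 1:80) {
    p[k] <- cur
    cur <- cur + (1 - cur) * i_by_age[k] - cur * 0.02
  }
  expect_equal(out$incidence_ratio, rep(ir, 80), tolerance = 1e-7)
  expect_equal(out$prevalence_obese, p, tolerance = 1e-7)
})

test_that("disease flows conserve mass against cumulative deaths", {
  # track living + cumulative disease deaths explicitly over many cycles
  p <- 0.1
  cum <- 0
  living <- 1
  for (k in 1:50) {
    st <- step_disease(list(prevalence = p, cum_disease_deaths = cum),
                       0.03, 0.05, 0.01)
    dead_this <- st$disease_mortality * living
    living <- living - dead_this
    cum <- cum + dead_this
    p <- st$prevalence
    expect_lt(abs(living + cum - 1), 1e-12)
  }
})
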