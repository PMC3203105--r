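test_that("weight regain follows the empirical trajectory", {
  sib <- weight_effect("sibutramine")
  expect_equal(mean_loss_at_year(sib, 1), 4.45)
  # 4.45 kg at 0.385 kg/month is fully regained before 24 post-course months
  expect_equal(mean_loss_at_year(sib, 3), 0)
  expect_equal(mean_loss_at_year(sib, 2), 0)  # 4.45 < 12 * 0.385
  expect_error(mean_loss_at_year(sib, 0), "year")
})

test_that("no-regain and permanent-fraction limits behave", {
  frozen <- weight_effect(loss_kg = 3, regain_rate = 0)
  expect_equal(mean_loss_at_year(frozen, 1:30), rep(3, 30))
  perm <- weight_effect("sibutramine", permanent_fraction = 0.23)
  expect_equal(mean_loss_at_year(perm, 20), 0.23 * 4.45)  # 1.0235 kg
  # monotone non-increasing for permanent_fraction < 1
  for (pf in c(0, 0.23, 0.9)) {
    e <- weight_effect(loss_kg = 5, permanent_fraction = pf)
    expect_true(all(diff(mean_loss_at_year(e, 1:30)) <= 0))
  }
})

test_that("linear 3-year regain interpolates the non-permanent loss to zero", {
  lin <- weight_effect("sibutramine", regain_mode = "linear_3yr")
  expect_equal(mean_loss_at_year(lin, 1), 4.45)
  expect_equal(mean_loss_at_year(lin, 4), 0)        # 36 months post-course
  expect_equal(mean_loss_at_year(lin, 2), 4.45 * (1 - 12 / 36))
  lin23 <- weight_effect("sibutramine", regain_mode = "linear_3yr",
                         permanent_fraction = 0.23)
  expect_equal(mean_loss_at_year(lin23, 10), 0.23 * 4.45)
})

test_that("obese-segment shift builds a normalised mixture with the right translation", {
  base <- bmi_normal(27, 4.5)
  mix <- shift_obese_distribution(base, 4.45, 0.42, 1.78)
  expect_equal(mix$delta, 4.45 / 1.78^2)           # ~1.404 BMI units
  mass <- integrate(mix$density, -20, 30, rel.tol = 1e-10)$value +
    integrate(mix$density, 30, 90, rel.tol = 1e-10)$value
  expect_lt(abs(mass - 1), 1e-8)
  # null shift and null uptake leave the density unchanged
  x <- seq(15, 45, by = 0.5)
  null_shift <- shift_obese_distribution(base, 0, 0.42, 1.78)
  expect_equal(null_shift$density(x), base$density(x))
  null_uptake <- shift_obese_distribution(base, 4.45, 0, 1.78)
  expect_equal(null_uptake$density(x), base$density(x))
  expect_error(shift_obese_distribution(base, 4.45, 0.42, 0), "height")
})

test_that("ideal distribution is N(21, 1) with a numerically empty obese tail", {
  ideal <- ideal_distribution()
  expect_equal(ideal$mean, 21)
  expect_equal(ideal$sd, 1)
  expect_lt(pnorm(30, 21, 1, lower.tail = FALSE), 1e-15)
})

test_that("the ideal counterfactual dominates any drug shift on PIF", {
  base <- bmi_normal(26.4, 4.5)
  drug <- shift_obese_distribution(base, 4.45, 0.42, 1.78)
  for (r in c(1.03, 1.06, 1.10, 1.16, 1.19)) {
    expect_gte(pif(base, ideal_distribution(), r),
               pif(base, drug, r))
  }
})
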