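test_that("log-linear RR compounds per BMI unit", {
  expect_equal(rr_at(22, 1.10, 21), 1.10)
  expect_equal(rr_at(23, 1.19, 21), 1.19^2)   # 1.4161
  expect_equal(rr_at(35, 1.0, 21), 1.0)
  expect_lt(rr_at(19, 1.10, 21), 1)           # no floor below the reference
  expect_error(rr_at(25, -0.5), ">= 0")
})

test_that("mean RR over a normal matches the lognormal closed form", {
  # X ~ N(ref, s^2) under RR = r^(X - ref): E[RR] = exp(s^2 (ln r)^2 / 2)
  for (r in c(1.03, 1.10, 1.19)) {
    for (s in c(1, 3, 4.5)) {
      closed <- exp(0.5 * s^2 * log(r)^2)
      expect_equal(mean_rr(bmi_normal(21, s), r, ref_bmi = 21), closed,
                   tolerance = 1e-8)
    }
  }
  expect_equal(mean_rr(bmi_normal(27, 4), 1), 1)
  # general normal: E[r^(X-ref)] = exp((mu-ref) ln r + s^2 (ln r)^2 / 2)
  lr <- log(1.12)
  expect_equal(mean_rr(bmi_normal(26, 3.5), 1.12, 21),
               exp((26 - 21) * lr + 0.5 * 3.5^2 * lr^2), tolerance = 1e-8)
})

test_that("mean_rr rejects an unnormalised density", {
  broken <- structure(
    list(type = "normal", mean = 25, sd = 4,
         density = function(x) 2 * dnorm(x, 25, 4)),
    class = "pmslt_bmi_dist")
  expect_error(mean_rr(broken, 1.1), "not normalised")
})

test_that("PIF equals the closed form for an equal-variance mean shift", {
  # mean shift D under log-linear RR with unchanged sd: PIF = 1 - r^-D
  expect_equal(pif(bmi_normal(27, 4), bmi_normal(26, 4), 1.10),
               1 - exp(-log(1.10)), tolerance = 1e-8)   # 0.0909...
  expect_equal(pif(bmi_normal(27, 4), bmi_normal(27, 4), 1.10), 0)
  expect_equal(pif(bmi_normal(27, 4), bmi_normal(24, 4), 1.0), 0)
})

test_that("PIF is invariant to the reference BMI", {
  base <- bmi_normal(26.4, 4.5)
  cf <- shift_obese_distribution(base, 4.45, 0.42, 1.78)
  refs <- withr::with_seed(9, runif(5, 15, 35))
  vals <- vapply(refs, function(rf) pif(base, cf, 1.10, ref_bmi = rf),
                 numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-9)
})

test_that("PIF grows with the size of the downward shift", {
  base <- bmi_normal(26.4, 4.5)
  shifts <- c(1, 2, 4, 8)
  vals <- vapply(shifts, function(kg) {
    pif(base, shift_obese_distribution(base, kg, 0.42, 1.78), 1.10)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("quadrature PIF agrees with Monte Carlo for mixtures and the ideal shift", {
  base <- bmi_normal(26.4, 4.5)
  delta <- 4.45 / 1.78^2
  cf <- shift_obese_distribution(base, 4.45, 0.42, 1.78)
  mc <- mc_pif_shift(26.4, 4.5, delta, 0.42, 1.10)
  expect_lt(abs(pif(base, cf, 1.10) - mc$pif), 3 * mc$se)
  mci <- mc_pif_ideal(26.4, 4.5, 1.10)
  expect_lt(abs(pif(base, ideal_distribution(), 1.10) - mci$pif),
            3 * mci$se)
})

test_that("the fixed-grid fast path matches adaptive quadrature", {
  grid <- pmslt:::gl_grid()
  mu <- c(26.4, 26.3)
  sd <- c(4.5, 5.0)
  r <- c(1.03, 1.10, 1.19)
  ex <- pmslt:::stratum_rr_expectations(mu, sd, r, grid)
  for (i in seq_along(mu)) {
    for (j in seq_along(r)) {
      expect_equal(ex$e_base[i, j], mean_rr(bmi_normal(mu[i], sd[i]), r[j]),
                   tolerance = 1e-9)
    }
  }
  # counterfactual decomposition: E_cf = E_base - u (1 - r^-delta) T(r)
  u <- 0.42
  delta <- 4.45 / 1.78^2
  mix <- shift_obese_distribution(bmi_normal(mu[1], sd[1]), 4.45, u, 1.78)
  for (j in seq_along(r)) {
    e_cf_fast <- ex$e_base[1, j] -
      u * (1 - r[j]^(-delta)) * ex$t_obese[1, j]
    expect_equal(e_cf_fast, mean_rr(mix, r[j]), tolerance = 1e-8)
  }
  # ideal closed form vs quadrature
  for (j in seq_along(r)) {
    expect_equal(pmslt:::ideal_rr_expectation(r[j]),
                 mean_rr(ideal_distribution(), r[j]), tolerance = 1e-8)
  }
})
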