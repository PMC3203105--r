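test_that("ICER handles sentinels and the published rounding rule", {
  expect_equal(icer(0, 10), 0)
  expect_equal(icer(100, 0), Inf)
  expect_equal(icer(100, -5), Inf)
  expect_equal(icer(1.4e9, 1.1e4, signif_digits = 2), 130000)
  expect_equal(format_icer(Inf), "∞")
  expect_equal(format_icer(84321), "84 000")
})

test_that("BMI-loss utility adds linearly to the effect size", {
  expect_equal(add_bmi_utility(10, 100, 0), 10)
  expect_equal(add_bmi_utility(0, 1, 0.017), 0.017)
  expect_equal(add_bmi_utility(5, 200, 0.017), 5 + 3.4)
  expect_error(add_bmi_utility(5, 1, -0.1), ">= 0")
})

test_that("PSA is reproducible and reports ratio-of-means ICERs", {
  sc <- scenario_config("sibutramine")
  a <- run_psa(tw, sc, n_iter = 40, seed = 11)
  b <- run_psa(tw, sc, n_iter = 40, seed = 11)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  s <- a$summary[a$summary$perspective == "health_sector", ]
  # point estimate is the ratio of means, not the mean of ratios
  expect_equal(s$icer, mean(a$draws$net_health_sector) /
                 mean(a$draws$effect_dalys))
  mean_of_ratios <- mean(a$draws$net_health_sector / a$draws$effect_dalys)
  expect_false(isTRUE(all.equal(s$icer, mean_of_ratios)))
  # interval ordering
  expect_lte(s$dalys_lo, s$dalys_mean)
  expect_lte(s$dalys_mean, s$dalys_hi)
  # p(CE) consistent with the draw-level definition
  ratio <- a$draws$net_health_sector / a$draws$effect_dalys
  expect_equal(s$p_cost_effective,
               mean(a$draws$effect_dalys > 0 & ratio < sc$threshold))
})

test_that("a degenerate PSA collapses to the deterministic point estimate", {
  det <- run_pipeline(tw, scenario_config("sibutramine"))
  psa <- run_psa(tw, scenario_config("sibutramine"), n_iter = 5, seed = 3,
                 uncertainty = uncertainty_spec(0, 0, 0, 0))
  s <- psa$summary[psa$summary$perspective == "health_sector", ]
  expect_equal(s$dalys_mean, det$dalys_averted)
  expect_equal(s$dalys_lo, s$dalys_hi)
  expect_equal(s$icer, det$icers[["health_sector"]])
  expect_error(run_psa(tw, scenario_config(), n_iter = 1), "n_iter")
})

test_that("PSA intervals cover the deterministic estimate for symmetric inputs", {
  det <- run_pipeline(tw, scenario_config("sibutramine"))
  psa <- run_psa(tw, scenario_config("sibutramine"), n_iter = 100, seed = 5)
  s <- psa$summary[psa$summary$perspective == "health_sector", ]
  expect_gte(det$dalys_averted, s$dalys_lo)
  expect_lte(det$dalys_averted, s$dalys_hi)
})

test_that("sensitivity grid validates keys and reruns selected scenarios", {
  expect_error(run_sensitivity_grid(tw, scenario_config(), "bogus"),
               "unknown scenario key")
  g <- run_sensitivity_grid(tw, scenario_config("sibutramine"),
                            scenarios = c("base", "discount_0"))
  expect_equal(g$scenario, c("base", "discount_0"))
  base <- g[g$scenario == "base", ]
  nodisc <- g[g$scenario == "discount_0", ]
  expect_gt(nodisc$dalys_averted, base$dalys_averted)
  expect_lt(nodisc$icer, base$icer)
})

test_that("result objects expose tidy, glance and autoplot methods", {
  run <- run_pipeline(tw, scenario_config("orlistat"), compute_burden = TRUE)
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_true(all(diff(td$icer) >= 0))  # widening perspectives
  gl <- glance(run)
  expect_equal(gl$drug, "orlistat")
  psa <- run_psa(tw, scenario_config("orlistat"), n_iter = 10, seed = 2)
  expect_s3_class(autoplot(psa), "ggplot")
  g <- run_sensitivity_grid(tw, scenario_config("orlistat"),
                            scenarios = c("base", "discount_0"))
  expect_s3_class(autoplot(g), "ggplot")
  expect_s3_class(plot_weight_trajectory(weight_effect("orlistat")), "ggplot")
})
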