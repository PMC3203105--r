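# ICERs, probabilistic sensitivity analysis and the univariate
# sensitivity grid.

#' Incremental cost-effectiveness ratio
#'
#' Discounted net cost divided by DALYs averted.  When no DALYs are
#' gained the intervention cannot buy health at any price and the ratio
#' is reported as the `Inf` sentinel.
#'
#' @param net_cost Discounted net cost (AUD).
#' @param dalys DALYs averted.
#' @param signif_digits Optional significant digits for reporting (the
#'   published tables round to 2); `NULL` returns full precision.
#' @return AUD per DALY averted (scalar; `Inf` if `dalys <= 0`).
#' @export
#' @examples
#' icer(1.4e9, 1.1e4, signif_digits = 2)  # 130000
#' icer(100, 0)                           # Inf
icer <- function(net_cost, dalys, signif_digits = NULL) {
  if (is.na(dalys) || dalys <= 0) return(Inf)
  out <- net_cost / dalys
  if (!is.null(signif_digits)) out <- signif(out, signif_digits)
  out
}

#' Format an ICER for reporting
#'
#' Two significant figures, with the infinity sentinel printed as the
#' infinity sign.
#'
#' @param x ICER value(s).
#' @return Character vector.
#' @export
format_icer <- function(x) {
  ifelse(is.infinite(x), "∞",
         format(signif(x, 2), big.mark = " ", scientific = FALSE,
                trim = TRUE))
}

#' Add a utility weight for BMI loss per se
#'
#' Credits a QALY-like utility per BMI-unit-year of exposure reduction on
#' top of the disease-mediated DALYs averted.
#'
#' @param dalys DALYs averted through disease pathways.
#' @param bmi_unit_years Discounted BMI-unit-years of exposure reduction
#'   across all treated persons.
#' @param utility Utility weight per BMI-unit-year (default 0.017).
#' @return Adjusted effect size (DALYs + utility-weighted BMI-unit-years).
#' @export
add_bmi_utility <- function(dalys, bmi_unit_years, utility = 0.017) {
  if (utility < 0) abort("utility must be >= 0")
  dalys + utility * bmi_unit_years
}

# triangular sampler (inverse CDF); degenerates to the mode
rtri <- function(n, min, mode, max) {
  if ((max - min) < .Machine$double.eps) return(rep(mode, n))
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Uncertainty specification for the PSA
#'
#' Scale factors applied to the spread of each parameter distribution in
#' [run_psa()].  The default of 1 reproduces the published uncertainty
#' model; 0 collapses a distribution to its point value (useful for
#' degenerate-PSA checks).  The medication price carries no distribution
#' under any setting.
#'
#' @param weight_sd_scale,rr_sd_scale,regain_sd_scale,tri_scale
#'   Non-negative multipliers on, respectively, the sd of the mean weight
#'   change, the sd of ln RR, the sd of the regain rate, and the
#'   half-width of the triangular cost components.
#' @return Named list of scale factors.
#' @export
uncertainty_spec <- function(weight_sd_scale = 1, rr_sd_scale = 1,
                             regain_sd_scale = 1, tri_scale = 1) {
  sc <- list(weight_sd_scale = weight_sd_scale, rr_sd_scale = rr_sd_scale,
             regain_sd_scale = regain_sd_scale, tri_scale = tri_scale)
  if (any(unlist(sc) < 0)) abort("scale factors must be >= 0")
  sc
}

# shrink a triangular c(min, mode, max) towards its mode
tri_scale_spread <- function(x, scale) {
  c(x[2] + (x[1] - x[2]) * scale, x[2], x[2] + (x[3] - x[2]) * scale)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo uncertainty analysis of the full pipeline.  Normal
#' distributions are drawn around the mean weight change and around the
#' natural log of each relative risk; the regain rate is normal;
#' triangular distributions cover the GP/travel minute components; the
#' medication price is fixed (centrally subsidised).  Parameter draws are
#' common to both arms within an iteration; the reference arm does not
#' depend on drawn parameters and is computed once.
#'
#' @param world A `pmslt_world`.
#' @param scenario A [scenario_config()].
#' @param n_iter Number of Monte Carlo iterations (default 2000).
#' @param seed Integer seed.
#' @param uncertainty An [uncertainty_spec()]; scale factors of 0 give a
#'   degenerate PSA whose intervals collapse to the point estimate.
#' @return A list of class `pmslt_cea`: `summary` (tibble per costing
#'   perspective with mean and 95% uncertainty intervals for DALYs, net
#'   cost and the per-iteration ICER distribution, the ratio-of-means
#'   ICER point estimate, and the probability of cost-effectiveness at
#'   the threshold), `draws` (per-iteration tibble), `n_iter`, `seed`,
#'   `scenario`.
#' @export
#' @examples
#' \donttest{
#' world <- synth_world(1)
#' psa <- run_psa(world, scenario_config("sibutramine"), n_iter = 50, seed = 1)
#' psa$summary
#' }
run_psa <- function(world, scenario = scenario_config(), n_iter = 2000,
                    seed = 1L, uncertainty = uncertainty_spec()) {
  if (n_iter < 2) abort("n_iter must be >= 2 for uncertainty intervals")
  ctx <- pipeline_context(world, scenario)
  dp <- if (scenario$drug == "none") NULL else drug_params(scenario$drug)
  eff0 <- weight_effect(regain_rate = scenario$regain_rate)
  cp <- default_cost_params()
  tri_i <- tri_scale_spread(cp$minutes_initial, uncertainty$tri_scale)
  tri_f <- tri_scale_spread(cp$minutes_followup, uncertainty$tri_scale)
  tri_t <- tri_scale_spread(cp$travel_minutes, uncertainty$tri_scale)
  rrt <- ctx$rr_entries
  rr_se <- rrt$ln_se * uncertainty$rr_sd_scale
  loss_sd <- if (is.null(dp)) 0 else dp$loss_se * uncertainty$weight_sd_scale
  regain_sd <- eff0$regain_sd * uncertainty$regain_sd_scale

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  rows <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    z <- rnorm(nrow(rrt))
    r_entries <- exp(log(rrt$rr) + z * rr_se)
    draw <- list(
      loss_kg = if (is.null(dp)) 0 else
        max(0, rnorm(1, dp$loss_kg, loss_sd)),
      regain_rate = max(0, rnorm(1, eff0$regain_rate, regain_sd)),
      r_entries = r_entries,
      minutes_initial = rtri(1, tri_i[1], tri_i[2], tri_i[3]),
      minutes_followup = rtri(1, tri_f[1], tri_f[2], tri_f[3]),
      travel_minutes = rtri(1, tri_t[1], tri_t[2], tri_t[3])
    )
    res <- eval_draw(ctx, draw, mode = "drug")
    net <- perspective_net_costs(res)
    rows[[it]] <- tibble(
      iter = it, dalys = res$dalys, effect_dalys = res$effect_dalys,
      cost_intervention = res$cost_intervention,
      cost_patient = res$cost_patient,
      cost_offsets = res$cost_offsets,
      cost_unrelated = res$cost_unrelated,
      net_health_sector = net[["health_sector"]],
      net_plus_patient = net[["plus_patient"]],
      net_plus_unrelated = net[["plus_unrelated"]]
    )
  }
  draws <- list_rbind(rows)

  q <- function(x, p) unname(stats::quantile(x, p, names = FALSE, type = 7))
  persp <- c(health_sector = "net_health_sector",
             plus_patient = "net_plus_patient",
             plus_unrelated = "net_plus_unrelated")
  summary <- imap(persp, function(col, nm) {
    net <- draws[[col]]
    eff <- draws$effect_dalys
    ratio <- ifelse(eff > 0, net / eff, Inf)
    ce <- eff > 0 & ratio < scenario$threshold
    tibble(
      perspective = nm,
      dalys_mean = mean(eff), dalys_lo = q(eff, 0.025),
      dalys_hi = q(eff, 0.975),
      net_cost_mean = mean(net), net_cost_lo = q(net, 0.025),
      net_cost_hi = q(net, 0.975),
      icer = icer(mean(net), mean(eff)),
      icer_lo = q(ratio, 0.025), icer_hi = q(ratio, 0.975),
      p_cost_effective = mean(ce)
    )
  }) %>% list_rbind()

  structure(
    list(summary = summary, draws = draws, n_iter = n_iter, seed = seed,
         scenario = scenario),
    class = "pmslt_cea"
  )
}

#' @export
print.pmslt_cea <- function(x, ...) {
  cat(sprintf("<pmslt_cea: %s, %d iterations, seed %d>\n",
              x$scenario$drug, x$n_iter, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %-14s DALYs %s (%s-%s)  ICER %s (%s-%s)  P(CE@%s) %.0f%%\n",
      s$perspective[i],
      format(signif(s$dalys_mean[i], 2), big.mark = " "),
      format(signif(s$dalys_lo[i], 2), big.mark = " "),
      format(signif(s$dalys_hi[i], 2), big.mark = " "),
      format_icer(s$icer[i]), format_icer(s$icer_lo[i]),
      format_icer(s$icer_hi[i]),
      format(x$scenario$threshold, big.mark = ","),
      100 * s$p_cost_effective[i]))
  }
  invisible(x)
}

#' @describeIn run_psa Per-perspective tidy summary with uncertainty
#'   intervals.
#' @param x A `pmslt_cea`.
#' @param ... Unused.
#' @export
tidy.pmslt_cea <- function(x, ...) x$summary

#' @describeIn run_psa One-row summary (health-sector perspective).
#' @export
glance.pmslt_cea <- function(x, ...) {
  s <- x$summary[x$summary$perspective == "health_sector", ]
  tibble(
    drug = x$scenario$drug, n_iter = x$n_iter,
    dalys_mean = s$dalys_mean, icer = s$icer,
    p_cost_effective = s$p_cost_effective
  )
}

#' Cost-effectiveness plane for a PSA run
#'
#' Per-iteration incremental costs against incremental effects, with the
#' threshold line.
#'
#' @param object A `pmslt_cea` from [run_psa()].
#' @param perspective Which net-cost perspective to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmslt_cea <- function(object,
                               perspective = c("health_sector",
                                               "plus_patient",
                                               "plus_unrelated"), ...) {
  perspective <- match.arg(perspective)
  col <- paste0("net_", perspective)
  df <- object$draws
  ggplot(df, aes(x = .data$effect_dalys, y = .data[[col]] / 1e6)) +
    geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = object$scenario$threshold / 1e6,
                         intercept = 0, linetype = "dashed") +
    labs(
      x = "DALYs averted",
      y = "Net cost (A$ million)",
      title = sprintf("Cost-effectiveness plane: %s", object$scenario$drug),
      subtitle = sprintf("dashed line: A$%s/DALY threshold",
                         format(object$scenario$threshold, big.mark = ","))
    ) +
    theme_minimal()
}

#' Univariate sensitivity grid
#'
#' Re-runs the deterministic pipeline under the published one-way
#' sensitivity scenarios: halved regain rate, linear regain over 3 years,
#' 23% of the loss permanent, a 0.017 utility per BMI-unit-year, no
#' discounting, all obese disease-free at baseline, and age-decade
#' subgroups 20-79.  ICERs use the widest perspective (patient time and
#' travel plus unrelated health-care costs in added years), as in the
#' published grid.
#'
#' @param world A `pmslt_world`.
#' @param scenario Base [scenario_config()] (defines the drug).
#' @param scenarios Subset of scenario keys to run (default all).
#' @return A tibble of class `pmslt_sensitivity`: `scenario`,
#'   `dalys_averted`, `effect_dalys`, `icer`, `icer_label`.
#' @export
run_sensitivity_grid <- function(world, scenario = scenario_config(),
                                 scenarios = NULL) {
  all_keys <- c("base", "regain_halved", "linear_3yr", "permanent_23pct",
                "utility_0.017_per_BMI", "discount_0",
                "disease_free_baseline",
                paste0("age_", seq(20, 70, 10), "_", seq(29, 79, 10)))
  scenarios <- scenarios %||% all_keys
  unknown <- setdiff(scenarios, all_keys)
  if (length(unknown)) {
    abort(paste0("unknown scenario key(s): ", paste(unknown, collapse = ", ")))
  }
  base_regain <- weight_effect(regain_rate = scenario$regain_rate)$regain_rate
  rows <- purrr::map(scenarios, function(key) {
    sc <- scenario
    if (key == "regain_halved") sc$regain_rate <- base_regain / 2
    if (key == "linear_3yr") sc$regain_mode <- "linear_3yr"
    if (key == "permanent_23pct") sc$permanent_fraction <- 0.23
    if (key == "utility_0.017_per_BMI") sc$utility_per_bmi_unit <- 0.017
    if (key == "discount_0") sc$discount_rate <- 0
    if (key == "disease_free_baseline") sc$disease_free_baseline <- TRUE
    if (grepl("^age_", key)) {
      lo <- as.integer(sub("^age_(\\d+)_.*$", "\\1", key))
      sc$age_range <- c(lo, lo + 10)
    }
    run <- run_pipeline(world, sc)
    full_icer <- run$icers[["plus_unrelated"]]
    tibble(scenario = key,
           dalys_averted = run$dalys_averted,
           effect_dalys = run$effect_dalys,
           icer = full_icer,
           icer_label = format_icer(full_icer))
  }) %>% list_rbind()
  class(rows) <- c("pmslt_sensitivity", class(rows))
  rows
}

#' Sensitivity-grid tornado-style plot
#'
#' DALYs averted by sensitivity scenario.
#'
#' @param object A `pmslt_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmslt_sensitivity <- function(object, ...) {
  df <- object %>%
    mutate(scenario = factor(.data$scenario, levels = rev(.data$scenario)))
  ggplot(df, aes(x = .data$effect_dalys, y = .data$scenario)) +
    geom_col() +
    labs(x = "DALYs averted (effect size)", y = NULL) +
    theme_minimal()
}
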