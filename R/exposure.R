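# Exposure model: drug-induced weight-loss trajectory (12-month loss,
# post-intervention regain, permanence scenarios) and baseline /
# counterfactual BMI distributions.

#' Weight-effect specification for a one-year drug course
#'
#' Mean weight loss at the end of the 12-month intervention, the
#' post-intervention regain rate, and the fraction of the loss that is
#' never regained.  Two named regain presets are provided: the trial-based
#' `"storm"` rate of 0.385 kg/month (default: it is the only rate
#' consistent with full regain of a 4.45 kg loss within two years) and the
#' meta-regression value `"meta_regression"` of 0.0309 (sd 0.0084)
#' kg/month.
#'
#' @param drug Optional drug name; fills `loss_kg`/`loss_se` from
#'   [drug_params()].
#' @param loss_kg Mean reduction in body weight (kg) at 12 months.
#' @param loss_se Standard error of the mean loss (used as the PSA sd of
#'   the population mean change).
#' @param regain_rate Weight regain (kg/month) after the intervention
#'   year, or a preset name (`"storm"`, `"meta_regression"`).
#' @param regain_sd PSA sd of the regain rate.  Defaults to the printed
#'   0.0084 for the meta-regression preset, scaled proportionally for
#'   other rates.
#' @param permanent_fraction Proportion of the 12-month loss never
#'   regained.
#' @param regain_mode `"empirical_rate"` (constant kg/month) or
#'   `"linear_3yr"` (non-permanent loss regained linearly over 36 months).
#' @return A list of class `pmslt_weight_effect`.
#' @export
#' @examples
#' weight_effect("sibutramine")
weight_effect <- function(drug = NULL, loss_kg = 4.45, loss_se = 0.426,
                          regain_rate = "storm", regain_sd = NULL,
                          permanent_fraction = 0,
                          regain_mode = c("empirical_rate", "linear_3yr")) {
  regain_mode <- match.arg(regain_mode)
  if (!is.null(drug)) {
    dp <- drug_params(drug)
    loss_kg <- dp$loss_kg
    loss_se <- dp$loss_se
  }
  if (is.character(regain_rate)) {
    regain_rate <- switch(regain_rate,
      storm = 0.385,
      meta_regression = 0.0309,
      abort("unknown regain preset; use 'storm' or 'meta_regression'")
    )
  }
  if (loss_kg < 0) abort("loss_kg must be >= 0")
  if (regain_rate < 0) abort("regain_rate must be >= 0")
  if (permanent_fraction < 0 || permanent_fraction > 1) {
    abort("permanent_fraction must lie in [0, 1]")
  }
  if (is.null(regain_sd)) regain_sd <- 0.0084 * regain_rate / 0.0309
  structure(
    list(drug = drug %||% "custom", loss_kg = loss_kg, loss_se = loss_se,
         regain_rate = regain_rate, regain_sd = regain_sd,
         permanent_fraction = permanent_fraction, regain_mode = regain_mode),
    class = "pmslt_weight_effect"
  )
}

# mean retained loss (kg) t months after starting the drug.  The loss is
# held at its 12-month value through the intervention year (intent-to-treat
# trial estimate); regain starts the month after the course ends and is
# floored at the permanent fraction of the loss.
loss_at_month <- function(effect, t_months) {
  loss <- effect$loss_kg
  floor_kg <- effect$permanent_fraction * loss
  m <- pmax(0, t_months - 12)
  if (effect$regain_mode == "empirical_rate") {
    pmax(ifelse(t_months <= 12, loss, loss - effect$regain_rate * m), floor_kg)
  } else {
    nonperm <- (1 - effect$permanent_fraction) * loss
    ifelse(t_months <= 12, loss, floor_kg + nonperm * pmax(0, 1 - m / 36))
  }
}

#' Mean retained weight loss at the end of a model year
#'
#' Year 1 is the intervention year and returns the 12-month loss; later
#' years subtract regain for the elapsed post-intervention months, floored
#' at `permanent_fraction * loss_kg` (in `"linear_3yr"` mode the
#' non-permanent part is interpolated to zero over 36 months).
#'
#' @param effect A [weight_effect()].
#' @param year Model year (integer >= 1).
#' @return Mean retained loss in kg (vectorised over `year`).
#' @export
#' @examples
#' sib <- weight_effect("sibutramine")
#' mean_loss_at_year(sib, 1:3)  # 4.45, then regain, 0 by year 3
mean_loss_at_year <- function(effect, year) {
  if (any(year < 1)) abort("`year` must be >= 1 (year 1 = intervention year)")
  loss_at_month(effect, 12 * year)
}

# exposure value used for the annual cycle: retained loss at the cycle
# midpoint (month 12*year - 6), the representative value for a year over
# which weight is regained continuously.
exposure_loss_at_year <- function(effect, year) {
  loss_at_month(effect, 12 * year - 6)
}

#' Baseline normal BMI distribution
#'
#' @param mean,sd Mean and standard deviation of BMI (kg/m^2), `sd > 0`.
#' @return An object of class `pmslt_bmi_dist` with a `density` closure.
#' @export
bmi_normal <- function(mean, sd) {
  if (sd <= 0) abort("sd must be > 0")
  structure(
    list(type = "normal", mean = mean, sd = sd,
         density = function(x) dnorm(x, mean, sd)),
    class = "pmslt_bmi_dist"
  )
}

#' Theoretical-minimum-risk BMI distribution
#'
#' The ideal counterfactual used to express population health gains as a
#' fraction of the total attributable burden: BMI normal with mean 21 and
#' standard deviation 1 in every sex/age stratum.
#'
#' @return A `pmslt_bmi_dist` (normal, mean 21, sd 1).
#' @export
ideal_distribution <- function() bmi_normal(21, 1)

#' Shift the treated obese segment of a BMI distribution
#'
#' Builds the counterfactual mixture in which a fraction `uptake` of the
#' obese (BMI >= 30) mass is translated down by `loss_kg / height^2` BMI
#' units while the non-obese and untreated obese mass is unchanged.
#'
#' @param base A `pmslt_bmi_dist` (normal baseline).
#' @param loss_kg Mean weight loss in kg applied to the treated.
#' @param uptake Proportion of the obese who are treated.
#' @param height Mean height in metres (> 0) for kg-to-BMI conversion.
#' @return A `pmslt_bmi_dist` mixture; its `density` integrates to 1.
#' @export
#' @examples
#' mix <- shift_obese_distribution(bmi_normal(27, 4.5), 4.45, 0.42, 1.78)
#' integrate(mix$density, -20, 30)$value + integrate(mix$density, 30, 90)$value
shift_obese_distribution <- function(base, loss_kg, uptake, height) {
  if (height <= 0) abort("height must be > 0")
  if (loss_kg < 0) abort("loss_kg must be >= 0")
  if (uptake < 0 || uptake > 1) abort("uptake must lie in [0, 1]")
  stopifnot(inherits(base, "pmslt_bmi_dist"), base$type == "normal")
  delta <- loss_kg / height^2
  f0 <- base$density
  dens <- function(x) {
    f0(x) * (x < 30) +
      (1 - uptake) * f0(x) * (x >= 30) +
      uptake * f0(x + delta) * ((x + delta) >= 30)
  }
  structure(
    list(type = "mixture", base = base, delta = delta, uptake = uptake,
         density = dens),
    class = "pmslt_bmi_dist"
  )
}

#' @export
print.pmslt_bmi_dist <- function(x, ...) {
  if (x$type == "normal") {
    cat(sprintf("<BMI distribution: Normal(%.3f, %.3f)>\n", x$mean, x$sd))
  } else {
    cat(sprintf(
      "<BMI mixture: base Normal(%.3f, %.3f), obese segment shifted %.4f units, uptake %.3f>\n",
      x$base$mean, x$base$sd, x$delta, x$uptake))
  }
  invisible(x)
}

#' Weight-loss trajectory plot
#'
#' Retained mean weight loss by model year for one or more weight-effect
#' specifications.
#'
#' @param effects A named list of [weight_effect()] objects.
#' @param years Integer vector of model years.
#' @return A ggplot object.
#' @export
plot_weight_trajectory <- function(effects, years = 1:6) {
  if (inherits(effects, "pmslt_weight_effect")) {
    effects <- list(effect = effects)
  }
  df <- imap(effects, function(e, nm) {
    tibble(scenario = nm, year = years,
           loss_kg = mean_loss_at_year(e, years))
  }) %>% list_rbind()
  ggplot(df, aes(x = .data$year, y = .data$loss_kg,
                 colour = .data$scenario)) +
    geom_line() +
    geom_point() +
    labs(x = "Model year", y = "Retained weight loss (kg)",
         colour = NULL) +
    theme_minimal()
}
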