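# Per-disease incidence -> prevalence -> disease-mortality propagation in
# annual cycles, and the steady-state derivation of baseline prevalence
# among the obese.
#
# The disease module tracks prevalence among the living; all deaths
# (disease-specific and other-cause) are removed from the population in
# the life-table module.  Flows are applied simultaneously to
# start-of-cycle stocks:
#   p' = p + (1 - p) i - p r - p f
# whose fixed point for r = 0 is the classic i / (i + f).

#' One annual cycle of the three-state disease model
#'
#' Advances a disease state (well / diseased / dead-from-disease) by one
#' year.  Incidence moves susceptibles into the diseased state, remission
#' moves diseased back, and case fatality generates disease-specific
#' deaths; all three flows act on start-of-cycle compartments.
#'
#' @param state A list with elements `prevalence` (proportion of the
#'   living who are diseased) and optionally `cum_disease_deaths`.
#'   A bare numeric prevalence is also accepted.
#' @param incidence,case_fatality,remission Annual rates (>= 0).
#' @param dt Cycle length in years (must be 1).
#' @return A list: `prevalence`, `disease_mortality` (deaths from the
#'   disease per living person this cycle, `p * f`), and
#'   `cum_disease_deaths`.
#' @export
#' @examples
#' s <- step_disease(list(prevalence = 0), incidence = 0.1,
#'                   case_fatality = 0, remission = 0)
#' s$prevalence  # 0.1
step_disease <- function(state, incidence, case_fatality, remission = 0,
                         dt = 1) {
  if (dt != 1) abort("the model uses annual cycles (dt = 1)")
  if (any(c(incidence, case_fatality, remission) < 0)) {
    abort("rates must be >= 0")
  }
  if (is.numeric(state)) state <- list(prevalence = state)
  p <- state$prevalence
  if (any(p < 0 | p > 1)) abort("prevalence must lie in [0, 1]")
  deaths <- p * case_fatality
  p_new <- p + (1 - p) * incidence - p * remission - deaths
  p_new <- pmin(pmax(p_new, 0), 1)
  list(
    prevalence = p_new,
    disease_mortality = deaths,
    cum_disease_deaths = (state$cum_disease_deaths %||% 0) + deaths
  )
}

#' Scale incidence by a potential impact fraction
#'
#' @param incidence Annual incidence rate.
#' @param pif Potential impact fraction (<= 1).
#' @return `incidence * (1 - pif)`.
#' @export
#' @examples
#' apply_pif_to_incidence(0.02, 0.0909)
apply_pif_to_incidence <- function(incidence, pif) {
  if (any(pif > 1)) abort("pif must be <= 1")
  out <- incidence * (1 - pif)
  if (any(out < 0)) abort("effective incidence would be negative")
  out
}

# run the disease recursion over a vector of ages.  incidence, case
# fatality, remission are vectors aligned with `ages`; returns prevalence
# AT each age (prevalence[1] = p0 at ages[1]) and the disease mortality
# rate generated DURING each age-year.
simulate_disease_path <- function(p0, incidence, case_fatality,
                                  remission = 0) {
  n <- length(incidence)
  remission <- rep_len(remission, n)
  prev <- numeric(n + 1)
  mort <- numeric(n)
  prev[1] <- p0
  for (k in seq_len(n)) {
    st <- step_disease(prev[k], incidence[k], case_fatality[k], remission[k])
    prev[k + 1] <- st$prevalence
    mort[k] <- st$disease_mortality
  }
  list(prevalence = prev[seq_len(n)], disease_mortality = mort,
       prevalence_end = prev[n + 1])
}

#' Baseline disease prevalence among the obese, derived from the model
#'
#' In the absence of measured prevalence among the obese, the model
#' itself generates it: assume a steady state, define a counterfactual in
#' which the whole population has the obese BMI distribution (the part of
#' the baseline distribution above 30 kg/m^2, renormalised), scale the
#' population incidence rates by the implied obese-to-population
#' incidence-rate ratio `E_obese[RR] / E_pop[RR]`, and run the disease
#' model over the lifetime of the youngest cohort.
#'
#' @param epi Disease epidemiology tibble (`disease`, `sex`, `age_lo`,
#'   `incidence`, `case_fatality`, `remission`).
#' @param bmi BMI parameter tibble (`sex`, `age_lo`, `mean_bmi`,
#'   `sd_bmi`).
#' @param rr Relative-risk tibble as from [default_rr_table()].
#' @param ages Integer ages to simulate (default 20:99).
#' @return A tibble `disease`, `sex`, `age`, `incidence_ratio`,
#'   `prevalence_obese`, `prevalence_population`.
#' @export
derive_obese_baseline <- function(epi, bmi, rr, ages = 20:99) {
  strata <- distinct(bmi, .data$sex)
  out <- list()
  for (sx in strata$sex) {
    bmi_s <- filter(bmi, .data$sex == sx)
    for (dis in unique(epi$disease)) {
      epi_d <- epi %>% filter(.data$disease == dis, .data$sex == sx) %>%
        arrange(.data$age_lo)
      if (!nrow(epi_d)) next
      band <- pmin(findInterval(ages, epi_d$age_lo), nrow(epi_d))
      inc <- epi_d$incidence[band]
      cf <- epi_d$case_fatality[band]
      rem <- epi_d$remission[band]
      rr_d <- rr %>% filter(.data$disease == dis)
      rr_age <- rr_d$rr[pmin(findInterval(ages, rr_d$age_lo), nrow(rr_d))]
      # per-age incidence-rate ratio from the stratum BMI distribution
      bband <- pmin(findInterval(ages, bmi_s$age_lo), nrow(bmi_s))
      ir <- map_dbl(seq_along(ages), function(k) {
        r <- rr_age[k]
        if (r == 1) return(1)
        mu <- bmi_s$mean_bmi[bband[k]]
        sdv <- bmi_s$sd_bmi[bband[k]]
        p_ob <- pnorm(30, mu, sdv, lower.tail = FALSE)
        if (p_ob <= 0) abort("truncated obese distribution has zero mass")
        lr <- log(r)
        e_pop <- integrate(function(x) dnorm(x, mu, sdv) * exp(lr * (x - 21)),
                           10, 60, rel.tol = 1e-9)$value
        e_ob <- integrate(
          function(x) dnorm(x, mu, sdv) * (x >= 30) * exp(lr * (x - 21)),
          10, 60, rel.tol = 1e-9)$value / p_ob
        e_ob / e_pop
      })
      path_pop <- simulate_disease_path(0, inc, cf, rem)
      path_ob <- simulate_disease_path(0, inc * ir, cf, rem)
      out[[length(out) + 1L]] <- tibble(
        disease = dis, sex = sx, age = ages,
        incidence_ratio = ir,
        prevalence_obese = path_ob$prevalence,
        prevalence_population = path_pop$prevalence
      )
    }
  }
  list_rbind(out)
}
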