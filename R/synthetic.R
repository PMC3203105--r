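# Synthetic Australian-like world: demography, disease epidemiology, BMI
# distributions.  Everything downstream runs from these tables, so the
# whole pipeline is testable with no external data.

age_band_los <- function() seq(20, 95, by = 5)

age_band_label <- function(lo) sprintf("%d-%d", lo, lo + 4)

#' Generator configuration for the synthetic world
#'
#' Defaults encode the study conditions: Gompertz adult mortality per sex,
#' age-increasing chronic-disease incidence with disease onset ages,
#' normal BMI per stratum calibrated so that P(BMI >= 30) matches obesity
#' prevalence targets of 21% (men) and 23% (women), fixed mean heights of
#' 1.78 m (men) and 1.64 m (women) for kg-to-BMI conversion, and no
#' secular BMI trend (an additive per-year mean-BMI drift hook is exposed
#' but defaults to 0).
#'
#' @param gompertz Named list per sex: `c(alpha, beta)` such that the
#'   all-cause mortality rate at age x is `alpha * exp(beta * x)`.
#' @param count_20_24 Persons per sex in the 20-24 band.
#' @param count_decline_age,count_decline_rate Cohort sizes decline
#'   exponentially at `count_decline_rate` per year of band midpoint above
#'   `count_decline_age`.
#' @param obesity_target Named per-sex target for P(BMI >= 30).
#' @param bmi_sd Named per-sex BMI standard deviation (kg/m^2).
#' @param height Named per-sex mean height (m).
#' @param bmi_trend_per_year Additive mean-BMI drift per calendar year
#'   (default 0: steady state).
#' @param incidence_jitter_sd Lognormal sd of seeded multiplicative noise
#'   applied to disease incidence across strata (0 disables).
#' @param baseline_yld Baseline years-lived-with-disability rate applied
#'   at every age (all-cause time in poor health).
#' @return A named list of class `pmslt_generator_config`.
#' @export
generator_config <- function(
    gompertz = list(male = c(alpha = 1.35e-4, beta = 0.081),
                    female = c(alpha = 4.0e-5, beta = 0.092)),
    count_20_24 = 650000,
    count_decline_age = 52,
    count_decline_rate = 0.035,
    obesity_target = c(male = 0.21, female = 0.23),
    bmi_sd = c(male = 4.5, female = 5.0),
    height = c(male = 1.78, female = 1.64),
    bmi_trend_per_year = 0,
    incidence_jitter_sd = 0.03,
    baseline_yld = 0.10) {
  cfg <- list(
    gompertz = gompertz,
    count_20_24 = count_20_24,
    count_decline_age = count_decline_age,
    count_decline_rate = count_decline_rate,
    obesity_target = obesity_target,
    bmi_sd = bmi_sd,
    height = height,
    bmi_trend_per_year = bmi_trend_per_year,
    incidence_jitter_sd = incidence_jitter_sd,
    baseline_yld = baseline_yld
  )
  if (cfg$count_20_24 <= 0) abort("cohort sizes must be positive")
  class(cfg) <- "pmslt_generator_config"
  cfg
}

#' Generate a synthetic reference population
#'
#' Population counts and all-cause mortality by sex and 5-year age band
#' (20-24 through 95-99).  Mortality follows a Gompertz curve evaluated at
#' band midpoints, which reproduces the exponential rise of adult
#' all-cause mortality with two parameters per sex.
#'
#' @param seed Integer seed (the population table is a deterministic
#'   function of the configuration; the seed is accepted for interface
#'   symmetry with the other generators).
#' @param config A [generator_config()].
#' @return Tibble: `sex`, `age_lo`, `age_group`, `count`,
#'   `mortality_rate` (deaths per person-year).
#' @export
#' @examples
#' generate_population(1)
generate_population <- function(seed = 1L, config = generator_config()) {
  lo <- age_band_los()
  mid <- lo + 2.5
  out <- purrr::map(c("male", "female"), function(sx) {
    g <- config$gompertz[[sx]]
    m <- unname(g["alpha"] * exp(g["beta"] * mid))
    cnt <- config$count_20_24 *
      exp(-config$count_decline_rate * pmax(0, mid - config$count_decline_age))
    tibble(sex = sx, age_lo = lo, age_group = age_band_label(lo),
           count = round(cnt), mortality_rate = pmin(m, 0.999))
  }) %>% list_rbind()
  validate_population(out)
  out
}

# per-disease synthetic epidemiology shape parameters: incidence at age 60
# (per person-year), exponential age slope, onset age, flat case fatality.
synthetic_epi_shapes <- function() {
  tribble(
    ~disease,             ~inc60_m, ~inc60_f, ~slope, ~onset, ~case_fatality,
    "ihd",                 0.008,    0.005,    0.07,    30,    0.05,
    "stroke",              0.003,    0.0025,   0.08,    30,    0.08,
    "hhd",                 0.0008,   0.0008,   0.07,    35,    0.04,
    "diabetes",            0.008,    0.007,    0.04,    25,    0.015,
    "osteoarthritis",      0.008,    0.012,    0.04,    25,    0.0,
    "colon_cancer",        0.0012,   0.0009,   0.06,    30,    0.12,
    "breast_cancer",       0.0,      0.0025,   0.03,    30,    0.06,
    "endometrial_cancer",  0.0,      0.0006,   0.05,    35,    0.05,
    "kidney_cancer",       0.0003,   0.00015,  0.06,    30,    0.12
  )
}

#' Generate synthetic disease epidemiology
#'
#' Incidence, case fatality and remission per person-year for the nine
#' obesity-related diseases by sex and 5-year age band.  Incidence rises
#' log-linearly with age from a disease-specific onset age and plateaus at
#' age 90; remission is 0 for all diseases (chronic-disease convention;
#' cancers are handled through incident-case costing).  Breast and
#' endometrial cancer have zero incidence in men.  A small seeded
#' lognormal jitter (configurable) makes strata realistically noisy while
#' remaining bit-identical for a fixed seed.
#'
#' @inheritParams generate_population
#' @param diseases Character vector of diseases to emit; must be a subset
#'   of [pmslt_diseases()].
#' @return Tibble: `disease`, `sex`, `age_lo`, `incidence`,
#'   `case_fatality`, `remission`.
#' @export
generate_disease_epi <- function(seed = 1L, config = generator_config(),
                                 diseases = pmslt_diseases()) {
  unknown <- setdiff(diseases, pmslt_diseases())
  if (length(unknown)) {
    abort(paste0("unknown disease name(s): ", paste(unknown, collapse = ", ")))
  }
  shapes <- synthetic_epi_shapes() %>% filter(.data$disease %in% diseases)
  lo <- age_band_los()
  mid <- lo + 2.5
  grid <- crossing(shapes, tibble(age_lo = lo, mid = mid),
                   sex = c("male", "female"))
  out <- grid %>%
    mutate(
      inc_base = ifelse(.data$sex == "male", .data$inc60_m, .data$inc60_f),
      eff_age = pmin(.data$mid, 90),
      incidence = ifelse(
        .data$mid < .data$onset, 0,
        .data$inc_base * exp(.data$slope * (.data$eff_age - 60))
      ),
      remission = 0
    )
  # female-only cancers: zero incidence in men (defensive; inc60_m is 0)
  femonly <- names(sex_specific_diseases())
  out$incidence[out$disease %in% femonly & out$sex == "male"] <- 0
  if (config$incidence_jitter_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    jit <- exp(rnorm(nrow(out), 0, config$incidence_jitter_sd))
    out$incidence <- out$incidence * jit
  }
  out <- out %>%
    select("disease", "sex", "age_lo", "incidence", "case_fatality",
           "remission") %>%
    arrange(.data$disease, .data$sex, .data$age_lo)
  validate_disease_epi(out, diseases)
  out
}

#' Generate synthetic BMI distribution parameters
#'
#' Fits a normal BMI model per sex so that the implied obesity prevalence
#' P(BMI >= 30) matches the per-sex target exactly: with sd fixed, the
#' mean is `30 - sd * qnorm(1 - target)`.  The same mean/sd applies to all
#' age bands (plus the optional configured per-year drift, off by
#' default).
#'
#' @inheritParams generate_population
#' @return Tibble: `sex`, `age_lo`, `mean_bmi`, `sd_bmi`, `mean_height`.
#' @export
#' @examples
#' b <- generate_bmi_params(1)
#' # implied male obesity prevalence
#' with(b[b$sex == "male", ][1, ], pnorm(30, mean_bmi, sd_bmi, lower.tail = FALSE))
generate_bmi_params <- function(seed = 1L, config = generator_config()) {
  lo <- age_band_los()
  out <- purrr::map(c("male", "female"), function(sx) {
    target <- config$obesity_target[[sx]]
    if (!is.finite(target) || target <= 0 || target >= 1) {
      abort("obesity prevalence target must lie strictly in (0, 1)")
    }
    sd <- config$bmi_sd[[sx]]
    mean <- 30 - sd * qnorm(1 - target)
    tibble(sex = sx, age_lo = lo, mean_bmi = mean, sd_bmi = sd,
           mean_height = config$height[[sx]])
  }) %>% list_rbind()
  out
}

#' Generate a complete synthetic world
#'
#' Bundles population, disease epidemiology, BMI parameters, and the
#' published relative-risk, disability-weight and disease-cost tables
#' into a single world object consumed by [run_pipeline()].
#'
#' @inheritParams generate_population
#' @return A list of class `pmslt_world` with elements `population`,
#'   `disease_epi`, `bmi`, `rr`, `disability`, `costs`, `baseline_yld`,
#'   `config`.
#' @export
#' @examples
#' world <- synth_world(seed = 1)
#' names(world)
synth_world <- function(seed = 1L, config = generator_config()) {
  world <- list(
    population  = generate_population(seed, config),
    disease_epi = generate_disease_epi(seed, config),
    bmi         = generate_bmi_params(seed, config),
    rr          = default_rr_table(),
    disability  = default_disability_weights(),
    costs       = default_disease_costs(),
    baseline_yld = config$baseline_yld,
    config      = config
  )
  class(world) <- "pmslt_world"
  world
}

#' @export
print.pmslt_world <- function(x, ...) {
  cat("<pmslt_world>\n")
  cat("  population :", nrow(x$population), "sex x age strata,",
      format(sum(x$population$count), big.mark = ","), "persons\n")
  cat("  diseases   :", length(unique(x$disease_epi$disease)), "\n")
  cat("  baseline_yld:", x$baseline_yld, "\n")
  invisible(x)
}

# preserve/restore the global RNG state so generators are pure
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

validate_population <- function(pop) {
  if (any(pop$count < 0)) abort("population counts must be >= 0")
  if (any(pop$mortality_rate <= 0 | pop$mortality_rate >= 1)) {
    abort("mortality_rate must lie strictly in (0, 1)")
  }
  bad <- pop %>%
    filter(.data$age_lo >= 30) %>%
    group_by(.data$sex) %>%
    summarise(mono = all(diff(.data$mortality_rate[order(.data$age_lo)]) >= 0),
              .groups = "drop")
  if (!all(bad$mono)) {
    abort("mortality_rate must be non-decreasing with age above 30 within sex")
  }
  invisible(pop)
}

validate_disease_epi <- function(epi, diseases = pmslt_diseases()) {
  rates <- c(epi$incidence, epi$case_fatality, epi$remission)
  if (any(rates < 0)) abort("epidemiological rates must be >= 0")
  missing <- setdiff(diseases, unique(epi$disease))
  if (length(missing)) {
    abort(paste0("disease_epi is missing: ", paste(missing, collapse = ", ")))
  }
  invisible(epi)
}
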