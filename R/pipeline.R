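# Pipeline orchestration: the proportional multi-state life table.
#
# A "context" precomputes everything that does not depend on drawn
# parameters (expanded rate matrices, the reference arm, quadrature node
# densities, cost lookups); evaluating one parameter draw then only
# recomputes the intervention arm.  This keeps 2000-iteration Monte Carlo
# runs tractable.

#' Scenario configuration
#'
#' Bundles the intervention choice, costing perspective flags, discount
#' rate and sensitivity-scenario toggles.
#'
#' @param drug `"sibutramine"`, `"orlistat"` or `"none"`.
#' @param discount_rate Annual discount rate for costs and benefits
#'   (default 0.03).
#' @param uptake Proportion of the obese recruited (default
#'   [recruitment_fraction()], 83.5% GP contact x 50% willingness).
#' @param regain_rate Regain preset or kg/month (see [weight_effect()]).
#' @param regain_mode `"empirical_rate"` or `"linear_3yr"`.
#' @param permanent_fraction Fraction of the weight loss never regained.
#' @param utility_per_bmi_unit QALY weight credited per BMI-unit-year
#'   lost (0 disables; the published sensitivity value is 0.017).
#' @param disease_free_baseline Start all cohorts free of the nine
#'   diseases?
#' @param age_range Optional length-2 vector restricting cohorts to
#'   baseline ages `[lo, hi)` (e.g. `c(20, 30)` for the 20-29 subgroup).
#' @param threshold Cost-effectiveness threshold in AUD per DALY
#'   (default 50000).
#' @return A list of class `pmslt_scenario`.
#' @export
#' @examples
#' scenario_config("sibutramine")
scenario_config <- function(drug = c("sibutramine", "orlistat", "none"),
                            discount_rate = 0.03,
                            uptake = recruitment_fraction(),
                            regain_rate = "storm",
                            regain_mode = "empirical_rate",
                            permanent_fraction = 0,
                            utility_per_bmi_unit = 0,
                            disease_free_baseline = FALSE,
                            age_range = NULL,
                            threshold = 50000) {
  drug <- match.arg(drug)
  if (discount_rate < 0) abort("discount_rate must be >= 0")
  structure(
    list(drug = drug, discount_rate = discount_rate, uptake = uptake,
         regain_rate = regain_rate, regain_mode = regain_mode,
         permanent_fraction = permanent_fraction,
         utility_per_bmi_unit = utility_per_bmi_unit,
         disease_free_baseline = disease_free_baseline,
         age_range = age_range, threshold = threshold),
    class = "pmslt_scenario"
  )
}

# ---- context ------------------------------------------------------------

pipeline_context <- function(world, scenario) {
  stopifnot(inherits(world, "pmslt_world"))
  diseases <- pmslt_diseases()
  nd <- length(diseases)
  ages <- 20:99                       # age-years simulated (80 cycles)
  nk <- length(ages)
  band_lo <- age_band_los()
  band_of_age <- pmin(findInterval(ages, band_lo), length(band_lo))
  grid <- gl_grid()

  # unique RR schedule entries (rr = 1 entries carry se = 0)
  rrt <- world$rr %>%
    mutate(entry = row_number(),
           ln_se = ifelse(.data$rr == 1, 0, ln_rr_se(.data$lo95, .data$hi95)))
  ent_mat <- matrix(0L, nk, nd, dimnames = list(NULL, diseases))
  for (d in diseases) {
    rd <- rrt %>% filter(.data$disease == d) %>% arrange(.data$age_lo)
    ent_mat[, d] <- rd$entry[pmin(findInterval(ages, rd$age_lo), nrow(rd))]
  }

  per_sex <- list()
  for (sx in c("male", "female")) {
    pop <- world$population %>% filter(.data$sex == sx) %>%
      arrange(.data$age_lo)
    if (!is.null(scenario$age_range)) {
      pop <- pop %>% filter(.data$age_lo >= scenario$age_range[1],
                            .data$age_lo < scenario$age_range[2])
    }
    if (!nrow(pop)) next
    a0 <- pop$age_lo + 2L                 # cohort start: band midpoint age
    a0_idx <- a0 - 19L
    ncoh <- length(a0)

    # expanded rate matrices over single ages
    M <- pop_full <- world$population %>% filter(.data$sex == sx) %>%
      arrange(.data$age_lo)
    M <- pop_full$mortality_rate[band_of_age]
    I <- F_ <- R_ <- matrix(0, nk, nd, dimnames = list(NULL, diseases))
    for (d in diseases) {
      ed <- world$disease_epi %>%
        filter(.data$disease == d, .data$sex == sx) %>% arrange(.data$age_lo)
      if (!nrow(ed)) next
      I[, d] <- ed$incidence[band_of_age]
      F_[, d] <- ed$case_fatality[band_of_age]
      R_[, d] <- ed$remission[band_of_age]
    }

    # BMI stratum per cohort (baseline band), obesity mass, height
    bmi_s <- world$bmi %>% filter(.data$sex == sx) %>% arrange(.data$age_lo)
    bband <- pmin(findInterval(a0, bmi_s$age_lo), nrow(bmi_s))
    mu <- bmi_s$mean_bmi[bband]
    sdv <- bmi_s$sd_bmi[bband]
    height <- bmi_s$mean_height[1]
    p_obese <- pnorm(30, mu, sdv, lower.tail = FALSE)

    # disability weights / cost lookups (missing sex-restricted -> 0)
    dw <- setNames(numeric(nd), diseases)
    dws <- world$disability %>% filter(.data$sex == sx)
    dw[dws$disease] <- dws$weight
    cost_mat <- matrix(0, nk, nd, dimnames = list(NULL, diseases))
    basis <- setNames(character(nd), diseases)
    ct <- world$costs %>% filter(.data$sex == sx)
    for (d in diseases) {
      cd <- ct %>% filter(.data$disease == d) %>% arrange(.data$age_lo)
      if (!nrow(cd)) next
      cost_mat[, d] <- cd$cost[pmin(findInterval(ages, cd$age_lo), nrow(cd))]
      basis[d] <- cd$basis[1]
    }
    ao <- ct %>% filter(.data$disease == "all_other") %>% arrange(.data$age_lo)
    all_other <- ao$cost[pmin(findInterval(ages, ao$age_lo), nrow(ao))]

    # time-since-intervention index (1-based model year), discounting,
    # activity mask
    TI <- outer(seq_len(ncoh), seq_len(nk),
                function(c, k) k - a0_idx[c] + 1L)
    active <- TI >= 1
    disc <- ifelse(active, (1 + scenario$discount_rate)^-(TI - 1), 0)

    # reference arm: baseline prevalence from the synthetic-cohort curve
    # (steady state), or zero for the disease-free-at-baseline scenario
    prev_curve <- matrix(0, nk, nd)
    for (d in seq_len(nd)) {
      prev_curve[, d] <- simulate_disease_path(
        0, I[, d], F_[, d], R_[, d])$prevalence
    }
    p0 <- matrix(0, ncoh, nd)
    if (!scenario$disease_free_baseline) {
      for (d in seq_len(nd)) p0[, d] <- prev_curve[a0_idx, d]
    }

    sdat <- list(
      sex = sx, ncoh = ncoh, a0 = a0, a0_idx = a0_idx, count = pop$count,
      M = M, I = I, F = F_, R = R_, ent_mat = ent_mat,
      mu = mu, sd = sdv, height = height, p_obese = p_obese,
      dw = dw, cost_mat = cost_mat, basis = basis, all_other = all_other,
      TI = TI, active = active, disc = disc, p0 = p0,
      yld0 = world$baseline_yld
    )
    sdat$ref <- propagate_arm(sdat, pif_arr = NULL)
    sdat$ref_lt <- arm_lifetable(sdat, sdat$ref, sdat$ref)
    per_sex[[sx]] <- sdat
  }

  list(
    scenario = scenario, diseases = diseases, ages = ages, nk = nk,
    grid = grid, rr_entries = rrt, per_sex = per_sex,
    n_clamps = 0L
  )
}

# propagate all nine disease models for one arm of one sex.
# pif_arr: NULL (reference) or array [ncoh, nd, nk].
propagate_arm <- function(sdat, pif_arr = NULL) {
  nd <- ncol(sdat$I)
  nk <- nrow(sdat$I)
  ncoh <- sdat$ncoh
  prev <- array(0, c(ncoh, nd, nk))
  increate <- array(0, c(ncoh, nd, nk))
  P <- sdat$p0
  for (k in seq_len(nk)) {
    not_started <- sdat$a0_idx > k
    if (any(not_started)) P[not_started, ] <- sdat$p0[not_started, ]
    prev[, , k] <- P
    ik <- matrix(sdat$I[k, ], ncoh, nd, byrow = TRUE)
    if (!is.null(pif_arr)) ik <- ik * (1 - pif_arr[, , k])
    frk <- matrix(sdat$F[k, ] + sdat$R[k, ], ncoh, nd, byrow = TRUE)
    inc_flow <- (1 - P) * ik
    increate[, , k] <- inc_flow
    P <- pmin(pmax(P + inc_flow - P * frk, 0), 1)
  }
  list(prev = prev, increate = increate)
}

# life table for one arm given its disease paths and the reference paths
# (mortality and disability deltas are taken against the reference).
arm_lifetable <- function(sdat, arm, ref) {
  nd <- ncol(sdat$I)
  nk <- nrow(sdat$I)
  ncoh <- sdat$ncoh
  fmat <- sdat$F
  dprev <- ref$prev - arm$prev                 # >= 0 under beneficial shift
  mdelta <- matrix(0, ncoh, nk)
  ydelta <- matrix(0, ncoh, nk)
  for (d in seq_len(nd)) {
    mdelta <- mdelta + dprev[, d, ] *
      matrix(fmat[, d], ncoh, nk, byrow = TRUE)
    ydelta <- ydelta + dprev[, d, ] * sdat$dw[d]
  }
  m <- matrix(sdat$M, ncoh, nk, byrow = TRUE) - mdelta
  n_clamp <- sum(m < 0)
  m[m < 0] <- 0
  dis <- pmin(pmax(sdat$yld0 - ydelta, 0), 1)
  l <- matrix(0, ncoh, nk + 1)
  l[cbind(seq_len(ncoh), sdat$a0_idx)] <- 1
  for (k in seq_len(nk)) {
    lnew <- l[, k] * exp(-m[, k])
    starting <- sdat$a0_idx == k + 1L
    lnew[starting] <- 1
    l[, k + 1] <- lnew
  }
  L <- (l[, seq_len(nk)] + l[, seq_len(nk) + 1]) / 2
  L[!sdat$active] <- 0
  list(m = m, d = dis, l = l, L = L, Lw = L * (1 - dis), n_clamp = n_clamp)
}

# PIF array for a drug scenario draw: u * (1 - r^-delta_t) * T(r)/E(r)
drug_pif_array <- function(sdat, ctx, r_entries, delta_years, uptake) {
  nd <- length(ctx$diseases)
  nk <- ctx$nk
  ncoh <- sdat$ncoh
  ex <- stratum_rr_expectations(sdat$mu, sdat$sd, r_entries, ctx$grid)
  ratio <- ex$t_obese / ex$e_base              # ncoh x entries
  delta_mat <- matrix(0, ncoh, nk)
  ok <- sdat$TI >= 1 & sdat$TI <= length(delta_years)
  delta_mat[ok] <- delta_years[sdat$TI[ok]]
  pif_arr <- array(0, c(ncoh, nd, nk))
  for (d in seq_len(nd)) {
    ent <- sdat$ent_mat[, d]
    lr <- log(r_entries[ent])                   # length nk
    factor <- 1 - exp(-delta_mat * matrix(lr, ncoh, nk, byrow = TRUE))
    pif_arr[, d, ] <- uptake * factor * ratio[, ent, drop = FALSE]
  }
  pif_arr
}

# PIF array for the ideal (theoretical-minimum) scenario:
# 1 - E_ideal(r) / E_base(r), whole population, all years
ideal_pif_array <- function(sdat, ctx, r_entries) {
  nd <- length(ctx$diseases)
  nk <- ctx$nk
  ncoh <- sdat$ncoh
  ex <- stratum_rr_expectations(sdat$mu, sdat$sd, r_entries, ctx$grid)
  e_ideal <- ideal_rr_expectation(r_entries)
  pif_by_entry <- 1 - matrix(e_ideal, ncoh, length(r_entries),
                             byrow = TRUE) / ex$e_base
  pif_arr <- array(0, c(ncoh, nd, nk))
  for (d in seq_len(nd)) {
    ent <- sdat$ent_mat[, d]
    pif_arr[, d, ] <- pif_by_entry[, ent, drop = FALSE]
  }
  pif_arr
}

# ---- evaluation of one parameter set ------------------------------------

# draw: list(loss_kg, regain_rate, r_entries, minutes_initial,
#            minutes_followup, travel_minutes)
point_draw <- function(ctx) {
  sc <- ctx$scenario
  cp <- default_cost_params()
  dp <- if (sc$drug == "none") NULL else drug_params(sc$drug)
  list(
    loss_kg = if (is.null(dp)) 0 else dp$loss_kg,
    regain_rate = sc$regain_rate,
    r_entries = ctx$rr_entries$rr,
    minutes_initial = tri_mode(cp$minutes_initial),
    minutes_followup = tri_mode(cp$minutes_followup),
    travel_minutes = tri_mode(cp$travel_minutes)
  )
}

eval_draw <- function(ctx, draw, mode = c("drug", "ideal"),
                      detail = FALSE) {
  mode <- match.arg(mode)
  sc <- ctx$scenario
  horizon <- ctx$nk
  effect <- weight_effect(
    loss_kg = draw$loss_kg, regain_rate = draw$regain_rate,
    permanent_fraction = sc$permanent_fraction,
    regain_mode = sc$regain_mode
  )
  delta_kg <- exposure_loss_at_year(effect, seq_len(horizon))
  dalys <- 0
  offsets <- 0
  unrelated <- 0
  bmi_unit_years <- 0
  starters <- 0
  n_clamp <- 0L
  cancers <- c("colon_cancer", "breast_cancer", "endometrial_cancer",
               "kidney_cancer")
  stream_rows <- list()
  py_rows <- list()

  for (sdat in ctx$per_sex) {
    if (mode == "ideal") {
      pif_arr <- ideal_pif_array(sdat, ctx, draw$r_entries)
    } else if (sc$drug == "none" || draw$loss_kg == 0) {
      pif_arr <- NULL
    } else {
      delta_units <- delta_kg / sdat$height^2
      pif_arr <- drug_pif_array(sdat, ctx, draw$r_entries, delta_units,
                                sc$uptake)
    }
    int <- if (is.null(pif_arr)) sdat$ref else propagate_arm(sdat, pif_arr)
    lt_int <- if (is.null(pif_arr)) sdat$ref_lt else
      arm_lifetable(sdat, int, sdat$ref)
    lt_ref <- sdat$ref_lt
    n_clamp <- n_clamp + lt_int$n_clamp
    cnt <- sdat$count
    disc <- sdat$disc
    dalys <- dalys + sum(cnt * rowSums((lt_int$Lw - lt_ref$Lw) * disc))
    if (mode == "drug") {
      for (di in seq_along(ctx$diseases)) {
        d <- ctx$diseases[di]
        if (!nzchar(sdat$basis[d])) next
        inc_av <- (sdat$ref$increate[, di, ] * lt_ref$L -
                     int$increate[, di, ] * lt_int$L) * cnt
        prev_av <- (sdat$ref$prev[, di, ] * lt_ref$L -
                      int$prev[, di, ] * lt_int$L) * cnt
        averted <- if (d %in% cancers) inc_av else prev_av
        offsets <- offsets -
          sum(((averted * disc) %*% sdat$cost_mat[, di]))
        if (detail) {
          idx <- which(sdat$active, arr.ind = TRUE)
          stream_rows[[length(stream_rows) + 1L]] <- tibble(
            disease = d, sex = sdat$sex,
            age = 19L + idx[, 2],
            t = sdat$TI[idx] - 1L,
            incident_cases_averted = inc_av[idx],
            prevalent_case_years_averted = prev_av[idx]
          )
        }
      }
      if (detail) {
        idx <- which(sdat$active, arr.ind = TRUE)
        py_rows[[length(py_rows) + 1L]] <- tibble(
          sex = sdat$sex, age = 19L + idx[, 2], t = sdat$TI[idx] - 1L,
          person_years_added = ((lt_int$L - lt_ref$L) * cnt)[idx]
        )
      }
      unrelated <- unrelated +
        sum(cnt * (((lt_int$L - lt_ref$L) * disc) %*% sdat$all_other))
      treated <- if (sc$drug == "none") 0 else
        cnt * sdat$p_obese * sc$uptake
      starters <- starters + sum(treated)
      delta_units <- delta_kg / sdat$height^2
      dmat <- matrix(0, sdat$ncoh, ctx$nk)
      ok <- sdat$TI >= 1 & sdat$TI <= length(delta_units)
      dmat[ok] <- delta_units[sdat$TI[ok]]
      bmi_unit_years <- bmi_unit_years +
        sum(treated * rowSums(dmat * lt_ref$L * disc))
    }
  }

  if (mode == "ideal") {
    return(list(dalys = dalys, n_clamp = n_clamp))
  }

  # intervention + patient costs, all at model year 0 (undiscounted)
  cost_int <- 0
  cost_pat <- 0
  if (sc$drug != "none") {
    cp <- default_cost_params()
    cp$minutes_initial <- draw$minutes_initial
    cp$minutes_followup <- draw$minutes_followup
    cp$travel_minutes <- draw$travel_minutes
    dp <- drug_params(sc$drug)
    cp$drug_year_cost <- dp$drug_year_cost
    cp$followup_visits <- dp$followup_visits
    per_starter <- intervention_cost_per_starter(
      cp, attrition_spec(dp$attrition), include_patient_costs = TRUE)
    cost_int <- starters * per_starter$health_sector
    cost_pat <- starters * per_starter$patient
  }

  effect_dalys <- dalys
  if (sc$utility_per_bmi_unit > 0) {
    effect_dalys <- add_bmi_utility(dalys, bmi_unit_years,
                                    sc$utility_per_bmi_unit)
  }
  out <- list(
    dalys = dalys,
    effect_dalys = effect_dalys,
    cost_intervention = cost_int,
    cost_patient = cost_pat,
    cost_offsets = offsets,
    cost_unrelated = unrelated,
    bmi_unit_years = bmi_unit_years,
    starters = starters,
    n_clamp = n_clamp
  )
  if (detail) {
    out$streams <- list(
      disease_deltas = list_rbind(stream_rows),
      py_deltas = list_rbind(py_rows)
    )
  }
  out
}

# the three cumulative costing perspectives
perspective_net_costs <- function(res) {
  c(health_sector = res$cost_intervention + res$cost_offsets,
    plus_patient = res$cost_intervention + res$cost_offsets +
      res$cost_patient,
    plus_unrelated = res$cost_intervention + res$cost_offsets +
      res$cost_patient + res$cost_unrelated)
}

#' Run the full cost-effectiveness pipeline deterministically
#'
#' Simulates the reference and intervention populations through the
#' proportional multi-state life table at the point estimates of all
#' parameters, and returns DALYs averted, cost components, and ICERs
#' under the three cumulative costing perspectives (health sector +
#' offsets; + patient time and travel; + unrelated health-care costs in
#' added years of life).
#'
#' @param world A `pmslt_world` (see [synth_world()] / [load_world()]).
#' @param scenario A [scenario_config()].
#' @param compute_burden Also run the ideal (BMI 21, sd 1) scenario and
#'   report the fraction of the total attributable burden averted?
#' @param detail Also return per-stratum averted-case and person-year
#'   streams (`$streams`), suitable for [cost_offsets()] and
#'   [unrelated_costs_in_added_years()].
#' @return A list of class `pmslt_run`: `dalys_averted`,
#'   `effect_dalys`, `costs` (named components), `net_costs` (per
#'   perspective), `icers` (per perspective), `starters`,
#'   `bmi_unit_years`, `burden_dalys` and `burden_fraction` (if
#'   computed), `scenario`.
#' @export
#' @examples
#' \donttest{
#' world <- synth_world(seed = 1)
#' run <- run_pipeline(world, scenario_config("sibutramine"))
#' tidy(run)
#' }
run_pipeline <- function(world, scenario = scenario_config(),
                         compute_burden = FALSE, detail = FALSE) {
  ctx <- pipeline_context(world, scenario)
  res <- eval_draw(ctx, point_draw(ctx), mode = "drug", detail = detail)
  net <- perspective_net_costs(res)
  icers <- vapply(net, function(x) icer(x, res$effect_dalys), numeric(1))
  out <- list(
    dalys_averted = res$dalys,
    effect_dalys = res$effect_dalys,
    costs = res[c("cost_intervention", "cost_patient", "cost_offsets",
                  "cost_unrelated")],
    net_costs = net,
    icers = icers,
    starters = res$starters,
    bmi_unit_years = res$bmi_unit_years,
    n_clamp = res$n_clamp,
    streams = res$streams,
    scenario = scenario
  )
  if (res$n_clamp > 0) {
    warn(sprintf("total mortality clamped to 0 in %d cohort-years",
                 res$n_clamp))
  }
  if (compute_burden) {
    ideal <- eval_draw(ctx, point_draw(ctx), mode = "ideal")
    out$burden_dalys <- ideal$dalys
    out$burden_fraction <- burden_fraction_averted(res$dalys, ideal$dalys)
  }
  class(out) <- "pmslt_run"
  out
}

#' @export
print.pmslt_run <- function(x, ...) {
  cat(sprintf("<pmslt_run: %s>\n", x$scenario$drug))
  cat(sprintf("  DALYs averted : %s\n", format(round(x$dalys_averted))))
  cat(sprintf("  Net cost (health sector): $%s\n",
              format(round(x$net_costs[["health_sector"]]), big.mark = ",")))
  for (p in names(x$icers)) {
    cat(sprintf("  ICER [%s]: %s\n", p, format_icer(x$icers[[p]])))
  }
  if (!is.null(x$burden_fraction)) {
    cat(sprintf("  Burden averted: %.3f%%\n", 100 * x$burden_fraction))
  }
  invisible(x)
}

#' @describeIn run_pipeline Tidy per-perspective summary of a
#'   deterministic run.
#' @param x A `pmslt_run`.
#' @param ... Unused.
#' @export
tidy.pmslt_run <- function(x, ...) {
  tibble(
    perspective = names(x$net_costs),
    dalys_averted = x$dalys_averted,
    net_cost = unname(x$net_costs),
    icer = unname(x$icers)
  )
}

#' @describeIn run_pipeline One-row summary of a deterministic run.
#' @export
glance.pmslt_run <- function(x, ...) {
  tibble(
    drug = x$scenario$drug,
    dalys_averted = x$dalys_averted,
    starters = x$starters,
    icer_health_sector = x$icers[["health_sector"]],
    burden_fraction = x$burden_fraction %||% NA_real_
  )
}
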