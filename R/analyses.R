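# clinical inputs for one strategy arm under the population/endpoint
# settings of the bundle
arm_clinical <- function(par, arm) {
  cl <- if (identical(par$analysis$endpoint, "pacqol")) {
    par$clinical$pacqol[[arm]]
  } else if (identical(par$analysis$population, "women")) {
    par$clinical$female[[arm]]
  } else {
    par$clinical[[arm]]
  }
  cl$switch_response <- par$clinical$switch_response
  cl
}

# run one arm end to end: trace, discounted costs and QALYs
run_arm <- function(par, arm, profiles = NULL) {
  tm <- build_transitions(arm_clinical(par, arm), par$analysis)
  trace <- run_cohort(tm, par$analysis$horizon_months, arm = arm)
  costs <- accrue_costs(trace, arm, par, profiles = profiles)
  qalys <- accrue_qalys(trace, state_utilities(par, arm), par$analysis)
  list(trace = trace, cost = costs$total, qaly = qalys,
       components = costs$component, ledger = costs$ledger)
}

#' Run the deterministic base case
#'
#' Evaluates both strategy arms under the bundle's settings and returns
#' the incremental cost-effectiveness result. Deterministic: re-running
#' with the same bundle is bit-identical.
#'
#' @param par Parameter bundle, e.g. [default_parameters()].
#' @param keep_traces Attach the cohort traces and cost ledgers.
#' @return A `cea_result` with per-arm cost components attached.
#' @export
#' @examples
#' run_base_case(default_parameters())
run_base_case <- function(par, keep_traces = FALSE) {
  profiles <- build_cost_profiles(par)
  a <- run_arm(par, "prucalopride", profiles)
  b <- run_arm(par, "laxative", profiles)
  res <- incremental_analysis(a$cost, b$cost, a$qaly, b$qaly)
  res$components <- rbind(prucalopride = a$components,
                          laxative = b$components)
  if (keep_traces) {
    res$traces <- list(prucalopride = a$trace, laxative = b$trace)
    res$ledgers <- list(prucalopride = a$ledger, laxative = b$ledger)
  }
  res
}

#' Default one-way sensitivity items
#'
#' The four parameters varied one at a time: week-4 and week-12
#' prucalopride response at their 95% interval bounds, and the two DBC
#' tariffs at +/-25%.
#'
#' @param par Parameter bundle.
#' @return Tibble with columns `parameter`, `low`, `high`.
#' @export
default_sensitivity_items <- function(par) {
  bw <- par$clinical$one_way_bounds
  u <- par$costs$units
  tibble::tibble(
    parameter = c("r4", "r12", "dbc_hospitalization", "dbc_specialist"),
    low = c(bw$r4[["low"]], bw$r12[["low"]],
            0.75 * u$dbc_hospitalization, 0.75 * u$dbc_specialist),
    high = c(bw$r4[["high"]], bw$r12[["high"]],
             1.25 * u$dbc_hospitalization, 1.25 * u$dbc_specialist))
}

# set a one-way parameter in a copy of the bundle
apply_one_way <- function(par, parameter, value) {
  if (parameter == "r4") {
    ev <- par$clinical$prucalopride$r4
    base_r4 <- ev$proportion
    par$clinical$prucalopride$r4 <-
      response_evidence(value * ev$total, ev$total)
    if (identical(par$analysis$one_way_r4_coupling, "proportional")) {
      # keep the conditional 12-week retention at its base value
      ev12 <- par$clinical$prucalopride$r12
      scaled <- ev12$proportion * value / base_r4
      par$clinical$prucalopride$r12 <-
        response_evidence(scaled * ev12$total, ev12$total)
    }
  } else if (parameter == "r12") {
    ev <- par$clinical$prucalopride$r12
    par$clinical$prucalopride$r12 <-
      response_evidence(value * ev$total, ev$total)
  } else if (parameter == "dbc_hospitalization") {
    par$costs$units$dbc_hospitalization <- value
  } else if (parameter == "dbc_specialist") {
    par$costs$units$dbc_specialist <- value
  } else {
    stop("unknown one-way parameter: ", parameter)
  }
  par
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the base case at the low and high value of each item with all
#' other parameters fixed. For the week-4 response the week-12 response
#' is scaled proportionally by default, holding the conditional retention
#' fixed (`analysis$one_way_r4_coupling`).
#'
#' @param par Parameter bundle.
#' @param items Tibble `parameter`/`low`/`high`; defaults to
#'   [default_sensitivity_items()].
#' @return Tibble with one row per item: ICER and arm totals at each
#'   bound plus the base ICER, ordered by ICER range (tornado order).
#' @export
run_one_way <- function(par, items = default_sensitivity_items(par)) {
  base <- run_base_case(par)
  one <- function(parameter, value) {
    r <- run_base_case(apply_one_way(par, parameter, value))
    c(cost = r$cost[1], qaly = r$qaly[1], icer = r$icer)
  }
  rows <- lapply(seq_len(nrow(items)), function(i) {
    lo <- one(items$parameter[i], items$low[i])
    hi <- one(items$parameter[i], items$high[i])
    tibble::tibble(parameter = items$parameter[i],
                   low = items$low[i], high = items$high[i],
                   icer_low = lo[["icer"]], icer_high = hi[["icer"]],
                   cost_low = lo[["cost"]], cost_high = hi[["cost"]],
                   qaly_low = lo[["qaly"]], qaly_high = hi[["qaly"]])
  })
  out <- do.call(rbind, rows)
  out$icer_base <- base$icer
  out$range <- abs(out$icer_low - out$icer_high)
  out[order(-out$range), ]
}

#' Scenario analyses
#'
#' Applies exactly one documented setting change and re-runs the model;
#' the input bundle is never modified.
#'
#' Available scenarios: `women_only`, `pacqol_endpoint`,
#' `no_stopping_rule`, `no_complications`, `dose_1_5mg`, `indirect_costs`,
#' `no_transport`, `parking`, `los_hospital_cost`, `horizon_3y`
#' (36 cycles, discounting 4% costs / 1.5% effects), `mortality`
#' (structural hook; `death_prob` defaults to the bundle value of 0
#' because no life-table input ships with the model) and `inflate_2014`
#' (re-expresses tariffs in 2014 euros using the configured post-2011
#' rates, zero by default).
#'
#' @param par Parameter bundle.
#' @param name Scenario label.
#' @param death_prob Monthly death probability for the `mortality`
#'   scenario.
#' @return A `cea_result`.
#' @export
#' @examples
#' run_scenario(default_parameters(), "women_only")$icer
run_scenario <- function(par, name, death_prob = NULL) {
  name <- match.arg(name, c(
    "women_only", "pacqol_endpoint", "no_stopping_rule",
    "no_complications", "dose_1_5mg", "indirect_costs", "no_transport",
    "parking", "los_hospital_cost", "horizon_3y", "mortality",
    "inflate_2014"))
  p <- par
  switch(name,
    women_only = { p$analysis$population <- "women" },
    pacqol_endpoint = { p$analysis$endpoint <- "pacqol" },
    no_stopping_rule = { p$analysis$stopping_rule <- FALSE },
    no_complications = { p$analysis$include_complications <- FALSE },
    dose_1_5mg = { p$analysis$dose <- "1.5mg" },
    indirect_costs = { p$analysis$include_indirect <- TRUE },
    no_transport = { p$analysis$include_transport <- FALSE },
    parking = { p$analysis$include_parking <- TRUE },
    los_hospital_cost = { p$analysis$hospital_costing <- "los_daily" },
    horizon_3y = {
      p$analysis$horizon_months <- 36
      p$analysis$discount_costs <- 0.04
      p$analysis$discount_effects <- 0.015
    },
    mortality = {
      p$analysis$death_prob_monthly <-
        if (is.null(death_prob)) par$analysis$death_prob_monthly
        else death_prob
    },
    inflate_2014 = { p$analysis$inflation_target_year <- 2014 })
  run_base_case(p)
}

#' Run the full scenario battery
#'
#' @param par Parameter bundle.
#' @param names Scenario labels (default: all).
#' @return Tibble with scenario, per-arm totals, increments and ICER.
#' @export
run_all_scenarios <- function(par,
                              names = c("women_only", "pacqol_endpoint",
                                        "no_stopping_rule",
                                        "no_complications", "dose_1_5mg",
                                        "indirect_costs", "no_transport",
                                        "los_hospital_cost", "horizon_3y",
                                        "inflate_2014")) {
  rows <- lapply(names, function(nm) {
    r <- run_scenario(par, nm)
    tibble::tibble(scenario = nm, cost_prucalopride = r$cost[1],
                   cost_laxative = r$cost[2], qaly_prucalopride = r$qaly[1],
                   qaly_laxative = r$qaly[2], delta_cost = r$delta_cost,
                   delta_qaly = r$delta_qaly, icer = r$icer)
  })
  do.call(rbind, rows)
}
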