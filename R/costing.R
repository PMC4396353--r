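# Inflated unit-cost basis used by all costing functions. Every tariff is
# expressed in euros of analysis$inflation_target_year before use.
cost_basis <- function(par) {
  infl <- par$costs$inflation
  target <- par$analysis$inflation_target_year
  u <- par$costs$units
  yr <- u$costing_year
  up <- function(cost, from) inflate_cost(cost, from, target, infl)
  list(
    pcp = up(u$pcp_visit, yr[["pcp_visit"]]),
    pcp_phone = up(u$pcp_phone, yr[["pcp_phone"]]),
    specialist_phone = up(u$specialist_phone, yr[["specialist_phone"]]),
    nurse = up(u$nurse_visit, yr[["nurse_visit"]]),
    nurse_phone = up(u$nurse_phone, yr[["nurse_phone"]]),
    dietician = up(u$dietician_visit, yr[["dietician_visit"]]),
    dbc_specialist = up(u$dbc_specialist, yr[["dbc_specialist"]]),
    dbc_hospitalization = up(u$dbc_hospitalization,
                             yr[["dbc_hospitalization"]]),
    procedures = vapply(par$costs$procedures, up, numeric(1),
                        from = par$costs$transport$costing_year),
    km = up(par$costs$transport$cost_per_km,
            par$costs$transport$costing_year),
    parking = up(par$costs$transport$parking,
                 par$costs$transport$costing_year),
    lax_start = up(weighted_laxative_daily_cost(par, "start"),
                   par$costs$laxatives$costing_year),
    lax_switch = up(weighted_laxative_daily_cost(par, "switch"),
                    par$costs$laxatives$costing_year),
    pr_first = up(prucalopride_daily(par, "first"),
                  par$costs$prucalopride$costing_year),
    pr_after = up(prucalopride_daily(par, "after"),
                  par$costs$prucalopride$costing_year),
    fee = par$costs$prescription_fee)
}

# daily prucalopride price under the dose setting; the 1.5 mg scenario
# prices the day at the mean of the 1 mg and 2 mg rates
prucalopride_daily <- function(par, phase = c("first", "after")) {
  phase <- match.arg(phase)
  key <- if (phase == "first") "first_pack_daily" else "after_daily"
  p <- par$costs$prucalopride
  if (identical(par$analysis$dose, "1.5mg"))
    (p$mg1[[key]] + p$mg2[[key]]) / 2
  else p$mg2[[key]]
}

switch_states <- function() {
  c("SWITCH_W1_4", "SWITCH_W5_8", "SWITCH_W9_12", "SWITCH_MAINTENANCE",
    "DROPOUT")
}

#' Drug cost of one state in one cycle
#'
#' Prucalopride-arm start states are priced at the daily drug rate (the
#' 28-day first pack in cycle 1, the post-pack rate over a 30.4-day cycle
#' thereafter) plus one prescription fee per dispensing. In maintenance
#' the annual treatment-days (130 in year 1 after the 90-day start phase,
#' the 220-day cap in later years) are spread uniformly over the
#' maintenance cycles of that year. All switch and drop-out states, and
#' every state of the comparator arm, carry the Delphi-weighted laxative
#' basket (switch-phase weights after a switch, start weights otherwise).
#'
#' @param arm `"prucalopride"` or `"laxative"`.
#' @param state A health state label.
#' @param cycle 1-based cycle (month) index.
#' @param par Parameter bundle.
#' @return Cost in target-year euros for a patient spending the cycle in
#'   `state`.
#' @export
#' @examples
#' par <- default_parameters()
#' drug_cost_per_cycle("prucalopride", "START_W1_4", 1, par)
drug_cost_per_cycle <- function(arm, state, cycle, par, basis = NULL) {
  if (!state %in% health_states()) stop("unknown state: ", state)
  arm <- match.arg(arm, c("prucalopride", "laxative"))
  b <- if (is.null(basis)) cost_basis(par) else basis
  dc <- par$analysis$cycle_days
  fee <- b$fee
  lax <- function(daily) daily * dc + fee
  if (arm == "laxative")
    return(if (state %in% switch_states()) lax(b$lax_switch)
           else lax(b$lax_start))
  if (state %in% switch_states()) return(lax(b$lax_switch))
  if (state == "START_W1_4")
    return(b$pr_first * par$analysis$first_pack_days + fee)
  if (state %in% c("START_W5_8", "START_W9_12"))
    return(b$pr_after * dc + fee)
  # MAINTENANCE: annual treatment days spread over that year's cycles
  sched <- par$costs$prucalopride
  year <- (cycle - 1) %/% 12 + 1
  if (year == 1) {
    days <- sched$first_year_maintenance_days
    n_cycles <- 9  # months 4-12 after the 90-day start phase
  } else {
    days <- sched$annual_cap_days
    n_cycles <- 12
  }
  (days * b$pr_after + (days / 28) * fee) / n_cycles
}

#' Medical resource cost of one state per cycle
#'
#' Monthly consultation and procedure counts of the state's phase column
#' priced at the inflated tariffs: specialist visits at the DBC
#' polyclinic tariff, procedures at their configured prices (zero by
#' default, treated as bundled in the DBC tariff).
#'
#' @inheritParams drug_cost_per_cycle
#' @return Cost in target-year euros per cycle.
#' @export
resource_cost_per_cycle <- function(state, par, basis = NULL) {
  phase <- par$analysis$resource_states[[state]]
  if (is.null(phase)) stop("state not mapped to a resource phase: ", state)
  q <- par$resources$phases[[phase]]
  b <- if (is.null(basis)) cost_basis(par) else basis
  q[["specialist_consult"]] * b$dbc_specialist +
    q[["specialist_phone"]] * b$specialist_phone +
    q[["pcp_consult"]] * b$pcp +
    q[["pcp_phone"]] * b$pcp_phone +
    q[["nurse_consult"]] * b$nurse +
    q[["dietician_consult"]] * b$dietician +
    sum(q[names(b$procedures)] * b$procedures)
}

# expected hospitalization cost per complication event
complication_hospital_cost <- function(par, b = cost_basis(par)) {
  items <- par$complications$items
  if (identical(par$analysis$hospital_costing, "los_daily")) {
    # daily cost anchored so that the scenario is cost-neutral at the
    # probability-weighted mean length of stay
    wts <- vapply(items, function(it) it$prob[["switch"]], numeric(1))
    los <- vapply(items, `[[`, numeric(1), "los_days")
    daily <- b$dbc_hospitalization / stats::weighted.mean(los, wts)
    vapply(items, function(it) it$los_days * daily, numeric(1))
  } else {
    rep(b$dbc_hospitalization, length(items))
  }
}

#' Expected complication cost of one state per cycle
#'
#' For states with an assigned complication probability column, sums over
#' the six complications: monthly probability (period-adjusted via
#' [period_to_monthly()]) times the event cost (PCP and specialist
#' consultations plus the expected hospitalization cost). States mapped
#' to `"none"` - by default all states whose phase resource profiles
#' already reflect complication-related care - cost nothing here, as does
#' everything when `include_complications` is off.
#'
#' @inheritParams drug_cost_per_cycle
#' @return Cost in target-year euros per cycle.
#' @export
complication_cost_per_cycle <- function(state, par, basis = NULL) {
  col <- par$analysis$complication_states[[state]]
  if (is.null(col)) stop("state not mapped for complications: ", state)
  if (identical(col, "none") || !isTRUE(par$analysis$include_complications))
    return(0)
  b <- if (is.null(basis)) cost_basis(par) else basis
  items <- par$complications$items
  k <- par$complications$period_months[[col]]
  hosp <- complication_hospital_cost(par, b)
  total <- 0
  for (i in seq_along(items)) {
    it <- items[[i]]
    pm <- period_to_monthly(it$prob[[col]], k,
                            par$analysis$probability_conversion)
    total <- total + pm * (it$pcp_consults * b$pcp +
                           it$specialist_consults * b$dbc_specialist +
                           it$hospitalization_fraction * hosp[i])
  }
  total
}

#' Transport cost of one state per cycle
#'
#' Round-trip travel for every face-to-face contact (specialist, PCP,
#' nurse at the PCP surgery, dietician) at the per-kilometre tariff, plus
#' travel for complication-related consultations in states with explicit
#' complication costing. Telephone contacts incur none. Parking is added
#' per visit only in the parking scenario; everything is zero when
#' transport is excluded.
#'
#' @inheritParams drug_cost_per_cycle
#' @return Cost in target-year euros per cycle.
#' @export
transport_cost_per_cycle <- function(state, par, basis = NULL) {
  if (!isTRUE(par$analysis$include_transport)) return(0)
  b <- if (is.null(basis)) cost_basis(par) else basis
  tr <- par$costs$transport
  phase <- par$analysis$resource_states[[state]]
  q <- par$resources$phases[[phase]]
  visits <- c(specialist = q[["specialist_consult"]],
              pcp = q[["pcp_consult"]], nurse = q[["nurse_consult"]],
              dietician = q[["dietician_consult"]])
  km <- c(specialist = tr$km_specialist, pcp = tr$km_pcp, nurse = tr$km_pcp,
          dietician = tr$km_dietician)
  total <- sum(visits * 2 * km * b$km)
  if (isTRUE(par$analysis$include_parking))
    total <- total + sum(visits) * b$parking
  col <- par$analysis$complication_states[[state]]
  if (!identical(col, "none") && isTRUE(par$analysis$include_complications)) {
    k <- par$complications$period_months[[col]]
    for (it in par$complications$items) {
      pm <- period_to_monthly(it$prob[[col]], k,
                              par$analysis$probability_conversion)
      cvis <- pm * c(it$pcp_consults, it$specialist_consults)
      total <- total + sum(cvis * 2 * c(tr$km_pcp, tr$km_specialist) * b$km)
      if (isTRUE(par$analysis$include_parking))
        total <- total + sum(cvis) * b$parking
    }
  }
  total
}

#' Productivity loss of one state per cycle (scenario only)
#'
#' Human-capital costing of work absence for the cohort fractions without
#' a treatment response: working-age share x share reporting absence x
#' days missed per month x hours per working day x cost per hour.
#' Responder states (`MAINTENANCE`, `SWITCH_MAINTENANCE`) and the base
#' case (flag off) cost nothing.
#'
#' @inheritParams drug_cost_per_cycle
#' @return Cost in euros per cycle.
#' @export
indirect_cost_per_cycle <- function(state, par) {
  if (!isTRUE(par$analysis$include_indirect)) return(0)
  if (state %in% c("MAINTENANCE", "SWITCH_MAINTENANCE")) return(0)
  ind <- par$indirect
  ind$working_age_share * ind$share_absent * ind$days_per_month *
    ind$hours_per_day * ind$cost_per_hour
}

#' One-off work-up cost charged per treatment failure
#'
#' Delphi practice after a treatment failure: referral to a specialist
#' (28.2%, priced at the DBC polyclinic tariff) or hospitalization
#' (4.9%, DBC hospitalization tariff). Charged once per failure event:
#' entries into `SWITCH_W1_4` and, with `failure_workup = "all"`
#' (default), entries into `DROPOUT`; `"initial"` restricts it to initial
#' failures and `"off"` disables it.
#'
#' @param par Parameter bundle.
#' @return Expected cost in target-year euros per failure event.
#' @export
failure_workup_cost <- function(par, basis = NULL) {
  if (identical(par$analysis$failure_workup, "off")) return(0)
  b <- if (is.null(basis)) cost_basis(par) else basis
  fp <- par$clinical$failure_practice
  fp$referral_specialist * b$dbc_specialist +
    fp$hospitalization * b$dbc_hospitalization
}

#' Per-state cost profiles for both arms
#'
#' Composes the drug, resource, complication, transport and indirect
#' costing operations for every state into the per-cycle profiles
#' consumed by the analysis layer.
#'
#' @param par Parameter bundle.
#' @return List with per-arm component matrices (`state x component` for
#'   cycle-invariant components), a `drug(arm, cycle)` function and the
#'   per-failure work-up cost.
#' @export
build_cost_profiles <- function(par) {
  states <- health_states()
  b <- cost_basis(par)
  fixed <- cbind(
    resource = vapply(states, resource_cost_per_cycle, numeric(1),
                      par = par, basis = b),
    complication = vapply(states, complication_cost_per_cycle, numeric(1),
                          par = par, basis = b),
    transport = vapply(states, transport_cost_per_cycle, numeric(1),
                       par = par, basis = b),
    indirect = vapply(states, indirect_cost_per_cycle, numeric(1),
                      par = par))
  horizon <- par$analysis$horizon_months
  drug_arr <- lapply(
    c(prucalopride = "prucalopride", laxative = "laxative"),
    function(arm) {
      m <- vapply(seq_len(horizon), function(t)
        vapply(states, drug_cost_per_cycle, numeric(1),
               arm = arm, cycle = t, par = par, basis = b),
        numeric(length(states)))
      dimnames(m) <- list(states, NULL)
      m
    })
  drug <- function(arm, cycle) {
    if (cycle <= horizon) drug_arr[[arm]][, cycle]
    else vapply(states, drug_cost_per_cycle, numeric(1),
                arm = arm, cycle = cycle, par = par, basis = b)
  }
  list(fixed = fixed, drug = drug,
       failure_workup = failure_workup_cost(par, basis = b))
}

#' Accrue discounted costs over a cohort trace
#'
#' @param trace A `cc_trace` from [run_cohort()].
#' @param arm `"prucalopride"` or `"laxative"`.
#' @param par Parameter bundle.
#' @param profiles Optional precomputed [build_cost_profiles()] result.
#' @return List with `total`, per-`component` totals, and a tidy
#'   `ledger` tibble (arm, cycle, component, cost).
#' @export
accrue_costs <- function(trace, arm, par, profiles = NULL) {
  if (is.null(profiles)) profiles <- build_cost_profiles(par)
  occ <- trace$occupancy
  horizon <- trace$horizon
  comp_names <- c("drug", colnames(profiles$fixed), "failure_workup")
  ledger <- matrix(0, horizon, length(comp_names),
                   dimnames = list(NULL, comp_names))
  workup_mode <- par$analysis$failure_workup
  for (t in seq_len(horizon)) {
    during <- occ[t, ]  # state occupied during month t
    df <- discount_factor(t, par$analysis$discount_costs)
    ledger[t, "drug"] <- df * sum(during * profiles$drug(arm, t))
    for (cmp in colnames(profiles$fixed))
      ledger[t, cmp] <- df * sum(during * profiles$fixed[, cmp])
    if (profiles$failure_workup > 0) {
      # SWITCH_W1_4 is transient, so its occupants are this month's new
      # failures; dropout entries are the increments of the D column
      events <- during[["SWITCH_W1_4"]]
      if (identical(workup_mode, "all") && t > 1)
        events <- events + max(0, occ[t, "DROPOUT"] - occ[t - 1, "DROPOUT"])
      ledger[t, "failure_workup"] <- df * events * profiles$failure_workup
    }
  }
  tidy <- tibble::tibble(
    arm = arm,
    cycle = rep(seq_len(horizon), times = length(comp_names)),
    component = rep(comp_names, each = horizon),
    cost = as.vector(ledger))
  list(total = sum(ledger), component = colSums(ledger), ledger = tidy)
}
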