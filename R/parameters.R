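#' Response evidence from trial counts
#'
#' A binomial responder count with its proportion, the unit of clinical
#' evidence feeding the transition model and the probabilistic analysis.
#'
#' @param responders Number of responders (0 <= responders <= total).
#' @param total Number of patients at risk (> 0).
#' @return A list with elements `responders`, `total`, `proportion`.
#' @export
#' @examples
#' response_evidence(178, 640)  # week-4 response, prucalopride 2 mg
response_evidence <- function(responders, total) {
  if (length(responders) != 1L || length(total) != 1L ||
      is.na(responders) || is.na(total)) {
    stop("responders and total must be single non-missing numbers")
  }
  if (total <= 0) stop("response evidence: total must be > 0")
  if (responders < 0 || responders > total) {
    stop("response evidence: need 0 <= responders <= total, got ",
         responders, "/", total)
  }
  structure(list(responders = responders, total = total,
                 proportion = responders / total),
            class = "response_evidence")
}

#' Default model parameters
#'
#' The complete default parameter bundle: pooled pivotal-trial response
#' rates, Delphi-panel switch/failure-practice/complication estimates,
#' per-state utilities mapped from PAC-QOL to EQ-5D, monthly resource-use
#' profiles, Dutch 2009-2011 tariffs and drug prices, and the analysis
#' settings of the 1-year base case. All currency values are euros in
#' their original costing year; costs are inflated to
#' `analysis$inflation_target_year` when cycle costs are computed.
#'
#' @return A nested list of class `cc_parameters`.
#' @export
#' @examples
#' par <- default_parameters()
#' par$clinical$prucalopride$r4$proportion  # 0.278
default_parameters <- function() {
  par <- list(
    clinical = list(
      prucalopride = list(r4 = response_evidence(178, 640),
                          r12 = response_evidence(151, 640)),
      laxative = list(r4 = response_evidence(68, 645),
                      r12 = response_evidence(73, 645)),
      female = list(
        prucalopride = list(r4 = response_evidence(166, 566),
                            r12 = response_evidence(138, 566)),
        laxative = list(r4 = response_evidence(58, 580),
                        r12 = response_evidence(62, 580))),
      pacqol = list(
        prucalopride = list(r4 = response_evidence(271, 598),
                            r12 = response_evidence(273, 621)),
        laxative = list(r4 = response_evidence(129, 605),
                        r12 = response_evidence(137, 618))),
      switch_response = 0.654,
      # practice after a treatment failure (Delphi): one-off work-up
      failure_practice = list(referral_specialist = 0.282,
                              hospitalization = 0.049,
                              none = 0.669),
      # printed one-way bounds for the response parameters (2.5%/97.5%)
      one_way_bounds = list(r4 = c(low = 0.244, high = 0.314),
                            r12 = c(low = 0.204, high = 0.250))),
    utilities = list(
      prucalopride = c(start = 0.786, weeks5_12 = 0.813, maintenance = 0.890),
      laxative = c(start = 0.781, weeks5_12 = 0.805, maintenance = 0.879),
      switch = c(start = 0.784, maintenance = 0.879, dropout = 0.784)),
    complications = list(
      # period probability per phase, monthly consults, hospitalization
      items = list(
        hemorrhoids = list(prob = c(weeks1_4 = 0.190, weeks5_12 = 0.220,
                                    switch = 0.120),
                           pcp_consults = 2.2, specialist_consults = 1.5,
                           hospitalization_fraction = 0.017, los_days = 1.0),
        anal_fissures = list(prob = c(weeks1_4 = 0.070, weeks5_12 = 0.110,
                                      switch = 0.060),
                             pcp_consults = 2.3, specialist_consults = 1.0,
                             hospitalization_fraction = 0.017, los_days = 3.0),
        fecal_incontinence = list(prob = c(weeks1_4 = 0.080,
                                           weeks5_12 = 0.070, switch = 0.060),
                                  pcp_consults = 1.8,
                                  specialist_consults = 1.6,
                                  hospitalization_fraction = 0.089,
                                  los_days = 4.5),
        perianal_thrombosis = list(prob = c(weeks1_4 = 0.070,
                                            weeks5_12 = 0.090, switch = 0.020),
                                   pcp_consults = 2.0,
                                   specialist_consults = 1.1,
                                   hospitalization_fraction = 0.056,
                                   los_days = 1.7),
        rectal_prolapse = list(prob = c(weeks1_4 = 0.034, weeks5_12 = 0.050,
                                        switch = 0.008),
                               pcp_consults = 1.2, specialist_consults = 1.7,
                               hospitalization_fraction = 0.367,
                               los_days = 5.2),
        fecal_impaction = list(prob = c(weeks1_4 = 0.141, weeks5_12 = 0.154,
                                        switch = 0.038),
                               pcp_consults = 1.8, specialist_consults = 1.2,
                               hospitalization_fraction = 0.162,
                               los_days = 3.0)),
      # elicitation period of each probability column, in months
      period_months = c(weeks1_4 = 1, weeks5_12 = 2, switch = 3)),
    resources = list(
      # monthly counts per phase column
      phases = list(
        weeks1_4 = c(specialist_consult = 0.6, specialist_phone = 0.3,
                     pcp_consult = 0.9, pcp_phone = 0.6, nurse_consult = 0.2,
                     dietician_consult = 0.1, colonoscopy = 0.6,
                     rectal_exam = 0.8, anoscopy = 0.2, blood_tests = 0.8,
                     radiograph = 0.2, gi_transit = 0.2, enema = 0.3),
        weeks5_12 = c(specialist_consult = 0.6, specialist_phone = 0.6,
                      pcp_consult = 1.0, pcp_phone = 1.1, nurse_consult = 0.2,
                      dietician_consult = 0.2, colonoscopy = 0.5,
                      rectal_exam = 0.6, anoscopy = 0.5, blood_tests = 0.9,
                      radiograph = 0.7, gi_transit = 0.0, enema = 0.6),
        maintenance = c(specialist_consult = 0.4, specialist_phone = 0.4,
                        pcp_consult = 0.7, pcp_phone = 0.5,
                        nurse_consult = 0.2, dietician_consult = 0.3,
                        colonoscopy = 0.4, rectal_exam = 0.4, anoscopy = 0.1,
                        blood_tests = 0.5, radiograph = 0.5, gi_transit = 0.0,
                        enema = 0.5),
        switch_weeks1_4 = c(specialist_consult = 0.8, specialist_phone = 0.4,
                            pcp_consult = 0.7, pcp_phone = 0.3,
                            nurse_consult = 0.2, dietician_consult = 0.2,
                            colonoscopy = 0.4, rectal_exam = 0.6,
                            anoscopy = 0.2, blood_tests = 0.0,
                            radiograph = 0.3, gi_transit = 0.2, enema = 0.2),
        switch_maintenance = c(specialist_consult = 0.3,
                               specialist_phone = 0.1, pcp_consult = 0.6,
                               pcp_phone = 0.3, nurse_consult = 0.1,
                               dietician_consult = 0.1, colonoscopy = 0.2,
                               rectal_exam = 0.3, anoscopy = 0.2,
                               blood_tests = 0.0, radiograph = 0.1,
                               gi_transit = 0.1, enema = 0.0))),
    costs = list(
      prucalopride = list(
        mg2 = c(first_pack_daily = 2.77, after_daily = 2.49),
        mg1 = c(first_pack_daily = 1.95, after_daily = 1.62),
        costing_year = 2010,
        annual_cap_days = 220, first_year_maintenance_days = 130),
      prescription_fee = 6.35,
      laxatives = list(
        items = list(
          movicolon = c(daily_cost = 0.48, start_share = 0.42,
                        switch_share = 0.27),
          bisacodyl = c(daily_cost = 0.17, start_share = 0.08,
                        switch_share = 0.17),
          forlax = c(daily_cost = 0.61, start_share = 0.15,
                     switch_share = 0.07),
          metamucil = c(daily_cost = 0.60, start_share = 0.18,
                        switch_share = 0.23),
          lactulose = c(daily_cost = 0.23, start_share = 0.17,
                        switch_share = 0.00),
          magnesium_oxide = c(daily_cost = 0.21, start_share = 0.00,
                              switch_share = 0.26)),
        costing_year = 2010),
      units = list(
        pcp_visit = 28.00, specialist_visit_manual = 72.00,
        pcp_phone = 14.00, specialist_phone = 14.00, nurse_visit = 10.00,
        nurse_phone = 0.00, dietician_visit = 27.00,
        dbc_specialist = 195.89, dbc_hospitalization = 3102.00,
        costing_year = c(pcp_visit = 2009, specialist_visit_manual = 2009,
                         pcp_phone = 2009, specialist_phone = 2009,
                         nurse_visit = 2009, nurse_phone = 2009,
                         dietician_visit = 2009, dbc_specialist = 2010,
                         dbc_hospitalization = 2010)),
      # procedure tariffs default to zero: diagnostic work-up is treated as
      # bundled in the DBC polyclinic tariff applied to specialist visits
      procedures = c(colonoscopy = 0, rectal_exam = 0, anoscopy = 0,
                     blood_tests = 0, radiograph = 0, gi_transit = 0,
                     enema = 0),
      transport = list(km_pcp = 1.1, km_specialist = 7.0, km_dietician = 1.7,
                       cost_per_km = 0.20, parking = 3.00,
                       costing_year = 2009),
      inflation = c(`2009` = 0.012, `2010` = 0.013, `2011` = 0,
                    `2012` = 0, `2013` = 0)),
    indirect = list(share_absent = 0.12, days_per_month = 2.4,
                    cost_per_hour = 26.99, annual_hours = 1540,
                    working_age_share = 0.870, hours_per_day = 8),
    analysis = list(
      horizon_months = 12, cycle_days = 30.4, first_pack_days = 28,
      discount_costs = 0, discount_effects = 0,
      stopping_rule = TRUE, include_complications = TRUE,
      include_transport = TRUE, include_indirect = FALSE,
      include_parking = FALSE,
      dose = "2mg", population = "all", endpoint = "bowel_function",
      hospital_costing = "dbc_fixed", inflation_target_year = 2011,
      death_prob_monthly = 0,
      # one-off failure work-up: "all" failures, "initial" only, or "off"
      failure_workup = "all",
      # complication probability column applied per state ("none" = no
      # explicit complication costing in that state)
      complication_states = c(
        START_W1_4 = "none", START_W5_8 = "none", START_W9_12 = "none",
        MAINTENANCE = "none", SWITCH_W1_4 = "switch", SWITCH_W5_8 = "none",
        SWITCH_W9_12 = "none", SWITCH_MAINTENANCE = "none",
        DROPOUT = "switch"),
      # resource-profile column applied per state
      resource_states = c(
        START_W1_4 = "weeks1_4", START_W5_8 = "weeks5_12",
        START_W9_12 = "weeks5_12", MAINTENANCE = "maintenance",
        SWITCH_W1_4 = "switch_weeks1_4", SWITCH_W5_8 = "switch_weeks1_4",
        SWITCH_W9_12 = "switch_weeks1_4",
        SWITCH_MAINTENANCE = "switch_maintenance",
        DROPOUT = "switch_weeks1_4"),
      one_way_r4_coupling = "proportional",
      week12_failure_split = "late",
      probability_conversion = "rate",
      psa = list(se_probability_frac = 0.20, se_utility = 0.05,
                 se_quantity_frac = 0.25, n_draws = 5000,
                 threshold_max = 80000, threshold_step = 1000)))
  class(par) <- "cc_parameters"
  validate_parameters(par)
  par
}

#' Validate a parameter bundle
#'
#' Checks every type invariant (probabilities in `[0, 1]`, non-negative
#' costs and counts, laxative shares summing to one, drug-schedule day
#' caps) and fails with the offending key in the message.
#'
#' @param par A parameter bundle as returned by [default_parameters()].
#' @return The bundle, invisibly, if valid.
#' @export
validate_parameters <- function(par) {
  fail <- function(key, msg) stop("invalid parameter '", key, "': ", msg,
                                  call. = FALSE)
  chk_prob <- function(x, key) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      fail(key, "must be a probability in [0, 1]")
  }
  chk_nonneg <- function(x, key) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
      fail(key, "must be non-negative")
  }
  for (arm in c("prucalopride", "laxative")) {
    for (ep in c("r4", "r12")) {
      ev <- par$clinical[[arm]][[ep]]
      if (ev$total <= 0) fail(paste0("clinical.", arm, ".", ep), "total = 0")
      if (ev$responders < 0 || ev$responders > ev$total)
        fail(paste0("clinical.", arm, ".", ep),
             "responders outside [0, total]")
      if (abs(ev$proportion - ev$responders / ev$total) > 5e-4)
        fail(paste0("clinical.", arm, ".", ep),
             "proportion inconsistent with counts")
    }
  }
  chk_prob(par$clinical$switch_response, "clinical.switch_response")
  chk_prob(unlist(par$clinical$failure_practice),
           "clinical.failure_practice")
  for (grp in names(par$utilities))
    chk_prob(par$utilities[[grp]], paste0("utilities.", grp))
  for (cm in names(par$complications$items)) {
    it <- par$complications$items[[cm]]
    chk_prob(it$prob, paste0("complications.", cm, ".prob"))
    chk_prob(it$hospitalization_fraction,
             paste0("complications.", cm, ".hospitalization_fraction"))
    chk_nonneg(c(it$pcp_consults, it$specialist_consults, it$los_days),
               paste0("complications.", cm, ".counts"))
  }
  for (ph in names(par$resources$phases))
    chk_nonneg(par$resources$phases[[ph]], paste0("resources.", ph))
  sched <- par$costs$prucalopride
  chk_nonneg(c(sched$mg2, sched$mg1), "costs.prucalopride.daily")
  if (sched$first_year_maintenance_days <= 0 ||
      sched$first_year_maintenance_days > sched$annual_cap_days ||
      sched$annual_cap_days > 366)
    fail("costs.prucalopride.days",
         "need 0 < maintenance days <= cap <= 366")
  for (phase in c("start_share", "switch_share")) {
    s <- sum(vapply(par$costs$laxatives$items, `[[`, numeric(1), phase))
    if (abs(s - 1) > 0.005)
      fail(paste0("costs.laxatives.", phase),
           sprintf("shares sum to %.4f, not 1", s))
  }
  chk_nonneg(unlist(par$costs$units[setdiff(names(par$costs$units),
                                            "costing_year")]), "costs.units")
  chk_nonneg(par$costs$procedures, "costs.procedures")
  chk_nonneg(unlist(par$costs$transport), "costs.transport")
  chk_nonneg(unlist(par$indirect), "indirect")
  chk_prob(c(par$indirect$share_absent, par$indirect$working_age_share),
           "indirect.fractions")
  a <- par$analysis
  if (a$horizon_months < 3) fail("analysis.horizon_months", "must be >= 3")
  chk_prob(c(a$discount_costs, a$discount_effects), "analysis.discounting")
  chk_prob(a$death_prob_monthly, "analysis.death_prob_monthly")
  if (!a$dose %in% c("2mg", "1.5mg")) fail("analysis.dose", "2mg or 1.5mg")
  if (!a$failure_workup %in% c("off", "initial", "all"))
    fail("analysis.failure_workup", "off, initial or all")
  if (!all(a$complication_states %in%
           c("none", "weeks1_4", "weeks5_12", "switch")))
    fail("analysis.complication_states", "unknown probability column")
  if (!identical(sort(names(a$complication_states)), sort(health_states())))
    fail("analysis.complication_states", "must map all nine states")
  if (!all(a$resource_states %in% names(par$resources$phases)))
    fail("analysis.resource_states", "unknown resource phase")
  invisible(par)
}

#' Convert a period probability to a monthly probability
#'
#' Constant-rate conversion `1 - (1 - p)^(1/k)`, the standard actuarial
#' adjustment used to align elicited multi-week probabilities with the
#' 1-month model cycle. A naive division alternative (`p / k`) is
#' available for calibration comparisons.
#'
#' @param p Period probability in `[0, 1]`.
#' @param period_months Length of the elicitation period in months (>= 1).
#' @param method `"rate"` (default, constant hazard) or `"linear"`.
#' @return Monthly probability in `[0, 1]`.
#' @export
#' @examples
#' period_to_monthly(0.22, 2)  # 0.1168...
period_to_monthly <- function(p, period_months, method = "rate") {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (any(period_months < 1)) stop("period_months must be >= 1")
  switch(match.arg(method, c("rate", "linear")),
         rate = 1 - (1 - p)^(1 / period_months),
         linear = pmin(1, p / period_months))
}

#' Inflate a cost between costing years
#'
#' Multiplies by `(1 + rate_y)` for every year `y` from `from_year` to
#' `to_year - 1`; the rate labelled with a year covers the step from that
#' year to the next.
#'
#' @param cost Cost in `from_year` euros.
#' @param from_year,to_year Integer years, `to_year >= from_year`.
#' @param rates Named numeric vector of annual rates (names are years).
#' @return Cost expressed in `to_year` euros.
#' @export
#' @examples
#' inflate_cost(28, 2009, 2011, c(`2009` = 0.012, `2010` = 0.013))
inflate_cost <- function(cost, from_year, to_year, rates) {
  if (to_year < from_year) stop("to_year must be >= from_year")
  if (to_year == from_year) return(cost)
  years <- seq(from_year, to_year - 1)
  idx <- as.character(years)
  if (!all(idx %in% names(rates)))
    stop("missing inflation rate for year(s): ",
         paste(setdiff(idx, names(rates)), collapse = ", "))
  cost * prod(1 + rates[idx])
}

#' Weighted daily cost of the laxative basket
#'
#' Delphi-weighted average of the daily costs of the six laxatives, using
#' the start-of-therapy or after-switch distribution.
#'
#' @param par Parameter bundle.
#' @param phase `"start"` or `"switch"`.
#' @return Daily cost in basket costing-year euros.
#' @export
#' @examples
#' weighted_laxative_daily_cost(default_parameters(), "start")  # 0.4538
weighted_laxative_daily_cost <- function(par, phase = c("start", "switch")) {
  phase <- match.arg(phase)
  key <- paste0(phase, "_share")
  items <- par$costs$laxatives$items
  shares <- vapply(items, `[[`, numeric(1), key)
  if (abs(sum(shares) - 1) > 0.005)
    stop("laxative ", phase, " shares sum to ", sum(shares), ", not 1")
  sum(shares * vapply(items, `[[`, numeric(1), "daily_cost"))
}

#' Wilson score interval for a binomial proportion
#'
#' @param evidence A [response_evidence()] object (or list with
#'   `responders` and `total`).
#' @param level Two-sided confidence level in (0, 1), default 0.95.
#' @return Named vector `c(low, high)`.
#' @export
#' @examples
#' proportion_ci(response_evidence(178, 640))  # c(0.2447, 0.3140)
proportion_ci <- function(evidence, level = 0.95) {
  n <- evidence$total
  if (n <= 0) stop("total must be > 0")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  p <- evidence$responders / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Tabulate the default parameters against their documented sources
#'
#' One row per scalar default with its value and data source, exportable
#' as CSV. Used by the test suite to pin every default to its documented
#' value in a single place.
#'
#' @return A tibble with columns `parameter`, `value`, `source`.
#' @export
parameter_table <- function() {
  par <- default_parameters()
  rows <- list(
    c("clinical.prucalopride.r4", 178 / 640, "pooled trials, week-4 response"),
    c("clinical.prucalopride.r12", 151 / 640,
      "pooled trials, weeks 1-12 response"),
    c("clinical.laxative.r4", 68 / 645, "pooled trials, placebo proxy week 4"),
    c("clinical.laxative.r12", 73 / 645,
      "pooled trials, placebo proxy weeks 1-12"),
    c("clinical.switch_response", 0.654, "Delphi panel, response after switch"),
    c("clinical.failure_practice.referral_specialist", 0.282,
      "Delphi panel, practice after failure"),
    c("clinical.failure_practice.hospitalization", 0.049,
      "Delphi panel, practice after failure"),
    c("utilities.prucalopride.start", 0.786, "PAC-QOL to EQ-5D mapping"),
    c("utilities.prucalopride.weeks5_12", 0.813, "PAC-QOL to EQ-5D mapping"),
    c("utilities.prucalopride.maintenance", 0.890, "PAC-QOL to EQ-5D mapping"),
    c("utilities.laxative.start", 0.781, "PAC-QOL to EQ-5D mapping"),
    c("utilities.laxative.weeks5_12", 0.805, "PAC-QOL to EQ-5D mapping"),
    c("utilities.laxative.maintenance", 0.879, "PAC-QOL to EQ-5D mapping"),
    c("utilities.switch.start", 0.784, "PAC-QOL to EQ-5D mapping"),
    c("utilities.switch.maintenance", 0.879, "PAC-QOL to EQ-5D mapping"),
    c("utilities.switch.dropout", 0.784, "PAC-QOL to EQ-5D mapping"),
    c("costs.prucalopride.mg2.first_pack_daily", 2.77,
      "Dutch list price 2010"),
    c("costs.prucalopride.mg2.after_daily", 2.49, "Dutch list price 2010"),
    c("costs.prucalopride.mg1.first_pack_daily", 1.95,
      "Dutch list price 2010"),
    c("costs.prucalopride.mg1.after_daily", 1.62, "Dutch list price 2010"),
    c("costs.prucalopride.annual_cap_days", 220, "label/long-term use data"),
    c("costs.prucalopride.first_year_maintenance_days", 130,
      "long-term use data, year 1"),
    c("costs.prescription_fee", 6.35, "Dutch prescription rule"),
    c("costs.units.pcp_visit", 28.00, "Dutch costing manual 2009"),
    c("costs.units.specialist_visit_manual", 72.00,
      "Dutch costing manual 2009"),
    c("costs.units.pcp_phone", 14.00, "Dutch costing manual 2009"),
    c("costs.units.nurse_visit", 10.00, "Dutch costing manual 2009"),
    c("costs.units.nurse_phone", 0.00, "Dutch costing manual 2009"),
    c("costs.units.dietician_visit", 27.00, "Dutch costing manual 2009"),
    c("costs.units.dbc_specialist", 195.89, "NZa DBC tariff 2010"),
    c("costs.units.dbc_hospitalization", 3102.00, "NZa DBC tariff 2010"),
    c("costs.transport.km_pcp", 1.1, "Dutch costing manual"),
    c("costs.transport.km_specialist", 7.0, "Dutch costing manual"),
    c("costs.transport.km_dietician", 1.7, "Dutch costing manual"),
    c("costs.transport.cost_per_km", 0.20, "Dutch costing manual 2009"),
    c("costs.transport.parking", 3.00, "scenario only"),
    c("costs.inflation.2009", 0.012, "CBS"),
    c("costs.inflation.2010", 0.013, "CBS"),
    c("indirect.share_absent", 0.12, "2007 workforce survey"),
    c("indirect.days_per_month", 2.4, "2007 workforce survey"),
    c("indirect.cost_per_hour", 26.99, "Dutch costing manual"),
    c("indirect.annual_hours", 1540, "Dutch costing manual"),
    c("indirect.working_age_share", 0.870, "pooled trial population"))
  lax <- par$costs$laxatives$items
  for (nm in names(lax)) {
    rows <- c(rows, list(
      c(paste0("costs.laxatives.", nm, ".daily_cost"),
        lax[[nm]][["daily_cost"]], "Dutch list price 2010"),
      c(paste0("costs.laxatives.", nm, ".start_share"),
        lax[[nm]][["start_share"]], "Delphi panel distribution"),
      c(paste0("costs.laxatives.", nm, ".switch_share"),
        lax[[nm]][["switch_share"]], "Delphi panel distribution")))
  }
  for (cm in names(par$complications$items)) {
    it <- par$complications$items[[cm]]
    rows <- c(rows, list(
      c(paste0("complications.", cm, ".prob.weeks1_4"), it$prob[["weeks1_4"]],
        "Delphi panel, complication probability"),
      c(paste0("complications.", cm, ".prob.weeks5_12"),
        it$prob[["weeks5_12"]], "Delphi panel, complication probability"),
      c(paste0("complications.", cm, ".prob.switch"), it$prob[["switch"]],
        "Delphi panel, complication probability"),
      c(paste0("complications.", cm, ".pcp_consults"), it$pcp_consults,
        "Delphi panel, complication resource use"),
      c(paste0("complications.", cm, ".specialist_consults"),
        it$specialist_consults, "Delphi panel, complication resource use"),
      c(paste0("complications.", cm, ".hospitalization_fraction"),
        it$hospitalization_fraction,
        "Delphi panel, complication resource use"),
      c(paste0("complications.", cm, ".los_days"), it$los_days,
        "Delphi panel, complication resource use")))
  }
  for (ph in names(par$resources$phases)) {
    q <- par$resources$phases[[ph]]
    for (item in names(q)) {
      rows <- c(rows, list(c(paste0("resources.", ph, ".", item), q[[item]],
                             "Delphi panel, monthly resource use")))
    }
  }
  tibble::tibble(
    parameter = vapply(rows, `[[`, character(1), 1),
    value = as.numeric(vapply(rows, `[[`, character(1), 2)),
    source = vapply(rows, `[[`, character(1), 3))
}

#' @export
print.cc_parameters <- function(x, ...) {
  cat("<cc_parameters>\n")
  cat("  arms: prucalopride (r4 ",
      sprintf("%.3f", x$clinical$prucalopride$r4$proportion),
      ", r12 ", sprintf("%.3f", x$clinical$prucalopride$r12$proportion),
      ") vs laxative (r4 ",
      sprintf("%.3f", x$clinical$laxative$r4$proportion),
      ", r12 ", sprintf("%.3f", x$clinical$laxative$r12$proportion), ")\n",
      sep = "")
  cat("  horizon:", x$analysis$horizon_months, "months; discounting",
      x$analysis$discount_costs, "/", x$analysis$discount_effects, "\n")
  invisible(x)
}
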