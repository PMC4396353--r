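#' Annual-step discount factor for a monthly cycle
#'
#' All cycles of a model year share one factor:
#' `1 / (1 + rate)^floor((cycle - 1) / 12)`, so year-1 cycles are
#' undiscounted. Mirrors guideline-style annual rates applied to a
#' monthly-cycle model.
#'
#' @param cycle 1-based cycle (month) index.
#' @param annual_rate Annual discount rate (>= 0).
#' @return Discount factor in (0, 1].
#' @export
#' @examples
#' discount_factor(13, 0.04)  # 1/1.04
discount_factor <- function(cycle, annual_rate) {
  if (annual_rate < 0) stop("annual_rate must be >= 0")
  1 / (1 + annual_rate)^((cycle - 1) %/% 12)
}

#' Utility of each health state for one arm
#'
#' @param par Parameter bundle.
#' @param arm `"prucalopride"` or `"laxative"`.
#' @return Named numeric vector of annual utilities per state.
#' @export
state_utilities <- function(par, arm = c("prucalopride", "laxative")) {
  arm <- match.arg(arm)
  u <- par$utilities[[arm]]
  s <- par$utilities$switch
  c(START_W1_4 = u[["start"]], START_W5_8 = u[["weeks5_12"]],
    START_W9_12 = u[["weeks5_12"]], MAINTENANCE = u[["maintenance"]],
    SWITCH_W1_4 = s[["start"]], SWITCH_W5_8 = s[["start"]],
    SWITCH_W9_12 = s[["start"]], SWITCH_MAINTENANCE = s[["maintenance"]],
    DROPOUT = s[["dropout"]])
}

#' Accrue discounted QALYs over a cohort trace
#'
#' Each month contributes occupancy times one twelfth of the state's
#' annual utility, discounted at the effect rate. Accrual uses the state
#' occupied during the month (trace row `t - 1`), matching the costing
#' convention; there is no half-cycle correction.
#'
#' @param trace A `cc_trace` from [run_cohort()].
#' @param utilities Named vector of annual utilities per state, e.g.
#'   [state_utilities()].
#' @param settings The `analysis` component of a parameter bundle.
#' @return Total QALYs (scalar).
#' @export
accrue_qalys <- function(trace, utilities, settings) {
  occ <- trace$occupancy
  states <- colnames(occ)
  if (!all(states %in% names(utilities))) {
    miss <- setdiff(states, names(utilities))
    stop("missing utility for state(s): ", paste(miss, collapse = ", "))
  }
  u <- utilities[states]
  total <- 0
  for (t in seq_len(trace$horizon)) {
    total <- total + discount_factor(t, settings$discount_effects) *
      sum(occ[t, ] * u) / 12
  }
  unname(total)
}

#' Incremental cost-effectiveness statistics
#'
#' Computes the cost and QALY differences between an intervention (a) and
#' a comparator (b) and labels the cost-effectiveness quadrant: an ICER
#' is reported when the intervention is more effective and more costly;
#' `"dominant"` when no worse on both dimensions (and better on one),
#' `"dominated"` when no better on both (and worse on one).
#'
#' @param cost_a,cost_b Total discounted cost per arm.
#' @param qaly_a,qaly_b Total discounted QALYs per arm.
#' @param labels Arm labels, used for printing.
#' @return A `cea_result` list: per-arm totals, `delta_cost`,
#'   `delta_qaly`, `icer` (NA when not defined), `dominance`.
#' @export
#' @examples
#' incremental_analysis(2511, 2446, 0.833, 0.826)$icer  # 9285.7
incremental_analysis <- function(cost_a, cost_b, qaly_a, qaly_b,
                                 labels = c("prucalopride", "laxative")) {
  dc <- cost_a - cost_b
  de <- qaly_a - qaly_b
  dominance <- "none"
  icer <- NA_real_
  if (dc <= 0 && de >= 0 && !(dc == 0 && de == 0)) {
    dominance <- "dominant"
  } else if (dc >= 0 && de <= 0 && !(dc == 0 && de == 0)) {
    dominance <- "dominated"
  } else if (de != 0) {
    icer <- dc / de
  }
  structure(list(arms = labels, cost = c(cost_a, cost_b),
                 qaly = c(qaly_a, qaly_b), delta_cost = dc,
                 delta_qaly = de, icer = icer, dominance = dominance),
            class = "cea_result")
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' `threshold x delta_QALY - delta_cost`; zero exactly at the ICER.
#'
#' @param result A `cea_result`.
#' @param threshold Willingness to pay per QALY (>= 0).
#' @return Net monetary benefit in euros.
#' @export
net_monetary_benefit <- function(result, threshold) {
  if (any(threshold < 0)) stop("threshold must be >= 0")
  threshold * result$delta_qaly - result$delta_cost
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  df <- data.frame(arm = x$arms, cost = round(x$cost, 0),
                   QALYs = round(x$qaly, 3))
  print(df, row.names = FALSE)
  cat(sprintf("  difference: %0.f EUR, %.4f QALYs\n",
              x$delta_cost, x$delta_qaly))
  if (!is.na(x$icer)) {
    cat(sprintf("  ICER: %.0f EUR/QALY\n", x$icer))
  } else {
    cat("  dominance:", x$dominance, "\n")
  }
  invisible(x)
}

#' Export a cost-effectiveness result as a tidy table
#'
#' @param x A `cea_result`.
#' @return Tibble in the arm / cost / QALYs layout with a difference row.
#' @export
cea_table <- function(x) {
  tibble::tibble(
    arm = c(x$arms, "difference"),
    cost = c(x$cost, x$delta_cost),
    qaly = c(x$qaly, x$delta_qaly),
    icer = c(NA_real_, NA_real_, x$icer))
}
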