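#' Build the cycle-indexed transition array for one arm
#'
#' Constructs the 9 x 9 x horizon transition probabilities implied by the
#' two trial response measurements and the Delphi switch-response
#' estimate. With the stopping rule on (default), week-4 non-responders
#' leave initial treatment at the end of cycle 1; week-4 responders are
#' carried through weeks 5-12 and the remaining conditional failure
#' `1 - r12/r4` is applied at the week-12 assessment, so the unconditional
#' mass entering `MAINTENANCE` at cycle 3 equals `r12` exactly. When
#' `r12 > r4` (possible with the placebo-proxy laxative arm) the
#' conditional retention is clamped at 1. With the stopping rule off, the
#' whole cohort is carried to week 12 and the total failure mass `1 - r12`
#' exits there. Failures after a successful switch drop out and are not
#' re-switched. A constant monthly death probability
#' (`settings$death_prob_monthly`, default 0) is supported as a structural
#' hook: it thins every row uniformly, so with a nonzero value rows sum to
#' the surviving fraction rather than 1.
#'
#' @param arm List with [response_evidence()] entries `r4` and `r12` (or
#'   bare proportions) and optionally `switch_response`.
#' @param settings The `analysis` component of a parameter bundle.
#' @return A `cc_transitions` object: array `[from, to, cycle]`.
#' @export
#' @examples
#' par <- default_parameters()
#' tm <- build_transitions(par$clinical$prucalopride, par$analysis)
#' tm$prob["START_W1_4", , 1]
build_transitions <- function(arm, settings) {
  states <- health_states()
  r4 <- if (inherits(arm$r4, "response_evidence")) arm$r4$proportion else arm$r4
  r12 <- if (inherits(arm$r12, "response_evidence")) arm$r12$proportion else
    arm$r12
  sw <- if (!is.null(arm$switch_response)) arm$switch_response else 0.654
  if (any(c(r4, r12, sw) < 0) || any(c(r4, r12, sw) > 1))
    stop("response probabilities must be in [0, 1]")
  if (r4 == 0 && r12 > 0)
    stop("r4 = 0 with r12 > 0: conditional retention undefined")
  horizon <- settings$horizon_months
  stopping <- isTRUE(settings$stopping_rule)
  split <- if (!is.null(settings$week12_failure_split))
    settings$week12_failure_split else "late"

  m <- matrix(0, 9, 9, dimnames = list(states, states))
  retain <- if (r4 > 0) min(1, r12 / r4) else 0
  if (stopping) {
    m["START_W1_4", "START_W5_8"] <- r4
    m["START_W1_4", "SWITCH_W1_4"] <- 1 - r4
    if (identical(split, "even")) {
      step <- sqrt(retain)
      m["START_W5_8", "START_W9_12"] <- step
      m["START_W5_8", "SWITCH_W1_4"] <- 1 - step
      m["START_W9_12", "MAINTENANCE"] <- step
      m["START_W9_12", "SWITCH_W1_4"] <- 1 - step
    } else {
      m["START_W5_8", "START_W9_12"] <- 1
      m["START_W9_12", "MAINTENANCE"] <- retain
      m["START_W9_12", "SWITCH_W1_4"] <- 1 - retain
    }
  } else {
    m["START_W1_4", "START_W5_8"] <- 1
    m["START_W5_8", "START_W9_12"] <- 1
    m["START_W9_12", "MAINTENANCE"] <- min(1, r12)
    m["START_W9_12", "SWITCH_W1_4"] <- 1 - min(1, r12)
  }
  m["SWITCH_W1_4", "SWITCH_W5_8"] <- sw
  m["SWITCH_W1_4", "DROPOUT"] <- 1 - sw
  m["SWITCH_W5_8", "SWITCH_W9_12"] <- 1
  m["SWITCH_W9_12", "SWITCH_MAINTENANCE"] <- 1
  for (s in absorbing_states()) m[s, s] <- 1

  pd <- settings$death_prob_monthly
  if (!is.null(pd) && pd > 0) m <- m * (1 - pd)

  allowed <- matrix(FALSE, 9, 9, dimnames = list(states, states))
  for (i in seq_len(nrow(allowed_transitions()))) {
    tr <- allowed_transitions()[i, ]
    allowed[tr[1], tr[2]] <- TRUE
  }
  if (any(m[!allowed] != 0))
    stop("internal error: transition outside the model structure")

  prob <- array(m, dim = c(9, 9, horizon),
                dimnames = list(states, states, NULL))
  structure(list(prob = prob, horizon = horizon,
                 death_prob = if (is.null(pd)) 0 else pd),
            class = "cc_transitions")
}

#' Propagate a cohort through the transition array
#'
#' The trace has `horizon + 1` rows: row 0 is the whole cohort in
#' `START_W1_4`, row `t` the distribution after `t` monthly transitions.
#' Costs and QALYs accrue on the state occupied during month `t`, i.e.
#' on row `t - 1` (no half-cycle correction).
#'
#' @param tm A `cc_transitions` object.
#' @param horizon Months to simulate (>= 3); defaults to the array depth.
#' @param arm Optional arm label stored in the result.
#' @return A `cc_trace` object: matrix `[cycle 0..horizon, state]`.
#' @export
#' @examples
#' par <- default_parameters()
#' tm <- build_transitions(par$clinical$prucalopride, par$analysis)
#' run_cohort(tm)$occupancy["3", "MAINTENANCE"]  # 0.236 (= r12)
run_cohort <- function(tm, horizon = tm$horizon, arm = "arm") {
  if (horizon < 3) stop("horizon must cover the three initial phases")
  states <- health_states()
  occ <- matrix(0, horizon + 1, 9,
                dimnames = list(0:horizon, states))
  occ[1, "START_W1_4"] <- 1
  for (t in seq_len(horizon)) {
    k <- min(t, dim(tm$prob)[3])
    occ[t + 1, ] <- occ[t, ] %*% tm$prob[, , k]
  }
  structure(list(occupancy = occ, horizon = horizon, arm = arm),
            class = "cc_trace")
}

#' Empirical cohort trace from individual patient walks
#'
#' Simulates `n_patients` independent trajectories through the transition
#' array and returns the empirical occupancy per cycle; converges to
#' [run_cohort()] as `n_patients` grows. Used as a Monte-Carlo oracle for
#' the deterministic trace.
#'
#' @param tm A `cc_transitions` object.
#' @param n_patients Number of simulated patients (>= 1).
#' @param horizon Months to simulate.
#' @param seed Integer seed (RNG state is restored on exit).
#' @return A `cc_trace` object with empirical occupancy fractions.
#' @export
microsimulate <- function(tm, n_patients, horizon = tm$horizon,
                          seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  states <- health_states()
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cur <- rep.int(1L, n_patients)
  occ <- matrix(0, horizon + 1, 9, dimnames = list(0:horizon, states))
  occ[1, 1] <- 1
  for (t in seq_len(horizon)) {
    k <- min(t, dim(tm$prob)[3])
    p <- tm$prob[, , k]
    for (s in unique(cur)) {
      idx <- which(cur == s)
      row <- p[s, ]
      if (sum(row) <= 0) next
      cur[idx] <- sample.int(9, length(idx), replace = TRUE,
                             prob = row / sum(row))
    }
    occ[t + 1, ] <- tabulate(cur, nbins = 9) / n_patients
  }
  structure(list(occupancy = occ, horizon = horizon, arm = "microsim"),
            class = "cc_trace")
}

#' Tidy export of a cohort trace
#'
#' @param trace A `cc_trace` object.
#' @return Tibble with columns `arm`, `cycle`, `state`, `occupancy`.
#' @export
trace_to_tibble <- function(trace) {
  occ <- trace$occupancy
  tibble::tibble(
    arm = trace$arm,
    cycle = rep(as.integer(rownames(occ)), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.vector(occ))
}

#' @export
print.cc_trace <- function(x, ...) {
  cat("<cc_trace> arm:", x$arm, "-", x$horizon, "cycles\n")
  print(round(utils::head(x$occupancy, 5), 4))
  if (nrow(x$occupancy) > 5) cat("...\n")
  invisible(x)
}
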