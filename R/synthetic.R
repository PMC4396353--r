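#' Simulate a responder trial arm
#'
#' Generates patient-level responder data with the nested structure the
#' cohort model assumes: week-4 response is Bernoulli(`p4`) and week-12
#' response is retained among week-4 responders with the conditional
#' probability `p12/p4`, so week-12 responders are a subset of week-4
#' responders and the unconditional week-12 proportion targets `p12`.
#' An optional PAC-QOL satisfaction responder flag is drawn
#' independently.
#'
#' @param p4,p12 Generating response probabilities, `0 <= p12 <= p4 <= 1`.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed (RNG state restored on exit).
#' @param p_pacqol Optional probability of a PAC-QOL >= 1-point
#'   improvement; `NULL` leaves the column `NA`.
#' @return A `cc_synthetic_trial`: tibble `patients` (patient, week4,
#'   week12, pacqol) plus the generating probabilities and seed.
#' @export
#' @examples
#' trial <- simulate_trial(0.278, 0.236, 640, seed = 42)
#' mean(trial$patients$week4)
simulate_trial <- function(p4, p12, n, seed = 1L, p_pacqol = NULL) {
  if (p12 > p4) stop("p12 must not exceed p4 (nested responders)")
  if (any(c(p4, p12) < 0) || any(c(p4, p12) > 1))
    stop("probabilities must be in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  week4 <- stats::runif(n) < p4
  retain <- if (p4 > 0) p12 / p4 else 0
  week12 <- week4 & (stats::runif(n) < retain)
  pacqol <- if (is.null(p_pacqol)) rep(NA, n) else stats::runif(n) < p_pacqol
  structure(list(
    patients = tibble::tibble(patient = seq_len(n), week4 = week4,
                              week12 = week12, pacqol = pacqol),
    p4 = p4, p12 = p12, p_pacqol = p_pacqol, seed = seed),
    class = "cc_synthetic_trial")
}

#' Estimate arm parameters from a synthetic trial
#'
#' Closes the recovery loop: observed responder counts become
#' [response_evidence()] objects that can feed [build_transitions()]
#' directly, whose cycle-3 maintenance mass then equals the observed
#' week-12 proportion exactly.
#'
#' @param trial A `cc_synthetic_trial`.
#' @param switch_response Switch-response probability carried into the
#'   arm parameters (default 0.654).
#' @return List with `r4`, `r12` evidence and `switch_response`.
#' @export
estimate_arm_parameters <- function(trial, switch_response = 0.654) {
  p <- trial$patients
  if (nrow(p) == 0) stop("empty trial")
  n4 <- sum(p$week4)
  n12 <- sum(p$week12)
  if (n4 == 0 && n12 > 0)
    stop("zero week-4 responders with nonzero week-12 responders")
  list(r4 = response_evidence(n4, nrow(p)),
       r12 = response_evidence(n12, nrow(p)),
       switch_response = switch_response)
}

#' Simulate a resource-use panel
#'
#' Emulates the elicitation target of the resource-use inputs: for each
#' item of a monthly-count profile, draws `n` virtual respondents from a
#' gamma distribution with the profile value as mean and `cv` times the
#' mean as standard deviation (the PSA's quantity layer). Zero-mean items
#' stay exactly zero.
#'
#' @param profile Named numeric vector of monthly counts (e.g. one
#'   column of `default_parameters()$resources$phases`).
#' @param cv Coefficient of variation (> 0).
#' @param n Panel size (>= 1).
#' @param seed Integer seed (RNG state restored on exit).
#' @return A `cc_resource_panel`: `samples` matrix (`n x item`), the
#'   generating `profile`, `cv` and `seed`.
#' @export
simulate_resource_panel <- function(profile, cv, n, seed = 1L) {
  if (cv <= 0) stop("cv must be > 0")
  if (n < 1) stop("n must be >= 1")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  samples <- vapply(profile, function(m) {
    if (m <= 0) return(rep(0, n))
    stats::rgamma(n, shape = 1 / cv^2, scale = m * cv^2)
  }, numeric(n))
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = n)
  colnames(samples) <- names(profile)
  structure(list(samples = samples, profile = profile, cv = cv,
                 seed = seed),
            class = "cc_resource_panel")
}

#' Tidy export of a synthetic trial
#'
#' @param trial A `cc_synthetic_trial`.
#' @param arm Arm label added to the output.
#' @return Tibble (patient, arm, week4, week12, pacqol).
#' @export
trial_to_tibble <- function(trial, arm = "arm") {
  tibble::tibble(patient = trial$patients$patient, arm = arm,
                 week4 = trial$patients$week4,
                 week12 = trial$patients$week12,
                 pacqol = trial$patients$pacqol)
}
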