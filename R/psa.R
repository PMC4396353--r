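# method-of-moments beta parameters; degenerate means stay fixed
beta_mom <- function(mean, se) {
  if (mean <= 0 || mean >= 1 || se <= 0)
    return(list(type = "fixed", value = mean))
  vmax <- mean * (1 - mean)
  if (se^2 >= vmax) se <- 0.95 * sqrt(vmax)
  nu <- vmax / se^2 - 1
  list(type = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

# method-of-moments gamma parameters; zero means stay fixed
gamma_mom <- function(mean, se) {
  if (mean <= 0 || se <= 0) return(list(type = "fixed", value = mean))
  list(type = "gamma", shape = (mean / se)^2, scale = se^2 / mean)
}

#' Assign probabilistic distributions to the model parameters
#'
#' Builds the sampling specification of the probabilistic sensitivity
#' analysis: trial response probabilities get conjugate-count beta
#' distributions (`beta(responders, total - responders)`); elicited
#' probabilities (switch response, failure practice, complication
#' probabilities, hospitalization fractions) get method-of-moments betas
#' with a standard error of `se_probability_frac` times the mean;
#' utilities get betas with absolute standard error `se_utility`;
#' resource quantities, complication consult counts and lengths of stay
#' get method-of-moments gammas with `se_quantity_frac` times the mean.
#' Unit tariffs are held fixed. Degenerate inputs (mean 0 or 1, or zero
#' dispersion) become point masses.
#'
#' @param par Parameter bundle.
#' @return A list of distribution descriptors (`path`, `type`,
#'   parameters), class `cc_distributions`.
#' @export
#' @examples
#' spec <- assign_distributions(default_parameters())
#' spec[[1]]
assign_distributions <- function(par) {
  psa <- par$analysis$psa
  sp <- psa$se_probability_frac
  sq <- psa$se_quantity_frac
  su <- psa$se_utility
  out <- list()
  add <- function(path, d) {
    d$path <- path
    out[[length(out) + 1]] <<- d
  }
  for (arm in c("prucalopride", "laxative")) {
    for (ep in c("r4", "r12")) {
      ev <- par$clinical[[arm]][[ep]]
      add(c("clinical", arm, ep, "proportion"),
          list(type = "beta", shape1 = ev$responders,
               shape2 = ev$total - ev$responders))
    }
  }
  add(c("clinical", "switch_response"),
      beta_mom(par$clinical$switch_response,
               sp * par$clinical$switch_response))
  for (fp in c("referral_specialist", "hospitalization")) {
    m <- par$clinical$failure_practice[[fp]]
    add(c("clinical", "failure_practice", fp), beta_mom(m, sp * m))
  }
  # all state utilities come from one PAC-QOL to EQ-5D mapping model, so
  # their dominant uncertainty is a common level (intercept) shock: draw
  # the anchor utility once per iteration and carry the estimated
  # state/arm contrasts, each utility keeping standard error se_utility
  anchor <- par$utilities$laxative[["start"]]
  d <- beta_mom(anchor, su)
  d$type <- if (d$type == "fixed") "fixed" else "utility_block"
  d$anchor <- anchor
  d$offsets <- list()
  for (grp in c("prucalopride", "laxative", "switch")) {
    for (nm in names(par$utilities[[grp]])) {
      d$offsets[[length(d$offsets) + 1]] <- list(
        path = c("utilities", grp, nm),
        offset = par$utilities[[grp]][[nm]] - anchor)
    }
  }
  d$path <- c("utilities", "laxative", "start")
  out[[length(out) + 1]] <- d
  for (cm in names(par$complications$items)) {
    it <- par$complications$items[[cm]]
    for (col in names(it$prob)) {
      m <- it$prob[[col]]
      add(c("complications", "items", cm, "prob", col), beta_mom(m, sp * m))
    }
    add(c("complications", "items", cm, "hospitalization_fraction"),
        beta_mom(it$hospitalization_fraction,
                 sp * it$hospitalization_fraction))
    for (q in c("pcp_consults", "specialist_consults", "los_days")) {
      m <- it[[q]]
      add(c("complications", "items", cm, q), gamma_mom(m, sq * m))
    }
  }
  for (ph in names(par$resources$phases)) {
    for (item in names(par$resources$phases[[ph]])) {
      m <- par$resources$phases[[ph]][[item]]
      add(c("resources", "phases", ph, item), gamma_mom(m, sq * m))
    }
  }
  structure(out, class = "cc_distributions")
}

# write a value at a nested path of the bundle
assign_path <- function(par, path, value) {
  if (length(path) == 1L) {
    if (length(path) == 1L && !is.null(names(par)) && !is.list(par)) {
      par[[path]] <- value
      return(par)
    }
    par[[path]] <- value
    return(par)
  }
  par[[path[1]]] <- assign_path(par[[path[1]]], path[-1], value)
  par
}

draw_one <- function(d) {
  switch(d$type,
    fixed = d$value,
    beta = stats::rbeta(1, d$shape1, d$shape2),
    gamma = stats::rgamma(1, shape = d$shape, scale = d$scale),
    utility_block = stats::rbeta(1, d$shape1, d$shape2),
    stop("unknown distribution type: ", d$type))
}

# one drawn parameter bundle; a utility_block descriptor writes the drawn
# anchor plus the fixed contrasts to every utility slot
draw_parameters <- function(par, spec) {
  for (d in spec) {
    v <- draw_one(d)
    if (identical(d$type, "utility_block")) {
      shock <- v - d$anchor
      for (o in d$offsets)
        par <- assign_path(par, o$path,
                           min(1, max(0, d$anchor + o$offset + shock)))
    } else {
      par <- assign_path(par, d$path, v)
    }
  }
  par
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` independent parameter bundles from the distribution
#' specification, evaluates the full model for each and summarises the
#' uncertainty: the ratio-of-means ICER (`mean(delta_cost) /
#' mean(delta_qaly)`), the cost-effectiveness acceptability curve over
#' thresholds 0 to `threshold_max` (step `threshold_step`), and the
#' running-mean ICER convergence series. Fully seeded and reproducible.
#'
#' @param par Parameter bundle.
#' @param n_draws Number of draws (>= 100 recommended; the reference
#'   analysis uses 5000).
#' @param seed Integer seed (RNG state restored on exit).
#' @param distributions Optional [assign_distributions()] specification.
#' @return A `cc_psa` object: `samples` tibble (per-draw arm costs,
#'   QALYs, increments), `icer`, `ceac` tibble, `convergence` tibble.
#' @export
run_psa <- function(par, n_draws = par$analysis$psa$n_draws, seed = 1L,
                    distributions = assign_distributions(par)) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cost_a <- cost_b <- qaly_a <- qaly_b <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    pi <- draw_parameters(par, distributions)
    profiles <- build_cost_profiles(pi)
    a <- run_arm(pi, "prucalopride", profiles)
    b <- run_arm(pi, "laxative", profiles)
    cost_a[i] <- a$cost; cost_b[i] <- b$cost
    qaly_a[i] <- a$qaly; qaly_b[i] <- b$qaly
  }
  samples <- tibble::tibble(
    draw = seq_len(n_draws), cost_prucalopride = cost_a,
    cost_laxative = cost_b, qaly_prucalopride = qaly_a,
    qaly_laxative = qaly_b, delta_cost = cost_a - cost_b,
    delta_qaly = qaly_a - qaly_b)
  thresholds <- seq(0, par$analysis$psa$threshold_max,
                    by = par$analysis$psa$threshold_step)
  conv <- tibble::tibble(
    draw = seq_len(n_draws),
    icer = cumsum(samples$delta_cost) / cumsum(samples$delta_qaly))
  structure(list(
    samples = samples,
    icer = mean(samples$delta_cost) / mean(samples$delta_qaly),
    ceac = ceac(samples, thresholds),
    convergence = conv, seed = seed, n_draws = n_draws),
    class = "cc_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of draws in which
#' the intervention has positive net monetary benefit
#' (`threshold x delta_QALY - delta_cost > 0`).
#'
#' @param samples Tibble with `delta_cost` and `delta_qaly` columns (as
#'   in `cc_psa$samples`).
#' @param thresholds Numeric vector of thresholds (euros per QALY).
#' @return Tibble with columns `threshold`, `probability`.
#' @export
#' @examples
#' s <- tibble::tibble(delta_cost = c(50, -10, 80, 120),
#'                     delta_qaly = c(0.01, 0.002, 0.004, -0.001))
#' ceac(s, c(0, 10000, 50000))
ceac <- function(samples, thresholds) {
  if (nrow(samples) == 0) stop("empty sample set")
  tibble::tibble(
    threshold = thresholds,
    probability = vapply(thresholds, function(th)
      mean(th * samples$delta_qaly - samples$delta_cost > 0), numeric(1)))
}

#' @export
print.cc_psa <- function(x, ...) {
  cat("<cc_psa>", x$n_draws, "draws (seed", x$seed, ")\n")
  cat(sprintf("  ratio-of-means ICER: %.0f EUR/QALY\n", x$icer))
  p20 <- x$ceac$probability[x$ceac$threshold == 20000]
  if (length(p20))
    cat(sprintf("  P(cost-effective at 20,000 EUR/QALY): %.2f\n", p20))
  invisible(x)
}
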