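# shared fixtures built in code

# bundle with inflation disabled (target year = costing years), so unit
# costs enter cycle costs at their printed values; used where expected
# values are hand sums of printed tariffs
uninflated_parameters <- function() {
  par <- default_parameters()
  par$costs$inflation[] <- 0
  par
}

# bundle whose complication map matches the phase-for-phase layout
# (start states and maintenance included), for testing the complication
# costing operation against hand arithmetic
phase_mapped_parameters <- function() {
  par <- uninflated_parameters()
  par$analysis$complication_states <- c(
    START_W1_4 = "weeks1_4", START_W5_8 = "weeks5_12",
    START_W9_12 = "weeks5_12", MAINTENANCE = "weeks5_12",
    SWITCH_W1_4 = "switch", SWITCH_W5_8 = "switch",
    SWITCH_W9_12 = "switch", SWITCH_MAINTENANCE = "switch",
    DROPOUT = "switch")
  par
}

# brute-force oracle: probability of at least one event in k months when
# each month has the same probability q, enumerated over outcomes
enumerate_period_prob <- function(q, k) {
  outcomes <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  probs <- apply(outcomes, 1, function(ev)
    prod(ifelse(ev, q, 1 - q)))
  sum(probs[apply(outcomes, 1, any)])
}
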