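#' Health states of the cohort model
#'
#' The model distinguishes nine states. Patients start treatment
#' (prucalopride or continued laxatives, identical structure) and are
#' assessed after 4 weeks (stopping rule) and after 12 weeks. Week-4
#' non-responders switch to another laxative and run through a mirrored
#' 12-week pathway; patients failing the switch drop out and remain
#' drop-outs, still on laxatives, for the rest of the horizon.
#' `MAINTENANCE`, `SWITCH_MAINTENANCE` and `DROPOUT` are absorbing.
#'
#' @return Character vector of the nine state labels, in model order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("START_W1_4", "START_W5_8", "START_W9_12", "MAINTENANCE",
    "SWITCH_W1_4", "SWITCH_W5_8", "SWITCH_W9_12", "SWITCH_MAINTENANCE",
    "DROPOUT")
}

#' Absorbing states
#' @return Character vector of the three absorbing state labels.
#' @export
absorbing_states <- function() {
  c("MAINTENANCE", "SWITCH_MAINTENANCE", "DROPOUT")
}

# transitions drawn in the model diagram; anything else must be zero
allowed_transitions <- function() {
  rbind(
    c("START_W1_4", "START_W5_8"),
    c("START_W1_4", "SWITCH_W1_4"),
    c("START_W5_8", "START_W9_12"),
    c("START_W5_8", "SWITCH_W1_4"),
    c("START_W9_12", "MAINTENANCE"),
    c("START_W9_12", "SWITCH_W1_4"),
    c("MAINTENANCE", "MAINTENANCE"),
    c("SWITCH_W1_4", "SWITCH_W5_8"),
    c("SWITCH_W1_4", "DROPOUT"),
    c("SWITCH_W5_8", "SWITCH_W9_12"),
    c("SWITCH_W9_12", "SWITCH_MAINTENANCE"),
    c("SWITCH_MAINTENANCE", "SWITCH_MAINTENANCE"),
    c("DROPOUT", "DROPOUT"))
}
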