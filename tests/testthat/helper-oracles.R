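# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles, without touching the package's own
# bookkeeping.

# Brute-force reversal recount from the presented delta sequence alone.
# `deltas` is the Δt in force on each trial; `final_delta` the Δt after the
# last trial (needed to classify the last trial's update). A trial is a
# reversal when the sign of the Δt change it triggered flips relative to
# the previous non-zero change.
oracle_reversals <- function(deltas, final_delta) {
  track <- c(deltas, final_delta)
  changes <- diff(track)
  flags <- logical(length(deltas))
  dir <- 0
  for (i in seq_along(deltas)) {
    if (changes[i] != 0) {
      d <- sign(changes[i])
      if (dir != 0 && d != dir) flags[i] <- TRUE
      dir <- d
    }
  }
  flags
}

# Brute-force Monte-Carlo 2IFC probability correct for a scalar-noise
# Gaussian observer: draws percepts directly, no package code.
oracle_p2ifc <- function(delta, standard_T, w, n = 40000) {
  comp <- rnorm(n, standard_T + delta, w * (standard_T + delta))
  std <- rnorm(n, standard_T, w * standard_T)
  mean(comp > std)
}

# Small stationary observer (no learning, no lapses) at a given internal
# Weber fraction, valid for one condition.
stationary_observer <- function(w, condition = "empty_200", lapse = 0) {
  conds <- setNames(
    list(list(wf_start = w, wf_asymptote = w, tau_sessions = 1)),
    condition)
  observer_params("EI", lapse_rate = lapse, conditions = conds,
                  id = "stat")
}
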