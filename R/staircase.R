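#' Staircase protocol configuration
#'
#' Protocol constants for the one-up-three-down 2IFC duration-discrimination
#' staircase. Defaults follow the standard protocol: the initial duration
#' difference Δt is 20% of the standard interval, changed in steps of 10% of
#' the standard interval until the third reversal and 5% thereafter, over
#' blocks of 60 trials. Three consecutive correct responses decrease Δt, one
#' error increases it, so the staircase tracks the 0.5^(1/3) ≈ 79.4% correct
#' point.
#'
#' @param standard_T standard interval in ms (> 0).
#' @param initial_delta_fraction initial Δt as a fraction of `standard_T`.
#' @param coarse_step_fraction step size before the step change, as a
#'   fraction of `standard_T`.
#' @param fine_step_fraction step size after the step change; must be
#'   smaller than `coarse_step_fraction`.
#' @param step_change_after_reversal the step switches from coarse to fine
#'   after this many recorded reversals.
#' @param trials_per_block trials per block.
#' @param down_rule consecutive correct responses required to decrease Δt.
#' @param up_rule incorrect responses required to increase Δt (the
#'   transformed up/down family; 1 in this protocol).
#' @param delta_floor smallest allowed Δt in ms; defaults to one fine step
#'   (`fine_step_fraction * standard_T`). Δt is clamped here, never zero or
#'   negative, so the comparison interval is always the physically longer
#'   one.
#' @param quantize_ms optional display-frame grid in ms (e.g. 10 for a
#'   100 Hz display); when set, Δt is rounded to this grid after every
#'   change. Default `NULL` (off).
#' @param timing_metadata presentation timing, for record-keeping only.
#' @return an object of class `staircase_config`.
#' @export
#' @examples
#' cfg <- staircase_config(200)
#' cfg$initial_delta_fraction * cfg$standard_T  # initial Δt: 40 ms
staircase_config <- function(standard_T,
                             initial_delta_fraction = 0.20,
                             coarse_step_fraction = 0.10,
                             fine_step_fraction = 0.05,
                             step_change_after_reversal = 3,
                             trials_per_block = 60,
                             down_rule = 3,
                             up_rule = 1,
                             delta_floor = fine_step_fraction * standard_T,
                             quantize_ms = NULL,
                             timing_metadata = list(fixation_ms = 500,
                                                    isi_ms = 800,
                                                    feedback_ms = 1000)) {
  if (!is.numeric(standard_T) || length(standard_T) != 1 || standard_T <= 0) {
    stop_invalid("standard_T must be a single positive duration (ms)")
  }
  fr <- c(initial_delta_fraction, coarse_step_fraction, fine_step_fraction)
  if (any(fr <= 0) || any(fr > 1)) {
    stop_invalid("all step/initial fractions must lie in (0, 1]")
  }
  if (fine_step_fraction >= coarse_step_fraction) {
    stop_invalid("fine_step_fraction must be smaller than coarse_step_fraction")
  }
  if (down_rule < 1 || up_rule < 1) {
    stop_invalid("down_rule and up_rule must be >= 1")
  }
  if (delta_floor <= 0 || delta_floor > initial_delta_fraction * standard_T) {
    stop_invalid("delta_floor must be positive and no larger than the initial Δt")
  }
  if (trials_per_block < 1) stop_invalid("trials_per_block must be >= 1")
  structure(
    list(standard_T = standard_T,
         initial_delta_fraction = initial_delta_fraction,
         coarse_step_fraction = coarse_step_fraction,
         fine_step_fraction = fine_step_fraction,
         step_change_after_reversal = step_change_after_reversal,
         trials_per_block = trials_per_block,
         down_rule = down_rule,
         up_rule = up_rule,
         delta_floor = delta_floor,
         quantize_ms = quantize_ms,
         timing_metadata = timing_metadata),
    class = "staircase_config"
  )
}

#' @export
print.staircase_config <- function(x, ...) {
  cat(sprintf(
    "<staircase_config> T=%g ms, %d-down-%d-up, Δt0=%g ms, steps %g/%g ms, %d trials\n",
    x$standard_T, x$down_rule, x$up_rule,
    x$initial_delta_fraction * x$standard_T,
    x$coarse_step_fraction * x$standard_T,
    x$fine_step_fraction * x$standard_T, x$trials_per_block))
  invisible(x)
}

#' Initialise staircase state
#'
#' Sets Δt to `initial_delta_fraction * standard_T` (40 ms at a 200 ms
#' standard), zeroes the consecutive-correct counter, and records no
#' movement direction and no reversals.
#'
#' @param config a [staircase_config()] object.
#' @return an object of class `staircase_state` with fields
#'   `current_delta`, `consecutive_correct`, `movement_direction`
#'   (`"none"`, `"down"` or `"up"`), `reversal_values`, `trial_index`, and
#'   bookkeeping fields `last_changed`/`last_reversal`/`last_step` describing
#'   the most recent update.
#' @export
init_staircase <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(
    list(current_delta = config$initial_delta_fraction * config$standard_T,
         consecutive_correct = 0L,
         movement_direction = "none",
         reversal_values = numeric(0),
         trial_index = 0L,
         last_changed = FALSE,
         last_reversal = FALSE,
         last_step = NA_real_),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(
    "<staircase_state> trial %d, Δt=%g ms, dir=%s, %d reversals\n",
    x$trial_index, x$current_delta, x$movement_direction,
    length(x$reversal_values)))
  invisible(x)
}

# Step size (ms) in force for the next delta change: coarse until the
# step_change_after_reversal-th reversal has been recorded, fine afterwards.
# The reversal-causing change itself still uses the coarse step; the switch
# applies from the first change after the reversal is on record.
step_in_force <- function(state, config) {
  if (length(state$reversal_values) >= config$step_change_after_reversal) {
    config$fine_step_fraction * config$standard_T
  } else {
    config$coarse_step_fraction * config$standard_T
  }
}

#' Advance the staircase by one response
#'
#' Applies the transformed up/down rule: a correct response increments the
#' consecutive-correct counter and, when it reaches `down_rule`, Δt
#' decreases by the step in force (clamped at `delta_floor`) and the counter
#' resets; an incorrect response increases Δt by the step in force and
#' resets the counter. A reversal is recorded when the realized direction of
#' Δt movement flips relative to the previous realized movement; the
#' reversal value is the Δt level at the turning point (the level in force
#' when the flip occurred). The first realized change establishes a
#' direction without counting as a reversal, and changes fully absorbed by
#' the floor clamp carry no direction. The step switches from coarse to fine
#' for the first Δt change after the `step_change_after_reversal`-th
#' reversal is recorded.
#'
#' @param state a `staircase_state`.
#' @param correct logical, whether the response was correct.
#' @param config the [staircase_config()].
#' @return the updated `staircase_state`; `last_changed`, `last_reversal`
#'   and `last_step` describe this update.
#' @export
update_staircase <- function(state, correct, config) {
  stopifnot(inherits(state, "staircase_state"),
            inherits(config, "staircase_config"),
            is.logical(correct), length(correct) == 1, !is.na(correct))
  step <- step_in_force(state, config)
  delta <- state$current_delta
  new_delta <- delta
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= config$down_rule) {
      new_delta <- max(delta - step, config$delta_floor)
      state$consecutive_correct <- 0L
    }
  } else {
    new_delta <- delta + step
    state$consecutive_correct <- 0L
  }
  if (!is.null(config$quantize_ms) && new_delta != delta) {
    new_delta <- max(round(new_delta / config$quantize_ms) * config$quantize_ms,
                     config$delta_floor)
  }
  state$last_changed <- new_delta != delta
  state$last_reversal <- FALSE
  state$last_step <- step
  if (state$last_changed) {
    dir_now <- if (new_delta < delta) "down" else "up"
    if (state$movement_direction != "none" &&
        dir_now != state$movement_direction) {
      state$reversal_values <- c(state$reversal_values, delta)
      state$last_reversal <- TRUE
    }
    state$movement_direction <- dir_now
  }
  state$current_delta <- new_delta
  state$trial_index <- state$trial_index + 1L
  state
}

#' Run one staircase block against a simulated observer
#'
#' Simulates `n_trials` 2IFC trials. On each trial the comparison interval
#' `T + Δt` is assigned to the first or second position with probability
#' 0.5, the observer responds via [respond_2ifc()] with its
#' session-appropriate noise coefficient, and the staircase advances via
#' [update_staircase()].
#'
#' @param config a [staircase_config()].
#' @param observer an [observer_params()] object.
#' @param condition condition key (see [condition_key()]).
#' @param session_index session index for [wf_trajectory()].
#' @param seed optional integer seed; when given, the block is fully
#'   reproducible in isolation.
#' @param n_trials number of trials (defaults to `config$trials_per_block`).
#' @return list with `trials` (a tibble of per-trial records: `trial`,
#'   `delta_ms`, `order` — position of the comparison interval, 1 or 2 —
#'   `choice`, `correct`, `reversal`, `step_ms`) and `state` (the final
#'   `staircase_state`).
#' @export
#' @examples
#' blk <- run_block(staircase_config(200), default_observer("EI"),
#'                  "empty_200", seed = 7)
#' nrow(blk$trials)
run_block <- function(config, observer, condition, session_index = 0,
                      seed = NULL, n_trials = config$trials_per_block) {
  stopifnot(inherits(config, "staircase_config"),
            inherits(observer, "observer_params"))
  if (is.null(observer$conditions[[condition]])) {
    stop_invalid("observer '%s' has no parameters for condition '%s'",
                 observer$id, condition)
  }
  if (!is.null(seed)) set.seed(seed)
  state <- init_staircase(config)
  n <- as.integer(n_trials)
  delta_ms <- numeric(n)
  order <- integer(n)
  choice <- integer(n)
  correct <- logical(n)
  reversal <- logical(n)
  step_ms <- numeric(n)
  T0 <- config$standard_T
  for (i in seq_len(n)) {
    delta_ms[i] <- state$current_delta
    step_ms[i] <- step_in_force(state, config)
    comp_pos <- if (runif(1) < 0.5) 1L else 2L
    t1 <- if (comp_pos == 1L) T0 + state$current_delta else T0
    t2 <- if (comp_pos == 2L) T0 + state$current_delta else T0
    resp <- respond_2ifc(t1, t2, observer, condition, session_index)
    order[i] <- comp_pos
    choice[i] <- resp$choice
    correct[i] <- resp$correct
    state <- update_staircase(state, resp$correct, config)
    reversal[i] <- state$last_reversal
  }
  list(
    trials = tibble::tibble(
      trial = seq_len(n), delta_ms = delta_ms, order = order,
      choice = choice, correct = correct, reversal = reversal,
      step_ms = step_ms
    ),
    state = state
  )
}

#' Drive the staircase with a scripted response sequence
#'
#' Feeds a fixed vector of correct/incorrect responses through
#' [update_staircase()] without any observer. Useful for testing and for
#' reconstructing staircase tracks from recorded response sequences.
#'
#' @param config a [staircase_config()].
#' @param responses logical vector of responses.
#' @return same shape as [run_block()], with `order`/`choice` set to `NA`.
#' @export
run_scripted <- function(config, responses) {
  stopifnot(inherits(config, "staircase_config"), is.logical(responses))
  state <- init_staircase(config)
  n <- length(responses)
  delta_ms <- numeric(n)
  reversal <- logical(n)
  step_ms <- numeric(n)
  for (i in seq_len(n)) {
    delta_ms[i] <- state$current_delta
    step_ms[i] <- step_in_force(state, config)
    state <- update_staircase(state, responses[i], config)
    reversal[i] <- state$last_reversal
  }
  list(
    trials = tibble::tibble(
      trial = seq_len(n), delta_ms = delta_ms, order = NA_integer_,
      choice = NA_integer_, correct = responses, reversal = reversal,
      step_ms = step_ms
    ),
    state = state
  )
}

#' Equilibrium accuracy of an n-down-1-up staircase
#'
#' A staircase that decreases the difficulty after `down_rule` consecutive
#' correct responses and increases it after each error equilibrates where
#' the probability of a downward move equals that of an upward move, i.e.
#' where `p^down_rule = 0.5`, so it tracks the `0.5^(1/down_rule)` correct
#' point: 50% for 1-down, ≈70.7% for 2-down, ≈79.4% for 3-down.
#'
#' @param down_rule number of consecutive correct responses per decrease.
#' @return the equilibrium probability correct.
#' @export
#' @examples
#' convergence_probability(3)  # 0.7937
convergence_probability <- function(down_rule) {
  if (!is.numeric(down_rule) || length(down_rule) != 1 || down_rule < 1) {
    stop_invalid("down_rule must be a single count >= 1")
  }
  0.5^(1 / down_rule)
}
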