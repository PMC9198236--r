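#' Parametric 2IFC duration-discrimination observer
#'
#' Defines a generative model of a participant: per-condition internal noise
#' coefficients (Weber fractions), a lapse rate, and exponential session-wise
#' learning dynamics. Internal noise follows the scalar property: the
#' standard deviation of the perceived duration is `noise_coeff * duration`.
#'
#' Each condition entry carries three learning parameters:
#' `wf_start` (internal Weber fraction before training), `wf_asymptote`
#' (value approached with training) and `tau_sessions` (exponential time
#' constant, in sessions). A condition with `wf_asymptote == wf_start` is
#' flat (no learning).
#'
#' @param group group label, `"EI"` (trained on empty intervals) or `"FI"`
#'   (trained on filled intervals).
#' @param lapse_rate probability of a stimulus-independent random response,
#'   in \[0, 0.5\].
#' @param conditions named list keyed by condition (see [condition_key()]),
#'   each element a list with `wf_start`, `wf_asymptote`, `tau_sessions`.
#' @param id participant identifier (character).
#' @return an object of class `observer_params`.
#' @seealso [default_observer()] for the standard parameterisation,
#'   [make_cohort()] for jittered cohorts.
#' @export
observer_params <- function(group = c("EI", "FI"), lapse_rate = 0.02,
                            conditions, id = "obs1") {
  group <- match.arg(group)
  if (!is.numeric(lapse_rate) || length(lapse_rate) != 1 ||
      lapse_rate < 0 || lapse_rate > 0.5) {
    stop_invalid("lapse_rate must be a single number in [0, 0.5], got %s",
                 format(lapse_rate))
  }
  if (!is.list(conditions) || is.null(names(conditions)) ||
      any(!nzchar(names(conditions)))) {
    stop_invalid("conditions must be a named list keyed by condition")
  }
  for (key in names(conditions)) {
    cc <- conditions[[key]]
    for (f in c("wf_start", "wf_asymptote", "tau_sessions")) {
      if (is.null(cc[[f]]) || !is.numeric(cc[[f]]) || length(cc[[f]]) != 1) {
        stop_invalid("condition '%s' lacks numeric field '%s'", key, f)
      }
    }
    if (cc$wf_start <= 0 || cc$wf_asymptote <= 0) {
      stop_invalid("condition '%s': noise coefficients must be > 0", key)
    }
    if (cc$tau_sessions < 0) {
      stop_invalid("condition '%s': tau_sessions must be >= 0", key)
    }
    if (cc$wf_asymptote > cc$wf_start) {
      stop_invalid("condition '%s': wf_asymptote must not exceed wf_start",
                   key)
    }
  }
  structure(
    list(id = id, group = group, lapse_rate = lapse_rate,
         conditions = conditions),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("<observer_params> id=%s group=%s lapse=%.3g\n",
              x$id, x$group, x$lapse_rate))
  for (key in names(x$conditions)) {
    cc <- x$conditions[[key]]
    cat(sprintf("  %-11s wf %.3g -> %.3g (tau %.3g)\n",
                key, cc$wf_start, cc$wf_asymptote, cc$tau_sessions))
  }
  invisible(x)
}

#' Default observer parameterisation
#'
#' The standard generative fixture: internal Weber fraction 0.20 in every
#' condition before training. For the EI group, the trained condition
#' (empty-200 ms) and the transfer condition (filled-200 ms) improve towards
#' 0.13 with a time constant of 1.5 sessions; all other conditions are flat.
#' The FI group is flat everywhere. This mirrors the qualitative group
#' structure the package is designed to emulate: learning plus
#' format-transfer at the trained duration for empty-interval training, and
#' no learning for filled-interval training.
#'
#' @param group `"EI"` or `"FI"`.
#' @param wf_start pre-training internal Weber fraction.
#' @param wf_asymptote post-training asymptote for improving conditions.
#' @param tau_sessions learning time constant (sessions).
#' @param lapse_rate lapse probability.
#' @param id participant identifier.
#' @return an `observer_params` object.
#' @export
#' @examples
#' default_observer("EI")
default_observer <- function(group = c("EI", "FI"), wf_start = 0.20,
                             wf_asymptote = 0.13, tau_sessions = 1.5,
                             lapse_rate = 0.02, id = "obs1") {
  group <- match.arg(group)
  improving <- if (group == "EI") c("empty_200", "filled_200") else character()
  conds <- lapply(test_conditions()$condition, function(key) {
    list(
      wf_start = wf_start,
      wf_asymptote = if (key %in% improving) wf_asymptote else wf_start,
      tau_sessions = tau_sessions
    )
  })
  names(conds) <- test_conditions()$condition
  observer_params(group = group, lapse_rate = lapse_rate,
                  conditions = conds, id = id)
}

#' Sample a perceived duration under scalar-timing noise
#'
#' Draws from a Gaussian with mean `duration` and standard deviation
#' `noise_coeff * duration`, truncated at zero by resampling (at realistic
#' noise levels the truncation is never reached in practice). Draws are
#' independent across calls and consume the current RNG stream.
#'
#' @param duration physical duration in ms, > 0.
#' @param noise_coeff internal Weber fraction, > 0.
#' @param n number of draws.
#' @return numeric vector of perceived durations (ms).
#' @export
#' @examples
#' set.seed(1)
#' mean(percept_sample(200, 0.1, n = 1000))
percept_sample <- function(duration, noise_coeff, n = 1) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop_invalid("duration must be a single positive number")
  }
  if (!is.numeric(noise_coeff) || length(noise_coeff) != 1 ||
      noise_coeff <= 0) {
    stop_invalid("noise_coeff must be a single positive number")
  }
  x <- rnorm(n, mean = duration, sd = noise_coeff * duration)
  bad <- which(x <= 0)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean = duration, sd = noise_coeff * duration)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Simulate one 2IFC response
#'
#' With probability `lapse_rate` the observer guesses uniformly; otherwise it
#' samples a percept for each interval (scalar noise at the given
#' coefficient) and reports the interval with the larger percept. Percept
#' ties (measure zero for continuous noise) are broken at random.
#' Correctness is judged against the physically longer interval; when
#' `t1 == t2` no longer interval exists and correctness is assigned at
#' random with probability 0.5 (degenerate-input guard: the staircase never
#' presents exact ties while its difference floor is positive).
#'
#' @param t1,t2 durations of the first and second interval (ms), > 0.
#' @param observer an `observer_params` object.
#' @param condition condition key present in `observer$conditions`.
#' @param session_index session index passed to [wf_trajectory()] to pick
#'   the session-appropriate noise coefficient.
#' @return list with `choice` (1 or 2) and `correct` (logical).
#' @export
respond_2ifc <- function(t1, t2, observer, condition, session_index = 0) {
  stopifnot(inherits(observer, "observer_params"))
  if (!is.numeric(t1) || t1 <= 0 || !is.numeric(t2) || t2 <= 0) {
    stop_invalid("interval durations must be positive")
  }
  w <- wf_trajectory(observer, session_index, condition)
  if (observer$lapse_rate > 0 && runif(1) < observer$lapse_rate) {
    choice <- sample(1:2, 1)
  } else {
    p1 <- percept_sample(t1, w)
    p2 <- percept_sample(t2, w)
    choice <- if (p1 > p2) 1L else if (p2 > p1) 2L else sample(1:2, 1)
  }
  correct <- if (t1 == t2) {
    runif(1) < 0.5
  } else if (t1 > t2) {
    choice == 1L
  } else {
    choice == 2L
  }
  list(choice = as.integer(choice), correct = correct)
}

#' Effective internal noise coefficient at a given session
#'
#' Exponential learning dynamics:
#' `wf(s) = wf_asymptote + (wf_start - wf_asymptote) * exp(-s / tau)`.
#' Session 0 is the pre-test (returns `wf_start` exactly); training days are
#' sessions 1-4 and the post-test is session 5. Conditions configured flat
#' (`wf_asymptote == wf_start`) return `wf_start` for every session. The
#' `tau -> 0` limit jumps to the asymptote from session 1 onward.
#'
#' @param observer an `observer_params` object.
#' @param session_index session index, >= 0.
#' @param condition condition key.
#' @return effective internal Weber fraction (dimensionless).
#' @export
#' @examples
#' obs <- default_observer("EI")
#' wf_trajectory(obs, 0, "empty_200")  # pre-test: 0.20
#' wf_trajectory(obs, 5, "empty_200")  # post-test: close to 0.13
wf_trajectory <- function(observer, session_index, condition) {
  stopifnot(inherits(observer, "observer_params"))
  if (!is.numeric(session_index) || length(session_index) != 1 ||
      session_index < 0) {
    stop_invalid("session_index must be a single number >= 0")
  }
  cc <- observer$conditions[[condition]]
  if (is.null(cc)) {
    stop_invalid("observer '%s' has no parameters for condition '%s'",
                 observer$id, condition)
  }
  if (cc$tau_sessions < 0) stop_invalid("tau_sessions must be >= 0")
  if (cc$wf_asymptote == cc$wf_start) return(cc$wf_start)
  if (cc$tau_sessions == 0) {
    return(if (session_index >= 1) cc$wf_asymptote else cc$wf_start)
  }
  cc$wf_asymptote +
    (cc$wf_start - cc$wf_asymptote) * exp(-session_index / cc$tau_sessions)
}

#' Closed-form 2IFC probability correct
#'
#' For a comparison interval `T + delta` against a standard `T`, with
#' independent Gaussian percepts of standard deviation `w * duration`
#' (scalar noise), the probability of choosing the comparison is
#' `pnorm(delta / sqrt(w^2 * (T + delta)^2 + w^2 * T^2))`. A lapse rate
#' `lambda` mixes in chance: `lambda / 2 + (1 - lambda) * p`.
#'
#' @param delta duration difference Δt in ms (>= 0).
#' @param standard_T standard interval in ms.
#' @param noise_coeff internal Weber fraction.
#' @param lapse_rate lapse probability.
#' @return probability of a correct response (vectorised over `delta`).
#' @export
#' @examples
#' psychometric_2ifc(40, 200, 0.1)
psychometric_2ifc <- function(delta, standard_T, noise_coeff,
                              lapse_rate = 0) {
  if (standard_T <= 0 || noise_coeff <= 0) {
    stop_invalid("standard_T and noise_coeff must be positive")
  }
  sigma <- noise_coeff * sqrt((standard_T + delta)^2 + standard_T^2)
  p <- pnorm(delta / sigma)
  lapse_rate / 2 + (1 - lapse_rate) * p
}

#' Invert the 2IFC psychometric function
#'
#' Finds the Δt at which [psychometric_2ifc()] equals a target probability —
#' e.g. the true 79.4% point tracked by a one-up-three-down staircase.
#'
#' @param p_target target probability correct, in (0.5, 1).
#' @param standard_T standard interval in ms.
#' @param noise_coeff internal Weber fraction.
#' @param lapse_rate lapse probability (must leave `p_target` attainable).
#' @return Δt in ms.
#' @export
#' @examples
#' invert_psychometric(0.5^(1 / 3), 200, 0.1)
invert_psychometric <- function(p_target, standard_T, noise_coeff,
                                lapse_rate = 0) {
  p_max <- lapse_rate / 2 + (1 - lapse_rate)
  if (p_target <= 0.5 || p_target >= p_max) {
    stop_invalid("p_target must lie in (0.5, %.4g)", p_max)
  }
  f <- function(d) {
    psychometric_2ifc(d, standard_T, noise_coeff, lapse_rate) - p_target
  }
  uniroot(f, lower = 1e-9, upper = 100 * standard_T, tol = 1e-10)$root
}

#' Generate a cohort of jittered observers
#'
#' Emits `n` observers of one group around the [default_observer()]
#' parameterisation, with log-normal inter-individual jitter on `wf_start`
#' (multiplicative factor `exp(rnorm(1, 0, jitter_sd))`). Improving
#' conditions keep the default asymptote-to-start ratio so every individual
#' shares the same proportional learning capacity; lapse rate and tau are
#' common to the cohort.
#'
#' @param n number of observers.
#' @param group `"EI"` or `"FI"`.
#' @param seed integer seed for the jitter draws.
#' @param jitter_sd standard deviation of the log-normal jitter.
#' @param ... further arguments passed to [default_observer()].
#' @return list of `observer_params`.
#' @export
#' @examples
#' cohort <- make_cohort(3, "EI", seed = 42)
#' length(cohort)
make_cohort <- function(n, group = c("EI", "FI"), seed = 1,
                        jitter_sd = 0.12, ...) {
  group <- match.arg(group)
  if (n < 1) stop_invalid("n must be >= 1")
  base <- default_observer(group, ...)
  ratio <- vapply(base$conditions,
                  function(cc) cc$wf_asymptote / cc$wf_start, numeric(1))
  set.seed(mix_seed(seed, match(group, c("EI", "FI"))))
  factors <- exp(rnorm(n, 0, jitter_sd))
  lapply(seq_len(n), function(i) {
    conds <- base$conditions
    for (key in names(conds)) {
      conds[[key]]$wf_start <- base$conditions[[key]]$wf_start * factors[i]
      conds[[key]]$wf_asymptote <- conds[[key]]$wf_start * ratio[key]
    }
    observer_params(group = group, lapse_rate = base$lapse_rate,
                    conditions = conds,
                    id = sprintf("%s%02d", group, i))
  })
}
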