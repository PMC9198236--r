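#' Reversal-based block threshold
#'
#' Estimates the block threshold as the arithmetic mean of the reversal Δt
#' values excluding the first three reversals. Blocks with fewer than five
#' reversals are excluded — exclusion is a value (`NA` with a reason), not
#' an error.
#'
#' @param reversal_values numeric vector of Δt values at reversals, in
#'   occurrence order, non-negative.
#' @param n_excluded_reversals number of initial reversals to discard.
#' @param min_reversals minimum number of reversals for a usable block.
#' @return list with `threshold` (ms, or `NA`), `n_reversals`, and
#'   `exclusion_reason` (`"none"` or `"too-few-reversals"`).
#' @export
#' @examples
#' block_threshold(c(30, 50, 30, 40, 20, 30))$threshold  # mean(40, 20, 30) = 30
block_threshold <- function(reversal_values, n_excluded_reversals = 3,
                            min_reversals = 5) {
  if (length(reversal_values) > 0 &&
      (!is.numeric(reversal_values) || any(reversal_values < 0))) {
    stop_invalid("reversal_values must be non-negative numbers")
  }
  n <- length(reversal_values)
  if (n < min_reversals) {
    return(list(threshold = NA_real_, n_reversals = n,
                exclusion_reason = "too-few-reversals"))
  }
  list(
    threshold = mean(reversal_values[(n_excluded_reversals + 1):n]),
    n_reversals = n,
    exclusion_reason = "none"
  )
}

#' Weber fraction
#'
#' The discrimination threshold Δt divided by the standard interval T — the
#' dimensionless unit of timing precision.
#'
#' @param threshold threshold Δt in ms (vectorised; `NA` passes through).
#' @param standard_T standard interval in ms, > 0.
#' @return Δt / T.
#' @export
#' @examples
#' weber_fraction(40, 200)  # 0.2
weber_fraction <- function(threshold, standard_T) {
  if (!is.numeric(standard_T) || any(standard_T <= 0)) {
    stop_invalid("standard_T must be positive")
  }
  threshold / standard_T
}

#' Session threshold with robust block screening
#'
#' Screens the blocks of one participant-session for outliers — values more
#' than three scaled median absolute deviations (MAD, normal-consistency
#' constant 1.4826) from the session's central value — and returns the mean
#' of the survivors. By default the center is the participant-session
#' median, the center a MAD criterion is coherent around; a group-session
#' mean can be supplied via `center` instead. The screen is the strict
#' `|x - center| <= n_mad * MAD` rule: when every block equals the center
#' the MAD is zero and nothing is excluded, while a zero MAD with
#' discrepant blocks removes exactly the blocks off the center (should
#' every block be removed — possible only with an external center matching
#' no block — all are kept as a degenerate-input guard).
#'
#' @param block_wfs numeric vector of block Weber fractions for one
#'   participant-session (`NA`s, i.e. already-excluded blocks, are dropped
#'   first).
#' @param n_mad exclusion radius in scaled-MAD units.
#' @param center optional numeric center; default is the median of
#'   `block_wfs`.
#' @return list with `session_wf` (mean of surviving blocks), `kept`
#'   (logical vector over the non-`NA` input), and `n_excluded`.
#' @export
#' @examples
#' session_threshold(c(rep(0.2, 11), 5))$session_wf  # outlier removed: 0.2
session_threshold <- function(block_wfs, n_mad = 3, center = NULL) {
  x <- block_wfs[!is.na(block_wfs)]
  if (length(x) == 0) {
    stop_invalid("session has no usable blocks")
  }
  if (is.null(center)) center <- median(x)
  s_mad <- mad(x, center = center, constant = 1.4826)
  kept <- abs(x - center) <= n_mad * s_mad
  if (!any(kept)) kept <- rep(TRUE, length(x))  # degenerate: keep all
  list(session_wf = mean(x[kept]), kept = kept,
       n_excluded = sum(!kept))
}

#' Participant-level exclusion
#'
#' Flags a participant-session when its Weber fraction exceeds the group
#' mean by more than `n_sd` group standard deviations (computed across
#' participants of the same group, per session), and excludes a participant
#' when more than `max_flags` sessions are flagged. Sessions with zero group
#' SD produce no flags. Deterministic.
#'
#' @param session_wfs tibble/data.frame with columns `participant`,
#'   `group`, `session`, `wf`.
#' @param n_sd flagging radius in group standard deviations.
#' @param max_flags maximum number of flagged sessions a participant may
#'   have and still be kept ("more than one" rule: default 1).
#' @return tibble with columns `participant`, `group`, `n_flagged`,
#'   `excluded`.
#' @export
exclude_participants <- function(session_wfs, n_sd = 3, max_flags = 1) {
  required <- c("participant", "group", "session", "wf")
  missing_cols <- setdiff(required, names(session_wfs))
  if (length(missing_cols) > 0) {
    stop_invalid("session_wfs lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  flagged <- session_wfs |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::mutate(
      grp_mean = mean(.data$wf, na.rm = TRUE),
      grp_sd = sd(.data$wf, na.rm = TRUE),
      flagged = !is.na(.data$wf) & !is.na(.data$grp_sd) & .data$grp_sd > 0 &
        .data$wf > .data$grp_mean + n_sd * .data$grp_sd
    ) |>
    dplyr::ungroup()
  flagged |>
    dplyr::group_by(.data$participant, .data$group) |>
    dplyr::summarise(n_flagged = sum(.data$flagged), .groups = "drop") |>
    dplyr::mutate(excluded = .data$n_flagged > max_flags)
}

#' Reduce a trial log to block-level thresholds
#'
#' Groups a trial-level log (the schema written by [simulate_experiment()]
#' or [write_trial_log()]) by participant, phase, session, block and
#' condition, collects the reversal Δt values in trial order, and applies
#' [block_threshold()] and [weber_fraction()]. Practice trials are dropped.
#'
#' @param trials tibble in the trial-log schema (see [trial_log_columns()]).
#' @return tibble with one row per block: `participant`, `group`, `phase`,
#'   `session`, `block`, `condition`, `condition_format`,
#'   `condition_duration`, `n_reversals`, `threshold_ms`, `wf`,
#'   `exclusion_reason`.
#' @export
block_table <- function(trials) {
  validate_trial_log(trials)
  trials |>
    dplyr::filter(.data$phase != "practice") |>
    dplyr::arrange(.data$participant, .data$session, .data$block,
                   .data$trial) |>
    dplyr::group_by(.data$participant, .data$group, .data$phase,
                    .data$session, .data$block, .data$condition_format,
                    .data$condition_duration) |>
    dplyr::summarise(
      n_reversals = sum(.data$reversal),
      threshold_ms = block_threshold(.data$delta_ms[.data$reversal])$threshold,
      exclusion_reason = block_threshold(
        .data$delta_ms[.data$reversal])$exclusion_reason,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      condition = paste0(.data$condition_format, "_",
                         .data$condition_duration),
      wf = weber_fraction(.data$threshold_ms, .data$condition_duration)
    ) |>
    dplyr::relocate("condition", .after = "block")
}

#' Reduce block thresholds to training-session thresholds
#'
#' Applies the scaled-MAD block screen of [session_threshold()] within each
#' participant x training session and averages the surviving block Weber
#' fractions. Only training-phase blocks enter; pre/post test blocks are
#' single measurements per condition and are reported at block level.
#'
#' @param blocks output of [block_table()].
#' @param n_mad scaled-MAD exclusion radius.
#' @param center `"participant_median"` (default) or `"group_mean"` — the
#'   center used by the MAD screen.
#' @return tibble with one row per participant x training session:
#'   `participant`, `group`, `session`, `condition`, `wf`,
#'   `n_blocks_used`, `n_blocks_outlier`.
#' @export
session_table <- function(blocks, n_mad = 3,
                          center = c("participant_median", "group_mean")) {
  center <- match.arg(center)
  train <- blocks |> dplyr::filter(.data$phase == "train")
  if (nrow(train) == 0) {
    stop_invalid("no training-phase blocks in input")
  }
  group_centers <- train |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(grp_center = mean(.data$wf, na.rm = TRUE),
                     .groups = "drop")
  train |>
    dplyr::left_join(group_centers, by = c("group", "session")) |>
    dplyr::group_by(.data$participant, .data$group, .data$session,
                    .data$condition) |>
    dplyr::summarise(
      res = list(session_threshold(
        .data$wf, n_mad = n_mad,
        center = if (center == "group_mean") .data$grp_center[1] else NULL)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      wf = vapply(.data$res, function(r) r$session_wf, numeric(1)),
      n_blocks_used = vapply(.data$res, function(r) sum(r$kept), integer(1)),
      n_blocks_outlier = vapply(.data$res, function(r) r$n_excluded,
                                integer(1))
    ) |>
    dplyr::select(-"res")
}
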