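#' Columns of the trial-level log
#'
#' The canonical schema for trial logs written by [simulate_experiment()]
#' and consumed by [run_pipeline()]: one row per trial.
#'
#' @return named character vector mapping column name to type
#'   (`"character"`, `"integer"`, `"double"`, `"logical"`).
#' @export
trial_log_columns <- function() {
  c(participant = "character", group = "character", phase = "character",
    session = "integer", block = "integer", condition_format = "character",
    condition_duration = "double", trial = "integer", delta_ms = "double",
    order = "integer", choice = "integer", correct = "logical",
    reversal = "logical", step_ms = "double", seed = "integer")
}

validate_trial_log <- function(trials) {
  cols <- trial_log_columns()
  missing_cols <- setdiff(names(cols), names(trials))
  if (length(missing_cols) > 0) {
    stop_invalid("trial log lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  if (nrow(trials) == 0) stop_invalid("trial log is empty")
  bad_phase <- which(!trials$phase %in% c("practice", "pre", "train", "post"))
  if (length(bad_phase) > 0) {
    stop_invalid("row %d: unknown phase '%s'", bad_phase[1],
                 trials$phase[bad_phase[1]])
  }
  bad_fmt <- which(!trials$condition_format %in% CONDITION_FORMATS)
  if (length(bad_fmt) > 0) {
    stop_invalid("row %d: unknown condition_format '%s'", bad_fmt[1],
                 trials$condition_format[bad_fmt[1]])
  }
  bad_delta <- which(!is.finite(trials$delta_ms) | trials$delta_ms <= 0)
  if (length(bad_delta) > 0) {
    stop_invalid("row %d: delta_ms must be positive", bad_delta[1])
  }
  invisible(trials)
}

#' Build the study schedule for one participant
#'
#' The five-day design: a pre-test (day 1) of four 60-trial blocks, one per
#' condition (empty/filled x 200/400 ms); four training sessions (days 1-4)
#' of 12 blocks on the group's trained condition — empty-200 ms for the EI
#' group, filled-200 ms for the FI group; and a post-test (day 5) identical
#' in structure to the pre-test. Ten practice trials precede the pre-test
#' (simulated but excluded from analysis). Session indices run 0 (pre)
#' through 5 (post).
#'
#' @param group `"EI"` or `"FI"`.
#' @param seed optional integer seed for shuffling the pre/post block order;
#'   `NULL` keeps the fixed canonical order (useful for regression tests).
#' @return tibble with one row per block: `phase`, `day`, `session`,
#'   `block`, `condition`, `condition_format`, `condition_duration`,
#'   `n_trials`.
#' @export
#' @examples
#' sched <- build_schedule("EI")
#' sum(sched$n_trials[sched$phase == "train"])  # 2880
build_schedule <- function(group = c("EI", "FI"), seed = NULL) {
  group <- match.arg(group)
  trained <- if (group == "EI") "empty_200" else "filled_200"
  conds <- test_conditions()
  pre_order <- seq_len(nrow(conds))
  post_order <- seq_len(nrow(conds))
  if (!is.null(seed)) {
    set.seed(mix_seed(seed, 1))
    pre_order <- sample(pre_order)
    post_order <- sample(post_order)
  }
  block_rows <- function(phase, day, session, idx, n_trials = 60) {
    tibble::tibble(
      phase = phase, day = day, session = session,
      block = seq_along(idx),
      condition = conds$condition[idx],
      condition_format = conds$format[idx],
      condition_duration = conds$duration_ms[idx],
      n_trials = n_trials
    )
  }
  trained_idx <- match(trained, conds$condition)
  practice <- block_rows("practice", 1L, 0L, pre_order[1], n_trials = 10)
  practice$block <- 0L
  pre <- block_rows("pre", 1L, 0L, pre_order)
  train <- dplyr::bind_rows(lapply(1:4, function(d) {
    block_rows("train", d, d, rep(trained_idx, 12))
  }))
  post <- block_rows("post", 5L, 5L, post_order)
  dplyr::bind_rows(practice, pre, train, post)
}

#' Simulate the full experiment for a cohort
#'
#' Runs every scheduled block of every observer through [run_block()], with
#' the observer's session-appropriate internal noise from
#' [wf_trajectory()], and returns the combined trial-level log. Fully
#' reproducible: each participant receives a seed derived deterministically
#' from the master seed, split into per-block sub-seeds, so any block can
#' be re-simulated in isolation.
#'
#' @param cohort list of [observer_params()] objects (e.g. from
#'   [make_cohort()]); a single observer is also accepted.
#' @param seed master integer seed.
#' @param staircase_opts named list of [staircase_config()] arguments other
#'   than `standard_T` (e.g. `trials_per_block`), applied to every block.
#' @param shuffle_tests logical; shuffle pre/post block order per
#'   participant (default) or keep the canonical fixed order.
#' @return tibble in the trial-log schema ([trial_log_columns()]).
#' @export
#' @examples
#' log1 <- simulate_experiment(default_observer("EI", id = "p1"), seed = 1)
#' nrow(log1)  # 10 + 240 + 2880 + 240 = 3370
simulate_experiment <- function(cohort, seed = 1, staircase_opts = list(),
                                shuffle_tests = TRUE) {
  if (inherits(cohort, "observer_params")) cohort <- list(cohort)
  stopifnot(length(cohort) > 0,
            all(vapply(cohort, inherits, logical(1), "observer_params")))
  cfg_cache <- new.env(parent = emptyenv())
  get_cfg <- function(T0, n_trials) {
    key <- paste0(T0, "_", n_trials)
    if (is.null(cfg_cache[[key]])) {
      args <- c(list(standard_T = T0), staircase_opts)
      args$trials_per_block <- n_trials
      cfg_cache[[key]] <- do.call(staircase_config, args)
    }
    cfg_cache[[key]]
  }
  phase_code <- c(practice = 1L, pre = 2L, train = 3L, post = 4L)
  out <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    obs <- cohort[[i]]
    p_seed <- mix_seed(seed, i, match(obs$group, c("EI", "FI")))
    sched <- build_schedule(obs$group,
                            seed = if (shuffle_tests) p_seed else NULL)
    blocks <- vector("list", nrow(sched))
    for (b in seq_len(nrow(sched))) {
      row <- sched[b, ]
      cfg <- get_cfg(row$condition_duration, row$n_trials)
      b_seed <- mix_seed(p_seed, phase_code[[row$phase]], row$session,
                         row$block)
      blk <- run_block(cfg, obs, row$condition,
                       session_index = row$session, seed = b_seed)
      blocks[[b]] <- dplyr::mutate(
        blk$trials,
        participant = obs$id, group = obs$group, phase = row$phase,
        session = row$session, block = row$block,
        condition_format = row$condition_format,
        condition_duration = row$condition_duration, seed = b_seed
      )
    }
    out[[i]] <- dplyr::bind_rows(blocks)
  }
  dplyr::bind_rows(out) |>
    dplyr::select(dplyr::all_of(names(trial_log_columns())))
}

#' Write / read a trial log as CSV
#'
#' Plain-text persistence of the trial-log schema; the round trip is exact
#' (identical tibbles up to readr's column typing, which is pinned to the
#' schema).
#'
#' @param trials tibble in the trial-log schema.
#' @param path CSV file path.
#' @return `write_trial_log()` returns `path` invisibly; `read_trial_log()`
#'   returns the validated tibble.
#' @export
write_trial_log <- function(trials, path) {
  validate_trial_log(trials)
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  if (file.size(path) == 0) stop_invalid("trial log '%s' is empty", path)
  cols <- trial_log_columns()
  spec <- do.call(readr::cols, lapply(cols, function(tp) {
    switch(tp,
           character = readr::col_character(),
           integer = readr::col_integer(),
           double = readr::col_double(),
           logical = readr::col_logical())
  }))
  trials <- readr::read_csv(path, col_types = spec, progress = FALSE)
  probs <- readr::problems(trials)
  if (nrow(probs) > 0) {
    stop_invalid("parse error in '%s' at row %d: expected %s, got '%s'",
                 path, probs$row[1], probs$expected[1], probs$actual[1])
  }
  validate_trial_log(trials)
  trials
}

#' Run the full analysis pipeline on a trial log
#'
#' Deterministic reduction of a trial-level log to all derived tables:
#' block thresholds and Weber fractions ([block_table()]), training-session
#' thresholds with scaled-MAD block screening ([session_table()]),
#' participant exclusion on training sessions ([exclude_participants()]),
#' per-participant learning summaries and learner flags
#' ([learning_summaries()]), the group-level learning-index table
#' ([group_summary()]), and per-participant learning curves. Participant
#' exclusion is applied once, before the learning analysis, using
#' training-session Weber fractions only.
#'
#' @param trials a trial-log tibble, or a path to a CSV in the trial-log
#'   schema.
#' @param n_mad scaled-MAD radius for block screening.
#' @param mad_center center for the MAD screen (see [session_table()]).
#' @param n_sd group-SD radius for participant flagging.
#' @param max_flags flagged-session tolerance before a participant is
#'   excluded.
#' @return object of class `tpl_pipeline`: a list with elements `blocks`,
#'   `sessions`, `participants` (exclusion table), `summaries`, `groups`,
#'   `curves`, and `counts` (per-stage bookkeeping).
#' @export
run_pipeline <- function(trials, n_mad = 3,
                         mad_center = c("participant_median", "group_mean"),
                         n_sd = 3, max_flags = 1) {
  mad_center <- match.arg(mad_center)
  if (is.character(trials) && length(trials) == 1) {
    trials <- read_trial_log(trials)
  }
  validate_trial_log(trials)
  blocks <- block_table(trials)
  sessions <- session_table(blocks, n_mad = n_mad, center = mad_center)
  participants <- exclude_participants(sessions, n_sd = n_sd,
                                       max_flags = max_flags)
  kept_ids <- participants$participant[!participants$excluded]
  blocks_kept <- blocks |> dplyr::filter(.data$participant %in% kept_ids)
  sessions_kept <- sessions |> dplyr::filter(.data$participant %in% kept_ids)
  summaries <- learning_summaries(blocks_kept)
  groups <- group_summary(summaries)
  curves <- dplyr::bind_rows(lapply(kept_ids, function(p) {
    cv <- learning_curve(blocks_kept, sessions_kept, p)
    cv$group <- blocks_kept$group[blocks_kept$participant == p][1]
    cv
  }))
  counts <- list(
    n_trials = nrow(trials),
    n_blocks = nrow(blocks),
    n_blocks_excluded = sum(blocks$exclusion_reason != "none"),
    n_participants = nrow(participants),
    n_participants_excluded = sum(participants$excluded)
  )
  structure(
    list(blocks = blocks, sessions = sessions, participants = participants,
         summaries = summaries, groups = groups, curves = curves,
         counts = counts),
    class = "tpl_pipeline"
  )
}

#' @export
print.tpl_pipeline <- function(x, ...) {
  cat("<tpl_pipeline>\n")
  cat(sprintf("  trials: %d  blocks: %d (excluded: %d)\n",
              x$counts$n_trials, x$counts$n_blocks,
              x$counts$n_blocks_excluded))
  cat(sprintf("  participants: %d (excluded: %d)\n",
              x$counts$n_participants, x$counts$n_participants_excluded))
  cat("  group learning-index table:\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' Write all pipeline tables to a directory
#'
#' Emits block-, session-, participant- and group-level CSVs plus a
#' manifest (JSON when jsonlite is available, YAML otherwise) recording the
#' options used.
#'
#' @param pipeline a `tpl_pipeline` object.
#' @param out_dir output directory (created if absent).
#' @param seed optional seed to record in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(pipeline, out_dir, seed = NULL) {
  stopifnot(inherits(pipeline, "tpl_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(pipeline$blocks, file.path(out_dir, "blocks.csv"))
  readr::write_csv(pipeline$sessions, file.path(out_dir, "sessions.csv"))
  readr::write_csv(pipeline$participants,
                   file.path(out_dir, "participants.csv"))
  readr::write_csv(pipeline$summaries, file.path(out_dir, "summaries.csv"))
  readr::write_csv(pipeline$groups, file.path(out_dir, "groups.csv"))
  readr::write_csv(pipeline$curves, file.path(out_dir, "curves.csv"))
  manifest <- list(created = format(Sys.time(), tz = "UTC"),
                   seed = seed, counts = pipeline$counts,
                   hash = rlang::hash(pipeline$blocks))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
  } else {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(out_dir)
}

#' Load an experiment configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) configuration with optional
#' sections `observer`, `staircase`, `cohort` and `analysis`, filling
#' defaults for anything unspecified.
#'
#' @param path configuration file path.
#' @return nested list with the four sections, defaults applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_invalid("no such config file: %s", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_invalid("config '%s' is not a mapping", path)
  defaults <- list(
    observer = list(wf_start = 0.20, wf_asymptote = 0.13,
                    tau_sessions = 1.5, lapse_rate = 0.02),
    cohort = list(n_ei = 11, n_fi = 12, jitter_sd = 0.12),
    staircase = list(initial_delta_fraction = 0.20,
                     coarse_step_fraction = 0.10,
                     fine_step_fraction = 0.05,
                     step_change_after_reversal = 3,
                     trials_per_block = 60),
    analysis = list(n_mad = 3, mad_center = "participant_median",
                    n_sd = 3, max_flags = 1)
  )
  for (sec in names(defaults)) {
    user <- raw[[sec]]
    if (!is.null(user) && !is.list(user)) {
      stop_invalid("config section '%s' must be a mapping", sec)
    }
    unknown <- setdiff(names(user), names(defaults[[sec]]))
    if (length(unknown) > 0) {
      stop_invalid("unknown key '%s' in config section '%s'",
                   unknown[1], sec)
    }
    defaults[[sec]][names(user)] <- user
  }
  defaults
}

#' Build the study cohorts from a configuration
#'
#' @param config output of [load_config()] (or a compatible list).
#' @param seed integer seed for inter-individual jitter.
#' @return list of `observer_params` covering both groups.
#' @export
cohort_from_config <- function(config, seed = 1) {
  ob <- config$observer
  co <- config$cohort
  c(
    make_cohort(co$n_ei, "EI", seed = seed, jitter_sd = co$jitter_sd,
                wf_start = ob$wf_start, wf_asymptote = ob$wf_asymptote,
                tau_sessions = ob$tau_sessions, lapse_rate = ob$lapse_rate),
    make_cohort(co$n_fi, "FI", seed = seed + 1, jitter_sd = co$jitter_sd,
                wf_start = ob$wf_start, wf_asymptote = ob$wf_asymptote,
                tau_sessions = ob$tau_sessions, lapse_rate = ob$lapse_rate)
  )
}
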