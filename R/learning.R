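#' Learning index
#'
#' Percentage change in the pre-test threshold:
#' `(pre - post) / pre`. Positive values indicate improvement
#' (the post-test Weber fraction decreased). Scale-invariant: multiplying
#' both thresholds by any positive constant leaves it unchanged.
#'
#' @param pre_wf pre-test Weber fraction, > 0 (vectorised).
#' @param post_wf post-test Weber fraction (vectorised).
#' @return dimensionless learning index.
#' @export
#' @examples
#' learning_index(0.2, 0.13)  # 0.35
learning_index <- function(pre_wf, post_wf) {
  if (!is.numeric(pre_wf) || !is.numeric(post_wf)) {
    stop_invalid("pre_wf and post_wf must be numeric")
  }
  if (any(pre_wf <= 0, na.rm = TRUE)) {
    stop_invalid("pre_wf must be strictly positive")
  }
  (pre_wf - post_wf) / pre_wf
}

#' Per-participant learning summaries
#'
#' Pairs pre- and post-test block Weber fractions per participant and
#' condition, computes the learning index, and classifies learners — a
#' learner is a participant whose threshold on the trained condition
#' strictly decreased from pre- to post-test (ties are non-learners).
#'
#' @param blocks output of [block_table()] containing `pre` and `post`
#'   phase rows.
#' @param trained_condition_by_group named character vector mapping group
#'   label to its trained condition key; the default is the standard design
#'   (EI trains empty-200 ms, FI trains filled-200 ms).
#' @return tibble with one row per participant x condition: `participant`,
#'   `group`, `condition`, `pre_wf`, `post_wf`, `learning_index`,
#'   `improved` (this condition's threshold decreased), `learner`
#'   (improvement on the trained condition, repeated on all of the
#'   participant's rows), `trained` (whether this row is the trained
#'   condition).
#' @export
learning_summaries <- function(blocks,
                               trained_condition_by_group =
                                 c(EI = "empty_200", FI = "filled_200")) {
  tests <- blocks |>
    dplyr::filter(.data$phase %in% c("pre", "post")) |>
    dplyr::select("participant", "group", "phase", "condition", "wf") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "wf") |>
    dplyr::rename(pre_wf = "pre", post_wf = "post")
  if (!all(c("pre_wf", "post_wf") %in% names(tests))) {
    stop_invalid("blocks must contain both pre and post phase rows")
  }
  tests <- tests |>
    dplyr::mutate(
      learning_index = learning_index(.data$pre_wf, .data$post_wf),
      improved = !is.na(.data$post_wf) & !is.na(.data$pre_wf) &
        .data$post_wf < .data$pre_wf,
      trained = .data$condition ==
        unname(trained_condition_by_group[.data$group])
    )
  learners <- tests |>
    dplyr::filter(.data$trained) |>
    dplyr::select("participant", learner = "improved")
  tests |>
    dplyr::left_join(learners, by = "participant") |>
    dplyr::mutate(learner = !is.na(.data$learner) & .data$learner)
}

#' Fraction of learners in a group
#'
#' The fraction of a group's participants whose threshold on the trained
#' condition decreased from pre- to post-test.
#'
#' @param summaries output of [learning_summaries()] (any subset containing
#'   the group of interest).
#' @param group group label.
#' @param condition condition defining the learner classification; defaults
#'   to the group's trained condition as marked in `summaries`.
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' # 10 of 11 improving participants give 0.909 (reported as 91%)
learner_ratio <- function(summaries, group, condition = NULL) {
  rows <- summaries |> dplyr::filter(.data$group == !!group)
  if (is.null(condition)) {
    rows <- rows |> dplyr::filter(.data$trained)
  } else {
    rows <- rows |> dplyr::filter(.data$condition == !!condition)
  }
  if (nrow(rows) == 0) {
    stop_invalid("no participants found for group '%s'", group)
  }
  mean(rows$improved)
}

#' Learning curve for one participant
#'
#' The ordered Weber fractions on the trained condition: pre-test, training
#' sessions 1-4, post-test — six points. Missing sessions are reported as
#' `NA`, never imputed.
#'
#' @param blocks output of [block_table()] for (at least) this participant.
#' @param sessions output of [session_table()].
#' @param participant participant identifier.
#' @param excluded optional output of [exclude_participants()]; an excluded
#'   participant raises an error.
#' @return tibble with columns `participant`, `point`
#'   (`pre`, `train1`..`train4`, `post`), `session`, `wf`.
#' @export
learning_curve <- function(blocks, sessions, participant, excluded = NULL) {
  if (!is.null(excluded)) {
    row <- excluded[excluded$participant == participant, ]
    if (nrow(row) == 1 && isTRUE(row$excluded)) {
      stop_invalid("participant '%s' is excluded from analysis", participant)
    }
  }
  pb <- blocks[blocks$participant == participant, ]
  if (nrow(pb) == 0) {
    stop_invalid("no blocks found for participant '%s'", participant)
  }
  grp <- pb$group[1]
  trained <- c(EI = "empty_200", FI = "filled_200")[[grp]]
  get_test <- function(phase) {
    w <- pb$wf[pb$phase == phase & pb$condition == trained]
    if (length(w) == 0) NA_real_ else w[1]
  }
  ps <- sessions[sessions$participant == participant, ]
  get_train <- function(s) {
    w <- ps$wf[ps$session == s]
    if (length(w) == 0) NA_real_ else w[1]
  }
  curve <- tibble::tibble(
    participant = participant,
    point = c("pre", paste0("train", 1:4), "post"),
    session = c(0, 1:4, 5),
    wf = c(get_test("pre"), vapply(1:4, get_train, numeric(1)),
           get_test("post"))
  )
  if (all(is.na(curve$wf[-1]))) {
    stop_invalid(
      "participant '%s' has only pre-test data; no curve can be formed",
      participant)
  }
  curve
}

#' Group-level learning-index table
#'
#' Condition x group means of the learning index with between-subject
#' standard errors (`SEM = SD / sqrt(n)`) and cell sizes, in a tidy table
#' ready for export to any standard statistics package. Cells with a single
#' participant have an undefined SEM and are flagged.
#'
#' @param summaries output of [learning_summaries()].
#' @return tibble with columns `group`, `condition`, `n`, `mean_li`,
#'   `sem_li`, `flagged` (TRUE when `n < 2`).
#' @export
group_summary <- function(summaries) {
  summaries |>
    dplyr::filter(!is.na(.data$learning_index)) |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_li = mean(.data$learning_index),
      sem_li = ifelse(dplyr::n() >= 2,
                      sd(.data$learning_index) / sqrt(dplyr::n()),
                      NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n < 2)
}

#' Plot learning curves (cosmetic helper)
#'
#' Line plot of per-participant learning curves with the group mean
#' overlaid. Requires ggplot2.
#'
#' @param curves tibble binding rows of [learning_curve()] outputs, with a
#'   `group` column added.
#' @return a ggplot object.
#' @export
plot_learning_curves <- function(curves) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_invalid("ggplot2 is required for plotting")
  }
  curves$point <- factor(curves$point,
                         levels = c("pre", paste0("train", 1:4), "post"))
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$point, y = .data$wf,
                               group = .data$participant)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2,
                          colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Weber fraction") +
    ggplot2::theme_minimal()
}
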