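#' Analyze a table of coded trials
#'
#' One-call front end: classifies every action, summarizes each trial and
#' each group, and returns a `cup_analysis` object with [tidy()],
#' [glance()] and [autoplot()] methods.
#'
#' @param trials a trials tibble (e.g. from [read_trials()] or
#'   [generate_cohort()]).
#' @param group_by grouping columns for the group summary (default
#'   `"group_label"` if present, else `"age_class"`).
#' @param last_trial_only keep only each participant's last largest-cup
#'   trial?
#' @return A `cup_analysis` object.
#' @examples
#' trials <- generate_cohort(study_schedule()[6, ], seed = 7)
#' fit <- analyze_trials(trials)
#' glance(fit)
#' @export
analyze_trials <- function(trials, group_by = NULL, last_trial_only = FALSE) {
  stopifnot(is.data.frame(trials))
  group_by <- group_by %||%
    (if ("group_label" %in% names(trials)) "group_label" else "age_class")
  if (last_trial_only) trials <- select_last_trial(trials)
  trial_summaries <- summarize_trials(trials)
  structure(
    list(
      trials = trials,
      labeled_events = classify_trials(trials),
      trial_summaries = trial_summaries,
      group_summaries = summarize_group(trial_summaries, by = group_by),
      group_by = group_by
    ),
    class = "cup_analysis"
  )
}

#' @export
print.cup_analysis <- function(x, ...) {
  cat("<cup_analysis>\n")
  cat("  trials:       ", nrow(x$trial_summaries), "\n")
  cat("  events:       ", nrow(x$labeled_events), "\n")
  cat("  groups (", paste(x$group_by, collapse = "+"), "): ",
      nrow(x$group_summaries), "\n", sep = "")
  g <- glance(x)
  cat("  success rate: ", round_half_up(g$success_rate), "%\n", sep = "")
  cat("  subassembly family (pooled): ",
      round_half_up(g$subassembly_family_pooled_pct), "%\n", sep = "")
  invisible(x)
}

#' Tidy a cup analysis
#'
#' @param x a `cup_analysis`.
#' @param type which table to return: per-`"trial"` summaries (default),
#'   per-`"group"` summaries, or the labelled `"events"`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cup_analysis <- function(x, type = c("trials", "groups", "events"), ...) {
  type <- match.arg(type)
  switch(type, trials = x$trial_summaries, groups = x$group_summaries,
         events = x$labeled_events)
}

#' One-row overview of a cup analysis
#'
#' @param x a `cup_analysis`.
#' @param ... unused.
#' @return A one-row tibble: trial/participant/event counts, overall
#'   success rate, manipulation mean, and the pooled subassembly-family
#'   percentage (classical subassembly + unit-unit).
#' @export
glance.cup_analysis <- function(x, ...) {
  ts <- x$trial_summaries
  pooled_total <- sum(ts$total_manipulations)
  fam <- if (pooled_total > 0) {
    100 * sum(ts$n_subassembly + ts$n_unit_unit) / pooled_total
  } else 0
  tibble(
    n_trials = nrow(ts),
    n_participants = if ("participant_id" %in% names(ts)) {
      dplyr::n_distinct(ts$participant_id)
    } else NA_integer_,
    n_events = pooled_total,
    success_rate = 100 * sum(ts$success) / nrow(ts),
    manipulations_mean = mean(ts$total_manipulations),
    subassembly_family_pooled_pct = fam
  )
}

#' Strategy-mix bar chart
#'
#' Per-category percentage of manipulative actions in each group, as a
#' stacked bar per group — the standard way to show how the strategy mix
#' shifts across age classes and species.
#'
#' @param group_summaries output of [summarize_group()].
#' @param source `"mean"` (unweighted mean of participant percentages,
#'   default) or `"pooled"` (pooled counts).
#' @return A ggplot object.
#' @export
plot_strategy_mix <- function(group_summaries, source = c("mean", "pooled")) {
  source <- match.arg(source)
  prefix <- if (source == "mean") "mean_pct_" else "pooled_pct_"
  label_cols <- names(group_summaries)[seq_len(match("n_trials", names(group_summaries)) - 1L)]
  long <- group_summaries %>%
    select(all_of(label_cols), dplyr::starts_with(prefix)) %>%
    tidyr::pivot_longer(dplyr::starts_with(prefix), names_to = "category",
                        values_to = "pct") %>%
    mutate(category = factor(sub(prefix, "", .data$category),
                             levels = rev(strategy_levels())))
  group_col <- label_cols[[1]]
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group_col]], y = .data$pct,
                                     fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set1", direction = -1) +
    ggplot2::labs(x = NULL, y = "% of manipulative actions", fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_strategy_mix
#' @param object a `cup_analysis`.
#' @param ... passed on to [plot_strategy_mix()].
#' @export
autoplot.cup_analysis <- function(object, ...) {
  plot_strategy_mix(object$group_summaries, ...)
}
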