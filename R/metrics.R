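# Trial- and group-level summaries: per-category counts and percentages of
# the actions in a trial, success (complete seriation of all provided cups),
# maximum nesting, hierarchical level; age-class binning and last-trial
# selection for developmental cohorts.

#' Round half away from zero
#'
#' Presentation rounding for percentages (R's `round()` rounds half to
#' even). Internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # the epsilon keeps values stored just below an exact .5 (e.g. 47.85)
  # rounding up as a human would
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' The six age classes
#'
#' Inclusive month bins used to group child participants: 12–17, 18–23,
#' 24–29, 30–35, 36–41 and 42–48 completed months (the last bin runs to a
#' full 4 years).
#'
#' @return A tibble with columns `age_class`, `lower_months`, `upper_months`.
#' @export
age_classes <- function() {
  tibble(
    age_class = c("1y0m-1y5m", "1y6m-1y11m", "2y0m-2y5m",
                  "2y6m-2y11m", "3y0m-3y5m", "3y6m-4y0m"),
    lower_months = c(12L, 18L, 24L, 30L, 36L, 42L),
    upper_months = c(17L, 23L, 29L, 35L, 41L, 48L)
  )
}

#' Assign ages in months to age classes
#'
#' @param age_months integer vector of completed months.
#' @return Factor over the six class labels; `NA` outside 12–48 months.
#' @export
assign_age_class <- function(age_months) {
  ac <- age_classes()
  idx <- findInterval(age_months, c(ac$lower_months, ac$upper_months[6] + 1L))
  idx[idx < 1 | idx > 6 | is.na(age_months)] <- NA_integer_
  factor(ac$age_class[idx], levels = ac$age_class)
}

#' Select each participant's analysis trial
#'
#' Among each participant's trials with their maximal number of cups
#' provided, keeps the chronologically last (by `date` when present,
#' otherwise by row order). The cup-count key dominates recency: an earlier
#' trial with more cups beats a later one with fewer.
#'
#' @param trials a trials tibble with `participant_id` and `n_cups`
#'   (optionally `date`).
#' @return A tibble with one row per participant.
#' @export
select_last_trial <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  trials %>%
    group_by(.data$participant_id) %>%
    filter(.data$n_cups == max(.data$n_cups)) %>%
    { if ("date" %in% names(.)) arrange(., .data$date, .by_group = TRUE) else . } %>%
    slice_tail(n = 1) %>%
    ungroup()
}

count_cols <- function() paste0("n_", strategy_levels())
pct_cols <- function() paste0("pct_", strategy_levels())

summary_core <- function(labels, n_cups, final_state) {
  counts <- as.integer(table(factor(labels, levels = strategy_levels())))
  total <- length(labels)
  pct <- if (total > 0) 100 * counts / total else rep(0, length(counts))
  row <- c(list(total_manipulations = total,
                success = is_complete_seriation(final_state),
                max_nesting = max_nesting(final_state),
                hierarchical_level_final = hierarchical_level(final_state),
                zero_events = total == 0L),
           setNames(as.list(counts), count_cols()),
           setNames(as.list(pct), pct_cols()))
  as_tibble(row)
}

#' Summarize one trial
#'
#' Classifies the trial's actions and reduces them to the per-trial record:
#' total manipulations, per-category counts and percentages (each category's
#' count divided by the total number of actions in the trial), success
#' (complete seriation of all provided cups at the end), maximum nesting
#' achieved, and the hierarchical level of the final structure. A trial with
#' no events gets zero percentages and `zero_events = TRUE` rather than
#' `NaN`s.
#'
#' @param events an event table or coded-sequence string.
#' @param n_cups number of cups provided.
#' @return A one-row tibble.
#' @examples
#' summarize_trial("1N2/12N3", n_cups = 3)
#' @export
summarize_trial <- function(events, n_cups) {
  if (is.character(events)) events <- parse_sequence(events, n_cups = n_cups)
  labelled <- classify_trial(events, n_cups)
  final <- attr(labelled, "final_state")
  dplyr::bind_cols(tibble(n_cups = as.integer(n_cups)),
                   summary_core(as.character(labelled$label), n_cups, final))
}

#' Summarize every trial of a trials table
#'
#' @param trials a trials tibble (see [classify_trials()] for expected
#'   columns).
#' @return A tibble with one row per trial: metadata plus the
#'   [summarize_trial()] columns.
#' @export
summarize_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  meta_cols <- intersect(c("participant_id", "species", "age_months",
                           "age_class", "group_label", "trial_id", "date"),
                         names(trials))
  rows <- map(seq_len(nrow(trials)), function(i) {
    ev <- if ("events" %in% names(trials) && !is.null(trials$events[[i]])) {
      trials$events[[i]]
    } else {
      trials$sequence[[i]]
    }
    dplyr::bind_cols(trials[i, meta_cols, drop = FALSE],
                     summarize_trial(ev, n_cups = trials$n_cups[[i]]))
  })
  list_rbind(rows)
}

#' Build a trial summary from published category counts
#'
#' Tables of per-individual category counts are the form in which coded
#' nesting-cup data are typically published; this constructs the same row
#' [summarize_trial()] would have produced, from counts alone (success and
#' nesting columns are taken from the arguments since they are not
#' recoverable from counts).
#'
#' @param counts named numeric vector; names must be among
#'   [strategy_levels()]. Unnamed categories count zero.
#' @param n_cups,success,max_nesting optional trial facts to carry along.
#' @return A one-row tibble with the [summarize_trial()] columns.
#' @examples
#' summary_from_counts(c(subassembly = 9, unit_unit = 2, other = 12))
#' @export
summary_from_counts <- function(counts, n_cups = NA_integer_,
                                success = NA, max_nesting = NA_integer_) {
  bad <- setdiff(names(counts), strategy_levels())
  if (length(bad) > 0 || is.null(names(counts))) {
    abort(paste("unknown category name(s):", paste(bad, collapse = ", ")),
          class = "cupgrammar_validation_error")
  }
  full <- setNames(rep(0, 9), strategy_levels())
  full[names(counts)] <- counts
  total <- sum(full)
  pct <- if (total > 0) 100 * full / total else rep(0, 9)
  as_tibble(c(list(n_cups = as.integer(n_cups), total_manipulations = total,
                   success = success, max_nesting = as.integer(max_nesting),
                   hierarchical_level_final = NA_integer_,
                   zero_events = total == 0),
              setNames(as.list(as.integer(full)), count_cols()),
              setNames(as.list(unname(pct)), pct_cols())))
}

#' Aggregate trial summaries into group summaries
#'
#' For each group (age class, species, or any grouping columns) reports the
#' number of trials, the range of cups provided and of maximum nesting
#' achieved, the success rate (percentage of trials ending in complete
#' seriation), min/max/mean/sample-SD of manipulations per trial, and two
#' per-category aggregates: `mean_pct_*`, the unweighted mean of the member
#' trials' percentages (one participant, one weight), and `pooled_pct_*`,
#' pooled counts divided by pooled totals. The SD uses the n-1 denominator
#' and is `NA` for singleton groups.
#'
#' @param trial_summaries output of [summarize_trials()].
#' @param by character vector of grouping columns, e.g. `"age_class"` or
#'   `"species"`.
#' @return A tibble with one row per group.
#' @export
summarize_group <- function(trial_summaries, by = "age_class") {
  stopifnot(is.data.frame(trial_summaries))
  if (nrow(trial_summaries) == 0) {
    abort("cannot summarize an empty group", class = "cupgrammar_domain_error")
  }
  missing_by <- setdiff(by, names(trial_summaries))
  if (length(missing_by) > 0) {
    abort(paste("grouping column(s) not found:", paste(missing_by, collapse = ", ")),
          class = "cupgrammar_domain_error")
  }
  grouped <- trial_summaries %>% group_by(across(all_of(by)))
  base <- grouped %>%
    summarise(
      n_trials = dplyr::n(),
      cups_min = min(.data$n_cups), cups_max = max(.data$n_cups),
      nesting_min = min(.data$max_nesting), nesting_max = max(.data$max_nesting),
      success_rate = 100 * sum(.data$success) / dplyr::n(),
      manipulations_min = min(.data$total_manipulations),
      manipulations_max = max(.data$total_manipulations),
      manipulations_mean = mean(.data$total_manipulations),
      manipulations_sd = if (dplyr::n() > 1) sd(.data$total_manipulations) else NA_real_,
      .groups = "drop"
    )
  means <- grouped %>%
    summarise(across(all_of(pct_cols()), ~ mean(.x), .names = "mean_{.col}"),
              .groups = "drop")
  pooled <- grouped %>%
    summarise(across(all_of(count_cols()), ~ sum(.x)),
              total = sum(.data$total_manipulations), .groups = "drop") %>%
    mutate(across(all_of(count_cols()),
                  ~ ifelse(.data$total > 0, 100 * .x / .data$total, 0))) %>%
    rename_with(~ sub("^n_", "pooled_pct_", .x), all_of(count_cols())) %>%
    select(-"total")
  base %>% left_join(means, by = by) %>% left_join(pooled, by = by)
}

#' Subassembly-family share of a summary
#'
#' The subassembly family pools the classical subassembly (multi-cup unit
#' into a single recipient cup) with the unit–unit combination (unit into a
#' larger unit, its more advanced form). Given trial or group summary rows,
#' returns the two components and their total on the percentage scale; the
#' total is the exact sum of the parts, rounding (one decimal, half up) is
#' applied only by the caller at presentation.
#'
#' @param summary a tibble with `pct_subassembly`/`pct_unit_unit` columns
#'   (trial summaries) or `mean_pct_*`/`pooled_pct_*` columns (group
#'   summaries, selected via `source`).
#' @param source which percentage columns to read from a group summary:
#'   `"pct"` (trial rows), `"mean"` or `"pooled"`.
#' @return A tibble with columns `single_recipient`, `unit_unit`, `total`
#'   (plus any grouping label columns present).
#' @examples
#' subassembly_family_pct(summary_from_counts(c(subassembly = 9, unit_unit = 2,
#'                                              other = 12)))
#' @export
subassembly_family_pct <- function(summary, source = c("pct", "mean", "pooled")) {
  source <- match.arg(source)
  prefix <- switch(source, pct = "pct_", mean = "mean_pct_", pooled = "pooled_pct_")
  sa <- paste0(prefix, "subassembly")
  uu <- paste0(prefix, "unit_unit")
  if (!all(c(sa, uu) %in% names(summary))) {
    abort(sprintf("summary lacks %s/%s columns", sa, uu),
          class = "cupgrammar_validation_error")
  }
  labels <- intersect(c("participant_id", "trial_id", "age_class", "species",
                        "group_label"), names(summary))
  dplyr::bind_cols(
    summary[, labels, drop = FALSE],
    tibble(single_recipient = summary[[sa]], unit_unit = summary[[uu]],
           total = summary[[sa]] + summary[[uu]])
  )
}

#' @importFrom dplyr rename_with
NULL
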