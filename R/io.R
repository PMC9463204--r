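# Trial tables on disk: CSV or JSON with one row per trial
# (participant_id, species, age_months, trial_id, n_cups, sequence, and an
# optional ISO-8601 date). The coded sequence column is the only
# domain-specific field; everything else is plain metadata.

TRIAL_COLUMNS <- c("participant_id", "species", "age_months", "trial_id",
                   "n_cups", "sequence")

#' Read a trial table
#'
#' Reads and validates a trials file. Every row's coded sequence is parsed
#' under its declared `n_cups`; offending rows either abort with their row
#' numbers (default) or are dropped with a warning.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @param on_error `"fail"` to abort on the first bad row, `"skip"` to drop
#'   bad rows with a warning listing them.
#' @return A trials tibble with an `events` list-column (parsed sequences)
#'   and an `age_class` column derived from `age_months`.
#' @export
read_trials <- function(path, format = NULL, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) {
    abort(paste("no such file:", path), class = "cupgrammar_schema_error")
  }
  format <- format %||% tolower(tools::file_ext(path))
  raw <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE),
    json = as_tibble(jsonlite::fromJSON(path)),
    abort(paste("unsupported format:", format), class = "cupgrammar_schema_error")
  )
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste("trial table lacks column(s):", paste(missing_cols, collapse = ", ")),
          class = "cupgrammar_schema_error")
  }
  raw$sequence[is.na(raw$sequence)] <- ""
  raw$n_cups <- as.integer(raw$n_cups)
  raw$age_months <- as.integer(raw$age_months)
  if ("date" %in% names(raw)) raw$date <- as.Date(raw$date)

  events <- vector("list", nrow(raw))
  bad <- integer(0)
  msgs <- character(0)
  for (i in seq_len(nrow(raw))) {
    ev <- tryCatch(parse_sequence(raw$sequence[[i]], n_cups = raw$n_cups[[i]]),
                   error = function(e) e)
    if (inherits(ev, "error")) {
      if (on_error == "fail") {
        abort(sprintf("row %d: %s", i, conditionMessage(ev)),
              class = "cupgrammar_validation_error")
      }
      bad <- c(bad, i)
      msgs <- c(msgs, sprintf("row %d: %s", i, conditionMessage(ev)))
    } else {
      events[[i]] <- ev
    }
  }
  if (length(bad) > 0) {
    warn(paste0("dropped ", length(bad), " unparseable row(s):\n",
                paste(msgs, collapse = "\n")))
    raw <- raw[-bad, , drop = FALSE]
    events <- events[-bad]
  }
  raw$events <- events
  raw$age_class <- as.character(assign_age_class(raw$age_months))
  raw
}

#' Write a trial table
#'
#' @param trials a trials tibble; an `events` list-column is rendered to
#'   coded text if the `sequence` column is absent.
#' @param path output file.
#' @param format `"csv"` or `"json"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, format = NULL) {
  stopifnot(is.data.frame(trials))
  format <- format %||% tolower(tools::file_ext(path))
  if (!"sequence" %in% names(trials) && "events" %in% names(trials)) {
    trials$sequence <- map_chr(trials$events, render_sequence)
  }
  out <- trials[, intersect(c(TRIAL_COLUMNS, "date", "age_class", "group_label"),
                            names(trials)), drop = FALSE]
  switch(format,
    csv = readr::write_csv(out, path),
    json = jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                                auto_unbox = TRUE, digits = NA),
    abort(paste("unsupported format:", format), class = "cupgrammar_schema_error")
  )
  invisible(path)
}

#' Run the whole analysis pipeline
#'
#' Reads (or takes) a trial table, optionally keeps only each participant's
#' analysis trial, classifies every action, summarizes trials and groups,
#' and writes four files to `out_dir`: `labeled_events.csv`,
#' `trial_summaries.csv`, `group_summaries.csv` and `manifest.json` (package
#' version, seed, grouping, input fingerprint). Outputs are byte-identical
#' across runs on the same inputs.
#'
#' @param trials a trials tibble or a path readable by [read_trials()].
#' @param out_dir output directory, created if needed.
#' @param group_by grouping columns for the group summary.
#' @param last_trial_only keep only each participant's last largest-cup
#'   trial before summarizing (the developmental analysis convention)?
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when `trials` came from the simulator).
#' @return Invisibly, a list with the three result tibbles and the manifest.
#' @export
run_pipeline <- function(trials, out_dir, group_by = "age_class",
                         last_trial_only = FALSE, seed = NULL) {
  if (is.character(trials) && length(trials) == 1) {
    trials <- read_trials(trials)
  }
  stopifnot(is.data.frame(trials))
  if (last_trial_only) trials <- select_last_trial(trials)
  inform(sprintf("pipeline: %d trial(s), grouping by %s",
                 nrow(trials), paste(group_by, collapse = "+")))
  labeled <- classify_trials(trials)
  inform(sprintf("pipeline: classified %d event(s)", nrow(labeled)))
  trial_summaries <- summarize_trials(trials)
  group_summaries <- summarize_group(trial_summaries, by = group_by)
  inform(sprintf("pipeline: %d group(s) summarized", nrow(group_summaries)))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  labeled_out <- labeled
  if ("intent" %in% names(labeled_out)) {
    labeled_out$intent <- as.character(labeled_out$intent)
  }
  labeled_out$label <- as.character(labeled_out$label)
  readr::write_csv(labeled_out, file.path(out_dir, "labeled_events.csv"))
  readr::write_csv(trial_summaries, file.path(out_dir, "trial_summaries.csv"))
  readr::write_csv(group_summaries, file.path(out_dir, "group_summaries.csv"))
  manifest <- list(
    package = "cupgrammar",
    version = as.character(utils::packageVersion("cupgrammar")),
    seed = seed,
    group_by = group_by,
    last_trial_only = last_trial_only,
    n_trials = nrow(trials),
    n_events = nrow(labeled),
    input_hash = rlang::hash(trials[, intersect(c(TRIAL_COLUMNS, "date"),
                                                names(trials))])
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(labeled_events = labeled, trial_summaries = trial_summaries,
                 group_summaries = group_summaries, manifest = manifest))
}
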