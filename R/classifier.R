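# Nine manipulative categories, assigned per action (not per whole process)
# from the pre-action state and the event alone:
#   pairing      N, single cup into a larger single cup
#   pot          N, single cup into a larger multi-cup unit
#   subassembly  N, multi-cup unit into a larger single cup
#   unit_unit    N, multi-cup unit into a larger multi-cup unit
#   pile         N, single cup onto a smaller cup/unit
#   pile_sub     N, multi-cup unit onto a smaller cup/unit
#   put          H, combined but retrieved without releasing the hand
#   disassemble  D, detached a cup/unit from a premade unit
#   other        X, mouthing / replacing on the floor / reversing / banging

#' The nine strategy categories
#'
#' Category labels in their canonical order, used as factor levels
#' throughout the package.
#'
#' @return Character vector of length 9.
#' @export
strategy_levels <- function() {
  c("pairing", "pot", "subassembly", "unit_unit", "pile", "pile_sub",
    "put", "disassemble", "other")
}

#' Classify one action against its pre-action state
#'
#' Deterministic rule table. The verb decides put/disassemble/other
#' directly. For a combine (`N`), the label depends on whether the moved
#' object is a single cup or a multi-cup unit, whether its contact (base)
#' cup is smaller or larger than the receiving structure's top cup, and —
#' for nesting combinations — whether the receiving structure is a single
#' cup or a unit. Pile vs pile-sub ignores the receiver's unit status.
#'
#' @param state the `cup_state` before the action.
#' @param event a one-row event table, canonical with respect to `state`.
#' @return One of [strategy_levels()].
#' @examples
#' classify_event(initial_state(3), action_events(1, "N", 2)) # "pairing"
#' @export
classify_event <- function(state, event) {
  stopifnot(inherits(state, "cup_state"))
  if (nrow(event) != 1) abort("classify_event takes exactly one event")
  validate_events(event, n_cups = state$n_cups)
  verb <- event$verb[[1]]
  if (verb == "H") return("put")
  if (verb == "D") return("disassemble")
  if (verb == "X") return("other")

  obj <- event$object[[1]]
  loc <- event$location[[1]]
  si <- locate_object(state, obj)
  li <- find_structure(state, loc[[1]])
  if (is.na(li) || li == si) {
    abort("event is not canonical: location is not a distinct structure; canonicalize first",
          class = "cupgrammar_classification_error")
  }
  target <- state$stacks[[li]]
  contact <- obj[[length(obj)]]     # base cup of the moved unit
  if (contact > top_cup(target)) {
    return(if (length(obj) == 1) "pile" else "pile_sub")
  }
  if (length(obj) == 1) {
    if (length(target) == 1) "pairing" else "pot"
  } else {
    if (length(target) == 1) "subassembly" else "unit_unit"
  }
}

#' Classify every action of a trial
#'
#' Replays the event sequence through the state machine, labelling each
#' event against the state just before it. Events are canonicalized first,
#' so hand-coded tokens naming partial units are resolved automatically.
#'
#' @param events an event table, or a coded-sequence string.
#' @param n_cups number of cups provided in the trial.
#' @return A tibble with one row per event: `event_index`, `code` (the
#'   canonical token), `verb`, `label` (factor over [strategy_levels()]),
#'   `outcome` (the state-machine move outcome), and `pre_state` (a compact
#'   rendering of the state the label was computed from).
#' @examples
#' classify_trial("1N2/12N3", n_cups = 3)
#' @export
classify_trial <- function(events, n_cups) {
  if (is.character(events)) events <- parse_sequence(events, n_cups = n_cups)
  if (nrow(events) == 0) {
    out <- tibble(event_index = integer(), code = character(),
                  verb = character(),
                  label = factor(character(), levels = strategy_levels()),
                  outcome = character(), pre_state = character())
    attr(out, "final_state") <- initial_state(n_cups)
    return(out)
  }
  events <- canonicalize(events, n_cups)
  state <- initial_state(n_cups)
  labels <- character(nrow(events))
  kinds <- character(nrow(events))
  digests <- character(nrow(events))
  codes <- map_chr(seq_len(nrow(events)),
                   ~ render_sequence(events[.x, c("object", "verb", "subtype", "location")]))
  for (i in seq_len(nrow(events))) {
    digests[[i]] <- format(state)
    labels[[i]] <- classify_event(state, events[i, ])
    out <- apply_event(state, events[i, ])
    kinds[[i]] <- out$kind
    state <- out$state
  }
  out <- tibble(event_index = seq_len(nrow(events)), code = codes,
                verb = events$verb,
                label = factor(labels, levels = strategy_levels()),
                outcome = kinds, pre_state = digests)
  attr(out, "final_state") <- state
  out
}

#' Classify every trial of a trials table
#'
#' Data-frame-first wrapper around [classify_trial()]: takes the trials
#' table used across the package (one row per trial, with a `sequence`
#' column or an `events` list-column) and returns one long table of labelled
#' events carrying the trial metadata.
#'
#' @param trials a trials tibble with at least `trial_id`, `n_cups`, and
#'   `sequence` (or `events`); any of `participant_id`, `species`,
#'   `age_months`, `age_class` are carried through.
#' @return A tibble of labelled events, one row per action.
#' @export
classify_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  meta_cols <- intersect(c("participant_id", "species", "age_months",
                           "age_class", "group_label", "trial_id", "n_cups"),
                         names(trials))
  rows <- map(seq_len(nrow(trials)), function(i) {
    ev <- if ("events" %in% names(trials) && !is.null(trials$events[[i]])) {
      trials$events[[i]]
    } else {
      trials$sequence[[i]]
    }
    labelled <- classify_trial(ev, n_cups = trials$n_cups[[i]])
    if ("intent" %in% names(trials) && !is.null(trials$intent[[i]]) &&
        nrow(labelled) > 0) {
      labelled$intent <- factor(trials$intent[[i]], levels = strategy_levels())
    }
    meta <- trials[i, meta_cols, drop = FALSE]
    if (nrow(labelled) == 0) meta <- meta[0, , drop = FALSE]
    dplyr::bind_cols(meta, labelled)
  })
  list_rbind(rows)
}
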