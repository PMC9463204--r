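# Action-grammar notation: each manipulative action is coded as an
# <object><verb><location> token, tokens separated by "/". The object and
# location are cup units written innermost/topmost cup first, base (contact)
# cup last, so "12N3" reads "the unit with cup 1 inside cup 2 is combined
# into cup 3". Verbs: N combine-and-release, H combine-without-release,
# D detach, X other (with subtype). "f" is the floor.

X_SUBTYPES <- c(m = "mouth", r = "replace", v = "reverse", b = "bang")

#' Construct an event table
#'
#' Builds the tibble-of-events representation used throughout the package.
#' Each row is one coded manipulative action: an object unit, a verb, and a
#' location unit (or the floor). Units are integer vectors of cup size ranks
#' (1 = smallest), ordered innermost/topmost first and base cup last.
#'
#' @param object list of integer vectors (or a single integer vector for a
#'   one-event table): the cup unit that was moved.
#' @param verb character vector over `"N"` (combine and release), `"H"`
#'   (combine without releasing the hand), `"D"` (detach), `"X"` (other).
#' @param location list of integer vectors; `integer(0)` (the sentinel
#'   returned by [cup_floor()]) codes the floor.
#' @param subtype character; for `"X"` events one of `"mouth"`, `"replace"`,
#'   `"reverse"`, `"bang"`, `"unspecified"`; `NA` otherwise.
#' @return A tibble with columns `object`, `verb`, `subtype`, `location`.
#' @examples
#' action_events(object = list(1L, c(1L, 2L)), verb = c("N", "N"),
#'               location = list(2L, 3L))
#' @export
action_events <- function(object = list(), verb = character(),
                          location = list(), subtype = NULL) {
  if (is.numeric(object)) object <- list(as.integer(object))
  if (is.numeric(location)) location <- list(as.integer(location))
  object <- lapply(object, as.integer)
  location <- lapply(location, as.integer)
  n <- length(verb)
  if (is.null(subtype)) subtype <- rep(NA_character_, n)
  subtype[verb == "X" & is.na(subtype)] <- "unspecified"
  ev <- tibble(
    object = object, verb = toupper(as.character(verb)),
    subtype = as.character(subtype), location = location
  )
  validate_events(ev)
  ev
}

#' Floor sentinel for event locations
#'
#' @return `integer(0)`, the location value meaning "the floor".
#' @export
cup_floor <- function() integer(0)

is_floor <- function(loc) length(loc) == 0

empty_events <- function() {
  tibble(object = list(), verb = character(),
         subtype = character(), location = list())
}

validate_events <- function(events, n_cups = NULL, call = caller_env()) {
  for (i in seq_len(nrow(events))) {
    obj <- events$object[[i]]
    loc <- events$location[[i]]
    verb <- events$verb[[i]]
    sub <- events$subtype[[i]]
    if (length(obj) == 0 || anyDuplicated(obj) || any(obj < 1)) {
      abort(sprintf("event %d: object unit must be a non-empty set of distinct positive ranks", i),
            class = "cupgrammar_validation_error", call = call)
    }
    if (anyDuplicated(loc) || any(loc < 1)) {
      abort(sprintf("event %d: location unit has duplicate or invalid ranks", i),
            class = "cupgrammar_validation_error", call = call)
    }
    if (length(intersect(obj, loc)) > 0) {
      abort(sprintf("event %d: object and location share cup(s) %s", i,
                    paste(intersect(obj, loc), collapse = ",")),
            class = "cupgrammar_validation_error", call = call)
    }
    if (!verb %in% c("N", "H", "D", "X")) {
      abort(sprintf("event %d: unknown verb '%s'", i, verb),
            class = "cupgrammar_validation_error", call = call)
    }
    if (verb %in% c("N", "H", "D") && is_floor(loc)) {
      abort(sprintf("event %d: verb %s requires a non-floor location", i, verb),
            class = "cupgrammar_validation_error", call = call)
    }
    if (verb == "X" && !sub %in% c(X_SUBTYPES, "unspecified")) {
      abort(sprintf("event %d: X subtype '%s' not recognised", i, sub),
            class = "cupgrammar_validation_error", call = call)
    }
    if (!is.null(n_cups) && any(c(obj, loc) > n_cups)) {
      abort(sprintf("event %d: cup rank exceeds declared n_cups = %d", i, n_cups),
            class = "cupgrammar_validation_error", call = call)
    }
  }
  invisible(events)
}

# token grammar, compact dialect: one digit per cup (n <= 9);
# extended dialect: ranks separated by ".", e.g. "1.10N11."; a singleton
# unit takes a trailing "." so that every extended token carries a dot and
# the two dialects can never be confused (e.g. "12N34" is compact, two cups
# into two cups; "12.N34." is cup twelve into cup thirty-four)
RX_COMPACT <- "^([1-9]+)([NnHhDd]|[Xx][mrvb]?)([Ff]|[1-9]+)$"
RX_EXTENDED <- "^([0-9]+(?:\\.[0-9]+)*\\.?)([NnHhDd]|[Xx][mrvb]?)([Ff]|[0-9]+(?:\\.[0-9]+)*\\.?)$"

parse_unit <- function(s, extended) {
  if (extended) as.integer(strsplit(sub("\\.$", "", s), ".", fixed = TRUE)[[1]])
  else as.integer(strsplit(s, "")[[1]])
}

parse_verb <- function(s) {
  v <- toupper(substr(s, 1, 1))
  sub <- NA_character_
  if (v == "X") {
    sub <- if (nchar(s) == 2) unname(X_SUBTYPES[tolower(substr(s, 2, 2))]) else "unspecified"
  }
  list(verb = v, subtype = sub)
}

#' Parse a coded manipulation sequence
#'
#' Turns a slash-separated action-grammar string such as `"1N2/12N3"` into an
#' event table. The dialect is auto-detected: compact (one digit per cup,
#' valid for up to nine cups) unless any token contains a `"."` rank
#' separator, in which case the extended dialect (`"1.10N11."`, singleton
#' units marked by a trailing dot) is used for
#' the whole sequence. Verb letters are case-insensitive and whitespace
#' around `"/"` is ignored.
#'
#' @param text a single coded-sequence string; `""` gives an empty event table.
#' @param n_cups optionally, the number of cups provided in the trial; ranks
#'   above it raise a validation error.
#' @return A tibble of events as produced by [action_events()].
#' @examples
#' parse_sequence("1N2/12N3")
#' @export
parse_sequence <- function(text, n_cups = NULL) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) return(empty_events())
  tokens <- trimws(strsplit(text, "/", fixed = TRUE)[[1]])
  extended <- grepl(".", text, fixed = TRUE)
  rx <- if (extended) RX_EXTENDED else RX_COMPACT
  obj <- loc <- vector("list", length(tokens))
  verb <- sub <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[[i]]
    m <- regmatches(tok, regexec(rx, tok))[[1]]
    if (length(m) == 0) {
      abort(sprintf("cannot parse token %d ('%s')", i, tok),
            class = "cupgrammar_parse_error")
    }
    obj[[i]] <- parse_unit(m[2], extended)
    v <- parse_verb(m[3])
    verb[[i]] <- v$verb
    sub[[i]] <- v$subtype
    loc[[i]] <- if (toupper(m[4]) == "F") cup_floor() else parse_unit(m[4], extended)
  }
  ev <- tibble(object = obj, verb = verb, subtype = sub, location = loc)
  validate_events(ev, n_cups = n_cups)
  ev
}

render_unit <- function(u, extended) {
  if (!extended) return(paste(u, collapse = ""))
  if (length(u) == 1) paste0(u, ".") else paste(u, collapse = ".")
}

#' Render an event table back to coded text
#'
#' Inverse of [parse_sequence()]: produces the canonical text form, using the
#' compact dialect when every rank is a single digit and the `"."`-separated
#' extended dialect otherwise. `parse_sequence(render_sequence(e))` is the
#' identity on valid event tables.
#'
#' @param events an event table ([action_events()]).
#' @return A single string; `""` for an empty table.
#' @examples
#' render_sequence(parse_sequence("1N2/12N3"))
#' @export
render_sequence <- function(events) {
  validate_events(events)
  if (nrow(events) == 0) return("")
  all_ranks <- unlist(c(events$object, events$location))
  extended <- any(all_ranks > 9)
  sub_letters <- setNames(names(X_SUBTYPES), X_SUBTYPES)
  toks <- map_chr(seq_len(nrow(events)), function(i) {
    v <- events$verb[[i]]
    vs <- if (v == "X" && events$subtype[[i]] != "unspecified") {
      paste0("X", sub_letters[[events$subtype[[i]]]])
    } else v
    loc <- events$location[[i]]
    paste0(render_unit(events$object[[i]], extended), vs,
           if (is_floor(loc)) "f" else render_unit(loc, extended))
  })
  paste(toks, collapse = "/")
}

#' Canonicalize hand-coded tokens against the tracked cup configuration
#'
#' Human coders sometimes name only the grasped cup of a moved unit or only
#' the top cup of a receiving structure. This replays the sequence through
#' the workspace state machine and rewrites every token to the full unit
#' actually moved or targeted: the object becomes the named base cup plus
#' everything stacked in/on it, and the location becomes the whole receiving
#' structure (for detachments, the remainder of the source structure).
#' Already-canonical sequences are returned unchanged.
#'
#' @param events an event table.
#' @param n_cups number of cups on the tabletop at trial start.
#' @return The canonical event table with an extra logical column
#'   `rewritten`, `TRUE` for every event whose token named a partial unit.
#' @examples
#' # coder wrote "1N3" after 2N3; cup 3 already holds cup 2
#' canonicalize(parse_sequence("2N3/1N3"), n_cups = 3)
#' @export
canonicalize <- function(events, n_cups) {
  validate_events(events, n_cups = n_cups)
  state <- initial_state(n_cups)
  out <- events
  out$rewritten <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- canonical_event(state, events[i, ], index = i)
    out$object[[i]] <- ev$object[[1]]
    out$location[[i]] <- ev$location[[1]]
    out$rewritten[[i]] <- ev$rewritten
    state <- apply_event(state, out[i, ])$state
  }
  out
}

# Rewrites one event's tokens to the full units implied by `state`.
# The object token's base (last-listed) cup anchors the moved unit: the unit
# is that cup plus every cup above it in its structure. All cups the coder
# listed must fall inside that segment, otherwise the token contradicts the
# state and cannot be auto-resolved.
canonical_event <- function(state, event, index = 1L) {
  obj <- event$object[[1]]
  loc <- event$location[[1]]
  verb <- event$verb[[1]]
  rewritten <- FALSE

  base_cup <- obj[[length(obj)]]
  si <- find_structure(state, base_cup)
  if (is.na(si)) {
    abort(sprintf("event %d: cup %d not on the tabletop", index, base_cup),
          class = "cupgrammar_canonicalization_error")
  }
  stack <- state$stacks[[si]]
  pos <- match(base_cup, stack)
  full_obj <- rev(stack[pos:length(stack)]) # token order: top first, base last
  if (!all(obj %in% full_obj)) {
    abort(sprintf("event %d: object token (%s) inconsistent with state unit (%s)",
                  index, paste(obj, collapse = ","), paste(full_obj, collapse = ",")),
          class = "cupgrammar_canonicalization_error")
  }
  if (!identical(as.integer(obj), as.integer(full_obj))) rewritten <- TRUE
  obj <- full_obj

  if (verb == "D") {
    # location is the remainder of the source structure after detachment
    remainder <- rev(stack[seq_len(pos - 1L)])
    if (length(remainder) == 0) {
      abort(sprintf("event %d: detach of a whole structure has no source remainder", index),
            class = "cupgrammar_canonicalization_error")
    }
    if (!identical(as.integer(loc), as.integer(remainder))) rewritten <- TRUE
    loc <- as.integer(remainder)
  } else if (!is_floor(loc)) {
    li <- find_structure(state, loc[[1]])
    if (is.na(li) || li == si) {
      abort(sprintf("event %d: location token (%s) names no distinct structure",
                    index, paste(loc, collapse = ",")),
            class = "cupgrammar_canonicalization_error")
    }
    full_loc <- rev(state$stacks[[li]])
    if (!all(loc %in% full_loc)) {
      abort(sprintf("event %d: location token (%s) spans structures", index,
                    paste(loc, collapse = ",")),
            class = "cupgrammar_canonicalization_error")
    }
    if (!identical(as.integer(loc), as.integer(full_loc))) rewritten <- TRUE
    loc <- as.integer(full_loc)
  }
  tibble(object = list(as.integer(obj)), verb = verb,
         subtype = event$subtype[[1]], location = list(as.integer(loc)),
         rewritten = rewritten)
}
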