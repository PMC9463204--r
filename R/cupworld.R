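# Idealized physical model of the tabletop. A structure is one connected
# stack of cups stored base-first; whether cup k sits IN or ON cup j is
# fully determined by their size ranks (smaller settles inside, larger
# rests on top), so adjacency relations are derived, never stored. Only the
# receiving structure's top cup decides nest-vs-pile: a dropped cup settles
# on whatever is uppermost, with no telescoping past intermediate sizes.

#' Initial tabletop state
#'
#' All cups start loose on the floor: `n_cups` singleton structures.
#'
#' @param n_cups number of distinctly sized cups, ranks `1..n_cups`
#'   (1 = smallest).
#' @return A `cup_state` object.
#' @examples
#' initial_state(3)
#' @export
initial_state <- function(n_cups) {
  n_cups <- as.integer(n_cups)
  if (is.na(n_cups) || n_cups < 1) {
    abort("n_cups must be a positive integer", class = "cupgrammar_domain_error")
  }
  new_cup_state(lapply(seq_len(n_cups), identity), n_cups)
}

new_cup_state <- function(stacks, n_cups) {
  structure(list(stacks = lapply(stacks, as.integer), n_cups = as.integer(n_cups)),
            class = "cup_state")
}

#' @export
print.cup_state <- function(x, ...) {
  cat("<cup_state>", x$n_cups, "cups:", format(x), "\n")
  invisible(x)
}

#' @export
format.cup_state <- function(x, ...) {
  paste0("{", paste(map_chr(x$stacks, ~ paste0("[", paste(.x, collapse = ">"), "]")),
                    collapse = " "), "}")
}

find_structure <- function(state, cup) {
  for (i in seq_along(state$stacks)) {
    if (cup %in% state$stacks[[i]]) return(i)
  }
  NA_integer_
}

# IN/ON relations along a stack, derived from ranks: the cup above is IN
# when smaller than the cup below it, ON otherwise.
stack_relations <- function(stack) {
  if (length(stack) < 2) return(character(0))
  ifelse(diff(stack) < 0, "IN", "ON")
}

top_cup <- function(stack) stack[[length(stack)]]

# Checks that `obj_token` (top-first order) is the top-contiguous segment of
# the structure holding its base cup; returns the structure index.
locate_object <- function(state, obj_token, call = caller_env()) {
  obj_stack <- rev(obj_token)
  si <- find_structure(state, obj_stack[[1]])
  if (is.na(si)) {
    abort(sprintf("cup %d is not on the tabletop", obj_stack[[1]]),
          class = "cupgrammar_illegal_move_error", call = call)
  }
  stack <- state$stacks[[si]]
  k <- length(obj_stack)
  if (length(stack) < k ||
      !identical(as.integer(tail(stack, k)), as.integer(obj_stack))) {
    abort(sprintf("object unit [%s] is not a top-contiguous segment of [%s]",
                  paste(obj_token, collapse = ","), paste(stack, collapse = ">")),
          class = "cupgrammar_illegal_move_error", call = call)
  }
  si
}

#' Apply one coded action to the tabletop state
#'
#' Implements the idealized contact rule. For a combine (`N`), the object
#' unit lands on the receiving structure's top cup `t`: if the object's base
#' (contact) cup is smaller than `t` it nests (`NESTED`), otherwise it rests
#' on top (`PILED`); the object's internal arrangement moves rigidly. A
#' combine without release (`H`) leaves the state unchanged (`HELD`). A
#' detach (`D`) splits a top-contiguous segment off into its own structure
#' (`DETACHED`). Of the `X` subtypes only `"replace"` (putting a cup back on
#' the floor) changes the state, acting as a detach-to-floor; the rest are
#' state-neutral (`NOOP`).
#'
#' @param state a `cup_state`.
#' @param event a one-row event table (see [action_events()]); the event
#'   must be canonical with respect to `state` (see [canonicalize()]).
#' @return A list with elements `kind` (one of `"NESTED"`, `"PILED"`,
#'   `"HELD"`, `"DETACHED"`, `"NOOP"`) and `state` (the new `cup_state`).
#' @examples
#' st <- initial_state(3)
#' apply_event(st, action_events(1, "N", 2))
#' @export
apply_event <- function(state, event) {
  stopifnot(inherits(state, "cup_state"))
  if (nrow(event) != 1) abort("apply_event takes exactly one event")
  validate_events(event, n_cups = state$n_cups)
  obj <- event$object[[1]]
  loc <- event$location[[1]]
  verb <- event$verb[[1]]
  sub <- event$subtype[[1]]

  if (verb == "H") return(list(kind = "HELD", state = state))
  if (verb == "X") {
    if (identical(sub, "replace")) {
      si <- locate_object(state, obj)
      if (length(state$stacks[[si]]) > length(obj)) {
        return(list(kind = "DETACHED", state = detach_segment(state, si, length(obj))))
      }
    }
    return(list(kind = "NOOP", state = state))
  }

  si <- locate_object(state, obj)
  if (verb == "D") {
    if (length(state$stacks[[si]]) == length(obj)) {
      abort("cannot detach a whole structure from itself",
            class = "cupgrammar_illegal_move_error")
    }
    return(list(kind = "DETACHED", state = detach_segment(state, si, length(obj))))
  }

  # verb N: combine-and-release
  li <- find_structure(state, loc[[1]])
  if (is.na(li) || li == si) {
    abort("combine location must be a different structure on the tabletop",
          class = "cupgrammar_illegal_move_error")
  }
  obj_stack <- rev(obj)
  target_top <- top_cup(state$stacks[[li]])
  kind <- if (obj_stack[[1]] < target_top) "NESTED" else "PILED"
  stacks <- state$stacks
  stacks[[li]] <- c(stacks[[li]], obj_stack)
  stacks[[si]] <- head(stacks[[si]], length(stacks[[si]]) - length(obj_stack))
  stacks <- stacks[lengths(stacks) > 0]
  list(kind = kind, state = new_cup_state(stacks, state$n_cups))
}

detach_segment <- function(state, si, k) {
  stack <- state$stacks[[si]]
  seg <- tail(stack, k)
  stacks <- state$stacks
  stacks[[si]] <- head(stack, length(stack) - k)
  new_cup_state(c(stacks, list(seg)), state$n_cups)
}

# Replays a whole event table from the initial state; returns the pre-state
# of every event, the outcome kinds, and the final state.
replay_events <- function(events, n_cups) {
  state <- initial_state(n_cups)
  pre_states <- vector("list", nrow(events))
  kinds <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    pre_states[[i]] <- state
    out <- apply_event(state, events[i, ])
    kinds[[i]] <- out$kind
    state <- out$state
  }
  list(pre_states = pre_states, kinds = kinds, final = state)
}

#' Is the tabletop a complete seriation?
#'
#' `TRUE` iff all cups form one structure in which every adjacency is a
#' nesting (equivalently, the stack reads ranks n, n-1, ..., 1 from base to
#' top) — the task's success criterion.
#'
#' @param state a `cup_state`.
#' @return Logical scalar.
#' @export
is_complete_seriation <- function(state) {
  length(state$stacks) == 1 &&
    identical(state$stacks[[1]], rev(seq_len(state$n_cups)))
}

#' Maximum number of cups in a nesting structure
#'
#' The size of the largest run of cups joined entirely by nesting
#' adjacencies anywhere on the tabletop. Nesting ignores contiguity of size
#' ranks (cup 1 directly inside cup 5 counts), but a pile adjacency breaks
#' the run. A tabletop with no nesting at all scores 1.
#'
#' @param state a `cup_state`.
#' @return Integer scalar, at least 1.
#' @export
max_nesting <- function(state) {
  best <- 1L
  for (stack in state$stacks) {
    rel <- stack_relations(stack)
    run <- 1L
    for (r in rel) {
      run <- if (r == "IN") run + 1L else 1L
      best <- max(best, run)
    }
  }
  best
}

#' Hierarchical level of a structure
#'
#' The number of combinatory relations in a structure: a two-object
#' combination is Level 1, three objects joined by two combinations Level 2,
#' and so on — one less than the number of cups in the structure.
#'
#' @param structure an integer vector of cup ranks (one stack), or a
#'   `cup_state`, in which case the maximum level over its structures is
#'   returned.
#' @return Integer scalar (0 for a lone cup).
#' @export
hierarchical_level <- function(structure) {
  if (inherits(structure, "cup_state")) {
    return(max(lengths(structure$stacks)) - 1L)
  }
  length(structure) - 1L
}

#' Minimum number of combine moves to full seriation
#'
#' Each combine joins two structures into one; starting from `n` loose cups
#' and ending with a single structure therefore takes exactly `n - 1`
#' combines, achieved by a pot strategy with perfect size judgment (insert
#' the second-largest cup into the largest, and so on).
#'
#' @param n_cups number of cups.
#' @return Integer scalar.
#' @export
min_moves <- function(n_cups) {
  n_cups <- as.integer(n_cups)
  if (is.na(n_cups) || n_cups < 1) {
    abort("n_cups must be a positive integer", class = "cupgrammar_domain_error")
  }
  n_cups - 1L
}

# JSON snapshot of a state, for debugging and run manifests.
state_to_json <- function(state) {
  jsonlite::toJSON(list(n_cups = state$n_cups, stacks = state$stacks))
}
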