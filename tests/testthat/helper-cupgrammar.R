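# Shared fixtures: random event generators and an exhaustive breadth-first
# search over the reachable state graph, used as an independent oracle for
# the minimum-move count.

# Random syntactically valid events (not necessarily state-legal): exercises
# the notation round-trip independently of the physics.
random_events <- function(n_events, max_rank = 9) {
  obj <- loc <- vector("list", n_events)
  verb <- character(n_events)
  sub <- rep(NA_character_, n_events)
  for (i in seq_len(n_events)) {
    verb[[i]] <- sample(c("N", "H", "D", "X"), 1,
                        prob = c(0.5, 0.15, 0.15, 0.2))
    ranks <- sample.int(max_rank, sample(2:min(5, max_rank), 1))
    split <- sample(seq_len(length(ranks) - 1L), 1)
    obj[[i]] <- ranks[seq_len(split)]
    loc[[i]] <- ranks[-seq_len(split)]
    if (verb[[i]] == "X") {
      sub[[i]] <- sample(c("mouth", "replace", "reverse", "bang", "unspecified"), 1)
      if (stats::runif(1) < 0.5) loc[[i]] <- cup_floor()
    }
  }
  action_events(object = obj, verb = verb, location = loc, subtype = sub)
}

# All states reachable from n loose cups via combine moves (any
# top-contiguous segment onto any other structure), as canonical strings.
state_key <- function(state) {
  paste(sort(vapply(state$stacks, paste, "", collapse = ".")), collapse = "|")
}

neighbour_states <- function(state) {
  out <- list()
  for (si in seq_along(state$stacks)) {
    stack <- state$stacks[[si]]
    for (k in seq_along(stack)) { # move the top k cups
      obj_token <- rev(utils::tail(stack, k))
      for (li in seq_along(state$stacks)) {
        if (li == si) next
        ev <- action_events(object = list(obj_token), verb = "N",
                            location = list(rev(state$stacks[[li]])))
        out[[length(out) + 1L]] <- apply_event(state, ev)$state
      }
    }
  }
  out
}

# Fewest combine moves from all-loose to complete seriation, by BFS.
bfs_min_moves <- function(n_cups) {
  start <- initial_state(n_cups)
  frontier <- list(start)
  seen <- state_key(start)
  depth <- 0L
  repeat {
    if (any(vapply(frontier, is_complete_seriation, logical(1)))) return(depth)
    nxt <- list()
    for (st in frontier) {
      for (nb in neighbour_states(st)) {
        key <- state_key(nb)
        if (!key %in% seen) {
          seen <- c(seen, key)
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    stopifnot(length(nxt) > 0) # seriation is always reachable
    frontier <- nxt
    depth <- depth + 1L
  }
}

# A state-legal random trial straight from the simulator, for physics and
# classifier property tests.
random_trial <- function(seed, n_cups = 6) {
  cfg <- agent_config(
    c(pairing = 1, pot = 1, subassembly = 0.7, unit_unit = 0.4, put = 0.4,
      disassemble = 0.6, other = 0.5),
    size_judgment_error = 0.2, action_budget = 40L, stop_on_success = FALSE
  )
  simulate_trial(cfg, n_cups, seed = seed)
}
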