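# Agent-based trial generator. At every step the agent samples an intended
# strategy from its propensity vector, restricted to strategy families that
# are feasible in the current cup configuration, then realizes the intent.
# Nest-intent realizations are size-greedy under perfect judgment (the
# competent pot strategist inserts the second-largest cup into the largest,
# and so on); with probability `size_judgment_error` the size comparison is
# corrupted and a nest intent lands as a pile (or a pile intent as a nest).
# The recorded ground-truth intent is the category the agent set out to
# realize before any corruption, so with zero error the classifier must
# agree with the intents event by event.

#' Agent configuration for the trial simulator
#'
#' @param propensities named non-negative weights over [strategy_levels()];
#'   missing names count zero. Weights are relative, not probabilities.
#' @param size_judgment_error probability in `[0, 1]` that one action's size
#'   comparison is corrupted (nest intents land as piles and vice versa).
#' @param action_budget maximum number of events in a trial.
#' @param stop_on_success stop as soon as the tabletop is a complete
#'   seriation?
#' @return An `agent_config` object.
#' @examples
#' agent_config(c(pot = 1), action_budget = 20)
#' @export
agent_config <- function(propensities, size_judgment_error = 0,
                         action_budget = 100L, stop_on_success = TRUE) {
  bad <- setdiff(names(propensities), strategy_levels())
  if (is.null(names(propensities)) || length(bad) > 0) {
    abort(paste("unknown propensity name(s):", paste(bad, collapse = ", ")),
          class = "cupgrammar_validation_error")
  }
  w <- setNames(rep(0, 9), strategy_levels())
  w[names(propensities)] <- propensities
  if (any(w < 0) || sum(w) <= 0) {
    abort("propensities must be non-negative with positive sum",
          class = "cupgrammar_validation_error")
  }
  if (size_judgment_error < 0 || size_judgment_error > 1) {
    abort("size_judgment_error must be in [0, 1]",
          class = "cupgrammar_validation_error")
  }
  if (action_budget < 0) {
    abort("action_budget must be non-negative",
          class = "cupgrammar_validation_error")
  }
  structure(list(propensities = w,
                 size_judgment_error = size_judgment_error,
                 action_budget = as.integer(action_budget),
                 stop_on_success = isTRUE(stop_on_success)),
            class = "agent_config")
}

# --- realization helpers ----------------------------------------------------
# Stacks are base-first; a whole structure moved as an object has token
# rev(stack) and contact cup = its base = stack[[1]].

# sample() treats a scalar first argument as 1:x; this draws uniformly on
# the inclusive integer range [a, b] without that trap
sample_range <- function(a, b) {
  if (a == b) as.integer(a) else as.integer(sample(seq(a, b), 1))
}

# (structure, position) pairs where the adjacency is not "exactly one rank
# smaller, nested" — junctions that cannot survive into a complete seriation
faulty_junctions <- function(state) {
  out <- matrix(integer(0), ncol = 2)
  for (i in seq_along(state$stacks)) {
    s <- state$stacks[[i]]
    if (length(s) < 2) next
    bad <- which(diff(s) != -1L)
    if (length(bad) > 0) out <- rbind(out, cbind(i, bad))
  }
  out
}

singles_of <- function(state) which(lengths(state$stacks) == 1)
multis_of <- function(state) which(lengths(state$stacks) >= 2)

# Legal (object structure, location structure) index pairs per category.
realizations <- function(state) {
  stacks <- state$stacks
  tops <- vapply(stacks, top_cup, integer(1))
  bases <- vapply(stacks, function(s) s[[1]], integer(1))
  sizes <- lengths(stacks)
  n <- length(stacks)
  pairs <- function(cond) {
    out <- which(outer(seq_len(n), seq_len(n), function(o, l) {
      o != l & cond(o, l)
    }), arr.ind = TRUE)
    out
  }
  list(
    pairing = pairs(function(o, l) sizes[o] == 1 & sizes[l] == 1 & bases[o] < tops[l]),
    pot = pairs(function(o, l) sizes[o] == 1 & sizes[l] >= 2 & bases[o] < tops[l]),
    subassembly = pairs(function(o, l) sizes[o] >= 2 & sizes[l] == 1 & bases[o] < tops[l]),
    unit_unit = pairs(function(o, l) sizes[o] >= 2 & sizes[l] >= 2 & bases[o] < tops[l]),
    pile = pairs(function(o, l) sizes[o] == 1 & bases[o] > tops[l]),
    pile_sub = pairs(function(o, l) sizes[o] >= 2 & bases[o] > tops[l])
  )
}

FAMILY <- list(pairing = c("pairing", "pot"), pot = c("pairing", "pot"),
               subassembly = c("subassembly", "unit_unit"),
               unit_unit = c("subassembly", "unit_unit"),
               pile = c("pile", "pile_sub"), pile_sub = c("pile", "pile_sub"))

# Perfect-judgment picks among nest realizations. Style depends on the
# intent: a pot strategist works top-down (largest object that fits
# anywhere, then the tightest-fitting location — start the pot with the
# biggest cups); a subassembly builder works bottom-up (the unit with the
# smallest base, moved into the next larger cup); a pairing intent joins
# similar-sized cups (uniform among the size-gap-minimal pairs). All share
# the tightest-fit location rule, the size-competent move.
greedy_pick <- function(state, re, style) {
  tops <- vapply(state$stacks, top_cup, integer(1))
  bases <- vapply(state$stacks, function(s) s[[1]], integer(1))
  if (style == "similar") {
    gap <- tops[re[, 2]] - bases[re[, 1]]
    cand <- re[gap == min(gap), , drop = FALSE]
    return(uniform_pick(cand))
  }
  oi <- if (style == "bottom_up") {
    re[, 1][bases[re[, 1]] == min(bases[re[, 1]])][1]
  } else {
    re[, 1][bases[re[, 1]] == max(bases[re[, 1]])][1]
  }
  cand <- re[re[, 1] == oi, 2]
  li <- cand[tops[cand] == min(tops[cand])][1]
  c(oi, li)
}

uniform_pick <- function(re) {
  re[sample.int(nrow(re), 1), ]
}

event_row <- function(state, oi, li, verb, subtype = NA_character_) {
  obj <- rev(state$stacks[[oi]])
  loc <- if (is.null(li)) cup_floor() else rev(state$stacks[[li]])
  tibble(object = list(as.integer(obj)), verb = verb,
         subtype = subtype, location = list(as.integer(loc)))
}

# One simulated step: returns NULL or list(event, intent).
sim_step <- function(state, config) {
  w <- config$propensities
  re <- realizations(state)
  feasible <- c(
    pairing = nrow(re$pairing) + nrow(re$pot) > 0,
    pot = nrow(re$pairing) + nrow(re$pot) > 0,
    subassembly = nrow(re$subassembly) + nrow(re$unit_unit) > 0,
    unit_unit = nrow(re$subassembly) + nrow(re$unit_unit) > 0,
    pile = nrow(re$pile) + nrow(re$pile_sub) > 0,
    pile_sub = nrow(re$pile) + nrow(re$pile_sub) > 0,
    put = length(state$stacks) >= 2,
    disassemble = length(multis_of(state)) > 0,
    other = TRUE
  )
  eff <- w * feasible[strategy_levels()]
  choice <- if (sum(eff) <= 0) "other" else {
    sample(strategy_levels(), 1, prob = eff)
  }

  if (choice %in% names(FAMILY)) {
    fam <- FAMILY[[choice]]
    # realize the chosen category, falling back to its family partner
    cat_re <- if (nrow(re[[choice]]) > 0) choice else setdiff(fam, choice)
    if (nrow(re[[cat_re]]) == 0) return(NULL) # family infeasible (race-proof)
    nestish <- cat_re %in% c("pairing", "pot", "subassembly", "unit_unit")
    intent <- cat_re
    corrupt <- config$size_judgment_error > 0 &&
      runif(1) < config$size_judgment_error
    if (corrupt) {
      # flip the size comparison: nest intent lands as pile, pile as nest
      flipped <- if (nestish) {
        if (intent %in% c("pairing", "pot")) re$pile else re$pile_sub
      } else {
        if (intent == "pile") rbind(re$pairing, re$pot) else rbind(re$subassembly, re$unit_unit)
      }
      if (nrow(flipped) > 0) {
        pick <- uniform_pick(flipped)
        return(list(event = event_row(state, pick[1], pick[2], "N"), intent = intent))
      }
    }
    style <- switch(choice, pairing = "similar", pot = "top_down",
                    subassembly = , unit_unit = "bottom_up", NULL)
    pick <- if (nestish) greedy_pick(state, re[[cat_re]], style) else uniform_pick(re[[cat_re]])
    return(list(event = event_row(state, pick[1], pick[2], "N"), intent = intent))
  }

  if (choice == "put") {
    oi <- sample.int(length(state$stacks), 1)
    cand <- setdiff(seq_along(state$stacks), oi)
    li <- if (length(cand) == 1) cand else sample(cand, 1)
    return(list(event = event_row(state, oi, li, "H"), intent = "put"))
  }
  if (choice == "disassemble") {
    # the task gives clear feedback: a junction that piles, or that skips a
    # size (so the skipped cups could never be inserted), must eventually be
    # undone — detach there when such a fault exists, explore otherwise
    faults <- faulty_junctions(state)
    if (nrow(faults) > 0) {
      f <- uniform_pick(faults)
      si <- f[[1]]
      k <- length(state$stacks[[si]]) - f[[2]]
    } else {
      mi <- multis_of(state)
      si <- if (length(mi) == 1) mi else sample(mi, 1)
      k <- sample.int(length(state$stacks[[si]]) - 1L, 1) # cups off the top
    }
    stack <- state$stacks[[si]]
    obj <- rev(tail(stack, k))
    locr <- rev(head(stack, length(stack) - k))
    return(list(event = tibble(object = list(as.integer(obj)), verb = "D",
                               subtype = NA_character_,
                               location = list(as.integer(locr))),
                intent = "disassemble"))
  }
  # other: state-neutral subtypes only
  oi <- sample.int(length(state$stacks), 1)
  sub <- sample(c("mouth", "reverse", "bang"), 1)
  list(event = event_row(state, oi, NULL, "X", subtype = sub), intent = "other")
}

#' Simulate one coded nesting-cup trial
#'
#' Runs the trial-and-error agent from an all-loose tabletop until complete
#' seriation (if `stop_on_success`) or the action budget is exhausted. All
#' randomness comes from one stream seeded with `seed`, so identical calls
#' reproduce the trial exactly.
#'
#' @param config an [agent_config()].
#' @param n_cups number of cups provided (3–10 is the usual task range).
#' @param seed integer seed for the trial's private random stream.
#' @return A list with `events` (event table), `intent` (character vector of
#'   ground-truth intended categories, one per event), `sequence` (the coded
#'   text), `success`, and `final_state`.
#' @examples
#' simulate_trial(agent_config(c(pot = 1)), n_cups = 5, seed = 1)
#' @export
simulate_trial <- function(config, n_cups, seed = 1L) {
  stopifnot(inherits(config, "agent_config"))
  n_cups <- as.integer(n_cups)
  if (is.na(n_cups) || n_cups < 1) {
    abort("n_cups must be a positive integer", class = "cupgrammar_domain_error")
  }
  withr::with_seed(as.integer(seed), {
    state <- initial_state(n_cups)
    events <- vector("list", config$action_budget)
    intents <- character(config$action_budget)
    k <- 0L
    while (k < config$action_budget) {
      if (config$stop_on_success && is_complete_seriation(state)) break
      step <- sim_step(state, config)
      if (is.null(step)) break
      k <- k + 1L
      events[[k]] <- step$event
      intents[[k]] <- step$intent
      state <- apply_event(state, step$event)$state
    }
    ev <- if (k == 0) empty_events() else list_rbind(events[seq_len(k)])
    list(events = ev, intent = intents[seq_len(k)],
         sequence = render_sequence(ev),
         success = is_complete_seriation(state), final_state = state)
  })
}

#' Cohort schedule mirroring the developmental study design
#'
#' One row per group: the six child age classes (7, 10, 12, 12, 12 and 14
#' participants, one analysed trial each) and an adult chimpanzee pool (ten
#' trials from five simulated subjects). Cup counts and action budgets
#' follow the observed task envelopes per group (3–10 cups provided;
#' trials of up to 140 actions for children, 192 for chimpanzees); strategy
#' propensities shift with age — pairing-dominated in the youngest class,
#' increasing pot then subassembly/unit-unit weight in older classes — and
#' size-judgment error declines with age.
#'
#' @return A tibble, one row per group, with a `config` list-column of
#'   [agent_config()] objects.
#' @export
study_schedule <- function() {
  ac <- age_classes()
  mk <- function(pair, pot, sub, uu, put, dis, oth, err, budget) {
    agent_config(c(pairing = pair, pot = pot, subassembly = sub, unit_unit = uu,
                   put = put, disassemble = dis, other = oth),
                 size_judgment_error = err, action_budget = budget)
  }
  human <- tibble(
    group_label = ac$age_class, species = "human",
    age_lower = ac$lower_months, age_upper = ac$upper_months,
    n_participants = c(7L, 10L, 12L, 12L, 12L, 14L),
    trials_per_participant = 1L,
    cups_min = c(3L, 4L, 5L, 9L, 7L, 9L),
    cups_max = c(6L, 9L, 9L, 10L, 10L, 10L),
    config = list(
      mk(1.0, 0.25, 0.03, 0.01, 0.25, 0.30, 1.5, 0.50, 37L),
      mk(0.9, 0.50, 0.10, 0.03, 0.20, 0.45, 1.1, 0.33, 44L),
      mk(0.8, 0.70, 0.22, 0.09, 0.20, 0.50, 1.0, 0.22, 81L),
      mk(0.7, 0.85, 0.40, 0.14, 0.20, 0.55, 0.9, 0.15, 140L),
      mk(0.5, 1.00, 0.55, 0.22, 0.15, 0.50, 0.6, 0.05, 67L),
      mk(0.4, 0.85, 0.85, 0.30, 0.10, 0.50, 0.4, 0.01, 60L)
    )
  )
  chimp <- tibble(
    group_label = "chimpanzee", species = "chimpanzee",
    age_lower = NA_integer_, age_upper = NA_integer_,
    n_participants = 5L, trials_per_participant = 2L,
    cups_min = 9L, cups_max = 10L,
    config = list(mk(0.4, 0.60, 0.90, 0.60, 0.5, 0.35, 1.7, 0.33, 192L))
  )
  bind_rows(human, chimp)
}

#' Generate a simulated cohort of coded trials
#'
#' Draws every participant's age (uniform within their group's month bin)
#' and cup count, then simulates each trial with a private seed derived
#' deterministically from the cohort seed, so the cohort is reproducible
#' and trials are independent.
#'
#' @param schedule a schedule tibble as returned by [study_schedule()]
#'   (columns `group_label`, `species`, `age_lower`, `age_upper`,
#'   `n_participants`, `trials_per_participant`, `cups_min`, `cups_max`,
#'   `config`).
#' @param seed integer cohort seed.
#' @return A trials tibble: one row per trial with participant/species/age
#'   metadata, `n_cups`, the coded `sequence`, an `events` list-column, and
#'   the ground-truth `intent` list-column.
#' @examples
#' sched <- study_schedule()[1, ]
#' generate_cohort(sched, seed = 42)
#' @export
generate_cohort <- function(schedule, seed = 1L) {
  stopifnot(is.data.frame(schedule))
  if (nrow(schedule) == 0) {
    abort("schedule has no groups", class = "cupgrammar_domain_error")
  }
  needed <- c("group_label", "species", "n_participants",
              "trials_per_participant", "cups_min", "cups_max", "config")
  missing_cols <- setdiff(needed, names(schedule))
  if (length(missing_cols) > 0) {
    abort(paste("schedule lacks column(s):", paste(missing_cols, collapse = ", ")),
          class = "cupgrammar_validation_error")
  }
  withr::with_seed(as.integer(seed), {
    rows <- list()
    pidx <- 0L
    for (g in seq_len(nrow(schedule))) {
      grp <- schedule[g, ]
      for (p in seq_len(grp$n_participants)) {
        pidx <- pidx + 1L
        age <- if (is.na(grp$age_lower)) NA_integer_ else {
          sample_range(grp$age_lower, grp$age_upper)
        }
        pid <- sprintf("%s_p%02d", grp$group_label, p)
        for (tr in seq_len(grp$trials_per_participant)) {
          n_cups <- sample_range(grp$cups_min, grp$cups_max)
          trial_seed <- sample.int(.Machine$integer.max - 1L, 1)
          sim <- simulate_trial(grp$config[[1]], n_cups, seed = trial_seed)
          rows[[length(rows) + 1L]] <- tibble(
            participant_id = pid, species = grp$species,
            age_months = age,
            age_class = as.character(assign_age_class(age)),
            group_label = grp$group_label,
            trial_id = sprintf("%s_t%d", pid, tr),
            n_cups = n_cups, sequence = sim$sequence,
            success = sim$success,
            events = list(sim$events), intent = list(sim$intent)
          )
        }
      }
    }
    list_rbind(rows)
  })
}
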