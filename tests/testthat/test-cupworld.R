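test_that("the initial state is all singletons and conserves cups", {
  st <- initial_state(3)
  expect_equal(st$stacks, list(1L, 2L, 3L))
  expect_equal(initial_state(1)$stacks, list(1L))
  st10 <- initial_state(10)
  expect_equal(sort(unlist(st10$stacks)), 1:10)
  expect_error(initial_state(0), class = "cupgrammar_domain_error")
})

test_that("combines nest or pile by the contact rule and move units rigidly", {
  st <- initial_state(3)
  out1 <- apply_event(st, action_events(1, "N", 2))
  expect_equal(out1$kind, "NESTED")
  expect_setequal(out1$state$stacks, list(c(2L, 1L), 3L))

  out2 <- apply_event(out1$state, action_events(c(1, 2), "N", 3))
  expect_equal(out2$kind, "NESTED")
  expect_equal(out2$state$stacks, list(c(3L, 2L, 1L)))

  # the largest cup dropped onto the two-cup unit rests on its top cup
  out3 <- apply_event(out1$state, action_events(3, "N", c(1, 2)))
  expect_equal(out3$kind, "PILED")
  expect_equal(out3$state$stacks, list(c(2L, 1L, 3L)))
})

test_that("hold leaves the state unchanged and detach splits a unit", {
  st <- apply_event(apply_event(initial_state(3),
                                action_events(1, "N", 2))$state,
                    action_events(c(1, 2), "N", 3))$state
  expect_error(apply_event(st, action_events(1, "H", 4)), # rank 4 of 3 cups
               class = "cupgrammar_validation_error")
  held <- apply_event(initial_state(2), action_events(1, "H", 2))
  expect_equal(held$kind, "HELD")
  expect_equal(held$state$stacks, initial_state(2)$stacks)

  det <- apply_event(st, action_events(1, "D", c(2, 3)))
  expect_equal(det$kind, "DETACHED")
  expect_setequal(det$state$stacks, list(c(3L, 2L), 1L))

  # re-combining the detached unit restores the prior state
  back <- apply_event(det$state, action_events(1, "N", c(2, 3)))
  expect_equal(back$state$stacks, st$stacks)
})

test_that("replace-on-floor detaches a nested cup; other X subtypes are noops", {
  st <- apply_event(initial_state(2), action_events(1, "N", 2))$state
  rep_out <- apply_event(st, action_events(1, "X", cup_floor(), subtype = "replace"))
  expect_equal(rep_out$kind, "DETACHED")
  expect_setequal(rep_out$state$stacks, list(2L, 1L))
  for (sub in c("mouth", "reverse", "bang")) {
    noop <- apply_event(st, action_events(1, "X", cup_floor(), subtype = sub))
    expect_equal(noop$kind, "NOOP")
    expect_equal(noop$state$stacks, st$stacks)
  }
})

test_that("moving a buried cup is an illegal move", {
  st <- apply_event(initial_state(3), action_events(2, "N", 3))$state
  expect_error(apply_event(st, action_events(3, "N", 1)),
               class = "cupgrammar_illegal_move_error")
})

test_that("cup conservation holds after every simulated event", {
  for (seed in 1:20) {
    sim <- random_trial(seed)
    st <- initial_state(6)
    for (i in seq_len(nrow(sim$events))) {
      st <- apply_event(st, sim$events[i, ])$state
      expect_equal(sort(unlist(st$stacks)), 1:6)
    }
  }
})

test_that("complete seriation requires one all-nested structure", {
  full <- apply_event(apply_event(initial_state(3),
                                  action_events(1, "N", 2))$state,
                      action_events(c(1, 2), "N", 3))$state
  expect_true(is_complete_seriation(full))
  expect_equal(max_nesting(full), 3)
  expect_equal(hierarchical_level(full), 2)

  part <- apply_event(initial_state(3), action_events(1, "N", 3))$state
  expect_false(is_complete_seriation(part))

  piled <- apply_event(apply_event(initial_state(3),
                                   action_events(1, "N", 2))$state,
                       action_events(3, "N", c(1, 2)))$state
  expect_false(is_complete_seriation(piled)) # one structure, but piled on top
})

test_that("max nesting counts non-contiguous nesting runs and breaks at piles", {
  st5 <- initial_state(5)
  st5$stacks <- list(c(5L, 3L, 1L), 2L, 4L)
  expect_equal(max_nesting(st5), 3) # 1 in 3 in 5, sizes skipped, still nesting
  st5b <- initial_state(5)
  st5b$stacks <- list(c(5L, 3L, 4L), 1L, 2L)
  expect_equal(max_nesting(st5b), 2) # run broken by 4 piled on 3
  expect_equal(max_nesting(initial_state(4)), 1)
})

test_that("hierarchical level counts combinatory relations", {
  expect_equal(hierarchical_level(c(2L, 1L)), 1)
  expect_equal(hierarchical_level(c(4L, 3L, 2L, 1L)), 3)
  expect_equal(hierarchical_level(rev(seq_len(10))), 9)
  expect_equal(hierarchical_level(5L), 0)
})

test_that("the closed-form minimum move count matches the exhaustive search", {
  for (n in 1:4) {
    expect_equal(min_moves(n), bfs_min_moves(n))
    expect_equal(min_moves(n), n - 1L)
  }
  expect_error(min_moves(0), class = "cupgrammar_domain_error")
})

test_that("a pure pot strategist with perfect judgment is move-optimal", {
  for (n in 3:10) {
    sim <- simulate_trial(agent_config(c(pot = 1)), n_cups = n, seed = n)
    expect_true(sim$success)
    expect_equal(nrow(sim$events), min_moves(n))
    expect_true(all(sim$events$verb == "N"))
  }
})
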