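make_trials <- function(n_cups, dates = NULL, pid = "p1") {
  if (is.null(dates)) dates <- as.Date("2020-01-01") + seq_along(n_cups)
  tibble::tibble(
    participant_id = pid,
    trial_id = paste0("t", seq_along(n_cups)),
    n_cups = as.integer(n_cups),
    sequence = "",
    date = dates
  )
}

test_that("last-trial selection keys on cup count first, then recency", {
  t1 <- select_last_trial(make_trials(c(5, 9, 9)))
  expect_equal(t1$trial_id, "t3")
  t2 <- select_last_trial(make_trials(c(9, 5)))
  expect_equal(t2$trial_id, "t1")
  t3 <- select_last_trial(make_trials(7))
  expect_equal(t3$trial_id, "t1")
  expect_error(select_last_trial(make_trials(integer(0))))
})

test_that("the worked code summarizes to a successful two-action trial", {
  s <- summarize_trial("1N2/12N3", n_cups = 3)
  expect_equal(s$total_manipulations, 2)
  expect_true(s$success)
  expect_equal(s$max_nesting, 3)
  expect_equal(s$hierarchical_level_final, 2)
  expect_equal(s$pct_pairing, 50)
  expect_equal(s$pct_subassembly, 50)
  expect_equal(s$pct_pot, 0)
})

test_that("trial percentages are counts over the trial total and sum to 100", {
  for (seed in 1:10) {
    sim <- random_trial(seed)
    if (nrow(sim$events) == 0) next
    s <- summarize_trial(sim$events, 6)
    counts <- unlist(s[paste0("n_", strategy_levels())])
    expect_equal(sum(counts), s$total_manipulations)
    expect_equal(sum(unlist(s[paste0("pct_", strategy_levels())])), 100,
                 tolerance = 1e-9)
  }
})

test_that("a zero-event trial reports flagged zero percentages, not NaN", {
  s <- summarize_trial("", n_cups = 3)
  expect_equal(s$total_manipulations, 0)
  expect_false(s$success)
  expect_true(s$zero_events)
  expect_equal(s$pct_pairing, 0)
})

test_that("published per-category counts rebuild the printed percentage", {
  # 23 recorded actions of which 9 single-recipient subassemblies and 2
  # unit-unit combinations: family share 11/23
  s <- summary_from_counts(c(subassembly = 9, unit_unit = 2, pairing = 3,
                             pot = 2, disassemble = 4, other = 3))
  expect_equal(s$total_manipulations, 23)
  fam <- subassembly_family_pct(s)
  expect_equal(fam$total, fam$single_recipient + fam$unit_unit)
  expect_equal(round_half_up(fam$total, 1), 47.8)
  expect_error(summary_from_counts(c(nonsense = 3)),
               class = "cupgrammar_validation_error")
})

test_that("subassembly family total is identically the sum of its parts", {
  withr::with_seed(99, {
    for (rep in 1:50) {
      x <- stats::runif(9)
      s <- summary_from_counts(setNames(x, strategy_levels()))
      fam <- subassembly_family_pct(s)
      expect_identical(fam$total, fam$single_recipient + fam$unit_unit)
    }
  })
})

test_that("group summaries aggregate success, spread and both percentage kinds", {
  sims <- purrr::map(1:8, function(s) {
    sim <- random_trial(s, n_cups = 4)
    tibble::tibble(participant_id = paste0("p", s), species = "human",
                   age_months = 40L + s, trial_id = "t1", n_cups = 4L,
                   events = list(sim$events))
  }) |> purrr::list_rbind()
  ts <- summarize_trials(sims)
  g <- summarize_group(ts, by = "species")
  expect_equal(g$n_trials, 8)
  expect_equal(g$success_rate, 100 * sum(ts$success) / 8)
  expect_equal(g$manipulations_min, min(ts$total_manipulations))
  expect_equal(g$manipulations_max, max(ts$total_manipulations))
  expect_equal(g$manipulations_mean, mean(ts$total_manipulations))
  expect_equal(g$manipulations_sd, sd(ts$total_manipulations))
  # hand-rolled tally oracle for the two aggregation rules
  expect_equal(g$mean_pct_pairing, mean(ts$pct_pairing))
  expect_equal(g$pooled_pct_pairing,
               100 * sum(ts$n_pairing) / sum(ts$total_manipulations))
  expect_error(summarize_group(ts[0, ], by = "species"),
               class = "cupgrammar_domain_error")
})

test_that("success-rate arithmetic matches simple fractions", {
  ts <- tibble::tibble(
    participant_id = paste0("c", 1:10), n_cups = 9L,
    total_manipulations = c(10L, 20L, rep(30L, 8)), success = rep(c(TRUE, FALSE), c(7, 3)),
    max_nesting = 5L
  )
  for (cat in strategy_levels()) {
    ts[[paste0("n_", cat)]] <- 0L
    ts[[paste0("pct_", cat)]] <- 0
  }
  ts$n_other <- ts$total_manipulations
  ts$pct_other <- 100
  ts$species <- "chimpanzee"
  g <- summarize_group(ts, by = "species")
  expect_equal(g$success_rate, 70)
  # invariant under trial reordering
  g2 <- summarize_group(ts[sample(1:10), ], by = "species")
  expect_equal(g2$success_rate, 70)
  # two-trial mean/min/max sanity
  g3 <- summarize_group(ts[1:2, ], by = "species")
  expect_equal(c(g3$manipulations_min, g3$manipulations_max,
                 g3$manipulations_mean), c(10, 20, 15))
})

test_that("group SD is the sample SD and absent for singleton groups", {
  sim <- random_trial(3, n_cups = 4)
  ts <- summarize_trials(tibble::tibble(participant_id = "p", species = "h",
                                        trial_id = "t", n_cups = 4L,
                                        events = list(sim$events)))
  g <- summarize_group(ts, by = "species")
  expect_true(is.na(g$manipulations_sd))
})

test_that("mean-of-percentages equals pooled percentages for equal-length trials", {
  ev <- parse_sequence("1N2/12N3")
  trials <- tibble::tibble(participant_id = c("a", "b"), species = "human",
                           trial_id = "t", n_cups = 3L,
                           events = list(ev, ev))
  g <- summarize_group(summarize_trials(trials), by = "species")
  for (cat in strategy_levels()) {
    expect_equal(g[[paste0("mean_pct_", cat)]], g[[paste0("pooled_pct_", cat)]])
  }
})

test_that("adding a family-free trial cannot raise the pooled family share", {
  sim <- random_trial(11)
  ts1 <- summarize_trials(tibble::tibble(participant_id = "a", species = "x",
                                         trial_id = "t", n_cups = 6L,
                                         events = list(sim$events)))
  fam1 <- subassembly_family_pct(summarize_group(ts1, "species"), source = "pooled")
  extra <- summarize_trials(tibble::tibble(participant_id = "b", species = "x",
                                           trial_id = "t", n_cups = 3L,
                                           sequence = "1N2/3Xbf/2Xmf"))
  expect_equal(extra$n_subassembly + extra$n_unit_unit, 0L)
  fam2 <- subassembly_family_pct(summarize_group(dplyr::bind_rows(ts1, extra),
                                                 "species"), source = "pooled")
  expect_lte(fam2$total, fam1$total)
})

test_that("age classes bin completed months inclusively, 48 in the last bin", {
  expect_equal(as.character(assign_age_class(c(12, 17, 18, 42, 48))),
               c("1y0m-1y5m", "1y0m-1y5m", "1y6m-1y11m", "3y6m-4y0m", "3y6m-4y0m"))
  expect_true(is.na(assign_age_class(11)))
  expect_true(is.na(assign_age_class(49)))
  ac <- age_classes()
  expect_equal(nrow(ac), 6)
  expect_true(all(ac$lower_months[-1] == ac$upper_months[-6] + 1))
})

test_that("half-up rounding differs from banker's rounding where it should", {
  expect_equal(round_half_up(47.85, 1), 47.9)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
  expect_equal(round_half_up(31.85 + 1e-12, 1), 31.9)
})
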