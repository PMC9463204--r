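---
title: "Action-grammar analysis of seriated nesting-cup manipulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Action-grammar analysis of seriated nesting-cup manipulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupgrammar)
```

## The task and the analysis problem

In a seriated nesting-cup task a participant — a human child or a nonhuman
great ape — is given 3 to 10 cups of graded diameter and may combine them
freely. The trial is a success when every cup ends up nested inside the next
larger one: a single *complete seriation*. What makes the task scientifically
interesting is not the endpoint but the route: each combinatory action can be
performed by adding one loose cup to a growing stack (*pot*), by joining two
loose cups (*pairing*), or by moving an already-built multi-cup unit as one
piece (*subassembly*), and the subassembly route — structurally analogous to
the merge operation in syntax — is the developmentally latest and most
debated one.

Coded records of such trials are written in an action grammar: each
manipulative action is one token `<object><verb><location>`, tokens joined by
`/`. Digits are cup size ranks (1 = smallest); a unit is written
innermost-cup-first, base cup last. `1N2/12N3` therefore reads: cup 1 is
combined into cup 2, then the `12` unit is combined into cup 3. This package
parses that notation, tracks the physical configuration event by event,
assigns each action to one of nine manipulative categories, and aggregates
trials into the summaries used in developmental comparisons. Because raw
video-coded event data for such studies are generally not deposited, the
package also ships an agent-based simulator that generates coded trials with
known ground-truth intents, so that every stage of the pipeline is testable.

## Notation

The verb letters are `N` (combine and release), `H` (combine without
releasing the hand), `D` (detach) and `X` (everything else: mouthing,
replacing on the floor, reversing, banging — written `Xm`, `Xr`, `Xv`, `Xb`,
or bare `X` when unspecified). Only `N` appears in published example codes;
`H`, `D` and `X` letters are this package's convention, chosen so that every
one of the nine behavioural categories has a textual form. `f` denotes the
floor. Verbs are case-insensitive and whitespace around `/` is ignored.

Two dialects exist. The compact dialect uses one digit per cup and is valid
for up to nine cups. The extended dialect separates ranks with `.`, and a
singleton unit carries a trailing dot (`12.N34.` is cup 12 into cup 34,
whereas `12N34` is the compact two-cup unit `{1,2}` into `{3,4}`). The
trailing-dot rule makes the dialects disjoint as string languages, so
`parse_sequence()` can auto-detect the dialect per sequence; without it,
strings such as `12N34` would be valid in both dialects with different
meanings.

Human coders often name only the grasped cup of a moved unit or only the top
cup of a receiving structure. `canonicalize()` replays the sequence and
rewrites each token to the full unit actually moved or targeted, flagging
every rewrite. Whether original coding conventions wrote whole units or top
cups varies between labs; supporting both, with the flag, covers either
convention.

## The idealized cup world

The tabletop state is a set of structures; each structure is an ordered
stack of cups from base to top. Whether one cup sits *in* or *on* its
neighbour is fully determined by size ranks — a smaller cup settles inside a
larger one, a larger cup rests on top of a smaller — so nesting/piling
relations are derived, never stored. The model is deliberately idealized:

* **Contact rule.** Only the receiving structure's top cup decides nest
  versus pile. A cup dropped onto a stack does not telescope past
  intermediate sizes; it settles on whatever is uppermost. This is the
  simplest rule consistent with all nine category definitions.
* **Top-contiguity.** A moved object must be the top segment of its
  structure. Grabbing a buried cup is an illegal move; coders would have
  coded a disassembly first.
* **Rigid composite moves.** Units containing pile adjacencies can still be
  moved as one object; their internal arrangement moves rigidly.
* **State-neutral others.** Of the `X` subtypes only "replace on the floor"
  changes the state (it detaches like `D`); mouthing, reversing and banging
  are no-ops.

Three structural metrics follow. `is_complete_seriation()` is true when one
structure holds all cups joined entirely by nesting. `max_nesting()` is the
largest run of cups joined entirely by nesting anywhere on the table —
non-contiguous sizes count (1 directly inside 5 is still nesting), a pile
adjacency breaks the run, and a bare singleton scores 1, which is why
reported minima of 2 mean "at least one insertion happened".
`hierarchical_level()` counts combinatory relations: a structure of $k$ cups
embodies $k-1$ relations (Level 1 = two objects, one relation; Level 3 =
four objects, three relations). Finally `min_moves(n)` is $n-1$: every
combine reduces the number of structures by exactly one, from $n$ loose cups
to one stack. The test suite checks this closed form against a breadth-first
search over the full reachable state graph for $n \le 4$ and against the
simulated pot strategist for $n$ up to 10.

## The nine-category classifier

Each action is classified against the state immediately before it —
per-action classification, not a judgement of the whole trial. The rule
table, first match wins:

| verb | object | contact comparison | receiver | label |
|------|--------|--------------------|----------|-------|
| `H`  | —      | —                  | —        | put |
| `D`  | —      | —                  | —        | disassemble |
| `X`  | —      | —                  | —        | other |
| `N`  | single | smaller than top   | single   | pairing |
| `N`  | single | smaller than top   | unit     | pot |
| `N`  | unit   | smaller than top   | single   | subassembly |
| `N`  | unit   | smaller than top   | unit     | unit_unit |
| `N`  | single | larger than top    | either   | pile |
| `N`  | unit   | larger than top    | either   | pile_sub |

The contact cup of a moved unit is its base (last-listed) cup. Pairing
versus pot depends only on the receiver's unit status at the moment of
action; the mover's history is irrelevant. Pile versus pile-sub ignores the
receiver's unit status entirely. A `put` is labelled put regardless of what
the combination would have been on release; no secondary label is kept,
because the category is defined by the retrieval itself. Classification is a
pure function of (state, event): replaying a trial twice yields identical
labels, and on noise-free simulated trials the labels equal the simulator's
intents event for event.

## Trial and group summaries

`summarize_trial()` reports per-category counts and percentages (each
category's count over the trial's total action count), success, maximum
nesting, and the final hierarchical level (the largest structure's level;
the level is defined per structure, so the trial scalar takes the maximum).
Zero-event trials report zero percentages with an explicit `zero_events`
flag rather than `NaN`.

`select_last_trial()` implements the developmental analysis convention: for
each participant, among the trials with their maximal cup count, the
chronologically last is analysed. The cup-count key dominates recency.

`summarize_group()` aggregates over age classes (six inclusive bins of
completed months: 12–17, 18–23, 24–29, 30–35, 36–41, 42–48) or species. Two
per-category aggregates are reported side by side: `mean_pct_*`, the
unweighted mean of member trials' percentages (one participant, one weight —
the aggregation implied when percentages are computed per participant), and
`pooled_pct_*`, pooled counts over pooled totals. They coincide exactly when
all member trials have equal lengths and differ otherwise; published group
figures rarely state which rule was used, so both are emitted. The spread
statistic is the sample standard deviation ($n-1$), reported as `NA` for
singleton groups. Rounding — one decimal, half away from zero — is applied
only at presentation (`round_half_up()`); all internal arithmetic is
unrounded. `summary_from_counts()` builds the same summary row from a named
count vector, because published per-individual tables report counts, and
percentages such as a family share of 11 of 23 actions are recomputable
from them.

The subassembly family pools classical subassembly (unit into a single
recipient cup) with unit–unit combination (unit into a larger unit);
`subassembly_family_pct()` returns both components and their exact sum.

## The trial simulator

`simulate_trial()` runs a stochastic agent from an all-loose tabletop until
complete seriation or an action budget is exhausted. Its design decisions:

* **Propensities over feasible families.** At each step an intended
  category is sampled from the agent's propensity weights, restricted to
  currently feasible strategy *families* ({pairing, pot}, {subassembly,
  unit_unit}, {pile, pile_sub}, put, disassemble, other). Feasibility is
  pooled within a family because the family members are
  configuration-determined variants of one intention: an agent intent on
  adding a cup to "the pot" must pair when no pot exists yet. The recorded
  ground-truth intent is the member actually realized under perfect
  judgment, so intents are feasibility-adjusted by construction and
  zero-error classifier agreement is exact.
* **Perfect judgment is tightest-fit.** A pot intent moves the largest
  object that fits anywhere into the tightest-fitting location (smallest
  accepting top) — top-down building, which reproduces the minimum-move pot
  strategy exactly ($n-1$ combines). A subassembly intent builds bottom-up:
  the unit with the smallest base, moved into the next larger cup — the
  subassembly chain route (pair two small cups, insert the unit into the
  next cup, and so on). A pairing intent joins the most similar-sized
  available pair, sampled uniformly among gap-minimal pairs. Uniform choice
  over *all* legal realizations was rejected because it strands agents in
  unmergeable configurations and cannot reproduce the move-optimal pot
  strategy that perfect size judgment implies.
* **Judgment error flips the comparison.** With probability
  `size_judgment_error` per combine, the size comparison is corrupted: a
  nest intent lands as a pile (or a pile intent as a nest), realized
  uniformly among the flipped alternatives. This produces the pile events
  observed in real coding without requiring a pile propensity, and makes
  the success rate monotonically non-increasing in the error rate.
* **Feedback-guided disassembly.** The task gives immediate visual
  feedback. A junction that piles, or that skips a size rank (the skipped
  cups could never be inserted later), can never survive into a complete
  seriation; when such faulty junctions exist a disassemble intent detaches
  at one of them (uniformly chosen), otherwise it splits a random unit at a
  random point. Purely random splitting was rejected: it made additional
  disassembly *reduce* success, the opposite of trial-and-error recovery.
* **Seeding.** Each trial consumes one private random stream seeded from
  the trial seed; `generate_cohort()` derives per-trial seeds from the
  cohort seed, so cohorts are reproducible end to end and trials are
  independent.

`study_schedule()` encodes the default cohort: six child age classes of 7,
10, 12, 12, 12 and 14 participants (one analysed trial each) and an adult
chimpanzee pool of ten trials (five simulated subjects, two trials each —
the real pool drew ten trials from six subjects, but the per-subject split
is not published). Cups provided and action budgets follow the observed
per-group envelopes (3–10 cups; up to 140 actions for children, 192 for
chimpanzees). The propensity profiles were chosen once to emulate the
qualitative developmental pattern: pairing-dominated manipulation and a
50% size-judgment error rate in the youngest class, rising pot then
subassembly/unit-unit weight and falling error with age, and a
high-churn, error-prone but subassembly-capable chimpanzee profile. Under
these defaults the simulated success rate rises from roughly 15–40% in the
youngest class to near 100% in the oldest, with chimpanzees intermediate
(about 70%) and chimpanzee trial lengths averaging around 100–130 actions.

```{r cohort, eval = FALSE}
cohort <- generate_cohort(study_schedule(), seed = 2026)
fit <- analyze_trials(cohort)
glance(fit)
autoplot(fit)
```

## What the simulator does and does not emulate

The generator reproduces the *statistical shape* the pipeline must handle:
trials of 3–10 cups, 0–192 actions, all nine categories present, age-shifted
category mixtures, trial-and-error combine/disassemble loops, and success
defined as complete seriation. It makes no cognitive claims: there is no
learning within or across trials, no memory, no imitation, and its agents
are not fitted to any real participant. Two known gaps between its defaults
and published group figures: simulated chimpanzees express a somewhat
smaller subassembly-family share (roughly 10–15% versus a reported 19.7%)
because the error rate that produces realistic failure also converts nest
intents into piles; and between-seed variance of per-class statistics is
substantial at realistic group sizes (7–14 participants), exactly as
sampling noise would be in the real design. Passing tests on simulated
cohorts therefore validate the pipeline's bookkeeping, not any empirical
claim about real children or apes.

## Numerical and degenerate-input choices

* Ranks are validated against the declared cup count; tokens with
  duplicates, overlapping object/location, or a floor location on `N`/`H`/`D`
  raise classed errors carrying the token index.
* A detach event's location token names the *remainder* of the source
  structure, so object and location never share a cup.
* `max_nesting()` of any configuration is at least 1; `min_moves(1)` is 0.
* Percentages on zero-event trials are 0 with a flag, never dropped rows.
* Group ranges (`cups_min`/`cups_max`, `nesting_min`/`nesting_max`) bound
  member trials; the suite property-tests conservation, label
  exhaustiveness, percentage sums and round-trips on seeded random data.

## Problem sizes used by the test suite

The suite replays the exhaustive state-graph oracle at up to four cups (73
reachable configurations), round-trips 400 random sequences, runs the
monotonicity sweep at 120 trials per error level with five cups, and the
recovery check at 200 nine-cup trials with a 100-action budget, where the
classified category proportions match the feasibility-adjusted intended
proportions to well within three percentage points and zero-noise agreement
is exact. These sizes keep the default check fast while leaving every
property's sampling error far from its threshold.

## Limitations

Only the top cup of a receiver matters physically: telescoping, cup
diameters in centimetres, grasp kinematics and gravity are out of scope, as
are probabilistic classification, intent inference, and inferential
statistics (the underlying comparative designs are descriptive at these
sample sizes). The notation covers single-table, single-participant trials;
video timestamps and natural-language annotations are not parsed.
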