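---
title: "Tracking search strategies in a binary decision tree task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking search strategies in a binary decision tree task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqstrat)
```

## The task

Participants interact with a four-level binary decision tree (BDT). Each
trial starts from an instruction of four concept words (a verb, two nouns
and a size adjective); the participant clicks through four screens of two
abstract icons each and receives a single positive or negative feedback at
the end of the path. The icon-concept mapping is fixed but hidden, so the
mapping must be discovered from feedback alone; a negative feedback does
not reveal *which* level was wrong (a credit-assignment problem). The last
screen is the same in every branch (the two adjectives), so the depth-4
tree has 8 choice contexts, 16 icons, 16 root-to-leaf paths and 16 valid
task instances.

The session protocol: a task instance is repeated until the participant
chooses the correct path 5 times in a row; after 15 successive wrong
answers the participant is asked whether to move on, asked again after 10
further wrong answers, and granted 5 final chances before being
force-advanced; the session is capped at 40 minutes. These constants are
the defaults of `session_config()` and are what the synthetic agents run
under.

In this package a location is the bit-string of the choices that reach it
(`"0"` = first-screen left, `"01"` = left-then-right, ...), and a path is
a 4-bit string. Logs are one row per click (CSV or JSONL with a JSON
header carrying the interface seed and configuration), so a log is fully
self-describing.

## Strategies as automata

Four increasingly sophisticated search strategies are formalized over the
tree. Each maintains a *domain of action* `D` (locations its rules allow),
a learned set `R` and a universe `G`, with knowledge gap

$$\alpha = 1 - |R|/|G|,$$

which is 1 with no knowledge and 0 at full knowledge.

* **random** — no systematic behavior; `D` is the whole tree, `R` stays
  empty, $\alpha \equiv 1$.
* **spatial** — navigates by screen positions only. `G` is the 30 location
  slots. At each task start, `D` is the unexplored slots plus the target
  path; each unsuccessful trial removes the chosen leaf and, bottom-up,
  any screen whose two branches are exhausted. When a task is mastered its
  target leaf enters `R`, closing upward when both siblings are known.
  Full knowledge needs all 16 paths.
* **generative** — learns icon-concept associations. `G` is the 16
  concept-icon pairs. A concept is learned when two tasks share it on
  their targets, the first was mastered, the icon was not clicked between
  the mastering and the second task's start, and it was clicked during the
  second task. Known concepts prune whole subtrees at task start. Full
  knowledge is reachable from positive feedback on 8 well-chosen paths.
* **discriminative** — a generative learner that also infers the
  *complement*: when concept A is learned, the on-screen neighbor is
  labeled not-A and enters `R` too. Full knowledge is reachable from 4
  paths. `minimal_positive_cover()` verifies the 16/8/4 cover sizes by
  brute-force subset search.

The bottom-up domain rule is implemented as exhausted-subtree propagation:
a screen leaves the domain only when both branches below it are out. A
strictly literal reading of the update rule would also discard a node with
an unexplored subtree whenever its sibling is exhausted, making parts of
the strategy's own search space unreachable while still unexplored, which
contradicts the rule's stated purpose (discarding *explored* parents).

## The behavioral model

The observer interprets every click through the observation alphabet
$V = \{\text{mistake}, \text{explore}, \text{hit}\}$.

**Emissions.** At each click step the candidate root-to-leaf paths
consistent with the clicks made so far in the trial are split into $H$
(every location in `D`, at least one off target) and $H^*$ (entirely on
target). The emission is
$(0,\ |H|/(|H|+|H^*|),\ |H^*|/(|H|+|H^*|))$, or the fallback $(1,0,0)$
when both sets are empty — the strategy's rules cannot explain the
behavior. The consistency condition covers the *already made* in-trial
clicks too: re-entering a region the strategy has ruled out yields the
fallback, which is how e.g. repeating a previously rewarded path under a
different instruction becomes a spatial mistake. The random strategy's
emission is fixed at $(1,0,0)$.

**Votes and transitions.** Per step, each strategy distributes its own
emission mass: the best explainers of each observation strengthen their
self-links, everyone else donates to them in equal parts. The random row
is overridden: it votes $1/|U|$ over
$U = \{s_i : P(\text{mistake}|s_i)=0\} \cup \{\text{random}\}$. Votes are
accumulated into transition probabilities by a Gaussian kernel
$\tau(n) = e^{-(n-t)^2/2\sigma^2}$ over past steps, normalized to a
maximum of 1 at the current step; rows of the transition matrix are
probability distributions, and the empty history starts from the identity.

A strategy whose rules are violated at a step (the fallback emission) is
treated as *inactive* there: it still votes — its mass flows to the best
explainers, i.e. toward random — but it is not a candidate best explainer
and earns no weight at that step. Under a plain argmax a violated strategy
would instead self-link with weight 1 while the random row donates itself
away, so mistakes would *reward* the strategy whose rules were broken;
the inactive treatment is what makes mistakes evidence for random behavior
and lets a dominant strategy be punished abruptly when the participant
stops honoring it. The exported `step_votes()`/`update_weights()` default
to the plain scheme (`active = NULL`); the tracker passes activity flags.

**Weights.** For each observation $v$, the best transition links maximize
$P(s_k \to s_j)P(v|s_j)$. Each strategy's cost is the best product chain
`prior * P(v|s_i) * prod(L * E)` over chains that start at it and end in a
best link; chains have distinct interior strategies but an unrestricted
final node (an optimal chain can always be shortened so that only its
final edge revisits). With four strategies exhaustive enumeration is exact
and cheap. The prior is the strategy's current weight when positive and
its self-transition $L_{ii}$ otherwise, so strategies at weight zero can
re-enter. Costs are weighted by each observation's kernel relevance
$\tau_v(t)$ (computed from the whole-session consensus history) and summed
over $V$, then normalized.

The consensus observation is the one with the greatest summed emission
probability; exact ties resolve by the fixed precedence
explore > hit > mistake (the weakest claim about the participant). When
two systematic strategies hold identical domains, only the one with the
smaller $\alpha$ enters the reported normalization; the rule is scoped to
the systematic strategies because the random strategy's emissions are
fixed rather than domain-derived (before the first trial ends all location
sets coincide, and including random would degenerate the model at session
start). Ties on $\alpha$ keep the hierarchically simplest strategy. The
excluded strategy's mass is carried in the all-strategy normalization used
as the next prior, so it rejoins as soon as the domains diverge.

The behavioral knowledge gap is the mixture
$\alpha^*(t) = \sum_i \alpha_i(t) w_i(t)$; the participant's approximate
learning curve is $1 - \alpha^*$.

## Prediction and scores

Before each click every strategy is asked which on-screen icon comes next:
a *dichotomous* answer when exactly one of the two candidate locations is
in its domain, otherwise a seeded coin toss (50/50 guess). The mixture
prediction is the action with the largest weight-summed support among
dichotomous experts; coin-tossing experts contribute their weight to
`guess_mass` and to neither action (their random pick only decides fully
ambiguous steps). Weights are those known *before* the click. Per-trial
scores average the consensus observations of the trial's four steps:
expertise scores hits 1, explorations 0.5 and mistakes 0, so
`expertise = exploitation + 0.5 * exploration` holds exactly.

A session counts as *learner* when all 16 instances were completed through
the advance streak (no force-advance, no timeout). Group curves average
per-trial vectors across participants after linear interpolation onto a
per-task grid whose size is the group-mean trial count of that task.

## Synthetic agents

`simulate_session()` runs scripted participants through the full protocol:
task instances in a seeded random order, prompts always accepted,
synthetic timestamps at 1.5 s per click (so the 40-minute cap is reachable
but not binding for rule-following agents). Agents apply the strategy
rules as a generative model: at each screen they click uniformly among the
sides that still lead to a rule-consistent full path (an in-domain
completion or the target) — a side whose subtree is entirely excluded is a
dead end a rule-follower would not enter. Once a task yields positive
feedback a systematic agent exploits (repeats the target); the random
agent stays memoryless. `epsilon` adds uniform lapse clicks; mixtures
switch kinds on a task schedule; `make_agent(..., full_knowledge = TRUE)`
starts from `R = G`, which collapses every task's domain to the target
path and produces the pure exploitation limit.

What the generator emulates: the session protocol, the strategy-consistent
click statistics, determinism under seeds. What it does not: human
reaction times, forgetting, attention lapses beyond the uniform `epsilon`,
or mid-task strategy blends. Tests passing on these agents therefore
validate the machinery and the model's formal properties, not claims about
human cohorts.

## Numerical choices

* `sigma` defaults to 20 click steps (about five trials), the width used
  for all reported modeling here; `sigma = 1` reacts fastest, larger
  values smooth the curves. The kernel's support is treated as finite
  beyond 7.5 sigma, where weights fall below 1e-12 of the peak.
* Initial weights are uniform over the four strategies; the model is told
  nothing about the participant at step 1.
* Chain products are evaluated in log space with a large negative sentinel
  for log(0), so zero probabilities propagate exactly.
* Argmax sets use a relative tolerance of 1e-12 so algebraically exact
  ties are recognized under floating point.
* If a step yields an all-zero weight vector (possible only when the
  required transition edges carry exactly zero mass), the tracker keeps
  the previous weights for that step; `update_weights()` itself treats it
  as an error.
* The prompt protocol is the literal sequence 15 wrongs, prompt, 10 more,
  prompt, 5 chances, force-advance; whether the 5 chances start after the
  first or second refusal is ambiguous in the protocol description, and
  the literal sequence is a design choice.

The test suite runs the full pipeline on simulated sessions of roughly
400-1600 clicks; the parameter-recovery study uses 20 replicates per pure
agent and the oracle-equivalence study 1000 randomized toy systems. These
sizes were chosen so each property is exercised across seeds while a
complete check runs in minutes on one core.

## Known limitations

* **Strategy identifiability.** Knowledge updates are computed from the
  feedback history alone, so the observer's concept automata accumulate
  knowledge from *any* participant who masters tasks — including one who
  navigates purely by position. Late in a mastered session every strategy's
  domain collapses toward the target and behavior is streak-dominated,
  which the most knowledge-efficient strategy (discriminative) explains
  best. Consequently pure spatial or generative generators are attributed
  to the discriminative strategy toward the session end; the same
  convergence is what the framework reports for human learners. Strategy
  identity is therefore reliably visible early and mid-session (and
  whenever rules are being violated), while late-session attribution
  reflects knowledge efficiency, not generating mechanism. The
  parameter-recovery acceptance test documents this: random and
  discriminative agents are recovered from their own logs, spatial and
  generative agents only part of the time.
* The generative strategy is additionally squeezed between spatial (a
  better explainer of exploration) and discriminative (a better explainer
  of hits), mirroring its brief prominence in human data.
* Locations once learned are never forgotten; within one session this is
  by construction of the protocol, but the framework would need a
  forgetting mechanism for longer horizons.
* The concept-learning predicate demands a click-free window between the
  mastering of one task and the start of the next shared-concept task, so
  not every concept can be checked within one session ordering; concept
  alphas need not reach 0 even for flawless participants unless the task
  order cooperates.
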