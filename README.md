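# seqstrat

Strategy tracking for sequential decision making in a binary decision
tree (BDT) task.

People become experts at multi-step interfaces (ATMs, menus, search
trees) by turning isolated exploratory clicks into practiced sequences.
`seqstrat` is for researchers who want to *watch that happen* in
trial-by-trial behavioral logs: it infers, click by click, which search
strategy best explains a participant's behavior, how much of the task
structure they have learned, and what they will click next.

The task is a 4-level BDT: an instruction of four concept words, four
binary icon choices, and a single positive/negative feedback at the end
of the chosen path (16 paths, 16 icons, 16 task instances; a task
advances after 5 correct trials in a row). The package implements:

* the task environment and session protocol, with self-describing
  CSV/JSONL click logs (`build_interface()`, `simulate_session()`,
  `write_session_log()`);
* four strategy automata — **random**, **spatial**, **generative**,
  **discriminative** — with formal domain-of-action updates, knowledge
  updates and knowledge gap `alpha_i = 1 - |R_i|/|G_i|`;
* a hidden-Markov-style observer: per-step emissions over
  `{mistake, explore, hit}` from the candidate path sets `H`/`H*`,
  vote-based transition probabilities under a Gaussian observation window
  `tau(n) = exp(-(n-t)^2 / 2 sigma^2)` (default `sigma = 20` steps), and
  observation-constrained Viterbi weight updates; the mixed gap
  `alpha* = sum_i alpha_i w_i` gives the learning curve `1 - alpha*`
  (`track_session()`);
* a Mixture-of-Experts next-choice predictor with 50/50-guess accounting
  (`predict_choices()`), path-level expertise/exploration/exploitation
  scores (`score_paths()`), learner classification and group-averaged
  curves;
* scripted synthetic agents (pure strategies, mixtures, noisy variants)
  for fixtures and parameter-recovery studies (`agent_policy()`,
  `generate_fixture_suite()`).

## Worked example

Simulate a discriminative learner and track it:

```r
library(seqstrat)
iface <- build_interface(depth = 4, seed = 1)
log   <- simulate_session(agent_policy("discriminative", rng_seed = 1),
                          iface, session_config(rng_seed = 1))
log
#> <bdt_session_log> participant discriminative_1: 404 clicks, 16 tasks (depth 4, interface seed 1)
classify_participant(log)
#> [1] "learner"

trace <- track_session(log, sigma = 20)
tail(trace[, c("step", "task_index", "v_consensus", "w_spatial",
               "w_discriminative", "alpha_discriminative", "alpha_star")], 3)
#>  step task_index v_consensus w_spatial w_discriminative alpha_discriminative alpha_star
#>   402         16         hit         0                1                    0          0
#>   403         16         hit         0                1                    0          0
#>   404         16         hit         0                1                    0          0
```

By the final task the discriminative strategy carries all the weight
(`w_discriminative = 1`), its knowledge gap has closed
(`alpha_discriminative = 0`) and the behavioral learning curve
`1 - alpha_star` has reached 1: the model has recognized a fully
knowledgeable, concept-driven participant. Prediction and per-trial
scores tell the same story:

```r
pred <- predict_choices(log, seed = 1)
mean(pred$correct[pred$step > 3 * nrow(pred) / 4])     # late-session accuracy
#> [1] 0.96
mean(pred$guess_mass[pred$step > 3 * nrow(pred) / 4])  # forced 50/50 guesses
#> [1] 0.05

head(score_paths(trace), 3)
#>  task_index trial_index expertise exploration exploitation
#>           1           1      0.62        0.75         0.25
#>           1           2      0.62        0.75         0.25
#>           1           3      0.62        0.75         0.25
```

Early trials score as exploration (expertise 0.62), the final trials as
pure exploitation (expertise 1): the identity
`expertise = exploitation + 0.5 * exploration` holds for every trial.

The strategies' efficiency hierarchy is a combinatorial fact of the tree:
the smallest set of rewarded target paths that completes a strategy's
knowledge is 16 (spatial), 8 (generative) and 4 (discriminative), found
by brute-force subset search:

```r
minimal_positive_cover("discriminative", iface)
#> [1] 4
```

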