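# Strategy automata: domains of action, knowledge updates, alpha, candidate
# paths and minimal positive-feedback covers.

test_that("fresh domains are the whole tree and alpha is 1", {
  iface <- test_interface()
  for (k in c("random", "spatial", "generative", "discriminative")) {
    st <- strategy_state(k, iface)
    st <- reset_for_task(st, "0000", iface)
    expect_setequal(st$D, iface$locations)
    expect_equal(alpha_gap(st), 1)
  }
  expect_equal(length(strategy_state("spatial", iface)$G), 30L)
  expect_equal(length(strategy_state("generative", iface)$G), 16L)
})

test_that("spatial reset excludes learned off-target leaves, keeps the target", {
  iface <- test_interface()
  st <- strategy_state("spatial", iface)
  st$R <- c("1111")                       # a learned leaf not on the target
  st <- reset_for_task(st, "0000", iface)
  expect_false("1111" %in% st$D)
  expect_true(all(path_locations("0000") %in% st$D))
  # a learned leaf on the target stays available
  st$R <- c("0000")
  st <- reset_for_task(st, "0000", iface)
  expect_true("0000" %in% st$D)
})

test_that("concept reset prunes the opposite half-tree of a learned level-1 concept", {
  iface <- test_interface()
  st <- strategy_state("generative", iface)
  st$R <- unname(iface$icon_of[["0"]])    # level-1 concept of the target
  st <- reset_for_task(st, "0000", iface)
  # subtree under the level-1 neighbor: 1 + 2 + 4 + 8 = 15 slots gone
  gone <- loc_subtree("1", 4L)
  expect_length(gone, 15L)
  expect_false(any(gone %in% st$D))
  expect_setequal(st$D, setdiff(iface$locations, gone))
})

test_that("reset never prunes the target for any systematic strategy", {
  iface <- test_interface()
  targets <- all_paths(4L)
  for (k in c("spatial", "generative", "discriminative")) {
    st <- strategy_state(k, iface, full_knowledge = TRUE)
    for (tg in targets[c(1L, 7L, 16L)]) {
      st2 <- reset_for_task(st, tg, iface)
      expect_true(all(path_locations(tg) %in% st2$D))
    }
  }
})

test_that("domain updates remove the chosen leaf, then exhausted parents", {
  iface <- test_interface()
  st <- reset_for_task(strategy_state("spatial", iface), "0000", iface)
  st <- update_domain(st, "0110")
  expect_setequal(setdiff(iface$locations, st$D), "0110")   # only its leaf
  # exhausting the sibling removes the level-3 slot too
  st <- update_domain(st, "0111")
  expect_setequal(setdiff(iface$locations, st$D), c("0110", "0111", "011"))
  # domains never grow within a task
  expect_true(all(st$D %in% iface$locations))
  # random is untouched
  rnd <- update_domain(strategy_state("random", iface), "0110")
  expect_setequal(rnd$D, iface$locations)
})

test_that("domain updates are monotone within a task", {
  iface <- test_interface()
  st <- reset_for_task(strategy_state("spatial", iface), "0000", iface)
  prev <- st$D
  for (chosen in c("1000", "1001", "1010", "1011", "0100")) {
    st <- update_domain(st, chosen)
    expect_true(all(st$D %in% prev))
    prev <- st$D
  }
})

test_that("spatial knowledge closes bottom-up over learned targets", {
  iface <- test_interface()
  st <- strategy_state("spatial", iface)
  tasks <- data.frame(task_index = 1:2, target = c("0000", "0001"),
                      t_start = c(1L, 41L), t_learned = c(40L, NA),
                      stringsAsFactors = FALSE)
  clicks <- data.frame(step = integer(0), icon = character(0))
  st <- update_knowledge(st, iface, tasks, clicks)
  expect_setequal(st$R, "0000")           # first learned target leaf only
  tasks$t_learned[2L] <- 80L
  st <- update_knowledge(st, iface, tasks, clicks)
  # both sibling leaves learned -> their screen (and its slot) is learned
  expect_setequal(st$R, c("0000", "0001", "000"))
})

test_that("concept knowledge needs two clean shared-target tasks", {
  iface <- test_interface()
  c1 <- unname(iface$icon_of[["0"]])      # shared level-1 icon
  # task a (target 0000) learned at step 40; task b (target 0111) starts at 41
  tasks <- data.frame(task_index = 1:2, target = c("0000", "0111"),
                      t_start = c(1L, 41L), t_learned = c(40L, NA),
                      stringsAsFactors = FALSE)
  clicks <- data.frame(step = c(37L, 41L), icon = c(c1, c1),
                       stringsAsFactors = FALSE)
  st <- update_knowledge(strategy_state("generative", iface), iface,
                         tasks, clicks)
  expect_setequal(st$R, c1)
  # a stray click of the concept between the tasks blocks learning
  stray <- rbind(clicks, data.frame(step = 40.5, icon = c1))
  st2 <- update_knowledge(strategy_state("generative", iface), iface,
                          tasks, stray)
  expect_length(st2$R, 0L)
  # discriminative learns the complement too
  st3 <- update_knowledge(strategy_state("discriminative", iface), iface,
                          tasks, clicks)
  expect_setequal(st3$R, c(c1, unname(iface$icon_of[["1"]])))
})

test_that("alpha follows 1 - |R|/|G| and random stays at 1", {
  iface <- test_interface()
  st <- strategy_state("generative", iface)
  expect_equal(alpha_gap(st), 1)
  st$R <- unique(unname(iface$icon_of))[1:4]
  expect_equal(alpha_gap(st), 0.75)
  st$R <- st$G
  expect_equal(alpha_gap(st), 0)
  expect_equal(alpha_gap(strategy_state("random", iface)), 1)
})

test_that("candidate paths match brute-force enumeration", {
  iface <- test_interface()
  st <- reset_for_task(strategy_state("spatial", iface), "0000", iface)
  sets <- candidate_paths(st, "", "0000")
  expect_length(sets$H, 15L)
  expect_length(sets$H_star, 1L)
  expect_length(intersect(sets$H, sets$H_star), 0L)
  # after three correct clicks only the final correct click remains on target
  sets3 <- candidate_paths(st, "000", "0000")
  expect_identical(sets3$H_star, "0000")
  # domain reduced exactly to the target: no off-target path is in-domain
  st$D <- path_locations("0000")
  expect_length(candidate_paths(st, "", "0000")$H, 0L)
  expect_identical(candidate_paths(st, "", "0000")$H_star, "0000")

  # randomized domains against the independent enumeration oracle
  set.seed(42)
  for (rep in 1:25) {
    st$D <- sample(iface$locations, sample(5:30, 1L))
    target <- sample(all_paths(4L), 1L)
    prefix <- substr(target, 1L, sample(0:3, 1L))
    got <- candidate_paths(st, prefix, target)
    want <- oracle_candidate_sets(st$D, target, prefix, 4L)
    expect_setequal(got$H, want$H)
    expect_setequal(got$H_star, want$H_star)
  }
})

test_that("minimal covers order discriminative <= generative <= spatial", {
  iface2 <- build_interface(depth = 2L, seed = 1L)
  cov2 <- c(spatial = minimal_positive_cover("spatial", iface2),
            generative = minimal_positive_cover("generative", iface2),
            discriminative = minimal_positive_cover("discriminative", iface2))
  # depth 2: 4 paths; each rewarded path reveals its 2 icons (1 per context
  # under not-A inference it reveals all 4)
  expect_equal(unname(cov2), c(4L, 2L, 1L))
  expect_true(cov2["discriminative"] <= cov2["generative"])
  expect_true(cov2["generative"] <= cov2["spatial"])
})

test_that("strategy states serialize and restore through JSON", {
  iface <- test_interface()
  st <- reset_for_task(strategy_state("discriminative", iface), "0101", iface)
  st$R <- c("*0", "*1")
  back <- strategy_state_from_json(strategy_state_json(st), iface)
  expect_equal(back$kind, st$kind)
  expect_setequal(back$D, st$D)
  expect_setequal(back$R, st$R)
})
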