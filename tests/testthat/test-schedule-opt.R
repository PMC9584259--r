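test_that("objective variants evaluate their stated formulas", {
  # double-book the LAST slot so exactly one certain patient waits 30 min
  ids <- paste0("p", 1:5)
  roster <- tibble::tibble(patient_id = ids,
                           group = c("nonB", "nonB", "nonB", "B", "B"))
  g <- slot_grid(4, 30)
  asg <- assignment(ids, c(1, 2, 3, 4, 4))  # p4, p5 double-booked last
  p <- setNames(rep(1, 5), ids)
  w <- cost_weights(1, 0, 0)

  trad <- objective_value(asg, g, p, roster, objective_spec("TRADITIONAL", w))
  ru <- objective_value(asg, g, p, roster, objective_spec("RACE_UNAWARE", w))
  ra <- objective_value(asg, g, p, roster, objective_spec("RACE_AWARE", w))
  expect_equal(trad, 30)        # only the second-served overbooked patient waits
  expect_equal(ru, 5 * 30)      # n * max individual expected wait
  expect_equal(ra, 5 * 15)      # worst group mean: B group waits (0+30)/2

  # equal waits across groups: race-aware wait term equals the mean wait
  asg2 <- assignment(ids[1:4], 1:4)
  roster2 <- roster[1:4, ]
  p2 <- setNames(rep(1, 4), ids[1:4])
  expect_equal(
    objective_value(asg2, g, p2, roster2, objective_spec("RACE_AWARE", w)),
    objective_value(asg2, g, p2, roster2, objective_spec("TRADITIONAL", w)))

  # single-group roster: race-aware reduces to n * overall mean wait
  roster3 <- dplyr::mutate(roster, group = "B")
  expect_equal(
    objective_value(asg, g, p, roster3, objective_spec("RACE_AWARE", w)),
    5 * mean(c(0, 0, 0, 0, 30)))

  expect_error(
    objective_value(asg, g, p, dplyr::select(roster, -"group"),
                    objective_spec("RACE_AWARE", w)),
    class = "fairbook_config_error")
})

test_that("the traditional oracle overbooks the lowest-show-probability patient", {
  roster <- tibble::tibble(patient_id = c("hi1", "hi2", "lo"))
  g <- slot_grid(2, 30)
  p <- c(hi1 = 0.9, hi2 = 0.9, lo = 0.3)
  best <- optimize_oracle(roster, g, p, objective_spec("TRADITIONAL"))
  load <- table(best$slot)
  overbooked_slot <- as.integer(names(load)[load == 2])
  expect_true("lo" %in% best$patient_id[best$slot == overbooked_slot])
})

test_that("with as many sure patients as slots the oracle finds the zero-cost schedule", {
  roster <- tibble::tibble(patient_id = paste0("q", 1:4))
  g <- slot_grid(4, 30)
  p <- setNames(rep(1, 4), roster$patient_id)
  best <- optimize_oracle(roster, g, p)
  expect_equal(attr(best, "objective"), 0)
  expect_equal(sort(best$slot), 1:4)
})

test_that("the race-aware oracle attains the enumerated min-max group wait", {
  set.seed(606)
  roster <- tibble::tibble(patient_id = paste0("p", 1:5),
                           group = c("B", "B", "nonB", "nonB", "nonB"))
  g <- slot_grid(3, 30)
  p <- setNames(round(runif(5, 0.3, 0.95), 2), roster$patient_id)
  spec <- objective_spec("RACE_AWARE", cost_weights(1, 1, 1))
  best <- optimize_oracle(roster, g, p, spec)
  # exhaustive re-check: no capacity-feasible assignment beats it
  best_obj <- attr(best, "objective")
  combos <- expand.grid(rep(list(1:3), 5))
  for (i in seq_len(nrow(combos))) {
    slots <- as.integer(combos[i, ])
    if (max(table(slots)) > 2) next
    asg <- assignment(roster$patient_id, slots)
    obj <- objective_value(asg, g, p, roster, spec)
    expect_gte(obj, best_obj - 1e-9)
  }
})

test_that("heuristic search matches the oracle objective on random small instances", {
  set.seed(707)
  for (k in 1:12) {
    n <- sample(3:6, 1)
    m <- sample(2:4, 1)
    if (n > 2 * m) next
    inst <- random_instance(n, m)
    for (variant in c("TRADITIONAL", "RACE_AWARE", "RACE_UNAWARE")) {
      spec <- objective_spec(variant)
      oracle <- optimize_oracle(inst$roster, inst$grid, inst$p, spec)
      heur <- optimize_heuristic(inst$roster, inst$grid, inst$p, spec,
                                 seed = k)
      expect_equal(attr(heur, "objective"), attr(oracle, "objective"),
                   tolerance = 1e-8)
    }
  }
})

test_that("the heuristic is seed-deterministic and zero passes return the greedy start", {
  set.seed(808)
  inst <- random_instance(8, 5)
  h1 <- optimize_heuristic(inst$roster, inst$grid, inst$p, seed = 3)
  h2 <- optimize_heuristic(inst$roster, inst$grid, inst$p, seed = 3)
  expect_identical(h1$slot, h2$slot)

  greedy <- optimize_heuristic(inst$roster, inst$grid, inst$p, seed = 3,
                               max_passes = 0)
  improved <- optimize_heuristic(inst$roster, inst$grid, inst$p, seed = 3)
  expect_lte(attr(improved, "objective"), attr(greedy, "objective") + 1e-9)
  # greedy start books the highest-probability patients one per slot
  top <- names(sort(inst$p, decreasing = TRUE))[1:5]
  expect_equal(sort(greedy$slot[match(top, greedy$patient_id)]), 1:5)
})

test_that("group-blind variants are invariant to permuting group labels", {
  set.seed(909)
  inst <- random_instance(6, 4)
  for (variant in c("TRADITIONAL", "RACE_UNAWARE")) {
    spec <- objective_spec(variant)
    base <- optimize_oracle(inst$roster, inst$grid, inst$p, spec)
    permuted <- inst$roster
    permuted$group <- sample(permuted$group)
    again <- optimize_oracle(permuted, inst$grid, inst$p, spec)
    expect_identical(base$slot, again$slot)
  }
})

test_that("quota checks count desirable-slot fractions and flag shortfalls", {
  # proportional allocation over an all-desirable schedule satisfies 20/60
  ids <- paste0("p", 1:10)
  roster <- tibble::tibble(patient_id = ids,
                           group = rep(c("B", "nonB"), c(3, 7)))
  g <- slot_grid(10, 30)
  asg <- assignment(ids, 1:10)
  con <- quota_constraint("group", c(B = 0.2, nonB = 0.6))
  chk <- check_quota(asg, g, roster, con)
  expect_true(chk$satisfied)
  expect_equal(chk$fractions$attained, c(0.3, 0.7))

  # zero minima are always satisfied
  expect_true(check_quota(asg, g, roster,
                          quota_constraint("group", c(B = 0, nonB = 0)))$satisfied)

  # worked example: both desirable slots go to non-B patients
  ex <- worked_example()
  chk2 <- check_quota(ex$assignment, ex$grid, ex$roster,
                      quota_constraint("group", c(B = 0.5)))
  expect_false(chk2$satisfied)
  expect_equal(chk2$fractions$attained, 0)

  # no desirable slot at all: fractions undefined, constraint unsatisfied
  g2 <- slot_grid(2, 30)
  packed <- assignment(paste0("x", 1:4), c(1, 1, 2, 2))
  roster2 <- tibble::tibble(patient_id = paste0("x", 1:4),
                            group = c("B", "B", "nonB", "nonB"))
  chk3 <- check_quota(packed, g2, roster2, quota_constraint("group", c(B = 0.2)))
  expect_false(chk3$satisfied)
  expect_true(is.na(chk3$fractions$attained))
})

test_that("risk quotas reserve desirable slots for the top no-show tercile", {
  ids <- paste0("p", 1:6)
  roster <- tibble::tibble(patient_id = ids)
  g <- slot_grid(6, 30)
  # ceil(6/3) = 2 highest-risk patients: p6 (0.3) and p5 (0.4)
  p <- setNames(c(0.9, 0.85, 0.8, 0.5, 0.4, 0.3), ids)
  asg <- assignment(ids, 1:6)
  chk <- check_quota(asg, g, roster, quota_constraint("risk", 0.3), p)
  expect_equal(chk$fractions$attained, 2 / 6)
  expect_true(chk$satisfied)
  chk2 <- check_quota(asg, g, roster, quota_constraint("risk", 0.5), p)
  expect_false(chk2$satisfied)
})

test_that("constrained optimization respects quotas or reports infeasibility", {
  set.seed(111)
  roster <- tibble::tibble(patient_id = paste0("p", 1:6),
                           group = rep(c("B", "nonB"), c(2, 4)))
  g <- slot_grid(4, 30)
  p <- setNames(c(0.4, 0.45, 0.9, 0.92, 0.88, 0.95), roster$patient_id)
  con <- quota_constraint("group", c(B = 0.5))
  spec <- objective_spec("TRADITIONAL", constraints = list(con))
  best <- optimize_oracle(roster, g, p, spec)
  expect_true(check_quota(best, g, roster, con, p)$satisfied)
  heur <- optimize_heuristic(roster, g, p, spec, seed = 4)
  expect_true(check_quota(heur, g, roster, con, p)$satisfied)
  # the unconstrained optimum overbooks both low-probability (B) patients,
  # so the constraint must cost something
  uncon <- optimize_oracle(roster, g, p, objective_spec("TRADITIONAL"))
  expect_gte(attr(best, "objective"), attr(uncon, "objective"))

  impossible <- objective_spec("TRADITIONAL",
                               constraints = list(quota_constraint("group", c(B = 1, nonB = 1))))
  expect_error(optimize_oracle(roster, g, p, impossible),
               class = "fairbook_infeasible")
})
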