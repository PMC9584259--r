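test_that("degenerate show probabilities reduce to deterministic days", {
  ex <- worked_example()
  ids <- ex$roster$patient_id
  sure <- setNames(rep(1, 5), ids)
  eo <- expected_outcome_exact(ex$assignment, ex$grid, sure)
  day <- simulate_day(ex$assignment, ex$grid, sure)
  expect_equal(setNames(eo$patients$expected_wait, eo$patients$patient_id),
               setNames(day$patients$wait, day$patients$patient_id))
  expect_equal(eo$idle, day$idle)
  expect_equal(eo$overtime, day$overtime)

  none <- expected_outcome_exact(ex$assignment, ex$grid, setNames(rep(0, 5), ids))
  expect_equal(none$patients$expected_wait, rep(0, 5))
  expect_equal(none$idle, ex$grid$session_length)
  expect_equal(none$overtime, 0)
})

test_that("two half-probability patients in one slot give the enumerated 7.5/7.5/7.5", {
  g <- slot_grid(1, 30)
  asg <- assignment(c("x", "y"), c(1, 1))
  eo <- expected_outcome_exact(asg, g, c(x = 0.5, y = 0.5))
  # four equiprobable outcomes: only the both-show outcome (prob .25)
  # produces a 30-min wait, 30 min of overtime; only the none-show outcome
  # leaves the whole 30-min session idle
  expect_equal(sum(eo$patients$expected_wait), 7.5)
  expect_equal(eo$idle, 7.5)
  expect_equal(eo$overtime, 7.5)
  expect_equal(schedule_cost(eo, cost_weights(1, 1, 1)), 22.5)
})

test_that("exact enumeration matches the independent reference on random instances", {
  set.seed(404)
  for (k in 1:10) {
    n <- sample(2:7, 1)
    m <- sample(2:4, 1)
    if (n > 2 * m) next
    asg <- random_assignment(n, m)
    grid <- slot_grid(m, 30)
    p <- setNames(runif(n, 0.1, 0.95), asg$patient_id)
    eo <- expected_outcome_exact(asg, grid, p)
    want <- ref_expected(asg, grid, p)
    got <- setNames(eo$patients$expected_wait, eo$patients$patient_id)
    expect_equal(got[names(want$waits)], want$waits, tolerance = 1e-10)
    expect_equal(eo$idle, want$idle, tolerance = 1e-10)
    expect_equal(eo$overtime, want$overtime, tolerance = 1e-10)
  }
})

test_that("Monte Carlo agrees with exact enumeration within 3 standard errors", {
  set.seed(505)
  for (k in 1:8) {
    n <- sample(4:10, 1)
    m <- sample(3:6, 1)
    if (n > 2 * m) next
    asg <- random_assignment(n, m)
    grid <- slot_grid(m, 30)
    p <- setNames(runif(n, 0.2, 0.95), asg$patient_id)
    exact <- expected_outcome_exact(asg, grid, p)
    mc <- expected_outcome_mc(asg, grid, p, n_samples = 4000, seed = k)
    expect_lt(abs(sum(mc$patients$expected_wait) -
                    sum(exact$patients$expected_wait)),
              3 * mc$se[["total_wait"]] + 1e-9)
    expect_lt(abs(mc$idle - exact$idle), 3 * mc$se[["idle"]] + 1e-9)
    expect_lt(abs(mc$overtime - exact$overtime),
              3 * mc$se[["overtime"]] + 1e-9)
  }
})

test_that("Monte Carlo evaluation is seed-deterministic and degenerate at p = 1", {
  ex <- worked_example()
  p <- setNames(ex$roster$show_prob, ex$roster$patient_id)
  a <- expected_outcome_mc(ex$assignment, ex$grid, p, n_samples = 500, seed = 9)
  b <- expected_outcome_mc(ex$assignment, ex$grid, p, n_samples = 500, seed = 9)
  expect_equal(a$patients, b$patients)
  expect_equal(a$idle, b$idle)

  sure <- setNames(rep(1, 5), ex$roster$patient_id)
  mc <- expected_outcome_mc(ex$assignment, ex$grid, sure, n_samples = 50, seed = 1)
  day <- simulate_day(ex$assignment, ex$grid, sure)
  expect_equal(setNames(mc$patients$expected_wait, mc$patients$patient_id),
               setNames(day$patients$wait, day$patients$patient_id))
  expect_equal(unname(mc$se), c(0, 0, 0))
})

test_that("schedule cost is linear in the weights and monotone in show probabilities", {
  ex <- worked_example()
  p <- setNames(ex$roster$show_prob, ex$roster$patient_id)
  eo <- expected_outcome_exact(ex$assignment, ex$grid, p)
  c1 <- schedule_cost(eo, cost_weights(1, 1, 1))
  c2 <- schedule_cost(eo, cost_weights(2, 2, 2))
  expect_equal(c2, 2 * c1)
  expect_equal(schedule_cost(eo, cost_weights(1, 0, 0)) +
                 schedule_cost(eo, cost_weights(0, 1, 0)) +
                 schedule_cost(eo, cost_weights(0, 0, 1)), c1)

  # with weight only on wait and overtime, raising any p never lowers cost
  w <- cost_weights(1, 0, 1)
  set.seed(7)
  for (k in 1:10) {
    p1 <- setNames(runif(5, 0.1, 0.9), ex$roster$patient_id)
    p2 <- p1
    i <- sample(5, 1)
    p2[i] <- min(1, p1[i] + runif(1, 0, 1 - p1[i]))
    cost1 <- schedule_cost(expected_outcome_exact(ex$assignment, ex$grid, p1), w)
    cost2 <- schedule_cost(expected_outcome_exact(ex$assignment, ex$grid, p2), w)
    expect_gte(cost2, cost1 - 1e-9)
  }
})

test_that("over-cutoff instances are directed to Monte Carlo; bad weights rejected", {
  ids <- sprintf("p%02d", 1:6)
  asg <- assignment(ids, c(1, 1, 2, 2, 3, 3))
  g <- slot_grid(3, 30)
  p <- setNames(rep(0.8, 6), ids)
  expect_error(expected_outcome_exact(asg, g, p, cutoff = 5),
               class = "fairbook_size_error")
  auto <- expected_outcome(asg, g, p, cutoff = 5, n_samples = 200, seed = 2)
  expect_equal(auto$mode, "mc")
  expect_error(cost_weights(-1, 1, 1), class = "fairbook_config_error")
  expect_error(cost_weights(0, 0, 0), class = "fairbook_config_error")
})
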