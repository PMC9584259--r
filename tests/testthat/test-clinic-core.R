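test_that("worked example: double-booking delays the second-served and following patients", {
  ex <- worked_example()
  out <- simulate_day(ex$assignment, ex$grid, all_show(ex$roster))
  waits <- setNames(out$patients$wait, out$patients$patient_id)
  expect_equal(waits[["a"]], 0)   # alone in slot 1, never waits
  expect_equal(waits[["d"]], 0)   # first served in the overbooked slot
  expect_equal(waits[["e"]], 30)  # second served waits one full slot
  expect_equal(waits[["c"]], 30)  # the delay propagates to the next slot
  expect_equal(waits[["b"]], 30)  # and, with everyone shown, to the last
  expect_equal(out$idle, 0)
  expect_equal(out$overtime, 30)
})

test_that("a saturated punctual schedule has zero wait, idle, and overtime", {
  g <- slot_grid(4, 30)
  asg <- assignment(paste0("p", 1:4), 1:4)
  out <- simulate_day(asg, g, setNames(rep(1, 4), paste0("p", 1:4)))
  expect_equal(out$patients$wait, rep(0, 4))
  expect_equal(out$idle, 0)
  expect_equal(out$overtime, 0)
})

test_that("partial attendance on the worked example matches hand execution", {
  ex <- worked_example()
  shows <- c(a = 1, d = 1, e = 1, c = 0, b = 0)
  out <- simulate_day(ex$assignment, ex$grid, shows)
  waits <- setNames(out$patients$wait, out$patients$patient_id)
  expect_equal(unname(waits[c("a", "d", "e")]), c(0, 0, 30))
  expect_equal(out$idle, 30)     # last completion 10:30, three 30-min services
  expect_equal(out$overtime, 0)
})

test_that("simulate_day agrees with an independent reference on random instances", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(2:8, 1)
    m <- sample(2:6, 1)
    if (n > 2 * m) next
    asg <- random_assignment(n, m)
    grid <- slot_grid(m, sample(c(15, 20, 30), 1))
    shows <- setNames(rbinom(n, 1, 0.7), asg$patient_id)
    got <- simulate_day(asg, grid, shows)
    want <- ref_day(asg, grid, shows)
    expect_equal(setNames(got$patients$wait, got$patients$patient_id)[names(want$waits)],
                 want$waits)
    expect_equal(got$idle, want$idle)
    expect_equal(got$overtime, want$overtime)
  }
})

test_that("waits are nonnegative and monotone in show indicators", {
  # flipping any no-show to a show never decreases another shown patient's
  # wait, the overtime, or total busy time
  set.seed(202)
  for (k in 1:40) {
    n <- sample(3:8, 1)
    m <- sample(2:5, 1)
    if (n > 2 * m) next
    asg <- random_assignment(n, m)
    grid <- slot_grid(m, 30)
    shows <- setNames(rbinom(n, 1, 0.5), asg$patient_id)
    base <- simulate_day(asg, grid, shows)
    expect_true(all(base$patients$wait >= 0))
    off <- names(shows)[shows == 0]
    if (length(off) == 0) next
    flip <- sample(off, 1)
    shows2 <- shows
    shows2[flip] <- 1L
    more <- simulate_day(asg, grid, shows2)
    w1 <- setNames(base$patients$wait, base$patients$patient_id)
    w2 <- setNames(more$patients$wait, more$patients$patient_id)
    shown_before <- names(shows)[shows == 1]
    expect_true(all(w2[shown_before] >= w1[shown_before]))
    expect_gte(more$overtime, base$overtime)
    busy <- function(o) sum(o$patients$shown) * grid$slot_duration
    expect_gte(busy(more), busy(base))
  }
})

test_that("the idle-time conservation identity holds on every simulated day", {
  set.seed(303)
  for (k in 1:30) {
    n <- sample(2:8, 1)
    m <- sample(2:5, 1)
    if (n > 2 * m) next
    asg <- random_assignment(n, m)
    grid <- slot_grid(m, 30)
    shows <- setNames(rbinom(n, 1, 0.6), asg$patient_id)
    out <- simulate_day(asg, grid, shows)
    day <- ref_day(asg, grid, shows)
    horizon <- max(grid$session_length, day$last_completion)
    expect_equal(horizon,
                 grid$slot_duration * sum(out$patients$shown) + out$idle)
  }
})

test_that("invalid assignments are rejected with informative errors", {
  g <- slot_grid(2, 30)
  roster <- tibble::tibble(patient_id = c("x", "y", "z"))
  expect_error(
    validate_assignment(assignment(c("x", "y", "w"), c(1, 1, 2)), roster, g),
    class = "fairbook_roster_mismatch"
  )
  expect_error(
    validate_assignment(assignment(c("x", "y"), c(1, 2)), roster, g),
    class = "fairbook_roster_mismatch"
  )
  expect_error(
    validate_assignment(assignment(c("x", "y", "z"), c(1, 1, 1)), roster, g),
    class = "fairbook_invalid_assignment"
  )
})

test_that("within-slot priority decides service order, not group labels", {
  g <- slot_grid(2, 30)
  asg <- assignment(c("u", "v"), c(1, 1), priority = c(2, 1))
  out <- simulate_day(asg, g, c(u = 1, v = 1))
  waits <- setNames(out$patients$wait, out$patients$patient_id)
  expect_equal(waits[["v"]], 0)
  expect_equal(waits[["u"]], 30)
})

test_that("slot desirability follows the overbooked / follows-overbooked rule", {
  ex <- worked_example()
  cls <- classify_slots(ex$assignment, ex$grid)
  expect_equal(cls$desirable, c(TRUE, FALSE, FALSE, TRUE))

  g <- slot_grid(3, 30)
  one_per <- assignment(paste0("p", 1:3), 1:3)
  expect_true(all(classify_slots(one_per, g)$desirable))

  g4 <- slot_grid(4, 30, capacity = 2)
  adjacent <- assignment(paste0("p", 1:5), c(1, 1, 2, 2, 4))
  expect_equal(classify_slots(adjacent, g4)$desirable,
               c(FALSE, FALSE, FALSE, TRUE))
})
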