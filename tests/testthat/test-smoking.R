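# The smoking Markov chain: initiation derivation, transition step, former
# bin bookkeeping, prevalence aggregation, and the chain's invariants.

test_that("initiation is the prevalence rise over one cohort-year", {
  # prev(16) = 0.10 now, prev(15) = 0.08 last year, 90% never smokers
  init <- derive_initiation_rates(prev_now = c(0.08, 0.10),
                                  prev_last = c(0.08, 0.10))
  expect_equal(init[2], 0.02 / 0.90, tolerance = 1e-12)
})

test_that("flat and declining prevalence curves give zero initiation", {
  flat <- rep(0.25, 10)
  expect_equal(derive_initiation_rates(flat, flat)[-1], rep(0, 9))
  # declining: prev_now(20) = 0.15 < prev_last(19) = 0.18 -> clamped to 0
  now <- c(0.18, 0.15)
  last <- c(0.18, 0.15)
  expect_equal(derive_initiation_rates(now, last)[2], 0)
})

test_that("clamped initiation keeps state counts non-negative", {
  # feed the (clamped) derived rates through the step: never shrinks but
  # never goes negative, whatever the curve shape
  set.seed(11)
  for (rep in 1:10) {
    curve <- runif(26, 0, 0.6)
    init <- derive_initiation_rates(curve, curve)
    ages <- 0:25
    never <- ag_grid(rep(100 * (1 - curve), 2), ages = ages)
    current <- ag_grid(rep(100 * curve, 2), ages = ages)
    st <- smoking_state(never, current)
    rates <- transition_rates(ag_grid(rep(init, 2), ages = ages),
                              ag_grid(0, ages = ages), 0, ages = ages)
    nxt <- step_smoking_states(st, rates)
    expect_true(min(nxt$never) >= 0)
    expect_equal(state_population(nxt), state_population(st))
  }
})

test_that("cessation moves smokers to former bin 1 before mortality", {
  st <- adult_cohort_state(n_current = 1000)
  nxt <- step_smoking_states(st, adult_rates(cessation = 0.05))
  expect_equal(sum(nxt$current), 950)
  expect_equal(sum(nxt$former[, , 1]), 50)
  expect_equal(sum(nxt$former[, , 2:16]), 0)
})

test_that("zero rates leave the state unchanged", {
  st <- adult_cohort_state(n_current = 500, n_never = 300, former1 = 100)
  nxt <- step_smoking_states(st, adult_rates())
  expect_equal(nxt$never, st$never)
  expect_equal(nxt$current, st$current)
  # former smokers still advance one duration bin
  expect_equal(sum(nxt$former[, , 2]), 100)
})

test_that("relapse splits a bin between returning and advancing (ledger)", {
  # 100 in bin 1, relapse 0.3/0.1 in bins 1/2:
  # step 1: 30 return, 70 advance to bin 2
  # step 2: 7 of the 70 return, 63 advance to bin 3
  st <- adult_cohort_state(n_current = 0, former1 = 100)
  rates <- adult_rates(relapse = c(0.3, 0.1, rep(0, 14)))
  s1 <- step_smoking_states(st, rates)
  expect_equal(sum(s1$current), 30)
  expect_equal(sum(s1$former[, , 2]), 70)
  s2 <- step_smoking_states(s1, rates)
  expect_equal(sum(s2$current), 37)
  expect_equal(sum(s2$former[, , 3]), 63)
})

test_that("the 16+ duration bin is absorbing", {
  ages <- 40:59
  former <- array(0, c(20, 2, 16))
  former[1, , 15] <- 50
  former[1, , 16] <- 25
  st <- smoking_state(ag_grid(0, ages = ages), ag_grid(0, ages = ages), former)
  nxt <- step_smoking_states(st, adult_rates())
  expect_equal(sum(nxt$former[, , 16]), 150)
})

test_that("state shares sum to one after every step", {
  b <- brazil_bundle()
  st <- b$state
  for (i in 1:5) {
    st <- step_smoking_states(st, b$rates)
    rel <- abs(state_population(st) - state_population(b$state)) /
      pmax(1e-12, state_population(b$state))
    expect_lt(max(rel), 1e-9)
  }
})

test_that("the chain is first-order: agreeing states agree thereafter", {
  b <- brazil_bundle()
  # two different histories arriving at the same state
  s1 <- step_smoking_states(b$state, b$rates)
  s2 <- smoking_state(s1$never, s1$current, s1$former)
  a1 <- step_smoking_states(s1, b$rates)
  a2 <- step_smoking_states(s2, b$rates)
  expect_identical(a1$current, a2$current)
  expect_identical(a1$former, a2$former)
})

test_that("with no initiation and no relapse a cohort's prevalence decays
           geometrically", {
  st <- adult_cohort_state(n_current = 1000, n_never = 1000)
  rates <- adult_rates(cessation = 0.05)
  cur <- numeric(10)
  for (i in 1:10) {
    st <- step_smoking_states(st, rates)
    cur[i] <- sum(st$current)
  }
  expect_equal(cur, 1000 * 0.95^(1:10), tolerance = 1e-12)
})

test_that("prevalence aggregates counts, not cell averages", {
  ages <- 40:59
  never <- ag_grid(0, ages = ages)
  current <- ag_grid(0, ages = ages)
  never["40", "male"] <- 80; current["40", "male"] <- 20   # 0.20
  never["41", "male"] <- 70; current["41", "male"] <- 30   # 0.30 same size
  st <- smoking_state(never, current)
  expect_equal(compute_prevalence(st, 40, 40, "male"), 0.20)
  expect_equal(compute_prevalence(st, 40, 41, "male"), 0.25)
  expect_error(compute_prevalence(st, 40, 41, "female"), "empty selection")
  expect_error(compute_prevalence(st, 200, 300), "empty age selection")
})

test_that("smoking state survives CSV and JSON round trips", {
  b <- brazil_bundle()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_smoking_state_csv(b$state, csv)
  back <- read_smoking_state_csv(csv)
  expect_equal(back$never, b$state$never)
  expect_equal(back$current, b$state$current)
  expect_equal(unname(back$former), unname(b$state$former))
  js <- state_to_json(b$state)
  back2 <- state_from_json(js)
  expect_equal(back2$current, b$state$current)
  expect_equal(unname(back2$former), unname(b$state$former))
})
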