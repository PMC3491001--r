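# Policy engine: price compounding, multiplicative combination, schedule ->
# effect conversion (enforcement, synergy, bounds), and effect application.

test_that("a 10% price rise reproduces the per-band effect sizes exactly", {
  expect_equal(price_effect(1.1, 16), 0.06)
  expect_equal(price_effect(1.1, 20), 0.04)
  expect_equal(price_effect(1.1, 30), 0.02)
  expect_equal(price_effect(1.1, 40), 0.01)
  expect_equal(price_effect(1.0, c(16, 40)), c(0, 0))
})

test_that("price compounding matches the constant-elasticity closed form", {
  # independently evaluated at 40-digit precision:
  # 1 - 2.3^(ln 0.99 / ln 1.1) = 0.0840826938943989...
  expect_equal(price_effect(2.3, 40), 0.0840826938943989, tolerance = 1e-12)
  # price drops raise prevalence (negative reduction)
  expect_lt(price_effect(0.9, 40), 0)
  expect_error(price_effect(-1, 40), "positive")
})

test_that("effects combine multiplicatively, bounded below one", {
  expect_equal(combined_effect(0.10), 0.10)
  expect_equal(combined_effect(c(0.10, 0.05)), 0.145)
  expect_equal(combined_effect(numeric(0)), 0)
  expect_error(combined_effect(c(0.5, 1)), "< 1")
})

test_that("combination is commutative, associative, and within bounds", {
  set.seed(3)
  for (rep in 1:20) {
    e <- runif(5, 0, 0.9)
    base <- combined_effect(e)
    expect_equal(combined_effect(sample(e)), base, tolerance = 1e-12)
    # associative under composition: combining a combination with the rest
    expect_equal(combined_effect(c(combined_effect(e[1:2]), e[3:5])), base,
                 tolerance = 1e-12)
    expect_true(base >= 0 && base < 1)
  }
})

make_row <- function(...) {
  row <- data.frame(
    year = 2000, price_index = 1,
    sf_worksite = 0, sf_restaurant = 0, sf_bar = 0, sf_other = 0,
    sf_enforcement = 1, media = "none", marketing = "none",
    marketing_enforcement = 1, warnings = "none",
    cessation_treatment = 0, youth_access = "none",
    stringsAsFactors = FALSE)
  modifyList(row, list(...))
}

two_year_schedule <- function(...) {
  base <- make_row(year = 1999)
  policy_schedule(rbind(base, make_row(...)), base_year = 1999)
}

test_that("levels at base-year values produce zero effects at all ages", {
  sc <- two_year_schedule()
  eff <- schedule_to_effects(sc, 2000)
  expect_equal(eff$prevalence, rep(0, 101))
  expect_equal(eff$initiation, rep(0, 101))
  expect_equal(eff$cessation, rep(0, 101))
})

test_that("media effects double only when other policies are active", {
  alone <- schedule_to_effects(two_year_schedule(media = "high"), 2000)
  expect_equal(alone$prevalence[40], 0.0325)
  with_tax <- schedule_to_effects(
    two_year_schedule(media = "high", price_index = 1.5), 2000)
  # remove the price part through the product rule: media contributed double
  price_part <- schedule_to_effects(
    two_year_schedule(price_index = 1.5), 2000)
  media_part <- 1 - (1 - with_tax$prevalence[40]) /
    (1 - price_part$prevalence[40])
  expect_equal(media_part, 0.065, tolerance = 1e-12)
})

test_that("strong warnings act on all three channels as published", {
  eff <- schedule_to_effects(two_year_schedule(warnings = "strong"), 2000)
  expect_equal(eff$prevalence[40], 0.04)
  expect_equal(eff$initiation[20], 0.04)
  expect_equal(eff$cessation[40], 0.10)
})

test_that("smoke-free components are additive and enforcement-scaled", {
  full <- two_year_schedule(sf_worksite = 1, sf_restaurant = 1, sf_bar = 1,
                            sf_other = 1, sf_enforcement = 1)
  eff <- schedule_to_effects(full, 2000)
  expect_equal(eff$prevalence[40], 0.09 + 0.03 + 0.015 + 0.01)
  none <- two_year_schedule(sf_worksite = 1, sf_restaurant = 1, sf_bar = 1,
                            sf_other = 1, sf_enforcement = 0)
  expect_equal(schedule_to_effects(none, 2000)$prevalence[40],
               0.145 / 2)  # weakened by half with no enforcement
})

test_that("incremental effects discount the part already in place", {
  # strengthening a weak marketing ban to comprehensive is worth less than
  # introducing comprehensive from nothing
  base_weak <- policy_schedule(
    rbind(make_row(year = 1999, marketing = "weak"),
          make_row(marketing = "comprehensive")), base_year = 1999)
  inc <- schedule_to_effects(base_weak, 2000)$prevalence[40]
  full <- schedule_to_effects(
    two_year_schedule(marketing = "comprehensive"), 2000)$prevalence[40]
  expect_lt(inc, full)
  expect_equal(inc, 1 - (1 - 0.10) / (1 - 0.02), tolerance = 1e-12)
  # no change contributes exactly zero
  same <- policy_schedule(
    rbind(make_row(year = 1999, marketing = "weak"),
          make_row(marketing = "weak")), base_year = 1999)
  expect_equal(schedule_to_effects(same, 2000)$prevalence, rep(0, 101))
})

test_that("youth access touches only under-18 prevalence and initiation", {
  eff <- schedule_to_effects(two_year_schedule(youth_access = "strong"), 2000)
  expect_equal(eff$prevalence[16], 0.30)   # age 15
  expect_equal(eff$prevalence[17], 0.20)   # age 16
  expect_equal(eff$prevalence[19], 0)      # age 18
  expect_equal(eff$cessation, rep(0, 101))
})

test_that("bound variants scale each domain's effect as specified", {
  sc <- two_year_schedule(warnings = "strong", youth_access = "strong")
  lo <- schedule_to_effects(sc, 2000, bound = "lower")
  up <- schedule_to_effects(sc, 2000, bound = "upper")
  expect_equal(lo$prevalence[40], 0.02)        # warnings x0.5
  expect_equal(up$prevalence[40], 0.06)        # warnings x1.5
  expect_equal(lo$prevalence[16], 0.02)        # youth lower bound: no effect
  expect_equal(up$prevalence[16],
               combined_effect(c(0.45, 0.06)), tolerance = 1e-12)
})

test_that("prevalence effects move smokers into former bin 1", {
  st <- adult_cohort_state(n_current = 1000)
  rates <- adult_rates(cessation = 0.05)
  eff <- smokesim:::zero_effects(ages = 40:59)
  eff$prevalence[] <- 0.10
  adj <- apply_effects(st, rates, eff)
  expect_equal(sum(adj$state$current), 900)
  expect_equal(sum(adj$state$former[, , 1]), 100)
  expect_equal(state_population(adj$state), state_population(st))
})

test_that("sustained effects rescale the flows, not the stock", {
  st <- adult_cohort_state(n_current = 1000)
  rates <- adult_rates(cessation = 0.05)
  eff <- smokesim:::zero_effects(ages = 40:59)
  eff$cessation[] <- 0.55
  adj <- apply_effects(st, rates, eff)
  expect_equal(unname(adj$rates$cessation[1, 1]), 0.05 * 1.55)
  expect_equal(adj$state$current, st$current)
  # an unchanged effect set applies no further prevalence reduction
  adj2 <- apply_effects(st, rates, eff, prev_effects = eff)
  expect_equal(adj2$state$current, st$current)
})

test_that("zero effects are the identity", {
  st <- adult_cohort_state(n_current = 1000, former1 = 50)
  rates <- adult_rates(cessation = 0.05, relapse = 0.1)
  adj <- apply_effects(st, rates, smokesim:::zero_effects(ages = 40:59))
  expect_equal(adj$state$current, st$current)
  expect_equal(unname(adj$rates$cessation), unname(rates$cessation))
})

test_that("unknown level labels are configuration errors", {
  sc <- two_year_schedule()
  sc$media[2] <- "shout"
  expect_error(policy_schedule(as.data.frame(sc), base_year = 1999),
               "unknown media")
})
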