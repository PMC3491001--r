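# Scenario runner and comparison statistics.

test_that("a frozen schedule equals a run with the policy engine off", {
  b <- brazil_bundle()
  frozen <- run_scenario(b, freeze_schedule(b$schedule, 2000), 2000,
                         label = "cf")
  off <- run_scenario(b, horizon = 2000, label = "cf", policies = FALSE)
  expect_equal(frozen$prevalence, off$prevalence)
  expect_equal(frozen$sads, off$sads)
})

test_that("a horizon at the base year returns the baseline unchanged", {
  b <- brazil_bundle()
  r <- run_scenario(b, horizon = 1989, label = "base")
  expect_equal(prevalence_series(r, "18+", "male")[["1989"]], 0.433)
  expect_equal(prevalence_series(r, "18+", "female")[["1989"]], 0.270)
  expect_error(run_scenario(b, horizon = 1980), "precedes")
})

test_that("identical inputs give bitwise-identical scenario outputs", {
  b <- brazil_bundle()
  r1 <- run_scenario(b, horizon = 2000, label = "a")
  r2 <- run_scenario(b, horizon = 2000, label = "a")
  expect_identical(r1$prevalence$value, r2$prevalence$value)
  expect_identical(r1$sads$total, r2$sads$total)
})

test_that("policies keep prevalence below the counterfactual every year", {
  b <- brazil_bundle()
  cf <- run_scenario(b, freeze_schedule(b$schedule), 2010, policies = FALSE)
  pol <- run_scenario(b, horizon = 2010)
  p_cf <- prevalence_series(cf)
  p_pol <- prevalence_series(pol)
  yrs <- as.character(1990:2010)   # first policy change is in 1990
  expect_true(all(p_pol[yrs] < p_cf[yrs]))
})

test_that("raising a policy level never raises later prevalence", {
  b <- brazil_bundle()
  sc <- as.data.frame(b$schedule)
  weaker <- sc
  weaker$warnings[weaker$year >= 2001] <- "weak"  # undo the 2001 upgrade
  r_strong <- run_scenario(b, b$schedule, 2010)
  r_weak <- run_scenario(b, policy_schedule(weaker, base_year = 1989), 2010)
  expect_true(all(prevalence_series(r_strong) <=
                    prevalence_series(r_weak) + 1e-12))
})

test_that("deaths averted is the counterfactual-minus-policy difference", {
  b <- brazil_bundle()
  cf <- run_scenario(b, freeze_schedule(b$schedule), 2000, policies = FALSE,
                     label = "cf")
  pol <- run_scenario(b, horizon = 2000, label = "pol")
  expect_equal(deaths_averted(pol, cf, 2000),
               sad_series(cf)[["2000"]] - sad_series(pol)[["2000"]])
  expect_equal(deaths_averted(pol, pol), 0)
  short <- run_scenario(b, horizon = 1999, label = "short")
  expect_error(deaths_averted(short, cf), "different horizons")
})

test_that("relative reduction is the percentage drop from the reference", {
  expect_equal(relative_reduction(0.168, 0.310), 45.80645, tolerance = 1e-5)
  expect_equal(relative_reduction(0.2, 0.2), 0)
  expect_error(relative_reduction(0.1, 0), "positive")
})

test_that("contribution shares are proportional and sum to 100", {
  expect_equal(decompose_contributions(c(A = 10, B = 10)),
               c(A = 50, B = 50))
  expect_equal(unname(decompose_contributions(c(A = 7))), 100)
  set.seed(9)
  for (rep in 1:10) {
    r <- runif(7)
    expect_equal(sum(decompose_contributions(r)), 100, tolerance = 1e-9)
  }
  expect_error(decompose_contributions(c(0, 0)), "positive")
  expect_error(decompose_contributions(c(-1, 2)), "non-negative")
})

test_that("the FCTC schedule jumps the price 1.6x and maxes every domain", {
  b <- brazil_bundle()
  f <- build_fctc_schedule(b$schedule, start_year = 2011, horizon = 2020)
  d <- as.data.frame(f)
  p2010 <- d$price_index[d$year == 2010]
  expect_equal(d$price_index[d$year == 2011], p2010 * 1.6)
  expect_equal(d$price_index[d$year == 2020], p2010 * 1.6)
  expect_equal(d$media[d$year == 2015], "high")
  expect_equal(d$cessation_treatment[d$year == 2015], 1)
  # status quo passthrough: before the start year nothing changes
  expect_equal(d[d$year <= 2010, ], as.data.frame(b$schedule),
               ignore_attr = TRUE)
})

test_that("all policies together beat the best single policy", {
  b <- brazil_bundle()
  res <- run_standard_scenarios(b, horizon = 2005)
  cf <- res$counterfactual
  averted <- sapply(setdiff(names(res), "counterfactual"),
                    function(nm) deaths_averted(res[[nm]], cf, 1989:2005))
  expect_gte(averted[["all_policies.central"]],
             max(averted[names(averted) != "all_policies.central"]))
  # and the combined central prevalence effect beats any single domain's
  singles <- setdiff(names(res), c("counterfactual", "all_policies.central"))
  p_all <- prevalence_series(res$all_policies.central)[["2005"]]
  for (nm in singles)
    expect_lte(p_all, prevalence_series(res[[nm]])[["2005"]] + 1e-12)
})

test_that("effect-size bounds nest the central run, every year", {
  b <- brazil_bundle()
  lo <- run_scenario(b, horizon = 2010, bound = "lower")
  ce <- run_scenario(b, horizon = 2010, bound = "central")
  up <- run_scenario(b, horizon = 2010, bound = "upper")
  expect_true(all(prevalence_series(up) <= prevalence_series(ce) + 1e-12))
  expect_true(all(prevalence_series(ce) <= prevalence_series(lo) + 1e-12))
  cf <- run_scenario(b, freeze_schedule(b$schedule), 2010, policies = FALSE)
  expect_lte(deaths_averted(lo, cf), deaths_averted(ce, cf))
  expect_lte(deaths_averted(ce, cf), deaths_averted(up, cf))
})
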