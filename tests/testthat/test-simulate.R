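test_that("simulated cohorts conserve totals, respect the seed, honour the truth", {
  scn <- small_scenario()
  s1 <- simulate_crosstab(scn, seed = 21)
  s2 <- simulate_crosstab(scn, seed = 21)
  s3 <- simulate_crosstab(scn, seed = 22)
  expect_identical(sum(s1$tab$births), 50000L)
  expect_identical(s1$tab$births, s2$tab$births)
  expect_identical(s1$tab$cases, s2$tab$cases)
  expect_false(identical(s1$tab$cases, s3$tab$cases))
  # truth curves are centred for comparability with sum-to-zero estimates
  expect_lt(abs(sum(s1$truth$maternal)), 1e-10)
  expect_lt(abs(sum(s1$truth$paternal)), 1e-10)
})

test_that("empirical prevalence is within 3 binomial SDs of the target", {
  scn <- sim_scenario(total_births = 1e7, target_prevalence = 5.4e-4,
                      maternal_curve = age_curve("flat"),
                      paternal_curve = age_curve("flat"))
  sim <- simulate_crosstab(scn, seed = 31)
  p <- 5.4e-4
  expect_lt(abs(sum(sim$tab$cases) - 1e7 * p),
            3 * sqrt(1e7 * p * (1 - p)))
  # with flat curves alpha is exactly the logit of the target
  expect_equal(plogis(scn$alpha), p, tolerance = 1e-10)
})

test_that("degenerate scenarios: zero prevalence and invalid probabilities", {
  scn <- small_scenario()
  scn$alpha <- -Inf
  s <- simulate_crosstab(scn, seed = 2)
  expect_identical(sum(s$tab$cases), 0L)

  scn2 <- small_scenario()
  scn2$alpha <- 60   # saturates to probability 1 in floating point
  expect_error(simulate_crosstab(scn2, seed = 2),
               "probability outside \\(0, 1\\).*maternal")

  expect_error(sim_scenario(rho = 1), "rho")
  expect_error(sim_scenario(total_births = 0), "positive")
})

test_that("correlated ages induce a spurious marginal paternal gradient in the raw counts", {
  # maternal ramp, flat paternal truth, strong age correlation: the crude
  # *marginal* paternal rates must rise with age even though the truth is flat
  scn <- sim_scenario(total_births = 2e6, target_prevalence = 2e-3,
                      maternal_curve = age_curve("ramp", height = log(10),
                                                 onset = 30,
                                                 saturation = 45),
                      paternal_curve = age_curve("flat"), rho = 0.8)
  sim <- simulate_crosstab(scn, seed = 41)
  marg <- marginalize(sim$tab, "paternal")
  young <- marg$ages >= 20 & marg$ages <= 30
  old <- marg$ages >= 40 & marg$ages <= 50
  rate_young <- sum(marg$cases[young]) / sum(marg$births[young])
  rate_old <- sum(marg$cases[old]) / sum(marg$births[old])
  expect_gt(rate_old / rate_young, 1.5)
})

test_that("recovery_report scores a point-mass fit at the truth as exact", {
  set.seed(7)
  scn <- small_scenario()
  sim <- simulate_crosstab(scn, seed = 3)
  truth <- sim$truth
  E <- matrix(rep(truth$maternal, each = 4), 4, byrow = FALSE)
  fit <- fake_car_fit(E, ages = scn$maternal_ages)
  fit$spec$maternal_ages <- scn$maternal_ages
  rec <- recovery_report(fit, truth, "maternal")
  expect_equal(rec$rmse, 0)
  expect_equal(rec$mean_bias, 0)
  expect_equal(rec$coverage, 1)
  bad <- fake_car_fit(E[, 1:10], ages = scn$maternal_ages[1:10])
  expect_error(recovery_report(bad, truth, "maternal"), "different age grids")
})

test_that("curve families evaluate as specified", {
  ages <- 15:49
  expect_equal(curve_eval(age_curve("flat"), ages), rep(0, 35))
  r <- curve_eval(age_curve("ramp", height = 2, onset = 30,
                            saturation = 45), ages)
  expect_equal(r[ages <= 30], rep(0, sum(ages <= 30)))
  expect_equal(r[ages >= 45], rep(2, sum(ages >= 45)))
  expect_equal(r[ages == 36], 2 * 6 / 15)
  lin <- curve_eval(age_curve("linear", slope = 0.1), ages)
  expect_equal(diff(lin), rep(0.1, 34))
  expect_error(age_curve("ramp", onset = 40, saturation = 30), "saturation")
})
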