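test_that("constrained Gaussian draws match closed-form moments on a CAR toy", {
  # 3-level CAR with fixed precision plus Gaussian pseudo-likelihood:
  # target N(Q^-1 b, Q^-1) conditioned on sum(theta) = 0
  tau <- 2.5
  Q <- tau * rw1_structure_matrix(3) + diag(c(1.2, 0.7, 2.0))
  b <- c(0.5, -1, 2)
  A <- matrix(1, 1, 3)
  # oracle by direct linear algebra
  kc <- mean(diag(Q)) + 1
  Qp <- Q + kc * crossprod(A)
  Sig <- solve(Qp)
  mu <- Sig %*% b
  V <- Sig %*% t(A) %*% solve(A %*% Sig %*% t(A)) %*% A
  mu_c <- drop(mu - V %*% mu)
  Sig_c <- Sig - V %*% Sig
  set.seed(5)
  draws <- t(replicate(20000,
    getFromNamespace("draw_constrained_gaussian", "parage")(Q, b, A)))
  expect_lt(max(abs(rowSums(draws))), 1e-9)
  expect_lt(max(abs(colMeans(draws) - mu_c)), 0.02)
  expect_lt(max(abs(cov(draws) - Sig_c)), 0.02)
})

test_that("sampler matches the quadrature posterior on a single binomial cell", {
  # flat prior on the logit; density of mu is then proportional to
  # mu^(Y-1) (1-mu)^(n-Y-1); build the CDF by numerical quadrature
  n <- 1500; Y <- 30
  tab <- age_margin(20, n, Y, "maternal", "oracle")
  fit <- fit_parage(tab, model_preset("intercept_only"), burn_in = 500,
                    samples = 2000, chains = 2, seed = 4)
  mu <- plogis(do.call(rbind, fit$draws)[, "(Intercept)"])
  grid <- seq(1e-6, 0.2, length.out = 20001)
  dens <- exp((Y - 1) * log(grid) + (n - Y - 1) * log1p(-grid))
  cdf <- cumsum(dens); cdf <- cdf / cdf[length(cdf)]
  u <- sort(approx(grid, cdf, xout = mu, rule = 2)$y)
  ks <- max(abs(u - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 0.05)
})

test_that("fits are bit-identical under an identical seed and differ across seeds", {
  sim <- simulate_crosstab(small_scenario(), seed = 2)
  f1 <- small_fit(sim, burn_in = 100, samples = 150, seed = 42)
  f2 <- small_fit(sim, burn_in = 100, samples = 150, seed = 42)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  f3 <- small_fit(sim, burn_in = 100, samples = 150, seed = 43)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("CAR effect vectors sum to zero at every retained draw", {
  sim <- simulate_crosstab(small_scenario(), seed = 3)
  fit <- small_fit(sim, burn_in = 100, samples = 200, seed = 8)
  for (ch in seq_along(fit$draws)) {
    d <- fit$draws[[ch]]
    sm <- rowSums(d[, paste0("maternal_", 20:34)])
    sp <- rowSums(d[, paste0("paternal_", 22:40)])
    expect_lt(max(abs(c(sm, sp))), 1e-10)
  }
})

test_that("convergence diagnostics separate mixed from unmixed chains", {
  sim <- simulate_crosstab(small_scenario(), seed = 2)
  fit <- small_fit(sim, burn_in = 100, samples = 400, seed = 1)
  # hand-built chains: iid same distribution vs shifted
  fake <- fit
  set.seed(1)
  nm <- colnames(fit$draws[[1]])
  mk <- function(shift) matrix(rnorm(400 * length(nm)) + shift, 400,
                               dimnames = list(NULL, nm))
  fake$draws <- list(mk(0), mk(0))
  fake$deviance <- list(rnorm(400), rnorm(400))
  cv <- check_convergence(fake)
  expect_true(cv$pass)
  expect_lt(cv$max_rhat, 1.05)
  fake$draws <- list(mk(0), mk(5))
  cv2 <- check_convergence(fake)
  expect_false(cv2$pass)
  expect_gt(cv2$max_rhat, 2)
  fake$config$chains <- 1
  expect_error(check_convergence(fake), "at least 2 chains")
})

test_that("a flat-truth cohort yields OR curves consistent with no age effect", {
  scn <- sim_scenario(total_births = 2e5, target_prevalence = 5e-3,
                      maternal_ages = 20:34, paternal_ages = 22:40,
                      maternal_mean = 27, maternal_sd = 4,
                      paternal_mean = 30, paternal_sd = 5, rho = 0.7,
                      maternal_curve = age_curve("flat"),
                      paternal_curve = age_curve("flat"))
  sim <- simulate_crosstab(scn, seed = 6)
  fit <- small_fit(sim, burn_in = 400, samples = 800, seed = 6)
  for (parent in c("maternal", "paternal")) {
    ort <- odds_ratios(fit, parent)
    expect_gt(mean(ort$lower <= 1 & ort$upper >= 1), 0.9)
    expect_lt(max(abs(log(ort$median))), log(2.5))
  }
})

test_that("PG and random-walk samplers agree on the same posterior", {
  scn <- small_scenario(total_births = 2e4, prevalence = 2e-2)
  sim <- simulate_crosstab(scn, seed = 4)
  fpg <- small_fit(sim, burn_in = 400, samples = 1200, seed = 5,
                   sampler = "pg")
  frw <- small_fit(sim, burn_in = 2000, samples = 4000, seed = 5,
                   sampler = "rwm")
  for (parent in c("maternal", "paternal")) {
    e1 <- apply(getFromNamespace("age_effect_draws", "parage")(fpg, parent),
                2, median)
    e2 <- apply(getFromNamespace("age_effect_draws", "parage")(frw, parent),
                2, median)
    expect_lt(max(abs(e1 - e2)), 0.25)
    expect_gt(cor(e1, e2), 0.95)
  }
  expect_lt(abs(median(combined_draws_t(fpg)[, 1]) -
                median(combined_draws_t(frw)[, 1])), 0.1)
})

test_that("single-parent specs marginalise a cross-tab to the identical fit", {
  sim <- simulate_crosstab(small_scenario(), seed = 9)
  f_tab <- small_fit(sim, model = "model1", burn_in = 100, samples = 200,
                     seed = 3)
  marg <- marginalize(sim$tab, "maternal")
  f_marg <- suppressWarnings(fit_parage(marg, "model1", burn_in = 100,
                                        samples = 200, seed = 3))
  expect_identical(f_tab$draws, f_marg$draws)
  expect_s3_class(f_tab$tab, "age_margin")
})

test_that("degenerate inputs are flagged", {
  tab <- age_crosstab(20:21, 25:26, matrix(50, 2, 2), matrix(0, 2, 2))
  expect_warning(
    fit_parage(tab, "model3", burn_in = 20, samples = 30, chains = 1,
               seed = 1, rhat_threshold = Inf),
    "no cases")
  sim <- simulate_crosstab(small_scenario(), seed = 2)
  expect_error(fit_parage(sim$tab, "model3", burn_in = -1, samples = 10),
               "burn_in")
  marg <- marginalize(sim$tab, "maternal")
  expect_error(fit_parage(marg, "model2", seed = 1),
               "maternal margin cannot fit")
})
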