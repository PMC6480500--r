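# independent brute-force binomial pmf via log-factorials
brute_loglik <- function(n, Y, mu) {
  lfact <- function(x) if (x == 0) 0 else sum(log(seq_len(x)))
  s <- 0
  for (i in seq_along(n)) {
    if (n[i] == 0) next
    s <- s + lfact(n[i]) - lfact(Y[i]) - lfact(n[i] - Y[i]) +
      Y[i] * log(mu[i]) + (n[i] - Y[i]) * log(1 - mu[i])
  }
  s
}

test_that("binomial_loglik matches brute-force pmf summation and its edge cases", {
  tab <- age_margin(20, 10, 5)
  expect_equal(binomial_loglik(tab, 0.5), lchoose(10, 5) - 10 * log(2))

  empty <- age_crosstab(20:21, 25:26, matrix(0, 2, 2), matrix(0, 2, 2))
  expect_identical(binomial_loglik(empty, matrix(0.3, 2, 2)), 0)

  set.seed(3)
  for (rep in 1:10) {
    n <- matrix(rpois(6, 20), 2, 3)
    Y <- matrix(rbinom(6, as.vector(n), 0.2), 2, 3)
    mu <- matrix(runif(6, 0.05, 0.6), 2, 3)
    tab <- age_crosstab(20:21, 25:27, n, Y)
    expect_equal(binomial_loglik(tab, mu),
                 brute_loglik(as.vector(n), as.vector(Y), as.vector(mu)))
  }

  # cell-wise MLE maximises the likelihood
  n <- matrix(c(10, 20, 0, 40), 2, 2)
  Y <- matrix(c(2, 5, 0, 10), 2, 2)
  tab <- age_crosstab(20:21, 25:26, n, Y)
  mu_hat <- ifelse(n > 0, Y / n, 0.5)
  best <- binomial_loglik(tab, mu_hat)
  for (eps in c(-0.03, 0.03))
    expect_lt(binomial_loglik(tab, pmin(pmax(mu_hat + eps, 0.01), 0.99)),
              best)
  expect_error(binomial_loglik(tab, mu_hat + 1), "\\[0, 1\\]")
})

test_that("RW1 log-density: frozen value, level invariance, quadratic scaling, structure matrix", {
  expect_equal(rw1_logdensity(c(0, 1, -1), 2), log(2) - 5)

  set.seed(11)
  for (rep in 1:10) {
    L <- sample(3:40, 1)
    x <- rnorm(L)
    tau <- runif(1, 0.1, 5)
    shift <- rnorm(1, 0, 10)
    expect_equal(rw1_logdensity(x + shift, tau), rw1_logdensity(x, tau))
    # doubling all first differences drops the density by (3 tau / 2) sum d^2
    S <- sum(diff(x)^2)
    x2 <- x[1] + 2 * cumsum(c(0, diff(x)))
    expect_equal(rw1_logdensity(x2, tau) - rw1_logdensity(x, tau),
                 -(3 * tau / 2) * S)
    # pairwise-difference form equals the structure-matrix quadratic form
    Q <- rw1_structure_matrix(L)
    expect_equal(rw1_logdensity(x, tau),
                 ((L - 1) / 2) * log(tau) -
                   (tau / 2) * drop(t(x) %*% Q %*% x))
  }
  expect_error(rw1_logdensity(c(0, Inf), 1), "non-finite")
})

test_that("the CAR sd hyperprior is flat on the open interval and -Inf outside", {
  expect_identical(sd_hyperprior_logdensity(5), 0)
  expect_identical(sd_hyperprior_logdensity(10.5), -Inf)
  expect_identical(sd_hyperprior_logdensity(0), -Inf)
  expect_identical(sd_hyperprior_logdensity(10), -Inf)
  expect_equal(sd_hyperprior_logdensity(c(0.5, 2, 12)), c(0, 0, -Inf))
})

test_that("linear predictor: identity, additivity, centred polynomial, piecewise bands", {
  # all-zero effects give log-odds 0, i.e. mu = 0.5
  sp <- model_spec("car", "car", maternal_ages = 15:17, paternal_ages = 15:18)
  par0 <- setNames(numeric(8), c("(Intercept)", paste0("maternal_", 15:17),
                                 paste0("paternal_", 15:18)))
  expect_equal(linear_predictor(sp, par0, 16, 17), 0)

  # a maternal contrast of log 2 shifts every paternal column equally
  sp3 <- model_spec("car", "car")
  pars <- setNames(numeric(1 + 35 + 51),
                   c("(Intercept)", paste0("maternal_", 15:49),
                     paste0("paternal_", 15:65)))
  pars["maternal_45"] <- log(2)
  pars[paste0("paternal_", 15:65)] <- rnorm(51)
  for (k in c(15, 40, 65))
    expect_equal(linear_predictor(sp3, pars, 45, k) -
                   linear_predictor(sp3, pars, 15, k), log(2))

  # curvilinear maternal at age 30, covariate centred at 32
  spc <- model_spec("curvilinear", "none")
  pc <- c("(Intercept)" = -7, maternal_lin = 0.1, maternal_quad = 0.01)
  expect_equal(linear_predictor(spc, pc, 30),
               -7 + 0.1 * (30 - 32) + 0.01 * (30 - 32)^2)

  # category5 is piecewise constant within bands
  spb <- model_spec("category5", "none")
  nmb <- spec_layout_t(spb)$names
  pb <- setNames(rnorm(length(nmb)), nmb)
  expect_equal(linear_predictor(spb, pb, 20), linear_predictor(spb, pb, 24))
  expect_equal(linear_predictor(spb, pb, 45), linear_predictor(spb, pb, 49))
  expect_false(isTRUE(all.equal(linear_predictor(spb, pb, 24),
                                linear_predictor(spb, pb, 25))))

  expect_error(linear_predictor(spc, pc, 55), "outside the declared range")
})

test_that("age-band schemes match the published grouping", {
  bm <- age_bands("maternal")
  expect_equal(bm$label, c("15-19", "20-24", "25-29", "30-34", "35-39",
                           "40-44", "45-49"))
  bp <- age_bands("paternal")
  expect_equal(tail(bp$label, 3), c("50-54", "55-59", "60-65"))
  expect_equal(nrow(bp), 10)
})
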