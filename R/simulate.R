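#' Parametric age-risk curve on the log-odds scale
#'
#' Truth curves for synthetic cohorts.  Families:
#' * `"flat"` — 0 at every age;
#' * `"linear"` — `slope * (age - min age)`;
#' * `"ramp"` — piecewise-linear rise from 0 to `height` between `onset`
#'   and `saturation`, flat outside (inflections at the two knots; with the
#'   defaults 30 and 45 this mimics the shape seen for maternal age and
#'   trisomies);
#' * `"quadratic"` — `slope * (age - min) + quad * (age - min)^2`.
#'
#' @param family curve family.
#' @param height,onset,saturation ramp parameters (log-OR units, years).
#' @param slope,quad linear/quadratic coefficients per year.
#' @return object of class `age_curve` (plain list, serialisable).
#' @export
age_curve <- function(family = c("flat", "linear", "ramp", "quadratic"),
                      height = 0, onset = 30, saturation = 45,
                      slope = 0, quad = 0) {
  family <- match.arg(family)
  if (family == "ramp" && saturation <= onset)
    stop("ramp needs saturation > onset")
  structure(list(family = family, height = height, onset = onset,
                 saturation = saturation, slope = slope, quad = quad),
            class = "age_curve")
}

#' Evaluate an age curve
#'
#' @param curve an [age_curve()].
#' @param ages integer ages.
#' @param min_age origin for the linear/quadratic families (default
#'   `min(ages)`).
#' @return numeric log-OR values along `ages`.
#' @export
curve_eval <- function(curve, ages, min_age = min(ages)) {
  stopifnot(inherits(curve, "age_curve"))
  switch(curve$family,
    flat = rep(0, length(ages)),
    linear = curve$slope * (ages - min_age),
    ramp = curve$height *
      pmin(pmax((ages - curve$onset) /
                  (curve$saturation - curve$onset), 0), 1),
    quadratic = curve$slope * (ages - min_age) +
      curve$quad * (ages - min_age)^2)
}

#' Synthetic-cohort scenario
#'
#' Defines the joint distribution of parental ages (a discretised bivariate
#' normal over the age rectangle, correlation `rho`) and the true log-odds
#' surface `alpha + m(maternal age) + p(paternal age)` from which case
#' counts are drawn.  Defaults emulate the structure of a large national
#' natality cohort: maternal ages 15-49 (mean 29, sd 6), paternal ages
#' 15-65 (mean 32, sd 7), strong age correlation (rho = 0.8), about 10.3
#' million births, a rare outcome (about 5.4 cases per 10,000 births), a
#' maternal risk ramp rising on the log scale between ages 30 and 45 and a
#' flat paternal truth.
#'
#' Either give `alpha` directly (log-odds at the curves' zero level) or a
#' `target_prevalence`; in the latter case `alpha` is solved so that the
#' births-weighted mean prevalence equals the target.
#'
#' @param total_births cohort size.
#' @param maternal_ages,paternal_ages age grids.
#' @param maternal_mean,maternal_sd,paternal_mean,paternal_sd,rho parameters
#'   of the age-pair distribution; `rho` strictly inside (-1, 1).
#' @param maternal_curve,paternal_curve [age_curve()] truths.
#' @param alpha true intercept; `-Inf` gives a zero-prevalence cohort.
#' @param target_prevalence overall prevalence used to solve for `alpha`
#'   when `alpha` is `NULL` (default 5.4e-4).
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(total_births = 10293589,
                         maternal_ages = 15:49, paternal_ages = 15:65,
                         maternal_mean = 29, maternal_sd = 6,
                         paternal_mean = 32, paternal_sd = 7, rho = 0.8,
                         maternal_curve = age_curve("ramp",
                                                    height = log(18.9),
                                                    onset = 30,
                                                    saturation = 45),
                         paternal_curve = age_curve("flat"),
                         alpha = NULL, target_prevalence = 5.4e-4) {
  if (!(rho > -1 && rho < 1)) stop("rho must lie strictly inside (-1, 1)")
  if (total_births <= 0) stop("total_births must be positive")
  check_age_vector(maternal_ages, "maternal")
  check_age_vector(paternal_ages, "paternal")
  scn <- structure(list(
    total_births = total_births,
    maternal_ages = as.integer(maternal_ages),
    paternal_ages = as.integer(paternal_ages),
    maternal_mean = maternal_mean, maternal_sd = maternal_sd,
    paternal_mean = paternal_mean, paternal_sd = paternal_sd, rho = rho,
    maternal_curve = maternal_curve, paternal_curve = paternal_curve,
    alpha = alpha, target_prevalence = target_prevalence),
    class = "sim_scenario")
  if (is.null(scn$alpha)) {
    if (is.null(target_prevalence) || target_prevalence <= 0 ||
        target_prevalence >= 1)
      stop("give either alpha or a target_prevalence in (0, 1)")
    scn$alpha <- solve_alpha(scn)
  }
  scn
}

# cell probabilities of the discretised bivariate-normal age-pair law
pair_probs <- function(scn) {
  m <- scn$maternal_ages; p <- scn$paternal_ages
  zm <- (m - scn$maternal_mean) / scn$maternal_sd
  zp <- (p - scn$paternal_mean) / scn$paternal_sd
  r <- scn$rho
  # log bivariate-normal kernel on the integer grid, then normalised
  lq <- outer(zm^2, zp^2, `+`) - 2 * r * outer(zm, zp)
  q <- exp(-lq / (2 * (1 - r^2)))
  q / sum(q)
}

truth_surface <- function(scn) {
  m <- curve_eval(scn$maternal_curve, scn$maternal_ages)
  p <- curve_eval(scn$paternal_curve, scn$paternal_ages)
  list(m = m, p = p)
}

solve_alpha <- function(scn) {
  w <- pair_probs(scn)
  tr <- truth_surface(scn)
  eta <- outer(tr$m, tr$p, `+`)
  f <- function(a) sum(w * plogis(a + eta)) - scn$target_prevalence
  uniroot(f, c(-30, 10), tol = 1e-12)$root
}

#' Simulate a cross-tabulated birth cohort with known truth
#'
#' Draws cell birth counts `n[j,k]` from a multinomial over the discretised
#' age-pair distribution and case counts
#' `Y[j,k] ~ Binomial(n[j,k], plogis(alpha + m(j) + p(k)))`.  Determinstic
#' given `seed`; total births are conserved exactly.  The returned truth
#' record carries the parental log-OR curves centred to sum to zero over
#' each age grid (the identification used by the CAR fits), with the
#' removed levels absorbed into the reported `alpha`.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @param outcome label for the generated table.
#' @return list with elements `tab` (an [age_crosstab()]) and `truth`
#'   (list: `alpha`, centred `maternal` and `paternal` log-OR vectors,
#'   `scenario`).
#' @export
simulate_crosstab <- function(scenario, seed = 1, outcome = "synthetic") {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(as.integer(seed))
  w <- pair_probs(scenario)
  J <- length(scenario$maternal_ages); K <- length(scenario$paternal_ages)
  n <- matrix(rmultinom(1, scenario$total_births, as.vector(w)), J, K)
  tr <- truth_surface(scenario)
  if (identical(scenario$alpha, -Inf)) {
    Y <- matrix(0L, J, K)
    mu <- matrix(0, J, K)
  } else {
    eta <- scenario$alpha + outer(tr$m, tr$p, `+`)
    mu <- plogis(eta)
    if (any(!(mu > 0 & mu < 1))) {
      bad <- which(!(mu > 0 & mu < 1), arr.ind = TRUE)[1, ]
      stop("case probability outside (0, 1) at (maternal ",
           scenario$maternal_ages[bad[1]], ", paternal ",
           scenario$paternal_ages[bad[2]], ")")
    }
    Y <- matrix(rbinom(J * K, as.vector(n), as.vector(mu)), J, K)
  }
  tab <- age_crosstab(scenario$maternal_ages, scenario$paternal_ages,
                      n, Y, outcome)
  mbar <- mean(tr$m); pbar <- mean(tr$p)
  truth <- list(alpha = scenario$alpha + mbar + pbar,
                maternal = tr$m - mbar, paternal = tr$p - pbar,
                scenario = scenario)
  list(tab = tab, truth = truth)
}

#' Score posterior recovery of a known truth
#'
#' Compares the centred parental log-OR effects of one or more fitted
#' models against the simulation truth: per-age bias of the posterior
#' median, RMSE, and empirical coverage of the equal-tailed 95% credible
#' intervals, pooled over replicates.
#'
#' @param fits a `parage_fit` or a list of replicate fits on the same grid.
#' @param truth the `truth` element returned by [simulate_crosstab()].
#' @param parent which parent's curve to score.
#' @return list with per-age data frame `by_age` (columns `age`, `truth`,
#'   `bias`, `rmse`, `coverage`) and scalars `mean_bias`, `rmse`,
#'   `coverage`.
#' @export
recovery_report <- function(fits, truth, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  if (inherits(fits, "parage_fit")) fits <- list(fits)
  tv <- truth[[parent]]
  ages <- if (parent == "maternal") truth$scenario$maternal_ages
          else truth$scenario$paternal_ages
  med <- cov <- matrix(NA_real_, length(fits), length(ages))
  for (i in seq_along(fits)) {
    E <- age_effect_draws(fits[[i]], parent)
    if (!identical(as.integer(colnames(E)), ages))
      stop("fit and truth are on different age grids")
    # centre each draw so fits of any form are comparable with the truth
    E <- E - rowMeans(E)
    qs <- apply(E, 2, quantile, probs = c(0.025, 0.5, 0.975))
    med[i, ] <- qs[2, ]
    cov[i, ] <- tv >= qs[1, ] - 1e-9 & tv <= qs[3, ] + 1e-9
  }
  err <- sweep(med, 2, tv)
  by_age <- data.frame(age = ages, truth = tv, bias = colMeans(err),
                       rmse = sqrt(colMeans(err^2)),
                       coverage = colMeans(cov))
  list(by_age = by_age, mean_bias = mean(err), rmse = sqrt(mean(err^2)),
       coverage = mean(cov))
}
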