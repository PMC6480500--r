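#' Fit a parental-age model by MCMC
#'
#' Draws from the posterior of a binomial-logit model for cross-tabulated
#' birth counts, `Y[j,k] ~ Binomial(n[j,k], mu[j,k])` with
#' `logit(mu[j,k]) = alpha + maternal_j + paternal_k`, where the parental
#' terms follow the chosen [model_spec()] (CAR/linear/curvilinear/5-year
#' bands).  The default sampler is a Pólya-Gamma Gibbs sampler: given PG
#' augmentation variables the full coefficient vector is conditionally
#' Gaussian and is drawn jointly, subject to an exact sum-to-zero constraint
#' on each CAR block (conditioning by kriging); each CAR precision is drawn
#' from its truncated-Gamma full conditional.  An adaptive single-site
#' random-walk Metropolis sampler (`sampler = "rwm"`) targets the same
#' posterior and serves as an internal cross-check.
#'
#' Chains start from "diverse" values: effects at zero and the intercept at
#' the empirical logit of the overall rate plus a chain-dependent offset of
#' +/-2 on the log-odds scale.  Cells with zero births are retained in the
#' table but contribute no likelihood.  Runs are deterministic given `seed`.
#'
#' @param tab an [age_crosstab()] or [age_margin()].  A cross-tabulation
#'   supplied to a single-parent model is marginalised automatically.
#' @param model a `parage_spec` or a preset name (see [model_preset()]).
#' @param burn_in iterations discarded per chain (default 5000).
#' @param samples retained iterations per chain (default 10000).
#' @param chains number of chains (default 2).
#' @param thin thinning interval (default 1).
#' @param seed integer seed; every chain's stream derives from it.
#' @param sampler `"pg"` (Pólya-Gamma Gibbs, default) or `"rwm"`.
#' @param pg_exact_max cell birth-count above which the Pólya-Gamma draws
#'   use a moment-matched Gaussian instead of exact summed draws (default
#'   40; the approximation error decays as 1/sqrt(count)).
#' @param rhat_threshold split-R-hat above which a convergence warning is
#'   raised (default 1.05).
#' @return an object of class `parage_fit` with methods `print`, `summary`,
#'   `coef`, `plot`, `simulate`, `residuals`, plus [dic()],
#'   [check_convergence()], [odds_ratios()].
#' @examples
#' scn <- sim_scenario(total_births = 2e4, target_prevalence = 0.01,
#'                     maternal_ages = 20:29, paternal_ages = 20:34)
#' sim <- simulate_crosstab(scn, seed = 1)
#' fit <- fit_parage(sim$tab, "model3", burn_in = 200, samples = 400,
#'                   seed = 1)
#' fit
#' @export
fit_parage <- function(tab, model = "model3", burn_in = 5000,
                       samples = 10000, chains = 2, thin = 1, seed = 1,
                       sampler = c("pg", "rwm"), rhat_threshold = 1.05,
                       pg_exact_max = 40) {
  sampler <- match.arg(sampler)
  if (is.character(model)) model <- model_preset(model)
  stopifnot(inherits(model, "parage_spec"))
  if (burn_in < 0 || samples < 1 || chains < 1 || thin < 1)
    stop("need burn_in >= 0, samples >= 1, chains >= 1, thin >= 1")
  prep <- prepare_fit(tab, model)
  if (sum(prep$cells$Y) == 0)
    warning("table has no cases: the intercept is only weakly identified")
  set.seed(as.integer(seed))
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  prep$pg_exact_max <- pg_exact_max
  run1 <- if (sampler == "pg") run_chain_pg else run_chain_rwm
  out <- vector("list", chains)
  mu_sum <- 0
  for (ch in seq_len(chains)) {
    res <- run1(prep, burn_in, samples, thin, chain_seeds[ch], ch)
    mu_sum <- mu_sum + res$mu_sum
    out[[ch]] <- res
  }
  fit <- structure(list(
    spec = prep$spec, tab = prep$tab, cells = prep$cells,
    layout = prep$layout,
    config = list(burn_in = burn_in, samples = samples, chains = chains,
                  thin = thin, seed = seed, sampler = sampler,
                  chain_seeds = chain_seeds),
    draws = lapply(out, `[[`, "draws"),
    deviance = lapply(out, `[[`, "deviance"),
    mu_mean = mu_sum / (chains * samples)), class = "parage_fit")
  if (chains >= 2) {
    conv <- check_convergence(fit, threshold = rhat_threshold)
    fit$convergence <- conv
    if (!conv$pass)
      warning("convergence not reached: max split-R-hat = ",
              round(conv$max_rhat, 3), " > ", rhat_threshold)
  }
  fit
}

# Harmonise spec and table; build cell-level design and prior structures.
prepare_fit <- function(tab, spec) {
  if (inherits(tab, "age_crosstab")) {
    validate_crosstab(tab)
    one_parent <- (spec$maternal_form == "none") !=
                  (spec$paternal_form == "none")
    if (one_parent) {
      keep <- if (spec$maternal_form != "none") "maternal" else "paternal"
      tab <- marginalize(tab, keep)
    }
  }
  if (inherits(tab, "age_margin")) {
    if (tab$parent == "maternal") {
      if (spec$paternal_form != "none")
        stop("a maternal margin cannot fit a model with a paternal term")
      spec$maternal_ages <- tab$ages
    } else {
      if (spec$maternal_form != "none")
        stop("a paternal margin cannot fit a model with a maternal term")
      spec$paternal_ages <- tab$ages
    }
  } else {
    spec$maternal_ages <- tab$maternal_ages
    spec$paternal_ages <- tab$paternal_ages
  }
  lay <- spec_layout(spec)
  p <- length(lay$names)
  if (inherits(tab, "age_margin")) {
    keep <- which(tab$births > 0)
    idx <- keep
    n <- tab$births[keep]; Y <- tab$cases[keep]
    term <- if (tab$parent == "maternal") lay$maternal else lay$paternal
    X <- cbind(1, term$X[keep, , drop = FALSE])
    jk <- NULL
  } else {
    J <- length(tab$maternal_ages); K <- length(tab$paternal_ages)
    keep <- which(tab$births > 0)
    j <- ((keep - 1) %% J) + 1
    k <- ((keep - 1) %/% J) + 1
    n <- as.vector(tab$births)[keep]; Y <- as.vector(tab$cases)[keep]
    X <- cbind(1, lay$maternal$X[j, , drop = FALSE],
               lay$paternal$X[k, , drop = FALSE])
    jk <- cbind(j, k)
  }
  colnames(X) <- lay$names
  # prior pieces
  prior_diag <- numeric(p)
  prior_diag[1] <- if (spec$intercept_prior == "normal") 1 / spec$fixed_var else 0
  car_blocks <- list()
  for (side in c("maternal", "paternal")) {
    term <- lay[[side]]
    cols <- if (side == "maternal") lay$m_cols else lay$p_cols
    if (term$form %in% c("linear", "curvilinear", "category5"))
      prior_diag[cols] <- 1 / spec$fixed_var
    if (term$form == "car") {
      L <- length(cols)
      R <- rw1_structure_matrix(L)
      nz <- which(R != 0, arr.ind = TRUE)
      rows <- cols[nz[, 1]]; cc <- cols[nz[, 2]]
      car_blocks[[side]] <- list(cols = cols, L = L,
                                 Qidx = (cc - 1) * p + rows,
                                 Qval = R[nz])
    }
  }
  ncon <- length(car_blocks)
  A <- matrix(0, ncon, p)
  for (i in seq_along(car_blocks)) A[i, car_blocks[[i]]$cols] <- 1
  # fast Q assembly only helps the big all-indicator joint CAR model
  fast <- !is.null(jk) && spec$maternal_form == "car" &&
    spec$paternal_form == "car"
  # per-cell position inside each CAR block (for the exact-likelihood
  # Metropolis boost); scalar columns keep per-column cell lists
  mpos <- ppos <- NULL
  if (inherits(tab, "age_margin")) {
    if (tab$parent == "maternal") mpos <- keep else ppos <- keep
  } else {
    mpos <- jk[, 1]; ppos <- jk[, 2]
  }
  car_cols <- unlist(lapply(car_blocks, `[[`, "cols"))
  scalar_cols <- setdiff(seq_len(p), car_cols)
  touch <- lapply(scalar_cols, function(i) which(X[, i] != 0))
  names(touch) <- scalar_cols
  list(spec = spec, tab = tab, layout = lay,
       cells = list(n = n, Y = Y, X = X, jk = jk, keep = keep,
                    kappa = Y - n / 2, mpos = mpos, ppos = ppos),
       p = p, prior_diag = prior_diag, car_blocks = car_blocks,
       scalar_cols = scalar_cols, touch = touch,
       A = A, tA = t(A), AtA = crossprod(A), fast = fast,
       sd_lo = spec$sd_lower, sd_hi = spec$sd_upper,
       fixed_var = spec$fixed_var)
}

# Exact draw from N(mean, Q^-1) restricted to the subspace {A theta = 0}.
# Q may be singular on the unconstrained space as long as Q + k A'A is
# positive definite; on the constraint subspace the two quadratic forms
# coincide, so conditioning by kriging under the ridged precision is exact.
draw_constrained_gaussian <- function(Q, b, A = NULL) {
  p <- ncol(Q)
  if (!is.null(A) && nrow(A) > 0) {
    kc <- mean(diag(Q)) + 1
    Q <- Q + kc * crossprod(A)
  }
  ch <- tryCatch(chol(Q), error = function(e) chol(Q + diag(1e-8 * mean(diag(Q)), p)))
  mu <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  z <- mu + backsolve(ch, rnorm(p))
  if (!is.null(A) && nrow(A) > 0) {
    Va <- backsolve(ch, backsolve(ch, t(A), transpose = TRUE))
    W <- A %*% Va
    z <- z - Va %*% solve(W, A %*% z)
  }
  drop(z)
}

# truncated-Gamma full conditional of one CAR precision, sampled by
# inverse CDF on sigma in (sd_lo, sd_hi)
draw_car_precision <- function(effects, sd_lo, sd_hi) {
  L <- length(effects)
  S <- max(sum(diff(effects)^2), 1e-300)
  shape <- (L - 2) / 2
  rate <- S / 2
  if (shape <= 0) {
    # L = 2: the Gamma form degenerates; grid inverse-CDF on log-sigma
    sig <- exp(seq(log(max(sd_lo, 1e-4)), log(sd_hi), length.out = 512))
    lp <- -(L - 1) * log(sig) - S / (2 * sig^2)
    w <- cumsum(exp(lp - max(lp)))
    s <- sig[findInterval(runif(1, 0, w[length(w)]), w) + 1]
    return(1 / s^2)
  }
  tau_lo <- 1 / sd_hi^2
  tau_hi <- if (sd_lo > 0) 1 / sd_lo^2 else Inf
  plo <- pgamma(tau_lo, shape, rate)
  phi <- if (is.finite(tau_hi)) pgamma(tau_hi, shape, rate) else 1
  u <- runif(1, plo, min(phi, 1 - 1e-14))
  max(qgamma(u, shape, rate), tau_lo + 1e-12)
}

assemble_Q <- function(prep, omega) {
  p <- prep$p
  if (prep$fast) {
    J <- length(prep$spec$maternal_ages)
    K <- length(prep$spec$paternal_ages)
    M <- matrix(0, J, K)
    M[prep$cells$jk] <- omega
    rs <- rowSums(M); cs <- colSums(M)
    Q <- matrix(0, p, p)
    mc <- prep$layout$m_cols; pc <- prep$layout$p_cols
    Q[1, 1] <- sum(rs)
    Q[1, mc] <- rs; Q[mc, 1] <- rs
    Q[1, pc] <- cs; Q[pc, 1] <- cs
    Q[cbind(mc, mc)] <- rs
    Q[cbind(pc, pc)] <- cs
    Q[mc, pc] <- M
    Q[pc, mc] <- t(M)
    Q
  } else {
    crossprod(prep$cells$X * sqrt(omega))
  }
}

chain_init <- function(prep, chain_id) {
  n <- prep$cells$n; Y <- prep$cells$Y
  a0 <- qlogis((sum(Y) + 0.5) / (sum(n) + 1))
  offset <- 2 * (-1)^(chain_id - 1) * ceiling(chain_id / 2)
  theta <- numeric(prep$p)
  theta[1] <- a0 + offset
  theta
}

run_chain_pg <- function(prep, burn_in, samples, thin, chain_seed, chain_id) {
  set.seed(chain_seed)
  p <- prep$p
  theta <- chain_init(prep, chain_id)
  tau <- vapply(prep$car_blocks, function(b) 1, numeric(1))
  X <- prep$cells$X; n <- prep$cells$n; Y <- prep$cells$Y
  b0 <- drop(crossprod(X, prep$cells$kappa))
  psi <- drop(X %*% theta)
  ncar <- length(prep$car_blocks)
  sd_names <- if (ncar) paste0("sd_", names(prep$car_blocks)) else character(0)
  draws <- matrix(NA_real_, samples, p + ncar,
                  dimnames = list(NULL, c(prep$layout$names, sd_names)))
  devs <- numeric(samples)
  mu_sum <- 0
  has_con <- ncar > 0
  # adaptive proposal scales for the exact-likelihood Metropolis boost
  sc <- rep(0.2, p)
  sc_scale <- rep(0.5, ncar)
  acc <- tries <- numeric(p)
  acc_s <- tries_s <- numeric(ncar)
  total <- burn_in + samples * thin
  isample <- 0L
  for (it in seq_len(total)) {
    omega <- rpg(n, psi, exact_max = prep$pg_exact_max)
    Q <- assemble_Q(prep, omega)
    if (any(prep$prior_diag > 0))
      diag(Q) <- diag(Q) + prep$prior_diag
    for (i in seq_along(prep$car_blocks)) {
      bl <- prep$car_blocks[[i]]
      Q[bl$Qidx] <- Q[bl$Qidx] + tau[i] * bl$Qval
    }
    theta <- draw_constrained_gaussian(Q, b0, if (has_con) prep$A)
    psi <- drop(X %*% theta)
    # exact-likelihood Metropolis boost: PG augmentation alone is sticky
    # for rare outcomes, so mix in moves on the exact posterior
    st <- mh_boost(prep, theta, psi, tau, sc, sc_scale, acc, tries,
                   acc_s, tries_s)
    theta <- st$theta; psi <- st$psi; tau <- st$tau
    acc <- st$acc; tries <- st$tries
    acc_s <- st$acc_s; tries_s <- st$tries_s
    if (ncar)
      for (i in seq_len(ncar))
        tau[i] <- draw_car_precision(theta[prep$car_blocks[[i]]$cols],
                                     prep$sd_lo, prep$sd_hi)
    if (it <= burn_in && it %% 50 == 0) {
      rate <- ifelse(tries > 0, acc / pmax(tries, 1), 0.44)
      sc <- pmin(pmax(sc * exp(rate - 0.44), 1e-4), 10)
      if (ncar) {
        rate_s <- ifelse(tries_s > 0, acc_s / pmax(tries_s, 1), 0.44)
        sc_scale <- pmin(pmax(sc_scale * exp(rate_s - 0.44), 1e-3), 5)
      }
      acc[] <- 0; tries[] <- 0; acc_s[] <- 0; tries_s[] <- 0
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      isample <- isample + 1L
      mu <- plogis(psi)
      draws[isample, ] <- c(theta, if (ncar) 1 / sqrt(tau))
      devs[isample] <- -2 * sum(dbinom(Y, n, mu, log = TRUE))
      mu_sum <- mu_sum + mu
    }
  }
  list(draws = draws, deviance = devs, mu_sum = mu_sum)
}

# One sweep of exact-likelihood Metropolis updates.  Scalar columns
# (intercept, linear/quadratic/band coefficients) move one at a time; each
# CAR block moves in vectorised odd/even half-updates (with neighbours
# fixed the full conditionals factorise over ages) and is recentred with
# the level transferred to the intercept; finally each CAR block gets a
# joint scale move that multiplies the effects and the CAR sd by a common
# factor, which carries the chain through the (sd, effects) funnel.
mh_boost <- function(prep, theta, psi, tau, sc, sc_scale, acc, tries,
                     acc_s, tries_s) {
  n <- prep$cells$n; Y <- prep$cells$Y
  ll <- dbinom(Y, n, plogis(psi), log = TRUE)
  for (i in prep$scalar_cols) {
    idx <- prep$touch[[as.character(i)]]
    d <- rnorm(1, 0, sc[i])
    xi <- prep$cells$X[idx, i]
    ll_new <- dbinom(Y[idx], n[idx], plogis(psi[idx] + xi * d), log = TRUE)
    dll <- sum(ll_new) - sum(ll[idx])
    dpr <- if (i == 1 && prep$spec$intercept_prior == "flat") 0
           else (theta[i]^2 - (theta[i] + d)^2) / (2 * prep$fixed_var)
    tries[i] <- tries[i] + 1
    if (is.finite(dll + dpr) && log(runif(1)) < dll + dpr) {
      theta[i] <- theta[i] + d
      psi[idx] <- psi[idx] + xi * d
      ll[idx] <- ll_new
      acc[i] <- acc[i] + 1
    }
  }
  for (bi in seq_along(prep$car_blocks)) {
    bl <- prep$car_blocks[[bi]]
    cols <- bl$cols; L <- bl$L
    pos <- if (names(prep$car_blocks)[bi] == "maternal") prep$cells$mpos
           else prep$cells$ppos
    m <- theta[cols]
    for (par in 0:1) {
      S <- seq(1 + par, L, by = 2)
      prop <- rnorm(L, 0, sc[cols])
      left <- c(NA, m[-L]); right <- c(m[-1], NA)
      mn <- m; mn[S] <- m[S] + prop[S]
      dpr <- -tau[bi] / 2 *
        (ifelse(is.na(left), 0, (mn - left)^2 - (m - left)^2) +
         ifelse(is.na(right), 0, (right - mn)^2 - (right - m)^2))
      aff <- which((pos %% 2) == ((1 + par) %% 2))
      dll <- numeric(L)
      lln <- NULL
      if (length(aff)) {
        pa <- pos[aff]
        lln <- dbinom(Y[aff], n[aff], plogis(psi[aff] + prop[pa]),
                      log = TRUE)
        tmp <- rowsum(lln - ll[aff], pa)
        dll[as.integer(rownames(tmp))] <- tmp
      }
      ok <- S[log(runif(length(S))) < dll[S] + dpr[S]]
      tries[cols[S]] <- tries[cols[S]] + 1
      if (length(ok)) {
        acc[cols[ok]] <- acc[cols[ok]] + 1
        dm <- numeric(L); dm[ok] <- prop[ok]
        m[ok] <- m[ok] + prop[ok]
        if (length(aff)) {
          sel <- pos[aff] %in% ok
          psi[aff][sel] <- psi[aff][sel] + prop[pos[aff]][sel]
          ll[aff][sel] <- lln[sel]
        }
      }
    }
    lev <- mean(m)           # recentre; psi is invariant to the shift
    theta[cols] <- m - lev
    theta[1] <- theta[1] + lev
    # joint scale move: s' = s e^eps, effects' = effects e^eps; the prior
    # and Jacobian terms collapse to exp(2 eps) for the RW1/uniform pair
    s_cur <- 1 / sqrt(tau[bi])
    eps <- rnorm(1, 0, sc_scale[bi])
    s_new <- s_cur * exp(eps)
    tries_s[bi] <- tries_s[bi] + 1
    if (s_new > prep$sd_lo && s_new < prep$sd_hi) {
      m <- theta[cols]
      dm <- m * (exp(eps) - 1)
      psi_new <- psi + dm[pos]
      ll_new <- dbinom(Y, n, plogis(psi_new), log = TRUE)
      if (log(runif(1)) < sum(ll_new) - sum(ll) + 2 * eps) {
        theta[cols] <- m * exp(eps)
        psi <- psi_new
        ll <- ll_new
        tau[bi] <- 1 / s_new^2
        acc_s[bi] <- acc_s[bi] + 1
      }
    }
  }
  list(theta = theta, psi = psi, tau = tau, acc = acc, tries = tries,
       acc_s = acc_s, tries_s = tries_s)
}

# Adaptive single-site random-walk Metropolis-within-Gibbs targeting the
# same posterior; CAR blocks are recentred after every sweep with the level
# transferred into the intercept (BUGS car.normal convention).
run_chain_rwm <- function(prep, burn_in, samples, thin, chain_seed, chain_id) {
  set.seed(chain_seed)
  p <- prep$p
  theta <- chain_init(prep, chain_id)
  tau <- vapply(prep$car_blocks, function(b) 1, numeric(1))
  X <- prep$cells$X; n <- prep$cells$n; Y <- prep$cells$Y
  touches <- lapply(seq_len(p), function(i) which(X[, i] != 0))
  car_col <- integer(p)   # which CAR block each column belongs to (0 = none)
  for (i in seq_along(prep$car_blocks))
    car_col[prep$car_blocks[[i]]$cols] <- i
  psi <- drop(X %*% theta)
  ll_cell <- dbinom(Y, n, plogis(psi), log = TRUE)
  prop_sd <- rep(0.1, p)
  acc <- integer(p); tries <- integer(p)
  ncar <- length(prep$car_blocks)
  sd_names <- if (ncar) paste0("sd_", names(prep$car_blocks)) else character(0)
  draws <- matrix(NA_real_, samples, p + ncar,
                  dimnames = list(NULL, c(prep$layout$names, sd_names)))
  devs <- numeric(samples)
  mu_sum <- 0
  log_prior_i <- function(i, val, th) {
    bi <- car_col[i]
    if (bi > 0) {
      cols <- prep$car_blocks[[bi]]$cols
      pos <- match(i, cols)
      s <- 0
      if (pos > 1) s <- s + (val - th[cols[pos - 1]])^2
      if (pos < length(cols)) s <- s + (th[cols[pos + 1]] - val)^2
      return(-tau[bi] / 2 * s)
    }
    if (i == 1 && prep$spec$intercept_prior == "flat") return(0)
    -val^2 / (2 * prep$fixed_var)
  }
  total <- burn_in + samples * thin
  isample <- 0L
  for (it in seq_len(total)) {
    for (i in seq_len(p)) {
      cur <- theta[i]
      cand <- cur + rnorm(1, 0, prop_sd[i])
      idx <- touches[[i]]
      psi_new <- psi[idx] + X[idx, i] * (cand - cur)
      ll_new <- dbinom(Y[idx], n[idx], plogis(psi_new), log = TRUE)
      lr <- sum(ll_new) - sum(ll_cell[idx]) +
        log_prior_i(i, cand, theta) - log_prior_i(i, cur, theta)
      tries[i] <- tries[i] + 1L
      if (is.finite(lr) && log(runif(1)) < lr) {
        theta[i] <- cand
        psi[idx] <- psi_new
        ll_cell[idx] <- ll_new
        acc[i] <- acc[i] + 1L
      }
    }
    # recentre CAR blocks, shifting the level into the intercept
    for (bl in prep$car_blocks) {
      m <- mean(theta[bl$cols])
      theta[bl$cols] <- theta[bl$cols] - m
      theta[1] <- theta[1] + m
    }
    psi <- drop(X %*% theta)
    ll_cell <- dbinom(Y, n, plogis(psi), log = TRUE)
    if (ncar)
      for (i in seq_len(ncar))
        tau[i] <- draw_car_precision(theta[prep$car_blocks[[i]]$cols],
                                     prep$sd_lo, prep$sd_hi)
    if (it <= burn_in && it %% 50 == 0) {
      rate <- ifelse(tries > 0, acc / pmax(tries, 1), 0.44)
      prop_sd <- prop_sd * exp(rate - 0.44)
      acc[] <- 0L; tries[] <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      isample <- isample + 1L
      mu <- plogis(psi)
      draws[isample, ] <- c(theta, if (ncar) 1 / sqrt(tau))
      devs[isample] <- -2 * sum(ll_cell)
      mu_sum <- mu_sum + mu
    }
  }
  list(draws = draws, deviance = devs, mu_sum = mu_sum)
}

# all chains row-bound
combined_draws <- function(fit) do.call(rbind, fit$draws)

#' @export
print.parage_fit <- function(x, ...) {
  cfg <- x$config
  cat("Bayesian parental-age model [", x$tab$outcome, "]: maternal = ",
      x$spec$maternal_form, ", paternal = ", x$spec$paternal_form, "\n",
      "  sampler: ", cfg$sampler, ", ", cfg$chains, " chain(s) x ",
      cfg$samples, " draws (burn-in ", cfg$burn_in, ", thin ", cfg$thin,
      "), seed ", cfg$seed, "\n", sep = "")
  d <- dic(x)
  cat(sprintf("  DIC %.1f (mean deviance %.1f, pD %.1f)\n",
              d$DIC, d$mean_deviance, d$pD))
  if (!is.null(x$convergence))
    cat(sprintf("  max split-R-hat %.3f (%s)\n", x$convergence$max_rhat,
                if (x$convergence$pass) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.parage_fit <- function(object, ...) {
  apply(combined_draws(object), 2, median)
}

#' @export
summary.parage_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  dr <- combined_draws(object)
  qs <- t(apply(dr, 2, quantile, probs = probs))
  out <- list(fit = object, quantiles = qs, dic = dic(object),
              convergence = object$convergence)
  class(out) <- "summary.parage_fit"
  out
}

#' @export
print.summary.parage_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior quantiles (selected parameters):\n")
  sel <- unique(c(1, grep("^sd_", rownames(x$quantiles))))
  print(round(x$quantiles[sel, , drop = FALSE], 4))
  for (parent in c("maternal", "paternal")) {
    form <- x$fit$spec[[paste0(parent, "_form")]]
    if (form == "none") next
    ort <- odds_ratios(x$fit, parent)
    top <- ort[nrow(ort), ]
    cat(sprintf(
      "%s OR (age %d vs %d): %.2f (%.2f, %.2f), P(OR>1) = %.3f\n",
      parent, top$age, attr(ort, "ref_age"), top$median, top$lower,
      top$upper, top$exceedance))
  }
  invisible(x)
}

#' @export
residuals.parage_fit <- function(object, type = c("pearson", "response"),
                                 ...) {
  type <- match.arg(type)
  n <- object$cells$n; Y <- object$cells$Y; mu <- object$mu_mean
  r <- Y - n * mu
  if (type == "pearson") r <- r / sqrt(pmax(n * mu * (1 - mu), 1e-12))
  r
}

#' Posterior-predictive simulation from a fitted model
#'
#' Resamples retained posterior draws and simulates new case counts
#' `Y* ~ Binomial(n, mu(draw))` on the fitted table's grid.
#'
#' @param object a `parage_fit`.
#' @param nsim number of simulated tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of tables of the same class as the fitted one.
#' @export
simulate.parage_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dr <- combined_draws(object)
  p <- length(object$layout$names)
  X <- object$cells$X
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    th <- dr[sample.int(nrow(dr), 1), seq_len(p)]
    mu <- plogis(drop(X %*% th))
    Ys <- rbinom(length(mu), object$cells$n, mu)
    tab <- object$tab
    if (inherits(tab, "age_crosstab")) {
      cases <- matrix(0, nrow(tab$cases), ncol(tab$cases))
      cases[object$cells$keep] <- Ys
      tab$cases <- cases
      dimnames(tab$cases) <- dimnames(tab$births)
    } else {
      cases <- numeric(length(tab$cases))
      cases[object$cells$keep] <- Ys
      tab$cases <- cases
    }
    out[[s]] <- tab
  }
  out
}

#' @export
plot.parage_fit <- function(x, baseline = c("age15", "overall_mean"),
                            log = TRUE, ...) {
  baseline <- match.arg(baseline)
  parents <- c("maternal", "paternal")
  parents <- parents[vapply(parents, function(p)
    x$spec[[paste0(p, "_form")]] != "none", logical(1))]
  old <- par(mfrow = c(1, length(parents)))
  on.exit(par(old))
  for (p in parents)
    plot(odds_ratios(x, p, baseline = baseline), log = log,
         main = paste(x$tab$outcome, p), ...)
  invisible(x)
}
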