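split_rhat <- function(mat) {
  # mat: iterations x chains; split each chain in half (Gelman et al.)
  n <- nrow(mat)
  half <- floor(n / 2)
  seqs <- cbind(mat[seq_len(half), , drop = FALSE],
                mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(seqs); nn <- nrow(seqs)
  means <- colMeans(seqs)
  W <- mean(apply(seqs, 2, var))
  B <- nn * var(means)
  if (W <= 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_one <- function(mat) {
  # effective sample size from per-chain autocorrelations (initial
  # positive-sequence truncation)
  n <- nrow(mat); m <- ncol(mat)
  if (var(as.vector(mat)) <= 1e-300) return(n * m)
  rho <- rowMeans(vapply(seq_len(m), function(ch) {
    a <- acf(mat[, ch], lag.max = min(n - 1, 200), plot = FALSE,
             demean = TRUE)$acf[-1]
    a
  }, numeric(min(n - 1, 200))))
  s <- 0
  for (l in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[l] + rho[l + 1]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
  }
  max(n * m / (1 + 2 * s), 1)
}

#' Convergence diagnostics for a fitted model
#'
#' Computes split potential-scale-reduction factors (split-R-hat) and
#' effective sample sizes for every scalar parameter (including the CAR
#' standard deviations and the deviance), and declares the fit converged
#' when the largest R-hat does not exceed `threshold`.
#'
#' @param fit a `parage_fit` with at least 2 chains.
#' @param threshold R-hat pass threshold (default 1.05).
#' @return an object of class `parage_convergence`: a list with a
#'   per-parameter data frame `parameters` (columns `rhat`, `ess`),
#'   `max_rhat`, and logical `pass`.
#' @export
check_convergence <- function(fit, threshold = 1.05) {
  stopifnot(inherits(fit, "parage_fit"))
  if (fit$config$chains < 2)
    stop("convergence checking requires at least 2 chains")
  pars <- colnames(fit$draws[[1]])
  arr <- lapply(seq_along(pars), function(i)
    vapply(fit$draws, function(d) d[, i], numeric(fit$config$samples)))
  arr <- c(arr, list(vapply(fit$deviance, identity,
                            numeric(fit$config$samples))))
  pars <- c(pars, "deviance")
  rhat <- vapply(arr, split_rhat, numeric(1))
  ess <- vapply(arr, ess_one, numeric(1))
  out <- list(parameters = data.frame(parameter = pars, rhat = rhat,
                                      ess = ess, row.names = NULL),
              max_rhat = max(rhat), threshold = threshold,
              pass = max(rhat) <= threshold)
  class(out) <- "parage_convergence"
  out
}

#' @export
print.parage_convergence <- function(x, ...) {
  cat("Convergence: max split-R-hat = ", round(x$max_rhat, 4),
      " (threshold ", x$threshold, ") -> ",
      if (x$pass) "PASS" else "FAIL", "\n", sep = "")
  worst <- x$parameters[order(-x$parameters$rhat), ][1:min(5, nrow(x$parameters)), ]
  print(worst, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Deviance Information Criterion
#'
#' `DIC = mean deviance + pD`, with `pD = mean deviance - plug-in deviance`
#' and the plug-in point taken as the posterior mean of the cell
#' probabilities `mu[j,k]` (the direct stochastic parents of the counts,
#' matching the classic BUGS DIC focus).  The per-iteration deviance is
#' `-2 *` the binomial log-likelihood.
#'
#' @param fit a `parage_fit`.
#' @return object of class `parage_dic`: list with `mean_deviance`,
#'   `plugin_deviance`, `pD`, `DIC`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "parage_fit"))
  mean_dev <- mean(unlist(fit$deviance))
  plugin <- -2 * sum(dbinom(fit$cells$Y, fit$cells$n, fit$mu_mean,
                            log = TRUE))
  pD <- mean_dev - plugin
  structure(list(mean_deviance = mean_dev, plugin_deviance = plugin,
                 pD = pD, DIC = mean_dev + pD), class = "parage_dic")
}

#' @export
print.parage_dic <- function(x, ...) {
  cat(sprintf("DIC = %.1f  (mean deviance %.1f, plug-in %.1f, pD %.1f)\n",
              x$DIC, x$mean_deviance, x$plugin_deviance, x$pD))
  invisible(x)
}
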