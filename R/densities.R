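#' Binomial log-likelihood of a count table
#'
#' Sum over cells of `log Binomial(Y | n, mu)`.  Cells with `n = 0`
#' contribute exactly 0 regardless of `mu`.
#'
#' @param tab an [age_crosstab()] or [age_margin()].
#' @param mu matrix (or vector, for a margin) of cell probabilities, same
#'   shape as `tab$births`; must lie in `[0, 1]` and strictly inside
#'   `(0, 1)` wherever `births > 0`.
#' @return scalar log-likelihood.
#' @examples
#' tab <- age_margin(15, 10, 5)
#' binomial_loglik(tab, 0.5)  # log C(10,5) - 10 log 2
#' @export
binomial_loglik <- function(tab, mu) {
  n <- if (inherits(tab, "age_crosstab")) tab$births else tab$births
  Y <- tab$cases
  mu <- if (is.matrix(n)) matrix(as.numeric(mu), nrow(n), ncol(n))
        else rep_len(as.numeric(mu), length(n))
  if (length(mu) != length(n)) stop("mu does not match the table's shape")
  if (any(mu < 0 | mu > 1)) stop("mu must lie in [0, 1]")
  keep <- n > 0
  if (!any(keep)) return(0)
  sum(dbinom(Y[keep], n[keep], mu[keep], log = TRUE))
}

#' First-order random-walk (intrinsic CAR) log-density
#'
#' Up to an additive constant,
#' `((L-1)/2) log(tau) - (tau/2) * sum of squared first differences`.
#' The density is improper over the overall level (rank deficiency 1), hence
#' invariant to adding a constant to all effects; identification in the
#' models comes from a sum-to-zero constraint.
#'
#' @param effects numeric vector of length L >= 2.
#' @param precision positive scalar `tau` (the CAR sd is `1/sqrt(tau)`).
#' @return scalar log-density (unnormalised).
#' @examples
#' rw1_logdensity(c(0, 1, -1), 2)  # log 2 - 5
#' @export
rw1_logdensity <- function(effects, precision) {
  if (any(!is.finite(effects)) || !is.finite(precision))
    stop("non-finite inputs")
  L <- length(effects)
  if (L < 2) stop("need at least 2 effects")
  if (precision <= 0) stop("precision must be positive")
  ((L - 1) / 2) * log(precision) -
    (precision / 2) * sum(diff(effects)^2)
}

#' RW1 structure matrix
#'
#' The L x L precision-structure matrix Q of the first-order random walk:
#' 1 on the corner diagonal entries, 2 on interior diagonal entries, -1 on
#' the first off-diagonals; `t(x) %*% Q %*% x` equals the sum of squared
#' first differences of `x`.
#'
#' @param L number of effects (>= 2).
#' @return L x L matrix.
#' @export
rw1_structure_matrix <- function(L) {
  if (L < 2) stop("need L >= 2")
  Q <- diag(c(1, rep(2, L - 2), 1))
  idx <- cbind(seq_len(L - 1), 2:L)
  Q[idx] <- -1
  Q[idx[, 2:1, drop = FALSE]] <- -1
  Q
}

#' Uniform hyperprior on a CAR standard deviation
#'
#' Log-density of the Uniform(sd_lower, sd_upper) prior on the CAR standard
#' deviation: the constant 0 on the open interval, `-Inf` outside (both
#' boundaries excluded, so tau = Inf is never proposed).
#'
#' @param sd standard deviation value(s).
#' @param sd_lower,sd_upper support bounds (defaults 0 and 10).
#' @return log-density, vectorised over `sd`.
#' @export
sd_hyperprior_logdensity <- function(sd, sd_lower = 0, sd_upper = 10) {
  ifelse(sd > sd_lower & sd < sd_upper, 0, -Inf)
}
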