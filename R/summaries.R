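# per-draw age effects (log-odds contribution of one parent at each age),
# combined across chains: ndraws x L matrix
age_effect_draws <- function(fit, parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  term <- fit$layout[[parent]]
  if (term$form == "none")
    stop("the fitted model has no ", parent, " term")
  cols <- term$names
  dr <- combined_draws(fit)[, cols, drop = FALSE]
  E <- dr %*% t(term$X)
  colnames(E) <- term$ages
  E
}

#' Age-specific odds ratios from a fitted model
#'
#' Transforms posterior draws into per-age odds ratios for one parent,
#' relative to either a reference age (default 15, the youngest age, as in
#' `baseline = "age15"`) or to the overall mean risk
#' (`baseline = "overall_mean"`, default births-weighted).  All summaries
#' are percentiles of the transformed draws (median, 2.5%, 97.5%), never
#' transforms of percentiles, and the exceedance probability is the
#' fraction of draws with OR strictly greater than 1.
#'
#' For `"age15"`, per draw `OR_a = exp(effect_a - effect_ref)`, so the OR at
#' the reference age is exactly 1 with a zero-width interval.  For
#' `"overall_mean"`, per draw the baseline log-odds is the weighted mean of
#' the parent's age effects (weights = the parent's marginal birth counts,
#' or uniform with `weighted = FALSE`); additive terms for the other parent
#' and the intercept cancel from the ratio.
#'
#' @param fit a `parage_fit`.
#' @param parent `"maternal"` or `"paternal"`.
#' @param baseline `"age15"` (reference age) or `"overall_mean"`.
#' @param ref_age reference age for `baseline = "age15"`; defaults to the
#'   youngest modelled age.
#' @param weighted births-weight the overall-mean baseline (default TRUE).
#' @return a data frame of class `parage_or` with columns `age`, `median`,
#'   `lower`, `upper`, `exceedance`; attributes `parent`, `baseline`,
#'   `ref_age`, `outcome`.
#' @export
odds_ratios <- function(fit, parent = c("maternal", "paternal"),
                        baseline = c("age15", "overall_mean"),
                        ref_age = NULL, weighted = TRUE) {
  parent <- match.arg(parent)
  baseline <- match.arg(baseline)
  E <- age_effect_draws(fit, parent)
  ages <- as.integer(colnames(E))
  if (baseline == "age15") {
    if (is.null(ref_age)) ref_age <- min(ages)
    r <- match(ref_age, ages)
    if (is.na(r)) stop("ref_age ", ref_age, " outside the modelled ages")
    logor <- E - E[, r]
  } else {
    w <- if (weighted) marginal_weights(fit, parent) else
      rep(1 / length(ages), length(ages))
    logor <- E - drop(E %*% w)
    ref_age <- NA_integer_
  }
  OR <- exp(logor)
  qs <- apply(OR, 2, quantile, probs = c(0.5, 0.025, 0.975))
  out <- data.frame(age = ages, median = qs[1, ], lower = qs[2, ],
                    upper = qs[3, ],
                    exceedance = colMeans(OR > 1), row.names = NULL)
  structure(out, class = c("parage_or", "data.frame"), parent = parent,
            baseline = baseline, ref_age = ref_age,
            outcome = fit$tab$outcome)
}

marginal_weights <- function(fit, parent) {
  tab <- fit$tab
  b <- if (inherits(tab, "age_margin")) tab$births
       else if (parent == "maternal") rowSums(tab$births)
       else colSums(tab$births)
  b / sum(b)
}

#' Posterior probability that an odds ratio exceeds 1
#'
#' Fraction of posterior draws with `OR = exp(effect_age - effect_ref)`
#' strictly greater than 1 (ties count as non-exceedance); at
#' `age == ref_age` the OR is identically 1 so the value is 0.
#'
#' @param fit a `parage_fit`.
#' @param parent `"maternal"` or `"paternal"`.
#' @param age age of interest.
#' @param ref_age reference age (default the youngest modelled age).
#' @return scalar in `[0, 1]`.
#' @export
exceedance_probability <- function(fit, parent = c("maternal", "paternal"),
                                   age, ref_age = NULL) {
  parent <- match.arg(parent)
  E <- age_effect_draws(fit, parent)
  ages <- as.integer(colnames(E))
  if (is.null(ref_age)) ref_age <- min(ages)
  a <- match(age, ages); r <- match(ref_age, ages)
  if (is.na(a) || is.na(r)) stop("age outside the modelled range")
  mean(E[, a] - E[, r] > 0)
}

#' @export
print.parage_or <- function(x, ...) {
  cat("Odds ratios [", attr(x, "outcome"), "]: ", attr(x, "parent"),
      " age, baseline = ",
      if (attr(x, "baseline") == "age15")
        paste0("age ", attr(x, "ref_age")) else "overall mean risk",
      "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname odds_ratios
#' @param x a `parage_or` table.
#' @param log plot the OR axis on the log scale (default TRUE).
#' @param main,col plot title and colour.
#' @param add overlay the median curve on an existing plot.
#' @param ... further arguments to `plot`.
#' @export
plot.parage_or <- function(x, log = TRUE, main = NULL, col = "steelblue4",
                           add = FALSE, ...) {
  if (is.null(main))
    main <- paste0(attr(x, "outcome"), ": ", attr(x, "parent"), " age OR")
  if (!add) {
    plot(x$age, x$median, type = "n", log = if (log) "y" else "",
         xlab = paste(attr(x, "parent"), "age (years)"),
         ylab = "odds ratio",
         ylim = range(pmax(x$lower, 1e-3), x$upper), main = main, ...)
    polygon(c(x$age, rev(x$age)), c(pmax(x$lower, 1e-6), rev(x$upper)),
            col = adjustcolor(col, 0.25), border = NA)
    abline(h = 1, lty = 3)
  }
  lines(x$age, x$median, col = col, lwd = 2)
  invisible(x)
}

#' Overlay odds-ratio curves from several models
#'
#' Draws the posterior-median OR curves of several fitted models on one
#' panel (the classic CAR vs linear vs curvilinear vs age-band comparison).
#'
#' @param tables named list of `parage_or` tables on a common age grid.
#' @param log log-scale the OR axis.
#' @param main title.
#' @param cols line colours (recycled).
#' @return invisibly, `tables`.
#' @export
plot_or_comparison <- function(tables, log = TRUE, main = "model comparison",
                               cols = c("steelblue4", "firebrick", "darkgreen",
                                        "goldenrod3")) {
  stopifnot(length(tables) >= 1)
  cols <- rep_len(cols, length(tables))
  rng <- range(unlist(lapply(tables, function(t) c(t$median))))
  t1 <- tables[[1]]
  plot(t1$age, t1$median, type = "n", log = if (log) "y" else "",
       xlab = paste(attr(t1, "parent"), "age (years)"), ylab = "odds ratio",
       ylim = rng, main = main)
  abline(h = 1, lty = 3)
  for (i in seq_along(tables))
    lines(tables[[i]]$age, tables[[i]]$median, col = cols[i], lwd = 2)
  if (!is.null(names(tables)))
    legend("topleft", legend = names(tables), col = cols, lwd = 2,
           bty = "n")
  invisible(tables)
}

#' Write an odds-ratio table to CSV
#'
#' @param x a `parage_or`.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_or_table <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
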