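#' Multi-model analysis of one or more outcomes
#'
#' Fits a set of model presets to each supplied table, writes per-model
#' draws, convergence and odds-ratio tables, assembles the classic
#' DIC-comparison table (rows: 5-yr age category, Linear, Curvi-linear,
#' CAR; columns per outcome: Deviance, Complexity, DIC) and an OR
#' comparison figure per outcome, and records seeds and package version in
#' a run log.
#'
#' @param tabs an [age_crosstab()] or named list of them (one per outcome).
#' @param models character vector of preset names (see [model_preset()]).
#' @param out_dir output directory (created if needed).
#' @param burn_in,samples,chains,thin,seed MCMC protocol, as in
#'   [fit_parage()].
#' @param baseline baseline for the exported OR tables.
#' @param write_draws write the full draws CSV per model (can be large).
#' @param on_nonconvergence `"error"` (default) or `"warn"` when any model
#'   fails the split-R-hat check.
#' @return invisibly, a list with the fitted models, the DIC table and the
#'   output directory.
#' @export
run_analysis <- function(tabs, models = c("model1", "model2", "model3",
                                          "linear", "curvilinear",
                                          "category5"),
                         out_dir = "parage-output", burn_in = 5000,
                         samples = 10000, chains = 2, thin = 1, seed = 1,
                         baseline = c("age15", "overall_mean"),
                         write_draws = FALSE,
                         on_nonconvergence = c("error", "warn")) {
  baseline <- match.arg(baseline)
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (inherits(tabs, "age_crosstab")) {
    tabs <- list(tabs)
    names(tabs) <- tabs[[1]]$outcome
  }
  if (is.null(names(tabs))) names(tabs) <- paste0("outcome", seq_along(tabs))
  if (length(models) < 1) stop("need at least one model preset")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run-log.txt")
  cat("parage ", as.character(packageVersion("parage")),
      " analysis run\nseed: ", seed, "\nprotocol: burn-in ", burn_in,
      ", samples ", samples, ", chains ", chains, ", thin ", thin, "\n",
      sep = "", file = log_path)
  fits <- list()
  dic_rows <- list()
  failed <- character(0)
  for (oc in names(tabs)) {
    tab <- tabs[[oc]]
    ors <- list()
    for (mod in models) {
      t0 <- proc.time()[3]
      fit <- withCallingHandlers(
        fit_parage(tab, mod, burn_in = burn_in, samples = samples,
                   chains = chains, thin = thin, seed = seed),
        warning = function(w) {
          if (grepl("convergence not reached", conditionMessage(w)))
            failed <<- c(failed, paste(oc, mod))
          invokeRestart("muffleWarning")
        })
      fits[[paste(oc, mod, sep = "_")]] <- fit
      d <- dic(fit)
      dic_rows[[length(dic_rows) + 1]] <- data.frame(
        outcome = oc, model = mod, deviance = d$mean_deviance,
        complexity = d$pD, dic = d$DIC)
      base <- file.path(out_dir, paste0(oc, "_", mod))
      if (write_draws) {
        dr <- combined_draws(fit)
        dd <- data.frame(chain = rep(seq_len(chains), each = samples),
                         iteration = rep(seq_len(samples), chains), dr,
                         deviance = unlist(fit$deviance),
                         check.names = FALSE)
        write.csv(dd, paste0(base, "_draws.csv"), row.names = FALSE)
      }
      if (!is.null(fit$convergence))
        write.csv(fit$convergence$parameters,
                  paste0(base, "_convergence.csv"), row.names = FALSE)
      for (parent in c("maternal", "paternal")) {
        if (fit$spec[[paste0(parent, "_form")]] == "none") next
        ort <- odds_ratios(fit, parent, baseline = baseline)
        write_or_table(ort, paste0(base, "_or_", parent, ".csv"))
        ors[[paste(mod, parent)]] <- ort
      }
      cat(sprintf("%s %s: DIC %.1f, pD %.1f, %.1f s\n", oc, mod, d$DIC,
                  d$pD, proc.time()[3] - t0),
          file = log_path, append = TRUE)
    }
    # comparison figure: median curves of all fitted models, per parent
    for (parent in c("maternal", "paternal")) {
      sel <- ors[grepl(paste0(" ", parent, "$"), names(ors))]
      if (length(sel) < 1) next
      fig <- file.path(out_dir, paste0(oc, "_compare_", parent, ".png"))
      png(fig, width = 800, height = 600)
      names(sel) <- sub(paste0(" ", parent, "$"), "", names(sel))
      plot_or_comparison(sel, main = paste(oc, parent, "age"))
      dev.off()
    }
  }
  dic_tab <- do.call(rbind, dic_rows)
  write.csv(dic_tab, file.path(out_dir, "dic_long.csv"), row.names = FALSE)
  write.csv(dic_table_layout(dic_tab),
            file.path(out_dir, "dic_comparison.csv"), row.names = FALSE)
  if (length(failed)) {
    msg <- paste("models failed convergence:", paste(failed, collapse = ", "))
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }
  invisible(list(fits = fits, dic = dic_tab, out_dir = out_dir))
}

# Reshape the long DIC table into the classic comparison layout:
# one row per model family, Deviance/Complexity/DIC columns per outcome.
dic_table_layout <- function(dic_long) {
  label <- c(category5 = "5-yr age category", linear = "Linear",
             curvilinear = "Curvi-linear", model3 = "CAR",
             model1 = "CAR (maternal only)", model2 = "CAR (paternal only)")
  order_pref <- c("category5", "linear", "curvilinear", "model3",
                  "model1", "model2")
  models <- intersect(order_pref, unique(dic_long$model))
  out <- data.frame(Model = label[models], row.names = NULL)
  for (oc in unique(dic_long$outcome)) {
    sub <- dic_long[dic_long$outcome == oc, ]
    i <- match(models, sub$model)
    out[[paste0(oc, "_Deviance")]] <- round(sub$deviance[i], 1)
    out[[paste0(oc, "_Complexity")]] <- round(sub$complexity[i], 1)
    out[[paste0(oc, "_DIC")]] <- round(sub$dic[i], 1)
  }
  out
}

#' Self-contained validation suite
#'
#' Runs the package's internal correctness checks without any external
#' data: (a) the single-cell sampler-vs-analytic oracle, (b) the RW1
#' structure-matrix identity, (c) a parameter-recovery study on synthetic
#' ramp/null cohorts with interval-coverage scoring, and (d) end-to-end
#' seed determinism.  Intended as a fast CI gate; the checks mirror the
#' package's test suite at reduced size.
#'
#' @param seed integer seed.
#' @param replicates recovery-study replicates (default 10).
#' @param out_dir optional directory for a CSV report.
#' @return data frame with columns `check`, `value`, `pass`; attribute
#'   `pass` gives the overall verdict.
#' @export
run_validation <- function(seed = 1, replicates = 10, out_dir = NULL) {
  checks <- list()
  add <- function(name, value, pass)
    checks[[length(checks) + 1]] <<- data.frame(check = name,
                                                value = value, pass = pass)
  # (a) single-cell oracle: flat-intercept posterior of mu is Beta(Y, n-Y)
  ks <- single_cell_ks(n = 2000, Y = 40, seed = seed)
  add("single_cell_sampler_vs_analytic_ks", ks, ks < 0.05)
  # (b) RW1 quadratic form equals the structure-matrix form
  set.seed(seed)
  dev <- max(vapply(1:20, function(i) {
    L <- sample(3:40, 1)
    x <- rnorm(L); tau <- runif(1, 0.1, 5)
    q1 <- rw1_logdensity(x, tau)
    q2 <- ((L - 1) / 2) * log(tau) -
      (tau / 2) * drop(t(x) %*% rw1_structure_matrix(L) %*% x)
    abs(q1 - q2)
  }, numeric(1)))
  add("rw1_structure_matrix_max_abs_dev", dev, dev < 1e-8)
  # (c) recovery: ramp maternal truth, flat paternal, strong age correlation
  rec <- recovery_study(replicates = replicates, seed = seed)
  add("recovery_maternal_coverage", rec$maternal_coverage,
      rec$maternal_coverage > 0.85 && rec$maternal_coverage <= 1)
  add("recovery_paternal_coverage", rec$paternal_coverage,
      rec$paternal_coverage > 0.85 && rec$paternal_coverage <= 1)
  # (d) determinism
  scn <- sim_scenario(total_births = 5e4, target_prevalence = 5e-3,
                      maternal_ages = 20:34, paternal_ages = 22:40)
  sim <- simulate_crosstab(scn, seed = seed)
  f1 <- suppressWarnings(fit_parage(sim$tab, "model3", burn_in = 100,
                                    samples = 200, seed = seed))
  f2 <- suppressWarnings(fit_parage(sim$tab, "model3", burn_in = 100,
                                    samples = 200, seed = seed))
  det <- identical(f1$draws, f2$draws)
  add("seed_determinism", as.numeric(det), det)
  out <- do.call(rbind, checks)
  attr(out, "pass") <- all(out$pass)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "validation.csv"), row.names = FALSE)
  }
  out
}

# KS distance between sampled mu draws of an intercept-only model on a
# single-cell table and the analytic flat-logit-prior posterior Beta(Y, n-Y)
single_cell_ks <- function(n, Y, seed = 1, burn_in = 500, samples = 2000) {
  tab <- age_margin(20, n, Y, "maternal", "oracle")
  fit <- fit_parage(tab, model_preset("intercept_only"),
                    burn_in = burn_in, samples = samples, chains = 2,
                    seed = seed)
  a <- combined_draws(fit)[, "(Intercept)"]
  mu <- plogis(a)
  u <- sort(pbeta(mu, Y, n - Y))
  m <- length(u)
  max(abs(u - (seq_len(m) - 0.5) / m))
}

# replicate fits of the ramp/null scenario; returns pooled 95% coverage
recovery_study <- function(replicates = 10, seed = 1,
                           total_births = 3e5, prevalence = 2e-3,
                           burn_in = 500, samples = 1000, chains = 2) {
  scn <- sim_scenario(total_births = total_births,
                      target_prevalence = prevalence,
                      maternal_curve = age_curve("ramp", height = log(8),
                                                 onset = 30,
                                                 saturation = 45),
                      paternal_curve = age_curve("flat"))
  fits <- vector("list", replicates)
  truth <- NULL
  for (r in seq_len(replicates)) {
    sim <- simulate_crosstab(scn, seed = seed + r)
    truth <- sim$truth
    fits[[r]] <- suppressWarnings(
      fit_parage(sim$tab, "model3", burn_in = burn_in,
                 samples = samples, chains = chains, seed = seed + r))
  }
  recm <- recovery_report(fits, truth, "maternal")
  recp <- recovery_report(fits, truth, "paternal")
  list(maternal_coverage = recm$coverage,
       paternal_coverage = recp$coverage,
       maternal_rmse = recm$rmse, paternal_rmse = recp$rmse,
       fits = fits, truth = truth)
}
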