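# shared fixtures: everything is generated in code at test time

# small correlated cohort with a known maternal ramp and flat paternal truth
small_scenario <- function(total_births = 5e4, prevalence = 5e-3,
                           height = log(6)) {
  sim_scenario(total_births = total_births,
               target_prevalence = prevalence,
               maternal_ages = 20:34, paternal_ages = 22:40,
               maternal_mean = 27, maternal_sd = 4,
               paternal_mean = 30, paternal_sd = 5, rho = 0.7,
               maternal_curve = age_curve("ramp", height = height,
                                          onset = 24, saturation = 32),
               paternal_curve = age_curve("flat"))
}

small_fit <- function(sim, model = "model3", burn_in = 300, samples = 600,
                      seed = 1, ...) {
  suppressWarnings(fit_parage(sim$tab, model, burn_in = burn_in,
                              samples = samples, seed = seed, ...))
}

# a 3x4 hand-sized cross-tab
toy_tab <- function() {
  age_crosstab(20:22, 25:28,
               births = matrix(c(50, 60, 70, 80, 90, 100, 55, 65, 75, 85,
                                 95, 105), 3, 4),
               cases = matrix(c(1, 2, 0, 3, 1, 2, 0, 1, 2, 1, 0, 3), 3, 4),
               outcome = "toy")
}

# minimal fitted-object skeleton with prescribed effect draws, used to test
# posterior summaries against hand-computable cases
fake_car_fit <- function(E, ages = 15:19, parent = "maternal",
                         intercept = 0, births = NULL) {
  m_form <- if (parent == "maternal") "car" else "none"
  p_form <- if (parent == "paternal") "car" else "none"
  spec <- model_spec(m_form, p_form,
                     maternal_ages = if (parent == "maternal") ages else 15:16,
                     paternal_ages = if (parent == "paternal") ages else 15:16)
  lay <- spec_layout_t(spec)
  if (is.null(births)) births <- rep(1000, length(ages))
  tab <- age_margin(ages, births, pmin(births, 1), parent, "fake")
  colnames(E) <- paste0(parent, "_", ages)
  dr <- cbind(`(Intercept)` = intercept, E,
              matrix(0.5, nrow(E), 1, dimnames = list(NULL, paste0("sd_", parent))))
  structure(list(spec = spec, tab = tab, layout = lay,
                 cells = list(n = births, Y = tab$cases,
                              keep = seq_along(ages)),
                 config = list(chains = 1, samples = nrow(E), burn_in = 0,
                               thin = 1, seed = 1, sampler = "pg"),
                 draws = list(dr),
                 deviance = list(rep(0, nrow(E))),
                 mu_mean = rep(0.001, length(ages))),
            class = "parage_fit")
}

spec_layout_t <- function(spec) getFromNamespace("spec_layout", "parage")(spec)

combined_draws_t <- function(fit) do.call(rbind, fit$draws)
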