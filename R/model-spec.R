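#' Declarative model specification
#'
#' Describes one model variant: how each parent's age enters the linear
#' predictor and which priors are attached.  The log-odds of a case in cell
#' (j, k) are `alpha + maternal_j + paternal_k`, where each parental term is
#' one of:
#'
#' * `"car"` — one free effect per single year of age under a first-order
#'   random-walk (intrinsic CAR) prior, standard deviation ~ Uniform(0, 10),
#'   identified by a sum-to-zero constraint;
#' * `"linear"` — `beta * age`, centred at the midpoint of the parent's age
#'   range for sampler conditioning (a pure reparameterisation);
#' * `"curvilinear"` — centred linear plus quadratic;
#' * `"category5"` — 5-year age bands (15-19 reference, paternal ages add
#'   50-54, 55-59 and 60-65), one coefficient per non-reference band;
#' * `"none"` — the parent's age is not in the model (marginal analyses).
#'
#' Fixed effects and, for the non-CAR models, the intercept get N(0, 1000)
#' priors; the CAR models use a flat improper intercept prior.
#'
#' @param maternal,paternal form of each parent's age term.
#' @param intercept_prior `"flat"` or `"normal"`; default is `"flat"` when
#'   any CAR term is present, otherwise `"normal"` (variance `fixed_var`).
#' @param sd_upper,sd_lower bounds of the uniform hyperprior on each CAR
#'   standard deviation (open interval; defaults 0 and 10).
#' @param fixed_var prior variance of intercept/linear/quadratic/band
#'   coefficients (default 1000).
#' @param maternal_ages,paternal_ages age grids the spec applies to
#'   (defaults 15:49 and 15:65); refitted to the data's grid by
#'   [fit_parage()].
#' @param allow_intercept_only permit `maternal = paternal = "none"` (an
#'   intercept-only model, used for sampler calibration); otherwise at least
#'   one parental term is required.
#' @return an object of class `parage_spec`.
#' @seealso [model_preset()] for the named presets.
#' @examples
#' model_spec("car", "car")            # the joint CAR model
#' model_spec("none", "car")           # marginal paternal model
#' @export
model_spec <- function(maternal = c("car", "none", "linear", "curvilinear",
                                    "category5"),
                       paternal = c("car", "none", "linear", "curvilinear",
                                    "category5"),
                       intercept_prior = NULL,
                       sd_upper = 10, sd_lower = 0, fixed_var = 1000,
                       maternal_ages = 15:49, paternal_ages = 15:65,
                       allow_intercept_only = FALSE) {
  maternal <- match.arg(maternal)
  paternal <- match.arg(paternal)
  if (maternal == "none" && paternal == "none" && !allow_intercept_only)
    stop("at least one of maternal/paternal must differ from \"none\" ",
         "(set allow_intercept_only = TRUE for an intercept-only model)")
  if (!(sd_lower >= 0 && sd_lower < sd_upper))
    stop("need 0 <= sd_lower < sd_upper")
  if (fixed_var <= 0) stop("fixed_var must be positive")
  if (is.null(intercept_prior))
    intercept_prior <- if (maternal == "car" || paternal == "car")
      "flat" else "normal"
  intercept_prior <- match.arg(intercept_prior, c("flat", "normal"))
  check_age_vector(maternal_ages, "maternal")
  check_age_vector(paternal_ages, "paternal")
  if (maternal == "car" && length(maternal_ages) < 2)
    stop("a CAR term needs at least 2 ages")
  if (paternal == "car" && length(paternal_ages) < 2)
    stop("a CAR term needs at least 2 ages")
  structure(list(maternal_form = maternal, paternal_form = paternal,
                 intercept_prior = intercept_prior,
                 sd_upper = sd_upper, sd_lower = sd_lower,
                 fixed_var = fixed_var,
                 maternal_ages = as.integer(maternal_ages),
                 paternal_ages = as.integer(paternal_ages)),
            class = "parage_spec")
}

#' @export
print.parage_spec <- function(x, ...) {
  cat("Model spec: logit(mu) = alpha",
      if (x$maternal_form != "none") paste0(" + maternal[", x$maternal_form, "]"),
      if (x$paternal_form != "none") paste0(" + paternal[", x$paternal_form, "]"),
      "\n  intercept prior: ", x$intercept_prior,
      "; CAR sd ~ U(", x$sd_lower, ",", x$sd_upper,
      "); fixed-effect prior N(0,", x$fixed_var, ")\n", sep = "")
  invisible(x)
}

#' Named model presets
#'
#' `model1` = maternal CAR only (unadjusted maternal), `model2` = paternal
#' CAR only, `model3` = joint maternal + paternal CAR, and the comparison
#' models `linear`, `curvilinear` and `category5`, each applying the same
#' form to both parents with N(0, 1000) priors.
#'
#' @param name one of `"model1"`, `"model2"`, `"model3"`, `"linear"`,
#'   `"curvilinear"`, `"category5"`, `"intercept_only"`.
#' @param ... passed to [model_spec()] (e.g. age grids).
#' @return a `parage_spec`.
#' @export
model_preset <- function(name, ...) {
  switch(match.arg(name, c("model1", "model2", "model3", "linear",
                           "curvilinear", "category5", "intercept_only")),
    model1 = model_spec("car", "none", ...),
    model2 = model_spec("none", "car", ...),
    model3 = model_spec("car", "car", ...),
    linear = model_spec("linear", "linear", ...),
    curvilinear = model_spec("curvilinear", "curvilinear", ...),
    category5 = model_spec("category5", "category5", ...),
    intercept_only = model_spec("none", "none",
                                allow_intercept_only = TRUE, ...))
}

#' 5-year age-band scheme
#'
#' Bands 15-19, 20-24, ..., 45-49 for either parent; paternal ages add
#' 50-54, 55-59 and a final 60-65 band.
#'
#' @param parent `"maternal"` or `"paternal"`.
#' @return data frame with columns `lower`, `upper`, `label`.
#' @export
age_bands <- function(parent = c("maternal", "paternal")) {
  parent <- match.arg(parent)
  lower <- if (parent == "maternal") seq(15, 45, 5) else seq(15, 60, 5)
  upper <- lower + 4
  upper[length(upper)] <- if (parent == "maternal") 49 else 65
  data.frame(lower = lower, upper = upper,
             label = paste0(lower, "-", upper))
}

band_of <- function(ages, parent) {
  bands <- age_bands(parent)
  i <- findInterval(ages, bands$lower)
  if (any(i < 1 | ages > max(bands$upper)))
    stop("age outside the ", parent, " band scheme (",
         min(bands$lower), "-", max(bands$upper), ")")
  i
}

# Design block for one parent's term, over that parent's age grid.
# Returns one design row per age level; cell-level rows are picked by index.
make_term <- function(form, ages, parent) {
  L <- length(ages)
  center <- (min(ages) + max(ages)) / 2
  if (form == "none")
    return(list(form = form, X = matrix(0, L, 0), names = character(0),
                ages = ages, parent = parent, center = center))
  if (form == "car") {
    X <- diag(L)
    return(list(form = form, X = X,
                names = paste0(parent, "_", ages),
                ages = ages, parent = parent, center = center))
  }
  if (form == "linear") {
    X <- cbind(ages - center)
    return(list(form = form, X = X, names = paste0(parent, "_lin"),
                ages = ages, parent = parent, center = center))
  }
  if (form == "curvilinear") {
    cc <- ages - center
    X <- cbind(cc, cc^2)
    return(list(form = form, X = X,
                names = paste0(parent, c("_lin", "_quad")),
                ages = ages, parent = parent, center = center))
  }
  # category5: reference band is the youngest band present
  b <- band_of(ages, parent)
  present <- sort(unique(b))
  ref <- present[1]
  keep <- present[-1]
  X <- matrix(0, L, length(keep))
  for (i in seq_along(keep)) X[b == keep[i], i] <- 1
  list(form = form, X = X,
       names = paste0(parent, "_", age_bands(parent)$label[keep]),
       ages = ages, parent = parent, center = center, ref_band = ref)
}

# full parameter layout for a spec on given age grids
spec_layout <- function(spec) {
  m <- make_term(spec$maternal_form, spec$maternal_ages, "maternal")
  p <- make_term(spec$paternal_form, spec$paternal_ages, "paternal")
  list(maternal = m, paternal = p,
       names = c("(Intercept)", m$names, p$names),
       m_cols = if (ncol(m$X)) 1 + seq_len(ncol(m$X)) else integer(0),
       p_cols = if (ncol(p$X)) 1 + ncol(m$X) + seq_len(ncol(p$X))
                else integer(0))
}

#' Evaluate the linear predictor of a model
#'
#' Returns the log-odds `alpha + maternal term + paternal term` at given
#' age pairs, for a complete named parameter vector in the model's internal
#' parameterisation (linear/quadratic covariates centred at the midpoint of
#' the parent's age range; see [model_spec()]).
#'
#' @param spec a `parage_spec`.
#' @param params named numeric vector covering every parameter of `spec`
#'   (names as in the fitted object's `coef()`).
#' @param maternal_age,paternal_age integer ages (vectorised, recycled).
#'   Pass only the parent(s) present in the model.
#' @return numeric vector of log-odds.
#' @examples
#' sp <- model_spec("linear", "none")
#' linear_predictor(sp, c("(Intercept)" = -7, maternal_lin = 0.1),
#'                  maternal_age = 30)
#' @export
linear_predictor <- function(spec, params, maternal_age = NULL,
                             paternal_age = NULL) {
  stopifnot(inherits(spec, "parage_spec"))
  lay <- spec_layout(spec)
  if (!all(lay$names %in% names(params)))
    stop("params must contain: ", paste(lay$names, collapse = ", "))
  nm <- max(length(maternal_age), length(paternal_age), 1)
  eta <- rep(unname(params["(Intercept)"]), nm)
  add_term <- function(term, age, eta) {
    if (term$form == "none") return(eta)
    if (is.null(age)) stop(term$parent, " age required for this model")
    i <- match(age, term$ages)
    if (anyNA(i))
      stop(term$parent, " age outside the declared range ",
           min(term$ages), "-", max(term$ages))
    eta + drop(term$X[i, , drop = FALSE] %*% params[term$names])
  }
  eta <- add_term(lay$maternal, maternal_age, eta)
  eta <- add_term(lay$paternal, paternal_age, eta)
  unname(eta)
}
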