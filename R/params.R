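#' Vital-rate parameter set
#'
#' Container for every fixed effect, residual variance and dependence
#' parameter used by the eight vital-rate model variants.  A single
#' `vr_params` object can drive any model: parameters that a given model
#' does not use are simply never read by its evaluation functions.
#'
#' Vital rates are regressions on natural-log body mass `m`:
#' survival and reproduction are logistic (`logit^-1(b0 + bm * m)`),
#' growth and offspring size are Gaussian (`N(b0 + bm * m, sigma2)`).
#' Dependence parameters:
#'
#' * `beta_g_given_r`: additive shift of expected growth when the
#'   individual reproduces (reproduction-conditional model `D1a`).
#' * `alpha`: off-diagonal of the 2x2 correlation matrix of the Gaussian
#'   copula joining growth and reproduction (`D1b`).
#' * `beta_bq`, `beta_gq`: coefficients of a shared observed annual driver
#'   (e.g. winter NAO) on reproduction and growth (`D2a`).
#' * `nu2_b`, `nu2_g`, `rho`: variances and correlation of random year
#'   effects on reproduction and growth (`I2` has `rho = 0`, `D2b` frees it).
#' * `theta2_b`, `theta2_g`, `psi`: variances and correlation of persistent
#'   individual random effects (`I3` has `psi = 0`, `D3` frees it).
#'
#' @param beta_s0,beta_sm Survival intercept and log-mass slope (logit scale).
#' @param beta_b0,beta_bm Reproduction intercept and slope (logit scale).
#' @param beta_g0,beta_gm Growth intercept and slope (log-mass scale).
#' @param beta_h0,beta_hm Offspring-size intercept and slope (log-mass scale).
#' @param sigma2_g,sigma2_h Residual variances of growth and offspring size.
#' @param beta_g_given_r Growth shift when reproducing (model `D1a`).
#' @param alpha Copula correlation, in (-1, 1) (model `D1b`).
#' @param beta_bq,beta_gq Driver coefficients (model `D2a`).
#' @param nu2_b,nu2_g,rho Year-effect variances and correlation (`I2`/`D2b`).
#' @param theta2_b,theta2_g,psi Individual-effect variances and correlation
#'   (`I3`/`D3`).
#' @return An object of class `vr_params` (a named list).
#' @examples
#' p <- vr_params()
#' p$beta_s0
#' @export
vr_params <- function(beta_s0 = -4.25, beta_sm = 1.92,
                      beta_b0 = -1.47, beta_bm = 0.50,
                      beta_g0 = 1.20, beta_gm = 0.63,
                      beta_h0 = 0.46, beta_hm = 0.57,
                      sigma2_g = 0.09^2, sigma2_h = 0.2^2,
                      beta_g_given_r = 0,
                      alpha = 0,
                      beta_bq = 0, beta_gq = 0.01,
                      nu2_b = 0.45^2, nu2_g = 0.03^2, rho = 0,
                      theta2_b = 0.45^2, theta2_g = 0.03^2, psi = 0) {
  p <- list(
    beta_s0 = beta_s0, beta_sm = beta_sm,
    beta_b0 = beta_b0, beta_bm = beta_bm,
    beta_g0 = beta_g0, beta_gm = beta_gm,
    beta_h0 = beta_h0, beta_hm = beta_hm,
    sigma2_g = sigma2_g, sigma2_h = sigma2_h,
    beta_g_given_r = beta_g_given_r,
    alpha = alpha,
    beta_bq = beta_bq, beta_gq = beta_gq,
    nu2_b = nu2_b, nu2_g = nu2_g, rho = rho,
    theta2_b = theta2_b, theta2_g = theta2_g, psi = psi
  )
  class(p) <- "vr_params"
  validate_vr_params(p)
  p
}

validate_vr_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar", call. = FALSE)
  }
  for (nm in c("sigma2_g", "sigma2_h", "nu2_b", "nu2_g", "theta2_b", "theta2_g")) {
    if (p[[nm]] <= 0) stop("variance '", nm, "' must be strictly positive", call. = FALSE)
  }
  for (nm in c("rho", "psi", "alpha")) {
    if (abs(p[[nm]]) >= 1) stop("correlation '", nm, "' must lie in (-1, 1)", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.vr_params <- function(x, ...) {
  cat("<vr_params>\n")
  v <- unlist(x)
  print(round(v, 5))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named parameters replaced, after
#' re-validation.  Convenient for perturbation analysis and model nesting.
#'
#' @param params A [vr_params()] object.
#' @param ... Named scalar replacements, e.g. `rho = 0.5`.
#' @return A `vr_params` object.
#' @export
set_params <- function(params, ...) {
  stopifnot(inherits(params, "vr_params"))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  if (is.null(names(repl)) || any(names(repl) == "")) stop("replacements must be named")
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params[names(repl)] <- repl
  validate_vr_params(params)
  params
}

MODEL_IDS <- c("I1", "I2", "I3", "D1a", "D1b", "D2a", "D2b", "D3")

#' Vital-rate model specification
#'
#' Identifies one of the eight model variants and the structural options
#' of the reproduction-conditional model.
#'
#' Variants: `I1` (vanilla, mass only), `I2` (independent random year
#' effects on reproduction and growth), `I3` (independent persistent
#' individual effects), `D1a` (breeding status as a growth covariate),
#' `D1b` (Gaussian copula joining growth and reproduction), `D2a`
#' (shared observed driver), `D2b` (correlated random year effects),
#' `D3` (correlated individual effects).
#'
#' @param model_id One of `"I1"`, `"I2"`, `"I3"`, `"D1a"`, `"D1b"`,
#'   `"D2a"`, `"D2b"`, `"D3"`.
#' @param newborn_only Logical; if `TRUE` the `beta_g_given_r` growth shift
#'   of `D1a` is applied only to records flagged as first-year individuals
#'   (a case-study refinement).  Affects likelihoods and simulation; the
#'   projection kernel always uses the marginal mixture form.
#' @param r_lagged Logical; if `TRUE`, `D1a` conditions growth on the
#'   *previous* breeding status `r_t` instead of the current `r_{t+1}`.
#'   Defaults to `FALSE` (current status).
#' @return An object of class `ipm_model`.
#' @examples
#' model_spec("D2b")
#' @export
model_spec <- function(model_id, newborn_only = FALSE, r_lagged = FALSE) {
  model_id <- match.arg(model_id, MODEL_IDS)
  stopifnot(is.logical(newborn_only), length(newborn_only) == 1L,
            is.logical(r_lagged), length(r_lagged) == 1L)
  if ((newborn_only || r_lagged) && model_id != "D1a") {
    stop("newborn_only / r_lagged apply only to model D1a")
  }
  structure(list(model_id = model_id, newborn_only = newborn_only,
                 r_lagged = r_lagged),
            class = "ipm_model")
}

#' @export
print.ipm_model <- function(x, ...) {
  cat("<ipm_model> ", x$model_id, "\n", sep = "")
  if (x$newborn_only) cat("  beta_g_given_r restricted to newborns\n")
  if (x$r_lagged) cat("  growth conditioned on lagged breeding status\n")
  invisible(x)
}

as_model <- function(model) {
  if (inherits(model, "ipm_model")) return(model)
  if (is.character(model) && length(model) == 1L) return(model_spec(model))
  stop("'model' must be an ipm_model or a model id string")
}

#' Which structural features a model uses
#'
#' @param model Model id or [model_spec()] object.
#' @return Named logical vector with elements `year_effects` (latent year
#'   effects), `driver` (observed annual covariate), `indiv_effects`
#'   (persistent individual effects), `temporal` (any year-to-year
#'   variation, latent or observed).
#' @export
model_features <- function(model) {
  id <- as_model(model)$model_id
  c(year_effects = id %in% c("I2", "D2b"),
    driver = id == "D2a",
    indiv_effects = id %in% c("I3", "D3"),
    temporal = id %in% c("I2", "D2a", "D2b"))
}
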