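# Sensitivity and elasticity of the (stochastic) growth rate to
# vital-rate parameters, by central differencing:
#   d lambda_s / d beta ~ (lambda_s(beta + eps) - lambda_s(beta - eps)) / (2 eps)
# with eps = eps_rel * beta (default 0.005 * beta).  Elasticity multiplies
# by beta / lambda_s.  For temporal models the two perturbed evaluations
# reuse the same standard-normal innovations (common random numbers), so
# Monte-Carlo noise cancels to first order in the difference.

lambda_s_value <- function(model, params, mesh, L, L0, innovations) {
  model <- as_model(model)
  if (model_features(model)[["temporal"]]) {
    est <- stochastic_log_lambda(model, params, mesh, L = L, L0 = L0,
                                 innovations = innovations)
  } else {
    est <- eigen_log_lambda(build_kernel(model, params, mesh))
  }
  exp(est$log_lambda)
}

#' Sensitivity of the growth rate to a parameter
#'
#' Central-difference estimate of `d lambda_s / d beta` for any model
#' variant and any [vr_params()] parameter.
#'
#' @param model Model id or [model_spec()].
#' @param params A [vr_params()] object.
#' @param target Name of the parameter to perturb (e.g. `"beta_g0"`).
#' @param mesh Integration mesh matching the model.
#' @param eps_rel Relative step; the absolute step is `eps_rel * beta`.
#' @param eps Absolute step overriding `eps_rel` (required when the
#'   target parameter is exactly 0).
#' @param L,L0 Element-selection settings for temporal models.
#' @param seed Seed for the shared innovations of temporal models.
#' @return An object of class `perturbation_result` with fields
#'   `sensitivity`, `elasticity`, `lambda_s`, `eps`, and metadata
#'   (`method`, `common_random_numbers`).
#' @export
sensitivity <- function(model, params, target, mesh, eps_rel = 0.005,
                        eps = NULL, L = 10000, L0 = 1000, seed = NULL) {
  model <- as_model(model)
  if (!target %in% names(params)) stop("unknown parameter: ", target)
  beta <- params[[target]]
  if (is.null(eps)) {
    if (beta == 0) {
      stop("target parameter is 0; supply an absolute step via eps =")
    }
    eps <- abs(eps_rel * beta)
  }
  temporal <- model_features(model)[["temporal"]]
  innovations <- NULL
  if (temporal) {
    if (!is.null(seed)) set.seed(seed)
    innovations <- if (model$model_id == "D2a") rnorm(L) else matrix(rnorm(2 * L), L, 2)
  }
  lam0 <- lambda_s_value(model, params, mesh, L, L0, innovations)
  p_hi <- params; p_hi[[target]] <- beta + eps; validate_vr_params(p_hi)
  p_lo <- params; p_lo[[target]] <- beta - eps; validate_vr_params(p_lo)
  lam_hi <- lambda_s_value(model, p_hi, mesh, L, L0, innovations)
  lam_lo <- lambda_s_value(model, p_lo, mesh, L, L0, innovations)
  sens <- (lam_hi - lam_lo) / (2 * eps)
  structure(list(target = target, sensitivity = sens,
                 elasticity = sens * beta / lam0,
                 lambda_s = lam0, beta = beta, eps = eps,
                 method = if (temporal) "element_selection" else "eigen",
                 common_random_numbers = temporal),
            class = "perturbation_result")
}

#' Elasticity of the growth rate to a parameter
#'
#' `(d lambda_s / d beta) * beta / lambda_s`, computed from
#' [sensitivity()].
#'
#' @inheritParams sensitivity
#' @return A `perturbation_result` (see [sensitivity()]).
#' @export
elasticity <- function(model, params, target, mesh, eps_rel = 0.005,
                       eps = NULL, L = 10000, L0 = 1000, seed = NULL) {
  res <- sensitivity(model, params, target, mesh, eps_rel = eps_rel,
                     eps = eps, L = L, L0 = L0, seed = seed)
  if (res$lambda_s == 0) stop("lambda_s is 0; elasticity undefined")
  res
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result> ", x$target,
      ": sensitivity = ", signif(x$sensitivity, 6),
      ", elasticity = ", signif(x$elasticity, 6),
      " (", x$method,
      if (x$common_random_numbers) ", common random numbers" else "",
      ")\n", sep = "")
  invisible(x)
}

#' Check the copula/vanilla perturbation equivalence
#'
#' Because the Gaussian copula leaves the marginal vital rates untouched,
#' the `D1b` kernel -- and therefore its growth rate, sensitivities and
#' elasticities -- coincides with the vanilla `I1` kernel at identical
#' shared parameters, for any copula correlation `alpha`.  This function
#' verifies that numerically for a set of target parameters.
#'
#' @param params Shared [vr_params()] (the `alpha` slot sets the copula
#'   correlation of the `D1b` side).
#' @param mesh Integration mesh.
#' @param targets Parameters whose elasticities to compare.
#' @param tol Largest tolerated absolute discrepancy.
#' @return A list with `ok`, `max_abs_diff_elasticity`,
#'   `abs_diff_log_lambda`, and the per-target elasticity table.
#' @export
copula_invariance_check <- function(params, mesh,
                                    targets = c("beta_g0", "beta_gm",
                                                "beta_b0", "beta_bm"),
                                    tol = 1e-8) {
  ll_i1 <- eigen_log_lambda(build_kernel("I1", params, mesh))$log_lambda
  ll_d1b <- eigen_log_lambda(build_kernel("D1b", params, mesh))$log_lambda
  tab <- do.call(rbind, lapply(targets, function(tg) {
    e1 <- elasticity("I1", params, tg, mesh)$elasticity
    e2 <- elasticity("D1b", params, tg, mesh)$elasticity
    data.frame(target = tg, elasticity_I1 = e1, elasticity_D1b = e2,
               abs_diff = abs(e1 - e2))
  }))
  res <- list(ok = max(tab$abs_diff) < tol && abs(ll_i1 - ll_d1b) < tol,
              max_abs_diff_elasticity = max(tab$abs_diff),
              abs_diff_log_lambda = abs(ll_i1 - ll_d1b),
              table = tab)
  if (!res$ok) {
    warning("copula/vanilla equivalence violated: max elasticity gap ",
            signif(res$max_abs_diff_elasticity, 3), ", log-lambda gap ",
            signif(res$abs_diff_log_lambda, 3))
  }
  res
}
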