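# Vital-rate functions for all eight model variants.
#
# Every variant shares the same skeleton: logistic regressions on log body
# mass for survival and reproduction, Gaussian regressions for growth and
# offspring size.  The variants differ only in which extra term enters the
# reproduction and growth linear predictors (a latent year effect, an
# observed driver, or a persistent individual effect) and in whether growth
# and reproduction are tied together (breeding-status covariate or copula).

inv_logit <- function(x) plogis(x)

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("'", what, "' must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

# Extract the additive shift on the reproduction (`rate = "b"`) or growth
# (`rate = "g"`) linear predictor implied by `effects` under `model`.
effect_shift <- function(model, params, effects, rate) {
  id <- as_model(model)$model_id
  pick <- function(nm) {
    if (is.null(effects) || is.null(effects[[nm]])) {
      stop("model ", id, " requires effects$", nm, call. = FALSE)
    }
    effects[[nm]]
  }
  switch(id,
    I1 = , D1a = , D1b = 0,
    I2 = , D2b = if (rate == "b") pick("u_b") else pick("u_g"),
    I3 = , D3 = if (rate == "b") pick("v_b") else pick("v_g"),
    D2a = if (rate == "b") params$beta_bq * pick("q") else params$beta_gq * pick("q")
  )
}

#' Survival probability
#'
#' `logit^-1(beta_s0 + beta_sm * m)`.  Survival carries no random effects
#' in any model variant, so this function is common to all of them.
#'
#' @param m Log body mass (vectorized).
#' @param params A [vr_params()] object.
#' @return Survival probabilities in (0, 1).
#' @examples
#' survival_prob(2.5, vr_params())
#' @export
survival_prob <- function(m, params) {
  check_finite(m, "m")
  inv_logit(params$beta_s0 + params$beta_sm * m)
}

#' Reproduction probability
#'
#' `logit^-1(beta_b0 + beta_bm * m + shift)`, where the shift is the year
#' effect `u_b` (models `I2`/`D2b`), the individual effect `v_b`
#' (`I3`/`D3`), the driver term `beta_bq * q` (`D2a`), or zero
#' (`I1`/`D1a`/`D1b`).
#'
#' @inheritParams survival_prob
#' @param model Model id or [model_spec()].
#' @param effects Named list supplying whichever of `u_b`, `v_b`, `q` the
#'   model requires; may be `NULL` for models without effects.
#' @return Reproduction probabilities in (0, 1).
#' @export
reproduction_prob <- function(m, params, model = "I1", effects = NULL) {
  check_finite(m, "m")
  shift <- effect_shift(model, params, effects, "b")
  inv_logit(params$beta_b0 + params$beta_bm * m + shift)
}

#' Growth transition density
#'
#' Density of next log mass `m_next` given current `m`:
#' `N(beta_g0 + beta_gm * m + shift, sigma2_g)` with the model-specific
#' shift (`u_g`, `v_g`, `beta_gq * q`, or zero).
#'
#' @inheritParams reproduction_prob
#' @param m_next Next log body mass (vectorized).
#' @param log Return log density?
#' @return Density values (or log densities).
#' @export
growth_density <- function(m_next, m, params, model = "I1", effects = NULL,
                           log = FALSE) {
  check_finite(m_next, "m_next"); check_finite(m, "m")
  if (params$sigma2_g <= 0) stop("sigma2_g must be > 0")
  shift <- effect_shift(model, params, effects, "g")
  dnorm(m_next, params$beta_g0 + params$beta_gm * m + shift,
        sqrt(params$sigma2_g), log = log)
}

#' Offspring-size density
#'
#' Density of offspring log mass given parent log mass:
#' `N(beta_h0 + beta_hm * m, sigma2_h)`.  Identical across all variants
#' (offspring random effects, where present, are drawn independently of
#' the parent and handled by the kernel, not here).
#'
#' @inheritParams growth_density
#' @param c_next Offspring log body mass (vectorized).
#' @return Density values (or log densities).
#' @export
offspring_density <- function(c_next, m, params, log = FALSE) {
  check_finite(c_next, "c_next"); check_finite(m, "m")
  if (params$sigma2_h <= 0) stop("sigma2_h must be > 0")
  dnorm(c_next, params$beta_h0 + params$beta_hm * m, sqrt(params$sigma2_h),
        log = log)
}

#' Marginal growth density of the reproduction-conditional model (D1a)
#'
#' With breeding status as a growth covariate, the growth density marginal
#' over reproduction is a two-component Gaussian mixture:
#' `b(m) * N(mu + beta_g_given_r, sigma2_g) + (1 - b(m)) * N(mu, sigma2_g)`
#' with `mu = beta_g0 + beta_gm * m`.  The induced covariance between next
#' mass and breeding status is `beta_g_given_r * b(m) * (1 - b(m))`,
#' largest in magnitude at `b(m) = 0.5`.
#'
#' @inheritParams growth_density
#' @return Mixture density values.
#' @export
growth_marginal_d1a <- function(m_next, m, params, log = FALSE) {
  check_finite(m_next, "m_next"); check_finite(m, "m")
  b <- reproduction_prob(m, params)
  mu <- params$beta_g0 + params$beta_gm * m
  sg <- sqrt(params$sigma2_g)
  d <- b * dnorm(m_next, mu + params$beta_g_given_r, sg) +
    (1 - b) * dnorm(m_next, mu, sg)
  if (log) base::log(d) else d
}

## ---- Gaussian copula for a continuous + binary response pair -------------

# The binary response Y2 ~ Bernoulli(1 - q_fail) is made continuous by
# adding an independent U[0,1] auxiliary: Y3 = Y2 + X.  Its CDF F3 is
# piecewise linear, which lets a Gaussian copula join it to the continuous
# growth response Y1 ~ N(mu, sigma2).

#' Piecewise-linear CDF of the continuity-augmented binary response
#'
#' `F3(y3) = q * y3` on `[0, 1)` and `q + (1 - q) * (y3 - 1)` on `[1, 2]`,
#' with `q = Pr(Y2 = 0)`; 0 below, 1 above.
#'
#' @param y3 Augmented response values (vectorized).
#' @param q_fail Probability that the binary response equals 0, in `[0, 1]`.
#' @return CDF values in `[0, 1]`.
#' @export
copula_margin_cdf <- function(y3, q_fail) {
  if (!is.numeric(q_fail) || anyNA(q_fail) || any(q_fail < 0 | q_fail > 1)) {
    stop("q_fail must lie in [0, 1]")
  }
  check_finite(y3, "y3")
  out <- ifelse(y3 < 0, 0,
         ifelse(y3 < 1, q_fail * y3,
         ifelse(y3 <= 2, q_fail + (1 - q_fail) * (y3 - 1), 1)))
  out
}

# density f3 of Y3 (uniform mixture)
copula_margin_pdf <- function(y3, q_fail) {
  ifelse(y3 >= 0 & y3 < 1, q_fail,
  ifelse(y3 >= 1 & y3 <= 2, 1 - q_fail, 0))
}

# Probit transform of F3 with clamping: the joint density is undefined at
# CDF values exactly 0 or 1 (a measure-zero set); clamp to keep boundary
# evaluations finite.
probit_f3 <- function(y3, q_fail) {
  qnorm(pmin(pmax(copula_margin_cdf(y3, q_fail), 1e-12), 1 - 1e-12))
}

# log density of a standard bivariate normal with correlation a at (z1, z2)
log_dbvnorm <- function(z1, z2, a) {
  -log(2 * pi) - 0.5 * log1p(-a^2) -
    (z1^2 - 2 * a * z1 * z2 + z2^2) / (2 * (1 - a^2))
}

#' Joint density of the Gaussian copula model for (growth, reproduction)
#'
#' Density of `(Y1, Y3)` where `Y1 ~ N(mu, sigma2)` is the continuous
#' response, `Y3 = Y2 + X` is the continuity-augmented binary response,
#' and the dependence is a bivariate Gaussian copula with correlation
#' `alpha`.  The marginals are preserved for every `alpha`: integrating
#' out `y3` over `[0, 2]` returns exactly `N(mu, sigma2)`, and
#' `Pr(Y2 = 1)` remains `1 - q_fail`.
#'
#' @param y1 Continuous response values (vectorized with `y3`).
#' @param y3 Augmented binary response in `[0, 2]`.
#' @param mu,sigma2 Mean and variance of the continuous margin.
#' @param q_fail `Pr(Y2 = 0)`.
#' @param alpha Copula correlation, in (-1, 1).
#' @param log Return log density?
#' @return (Log) joint density values.
#' @export
copula_joint_density <- function(y1, y3, mu, sigma2, q_fail, alpha,
                                 log = FALSE) {
  if (abs(alpha) >= 1) stop("alpha must lie in (-1, 1)")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  sigma <- sqrt(sigma2)
  z1 <- (y1 - mu) / sigma
  z2 <- probit_f3(y3, q_fail)
  f3 <- copula_margin_pdf(y3, q_fail)
  ll <- log_dbvnorm(z1, z2, alpha) - base::log(sigma) + base::log(f3) -
    dnorm(z2, log = TRUE)
  ll[f3 == 0] <- -Inf
  if (log) ll else exp(ll)
}

#' Copula log-likelihood contribution of one growth/reproduction record
#'
#' Evaluates the log joint density of observed next mass `m_next` and
#' breeding status `r_next` under the copula model `D1b`, with
#' `mu = beta_g0 + beta_gm * m`, `q_fail = 1 - b(m)` and
#' `y3 = r_next + x_aux` (the sampled uniform auxiliary).
#'
#' @param m_next Observed next log mass.
#' @param r_next Breeding status in `{0, 1}`.
#' @param m Current log mass.
#' @param x_aux Uniform auxiliary in `[0, 1]` (one per record).
#' @param params A [vr_params()] object (uses `alpha`).
#' @return Log density values (vectorized).
#' @export
copula_loglik_record <- function(m_next, r_next, m, x_aux, params) {
  if (any(!(r_next %in% c(0, 1)))) stop("r_next must be in {0, 1}")
  if (any(x_aux < 0 | x_aux > 1)) stop("x_aux must lie in [0, 1]")
  mu <- params$beta_g0 + params$beta_gm * m
  q_fail <- 1 - reproduction_prob(m, params)
  copula_joint_density(m_next, r_next + x_aux, mu, params$sigma2_g,
                       q_fail, params$alpha, log = TRUE)
}
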