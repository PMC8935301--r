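# Individual-based simulation of demographic panel data under any model
# variant, plus the replicated simulation-study driver that compares
# models on log lambda_s and on the elasticity of the growth intercept.

#' Simulation-study design
#'
#' Bundles the study conditions: regression coefficients are drawn per
#' replicate from normal distributions centred on the Soay-sheep-like
#' values (`beta_s0 ~ N(-4.25, 0.05^2)`, `beta_sm ~ N(1.92, 0.01^2)`,
#' `beta_b0 ~ N(-1.47, 0.05^2)`, `beta_bm ~ N(0.50, 0.01^2)`,
#' `beta_g0 ~ N(1.20, 0.05^2)`, `beta_gm ~ N(0.63, 0.01^2)`,
#' `beta_h0 ~ N(0.46, 0.05^2)`, `beta_hm ~ N(0.57, 0.01^2)`), while
#' variances stay fixed (`beta_gq = 0.01`, `sigma2_g = 0.09^2`,
#' `sigma2_h = 0.2^2`, `nu2_g = 0.03^2`, `nu2_b = 0.45^2`,
#' `theta2_g = 0.03^2`, `theta2_b = 0.45^2`).  Dependence parameters are
#' toggled over `rho_values` / `psi_values` / `beta_bq_values`.
#'
#' @param models Model ids to evaluate (subset of the eight variants).
#' @param n_rep Number of replicates (default 100).
#' @param rho_values Year-effect correlations toggled for `I2`/`D2b`
#'   (`rho = 0` is `I2`).
#' @param psi_values Individual-effect correlations toggled for `I3`/`D3`.
#' @param beta_bq_values Reproduction driver coefficients toggled for `D2a`.
#' @param L,L0 Element-selection horizon and burn-in for temporal models.
#' @param n_mesh,n_z Mesh resolution (mass nodes; individual-effect nodes
#'   per axis for `I3`/`D3`).
#' @param elasticity Also compute the elasticity of `beta_g0` per model?
#' @return A `sim_design` list.
#' @export
sim_design <- function(models = c("I1", "I2", "I3", "D2a", "D2b", "D3"),
                       n_rep = 100,
                       rho_values = c(0, 0.5, 0.9),
                       psi_values = c(0, 0.5, 0.9),
                       beta_bq_values = c(0, 0.2, 0.4),
                       L = 10000, L0 = 1000,
                       n_mesh = 100, n_z = 7,
                       elasticity = TRUE) {
  stopifnot(n_rep >= 1)
  models <- vapply(models, function(m) as_model(m)$model_id, character(1))
  structure(list(models = unname(models), n_rep = n_rep,
                 rho_values = rho_values, psi_values = psi_values,
                 beta_bq_values = beta_bq_values,
                 L = L, L0 = L0, n_mesh = n_mesh, n_z = n_z,
                 elasticity = elasticity),
            class = "sim_design")
}

#' Draw one replicate's parameter set
#'
#' Regression coefficients from the study's normal distributions; all
#' variances at their fixed values; dependence parameters at zero (they
#' are toggled separately by the study driver).
#'
#' @param seed Optional integer seed.
#' @return A [vr_params()] object.
#' @examples
#' draw_parameters(seed = 1)
#' @export
draw_parameters <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vr_params(
    beta_s0 = rnorm(1, -4.25, 0.05), beta_sm = rnorm(1, 1.92, 0.01),
    beta_b0 = rnorm(1, -1.47, 0.05), beta_bm = rnorm(1, 0.50, 0.01),
    beta_g0 = rnorm(1, 1.20, 0.05), beta_gm = rnorm(1, 0.63, 0.01),
    beta_h0 = rnorm(1, 0.46, 0.05), beta_hm = rnorm(1, 0.57, 0.01)
  )
}

# Empty demographic records table (canonical column set).
empty_records <- function() {
  data.frame(id = integer(0), year = integer(0), m = numeric(0),
             a_next = integer(0), r_next = integer(0), m_next = numeric(0),
             c_next = numeric(0), newborn = logical(0))
}

#' Simulate a demographic panel
#'
#' Forward-simulates `n0` founder individuals for `T_years` under the
#' chosen model variant, producing one record per individual-year with
#' the fields used by the likelihoods: current log mass `m`, survival
#' indicator `a_next`, breeding indicator `r_next`, next log mass
#' `m_next` (survivors only), offspring log mass `c_next` (breeders
#' only), and a `newborn` flag (first full year of life).
#'
#' Year effects are drawn once per year (bivariate normal with
#' correlation `rho` for `D2b`; independent for `I2`); the driver
#' `q_t ~ N(-0.019, 1.09^2)` once per year for `D2a`; individual
#' effects once per individual at birth (bivariate with `psi` for `D3`),
#' with offspring effects independent of their parent's.  Under `D1b`
#' breeding status and growth are drawn jointly through the Gaussian
#' copula; under `D1a` growth is shifted by `beta_g_given_r` when the
#' individual breeds (optionally only for newborns).  Births are
#' singletons.
#'
#' Founder log masses are drawn from a normal approximation to the
#' stable size distribution of the vanilla kernel at the same
#' parameters, which keeps the panel near demographic equilibrium from
#' the first year.
#'
#' @param model Model id or [model_spec()].
#' @param params A [vr_params()] object.
#' @param n0 Number of founder individuals.
#' @param T_years Number of simulated transitions.
#' @param seed Optional integer seed.
#' @param missing_rate Fraction of observed `r_next` values masked as
#'   missing (emulates unrecorded breeding status; default 0).
#' @param max_pop Hard cap on live individuals (guards runaway growth).
#' @return A records data frame; the drawn year effects/driver values are
#'   attached as attribute `"year_conditions"` and individual effects (for
#'   `I3`/`D3`) as attribute `"individual_effects"`.
#' @export
simulate_population <- function(model, params, n0 = 300, T_years = 20,
                                seed = NULL, missing_rate = 0,
                                max_pop = 20000) {
  model <- as_model(model)
  id <- model$model_id
  feats <- model_features(model)
  stopifnot(n0 >= 1, T_years >= 1)
  if (!is.null(seed)) set.seed(seed)

  # founder sizes from the stable distribution of the vanilla kernel
  mesh0 <- make_mesh(params = params, n = 80)
  w <- eigen_log_lambda(build_kernel("I1", params, mesh0))$w
  mu0 <- sum(mesh0$x * w)
  sd0 <- sqrt(sum((mesh0$x - mu0)^2 * w))

  sg <- sqrt(params$sigma2_g); sh <- sqrt(params$sigma2_h)

  draw_indiv_effects <- function(k) {
    if (!feats[["indiv_effects"]]) return(NULL)
    tb <- sqrt(params$theta2_b); tg <- sqrt(params$theta2_g)
    z1 <- rnorm(k); z2 <- rnorm(k)
    v_b <- tb * z1
    v_g <- tg * (params$psi * z1 + sqrt(1 - params$psi^2) * z2)
    cbind(v_b = v_b, v_g = v_g)
  }

  # live individual state
  ids <- seq_len(n0)
  mass <- rnorm(n0, mu0, sd0)
  born <- rep(-1L, n0)         # founders: age unknown, never flagged newborn
  vz <- draw_indiv_effects(n0)
  next_id <- n0 + 1L
  all_v <- vz

  if (feats[["temporal"]]) {
    cond <- draw_year_conditions(model, params, T_years)
  }

  rows <- vector("list", T_years)
  for (t in seq_len(T_years)) {
    k <- length(ids)
    if (k == 0L) {
      warning("population extinct after year ", t - 1L, "; table truncated")
      break
    }
    u_b <- u_g <- 0; q_t <- NULL
    if (feats[["year_effects"]]) { u_b <- cond$u[t, 1]; u_g <- cond$u[t, 2] }
    if (feats[["driver"]]) q_t <- cond$q[t]

    eta_b <- params$beta_b0 + params$beta_bm * mass
    mu_g <- params$beta_g0 + params$beta_gm * mass
    if (feats[["year_effects"]]) { eta_b <- eta_b + u_b; mu_g <- mu_g + u_g }
    if (feats[["driver"]]) {
      eta_b <- eta_b + params$beta_bq * q_t
      mu_g <- mu_g + params$beta_gq * q_t
    }
    if (feats[["indiv_effects"]]) {
      eta_b <- eta_b + vz[, "v_b"]
      mu_g <- mu_g + vz[, "v_g"]
    }
    b <- inv_logit(eta_b)
    s <- survival_prob(mass, params)

    alive <- rbinom(k, 1L, s)
    r_next <- rep(NA_integer_, k)
    m_next <- rep(NA_real_, k)
    c_next <- rep(NA_real_, k)
    surv <- alive == 1L
    ns <- sum(surv)
    if (ns > 0) {
      if (id == "D1b") {
        # joint draw through the Gaussian copula: r = 1 iff the uniform
        # implied by the second Gaussian coordinate exceeds q_fail = 1 - b
        z1 <- rnorm(ns); z2 <- rnorm(ns)
        a <- params$alpha
        zc <- a * z1 + sqrt(1 - a^2) * z2
        m_next[surv] <- mu_g[surv] + sg * z1
        r_next[surv] <- as.integer(pnorm(zc) > (1 - b[surv]))
      } else {
        r_next[surv] <- rbinom(ns, 1L, b[surv])
        shift <- 0
        if (id == "D1a") {
          eligible <- if (model$newborn_only) born[surv] == t - 1L else TRUE
          shift <- params$beta_g_given_r * (r_next[surv] == 1L) * eligible
        }
        m_next[surv] <- rnorm(ns, mu_g[surv] + shift, sg)
      }
      breeders <- which(surv & r_next == 1L)
      nb <- length(breeders)
      if (nb > 0) c_next[breeders] <- rnorm(nb, params$beta_h0 + params$beta_hm * mass[breeders], sh)
    }

    # masking hides the breeding record (and the offspring link) from the
    # observer; the lamb itself still recruits into the population
    r_obs <- r_next; c_obs <- c_next
    obs_r <- !is.na(r_next)
    if (missing_rate > 0 && any(obs_r)) {
      mask <- obs_r & runif(k) < missing_rate
      r_obs[mask] <- NA_integer_
      c_obs[mask] <- NA_real_
    }

    rows[[t]] <- data.frame(id = ids, year = t, m = mass,
                            a_next = alive, r_next = r_obs,
                            m_next = m_next, c_next = c_obs,
                            newborn = born == t - 1L)

    # advance: survivors keep identity; each breeder recruits one newborn
    rec <- which(surv & !is.na(c_next))
    new_mass <- c_next[rec]
    n_new <- length(new_mass)
    keep <- which(surv)
    ids2 <- ids[keep]; mass2 <- m_next[keep]; born2 <- born[keep]
    vz2 <- if (feats[["indiv_effects"]]) vz[keep, , drop = FALSE] else NULL
    if (n_new > 0 && length(ids2) + n_new <= max_pop) {
      new_ids <- next_id:(next_id + n_new - 1L)
      next_id <- next_id + n_new
      ids2 <- c(ids2, new_ids)
      mass2 <- c(mass2, new_mass)
      born2 <- c(born2, rep(t, n_new))
      if (feats[["indiv_effects"]]) {
        vz_new <- draw_indiv_effects(n_new)
        vz2 <- rbind(vz2, vz_new)
        all_v <- rbind(all_v, vz_new)
      }
    }
    ids <- ids2; mass <- mass2; born <- born2; vz <- vz2
  }

  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_records()
  rownames(out) <- NULL
  if (feats[["temporal"]]) {
    attr(out, "year_conditions") <- if (feats[["driver"]]) cond$q else cond$u
  }
  if (feats[["indiv_effects"]]) attr(out, "individual_effects") <- all_v
  out
}

# log lambda_s for one (model, params, dependence value) under the study
# machinery; shared innovations may be supplied for paired comparisons.
study_log_lambda <- function(model_id, params, design, innovations = NULL) {
  model <- model_spec(model_id)
  feats <- model_features(model)
  if (feats[["temporal"]]) {
    mesh <- make_mesh(params = params, n = design$n_mesh, model = model)
    stochastic_log_lambda(model, params, mesh, L = design$L, L0 = design$L0,
                          innovations = innovations)$log_lambda
  } else {
    mesh <- make_mesh(params = params, n = design$n_mesh,
                      n_z = if (feats[["indiv_effects"]]) design$n_z else 0,
                      model = model)
    eigen_log_lambda(build_kernel(model, params, mesh))$log_lambda
  }
}

study_elasticity_g0 <- function(model_id, params, design, seed) {
  model <- model_spec(model_id)
  feats <- model_features(model)
  mesh <- make_mesh(params = params, n = design$n_mesh,
                    n_z = if (feats[["indiv_effects"]]) design$n_z else 0,
                    model = model)
  elasticity(model, params, "beta_g0", mesh,
             L = design$L, L0 = design$L0, seed = seed)$elasticity
}

#' Run the replicated model-comparison study
#'
#' For each replicate: draw one shared coefficient set
#' ([draw_parameters()]), then evaluate every requested model variant on
#' it -- `I1`/`D1a`/`D1b` by eigenanalysis, `I2`/`D2a`/`D2b` by
#' element-selection (with innovations shared across dependence values so
#' comparisons are paired), `I3`/`D3` by extended-state eigenanalysis --
#' recording `log lambda_s`, its difference from `I1`, and (optionally)
#' the percent change of the elasticity of `beta_g0` relative to `I1`.
#'
#' @param design A [sim_design()].
#' @param seed Integer seed; replicate `r` uses an RNG stream derived
#'   from `seed + r`.
#' @return A long data frame with columns `rep`, `model`, `dep_param`,
#'   `dep_value`, `log_lambda`, `diff_vs_I1`, `elasticity_g0`,
#'   `pct_change_elasticity_g0`.
#' @export
run_simulation_study <- function(design = sim_design(), seed = 1) {
  stopifnot(inherits(design, "sim_design"))
  out <- vector("list", design$n_rep)
  for (r in seq_len(design$n_rep)) {
    set.seed(seed + r)
    params <- draw_parameters()
    # reference model I1
    ll_i1 <- study_log_lambda("I1", params, design)
    e_i1 <- if (design$elasticity) study_elasticity_g0("I1", params, design, seed + r) else NA_real_

    rows <- list(data.frame(rep = r, model = "I1", dep_param = NA_character_,
                            dep_value = NA_real_, log_lambda = ll_i1,
                            elasticity_g0 = e_i1))
    # shared innovations for all temporal variants of this replicate
    innov_u <- matrix(rnorm(2 * design$L), design$L, 2)
    innov_q <- rnorm(design$L)

    for (mid in setdiff(design$models, "I1")) {
      vals <- switch(mid,
        I2 = 0, D2b = design$rho_values,
        I3 = 0, D3 = design$psi_values,
        D2a = design$beta_bq_values,
        D1a = params$beta_g_given_r, D1b = params$alpha)
      dep <- switch(mid, I2 = "rho", D2b = "rho", I3 = "psi", D3 = "psi",
                    D2a = "beta_bq", D1a = "beta_g_given_r", D1b = "alpha")
      for (v in vals) {
        p <- switch(dep,
                    rho = set_params(params, rho = v),
                    psi = set_params(params, psi = v),
                    beta_bq = set_params(params, beta_bq = v),
                    beta_g_given_r = set_params(params, beta_g_given_r = v),
                    alpha = set_params(params, alpha = v))
        innov <- if (mid %in% c("I2", "D2b")) innov_u else
                 if (mid == "D2a") innov_q else NULL
        ll <- study_log_lambda(mid, p, design, innovations = innov)
        el <- if (design$elasticity) study_elasticity_g0(mid, p, design, seed + r) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          rep = r, model = mid, dep_param = dep, dep_value = v,
          log_lambda = ll, elasticity_g0 = el)
      }
    }
    tab <- do.call(rbind, rows)
    tab$diff_vs_I1 <- tab$log_lambda - ll_i1
    tab$pct_change_elasticity_g0 <-
      if (design$elasticity) 100 * (tab$elasticity_g0 - e_i1) / e_i1 else NA_real_
    out[[r]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
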