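# Bayesian fitting of the vital-rate models by adaptive random-walk
# Metropolis within Gibbs.
#
# Sampled blocks: survival coefficients; offspring-size coefficients and
# residual SD; the reproduction/growth block (coefficients, residual SD,
# and the model's dependence parameter); random-effect vectors (updated
# jointly per year or per individual, vectorized across units); year- or
# individual-effect hyperparameters; and the per-record copula
# auxiliaries of D1b.  Log-mass covariates are centred internally so that
# intercept and slope mix independently; draws are transformed back to
# the natural parameterization before storage.  Proposal scales adapt
# toward a 44% acceptance rate during burn-in only.

#' MCMC configuration
#'
#' @param n_iter Total iterations per chain.
#' @param n_burnin Burn-in iterations discarded (and used for adaptation).
#' @param n_chains Number of chains (>= 2 recommended for diagnostics).
#' @param seed Top-level integer seed; chain `c` uses `seed + c`.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param store_effects Also store thinned random-effect draws?
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 20000, n_burnin = 5000, n_chains = 3,
                        seed = 1, thin = 1, store_effects = FALSE) {
  if (n_burnin >= n_iter) stop("need n_burnin < n_iter")
  structure(list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 thin = as.integer(thin), store_effects = store_effects),
            class = "mcmc_config")
}

#' Prior configuration
#'
#' Weakly informative defaults: Normal(0, `coef_sd`^2) on regression
#' coefficients (applied on the centred-covariate scale), half-Normal(0,
#' `sd_scale`^2) on residual and random-effect SDs, Uniform(-1, 1) on the
#' correlations `rho`, `psi`, `alpha`.
#'
#' @param coef_sd Prior SD of regression coefficients.
#' @param sd_scale Scale of the half-normal priors on SD parameters.
#' @return A `prior_config` list.
#' @export
prior_config <- function(coef_sd = 10, sd_scale = 5) {
  structure(list(coef_sd = coef_sd, sd_scale = sd_scale),
            class = "prior_config")
}

lp_coef <- function(x, priors) dnorm(x, 0, priors$coef_sd, log = TRUE)
# log prior of log-SD parameter ls (half-normal on sd, with Jacobian)
lp_logsd <- function(ls, priors) {
  dnorm(exp(ls), 0, priors$sd_scale, log = TRUE) + log(2) + ls
}

# bivariate normal log density of effect pairs (vectorized over rows)
lp_pairs <- function(E, sb, sg, corr) {
  zb <- E[, 1] / sb; zg <- E[, 2] / sg
  -log(2 * pi) - log(sb * sg) - 0.5 * log1p(-corr^2) -
    (zb^2 - 2 * corr * zb * zg + zg^2) / (2 * (1 - corr^2))
}

#' Fit a vital-rate model by MCMC
#'
#' Runs `n_chains` adaptive Metropolis-within-Gibbs chains for any of the
#' eight model variants, marginalizing missing breeding records
#' analytically and sampling random effects (and, for `D1b`, per-record
#' uniform copula auxiliaries) as unobserved parameters.
#'
#' @param model Model id or [model_spec()].
#' @param records Demographic records data frame (see
#'   [validate_records()]).
#' @param mcmc An [mcmc_config()].
#' @param priors A [prior_config()].
#' @param driver Named numeric vector of annual driver values (names =
#'   years) for model `D2a`.
#' @param verbose Print a progress line per chain?
#' @return A `posterior_samples` object: post-burn-in thinned draws on the
#'   natural parameter scale (`draws`, with a `chain` column), the
#'   Brooks-Gelman-Rubin statistic per parameter (`rhat`, when
#'   `n_chains >= 2`), posterior means of random effects, and the
#'   configuration used.
#' @export
fit_ipm <- function(model, records, mcmc = mcmc_config(),
                    priors = prior_config(), driver = NULL, verbose = FALSE) {
  model <- as_model(model)
  id <- model$model_id
  feats <- model_features(model)
  records <- validate_records(records)
  if (nrow(records) == 0) stop("records table is empty")
  if (feats[["driver"]]) {
    if (is.null(driver) || is.null(names(driver))) {
      stop("model D2a needs a named driver vector (names = years)")
    }
    if (!all(as.character(records$year) %in% names(driver))) {
      stop("driver values missing for some record years")
    }
  }

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch)
    chains[[ch]] <- run_chain(model, records, mcmc, priors, driver,
                              chain_id = ch, verbose = verbose)
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  rhat <- if (mcmc$n_chains >= 2) {
    gelman_rubin_matrixes(lapply(chains, function(c)
      as.matrix(c$draws[setdiff(names(c$draws), c("chain", "iter"))])))
  } else NULL
  structure(list(model_id = id, draws = draws, rhat = rhat,
                 effects_mean = chains[[1]]$effects_mean,
                 effects_draws = if (mcmc$store_effects)
                   lapply(chains, `[[`, "effects_draws") else NULL,
                 mcmc = mcmc, priors = priors,
                 acceptance = chains[[1]]$acceptance),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> model ", x$model_id, ": ",
      nrow(x$draws), " draws x ", ncol(x$draws) - 2L, " parameters",
      sep = "")
  if (!is.null(x$rhat)) {
    cat("; max Rhat = ", round(max(x$rhat), 3),
        if (max(x$rhat) < 1.05) " (converged)" else " (NOT converged)", sep = "")
  }
  cat("\n")
  invisible(x)
}

# ---- single chain ---------------------------------------------------------

run_chain <- function(model, records, mcmc, priors, driver, chain_id,
                      verbose = FALSE) {
  id <- model$model_id
  feats <- model_features(model)
  n_rec <- nrow(records)
  mbar <- mean(records$m)
  rec <- records
  rec$m <- rec$m - mbar   # centred covariate

  years <- sort(unique(rec$year))
  ids <- sort(unique(rec$id))
  t_idx <- match(rec$year, years)
  j_idx <- match(rec$id, ids)
  Ty <- length(years); J <- length(ids)

  q_rec <- if (feats[["driver"]]) unname(driver[as.character(records$year)]) else NULL

  # ---- initial values from per-rate regressions -------------------------
  init <- chain_inits(id, rec, chain_id)
  st <- init$state          # named numeric vector of sampled parameters
  u <- matrix(0, Ty, 2)     # year effects (b, g)
  v <- matrix(0, J, 2)      # individual effects (b, g)
  x_aux <- rep(0.5, n_rec)  # copula auxiliaries

  has_r <- !is.na(rec$r_next); has_g <- !is.na(rec$m_next)
  cop_set <- which(has_r & has_g)   # records carrying a copula auxiliary

  # precomputed response subsets for the fast block likelihoods
  sidx <- which(!is.na(rec$a_next)); cidx <- which(!is.na(rec$c_next))
  ridx <- which(has_r); gidx <- which(has_g)
  m_s <- rec$m[sidx]; sgn_s <- ifelse(rec$a_next[sidx] == 1, 1, -1)
  m_c <- rec$m[cidx]; c_c <- rec$c_next[cidx]
  m_r <- rec$m[ridx]; sgn_r <- ifelse(rec$r_next[ridx] == 1, 1, -1)
  m_g <- rec$m[gidx]; mn_g <- rec$m_next[gidx]
  t_r <- t_idx[ridx]; t_g <- t_idx[gidx]
  j_r <- j_idx[ridx]; j_g <- j_idx[gidx]
  q_r <- q_rec[ridx]; q_g <- q_rec[gidx]
  LOG2PI <- log(2 * pi)
  joint_rg <- id %in% c("D1a", "D1b")   # models needing the generic path

  # per-record shifts implied by current effects and state
  shifts_fun <- function(p, u, v) {
    if (feats[["year_effects"]]) {
      list(b = u[t_idx, 1], g = u[t_idx, 2])
    } else if (feats[["indiv_effects"]]) {
      list(b = v[j_idx, 1], g = v[j_idx, 2])
    } else if (feats[["driver"]]) {
      list(b = p$beta_bq * q_rec, g = p$beta_gq * q_rec)
    } else list(b = numeric(n_rec), g = numeric(n_rec))
  }

  # unvalidated parameter view of the sampled state (support constraints
  # are enforced by proposal rejection, variances by the log transform)
  params_of <- function(st) {
    list(beta_s0 = st[["beta_s0"]], beta_sm = st[["beta_sm"]],
         beta_b0 = st[["beta_b0"]], beta_bm = st[["beta_bm"]],
         beta_g0 = st[["beta_g0"]], beta_gm = st[["beta_gm"]],
         beta_h0 = st[["beta_h0"]], beta_hm = st[["beta_hm"]],
         sigma2_g = exp(2 * st[["lsg"]]), sigma2_h = exp(2 * st[["lsh"]]),
         beta_g_given_r = st["beta_g_given_r"] %|% 0,
         alpha = st["alpha"] %|% 0,
         beta_bq = st["beta_bq"] %|% 0, beta_gq = st["beta_gq"] %|% 0.01,
         rho = st["rho"] %|% 0, psi = st["psi"] %|% 0)
  }

  fast_surv <- function(st) {
    eta <- st[["beta_s0"]] + st[["beta_sm"]] * m_s
    sum(plogis(sgn_s * eta, log.p = TRUE))
  }
  fast_off <- function(st) {
    mu <- st[["beta_h0"]] + st[["beta_hm"]] * m_c
    sh <- exp(st[["lsh"]])
    -length(m_c) * (st[["lsh"]] + 0.5 * LOG2PI) -
      sum((c_c - mu)^2) / (2 * sh^2)
  }
  ll_rg_vec <- function(st, u, v, x_aux) {
    if (joint_rg) {
      p <- params_of(st)
      return(ll_repro_growth_vec(model, p, rec, shifts_fun(p, u, v),
                                 x_aux = x_aux))
    }
    out <- numeric(n_rec)
    if (feats[["year_effects"]]) {
      shift_br <- u[t_r, 1]; shift_gg <- u[t_g, 2]
    } else if (feats[["indiv_effects"]]) {
      shift_br <- v[j_r, 1]; shift_gg <- v[j_g, 2]
    } else if (feats[["driver"]]) {
      shift_br <- (st["beta_bq"] %|% 0) * q_r
      shift_gg <- (st["beta_gq"] %|% 0) * q_g
    } else {
      shift_br <- 0; shift_gg <- 0
    }
    eta <- st[["beta_b0"]] + st[["beta_bm"]] * m_r + shift_br
    out[ridx] <- plogis(sgn_r * eta, log.p = TRUE)
    mu <- st[["beta_g0"]] + st[["beta_gm"]] * m_g + shift_gg
    sg <- exp(st[["lsg"]])
    out[gidx] <- out[gidx] - (st[["lsg"]] + 0.5 * LOG2PI) -
      (mn_g - mu)^2 / (2 * sg^2)
    out
  }

  # adaptive scales
  sc <- init$scales
  adapt <- function(name, acc, iter) {
    gam <- min(0.2, 2 / sqrt(iter))
    sc[[name]] <<- sc[[name]] * exp(gam * (acc - 0.44))
  }

  n_store <- (mcmc$n_iter - mcmc$n_burnin) %/% mcmc$thin
  par_names <- names(st)
  stored <- matrix(NA_real_, n_store, length(par_names),
                   dimnames = list(NULL, par_names))
  eff_sum <- list(u = u * 0, v = v * 0, n = 0L)
  eff_draws <- if (mcmc$store_effects) vector("list", n_store) else NULL
  acc_count <- setNames(numeric(length(sc)), names(sc))
  acc_tries <- setNames(numeric(length(sc)), names(sc))
  k_store <- 0L

  # cached log-likelihood pieces
  ll_s <- fast_surv(st)
  ll_h <- fast_off(st)
  ll_rg <- ll_rg_vec(st, u, v, x_aux)
  if (!all(is.finite(c(ll_s, ll_h))) || !all(is.finite(ll_rg))) {
    stop("non-finite log-likelihood at initial state")
  }

  scalar_update <- function(name, block, iter) {
    prop <- st
    prop[[name]] <- st[[name]] + sc[[name]] * rnorm(1)
    if (name %in% c("rho", "psi", "alpha") && abs(prop[[name]]) >= 1) {
      acc_tries[name] <<- acc_tries[name] + 1
      if (iter <= mcmc$n_burnin) adapt(name, 0, iter)
      return(invisible(NULL))
    }
    lp_old <- prior_of(name, st, priors)
    lp_new <- prior_of(name, prop, priors)
    if (block == "surv") {
      new_ll <- fast_surv(prop)
      ratio <- new_ll - ll_s + lp_new - lp_old
      if (is.finite(ratio) && log(runif(1)) < ratio) {
        st <<- prop; ll_s <<- new_ll
        acc_count[name] <<- acc_count[name] + 1
      }
    } else if (block == "off") {
      new_ll <- fast_off(prop)
      ratio <- new_ll - ll_h + lp_new - lp_old
      if (is.finite(ratio) && log(runif(1)) < ratio) {
        st <<- prop; ll_h <<- new_ll
        acc_count[name] <<- acc_count[name] + 1
      }
    } else if (block == "rg") {
      new_vec <- ll_rg_vec(prop, u, v, x_aux)
      ratio <- sum(new_vec) - sum(ll_rg) + lp_new - lp_old
      if (is.finite(ratio) && log(runif(1)) < ratio) {
        st <<- prop; ll_rg <<- new_vec
        acc_count[name] <<- acc_count[name] + 1
      }
    } else if (block == "hyper_u") {
      lpr_old <- sum(lp_pairs(u, exp(st["lnb"] %|% 0), exp(st["lng"] %|% 0),
                              st["rho"] %|% 0))
      lpr_new <- sum(lp_pairs(u, exp(prop["lnb"] %|% 0), exp(prop["lng"] %|% 0),
                              prop["rho"] %|% 0))
      ratio <- lpr_new - lpr_old + lp_new - lp_old
      if (is.finite(ratio) && log(runif(1)) < ratio) {
        st <<- prop
        acc_count[name] <<- acc_count[name] + 1
      }
    } else if (block == "hyper_v") {
      lpr_old <- sum(lp_pairs(v, exp(st["ltb"] %|% 0), exp(st["ltg"] %|% 0),
                              st["psi"] %|% 0))
      lpr_new <- sum(lp_pairs(v, exp(prop["ltb"] %|% 0), exp(prop["ltg"] %|% 0),
                              prop["psi"] %|% 0))
      ratio <- lpr_new - lpr_old + lp_new - lp_old
      if (is.finite(ratio) && log(runif(1)) < ratio) {
        st <<- prop
        acc_count[name] <<- acc_count[name] + 1
      }
    }
    acc_tries[name] <<- acc_tries[name] + 1
    if (iter <= mcmc$n_burnin) {
      adapt(name, as.numeric(st[[name]] == prop[[name]]), iter)
    }
    invisible(NULL)
  }

  effect_update <- function(iter) {
    if (feats[["year_effects"]]) {
      E <- u; grp <- t_idx
      sb <- exp(st["lnb"] %|% 0); sg_ <- exp(st["lng"] %|% 0)
      corr <- st["rho"] %|% 0
      key <- "u_scale"
    } else {
      E <- v; grp <- j_idx
      sb <- exp(st["ltb"] %|% 0); sg_ <- exp(st["ltg"] %|% 0)
      corr <- st["psi"] %|% 0
      key <- "v_scale"
    }
    nE <- nrow(E)
    Ep <- E + sc[[key]] * matrix(rnorm(2 * nE), nE, 2)
    old_by <- rowsum_safe(ll_rg, grp, nE)
    new_vec <- if (feats[["year_effects"]]) ll_rg_vec(st, Ep, v, x_aux)
               else ll_rg_vec(st, u, Ep, x_aux)
    new_by <- rowsum_safe(new_vec, grp, nE)
    ratio <- (new_by + lp_pairs(Ep, sb, sg_, corr)) -
             (old_by + lp_pairs(E, sb, sg_, corr))
    acc <- log(runif(nE)) < ratio & is.finite(ratio)
    E[acc, ] <- Ep[acc, ]
    if (feats[["year_effects"]]) u <<- E else v <<- E
    touched <- grp %in% which(acc)
    ll_rg[touched] <<- new_vec[touched]
    acc_count[key] <<- acc_count[key] + mean(acc)
    acc_tries[key] <<- acc_tries[key] + 1
    if (iter <= mcmc$n_burnin) adapt(key, mean(acc), iter)
  }

  # translation move: shift an intercept and the matching effects in
  # opposite directions; the likelihood is invariant, only priors change
  sweep_update <- function(coord, iter) {
    E <- if (feats[["year_effects"]]) u else v
    sb <- if (feats[["year_effects"]]) exp(st["lnb"] %|% 0) else exp(st["ltb"] %|% 0)
    sgv <- if (feats[["year_effects"]]) exp(st["lng"] %|% 0) else exp(st["ltg"] %|% 0)
    corr <- if (feats[["year_effects"]]) st["rho"] %|% 0 else st["psi"] %|% 0
    key <- paste0("sweep_", coord)
    delta <- sc[[key]] * rnorm(1)
    icol <- if (coord == "b") 1 else 2
    iname <- if (coord == "b") "beta_b0" else "beta_g0"
    Ep <- E; Ep[, icol] <- E[, icol] - delta
    prop <- st; prop[[iname]] <- st[[iname]] + delta
    ratio <- sum(lp_pairs(Ep, sb, sgv, corr)) - sum(lp_pairs(E, sb, sgv, corr)) +
      lp_coef(prop[[iname]], priors) - lp_coef(st[[iname]], priors)
    if (is.finite(ratio) && log(runif(1)) < ratio) {
      st <<- prop
      if (feats[["year_effects"]]) u <<- Ep else v <<- Ep
      acc_count[key] <<- acc_count[key] + 1
    }
    acc_tries[key] <<- acc_tries[key] + 1
    if (iter <= mcmc$n_burnin) {
      adapt(key, as.numeric(st[[iname]] == prop[[iname]]), iter)
    }
  }

  # interweaving scale move: multiply one effect coordinate and its SD by
  # a common factor; the standardized effect prior cancels exactly, so the
  # ratio involves only the data likelihood and the SD prior -- this
  # decouples the effect-variance parameters from the funnel
  scale_update <- function(coord, iter) {
    key <- paste0("scale_", coord)
    lname <- if (feats[["year_effects"]]) {
      if (coord == "b") "lnb" else "lng"
    } else {
      if (coord == "b") "ltb" else "ltg"
    }
    icol <- if (coord == "b") 1 else 2
    eps <- sc[[key]] * rnorm(1)
    prop <- st
    prop[[lname]] <- st[[lname]] + eps
    if (feats[["year_effects"]]) {
      Ep <- u; Ep[, icol] <- u[, icol] * exp(eps)
      new_vec <- ll_rg_vec(st, Ep, v, x_aux)
    } else {
      Ep <- v; Ep[, icol] <- v[, icol] * exp(eps)
      new_vec <- ll_rg_vec(st, u, Ep, x_aux)
    }
    ratio <- sum(new_vec) - sum(ll_rg) +
      lp_logsd(prop[[lname]], priors) - lp_logsd(st[[lname]], priors)
    if (is.finite(ratio) && log(runif(1)) < ratio) {
      st <<- prop; ll_rg <<- new_vec
      if (feats[["year_effects"]]) u <<- Ep else v <<- Ep
      acc_count[key] <<- acc_count[key] + 1
    }
    acc_tries[key] <<- acc_tries[key] + 1
    if (iter <= mcmc$n_burnin) {
      adapt(key, as.numeric(st[[lname]] == prop[[lname]]), iter)
    }
  }

  aux_update <- function() {
    if (length(cop_set) == 0) return(invisible(NULL))
    xp <- x_aux
    xp[cop_set] <- runif(length(cop_set))
    new_vec <- ll_rg_vec(st, u, v, xp)
    ratio <- new_vec[cop_set] - ll_rg[cop_set]
    acc <- log(runif(length(cop_set))) < ratio & is.finite(ratio)
    idx <- cop_set[acc]
    x_aux[idx] <<- xp[idx]
    ll_rg[idx] <<- new_vec[idx]
  }

  rg_names <- init$rg_names
  for (iter in seq_len(mcmc$n_iter)) {
    scalar_update("beta_s0", "surv", iter)
    scalar_update("beta_sm", "surv", iter)
    scalar_update("beta_h0", "off", iter)
    scalar_update("beta_hm", "off", iter)
    scalar_update("lsh", "off", iter)
    for (nm in rg_names) scalar_update(nm, "rg", iter)
    if (feats[["year_effects"]]) {
      effect_update(iter)
      scalar_update("lnb", "hyper_u", iter)
      scalar_update("lng", "hyper_u", iter)
      if (id == "D2b") scalar_update("rho", "hyper_u", iter)
      sweep_update("b", iter); sweep_update("g", iter)
      scale_update("b", iter); scale_update("g", iter)
    }
    if (feats[["indiv_effects"]]) {
      effect_update(iter)
      scalar_update("ltb", "hyper_v", iter)
      scalar_update("ltg", "hyper_v", iter)
      if (id == "D3") scalar_update("psi", "hyper_v", iter)
      sweep_update("b", iter); sweep_update("g", iter)
      scale_update("b", iter); scale_update("g", iter)
    }
    if (id == "D1b") aux_update()

    if (iter > mcmc$n_burnin) {
      eff_sum$u <- eff_sum$u + u; eff_sum$v <- eff_sum$v + v
      eff_sum$n <- eff_sum$n + 1L
      if ((iter - mcmc$n_burnin) %% mcmc$thin == 0L) {
        k_store <- k_store + 1L
        stored[k_store, ] <- st
        if (mcmc$store_effects) {
          eff_draws[[k_store]] <- list(u = u, v = v)
        }
      }
    }
    if (verbose && iter %% 5000 == 0) {
      message("chain ", chain_id, ": iteration ", iter, "/", mcmc$n_iter)
    }
  }

  draws <- uncentre_draws(stored[seq_len(k_store), , drop = FALSE], id, mbar)
  draws <- as.data.frame(draws)
  draws$chain <- chain_id
  draws$iter <- seq_len(nrow(draws))
  em <- list()
  if (feats[["year_effects"]]) {
    em$u <- eff_sum$u / eff_sum$n; rownames(em$u) <- years
    colnames(em$u) <- c("u_b", "u_g")
  }
  if (feats[["indiv_effects"]]) {
    em$v <- eff_sum$v / eff_sum$n; rownames(em$v) <- ids
    colnames(em$v) <- c("v_b", "v_g")
  }
  list(draws = draws, effects_mean = em, effects_draws = eff_draws,
       acceptance = ifelse(acc_tries > 0, acc_count / acc_tries, NA))
}

`%|%` <- function(x, default) {
  if (length(x) == 0 || is.na(x)) default else unname(x)
}

rowsum_safe <- function(x, grp, n) {
  out <- numeric(n)
  agg <- rowsum(x, grp)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

prior_of <- function(name, st, priors) {
  if (name %in% c("lsg", "lsh", "lnb", "lng", "ltb", "ltg")) {
    lp_logsd(st[[name]], priors)
  } else if (name %in% c("rho", "psi", "alpha")) {
    0  # uniform(-1, 1); support enforced by proposal rejection
  } else {
    lp_coef(st[[name]], priors)
  }
}

# initial state via per-rate least squares / logistic fits
chain_inits <- function(id, rec, chain_id) {
  # deterministic inits; chains differ through their RNG streams
  safe_glm <- function(y, x, family) {
    ok <- !is.na(y)
    if (sum(ok) < 3 || length(unique(y[ok])) < 2) return(c(0, 0))
    f <- suppressWarnings(glm.fit(cbind(1, x[ok]), y[ok], family = family))
    co <- f$coefficients
    co[!is.finite(co)] <- 0
    co
  }
  cs <- safe_glm(rec$a_next, rec$m, binomial())
  cb <- safe_glm(rec$r_next, rec$m, binomial())
  okg <- !is.na(rec$m_next)
  cg <- if (sum(okg) >= 3) stats::lm.fit(cbind(1, rec$m[okg]), rec$m_next[okg]) else NULL
  okh <- !is.na(rec$c_next)
  chh <- if (sum(okh) >= 3) stats::lm.fit(cbind(1, rec$m[okh]), rec$c_next[okh]) else NULL
  g_coef <- if (is.null(cg)) c(2, 0.5) else cg$coefficients
  h_coef <- if (is.null(chh)) c(1, 0.5) else chh$coefficients
  sg0 <- if (is.null(cg)) 0.1 else max(sd(cg$residuals), 1e-3)
  sh0 <- if (is.null(chh)) 0.2 else max(sd(chh$residuals), 1e-3)

  st <- c(beta_s0 = unname(cs[1]), beta_sm = unname(cs[2]),
          beta_h0 = unname(h_coef[1]), beta_hm = unname(h_coef[2]),
          lsh = log(sh0),
          beta_b0 = unname(cb[1]), beta_bm = unname(cb[2]),
          beta_g0 = unname(g_coef[1]), beta_gm = unname(g_coef[2]),
          lsg = log(sg0))
  rg_names <- c("beta_b0", "beta_bm", "beta_g0", "beta_gm", "lsg")
  if (id == "D1a") { st <- c(st, beta_g_given_r = 0); rg_names <- c(rg_names, "beta_g_given_r") }
  if (id == "D1b") { st <- c(st, alpha = 0); rg_names <- c(rg_names, "alpha") }
  if (id == "D2a") { st <- c(st, beta_bq = 0, beta_gq = 0); rg_names <- c(rg_names, "beta_bq", "beta_gq") }
  if (id %in% c("I2", "D2b")) st <- c(st, lnb = log(0.3), lng = log(0.05), rho = 0)
  if (id %in% c("I3", "D3")) st <- c(st, ltb = log(0.3), ltg = log(0.05), psi = 0)

  scales <- as.list(setNames(rep(0.1, length(st)), names(st)))
  scales$lsg <- scales$lsh <- 0.05
  scales$u_scale <- 0.2; scales$v_scale <- 0.3
  scales$sweep_b <- 0.2; scales$sweep_g <- 0.05
  scales$scale_b <- 0.3; scales$scale_g <- 0.3
  list(state = st, scales = scales, rg_names = rg_names)
}

# transform draws from the centred parameterization back to natural scale
uncentre_draws <- function(stored, id, mbar) {
  out <- list()
  out$beta_s0 <- stored[, "beta_s0"] - stored[, "beta_sm"] * mbar
  out$beta_sm <- stored[, "beta_sm"]
  out$beta_b0 <- stored[, "beta_b0"] - stored[, "beta_bm"] * mbar
  out$beta_bm <- stored[, "beta_bm"]
  out$beta_g0 <- stored[, "beta_g0"] - stored[, "beta_gm"] * mbar
  out$beta_gm <- stored[, "beta_gm"]
  out$beta_h0 <- stored[, "beta_h0"] - stored[, "beta_hm"] * mbar
  out$beta_hm <- stored[, "beta_hm"]
  out$sigma2_g <- exp(2 * stored[, "lsg"])
  out$sigma2_h <- exp(2 * stored[, "lsh"])
  if (id == "D1a") out$beta_g_given_r <- stored[, "beta_g_given_r"]
  if (id == "D1b") out$alpha <- stored[, "alpha"]
  if (id == "D2a") {
    out$beta_bq <- stored[, "beta_bq"]; out$beta_gq <- stored[, "beta_gq"]
  }
  if (id %in% c("I2", "D2b")) {
    out$nu2_b <- exp(2 * stored[, "lnb"]); out$nu2_g <- exp(2 * stored[, "lng"])
    if (id == "D2b") out$rho <- stored[, "rho"]
  }
  if (id %in% c("I3", "D3")) {
    out$theta2_b <- exp(2 * stored[, "ltb"]); out$theta2_g <- exp(2 * stored[, "ltg"])
    if (id == "D3") out$psi <- stored[, "psi"]
  }
  do.call(cbind, out)
}
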