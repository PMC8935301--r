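# Likelihoods over individual-level demographic records.
#
# A record is one individual-year: log mass m at t, survival indicator
# a_next to t+1, breeding indicator r_next at t+1 (given survival, may be
# missing), next log mass m_next (given survival), offspring log mass
# c_next (given breeding).  Missing binary responses are marginalized
# analytically -- the contribution is b * f(data | r = 1) + (1 - b) *
# f(data | r = 0) -- and missing Gaussian responses simply drop their
# term.  Missing covariates (m itself) are not allowed.

#' Validate a demographic records table
#'
#' Checks the canonical column set (`id`, `year`, `m`, `a_next`,
#' `r_next`, `m_next`, `c_next`, optional `newborn`), binary indicators,
#' the consistency rules `c_next present => r_next = 1` and
#' `m_next present => a_next = 1`, finiteness of `m`, and uniqueness of
#' `(id, year)` pairs.  Problems are reported with row numbers.
#'
#' @param records Data frame of records.
#' @return The records, invisibly, with `newborn` added (all `FALSE`) if
#'   absent.
#' @export
validate_records <- function(records) {
  need <- c("id", "year", "m", "a_next", "r_next", "m_next", "c_next")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (!"newborn" %in% names(records)) records$newborn <- FALSE
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      rows <- which(cond)
      stop(what, " (rows ", paste(utils::head(rows, 5), collapse = ", "),
           if (length(rows) > 5) ", ..." else "", ")", call. = FALSE)
    }
  }
  bad(!is.finite(records$m), "non-finite log mass m")
  bad(!(records$a_next %in% c(0, 1) | is.na(records$a_next)),
      "survival indicator a_next not binary")
  bad(!(records$r_next %in% c(0, 1) | is.na(records$r_next)),
      "reproduction indicator r_next not binary")
  bad(!is.na(records$c_next) & (is.na(records$r_next) | records$r_next != 1),
      "offspring size c_next present without r_next = 1")
  bad(!is.na(records$m_next) & (is.na(records$a_next) | records$a_next != 1),
      "next mass m_next present without a_next = 1")
  if (anyDuplicated(records[c("id", "year")])) {
    stop("duplicate (id, year) pairs in records")
  }
  invisible(records)
}

# Per-record additive shifts on the reproduction / growth predictors for a
# full effects specification (vectors indexed by year label or id label).
record_shifts <- function(model, params, effects, records) {
  id <- as_model(model)$model_id
  feats <- model_features(model)
  shift_b <- shift_g <- numeric(nrow(records))
  lookup <- function(vec, keys, what) {
    if (is.null(vec)) stop("model ", id, " requires effects$", what, call. = FALSE)
    if (is.null(names(vec))) stop("effects$", what, " must be named by ",
                                  if (what %in% c("u_b", "u_g", "q")) "year" else "id",
                                  call. = FALSE)
    out <- vec[as.character(keys)]
    if (anyNA(out)) stop("effects$", what, " missing entries", call. = FALSE)
    unname(out)
  }
  if (feats[["year_effects"]]) {
    shift_b <- lookup(effects$u_b, records$year, "u_b")
    shift_g <- lookup(effects$u_g, records$year, "u_g")
  } else if (feats[["indiv_effects"]]) {
    shift_b <- lookup(effects$v_b, records$id, "v_b")
    shift_g <- lookup(effects$v_g, records$id, "v_g")
  } else if (feats[["driver"]]) {
    q <- lookup(effects$q, records$year, "q")
    shift_b <- params$beta_bq * q
    shift_g <- params$beta_gq * q
  }
  list(b = shift_b, g = shift_g)
}

# Survival block: identical across models.
ll_survival <- function(params, records) {
  ok <- !is.na(records$a_next)
  if (!any(ok)) return(0)
  s <- survival_prob(records$m[ok], params)
  sum(ifelse(records$a_next[ok] == 1, log(s), log1p(-s)))
}

# Offspring-size block: identical across models.
ll_offspring <- function(params, records) {
  ok <- !is.na(records$c_next)
  if (!any(ok)) return(0)
  sum(offspring_density(records$c_next[ok], records$m[ok], params, log = TRUE))
}

# Reproduction + growth block, per record (vector).  `shifts` are the
# per-record additive effects; `x_aux` the copula auxiliaries (D1b).
ll_repro_growth_vec <- function(model, params, records, shifts, x_aux = NULL) {
  model <- as_model(model)
  id <- model$model_id
  n <- nrow(records)
  eta_b <- params$beta_b0 + params$beta_bm * records$m + shifts$b
  mu_g <- params$beta_g0 + params$beta_gm * records$m + shifts$g
  b <- inv_logit(eta_b)
  sg <- sqrt(params$sigma2_g)
  r <- records$r_next
  mn <- records$m_next
  has_r <- !is.na(r)
  has_g <- !is.na(mn)
  out <- numeric(n)

  if (id == "D1b") {
    both <- has_r & has_g
    if (any(both)) {
      if (is.null(x_aux)) stop("model D1b requires copula auxiliaries x_aux")
      out[both] <- copula_joint_density(
        mn[both], r[both] + x_aux[both], mu_g[both], params$sigma2_g,
        1 - b[both], params$alpha, log = TRUE)
    }
    ronly <- has_r & !has_g
    out[ronly] <- ifelse(r[ronly] == 1, log(b[ronly]), log1p(-b[ronly]))
    # marginalizing the copula over a missing breeding record returns the
    # plain Gaussian growth margin
    gonly <- !has_r & has_g
    out[gonly] <- dnorm(mn[gonly], mu_g[gonly], sg, log = TRUE)
    return(out)
  }

  if (id == "D1a") {
    elig <- if (model$newborn_only) as.numeric(records$newborn) else rep(1, n)
    if (model$r_lagged) {
      # growth conditions on the previous year's breeding status
      key <- paste(records$id, records$year - 1)
      prev <- match(key, paste(records$id, records$year))
      r_cov <- records$r_next[prev]     # NA when no previous record
    } else {
      r_cov <- r
    }
    shift_r <- params$beta_g_given_r * elig
    known <- !is.na(r_cov)
    # observed breeding covariate
    i <- has_g & known
    out[i] <- dnorm(mn[i], mu_g[i] + shift_r[i] * r_cov[i], sg, log = TRUE)
    # missing breeding covariate: analytic two-branch marginalization
    i <- has_g & !known
    if (any(i)) {
      out[i] <- log(b[i] * dnorm(mn[i], mu_g[i] + shift_r[i], sg) +
                    (1 - b[i]) * dnorm(mn[i], mu_g[i], sg))
    }
    out[has_r] <- out[has_r] +
      ifelse(r[has_r] == 1, log(b[has_r]), log1p(-b[has_r]))
    return(out)
  }

  # all remaining models: independent Bernoulli + Gaussian terms
  out[has_r] <- ifelse(r[has_r] == 1, log(b[has_r]), log1p(-b[has_r]))
  out[has_g] <- out[has_g] + dnorm(mn[has_g], mu_g[has_g], sg, log = TRUE)
  out
}

#' Log-likelihood of a records table under a model variant
#'
#' Sums the model's log contributions over records: Bernoulli terms for
#' survival and breeding, Gaussian terms for growth and offspring size,
#' the joint breeding-conditional growth term for `D1a`, and the copula
#' joint density for `D1b`.  Missing breeding indicators are marginalized
#' analytically; missing Gaussian responses drop their term.
#'
#' @param model Model id or [model_spec()].
#' @param params A [vr_params()] object.
#' @param effects Named list of conditioning values as the model requires:
#'   year effects `u_b`, `u_g` (named by year; `I2`/`D2b`), individual
#'   effects `v_b`, `v_g` (named by id; `I3`/`D3`), driver values `q`
#'   (named by year; `D2a`), and copula auxiliaries `x_aux` (one per
#'   record, `D1b`).
#' @param records Validated records data frame.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, params, effects = NULL, records) {
  records <- validate_records(records)
  if (nrow(records) == 0) return(0)
  shifts <- record_shifts(model, params, effects, records)
  ll_survival(params, records) + ll_offspring(params, records) +
    sum(ll_repro_growth_vec(model, params, records, shifts,
                            x_aux = effects$x_aux))
}
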