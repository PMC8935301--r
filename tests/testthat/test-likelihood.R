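test_that("record validation flags inconsistent rows with their positions", {
  r <- toy_records()
  expect_silent(validate_records(r))
  r2 <- r; r2$r_next[1] <- 2L
  expect_error(validate_records(r2), "not binary.*rows 1")
  r3 <- r; r3$c_next[2] <- 2.0   # offspring without breeding
  expect_error(validate_records(r3), "c_next present.*rows 2")
  r4 <- r; r4$m_next[4] <- 2.1   # next mass without survival
  expect_error(validate_records(r4), "m_next present.*rows 4")
  r5 <- rbind(r, r[1, ])
  expect_error(validate_records(r5), "duplicate")
  r6 <- r[, setdiff(names(r), "c_next")]
  expect_error(validate_records(r6), "lack column")
})

test_that("the log-likelihood of one fully observed record is the product of its terms", {
  p <- vr_params()
  r <- toy_records()[1, , drop = FALSE]  # all four responses observed
  manual <- dbinom(1, 1, survival_prob(r$m, p), log = TRUE) +
    dbinom(1, 1, reproduction_prob(r$m, p), log = TRUE) +
    growth_density(r$m_next, r$m, p, log = TRUE) +
    offspring_density(r$c_next, r$m, p, log = TRUE)
  expect_equal(log_likelihood("I1", p, NULL, r), manual, tolerance = 1e-12)
  expect_equal(exp(log_likelihood("I1", p, NULL, r)),
               survival_prob(r$m, p) * reproduction_prob(r$m, p) *
                 growth_density(r$m_next, r$m, p) *
                 offspring_density(r$c_next, r$m, p), tolerance = 1e-12)
  # empty table
  expect_equal(log_likelihood("I1", p, NULL, toy_records()[0, ]), 0)
})

test_that("missing responses drop their terms; missing breeding marginalizes exactly", {
  p <- set_params(vr_params(), beta_g_given_r = -0.3)
  r <- toy_records()[3, , drop = FALSE]  # r_next missing, m_next observed
  # under independent models the Bernoulli term is simply absent
  expect_equal(log_likelihood("I1", vr_params(), NULL, r),
               dbinom(1, 1, survival_prob(r$m, vr_params()), log = TRUE) +
                 growth_density(r$m_next, r$m, vr_params(), log = TRUE),
               tolerance = 1e-12)
  # under D1a the completed-data likelihood summed over r equals the
  # marginalized likelihood (law of total probability, exact)
  b <- reproduction_prob(r$m, p)
  r1 <- r; r1$r_next <- 1L
  r0 <- r; r0$r_next <- 0L
  completed <- b * exp(log_likelihood("D1a", p, NULL, r1) -
                         dbinom(1, 1, b, log = TRUE)) +
    (1 - b) * exp(log_likelihood("D1a", p, NULL, r0) -
                    dbinom(0, 1, b, log = TRUE))
  expect_equal(exp(log_likelihood("D1a", p, NULL, r)), completed,
               tolerance = 1e-12)
  # same identity for the copula model (reduces to the Gaussian margin)
  pa <- set_params(vr_params(), alpha = 0.5)
  expect_equal(log_likelihood("D1b", pa, list(x_aux = rep(0.5, 1)), r),
               dbinom(1, 1, survival_prob(r$m, pa), log = TRUE) +
                 growth_density(r$m_next, r$m, pa, log = TRUE),
               tolerance = 1e-12)
})

test_that("year, individual and driver effects enter through their labels", {
  p <- vr_params()
  r <- toy_records()
  u <- list(u_b = c("1" = 0.2, "2" = -0.1), u_g = c("1" = 0.05, "2" = 0))
  ll <- log_likelihood("I2", p, u, r)
  # manual: per-record shifts by year
  manual <- sum(sapply(seq_len(nrow(r)), function(i) {
    ri <- r[i, , drop = FALSE]
    ub <- u$u_b[as.character(ri$year)]; ug <- u$u_g[as.character(ri$year)]
    dbinom(ri$a_next, 1, survival_prob(ri$m, p), log = TRUE) +
      (if (!is.na(ri$r_next)) dbinom(ri$r_next, 1, plogis(p$beta_b0 + p$beta_bm * ri$m + ub), log = TRUE) else 0) +
      (if (!is.na(ri$m_next)) dnorm(ri$m_next, p$beta_g0 + p$beta_gm * ri$m + ug, sqrt(p$sigma2_g), log = TRUE) else 0) +
      (if (!is.na(ri$c_next)) offspring_density(ri$c_next, ri$m, p, log = TRUE) else 0)
  }))
  expect_equal(ll, manual, tolerance = 1e-12)
  expect_error(log_likelihood("I2", p, list(u_b = c("1" = 0.2, "2" = 0)), r), "u_g")
  expect_error(log_likelihood("D3", p, list(v_b = c(`1` = 0)), r), "v_g|v_b")
  # D2a: driver by year
  q <- c("1" = 0.8, "2" = -0.4)
  p2 <- set_params(p, beta_bq = 0.3, beta_gq = 0.05)
  ll2 <- log_likelihood("D2a", p2, list(q = q), r)
  shift_by_year <- function(i) q[as.character(r$year[i])]
  expect_true(is.finite(ll2))
  # zero driver equals I1
  expect_equal(log_likelihood("D2a", p2, list(q = c("1" = 0, "2" = 0)), r),
               log_likelihood("I1", p2, NULL, r), tolerance = 1e-12)
})

test_that("newborn-restricted breeding-status effect shifts only first-year growth", {
  p <- set_params(vr_params(), beta_g_given_r = -0.4)
  r <- data.frame(id = 1:2, year = 1L, m = c(2.2, 3.0),
                  a_next = 1L, r_next = 1L, m_next = c(2.6, 3.1),
                  c_next = NA_real_, newborn = c(TRUE, FALSE))
  m_nb <- model_spec("D1a", newborn_only = TRUE)
  ll <- log_likelihood(m_nb, p, NULL, r)
  b <- reproduction_prob(r$m, p)
  manual <- sum(dbinom(1, 1, survival_prob(r$m, p), log = TRUE)) +
    sum(dbinom(1, 1, b, log = TRUE)) +
    dnorm(r$m_next[1], p$beta_g0 + p$beta_gm * r$m[1] - 0.4, 0.09, log = TRUE) +
    dnorm(r$m_next[2], p$beta_g0 + p$beta_gm * r$m[2], 0.09, log = TRUE)
  expect_equal(ll, manual, tolerance = 1e-12)
})

test_that("the lagged-status variant conditions growth on the previous year's breeding", {
  p <- set_params(vr_params(), beta_g_given_r = -0.4)
  r <- data.frame(id = c(1L, 1L), year = c(1L, 2L), m = c(2.2, 2.6),
                  a_next = 1L, r_next = c(1L, 0L), m_next = c(2.6, 2.9),
                  c_next = NA_real_, newborn = FALSE)
  m_lag <- model_spec("D1a", r_lagged = TRUE)
  ll <- log_likelihood(m_lag, p, NULL, r)
  b <- reproduction_prob(r$m, p)
  # record 1 has no predecessor -> mixture; record 2 uses r_next of year 1
  mix1 <- b[1] * dnorm(r$m_next[1], p$beta_g0 + p$beta_gm * r$m[1] - 0.4, 0.09) +
    (1 - b[1]) * dnorm(r$m_next[1], p$beta_g0 + p$beta_gm * r$m[1], 0.09)
  manual <- sum(dbinom(1, 1, survival_prob(r$m, p), log = TRUE)) +
    dbinom(1, 1, b[1], log = TRUE) + dbinom(0, 1, b[2], log = TRUE) +
    log(mix1) +
    dnorm(r$m_next[2], p$beta_g0 + p$beta_gm * r$m[2] - 0.4, 0.09, log = TRUE)
  expect_equal(ll, manual, tolerance = 1e-12)
})
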