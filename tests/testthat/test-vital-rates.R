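test_that("survival and reproduction probabilities follow the logistic regressions", {
  p <- vr_params()
  # zero linear predictor
  p0 <- set_params(p, beta_s0 = 0, beta_sm = 0)
  expect_equal(survival_prob(c(-3, 0, 7), p0), rep(0.5, 3))
  # closed-form evaluation at the study's mean coefficients
  expect_equal(survival_prob(2.5, p), plogis(-4.25 + 1.92 * 2.5), tolerance = 1e-12)
  expect_equal(survival_prob(2.5, p), 0.634, tolerance = 1e-3)
  expect_equal(reproduction_prob(2.5, p), plogis(-1.47 + 0.50 * 2.5), tolerance = 1e-12)
  # monotone increasing in mass for positive slope
  m <- seq(0, 4, by = 0.1)
  expect_true(all(diff(survival_prob(m, p)) > 0))
  expect_error(survival_prob(NaN, p), "finite")
})

test_that("effect shifts enter the correct linear predictor and vanish at zero", {
  p <- vr_params()
  m <- c(1.8, 2.5, 3.2)
  expect_equal(reproduction_prob(m, p, "I2", list(u_b = 0)),
               reproduction_prob(m, p))
  expect_equal(reproduction_prob(m, p, "D2a", list(q = 0)),
               reproduction_prob(m, p))
  expect_equal(reproduction_prob(m, p, "D3", list(v_b = 0.3)),
               plogis(p$beta_b0 + p$beta_bm * m + 0.3))
  expect_equal(growth_density(2.9, 2.5, p, "D2b", list(u_g = 0)),
               growth_density(2.9, 2.5, p))
  expect_error(reproduction_prob(m, p, "I2"), "u_b")
  expect_error(growth_density(2.9, 2.5, p, "D3"), "v_g")
})

test_that("growth and offspring densities are proper and correctly located", {
  p <- vr_params()
  grid <- seq(-2, 6, length.out = 4001)
  dx <- diff(grid[1:2])
  for (m in c(2.0, 3.0)) {
    expect_equal(sum(growth_density(grid, m, p)) * dx, 1, tolerance = 1e-6)
    expect_equal(sum(offspring_density(grid, m, p)) * dx, 1, tolerance = 1e-6)
    # Gaussian mode at the regression mean
    expect_equal(grid[which.max(growth_density(grid, m, p, "I2", list(u_g = 0.1)))],
                 p$beta_g0 + p$beta_gm * m + 0.1, tolerance = 2 * dx)
  }
  # offspring mean linear in parent mass with slope beta_hm
  mu <- sapply(c(2, 2.5, 3), function(m) sum(grid * offspring_density(grid, m, p)) * dx)
  expect_equal(diff(mu) / 0.5, rep(p$beta_hm, 2), tolerance = 1e-6)
  p_bad <- p; p_bad$sigma2_g <- 0
  expect_error(growth_density(2, 2, p_bad), "sigma2_g")
  expect_error(vr_params(sigma2_g = 0), "positive")
})

test_that("the D1a marginal growth density is the stated two-component mixture", {
  p <- set_params(vr_params(), beta_g_given_r = -0.3)
  grid <- seq(-2, 6, length.out = 4001)
  dx <- diff(grid[1:2])
  m <- 2.5
  b <- reproduction_prob(m, p)
  mu <- p$beta_g0 + p$beta_gm * m
  manual <- b * dnorm(grid, mu - 0.3, 0.09) + (1 - b) * dnorm(grid, mu, 0.09)
  expect_equal(growth_marginal_d1a(grid, m, p), manual, tolerance = 1e-12)
  expect_equal(sum(growth_marginal_d1a(grid, m, p)) * dx, 1, tolerance = 1e-6)
  # collapses to the vanilla density when the shift is zero
  p0 <- set_params(p, beta_g_given_r = 0)
  expect_equal(growth_marginal_d1a(grid, m, p0), growth_density(grid, m, p0))
  # b -> 1 gives a single shifted Gaussian
  p1 <- set_params(p, beta_b0 = 60)
  expect_equal(growth_marginal_d1a(grid, m, p1), dnorm(grid, mu - 0.3, 0.09),
               tolerance = 1e-10)
})

test_that("the growth/breeding covariance identity holds and peaks at b = 0.5", {
  p <- set_params(vr_params(), beta_g_given_r = -0.3)
  # mass where b(m) = 0.5 exactly
  m_half <- (qlogis(0.5) - p$beta_b0) / p$beta_bm
  covs <- sapply(c(0.2, 0.5, 0.8), function(btarget) {
    m <- (qlogis(btarget) - p$beta_b0) / p$beta_bm
    b <- reproduction_prob(m, p)
    set.seed(42)
    r <- rbinom(20000, 1, b)
    mn <- rnorm(20000, p$beta_g0 + p$beta_gm * m + p$beta_g_given_r * r,
                sqrt(p$sigma2_g))
    c(mc = cov(mn, r), analytic = p$beta_g_given_r * b * (1 - b))
  })
  expect_equal(covs["mc", ], covs["analytic", ], tolerance = 0.05)
  expect_equal(unname(covs["analytic", 2]), -0.075, tolerance = 1e-12)
  expect_true(all(abs(covs["analytic", 2]) >= abs(covs["analytic", c(1, 3)])))
})

test_that("the augmented binary margin has the stated piecewise-linear CDF", {
  expect_equal(copula_margin_cdf(0.5, 0.4), 0.2)
  expect_equal(copula_margin_cdf(1, 0.37), 0.37)
  expect_equal(copula_margin_cdf(c(-1, 0, 2, 2.5), 0.4), c(0, 0, 1, 1))
  expect_equal(copula_margin_cdf(1.5, 0.4), 0.4 + 0.6 * 0.5)
  expect_error(copula_margin_cdf(0.5, 1.2), "q_fail")
})

test_that("the copula joint density factorizes at alpha = 0 and is proper", {
  mu <- 2; s2 <- 0.09^2; q <- 0.4
  y1 <- c(1.9, 2.0, 2.15); y3 <- c(0.3, 1.2, 1.9)
  f <- copula_joint_density(y1, y3, mu, s2, q, alpha = 0)
  f3 <- ifelse(y3 < 1, q, 1 - q)
  expect_equal(f, dnorm(y1, mu, sqrt(s2)) * f3, tolerance = 1e-9)
  # total mass 1
  tot <- integrate(function(y3) sapply(y3, function(z)
    integrate(function(y1) copula_joint_density(y1, z, mu, s2, q, 0.6),
              mu - 8 * 0.09, mu + 8 * 0.09, rel.tol = 1e-9)$value),
    0, 2, rel.tol = 1e-8)$value
  expect_equal(tot, 1, tolerance = 1e-6)
  expect_error(copula_joint_density(2, 1, mu, s2, q, alpha = 1), "alpha")
})

test_that("copula marginals are preserved for every correlation", {
  mu <- 2; s2 <- 0.09^2; q <- 0.35
  y1s <- seq(mu - 3 * 0.09, mu + 3 * 0.09, length.out = 20)
  for (a in c(-0.9, -0.5, 0, 0.5, 0.9)) {
    marg <- sapply(y1s, function(y1) {
      integrate(function(y3) copula_joint_density(y1, y3, mu, s2, q, a),
                0, 1, rel.tol = 1e-10)$value +
      integrate(function(y3) copula_joint_density(y1, y3, mu, s2, q, a),
                1, 2, rel.tol = 1e-10)$value
    })
    expect_equal(marg, dnorm(y1s, mu, sqrt(s2)), tolerance = 1e-6)
    # implied breeding probability unchanged
    pr1 <- integrate(function(y3) sapply(y3, function(z)
      integrate(function(y1) copula_joint_density(y1, z, mu, s2, q, a),
                mu - 8 * 0.09, mu + 8 * 0.09, rel.tol = 1e-9)$value),
      1, 2, rel.tol = 1e-8)$value
    expect_equal(pr1, 1 - q, tolerance = 1e-6)
  }
})

test_that("the per-record copula log-likelihood matches its independent pieces", {
  p <- vr_params()  # alpha = 0
  m <- 2.5; mn <- 2.9
  for (r in c(0, 1)) {
    ll <- copula_loglik_record(mn, r, m, x_aux = 0.3, p)
    b <- reproduction_prob(m, p)
    manual <- growth_density(mn, m, p, log = TRUE) +
      (if (r == 1) log(1 - (1 - b)) else log(1 - b))
    expect_equal(ll, manual, tolerance = 1e-9)
  }
  # boundary auxiliaries stay finite through clamping
  pa <- set_params(p, alpha = 0.8)
  expect_true(is.finite(copula_loglik_record(2.9, 0, 2.5, 0, pa)))
  expect_true(is.finite(copula_loglik_record(2.9, 1, 2.5, 1, pa)))
  expect_error(copula_loglik_record(2.9, 2, 2.5, 0.5, pa), "r_next")
})

test_that("averaging the copula likelihood over the auxiliary recovers the joint mass-density", {
  # Monte-Carlo over X ~ U[0,1] should integrate the augmented density to
  # the mixed mass-density of (m_next, r_next)
  p <- set_params(vr_params(), alpha = -0.6)
  m <- 2.7; mn <- 2.95
  set.seed(7)
  x <- runif(40000)
  for (r in c(0, 1)) {
    mc <- mean(exp(copula_loglik_record(rep(mn, length(x)), r, m, x, p)))
    direct <- integrate(function(xx)
      exp(copula_loglik_record(rep(mn, length(xx)), r, m, xx, p)),
      0, 1, rel.tol = 1e-9)$value
    expect_equal(mc, direct, tolerance = 0.02)
  }
})

test_that("zeroed dependence parameters make every variant collapse to the vanilla model", {
  p <- vr_params()  # all dependence parameters at zero
  m <- c(1.9, 2.6, 3.3); mn <- c(2.3, 2.9, 3.4)
  zero_eff <- list(u_b = 0, u_g = 0, v_b = 0, v_g = 0, q = 0)
  base_b <- reproduction_prob(m, p)
  base_g <- growth_density(mn, m, p)
  for (id in c("I2", "I3", "D2a", "D2b", "D3")) {
    expect_equal(reproduction_prob(m, p, id, zero_eff), base_b, info = id)
    expect_equal(growth_density(mn, m, p, id, zero_eff), base_g, info = id)
  }
  expect_equal(growth_marginal_d1a(mn, m, p), base_g)      # beta_g_given_r = 0
  expect_equal(copula_loglik_record(mn, c(1, 0, 1), m, rep(0.5, 3), p),
               log(base_g) + ifelse(c(1, 0, 1) == 1, log(base_b), log(1 - base_b)),
               tolerance = 1e-9)                            # alpha = 0
})
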