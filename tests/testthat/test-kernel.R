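test_that("meshes are uniform midpoints with proper individual-effect weights", {
  m <- make_mesh(c(0, 1), n = 4)
  expect_equal(m$x, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(m$dx, 0.25)
  expect_error(make_mesh(c(1, 1), n = 4), "degenerate")
  expect_error(make_mesh(c(0, 1), n = 1), "n must be")

  p <- vr_params()
  mz <- make_mesh(params = p, n = 20, n_z = 5, model = "I3")
  expect_equal(sum(mz$z_w), 1)
  # psi = 0: the grid is the outer product of two univariate quantile grids
  a <- qnorm((1:5 - 0.5) / 5)
  expect_equal(sort(unique(mz$z[, "v_b"])), sort(a * sqrt(p$theta2_b)),
               tolerance = 1e-12)
  expect_equal(sort(unique(mz$z[, "v_g"])), sort(a * sqrt(p$theta2_g)),
               tolerance = 1e-12)
  # psi != 0 tilts the grid: sample correlation of nodes matches psi
  pz <- set_params(p, psi = 0.6)
  mz2 <- make_mesh(params = pz, n = 20, n_z = 9, model = "D3")
  vb <- mz2$z[, "v_b"]; vg <- mz2$z[, "v_g"]
  w <- mz2$z_w
  cb <- sum(w * vb * vg) / sqrt(sum(w * vb^2) * sum(w * vg^2))
  expect_equal(cb, 0.6, tolerance = 0.02)
})

test_that("kernel outflow matches s(x) (1 + b(x)) for every source state", {
  p <- vr_params()
  for (id in c("I1", "D1a")) {
    K <- build_kernel(id, set_params(p, beta_g_given_r = -0.3), small_mesh(p, 80))
    expect_lt(max(eviction_deficit(K)), 1e-3)
  }
  yr <- list(u_b = 0.3, u_g = 0.05)
  K2 <- build_kernel("D2b", p, small_mesh(p, 80, model = "D2b"), year = yr)
  expect_lt(max(eviction_deficit(K2)), 1e-3)
  mz <- make_mesh(params = p, n = 80, n_z = 5, model = "I3")
  K3 <- build_kernel("I3", p, mz)
  expect_lt(max(eviction_deficit(K3)), 1e-3)
  # direct check of the analytic outflow on the dense form
  M <- as.matrix(K3)
  s <- survival_prob(mz$x, p)
  expected <- as.vector(sapply(seq_len(nrow(mz$z)), function(k)
    s * (1 + reproduction_prob(mz$x, p, "I3", list(v_b = mz$z[k, 1])))))
  expect_equal(colSums(M), expected, tolerance = 1e-3)
})

test_that("data-derived bounds keep eviction below tolerance", {
  p <- vr_params()
  recs <- simulate_population("I1", p, n0 = 200, T_years = 10, seed = 11)
  mesh <- make_mesh(recs, n = 100)
  K <- build_kernel("I1", p, mesh)
  expect_lt(max(eviction_deficit(K)), 1e-3)
})

test_that("a survival-only kernel has constant column outflow s0", {
  p <- set_params(vr_params(), beta_b0 = -40, beta_s0 = qlogis(0.8), beta_sm = 0)
  mesh <- small_mesh(p, 80)
  K <- build_kernel("I1", p, mesh)
  expect_equal(colSums(K$matrix), rep(0.8, mesh$n), tolerance = 1e-3)
  expect_equal(eigen_log_lambda(K)$lambda, 0.8, tolerance = 1e-3)
})

test_that("the copula kernel is entrywise identical to the vanilla kernel", {
  p <- set_params(vr_params(), alpha = 0.7)
  mesh <- small_mesh(p, 60)
  expect_identical(build_kernel("I1", p, mesh)$matrix,
                   build_kernel("D1b", p, mesh)$matrix)
})

test_that("projection is linear, composable, and mass-conserving for a survival-only kernel", {
  p <- vr_params()
  mesh <- small_mesh(p, 50)
  K <- build_kernel("I1", p, mesh)
  set.seed(1)
  n1 <- runif(mesh$n)
  expect_equal(project(3 * n1, K), 3 * project(n1, K))
  expect_equal(project(project(n1, K), K),
               as.vector(K$matrix %*% K$matrix %*% n1))
  expect_error(project(n1[-1], K), "length")
  # near-identity kernel: s = 1, b = 0, tight growth around the current mass
  pid <- set_params(vr_params(), beta_s0 = 50, beta_sm = 0, beta_b0 = -50,
                    beta_g0 = 0, beta_gm = 1 - 1e-9, sigma2_g = 0.05^2)
  mid <- make_mesh(c(1, 4), n = 200)
  Kid <- suppressWarnings(build_kernel("I1", pid, mid))
  nid <- dnorm(mid$x, 2.5, 0.3)
  expect_equal(total_abundance(project(nid, Kid), mid),
               total_abundance(nid, mid), tolerance = 1e-3)
})

test_that("model and mesh requirements are enforced", {
  p <- vr_params()
  mesh <- small_mesh(p, 30)
  meshz <- make_mesh(params = p, n = 30, n_z = 3, model = "I3")
  expect_error(build_kernel("I3", p, mesh), "individual-effect grid")
  expect_error(build_kernel("I1", p, meshz), "q-state")
  expect_error(build_kernel("I2", p, mesh), "year draw")
  expect_error(build_kernel("D2a", p, mesh, year = list(u_b = 1)), "q")
  expect_error(build_kernel("I1", p, mesh, year = list(u_b = 0, u_g = 0)),
               "no year draw")
  expect_warning(build_kernel("I1", p, make_mesh(c(2.4, 3.2), n = 30)),
                 "eviction")
})

test_that("the individual-effect kernel is block-diagonal in z for growth and mixes z at birth", {
  p <- set_params(vr_params(), psi = 0.4)
  mz <- make_mesh(params = p, n = 25, n_z = 3, model = "D3")
  K <- suppressWarnings(build_kernel("D3", p, mz))
  M <- as.matrix(K)
  n <- mz$n; nz <- nrow(mz$z)
  # kill fecundity: remaining flow must stay within the source z block
  p0 <- set_params(p, beta_b0 = -40)
  M0 <- as.matrix(suppressWarnings(build_kernel("D3", p0, mz)))
  for (k in 1:nz) for (kp in 1:nz) {
    blk <- M0[(kp - 1) * n + 1:n, (k - 1) * n + 1:n]
    if (k == kp) expect_gt(sum(blk), 0) else expect_equal(sum(blk), 0)
  }
  # offspring flow carries the target-z weights
  fec <- M - M0
  wts <- sapply(1:nz, function(kp) sum(fec[(kp - 1) * n + 1:n, 1:n]))
  expect_equal(wts / sum(wts), K$z_w[1:nz] / sum(K$z_w[1:nz]), tolerance = 1e-6)
  # structured apply agrees with the dense matrix
  set.seed(2)
  v <- runif(n * nz)
  expect_equal(project(v, K), as.vector(M %*% v), tolerance = 1e-10)
})

test_that("doubling the mesh resolution leaves log lambda unchanged to 1e-4", {
  p <- vr_params()
  ll1 <- eigen_log_lambda(build_kernel("I1", p, small_mesh(p, 100)))$log_lambda
  ll2 <- eigen_log_lambda(build_kernel("I1", p, small_mesh(p, 200)))$log_lambda
  expect_lt(abs(ll1 - ll2), 1e-4)
  mz1 <- make_mesh(params = p, n = 60, n_z = 7, model = "I3")
  mz2 <- make_mesh(params = p, n = 120, n_z = 7, model = "I3")
  lz1 <- eigen_log_lambda(build_kernel("I3", p, mz1))$log_lambda
  lz2 <- eigen_log_lambda(build_kernel("I3", p, mz2))$log_lambda
  expect_lt(abs(lz1 - lz2), 1e-4)
})
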