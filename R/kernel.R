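# Discretized projection kernels.
#
# The kernel density is k(x'|x) = s(x) [ b(x) h(x'|x) + g(x'|x) ]:
# survivors either grow (g) and/or leave one offspring with probability
# b and size density h.  Midpoint discretization multiplies each density
# by the cell width dx, giving a projection matrix with (target row,
# source column) orientation, n_{t+1} = K n_t.
#
# For models with persistent individual effects (I3/D3) the state is
# (x, z) with z = (v_b, v_g) fixed for life: growth is block-diagonal in
# z, while offspring draw a fresh z from the quantile grid weights.  The
# kernel is stored in that structured form (survival vector, per-z
# reproduction matrix, per-z growth blocks, offspring matrix) and only
# assembled into a dense matrix on request.

#' Build a discretized projection kernel
#'
#' @param model Model id or [model_spec()].
#' @param params A [vr_params()] object.
#' @param mesh An [make_mesh()] mesh; must carry an individual-effect grid
#'   exactly when `model` is `I3` or `D3`.
#' @param year For temporal models, a list with the year-specific
#'   conditions: `u_b`, `u_g` (models `I2`/`D2b`) or `q` (model `D2a`).
#'   Must be `NULL` for other models.
#' @param eviction_tol Warn if any source state loses more than this much
#'   probability outflow to eviction (default `1e-3`).
#' @return An object of class `ipm_kernel`.  For scalar-state models the
#'   field `matrix` holds the dense projection matrix; for `I3`/`D3` the
#'   kernel is stored blockwise (see Details) and can be densified with
#'   `as.matrix()`.
#' @examples
#' p <- vr_params()
#' K <- build_kernel("I1", p, make_mesh(params = p, n = 60))
#' @export
build_kernel <- function(model, params, mesh, year = NULL,
                         eviction_tol = 1e-3) {
  model <- as_model(model)
  id <- model$model_id
  feats <- model_features(model)
  if (feats[["indiv_effects"]] && mesh$n_z == 0) {
    stop("model ", id, " needs a mesh with an individual-effect grid (n_z > 0)")
  }
  if (!feats[["indiv_effects"]] && mesh$n_z > 0) {
    stop("mesh has an individual-effect grid but model ", id, " has no q-state")
  }
  if (feats[["temporal"]]) {
    if (is.null(year)) stop("model ", id, " needs a year draw")
    if (feats[["year_effects"]] && (is.null(year$u_b) || is.null(year$u_g))) {
      stop("model ", id, " needs year$u_b and year$u_g")
    }
    if (feats[["driver"]] && is.null(year$q)) stop("model D2a needs year$q")
  } else if (!is.null(year)) {
    stop("model ", id, " takes no year draw")
  }

  x <- mesh$x; dx <- mesh$dx
  s <- survival_prob(x, params)
  H <- outer(x, x, function(xp, xs) offspring_density(xp, xs, params)) * dx

  if (feats[["indiv_effects"]]) {
    nz <- nrow(mesh$z)
    B <- sapply(seq_len(nz), function(k) {
      reproduction_prob(x, params, model, effects = list(v_b = mesh$z[k, 1]))
    })  # n x nz
    G <- array(0, c(mesh$n, mesh$n, nz))
    for (k in seq_len(nz)) {
      G[, , k] <- outer(x, x, function(xp, xs) {
        growth_density(xp, xs, params, model, effects = list(v_g = mesh$z[k, 2]))
      }) * dx
    }
    K <- structure(list(s = s, B = B, G = G, H = H, z_w = mesh$z_w,
                        mesh = mesh, model_id = id, year = year,
                        dense = FALSE),
                   class = "ipm_kernel")
  } else {
    b <- switch(id,
      I1 = , D1a = , D1b = reproduction_prob(x, params),
      I2 = , D2b = reproduction_prob(x, params, model, effects = list(u_b = year$u_b)),
      D2a = reproduction_prob(x, params, model, effects = list(q = year$q)))
    g_fun <- switch(id,
      D1a = function(xp, xs) growth_marginal_d1a(xp, xs, params),
      # The copula (D1b) leaves the growth marginal untouched, so its
      # kernel coincides with the vanilla kernel by construction.
      I1 = , D1b = function(xp, xs) growth_density(xp, xs, params),
      I2 = , D2b = function(xp, xs) {
        growth_density(xp, xs, params, model, effects = list(u_g = year$u_g))
      },
      D2a = function(xp, xs) {
        growth_density(xp, xs, params, model, effects = list(q = year$q))
      })
    Gm <- outer(x, x, g_fun) * dx
    Km <- Gm + H * rep(b, each = mesh$n)
    Km <- Km * rep(s, each = mesh$n)
    K <- structure(list(matrix = Km, s = s, b = b, mesh = mesh,
                        model_id = id, year = year, dense = TRUE),
                   class = "ipm_kernel")
  }
  ev <- eviction_deficit(K)
  if (max(ev) > eviction_tol) {
    warning(sprintf("kernel eviction: max outflow deficit %.2e exceeds %.1e; widen the mesh bounds",
                    max(ev), eviction_tol))
  }
  K$max_eviction <- max(ev)
  K
}

#' Per-source eviction deficit of a kernel
#'
#' Difference between the analytic outflow `s(x) (1 + b(x))` and the
#' realized column outflow of the discretized kernel; positive values are
#' probability mass lost off the mesh.
#'
#' @param K An `ipm_kernel`.
#' @return Numeric vector over source states.
#' @export
eviction_deficit <- function(K) {
  if (K$dense) {
    K$s * (1 + K$b) - colSums(K$matrix)
  } else {
    n <- K$mesh$n; nz <- ncol(K$B)
    hcol <- colSums(K$H)
    out <- sapply(seq_len(nz), function(k) {
      K$s * (colSums(K$G[, , k]) + K$B[, k] * hcol)
    })
    expected <- sapply(seq_len(nz), function(k) K$s * (1 + K$B[, k]))
    as.vector(expected - out)
  }
}

#' Number of discretized states of a kernel
#' @param K An `ipm_kernel`.
#' @return Integer state count.
#' @export
n_states <- function(K) {
  if (K$dense) K$mesh$n else K$mesh$n * ncol(K$B)
}

#' @export
print.ipm_kernel <- function(x, ...) {
  cat("<ipm_kernel> model ", x$model_id, ", ", n_states(x), " states",
      sprintf(", max eviction %.1e", x$max_eviction), "\n", sep = "")
  invisible(x)
}

#' Densify a kernel
#'
#' For `I3`/`D3` kernels, assembles the dense extended-state matrix with
#' states ordered z-major (mass index fastest).  Offspring entries carry
#' the target-z probability weight; growth entries are block-diagonal in z.
#'
#' @param x An `ipm_kernel`.
#' @param ... Unused.
#' @return A square numeric matrix.
#' @export
as.matrix.ipm_kernel <- function(x, ...) {
  if (x$dense) return(x$matrix)
  n <- x$mesh$n; nz <- ncol(x$B)
  N <- n * nz
  M <- matrix(0, N, N)
  for (k in seq_len(nz)) {       # source z
    src <- (k - 1L) * n + seq_len(n)
    fec <- x$H * rep(x$s * x$B[, k], each = n)  # n x n offspring flow
    for (kp in seq_len(nz)) {    # target z
      tgt <- (kp - 1L) * n + seq_len(n)
      M[tgt, src] <- x$z_w[kp] * fec
    }
    M[src, src] <- M[src, src] + x$G[, , k] * rep(x$s, each = n)
  }
  M
}

#' Apply a kernel to a population vector
#'
#' One projection step `n_{t+1} = K n_t`.  The population vector is a
#' density over mass nodes (times probability mass over the individual-
#' effect grid for extended-state kernels), ordered as in
#' [as.matrix.ipm_kernel()].
#'
#' @param state Numeric population vector (length [n_states()]).
#' @param K An `ipm_kernel`.
#' @return The projected population vector.
#' @export
project <- function(state, K) {
  if (!is.numeric(state)) stop("state must be numeric")
  if (length(state) != n_states(K)) {
    stop("state length ", length(state), " does not match kernel states ", n_states(K))
  }
  if (K$dense) return(as.vector(K$matrix %*% state))
  n <- K$mesh$n; nz <- ncol(K$B)
  S <- matrix(state, n, nz)
  grown <- matrix(0, n, nz)
  pool <- numeric(n)   # survival-weighted reproducing density, by mass
  for (k in seq_len(nz)) {
    sn <- K$s * S[, k]
    grown[, k] <- K$G[, , k] %*% sn
    pool <- pool + K$B[, k] * sn
  }
  births <- as.vector(K$H %*% pool)
  out <- grown + outer(births, K$z_w)
  as.vector(out)
}

#' Total abundance of a population vector
#'
#' @param state Population vector over mesh states.
#' @param mesh The mesh the vector lives on.
#' @return `sum(state) * dx`.
#' @export
total_abundance <- function(state, mesh) sum(state) * mesh$dx
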