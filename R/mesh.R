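# Midpoint-rule meshes over log body mass, optionally extended by a grid
# over the persistent individual-effect pair (v_b, v_g).

#' Default log-mass integration bounds for a parameter set
#'
#' Chooses bounds wide enough that kernel eviction is negligible for every
#' source node.  The upper bound solves `hi = beta_g0 + shift + beta_gm *
#' hi + n_sd * sigma_g`, i.e. even an individual already at `hi` sends at
#' most a `pnorm(-n_sd)` tail above the mesh; `shift` allows for the
#' largest growth shift the model can produce (year effects, driver,
#' individual effects, or a positive breeding-status effect).  The lower
#' bound is the analogous fixed point of the offspring-size map minus
#' `n_sd` offspring SDs, below which recruitment density cannot reach.
#'
#' @param params A [vr_params()] object.
#' @param model Model id or [model_spec()]; controls the shift allowance.
#' @param n_sd Number of residual SDs of slack (default 4).
#' @return Numeric bounds `c(lo, hi)`.
#' @export
default_bounds <- function(params, model = "I1", n_sd = 4) {
  id <- as_model(model)$model_id
  if (params$beta_gm >= 1 || params$beta_hm >= 1) {
    stop("default bounds require growth and offspring slopes < 1; supply bounds explicitly")
  }
  shift <- switch(id,
    I2 = , D2b = 3 * sqrt(params$nu2_g),
    I3 = , D3 = 3 * sqrt(params$theta2_g),
    D2a = abs(params$beta_gq) * 3 * 1.09,
    D1a = max(0, params$beta_g_given_r),
    0)
  hi <- (params$beta_g0 + shift + n_sd * sqrt(params$sigma2_g)) / (1 - params$beta_gm)
  lo <- (params$beta_h0 - n_sd * sqrt(params$sigma2_h)) / (1 - params$beta_hm)
  if (lo >= hi) stop("degenerate bounds derived from parameters")
  c(lo, hi)
}

#' Build an integration mesh
#'
#' Uniform midpoint-rule nodes over log body mass, optionally crossed with
#' an `n_z` x `n_z` grid over the persistent individual effects `(v_b,
#' v_g)` for models `I3`/`D3`.  The individual-effect nodes are uniform
#' quantiles (cell midpoints) of the marginal standard normal, transformed
#' through the Cholesky factor of the 2x2 effect covariance so that a
#' nonzero `psi` tilts the grid; each node carries probability weight
#' `1 / n_z^2`.
#'
#' @param x Either numeric bounds `c(lo, hi)`, a demographic records data
#'   frame (bounds become the observed log-mass range +/- `n_sd` marginal
#'   SDs), or `NULL` to derive bounds from `params` via [default_bounds()].
#' @param n Number of log-mass nodes (>= 2); default 100.
#' @param n_z Number of quantile nodes per individual effect (0 for models
#'   without persistent effects).
#' @param params A [vr_params()] object; required when `x` is `NULL` or
#'   when `n_z > 0`.
#' @param model Model id used for parameter-derived bounds.
#' @param n_sd Bound slack in residual/marginal SDs.
#' @return An object of class `ipm_mesh` with fields `x` (midpoints), `dx`
#'   (cell width), `bounds`, and when `n_z > 0` a matrix `z` of
#'   `(v_b, v_g)` node pairs with weights `z_w`.
#' @examples
#' make_mesh(c(0, 1), n = 4)$x
#' @export
make_mesh <- function(x = NULL, n = 100, n_z = 0, params = NULL,
                      model = "I1", n_sd = 4) {
  if (n < 2) stop("n must be >= 2")
  if (is.null(x)) {
    if (is.null(params)) stop("supply bounds, records, or params")
    bounds <- default_bounds(params, model, n_sd)
  } else if (is.data.frame(x)) {
    masses <- c(x$m, x$m_next, x$c_next)
    masses <- masses[is.finite(masses)]
    if (length(masses) < 2) stop("no usable mass observations in records")
    bounds <- range(masses) + c(-1, 1) * n_sd * sd(masses)
  } else {
    if (length(x) != 2 || !is.numeric(x)) stop("bounds must be numeric length 2")
    bounds <- sort(x)
  }
  if (diff(bounds) <= 0) stop("degenerate bounds")
  dx <- diff(bounds) / n
  mids <- bounds[1] + (seq_len(n) - 0.5) * dx
  mesh <- list(x = mids, dx = dx, bounds = bounds, n = n, n_z = as.integer(n_z))
  if (n_z > 0) {
    if (is.null(params)) stop("params needed to build the individual-effect grid")
    a <- qnorm((seq_len(n_z) - 0.5) / n_z)
    grid <- as.matrix(expand.grid(zb = a, zg = a))
    sb <- sqrt(params$theta2_b); sg <- sqrt(params$theta2_g)
    Sigma <- matrix(c(sb^2, params$psi * sb * sg,
                      params$psi * sb * sg, sg^2), 2, 2)
    Lt <- chol(Sigma)  # upper triangular: z = grid %*% Lt
    z <- grid %*% Lt
    colnames(z) <- c("v_b", "v_g")
    mesh$z <- z
    mesh$z_w <- rep(1 / nrow(z), nrow(z))
  }
  class(mesh) <- "ipm_mesh"
  mesh
}

#' @export
print.ipm_mesh <- function(x, ...) {
  cat("<ipm_mesh> ", x$n, " mass nodes on [",
      round(x$bounds[1], 3), ", ", round(x$bounds[2], 3), "], dx = ",
      signif(x$dx, 4), sep = "")
  if (x$n_z > 0) cat("; ", x$n_z, "x", x$n_z, " individual-effect nodes", sep = "")
  cat("\n")
  invisible(x)
}
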