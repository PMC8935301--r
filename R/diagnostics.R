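# Convergence diagnostics and posterior summaries.

# PSRF from a list of draws matrices (one per chain, equal dims).
gelman_rubin_matrixes <- function(mats) {
  m <- length(mats)
  if (m < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains")
  n <- nrow(mats[[1]])
  pars <- colnames(mats[[1]])
  vapply(pars, function(p) {
    x <- sapply(mats, function(M) M[, p])
    means <- colMeans(x)
    vars <- apply(x, 2, var)
    W <- mean(vars)
    B <- n * var(means)
    if (W == 0) return(if (B == 0) 1 else Inf)
    # floored at 1: values below 1 are finite-sample artifacts
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  }, numeric(1))
}

#' Brooks-Gelman-Rubin convergence statistic
#'
#' Potential scale reduction factor per monitored parameter, computed
#' across chains; values below 1.05 are conventionally treated as
#' converged.
#'
#' @param samples A `posterior_samples` object from [fit_ipm()] (with at
#'   least two chains), or a list of per-chain draws matrices.
#' @param threshold Convergence threshold (default 1.05).
#' @return Named vector of statistics with attribute `"converged"`.
#' @export
gelman_rubin <- function(samples, threshold = 1.05) {
  mats <- if (inherits(samples, "posterior_samples")) {
    if (is.null(samples$rhat)) stop("Gelman-Rubin diagnostic needs at least 2 chains")
    ch <- split(samples$draws, samples$draws$chain)
    lapply(ch, function(d) as.matrix(d[setdiff(names(d), c("chain", "iter"))]))
  } else samples
  r <- gelman_rubin_matrixes(mats)
  attr(r, "converged") <- all(r < threshold)
  r
}

#' Posterior summary table
#'
#' Means, SDs and equal-tailed quantile intervals per parameter.
#'
#' @param samples A `posterior_samples` object or a data frame of draws.
#' @param quantiles Probabilities of the reported quantiles.
#' @return A data frame with one row per parameter.
#' @export
posterior_summary <- function(samples, quantiles = c(0.025, 0.5, 0.975)) {
  draws <- if (inherits(samples, "posterior_samples")) samples$draws else samples
  pars <- setdiff(names(draws), c("chain", "iter"))
  out <- do.call(rbind, lapply(pars, function(p) {
    x <- draws[[p]]
    qs <- quantile(x, quantiles, names = FALSE)
    df <- data.frame(parameter = p, mean = mean(x), sd = sd(x))
    for (i in seq_along(quantiles)) df[[paste0("q", quantiles[i])]] <- qs[i]
    df
  }))
  rownames(out) <- NULL
  out
}

#' Write posterior draws as columnar text
#'
#' One column per parameter plus `chain` and `iter`, tab-separated with a
#' header row; readable back with [read_posterior()].
#'
#' @param samples A `posterior_samples` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(samples, path) {
  stopifnot(inherits(samples, "posterior_samples"))
  utils::write.table(samples$draws, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_posterior()]
#'
#' @param path File path.
#' @return Data frame of draws (with `chain` and `iter` columns).
#' @export
read_posterior <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
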