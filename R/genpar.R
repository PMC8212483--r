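#' Additive genetic variance at a gradient value
#'
#' `var_a(theta) = v0 + 2*cov*theta + v1*theta^2`, the quadratic form
#' `[1, theta] B [1, theta]'` of the 2x2 intercept/slope block.
#'
#' @param block 2x2 covariance block (intercept/slope).
#' @param theta gradient value(s).
#' @return Variance per theta.
#' @export
additive_variance_at <- function(block, theta) {
  block[1, 1] + 2 * block[1, 2] * theta + block[2, 2] * theta^2
}

#' Heritability at a gradient value
#'
#' Ratio of the additive variance to the total variance at `theta`; every
#' fitted random effect contributes the same quadratic form of its own
#' block, and the residual is `sigma2` or `exp(d0 + d1*theta)`.
#'
#' @param varcomp a `varcomp` (or fitted [rnm()]) object.
#' @param theta gradient value(s).
#' @return Heritability per theta.
#' @export
heritability_at <- function(varcomp, theta) {
  if (inherits(varcomp, "rnm")) varcomp <- varcomp$varcomp
  va <- additive_variance_at(varcomp$blocks$a, theta)
  tot <- 0
  for (B in varcomp$blocks) tot <- tot + additive_variance_at(B, theta)
  tot <- tot + residual_variance_at(varcomp, theta)
  if (any(tot <= 0)) stop("non-positive total variance at some theta")
  va / tot
}

#' Genetic correlation between two environments
#'
#' `cov(u_i, u_i') = v0 + cov*(theta_i + theta_j) + v1*theta_i*theta_j`
#' scaled by the geometric mean of the two additive variances.
#'
#' @param block 2x2 additive block.
#' @param theta_i,theta_j the two gradient values (vectorized).
#' @return Correlation(s) in `[-1, 1]`.
#' @export
env_genetic_correlation <- function(block, theta_i, theta_j) {
  vi <- additive_variance_at(block, theta_i)
  vj <- additive_variance_at(block, theta_j)
  if (any(vi <= 0) || any(vj <= 0))
    stop("zero additive variance at one of the environments")
  cv <- block[1, 1] + block[1, 2] * (theta_i + theta_j) +
    block[2, 2] * theta_i * theta_j
  pmin(1, pmax(-1, cv / sqrt(vi * vj)))
}

#' Genetic correlation between the reaction-norm intercept and slope
#'
#' `cov / sqrt(v0 * v1)` of a 2x2 block.
#'
#' @param block 2x2 covariance block, or a vector `(v0, cov, v1)`.
#' @return The correlation.
#' @export
intercept_slope_correlation <- function(block) {
  if (!is.matrix(block)) block <- block2(block[1], block[2], block[3])
  if (block[1, 1] <= 0 || block[2, 2] <= 0)
    stop("intercept and slope variances must be positive")
  block[1, 2] / sqrt(block[1, 1] * block[2, 2])
}

#' Gradient-dependent parameter curve
#'
#' Additive, total and residual variance plus heritability on a grid of
#' gradient values (by default 101 points spanning the retained gradient).
#'
#' @param fit a fitted [rnm()] model (or a `varcomp` plus explicit grid).
#' @param grid explicit theta grid; computed from the fit's gradient when
#'   `NULL`.
#' @param n_grid grid size when `grid` is `NULL`.
#' @return Data frame of class `parameter_curve`: `theta`, `var_a`,
#'   `var_total`, `var_e`, `h2`.
#' @export
parameter_curve <- function(fit, grid = NULL, n_grid = 101) {
  vc <- if (inherits(fit, "rnm")) fit$varcomp else fit
  if (is.null(grid)) {
    if (!inherits(fit, "rnm"))
      stop("supply an explicit grid when not passing a fitted model")
    th <- fit$gradient$theta[fit$gradient$kept]
    grid <- seq(min(th), max(th), length.out = n_grid)
  }
  va <- additive_variance_at(vc$blocks$a, grid)
  ve <- residual_variance_at(vc, grid)
  tot <- ve
  for (B in vc$blocks) tot <- tot + additive_variance_at(B, grid)
  out <- data.frame(theta = grid, var_a = va, var_total = tot, var_e = ve,
                    h2 = va / tot)
  class(out) <- c("parameter_curve", "data.frame")
  out
}

#' Average and extreme genetic correlations across environments
#'
#' Pairwise [env_genetic_correlation()] over the retained CG gradient
#' values: the mean over all distinct pairs (a reporting convention) and the
#' correlation between the most extreme environments.
#'
#' @param fit a fitted [rnm()] model, or a 2x2 block with `theta` supplied.
#' @param theta optional explicit gradient values.
#' @return List: `mean`, `min`, `extreme` (correlation between min and max
#'   theta), `matrix` (full pairwise matrix).
#' @export
env_correlation_summary <- function(fit, theta = NULL) {
  block <- if (inherits(fit, "rnm")) fit$varcomp$blocks$a else fit
  if (is.null(theta)) {
    stopifnot(inherits(fit, "rnm"))
    theta <- fit$gradient$theta[fit$gradient$kept]
  }
  theta <- sort(theta)
  k <- length(theta)
  M <- outer(theta, theta, function(a, b) env_genetic_correlation(block, a, b))
  dimnames(M) <- list(format(theta, digits = 3), format(theta, digits = 3))
  off <- M[upper.tri(M)]
  list(mean = mean(off), min = min(off),
       extreme = env_genetic_correlation(block, theta[1], theta[k]),
       matrix = M)
}
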