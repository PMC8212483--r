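#' @importFrom stats aggregate ave coef complete.cases cor lm model.matrix
#'   optim pnorm quantile rbinom rnorm rpois runif sd setNames var drop1
#'   as.formula model.frame nlminb logLik AIC terms update.formula na.omit
#'   qnorm
#' @importFrom utils head read.table write.table tail read.csv write.csv
#' @importFrom methods as is new
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Moore-Penrose pseudo-inverse via SVD; used where a cross-product matrix
## may be rank deficient (e.g. more animals than SNPs in back-solving).
pinv <- function(m, tol = NULL) {
  s <- svd(m)
  if (is.null(tol)) tol <- max(dim(m)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

check_block <- function(block, name) {
  if (!is.matrix(block) || !identical(dim(block), c(2L, 2L)))
    stop(sprintf("covariance block for effect '%s' must be a 2x2 matrix", name))
  if (abs(block[1, 2] - block[2, 1]) > 1e-10)
    stop(sprintf("covariance block for effect '%s' is not symmetric", name))
  if (!is_psd(block))
    stop(sprintf("covariance block for effect '%s' is not positive semi-definite",
                 name))
  invisible(block)
}

#' Build a 2x2 intercept-slope covariance block
#'
#' Convenience constructor for the covariance blocks used by [true_params()]
#' and reported by [rnm()].
#'
#' @param v0 intercept variance.
#' @param cov intercept-slope covariance.
#' @param v1 slope variance.
#' @return Symmetric 2x2 matrix with intercept/slope dimnames.
#' @export
block2 <- function(v0, cov, v1) {
  matrix(c(v0, cov, cov, v1), 2, 2,
         dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
}
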