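#' @export
print.rnm <- function(x, ...) {
  cat(sprintf("Single-step reaction norm model (%s, %s residual)\n",
              x$model, x$residual_kind))
  cat(sprintf("  records: %d   fixed effects: %d   random: %s (kernel %s)\n",
              x$n, x$p, paste(x$random, collapse = ", "), x$kernel_kind))
  cat(sprintf("  logL = %.4f   AIC = %.4f   %s\n", x$logLik, x$AIC,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Summarize a fitted reaction-norm model
#'
#' Variance components with average-information standard errors, the
#' intercept-slope genetic correlation, and the fixed-effect estimates.
#'
#' @param object a fitted [rnm()] model.
#' @param ... unused.
#' @export
summary.rnm <- function(object, ...) {
  vc <- object$varcomp
  rows <- list()
  for (nm in names(vc$blocks)) {
    B <- vc$blocks[[nm]]
    rows[[nm]] <- data.frame(
      effect = nm,
      parameter = c("var_intercept", "cov_int_slope", "var_slope"),
      estimate = c(B[1, 1], B[1, 2], B[2, 2]))
  }
  rows$residual <- data.frame(effect = "residual",
                              parameter = names(vc$residual),
                              estimate = unname(vc$residual))
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(vc$se)) {
    key <- c(unlist(lapply(names(vc$blocks), function(nm)
      paste(nm, c("v0", "cov", "v1"), sep = "."))),
      names(vc$residual))
    tab$se <- unname(vc$se$se[key])
  }
  r01 <- vapply(vc$blocks, intercept_slope_correlation, numeric(1))
  out <- list(model = object$model, varcomp_table = tab,
              intercept_slope_correlation = r01,
              beta = object$beta, logLik = object$logLik, AIC = object$AIC,
              n = object$n, converged = object$converged,
              iterations = object$iterations)
  class(out) <- "summary.rnm"
  out
}

#' @export
print.summary.rnm <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.4f, AIC = %.4f, n = %d (%s)\n\n",
              x$model, x$logLik, x$AIC, x$n,
              if (x$converged) "converged" else "not converged"))
  cat("Variance components:\n")
  print(x$varcomp_table, digits = 4, row.names = FALSE)
  cat("\nIntercept-slope genetic correlation:\n")
  print(round(x$intercept_slope_correlation, 4))
  cat("\nFixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.rnm <- function(object, ...) object$beta

#' @export
logLik.rnm <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$nobs,
            class = "logLik")
}

#' @export
fitted.rnm <- function(object, ...) object$fitted

#' @export
residuals.rnm <- function(object, ...) object$residuals

#' Random-effect solutions of a fitted reaction-norm model
#'
#' Per-level intercept and slope solutions (for `effect = "a"` these are the
#' GEBV coefficients) with standard errors from the inverse left-hand side
#' of the mixed-model equations.
#'
#' @param fit a fitted [rnm()] model.
#' @param effect one of the fitted random effects (default `"a"`).
#' @return Data frame: `level`, `intercept`, `slope`, `se_intercept`,
#'   `se_slope`.
#' @export
solutions <- function(fit, effect = "a") {
  stopifnot(inherits(fit, "rnm"))
  if (!effect %in% names(fit$solutions))
    stop("effect '", effect, "' was not fitted")
  fit$solutions[[effect]]
}

#' Predict breeding values along the gradient
#'
#' Evaluates the linear reaction norm `GEBV(theta) = a0 + a1 * theta` for
#' every animal at the requested gradient values.
#'
#' @param object a fitted [rnm()] model.
#' @param theta gradient value(s); default 0 (the intercept GEBV).
#' @param effect which random effect to evaluate (default `"a"`).
#' @param ... unused.
#' @return Matrix animals x theta (dropped to a vector for a single theta).
#' @export
predict.rnm <- function(object, theta = 0, effect = "a", ...) {
  s <- solutions(object, effect)
  out <- outer(s$slope, theta) + s$intercept
  rownames(out) <- s$level
  colnames(out) <- format(theta)
  if (length(theta) == 1L) drop(out) else out
}

#' Plot gradient-dependent parameters of a fit
#'
#' Heritability (and variance) curves over the observed gradient range.
#'
#' @param x a fitted [rnm()] model.
#' @param what `"h2"` or `"variance"`.
#' @param n_grid grid size.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rnm <- function(x, what = c("h2", "variance"), n_grid = 101, ...) {
  what <- match.arg(what)
  pc <- parameter_curve(x, n_grid = n_grid)
  if (what == "h2") {
    graphics::plot(pc$theta, pc$h2, type = "l", xlab = "environmental gradient",
                   ylab = "heritability", ...)
  } else {
    graphics::plot(pc$theta, pc$var_a, type = "l",
                   xlab = "environmental gradient",
                   ylab = "additive genetic variance", ...)
  }
  invisible(pc)
}
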