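#' Evaluate GEBV at gradient values
#'
#' `GEBV(theta) = intercept + slope * theta` per animal.
#'
#' @param table data frame with `intercept` and `slope` columns (e.g. from
#'   [solutions()]).
#' @param theta gradient value(s).
#' @return Vector (single theta) or matrix animals x theta.
#' @export
gebv_at <- function(table, theta) {
  out <- outer(table$slope, theta) + table$intercept
  rownames(out) <- table$level %||% rownames(table)
  if (length(theta) == 1L) drop(out) else out
}

#' GEBV accuracy from prediction-error variance
#'
#' `Acc = sqrt(1 - SE^2 / ((1 + F) * var_coeff))`, with the radicand clamped
#' to `[0, 1]`.  `SE` is the standard error of the intercept or slope
#' solution (square root of the corresponding diagonal of the inverse
#' left-hand side), `F` the pedigree inbreeding coefficient and `var_coeff`
#' the additive variance of the respective coefficient.
#'
#' @param se solution standard error(s).
#' @param f inbreeding coefficient(s), recycled.
#' @param var_coeff additive variance of the coefficient (scalar).
#' @return Accuracies in `[0, 1]`.
#' @export
gebv_accuracy <- function(se, f = 0, var_coeff) {
  if (var_coeff <= 0) stop("var_coeff must be positive")
  if (any(f < 0)) stop("inbreeding coefficients must be >= 0")
  rad <- 1 - se^2 / ((1 + f) * var_coeff)
  sqrt(pmin(1, pmax(0, rad)))
}

#' Accuracy table for a fitted model
#'
#' Convenience: intercept and slope accuracies for every animal of a fitted
#' [rnm()] model, using its pedigree inbreeding and additive block.
#'
#' @param fit a fitted [rnm()] model (with solution SEs).
#' @return Data frame: `level`, `intercept`, `slope`, `acc_intercept`,
#'   `acc_slope`, `F`.
#' @export
accuracy_table <- function(fit) {
  s <- solutions(fit, "a")
  if (is.null(s$se_intercept))
    stop("fit has no solution standard errors (refit with se = TRUE)")
  f <- fit$F[s$level]
  B <- fit$varcomp$blocks$a
  data.frame(level = s$level, intercept = s$intercept, slope = s$slope,
             acc_intercept = gebv_accuracy(s$se_intercept, f, B[1, 1]),
             acc_slope = gebv_accuracy(s$se_slope, f, B[2, 2]),
             F = unname(f), stringsAsFactors = FALSE)
}

#' Weighted Pearson correlation of GEBV between traits
#'
#' Animals with accuracy above `min_acc` on both traits enter; each animal
#' is weighted by `w = Acc_x * Acc_y` (the algebraic value of the
#' accuracy-product weight).  The standard error is
#' `sqrt((1 - r^2) / (n - 2))` with `n` the selected animals.
#'
#' @param x,y GEBV vectors of the two traits (same animals).
#' @param acc_x,acc_y accuracy vectors.
#' @param min_acc selection threshold (default 0.35, strict `>`).
#' @return List of class `gebv_correlation`: `r`, `se`, `n`, `min_acc`.
#' @export
weighted_gebv_correlation <- function(x, y, acc_x, acc_y, min_acc = 0.35) {
  stopifnot(length(x) == length(y), length(acc_x) == length(x),
            length(acc_y) == length(x))
  sel <- acc_x > min_acc & acc_y > min_acc & complete.cases(x, y)
  n <- sum(sel)
  if (n < 3) stop("fewer than 3 animals pass the accuracy threshold")
  x <- x[sel]; y <- y[sel]
  w <- acc_x[sel] * acc_y[sel]
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  cxy <- sum(w * (x - mx) * (y - my)) / sum(w)
  vx <- sum(w * (x - mx)^2) / sum(w)
  vy <- sum(w * (y - my)^2) / sum(w)
  r <- cxy / sqrt(vx * vy)
  se <- sqrt(max(0, 1 - r^2) / (n - 2))
  structure(list(r = r, se = se, n = n, min_acc = min_acc),
            class = "gebv_correlation")
}

#' @export
print.gebv_correlation <- function(x, ...) {
  cat(sprintf("weighted GEBV correlation: r = %.3f (SE %.3f, n = %d, Acc > %.2f)\n",
              x$r, x$se, x$n, x$min_acc))
  invisible(x)
}

#' Number of offspring per animal
#'
#' Counts how often each pedigree animal appears as sire or dam.
#'
#' @param ped a [as_pedigree()] object.
#' @return Named integer vector over all animals (zeros included).
#' @export
offspring_counts <- function(ped) {
  cnt <- table(factor(c(ped$sire, ped$dam), levels = ped$animal))
  setNames(as.integer(cnt), ped$animal)
}

#' Rank stability of GEBV across representative environments
#'
#' Evaluates GEBV at quantiles of the retained gradient (by default the 15,
#' 50 and 85 percent quantiles: a poor, a medium and a good environment),
#' restricts to animals with more than `min_offspring` offspring and
#' accuracy above `min_acc` for both coefficients, and returns the pairwise
#' Spearman rank correlations (ties as average ranks).
#'
#' @param fit a fitted [rnm()] model with solution SEs.
#' @param ped pedigree (for offspring counts).
#' @param quantiles gradient quantiles defining the environments.
#' @param min_offspring strict offspring threshold (default 10).
#' @param min_acc strict accuracy threshold (default 0.30).
#' @return List: `spearman` (matrix), `theta` (environment values), `n`.
#' @export
rank_stability <- function(fit, ped, quantiles = c(0.15, 0.50, 0.85),
                           min_offspring = 10, min_acc = 0.30) {
  th <- fit$gradient$theta[fit$gradient$kept]
  if (!length(th)) stop("empty gradient")
  qs <- quantile(th, quantiles, names = FALSE)
  acc <- accuracy_table(fit)
  off <- offspring_counts(ped)[acc$level]
  sel <- off > min_offspring & acc$acc_intercept > min_acc &
    acc$acc_slope > min_acc
  if (!any(sel)) stop("no animals pass the offspring/accuracy thresholds")
  g <- gebv_at(acc[sel, ], qs)
  S <- cor(g, method = "spearman")
  dimnames(S) <- list(format(qs, digits = 3), format(qs, digits = 3))
  list(spearman = S, theta = qs, n = sum(sel))
}

#' GEBV trajectories of extreme-slope sires
#'
#' Among sires with more than `min_offspring` offspring, selects the `top_k`
#' highest- and lowest-slope animals and returns their reaction-norm lines
#' over a gradient grid.
#'
#' @param fit a fitted [rnm()] model.
#' @param ped pedigree.
#' @param min_offspring strict threshold (default 30).
#' @param top_k sires per tail (default 20).
#' @param grid theta grid (default 41 points over the retained gradient).
#' @return Data frame: `level`, `group` (`"high"`/`"low"`), `theta`, `gebv`.
#' @export
sire_trajectories <- function(fit, ped, min_offspring = 30, top_k = 20,
                              grid = NULL) {
  s <- solutions(fit, "a")
  sires <- unique(na.omit(ped$sire))
  off <- offspring_counts(ped)
  qual <- sires[off[sires] > min_offspring]
  s <- s[s$level %in% qual, , drop = FALSE]
  if (nrow(s) < 2 * top_k) {
    warning(sprintf("only %d qualifying sires for 2 x %d requested",
                    nrow(s), top_k))
  }
  if (!nrow(s)) return(data.frame(level = character(0), group = character(0),
                                  theta = numeric(0), gebv = numeric(0)))
  s <- s[order(s$slope), ]
  lo <- head(s, min(top_k, nrow(s)))
  hi <- tail(s, min(top_k, nrow(s)))
  if (is.null(grid)) {
    th <- fit$gradient$theta[fit$gradient$kept]
    grid <- seq(min(th), max(th), length.out = 41)
  }
  mk <- function(d, gname) {
    do.call(rbind, lapply(seq_len(nrow(d)), function(i)
      data.frame(level = d$level[i], group = gname, theta = grid,
                 gebv = d$intercept[i] + d$slope[i] * grid,
                 stringsAsFactors = FALSE)))
  }
  rbind(mk(hi, "high"), mk(lo, "low"))
}
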