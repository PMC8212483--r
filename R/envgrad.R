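#' Apply record-level filters
#'
#' Removes contemporary groups with too few records and phenotypic outliers.
#' CGs with fewer than `min_cg` records are dropped first; outliers are then
#' records deviating from the trait mean by more than `sd_cut` standard
#' deviations, with mean and SD computed before any outlier is removed.
#'
#' @param pheno data frame with at least `y` and `cg` columns.
#' @param min_cg minimum records per CG (default 10).
#' @param sd_cut outlier cut in SD units (default 3.5).
#' @return Filtered data frame; attribute `"filter_log"` reconciles counts
#'   (`n_in = n_out + n_small_cg + n_outlier`).
#' @export
apply_record_filters <- function(pheno, min_cg = 10, sd_cut = 3.5) {
  if (!nrow(pheno)) stop("empty phenotype table")
  n_in <- nrow(pheno)
  cnt <- table(pheno$cg)
  small <- names(cnt)[cnt < min_cg]
  keep1 <- !(pheno$cg %in% small)
  n_small <- sum(!keep1)
  pheno <- pheno[keep1, , drop = FALSE]
  if (!nrow(pheno)) stop("record filters removed every record")
  mu <- mean(pheno$y); s <- sd(pheno$y)
  out <- if (is.na(s) || s == 0) rep(FALSE, nrow(pheno)) else
    abs(pheno$y - mu) > sd_cut * s
  n_outlier <- sum(out)
  pheno <- pheno[!out, , drop = FALSE]
  if (!nrow(pheno)) stop("record filters removed every record")
  rownames(pheno) <- NULL
  attr(pheno, "filter_log") <- list(n_in = n_in, n_small_cg = n_small,
                                    dropped_cgs = small,
                                    n_outlier = n_outlier,
                                    n_out = nrow(pheno))
  pheno
}

#' Backward elimination of fixed effects
#'
#' Repeatedly drops the least significant candidate term whose partial-F
#' p-value is at or above `alpha` from an ordinary linear model; the CG
#' factor is always retained.  Mirrors standard model pruning with
#' `lm`/`drop1`.
#'
#' @param pheno phenotype data frame (response `y`).
#' @param candidates character vector of candidate terms, e.g.
#'   `c("factor(parity)", "age", "I(age^2)")`.
#' @param alpha retention threshold (default 0.05).
#' @param keep terms never dropped (default `"factor(cg)"`).
#' @return List (`ModelSpec`): `fixed` = retained candidate terms, `keep`,
#'   and the elimination `trace`.
#' @export
select_fixed_effects <- function(pheno, candidates, alpha = 0.05,
                                 keep = "factor(cg)") {
  terms_now <- candidates
  trace <- character(0)
  repeat {
    fml <- as.formula(paste("y ~", paste(c(keep, terms_now), collapse = " + ")))
    fit <- lm(fml, data = pheno)
    if (any(is.na(coef(fit)))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      stop("rank-deficient design; confounded terms: ",
           paste(bad, collapse = ", "))
    }
    if (!length(terms_now)) break
    dr <- drop1(fit, scope = as.formula(paste("~", paste(terms_now, collapse = "+"))),
                test = "F")
    pv <- dr[["Pr(>F)"]][-1]
    names(pv) <- rownames(dr)[-1]
    pv <- pv[!is.na(pv)]
    if (!length(pv)) break
    worst <- names(pv)[which.max(pv)]
    if (pv[worst] < alpha) break
    trace <- c(trace, sprintf("dropped %s (p = %.4g)", worst, pv[worst]))
    terms_now <- setdiff(terms_now, worst)
  }
  list(fixed = terms_now, keep = keep, trace = trace)
}

#' BLUE estimates of contemporary-group effects
#'
#' Solves a fixed-effects-only linear model containing the systematic effects
#' plus the CG factor by ordinary least squares, returning one estimate per
#' CG under a sum-to-zero identifiability constraint (so the raw estimates
#' are centered before standardization).
#'
#' @param pheno phenotype data frame (`y`, `cg`, covariate columns).
#' @param fixed character vector of systematic-effect terms besides CG
#'   (may be empty).
#' @return Data frame `cg`, `estimate`, `n`.
#' @export
estimate_cg_effects <- function(pheno, fixed = character(0)) {
  pheno <- as.data.frame(pheno)
  pheno$.cg <- factor(pheno$cg)
  ncg <- nlevels(pheno$.cg)
  if (ncg == 1L) {
    return(data.frame(cg = levels(pheno$.cg), estimate = 0,
                      n = nrow(pheno), stringsAsFactors = FALSE))
  }
  rhs <- paste(c(".cg", fixed), collapse = " + ")
  fit <- lm(as.formula(paste("y ~", rhs)), data = pheno,
            contrasts = list(.cg = "contr.sum"))
  cf <- coef(fit)
  cg_cf <- cf[grep("^\\.cg", names(cf))]
  if (anyNA(cg_cf) || anyNA(cf))
    stop("contemporary groups confounded with other model terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  est <- c(cg_cf, -sum(cg_cf))
  data.frame(cg = levels(pheno$.cg), estimate = unname(est),
             n = as.integer(table(pheno$.cg)), stringsAsFactors = FALSE)
}

#' Standardize CG estimates into an environmental gradient
#'
#' Z-scores the raw CG estimates, drops CGs beyond `sd_cut` SD, and
#' re-standardizes the remainder (iterating until no retained value exceeds
#' the cut), so the retained gradient has mean 0 and SD 1 exactly.
#'
#' @param raw data frame from [estimate_cg_effects()] (or a named numeric
#'   vector of raw estimates).
#' @param sd_cut outlier cut (default 3.5).
#' @return Data frame of class `env_gradient`: `cg`, `raw`, `theta`, `n`,
#'   `kept`.  Dropped CGs have `NA` theta.
#' @export
standardize_gradient <- function(raw, sd_cut = 3.5) {
  if (is.numeric(raw))
    raw <- data.frame(cg = names(raw) %||% as.character(seq_along(raw)),
                      estimate = unname(raw), n = NA_integer_)
  if (nrow(raw) < 2) stop("need at least two CGs to standardize")
  kept <- rep(TRUE, nrow(raw))
  theta <- rep(NA_real_, nrow(raw))
  repeat {
    x <- raw$estimate[kept]
    s <- sd(x)
    if (is.na(s) || s == 0) stop("zero variance among CG estimates")
    z <- (x - mean(x)) / s
    drop <- abs(z) > sd_cut
    if (!any(drop)) {
      theta[kept] <- z
      break
    }
    kept[kept][drop] <- FALSE
    if (sum(kept) < 2) stop("gradient standardization dropped almost all CGs")
  }
  out <- data.frame(cg = raw$cg, raw = raw$estimate, theta = theta,
                    n = raw$n, kept = kept, stringsAsFactors = FALSE)
  class(out) <- c("env_gradient", "data.frame")
  out
}

#' Estimate the environmental gradient from phenotypes
#'
#' Convenience wrapper: [estimate_cg_effects()] followed by
#' [standardize_gradient()].
#'
#' @inheritParams estimate_cg_effects
#' @inheritParams standardize_gradient
#' @return An `env_gradient` object.
#' @export
env_gradient <- function(pheno, fixed = character(0), sd_cut = 3.5) {
  standardize_gradient(estimate_cg_effects(pheno, fixed), sd_cut = sd_cut)
}

#' Look up gradient values for records
#'
#' @param gradient an `env_gradient` object.
#' @param cg vector of CG keys.
#' @return Numeric theta per record; errors if any record's CG has no
#'   retained gradient value.
#' @export
gradient_for <- function(gradient, cg) {
  th <- setNames(gradient$theta, gradient$cg)
  out <- th[as.character(cg)]
  if (anyNA(out))
    stop("records in CGs without a retained gradient value: ",
         paste(unique(cg[is.na(out)]), collapse = ", "))
  unname(out)
}

#' AIC-based selection of the random-effect structure
#'
#' Fits each candidate subset of random effects with [rnm()] on the same
#' data and returns the subset (and fit) with the smallest AIC.
#'
#' @param pheno,gradient,... passed to [rnm()].
#' @param subsets list of character vectors, each containing `"a"`.
#' @return List: `random` (winning subset), `fit`, `aic` (named vector).
#' @export
select_random_effects <- function(pheno, gradient, subsets, ...) {
  stopifnot(length(subsets) >= 1)
  for (s in subsets) if (!"a" %in% s)
    stop("every candidate subset must contain the additive effect 'a'")
  fits <- lapply(subsets, function(s) rnm(data = pheno, gradient = gradient,
                                          random = s, ...))
  aic <- vapply(fits, AIC, numeric(1))
  names(aic) <- vapply(subsets, paste, character(1), collapse = "+")
  best <- which.min(aic)
  list(random = subsets[[best]], fit = fits[[best]], aic = aic)
}
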