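#' Back-solve SNP effects from GEBV
#'
#' `u = Z' (Z Z')^{-1} a` with identity SNP-variance weighting: the
#' minimum-norm SNP-effect vector whose genomic values reproduce the GEBV of
#' the genotyped animals.  A pseudo-inverse is used when `Z Z'` is singular
#' (e.g. fewer SNPs than animals).
#'
#' @param Z column-centered genotype matrix of the genotyped animals.
#' @param gebv GEBV vector for those animals (intercept or slope).
#' @return Named numeric vector of SNP effects.
#' @export
backsolve_snp_effects <- function(Z, gebv) {
  if (nrow(Z) != length(gebv))
    stop(sprintf("dimension mismatch: %d animals in Z, %d GEBV",
                 nrow(Z), length(gebv)))
  ZZt <- tcrossprod(Z)
  sol <- tryCatch(solve(ZZt, gebv), error = function(e) NULL)
  if (is.null(sol)) sol <- pinv(ZZt) %*% gebv
  u <- as.numeric(crossprod(Z, sol))
  names(u) <- colnames(Z)
  u
}

#' SNP effects for the reaction-norm intercept and slope
#'
#' Back-solves the intercept and slope GEBV of a fitted model through the
#' genotype matrix, restricted to genotyped animals.
#'
#' @param fit a fitted [rnm()] model.
#' @param geno a [genotypes()] object (same animals as in the fit).
#' @return Data frame of class `snp_effects`: `snp`, `chr`, `bp`, `u0`
#'   (intercept effect), `u1` (slope effect); attribute `"Z"` holds the
#'   centered genotype matrix used.
#' @export
snp_effects <- function(fit, geno) {
  ids <- intersect(fit$genotyped_ids, rownames(geno$dosage))
  if (length(ids) < 2) stop("no genotyped animals shared with the fit")
  Z <- center_dosages(geno, ids)
  s <- solutions(fit, "a")
  s <- s[match(ids, s$level), ]
  out <- data.frame(snp = geno$map$snp, chr = geno$map$chr, bp = geno$map$bp,
                    u0 = backsolve_snp_effects(Z, s$intercept),
                    u1 = backsolve_snp_effects(Z, s$slope),
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_effects", "data.frame")
  attr(out, "Z") <- Z
  out
}

#' Variance explained by sliding genomic windows
#'
#' For every window of `window` map-adjacent SNPs (stride 1, never spanning
#' chromosomes) computes the variance over genotyped animals of the windowed
#' genomic value `g_wj = sum_k z_jk u_k`, as a percentage of the additive
#' variance of the respective coefficient: intercept effects against
#' `var_a0`, slope effects against `var_a1`.
#'
#' @param effects a [snp_effects()] data frame (or one with `snp`, `chr`,
#'   `bp`, `u0`, `u1`).
#' @param Z centered genotype matrix (defaults to the attribute stored by
#'   [snp_effects()]); columns must match `effects` rows.
#' @param var_a0,var_a1 additive variances of intercept and slope.
#' @param window SNPs per window (default 5).
#' @return Data frame of class `genomic_windows`: `chr`, `start`, `end`,
#'   `first_snp`, `pct_intercept`, `pct_slope`.
#' @export
window_variance_proportions <- function(effects, Z = attr(effects, "Z"),
                                        var_a0, var_a1, window = 5) {
  if (var_a0 <= 0 || var_a1 <= 0) stop("additive variances must be positive")
  if (is.null(Z)) stop("supply the centered genotype matrix Z")
  if (ncol(Z) != nrow(effects)) stop("Z columns must match SNP effects rows")
  res <- list()
  for (ch in unique(effects$chr)) {
    ix <- which(effects$chr == ch)
    if (length(ix) < window) {
      warning(sprintf("chromosome %s has fewer than %d SNPs: no windows", ch,
                      window))
      next
    }
    ## cumulative genomic values: variance of each window slice
    g0 <- Z[, ix, drop = FALSE] %*% diag(effects$u0[ix], length(ix))
    g1 <- Z[, ix, drop = FALSE] %*% diag(effects$u1[ix], length(ix))
    c0 <- cbind(0, t(apply(g0, 1, cumsum)))
    c1 <- cbind(0, t(apply(g1, 1, cumsum)))
    nw <- length(ix) - window + 1L
    starts <- seq_len(nw)
    v0 <- vapply(starts, function(s)
      var(c0[, s + window] - c0[, s]), numeric(1))
    v1 <- vapply(starts, function(s)
      var(c1[, s + window] - c1[, s]), numeric(1))
    res[[ch]] <- data.frame(
      chr = ch,
      start = effects$bp[ix[starts]],
      end = effects$bp[ix[starts + window - 1L]],
      first_snp = effects$snp[ix[starts]],
      pct_intercept = 100 * v0 / var_a0,
      pct_slope = 100 * v1 / var_a1,
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chr = character(0), start = numeric(0), end = numeric(0),
               first_snp = character(0), pct_intercept = numeric(0),
               pct_slope = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("genomic_windows", "data.frame")
  out
}

#' Concatenate relevant windows into candidate regions
#'
#' Windows explaining at least `threshold_percent` of the additive variance
#' are retained; overlapping retained windows on the same chromosome are
#' merged into regions spanning the minimum start to the maximum end
#' (1-based inclusive coordinates).
#'
#' @param windows a [window_variance_proportions()] data frame.
#' @param coefficient `"intercept"` or `"slope"`: which percentage column to
#'   threshold.
#' @param threshold_percent relevance threshold (default 0.5; `>=`).
#' @return Data frame: `chr`, `start`, `end`, `n_windows`, `max_percent`,
#'   `coefficient`.  Zero rows when nothing is relevant.
#' @export
find_relevant_regions <- function(windows,
                                  coefficient = c("slope", "intercept"),
                                  threshold_percent = 0.5) {
  coefficient <- match.arg(coefficient)
  pct <- windows[[paste0("pct_", coefficient)]]
  rel <- windows[pct >= threshold_percent, , drop = FALSE]
  relpct <- pct[pct >= threshold_percent]
  if (!nrow(rel))
    return(data.frame(chr = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      max_percent = numeric(0), coefficient = character(0)))
  out <- list()
  for (ch in unique(rel$chr)) {
    d <- rel[rel$chr == ch, ]
    pc <- relpct[rel$chr == ch]
    o <- order(d$start)
    d <- d[o, ]; pc <- pc[o]
    cs <- d$start[1]; ce <- d$end[1]; nw <- 1L; mp <- pc[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= ce) {
        ce <- max(ce, d$end[i]); nw <- nw + 1L; mp <- max(mp, pc[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(
          chr = ch, start = cs, end = ce, n_windows = nw, max_percent = mp,
          coefficient = coefficient, stringsAsFactors = FALSE)
        cs <- d$start[i]; ce <- d$end[i]; nw <- 1L; mp <- pc[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      chr = ch, start = cs, end = ce, n_windows = nw, max_percent = mp,
      coefficient = coefficient, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
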