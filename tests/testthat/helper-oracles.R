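# Independent reference implementations used to validate the package
# internals.  Each oracle is written in the most transparent form available
# (recursions and dense linear algebra), deliberately sharing no code with
# the package.

# Additive relationship by recursive coancestry:
# f(i, j) = coancestry; A[i, j] = 2 f(i, j).  Memoised on the pair.
oracle_A <- function(ped) {
  ord <- ped$animal
  sire <- match(ped$sire, ord)
  dam <- match(ped$dam, ord)
  n <- length(ord)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i > j) { k <- i; i <- j; j <- k }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      si <- sire[i]; di <- dam[i]
      0.5 * (1 + f(ifelse(is.na(si), 0, si), ifelse(is.na(di), 0, di)))
    } else {
      # j is the younger animal (pedigree is parent-before-offspring)
      sj <- sire[j]; dj <- dam[j]
      0.5 * (f(i, ifelse(is.na(sj), 0, sj)) +
               f(i, ifelse(is.na(dj), 0, dj)))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ord, ord))
  for (i in seq_len(n))
    for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# VanRaden method-1 genomic relationship, element by element.
oracle_G <- function(M, p, A22 = NULL, blend = 0) {
  n <- nrow(M)
  denom <- 2 * sum(p * (1 - p))
  G <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n))
    for (j in seq_len(n)) {
      s <- 0
      for (k in seq_len(ncol(M)))
        s <- s + (M[i, k] - 2 * p[k]) * (M[j, k] - 2 * p[k])
      G[i, j] <- s / denom
    }
  if (blend > 0) G <- (1 - blend) * G + blend * A22
  G
}

# H built directly (Legarra et al. form), then inverted densely.
oracle_Hinv <- function(A, G, gids) {
  ids <- rownames(A)
  g <- match(gids, ids)
  ng <- setdiff(seq_along(ids), g)
  A11 <- A[ng, ng, drop = FALSE]; A12 <- A[ng, g, drop = FALSE]
  A21 <- A[g, ng, drop = FALSE]; A22 <- A[g, g, drop = FALSE]
  A22i <- solve(A22)
  H <- A
  H[ng, ng] <- A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% A21
  H[ng, g] <- A12 %*% A22i %*% G
  H[g, ng] <- G %*% A22i %*% A21
  H[g, g] <- G
  solve(H)
}

# Dense-V restricted likelihood (-2 logL) of a reaction-norm model.
# kernels: named list of relationship matrices per random effect (animals /
# litters in the order of `levels`); blocks: 2x2 covariance per effect;
# design: record-level incidence index per effect.
oracle_m2logL <- function(y, X, theta, effects, resid_var) {
  n <- length(y)
  V <- diag(resid_var, n)
  for (e in effects) {
    q <- nrow(e$K)
    Wd <- matrix(0, n, 2 * q)
    for (r in seq_len(n)) {
      Wd[r, e$j[r]] <- 1
      Wd[r, q + e$j[r]] <- theta[r]
    }
    V <- V + Wd %*% kronecker(e$B, e$K) %*% t(Wd)
  }
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  as.numeric(determinant(V)$modulus + determinant(XtViX)$modulus +
               t(y) %*% P %*% y + (n - ncol(X)) * log(2 * pi))
}

# Brute-force sliding-window variance proportions.
oracle_windows <- function(Z, u, chr, bp, var_ref, window = 5) {
  out <- NULL
  for (ch in unique(chr)) {
    ix <- which(chr == ch)
    if (length(ix) < window) next
    for (s in seq_len(length(ix) - window + 1)) {
      cols <- ix[s:(s + window - 1)]
      g <- as.numeric(Z[, cols, drop = FALSE] %*% u[cols])
      out <- rbind(out, data.frame(chr = ch, start = bp[cols[1]],
                                   end = bp[cols[window]],
                                   pct = 100 * var(g) / var_ref))
    }
  }
  out
}

# Small deterministic demo dataset shared across module tests.
make_demo <- function(seed = 42, n_founders = 30, n_generations = 3,
                      n_cg = 8, ...) {
  cfg <- sim_config(n_founders = n_founders, n_generations = n_generations,
                    n_cg = n_cg, seed = seed, ...)
  simulate_dataset(cfg, true_params())
}
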