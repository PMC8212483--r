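#' Control parameters for the reaction-norm REML fit
#'
#' @param rel_tol relative convergence tolerance of the optimizer.
#' @param iter_max,eval_max optimizer iteration / evaluation caps.
#' @param r_bound boundary at which intercept-slope correlations are pinned
#'   (default 0.9999, reported as such when the optimum lies on the bound).
#' @param lv_span half-width of the log-variance search box around the
#'   phenotypic variance.
#' @param trace optimizer trace level.
#' @return List of class `rnm_control`.
#' @export
rnm_control <- function(rel_tol = 1e-8, iter_max = 400, eval_max = 3000,
                        r_bound = 0.9999, lv_span = 25, trace = 0) {
  structure(list(rel_tol = rel_tol, iter_max = iter_max, eval_max = eval_max,
                 r_bound = r_bound, lv_span = lv_span, trace = trace),
            class = "rnm_control")
}

#' Additive-effect inverse covariance kernel
#'
#' Builds the inverse relationship structure used for the additive genetic
#' effect: the sparse pedigree inverse `A^{-1}` when no genotypes are given,
#' or the single-step hybrid inverse `H^{-1}` when a genotyped subset is
#' available (VanRaden method-1 `G`, blended toward `A22`).
#'
#' @param pedigree a [as_pedigree()] object.
#' @param geno optional [genotypes()] object; animals flagged `genotyped`
#'   enter the genomic block.
#' @param blend blending weight of `G` toward `A22` (default 0.05).
#' @param include_x include X-chromosome SNPs in `G` (default `TRUE`; males
#'   are hemizygous-coded \{0, 2\}).  Setting `FALSE` reproduces the
#'   autosome-only sensitivity scenario.
#' @return List: `Kinv` (sparse), `logdetK`, `F` (inbreeding), `ids`,
#'   `genotyped_ids`, `kind` (`"A"` or `"H"`).
#' @export
additive_kernel <- function(pedigree, geno = NULL, blend = 0.05,
                            include_x = TRUE) {
  f <- inbreeding(pedigree)
  Ainv <- build_Ainv(pedigree, f)
  gids <- character(0)
  if (!is.null(geno)) gids <- rownames(geno$dosage)[geno$genotyped]
  if (length(gids) >= 2) {
    if (!all(gids %in% pedigree$animal))
      stop("genotyped animals absent from pedigree: ",
           paste(setdiff(gids, pedigree$animal), collapse = ", "))
    g2 <- geno
    if (!include_x) {
      keep <- g2$map$chr != "X"
      g2$dosage <- g2$dosage[, keep, drop = FALSE]
      g2$map <- g2$map[keep, , drop = FALSE]
    }
    A <- build_A(pedigree)
    A22 <- A[gids, gids]
    G <- build_G(g2, A22 = A22, blend = blend)
    Kinv <- build_Hinv(Ainv, invert_G(G), solve(A22), gids)
    kind <- "H"
  } else {
    Kinv <- Ainv
    kind <- "A"
  }
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(as(Kinv, "CsparseMatrix")),
                         LDL = FALSE, perm = TRUE)
  ld <- -2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  list(Kinv = Kinv, logdetK = ld, chol_Kinv = ch, F = f,
       ids = pedigree$animal, genotyped_ids = gids, kind = kind)
}

## ---- internal model context -------------------------------------------

rnm_context <- function(fixed, data, gradient, random, residual,
                        pedigree = NULL, genotypes = NULL, kernel = NULL,
                        animal = "animal", litter = "litter", cg = "cg",
                        cg_as_class = FALSE, blend = 0.05, include_x = TRUE) {
  data <- as.data.frame(data)
  random <- match.arg(random, c("a", "pe", "ce"), several.ok = TRUE)
  if (!"a" %in% random) stop("the additive effect 'a' must be fitted")
  theta <- gradient_for(gradient, data[[cg]])
  y <- data$y
  if (!is.numeric(y) || anyNA(y)) stop("response 'y' must be numeric, no NAs")
  n <- length(y)

  ## fixed design: user terms plus either b*theta or CG classes
  X <- model.matrix(fixed, data)
  if (cg_as_class) {
    Xcg <- model.matrix(~ factor(data[[cg]]))[, -1, drop = FALSE]
    colnames(Xcg) <- paste0("cg", seq_len(ncol(Xcg)))
    X <- cbind(X, Xcg)
  } else {
    X <- cbind(X, `b.theta` = theta)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- qx$pivot[-seq_len(qx$rank)]
    X <- X[, -drop_cols, drop = FALSE]
  }
  p <- ncol(X)

  if (is.null(kernel)) {
    if (is.null(pedigree)) stop("supply a pedigree or a precomputed kernel")
    kernel <- additive_kernel(pedigree, genotypes, blend = blend,
                              include_x = include_x)
  }
  aid <- match(data[[animal]], kernel$ids)
  if (anyNA(aid))
    stop("records for animals absent from the pedigree: ",
         paste(unique(data[[animal]][is.na(aid)]), collapse = ", "))

  eff <- list()
  rec <- seq_len(n)
  for (e in random) {
    if (e == "a") {
      q <- length(kernel$ids)
      lev <- kernel$ids
      j <- aid
      Kinv <- kernel$Kinv
      ldK <- kernel$logdetK
      chK <- kernel$chol_Kinv
    } else if (e == "pe") {
      lev <- unique(data[[animal]])
      q <- length(lev)
      j <- match(data[[animal]], lev)
      Kinv <- NULL; ldK <- 0; chK <- NULL
    } else {
      if (is.null(data[[litter]])) stop("'ce' requested but no litter column")
      lev <- unique(as.character(data[[litter]]))
      q <- length(lev)
      j <- match(as.character(data[[litter]]), lev)
      Kinv <- NULL; ldK <- 0; chK <- NULL
    }
    W <- Matrix::sparseMatrix(i = c(rec, rec), j = c(j, q + j),
                              x = c(rep(1, n), theta), dims = c(n, 2L * q))
    eff[[e]] <- list(name = e, q = q, levels = lev, W = W,
                     Kinv = Kinv, ldK = ldK, chK = chK)
  }
  Wall <- do.call(cbind, lapply(eff, `[[`, "W"))
  off <- cumsum(c(0, vapply(eff, function(e) 2L * e$q, integer(1))))
  for (i in seq_along(eff)) eff[[i]]$cols <- off[i] + seq_len(2L * eff[[i]]$q)

  list(y = y, X = X, W = Wall, eff = eff, theta = theta, n = n, p = p,
       residual = residual, kernel = kernel, gradient = gradient,
       random = random, cache = new.env(parent = emptyenv()),
       data_hash = c(n = n, sy = sum(y), syy = sum(y^2)))
}

## precomputed triplet layouts of the MME coefficient matrix; the same
## pattern is emitted at every likelihood evaluation so the sparse Cholesky
## can reuse its symbolic analysis
mme_templates <- function(ctx) {
  p <- ctx$p
  M <- ncol(ctx$W)
  g <- list()
  for (e in ctx$eff) {
    K <- if (is.null(e$Kinv)) Matrix::Diagonal(e$q) else e$Kinv
    K <- as(as(K, "generalMatrix"), "TsparseMatrix")
    ki <- K@i + 1L; kj <- K@j + 1L; kx <- K@x
    q <- e$q
    off <- p + e$cols[1] - 1L
    g[[e$name]] <- list(
      ci = off + c(ki, q + ki, ki, q + ki),
      cj = off + c(kj, kj, q + kj, q + kj),
      code = rep(1:4, each = length(kx)),
      xk = rep(kx, 4))
  }
  list(xtx_ci = rep(seq_len(p), times = p),
       xtx_cj = rep(seq_len(p), each = p),
       xtw_ci = c(p + rep(seq_len(M), p), rep(seq_len(p), each = M)),
       xtw_cj = c(rep(seq_len(p), each = M), p + rep(seq_len(M), p)),
       g = g,
       g_ci = unlist(lapply(g, `[[`, "ci"), use.names = FALSE),
       g_cj = unlist(lapply(g, `[[`, "cj"), use.names = FALSE),
       dim = p + M)
}

## parameter packing: per effect (log v0, atanh r, log v1); then d0 (+ d1)
unpack_par <- function(par, ctx) {
  k <- 0L
  blocks <- list()
  for (e in ctx$eff) {
    v0 <- exp(par[k + 1]); r <- tanh(par[k + 2]); v1 <- exp(par[k + 3])
    blocks[[e$name]] <- block2(v0, r * sqrt(v0 * v1), v1)
    k <- k + 3L
  }
  if (ctx$residual == "heteroscedastic") {
    d0 <- par[k + 1]; d1 <- par[k + 2]
  } else {
    d0 <- par[k + 1]; d1 <- 0
  }
  list(blocks = blocks, d0 = d0, d1 = d1)
}

block_inverse <- function(B) {
  det <- B[1, 1] * B[2, 2] - B[1, 2]^2
  if (det <= 0) return(NULL)
  matrix(c(B[2, 2], -B[1, 2], -B[1, 2], B[1, 1]), 2, 2) / det
}

## assemble the mixed-model equations for given parameter values
mme_parts <- function(ctx, vp) {
  ve <- exp(vp$d0 + vp$d1 * ctx$theta)
  sqrtri <- 1 / sqrt(ve)
  Xs <- ctx$X * sqrtri
  Ws <- ctx$W * sqrtri
  ys <- ctx$y * sqrtri
  cache <- ctx$cache
  if (is.null(cache$tmpl)) cache$tmpl <- mme_templates(ctx)
  tm <- cache$tmpl
  M <- ncol(ctx$W)

  xtx <- as.numeric(crossprod(Xs))
  xtw <- as.numeric(as.matrix(Matrix::crossprod(Ws, Xs)))

  w <- Matrix::crossprod(Ws)
  wi <- w@i + 1L
  if (is.null(cache$wtw) || !identical(wi, cache$wtw$wi)) {
    wj <- rep.int(seq_len(M), diff(w@p))
    sym <- methods::is(w, "symmetricMatrix")
    m <- if (sym) wi != wj else logical(0)
    cache$wtw <- list(wi = wi, sym = sym, m = m,
                      ci = ctx$p + c(wi, wj[m]),
                      cj = ctx$p + c(wj, wi[m]))
  }
  wc <- cache$wtw
  wx <- if (wc$sym) c(w@x, w@x[wc$m]) else w@x

  gx <- unlist(lapply(ctx$eff, function(e) {
    Bi <- block_inverse(vp$blocks[[e$name]])
    if (is.null(Bi)) stop("singular covariance block") # caught by objective
    t <- tm$g[[e$name]]
    c(Bi)[t$code] * t$xk
  }), use.names = FALSE)

  C <- Matrix::sparseMatrix(
    i = c(tm$xtx_ci, tm$xtw_ci, wc$ci, tm$g_ci),
    j = c(tm$xtx_cj, tm$xtw_cj, wc$cj, tm$g_cj),
    x = c(xtx, xtw, xtw, wx, gx),
    dims = c(tm$dim, tm$dim))
  C <- Matrix::forceSymmetric(C)
  rhs <- c(as.numeric(crossprod(Xs, ys)),
           as.numeric(Matrix::crossprod(Ws, ys)))
  list(C = C, rhs = rhs, ve = ve, ys = ys, ldR = sum(log(ve)))
}

minus2_logLik <- function(ctx, vp, parts = NULL, return_sol = FALSE) {
  if (is.null(parts)) parts <- mme_parts(ctx, vp)
  ch <- NULL
  if (!is.null(ctx$cache$chol))
    ch <- tryCatch(Matrix::update(ctx$cache$chol, parts$C),
                   error = function(e) NULL)
  if (is.null(ch)) ch <- Matrix::Cholesky(parts$C, LDL = FALSE, perm = TRUE)
  ctx$cache$chol <- ch
  ldC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  sol <- as.numeric(Matrix::solve(ch, parts$rhs, system = "A"))
  yPy <- sum(parts$ys^2) - sum(sol * parts$rhs)
  ldG <- 0
  for (e in ctx$eff) {
    B <- vp$blocks[[e$name]]
    det <- B[1, 1] * B[2, 2] - B[1, 2]^2
    ldG <- ldG + e$q * log(det) + 2 * e$ldK
  }
  m2 <- parts$ldR + ldG + ldC + yPy + (ctx$n - ctx$p) * log(2 * pi)
  if (return_sol) list(m2 = m2, sol = sol, ch = ch, parts = parts) else m2
}

rnm_start <- function(ctx, init) {
  vy <- var(ctx$y)
  par <- numeric(0)
  for (e in ctx$eff) {
    v0 <- if (e$name == "a") 0.5 * vy else 0.1 * vy
    par <- c(par, log(v0), 0, log(0.1 * vy))
  }
  par <- c(par, log(0.4 * vy))
  if (ctx$residual == "heteroscedastic") par <- c(par, 0)
  if (!is.null(init)) par[seq_along(init)] <- init
  par
}

rnm_bounds <- function(ctx, control) {
  vy <- var(ctx$y)
  zmax <- atanh(control$r_bound)
  lo <- hi <- numeric(0)
  for (e in ctx$eff) {
    lo <- c(lo, log(vy) - control$lv_span, -zmax, log(vy) - control$lv_span)
    hi <- c(hi, log(vy) + 6, zmax, log(vy) + 6)
  }
  lo <- c(lo, log(vy) - control$lv_span)
  hi <- c(hi, log(vy) + 6)
  if (ctx$residual == "heteroscedastic") {
    lo <- c(lo, -5); hi <- c(hi, 5)
  }
  list(lower = lo, upper = hi)
}

#' Assemble Henderson's mixed-model equations for a reaction-norm model
#'
#' Exposes the coefficient matrix and right-hand side of the single-step
#' reaction-norm mixed model at given (co)variance values: per random effect
#' the design carries an intercept column (1) and a slope column (theta per
#' record), the additive effect has inverse covariance `B^-1` kron `K^-1`
#' (with `K = H` or `A`), and pe/ce use identity kernels.  Records are
#' weighted by the inverse residual variance (`exp(d0 + d1 theta)` under the
#' heteroscedastic model).
#'
#' @inheritParams rnm
#' @param varcomp list with `blocks` (named 2x2 matrices per random effect)
#'   and either `sigma2` or `d0`,`d1` residual values.
#' @return List: `C` (sparse symmetric coefficient matrix), `rhs`, `solution`
#'   (solved equations), `labels` (equation labels), `n`, `p`.
#' @export
assemble_mme <- function(fixed = y ~ 1, data, gradient, varcomp,
                         random = names(varcomp$blocks),
                         pedigree = NULL, genotypes = NULL, kernel = NULL,
                         animal = "animal", litter = "litter", cg = "cg",
                         cg_as_class = FALSE, blend = 0.05) {
  res_par <- varcomp$residual %||%
    c(varcomp[intersect(names(varcomp), c("sigma2", "d0", "d1"))],
      recursive = TRUE)
  residual <- if (all(c("d0", "d1") %in% names(res_par)))
    "heteroscedastic" else "homogeneous"
  ctx <- rnm_context(fixed, data, gradient, random, residual,
                     pedigree = pedigree, genotypes = genotypes,
                     kernel = kernel, animal = animal, litter = litter,
                     cg = cg, cg_as_class = cg_as_class, blend = blend)
  d0 <- if (residual == "heteroscedastic") res_par[["d0"]] else
    log(res_par[["sigma2"]])
  d1 <- if (residual == "heteroscedastic") res_par[["d1"]] else 0
  vp <- list(blocks = varcomp$blocks, d0 = d0, d1 = d1)
  parts <- mme_parts(ctx, vp)
  ch <- Matrix::Cholesky(parts$C, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, parts$rhs, system = "A"))
  labels <- c(colnames(ctx$X),
              unlist(lapply(ctx$eff, function(e)
                paste(e$name, rep(c("int", "slo"), each = e$q),
                      rep(e$levels, 2), sep = "."))))
  list(C = parts$C, rhs = parts$rhs, solution = sol, labels = labels,
       n = ctx$n, p = ctx$p)
}

#' Fit a single-step genomic reaction-norm model by REML
#'
#' Estimates the (co)variance components and solutions of the reaction-norm
#' mixed model `y = X beta + b*theta + sum_n (n0 + n1*theta) + e` by
#' restricted maximum likelihood.  The additive effect is correlated across
#' animals through the hybrid matrix `H` (pedigree + genomic) or through `A`
#' when no genotypes are supplied; `pe` and `ce` are i.i.d.  The residual is
#' homogeneous (`RNM1`) or exponentially heteroscedastic along the gradient,
#' `var(e) = exp(d0 + d1*theta)` (`RNM2`); the homogeneous model is the
#' `d1 = 0` special case of the same code path.
#'
#' The exact restricted likelihood is evaluated through a sparse Cholesky
#' factorization of the mixed-model equations and maximized on an
#' unconstrained scale (log variances, Fisher-z correlations, raw `d0`/`d1`),
#' which keeps every block positive semi-definite; correlations are pinned at
#' +-0.9999 when the optimum lies on the boundary.  Standard errors of the
#' (co)variance parameters come from the inverse average-information matrix
#' evaluated at the optimum; standard errors of individual solutions come
#' from the diagonal of the inverse coefficient matrix.
#'
#' @param fixed formula for the systematic effects (response `y`), e.g.
#'   `y ~ factor(parity) + age`.  The overall gradient regression `b*theta`
#'   is appended automatically (unless `cg_as_class = TRUE`, which fits CG
#'   classes instead).
#' @param data phenotype data frame (`y`, `cg`, animal/litter id columns).
#' @param gradient an [env_gradient()] object; every record's CG must have a
#'   retained theta.
#' @param random random effects to fit, a subset of `c("a","pe","ce")`
#'   containing `"a"`.
#' @param residual `"homogeneous"` (RNM1) or `"heteroscedastic"` (RNM2).
#' @param pedigree a [as_pedigree()] object (all record animals must appear).
#' @param genotypes optional [genotypes()] object for the single-step `H`.
#' @param kernel optional precomputed [additive_kernel()] (saves rebuilding
#'   `H^{-1}` across fits on the same data).
#' @param animal,litter,cg column names in `data`.
#' @param cg_as_class fit CG as a fixed class effect instead of `b*theta`.
#' @param blend,include_x passed to [additive_kernel()].
#' @param init optional starting values on the optimizer scale.
#' @param se compute standard errors of solutions (inverse left-hand side);
#'   disable to save time in simulations.
#' @param control an [rnm_control()] list.
#' @return Object of class `rnm`; see [summary.rnm()], [coef.rnm()],
#'   [predict.rnm()], [solutions()].
#' @export
rnm <- function(fixed = y ~ 1, data, gradient,
                random = c("a"), residual = c("homogeneous", "heteroscedastic"),
                pedigree = NULL, genotypes = NULL, kernel = NULL,
                animal = "animal", litter = "litter", cg = "cg",
                cg_as_class = FALSE, blend = 0.05, include_x = TRUE,
                init = NULL, se = TRUE, control = rnm_control()) {
  residual <- match.arg(residual)
  cl <- match.call()
  ctx <- rnm_context(fixed, data, gradient, random, residual,
                     pedigree = pedigree, genotypes = genotypes,
                     kernel = kernel, animal = animal, litter = litter,
                     cg = cg, cg_as_class = cg_as_class, blend = blend,
                     include_x = include_x)
  obj <- function(par) {
    vp <- unpack_par(par, ctx)
    val <- tryCatch(minus2_logLik(ctx, vp), error = function(e) NA_real_)
    if (!is.finite(val)) return(1e10)
    val / 2
  }
  start <- rnm_start(ctx, init)
  bb <- rnm_bounds(ctx, control)
  opt <- nlminb(start, obj, lower = bb$lower, upper = bb$upper,
                control = list(rel.tol = control$rel_tol,
                               iter.max = control$iter_max,
                               eval.max = control$eval_max,
                               trace = control$trace))
  if (!opt$convergence %in% c(0, 1) && opt$objective >= 1e9)
    stop("REML did not converge: ", opt$message)
  vp <- unpack_par(opt$par, ctx)
  fin <- minus2_logLik(ctx, vp, return_sol = TRUE)

  npar <- length(opt$par)
  logL <- -fin$m2 / 2
  aic <- fin$m2 + 2 * npar

  ## split solutions
  beta <- setNames(fin$sol[seq_len(ctx$p)], colnames(ctx$X))
  sols <- list()
  pev <- NULL
  if (se) pev <- mme_diag_inverse(fin$ch, ctx$p + sum(vapply(ctx$eff, function(e)
    2L * e$q, integer(1))))
  for (e in ctx$eff) {
    ix <- ctx$p + e$cols
    u <- fin$sol[ix]
    df <- data.frame(level = e$levels,
                     intercept = u[seq_len(e$q)],
                     slope = u[e$q + seq_len(e$q)],
                     stringsAsFactors = FALSE)
    if (!is.null(pev)) {
      df$se_intercept <- sqrt(pmax(0, pev[ix[seq_len(e$q)]]))
      df$se_slope <- sqrt(pmax(0, pev[ix[e$q + seq_len(e$q)]]))
    }
    sols[[e$name]] <- df
  }

  residual_par <- if (residual == "heteroscedastic")
    c(d0 = vp$d0, d1 = vp$d1) else c(sigma2 = exp(vp$d0))
  varcomp <- structure(list(blocks = vp$blocks,
                            residual_kind = residual,
                            residual = residual_par,
                            se = NULL),
                       class = "varcomp")
  vse <- tryCatch(ai_standard_errors(ctx, vp, fin), error = function(e) NULL)
  varcomp$se <- vse

  yhat_fixed <- as.numeric(ctx$X %*% beta)
  yhat <- yhat_fixed + as.numeric(ctx$W %*% fin$sol[-seq_len(ctx$p)])

  structure(list(call = cl, model = if (residual == "heteroscedastic")
    "RNM2" else "RNM1",
    residual_kind = residual, varcomp = varcomp, beta = beta,
    b = if ("b.theta" %in% names(beta)) unname(beta[["b.theta"]]) else NA_real_,
    solutions = sols, logLik = logL, npar = npar, AIC = aic,
    n = ctx$n, p = ctx$p, nobs = ctx$n - ctx$p,
    converged = opt$convergence == 0, iterations = opt$iterations,
    evaluations = opt$evaluations, message = opt$message,
    fitted = yhat, residuals = ctx$y - yhat, theta = ctx$theta,
    gradient = ctx$gradient, random = ctx$random,
    F = ctx$kernel$F, genotyped_ids = ctx$kernel$genotyped_ids,
    kernel_kind = ctx$kernel$kind,
    data_hash = ctx$data_hash),
    class = "rnm")
}

## diagonal of the inverse MME coefficient matrix, chunked to bound memory
mme_diag_inverse <- function(ch, n_eq, chunk = 1024L) {
  out <- numeric(n_eq)
  for (s in seq(1L, n_eq, by = chunk)) {
    ix <- s:min(n_eq, s + chunk - 1L)
    E <- Matrix::sparseMatrix(i = ix, j = seq_along(ix), x = 1,
                              dims = c(n_eq, length(ix)))
    V <- Matrix::solve(ch, E, system = "A")
    out[ix] <- vapply(seq_along(ix), function(k) V[ix[k], k], numeric(1))
  }
  out
}

## average-information matrix at the optimum, on the natural scale
ai_standard_errors <- function(ctx, vp, fin) {
  parts <- fin$parts
  ch <- fin$ch
  rinv <- 1 / parts$ve
  sol <- fin$sol
  ehat <- ctx$y - as.numeric(ctx$X %*% sol[seq_len(ctx$p)]) -
    as.numeric(ctx$W %*% sol[-seq_len(ctx$p)])
  Py <- ehat * rinv

  tvecs <- list(); labs <- character(0)
  for (e in ctx$eff) {
    Wn <- e$W
    w <- as.numeric(Matrix::crossprod(Wn, Py))
    w0 <- w[seq_len(e$q)]; w1 <- w[e$q + seq_len(e$q)]
    Kv <- function(v) if (is.null(e$chK)) v else
      as.numeric(Matrix::solve(e$chK, v, system = "A"))
    K0 <- Kv(w0); K1 <- Kv(w1)
    tvecs <- c(tvecs, list(
      as.numeric(Wn %*% c(K0, numeric(e$q))),
      as.numeric(Wn %*% c(K1, K0)),
      as.numeric(Wn %*% c(numeric(e$q), K1))))
    labs <- c(labs, paste(e$name, c("v0", "cov", "v1"), sep = "."))
  }
  if (ctx$residual == "heteroscedastic") {
    tvecs <- c(tvecs, list(parts$ve * Py, ctx$theta * parts$ve * Py))
    labs <- c(labs, "d0", "d1")
  } else {
    tvecs <- c(tvecs, list(Py))
    labs <- c(labs, "sigma2")
  }
  ## P t = R^-1 (t - X b_t - W u_t)
  Pt <- lapply(tvecs, function(tv) {
    r2 <- c(as.numeric(crossprod(ctx$X, tv * rinv)),
            as.numeric(Matrix::crossprod(ctx$W, tv * rinv)))
    st <- as.numeric(Matrix::solve(ch, r2, system = "A"))
    rinv * (tv - as.numeric(ctx$X %*% st[seq_len(ctx$p)]) -
              as.numeric(ctx$W %*% st[-seq_len(ctx$p)]))
  })
  k <- length(tvecs)
  AI <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in i:k) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(tvecs[[i]] * Pt[[j]])
  }
  V <- tryCatch(solve(AI), error = function(e) pinv(AI))
  se <- sqrt(pmax(0, diag(V)))
  names(se) <- labs
  list(se = se, AI = AI, vcov = V)
}

#' Residual variance along the gradient
#'
#' `exp(d0 + d1*theta)` for a heteroscedastic fit; the constant `sigma2` for
#' a homogeneous one (documented convenience).
#'
#' @param varcomp a `varcomp` (or fitted [rnm()]) object.
#' @param theta gradient value(s).
#' @return Residual variance per theta.
#' @export
residual_variance_at <- function(varcomp, theta) {
  if (inherits(varcomp, "rnm")) varcomp <- varcomp$varcomp
  if (varcomp$residual_kind == "heteroscedastic")
    exp(varcomp$residual[["d0"]] + varcomp$residual[["d1"]] * theta)
  else rep(varcomp$residual[["sigma2"]], length(theta))
}

#' Choose between the homogeneous and heteroscedastic fits by AIC
#'
#' Returns the fit with the lower AIC; ties go to the homogeneous model
#' (parsimony).  Both fits must be on identical data.
#'
#' @param fit1,fit2 fitted [rnm()] objects on the same records.
#' @return The preferred fit, with attribute `"aic"` holding both values.
#' @export
choose_model <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "rnm"), inherits(fit2, "rnm"))
  if (!isTRUE(all.equal(fit1$data_hash, fit2$data_hash)))
    stop("fits were not obtained on the same data")
  aic <- c(fit1$AIC, fit2$AIC)
  hom <- c(fit1$residual_kind, fit2$residual_kind) == "homogeneous"
  pick <- if (aic[1] < aic[2]) 1L else if (aic[2] < aic[1]) 2L else
    if (any(hom)) which(hom)[1] else 1L
  out <- list(fit1, fit2)[[pick]]
  attr(out, "aic") <- setNames(aic, c(fit1$model, fit2$model))
  out
}
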