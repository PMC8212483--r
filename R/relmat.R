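#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree-based numerator relationship matrix `A` by the tabular
#' method.  The diagonal equals `1 + F_j`.
#'
#' @param ped a [as_pedigree()] object.
#' @return Dense symmetric matrix with animal ids as dimnames and attribute
#'   `"F"` holding the inbreeding coefficients.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  pi <- ped_indices(ped)
  s <- pi$sire; d <- pi$dam
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    up <- seq_len(i - 1L)
    asd <- if (s[i] > 0 && d[i] > 0) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      ri <- numeric(i - 1L)
      if (s[i] > 0) ri <- ri + 0.5 * A[up, s[i]]
      if (d[i] > 0) ri <- ri + 0.5 * A[up, d[i]]
      A[up, i] <- ri
      A[i, up] <- ri
    }
  }
  attr(A, "F") <- setNames(diag(A) - 1, ped$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules accounting for inbreeding.  Mendelian-sampling variances
#' use the parental inbreeding coefficients, so the result is the exact
#' inverse of [build_A()].
#'
#' @param ped a [as_pedigree()] object.
#' @param f optional precomputed inbreeding coefficients (pedigree order);
#'   computed with [inbreeding()] when missing.
#' @return Sparse symmetric `Matrix` (class `dsCMatrix`) with animal dimnames.
#' @export
build_Ainv <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(f)) f <- inbreeding(ped)
  pi <- ped_indices(ped)
  s <- pi$sire; d <- pi$dam
  n <- nrow(ped)
  fs <- ifelse(s > 0, f[pmax(s, 1L)], -1)
  fd <- ifelse(d > 0, f[pmax(d, 1L)], -1)
  b <- 0.5 - 0.25 * (fs + fd)   # Mendelian sampling variance
  al <- 1 / b
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  idx <- seq_len(n)
  push(idx, idx, al)
  hs <- s > 0
  push(idx[hs], s[hs], -al[hs] / 2); push(s[hs], idx[hs], -al[hs] / 2)
  push(s[hs], s[hs], al[hs] / 4)
  hd <- d > 0
  push(idx[hd], d[hd], -al[hd] / 2); push(d[hd], idx[hd], -al[hd] / 2)
  push(d[hd], d[hd], al[hd] / 4)
  hb <- hs & hd
  push(s[hb], d[hb], al[hb] / 4); push(d[hb], s[hb], al[hb] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(M)
}

#' Genotype quality control
#'
#' Filters SNPs on call rate, minor allele frequency, and the absolute
#' difference between observed and expected heterozygote frequencies, and
#' animals on call rate.  Defaults follow common SNP-chip practice
#' (0.90 / 0.01 / 0.15).  For X-linked SNPs the heterozygote comparison uses
#' females only, since males are coded hemizygous on the \{0, 2\} scale.
#'
#' @param geno a [genotypes()] object.
#' @param call_rate_min,maf_min,het_diff_max per-SNP thresholds.
#' @param animal_call_rate_min per-animal call-rate threshold.
#' @return List with the filtered `genotypes` object and a `QCReport` data
#'   frame (`snp`, `call_rate`, `maf`, `het_diff`, `kept`, `reason`), plus
#'   removed-animal ids.
#' @export
qc_genotypes <- function(geno, call_rate_min = 0.90, maf_min = 0.01,
                         het_diff_max = 0.15, animal_call_rate_min = 0.90) {
  stopifnot(inherits(geno, "genotypes"))
  for (v in c(call_rate_min, maf_min, het_diff_max, animal_call_rate_min))
    if (v < 0 || v > 1) stop("QC thresholds must lie in [0, 1]")
  M <- geno$dosage
  acr <- rowMeans(!is.na(M))
  bad_animals <- rownames(M)[acr < animal_call_rate_min]
  if (length(bad_animals)) {
    keep <- !(rownames(M) %in% bad_animals)
    M <- M[keep, , drop = FALSE]
    geno$dosage <- M
    geno$genotyped <- geno$genotyped[keep]
  }

  cr <- colMeans(!is.na(M))
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  isx <- geno$map$chr == "X"
  fem <- if (!is.null(geno$sex)) geno$sex[rownames(M)] == "F" else
    rep(TRUE, nrow(M))
  het_obs <- colMeans(M == 1, na.rm = TRUE)
  if (any(isx) && any(fem)) {
    Mx <- M[fem, isx, drop = FALSE]
    het_obs[isx] <- colMeans(Mx == 1, na.rm = TRUE)
    px <- colMeans(Mx, na.rm = TRUE) / 2
    het_exp_x <- 2 * px * (1 - px)
  }
  het_exp <- 2 * p * (1 - p)
  if (any(isx) && any(fem)) het_exp[isx] <- het_exp_x
  hd <- abs(het_obs - het_exp)

  reason <- rep(NA_character_, ncol(M))
  reason[is.na(reason) & cr < call_rate_min] <- "call_rate"
  reason[is.na(reason) & maf < maf_min] <- "maf"
  reason[is.na(reason) & hd > het_diff_max] <- "het_diff"
  kept <- is.na(reason)
  if (!any(kept)) stop("genotype QC removed every SNP")
  report <- data.frame(snp = geno$map$snp, chr = geno$map$chr,
                       call_rate = cr, maf = maf, het_diff = hd,
                       kept = kept, reason = reason,
                       row.names = NULL, stringsAsFactors = FALSE)
  geno$dosage <- M[, kept, drop = FALSE]
  geno$map <- geno$map[kept, , drop = FALSE]
  rownames(geno$map) <- NULL
  list(genotypes = geno, report = report, removed_animals = bad_animals)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum(p_k (1 - p_k)))` with `Z` the dosage matrix centered
#' by twice the allele frequency.  Frequencies are computed from the data by
#' default.  Optionally blends toward the pedigree relationships of the
#' genotyped animals, `G* = (1 - w) G + w A22`, which guarantees
#' invertibility.
#'
#' @param geno a [genotypes()] object (genotyped animals only are used).
#' @param freqs optional per-SNP allele frequencies; observed when `NULL`.
#' @param A22 optional pedigree relationship matrix of the genotyped animals,
#'   required when `blend > 0`.
#' @param blend blending weight toward `A22` (default 0.05).
#' @return Dense symmetric matrix with animal dimnames; attribute `"p"`
#'   holds the allele frequencies used.
#' @export
build_G <- function(geno, freqs = NULL, A22 = NULL, blend = 0.05) {
  stopifnot(inherits(geno, "genotypes"))
  M <- geno$dosage[geno$genotyped, , drop = FALSE]
  if (nrow(M) < 2) stop("need at least two genotyped animals")
  if (ncol(M) < 1) stop("need at least one SNP")
  p <- if (is.null(freqs)) colMeans(M, na.rm = TRUE) / 2 else freqs
  den <- 2 * sum(p * (1 - p))
  if (den <= 0)
    stop("all SNPs monomorphic: scaling denominator 2*sum(p(1-p)) is zero")
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / den
  if (blend > 0) {
    if (is.null(A22))
      stop("blending requested but A22 not supplied")
    A22 <- A22[rownames(G), rownames(G)]
    G <- (1 - blend) * G + blend * A22
  }
  attr(G, "p") <- p
  G
}

#' Inverse of the hybrid (single-step) relationship matrix
#'
#' `H^{-1} = A^{-1} + [0 0; 0 G^{-1} - A22^{-1}]`, the single-step GBLUP
#' combination of pedigree and genomic information: the genotyped block of
#' the pedigree inverse is corrected by the difference between the genomic
#' and pedigree-subset inverses.
#'
#' @param Ainv sparse inverse of `A` over all animals (from [build_Ainv()]).
#' @param Ginv inverse of the (blended) genomic relationship matrix.
#' @param A22inv inverse of the pedigree relationships among genotyped
#'   animals.
#' @param genotyped_ids animal ids of the genotyped block, in the row order
#'   of `Ginv`/`A22inv`.  May be empty, in which case `H^{-1} = A^{-1}`.
#' @return Sparse symmetric `Matrix`.
#' @export
build_Hinv <- function(Ainv, Ginv, A22inv, genotyped_ids) {
  if (length(genotyped_ids) == 0) return(Ainv)
  ids <- rownames(Ainv)
  j <- match(genotyped_ids, ids)
  if (anyNA(j))
    stop("genotyped animals absent from A: ",
         paste(genotyped_ids[is.na(j)], collapse = ", "))
  corr <- as(Ginv - A22inv, "matrix")
  H <- as(Ainv, "CsparseMatrix")
  H <- H + Matrix::sparseMatrix(
    i = rep(j, times = length(j)), j = rep(j, each = length(j)),
    x = as.numeric(corr), dims = dim(Ainv))
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  dimnames(H) <- list(ids, ids)
  H
}

#' Invert a genomic relationship matrix
#'
#' Plain dense inversion with an informative failure for singular unblended
#' `G`.
#'
#' @param G matrix from [build_G()].
#' @return Dense inverse with the same dimnames.
#' @export
invert_G <- function(G) {
  out <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(out))
    stop("G is singular; blend toward A22 (see build_G(blend=)) and retry")
  dimnames(out) <- dimnames(G)
  out
}
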