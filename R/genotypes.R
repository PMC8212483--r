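#' Construct a genotype container
#'
#' Holds allele dosages on the \{0, 1, 2\} scale (males hemizygous \{0, 2\}
#' on the X), a SNP map, the sex of each animal, and a flag marking which
#' animals are treated as genotyped in downstream single-step analyses.
#'
#' @param dosage integer matrix, animals x SNPs, rownames = animal ids.
#' @param map data frame with columns `snp`, `chr` (1..18 or `"X"`), `bp`
#'   (1-based positions, sorted within chromosome).
#' @param genotyped logical vector per animal (default all `TRUE`).
#' @param sex optional named vector (`"M"`/`"F"`) used for X-chromosome QC.
#' @return Object of class `genotypes`.
#' @export
genotypes <- function(dosage, map, genotyped = NULL, sex = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage needs animal ids as rownames")
  if (!all(c("snp", "chr", "bp") %in% names(map)))
    stop("map needs columns snp, chr, bp")
  if (nrow(map) != ncol(dosage))
    stop("map rows must match dosage columns")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in {0, 1, 2}")
  map$chr <- as.character(map$chr)
  if (any(map$bp < 0)) stop("bp positions must be non-negative")
  ok <- unlist(lapply(split(map$bp, map$chr), function(b) !is.unsorted(b)))
  if (!all(ok))
    stop("bp positions must be sorted within chromosome: ",
         paste(names(ok)[!ok], collapse = ", "))
  colnames(dosage) <- map$snp
  if (is.null(genotyped)) genotyped <- rep(TRUE, nrow(dosage))
  structure(list(dosage = dosage, map = map,
                 genotyped = genotyped, sex = sex),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat(sprintf("genotypes: %d animals (%d genotyped) x %d SNPs (%d autosomal, %d X)\n",
              nrow(x$dosage), sum(x$genotyped), ncol(x$dosage),
              sum(x$map$chr != "X"), sum(x$map$chr == "X")))
  invisible(x)
}

#' Center a dosage matrix by twice the allele frequency
#'
#' @param geno a [genotypes()] object.
#' @param ids animals to include (default: the genotyped subset).
#' @param freqs optional allele frequencies; observed among `ids` when `NULL`.
#' @return Centered matrix `Z` with attribute `"p"`.
#' @export
center_dosages <- function(geno, ids = NULL, freqs = NULL) {
  if (is.null(ids)) ids <- rownames(geno$dosage)[geno$genotyped]
  M <- geno$dosage[ids, , drop = FALSE]
  p <- if (is.null(freqs)) colMeans(M, na.rm = TRUE) / 2 else freqs
  Z <- sweep(M, 2, 2 * p)
  attr(Z, "p") <- p
  Z
}
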