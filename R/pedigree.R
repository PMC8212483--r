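#' Construct and validate a pedigree
#'
#' Builds a `pedigree` object from a table of animal, sire, dam and sex
#' records.  Animals are reordered so that parents always precede their
#' offspring (topological order); unknown parents are represented by `NA`.
#' Sires must be male and dams female wherever the parent's own record is
#' present.
#'
#' @param x data frame with columns `animal`, `sire`, `dam`, `sex`
#'   (`"M"`/`"F"`).  `0`, `""` and `NA` are accepted as unknown-parent codes.
#'   Extra columns (e.g. `generation`, `litter`) are carried along.
#' @return A data frame of class `pedigree` in topological order.  Row order
#'   defines the integer index used by all relationship-matrix functions.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   animal = c("s", "d", "o"), sire = c(NA, NA, "s"),
#'   dam = c(NA, NA, "d"), sex = c("M", "F", "F")))
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x)
  need <- c("animal", "sire", "dam", "sex")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  x$animal <- as.character(x$animal)
  norm_parent <- function(p) {
    p <- as.character(p)
    p[p %in% c("0", "", "NA")] <- NA_character_
    p
  }
  x$sire <- norm_parent(x$sire)
  x$dam <- norm_parent(x$dam)
  if (anyDuplicated(x$animal))
    stop("duplicated animal ids in pedigree: ",
         paste(unique(x$animal[duplicated(x$animal)]), collapse = ", "))
  ## parents that never appear as animals become founders of unknown ancestry
  ## only if referenced; we require referenced parents to have records
  miss <- setdiff(c(x$sire, x$dam), c(NA, x$animal))
  if (length(miss))
    stop("parents without own pedigree record: ", paste(miss, collapse = ", "))

  ## topological sort (Kahn); detects cycles
  n <- nrow(x)
  idx <- setNames(seq_len(n), x$animal)
  si <- ifelse(is.na(x$sire), 0L, idx[x$sire])
  di <- ifelse(is.na(x$dam), 0L, idx[x$dam])
  placed <- logical(n)
  ord <- integer(n)
  k <- 0L
  repeat {
    ready <- which(!placed & (si == 0L | placed[pmax(si, 1L)]) &
                     (di == 0L | placed[pmax(di, 1L)]))
    if (!length(ready)) break
    ord[k + seq_along(ready)] <- ready
    k <- k + length(ready)
    placed[ready] <- TRUE
  }
  if (k < n)
    stop("pedigree contains a cycle involving: ",
         paste(x$animal[!placed], collapse = ", "))
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL

  sx <- x$sex[match(x$sire, x$animal)]
  if (any(!is.na(sx) & sx != "M"))
    stop("sire with non-male sex record: ",
         paste(unique(x$sire[which(!is.na(sx) & sx != "M")]), collapse = ", "))
  dx <- x$sex[match(x$dam, x$animal)]
  if (any(!is.na(dx) & dx != "F"))
    stop("dam with non-female sex record: ",
         paste(unique(x$dam[which(!is.na(dx) & dx != "F")]), collapse = ", "))
  class(x) <- c("pedigree", "data.frame")
  x
}

ped_indices <- function(ped) {
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  list(sire = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
       dam = ifelse(is.na(ped$dam), 0L, idx[ped$dam]))
}

#' Pedigree inbreeding coefficients
#'
#' Inbreeding coefficient `F_j` of every animal, computed by the
#' Meuwissen-Luo recursion on the Cholesky decomposition of the numerator
#' relationship matrix (no dense matrix is formed).
#'
#' @param ped a [as_pedigree()] object.
#' @return Named numeric vector of `F_j`, in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  pi <- ped_indices(ped)
  s <- pi$sire; d <- pi$dam
  n <- nrow(ped)
  f <- numeric(n)     # F_j
  dii <- numeric(n)   # within-family (Mendelian sampling) variance scale
  L <- vector("list", n)  # sparse rows of L as named numeric on ancestor index
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0) f[s[i]] else -1
    fd <- if (d[i] > 0) f[d[i]] else -1
    dii[i] <- 0.5 - 0.25 * (fs + fd)
    ## accumulate row i of L: contributions of ancestor founder-sampling terms
    row <- numeric(0)
    acc <- function(row, par) {
      if (par == 0) return(row)
      pr <- L[[par]]
      ii <- match(as.integer(names(pr)), as.integer(names(row)))
      add <- 0.5 * pr
      hit <- !is.na(ii)
      if (any(hit)) row[ii[hit]] <- row[ii[hit]] + add[hit]
      if (any(!hit)) row <- c(row, add[!hit])
      row
    }
    row <- acc(row, s[i])
    row <- acc(row, d[i])
    row <- c(row, setNames(sqrt(dii[i]), i))
    L[[i]] <- row
    f[i] <- sum(row^2) - 1
  }
  ## sum(row^2) - 1 can round to a tiny negative for non-inbred animals
  setNames(pmax(0, f), ped$animal)
}
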