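# Pedigree handling and relationship matrices.

toy_ped <- function() {
  # classic 6-animal example with inbreeding (parents mated to descendants)
  data.frame(
    animal = c("1", "2", "3", "4", "5", "6"),
    sire   = c(NA, NA, "1", "1", "4", "5"),
    dam    = c(NA, NA, "2", NA, "3", "2"),
    sex    = c("M", "F", "F", "M", "M", "F"),
    stringsAsFactors = FALSE)
}

test_that("as_pedigree validates and topologically sorts", {
  p <- toy_ped()
  shuffled <- p[c(5, 3, 1, 6, 2, 4), ]
  ped <- as_pedigree(shuffled)
  ix <- match(ped$animal, p$animal)
  expect_true(all(diff(order(ix)) != 0))
  # every parent precedes its offspring
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$animal
  for (i in pos) {
    if (!is.na(ped$sire[i])) expect_lt(pos[ped$sire[i]], i)
    if (!is.na(ped$dam[i])) expect_lt(pos[ped$dam[i]], i)
  }
  expect_true(all(c("animal", "sire", "dam") %in% names(ped)))
})

test_that("as_pedigree normalises unknown parents and rejects cycles", {
  p <- toy_ped()
  p$sire[3] <- "0"; p$dam[4] <- ""
  ped <- as_pedigree(p)
  expect_true(is.na(ped$sire[ped$animal == "3"]))
  expect_true(is.na(ped$dam[ped$animal == "4"]))

  bad <- data.frame(animal = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA), sex = c("M", "M"),
                    stringsAsFactors = FALSE)
  expect_error(as_pedigree(bad), "cycle|sort")
})

test_that("as_pedigree rejects sex-inconsistent parent usage", {
  p <- toy_ped()
  p$sire[6] <- "2"   # dam used as sire
  expect_error(as_pedigree(p), "sire|sex")
})

test_that("A matches the recursive coancestry oracle exactly", {
  ped <- as_pedigree(toy_ped())
  A <- build_A(ped)
  Ao <- oracle_A(ped)
  expect_lt(max(abs(A - Ao[rownames(A), colnames(A)])), 1e-12)
})

test_that("A oracle agreement holds on a simulated inbred pedigree", {
  sim <- make_demo(seed = 7, n_founders = 12, n_generations = 4)
  ped <- sim$pedigree
  A <- build_A(ped)
  Ao <- oracle_A(ped)
  expect_lt(max(abs(A - Ao)), 1e-12)
  expect_gt(max(attr(A, "F")), 0)  # inbreeding does arise
})

test_that("inbreeding equals diag(A) - 1", {
  sim <- make_demo(seed = 8, n_founders = 10, n_generations = 4)
  ped <- sim$pedigree
  A <- build_A(ped)
  expect_equal(unname(inbreeding(ped)), unname(diag(A) - 1),
               tolerance = 1e-12)
})

test_that("Ainv is the exact inverse of A under inbreeding", {
  sim <- make_demo(seed = 9, n_founders = 10, n_generations = 4)
  ped <- sim$pedigree
  A <- build_A(ped)
  Ainv <- as.matrix(build_Ainv(ped))
  n <- nrow(A)
  expect_lt(max(abs(A %*% Ainv - diag(n))), 1e-8)
})

test_that("G matches brute-force VanRaden method 1", {
  sim <- make_demo(seed = 10, n_founders = 10, n_generations = 2,
                   n_auto_snps = 40, n_x_snps = 0)
  geno <- sim$genotypes
  G <- build_G(geno, blend = 0)
  M <- geno$dosage[geno$genotyped, ]
  p <- colMeans(M) / 2
  Go <- oracle_G(M, p)
  expect_lt(max(abs(G - Go)), 1e-10)
})

test_that("G blending moves toward A22 and fixes singularity", {
  sim <- make_demo(seed = 11, n_founders = 10, n_generations = 2,
                   n_auto_snps = 30, n_x_snps = 0)
  geno <- sim$genotypes
  ped <- sim$pedigree
  A <- build_A(ped)
  gids <- rownames(geno$dosage)[geno$genotyped]
  A22 <- A[gids, gids]
  G0 <- build_G(geno, blend = 0)
  Gb <- build_G(geno, A22 = A22, blend = 0.05)
  expect_equal(unclass(Gb), 0.95 * unclass(G0) + 0.05 * A22,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("build_G errors when all SNPs are monomorphic", {
  M <- matrix(2L, 4, 3, dimnames = list(paste0("a", 1:4), NULL))
  map <- data.frame(snp = paste0("s", 1:3), chr = "1", bp = 1:3)
  g <- genotypes(M, map)
  expect_error(build_G(g, blend = 0), "monomorphic")
})

test_that("Hinv matches direct construction and inversion of H", {
  sim <- make_demo(seed = 12, n_founders = 6, n_generations = 1,
                   n_auto_snps = 60, n_x_snps = 0, genotyping_fraction = 0.5)
  ped <- sim$pedigree
  geno <- sim$genotypes
  A <- build_A(ped)
  gids <- rownames(geno$dosage)[geno$genotyped]
  A22 <- A[gids, gids]
  G <- build_G(geno, A22 = A22, blend = 0.05)
  Hinv <- build_Hinv(build_Ainv(ped), invert_G(G), solve(A22), gids)
  Ho <- oracle_Hinv(A, G[gids, gids], gids)
  expect_lt(max(abs(as.matrix(Hinv) - Ho)), 1e-8)
})

test_that("Hinv without genotyped animals reduces to Ainv", {
  ped <- as_pedigree(toy_ped())
  Ainv <- build_Ainv(ped)
  expect_identical(build_Hinv(Ainv, NULL, NULL, character(0)), Ainv)
})

test_that("QC removes SNPs with the documented reason precedence", {
  set.seed(1)
  # n large enough that sampling noise in the observed heterozygosity of a
  # clean SNP stays well inside the 0.15 tolerance (sd ~ 0.035 here)
  n <- 200
  m <- 50
  M <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(sprintf("a%03d", 1:n), NULL))
  M[1:40, 1] <- NA                  # call rate 0.80 < 0.90
  M[, 2] <- 0L                      # maf 0
  M[, 3] <- rep(c(0L, 2L), n / 2)   # no hets at maf 0.5: het_diff 0.5
  M[1:60, 4] <- NA; M[, 4] <- ifelse(is.na(M[, 4]), NA, 0L)  # cr and maf fail
  map <- data.frame(snp = paste0("s", 1:m), chr = "1", bp = 1:m)
  g <- genotypes(M, map)
  qc <- qc_genotypes(g)
  r <- qc$report
  expect_equal(r$reason[1:4], c("call_rate", "maf", "het_diff", "call_rate"))
  expect_true(all(r$kept[5:50]))
  expect_equal(ncol(qc$genotypes$dosage), 46)
})

test_that("QC is idempotent and can drop low-call-rate animals", {
  set.seed(2)
  M <- matrix(rbinom(40 * 20, 2, 0.3), 40, 20,
              dimnames = list(sprintf("a%02d", 1:40), NULL))
  M[1, 1:15] <- NA   # animal call rate 5/20
  map <- data.frame(snp = paste0("s", 1:20), chr = "1", bp = 1:20)
  g <- genotypes(M, map)
  qc1 <- qc_genotypes(g)
  expect_true("a01" %in% qc1$removed_animals)
  qc2 <- qc_genotypes(qc1$genotypes)
  expect_identical(dim(qc2$genotypes$dosage), dim(qc1$genotypes$dosage))
  expect_identical(qc2$removed_animals, character(0))
})

test_that("X-chromosome QC judges heterozygosity on females only", {
  set.seed(3)
  n <- 40
  sexes <- rep(c("M", "F"), n / 2)
  ids <- sprintf("a%02d", 1:n)
  fem <- sexes == "F"
  # X SNP in Hardy-Weinberg among females, males hemizygous {0,2}
  p <- 0.4
  x <- integer(n)
  x[fem] <- rbinom(sum(fem), 2, p)
  x[!fem] <- 2L * rbinom(sum(!fem), 1, p)
  M <- cbind(auto = rbinom(n, 2, 0.3), xsnp = x)
  rownames(M) <- ids
  map <- data.frame(snp = c("auto", "xsnp"), chr = c("1", "X"), bp = c(1, 1))
  g <- genotypes(M, map, sex = setNames(sexes, ids))
  qc <- qc_genotypes(g)
  # with males included the observed het would be biased far below expected;
  # restricted to females the SNP must survive
  expect_true(qc$report$kept[qc$report$snp == "xsnp"])
})
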