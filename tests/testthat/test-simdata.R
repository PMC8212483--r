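# Gene-dropping simulator.

test_that("simulate_pedigree is reproducible and well-formed", {
  cfg <- sim_config(n_founders = 20, n_generations = 3, seed = 99)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  expect_identical(p1, p2)
  expect_s3_class(p1, "pedigree")
  expect_true(all(p1$generation[is.na(p1$sire)] == 0))
  # litters are full-sib groups
  bylit <- split(p1[p1$generation > 0, ], p1$litter[p1$generation > 0])
  for (d in bylit) {
    expect_equal(length(unique(d$sire)), 1)
    expect_equal(length(unique(d$dam)), 1)
  }
})

test_that("different seeds give different pedigrees", {
  a <- simulate_pedigree(sim_config(n_founders = 20, n_generations = 2,
                                    seed = 1))
  b <- simulate_pedigree(sim_config(n_founders = 20, n_generations = 2,
                                    seed = 2))
  expect_false(identical(a, b))
})

test_that("simulate_pedigree fails cleanly on impossible structures", {
  expect_error(sim_config(n_founders = 1, n_generations = 1, seed = 1),
               "two founders")
  # with two founders and tiny litters a single-sex generation occurs
  expect_error(
    simulate_pedigree(sim_config(n_founders = 2, n_generations = 6,
                                 litter_size_mean = 0.5, seed = 1)),
    "impossible mating structure")
})

test_that("gene-dropped dosages are valid and X males are hemizygous {0,2}", {
  cfg <- sim_config(n_founders = 16, n_generations = 3, n_auto_snps = 60,
                    n_x_snps = 20, seed = 21)
  ped <- simulate_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  D <- geno$dosage
  expect_true(all(D %in% 0:2))
  isx <- geno$map$chr == "X"
  males <- ped$animal[ped$sex == "M"]
  expect_true(all(D[males, isx] %in% c(0L, 2L)))
  # females can be heterozygous on the X
  females <- ped$animal[ped$sex == "F"]
  expect_true(any(D[females, isx] == 1L))
})

test_that("X transmission: daughters carry the sire's X allele", {
  cfg <- sim_config(n_founders = 16, n_generations = 3, n_auto_snps = 10,
                    n_x_snps = 30, seed = 22)
  ped <- simulate_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  D <- geno$dosage
  isx <- which(geno$map$chr == "X")
  daughters <- which(ped$sex == "F" & !is.na(ped$sire))
  for (i in daughters) {
    sx <- D[ped$sire[i], isx] / 2      # sire's single X allele
    dx <- D[ped$animal[i], isx]
    # daughter dosage = sire allele + maternal allele: never below the sire
    # allele alone and never more than one above it
    expect_true(all(dx >= sx & dx <= sx + 1))
  }
})

test_that("realised founder allele frequencies track the target range", {
  cfg <- sim_config(n_founders = 60, n_generations = 1, n_auto_snps = 200,
                    n_x_snps = 0, founder_maf_range = c(0.2, 0.4), seed = 23)
  ped <- simulate_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  founders <- ped$animal[is.na(ped$sire)]
  p <- colMeans(geno$dosage[founders, ]) / 2
  expect_gt(mean(p), 0.15)
  expect_lt(mean(p), 0.45)
})

test_that("simulated additive values have approximately the target covariance", {
  cfg <- sim_config(n_founders = 300, n_generations = 2, n_auto_snps = 10,
                    n_x_snps = 0, seed = 24)
  tp <- true_params(a = block2(2, 0.5, 0.4))
  ped <- simulate_pedigree(cfg)
  ph <- simulate_phenotypes(ped, tp, cfg)
  a <- attr(ph, "truth")$a
  founders <- is.na(ped$sire) & is.na(ped$dam)
  S <- cov(a[founders, ])
  # founder (a0, a1) are i.i.d. with covariance block_a
  expect_equal(S[1, 1], 2, tolerance = 0.35)
  expect_equal(S[2, 2], 0.4, tolerance = 0.3)
  expect_equal(S[1, 2], 0.5, tolerance = 0.3)
})

test_that("phenotypes respond to the gradient as specified", {
  cfg <- sim_config(n_founders = 80, n_generations = 3, seed = 25,
                    records_per_animal = 3)
  tp <- true_params(a = block2(1, 0.25, 0.18), residual = c(sigma2 = 1),
                    b = 2)
  sim <- simulate_dataset(cfg, tp)
  ph <- sim$phenotypes
  th <- attr(ph, "truth")$theta[ph$cg]
  # regression of y on true theta recovers roughly the fixed slope b
  co <- coef(lm(ph$y ~ th))[2]
  expect_equal(unname(co), 2, tolerance = 0.3)
})

test_that("heteroscedastic residuals grow along the gradient", {
  cfg <- sim_config(n_founders = 200, n_generations = 1, n_cg = 40,
                    records_per_animal = 4, seed = 26)
  tp <- true_params(a = block2(0.01, 0, 0.001), residual = c(d0 = 0, d1 = 0.8),
                    b = 0)
  sim <- simulate_dataset(cfg, tp)
  ph <- sim$phenotypes
  th <- attr(ph, "truth")$theta[ph$cg]
  res <- ph$y - mean(ph$y)
  vlow <- var(res[th < -0.5]); vhigh <- var(res[th > 0.5])
  expect_gt(vhigh, vlow)
})

test_that("simulate_dataset is fully deterministic given the config seed", {
  cfg <- sim_config(n_founders = 15, n_generations = 2, seed = 31)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$phenotypes$y, s2$phenotypes$y)
})

test_that("genotyping flags are biased toward recent generations", {
  cfg <- sim_config(n_founders = 60, n_generations = 4,
                    genotyping_fraction = 0.3, seed = 32)
  sim <- simulate_dataset(cfg)
  ped <- sim$pedigree
  g <- sim$genotypes$genotyped
  mean_gen_genotyped <- mean(ped$generation[g])
  mean_gen_all <- mean(ped$generation)
  expect_gt(mean_gen_genotyped, mean_gen_all)
})
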