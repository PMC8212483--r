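# REML fitting of the reaction-norm models.

# one small shared dataset + fits, computed once for this file
rnm_sim <- local({
  cfg <- sim_config(n_founders = 24, n_generations = 3, n_cg = 8,
                    records_per_animal = 3, n_auto_snps = 80, n_x_snps = 8,
                    seed = 71)
  tp <- true_params(a = block2(1, 0.25, 0.18), ce = block2(0.3, 0, 0.05),
                    residual = c(sigma2 = 1))
  sim <- simulate_dataset(cfg, tp)
  ph <- apply_record_filters(sim$phenotypes, min_cg = 5)
  gr <- env_gradient(ph)
  list(sim = sim, ph = ph, gr = gr)
})
rnm_fit1 <- rnm(y ~ factor(parity) + age, rnm_sim$ph, rnm_sim$gr,
                random = c("a", "ce"), residual = "homogeneous",
                pedigree = rnm_sim$sim$pedigree,
                genotypes = rnm_sim$sim$genotypes)
rnm_fit2 <- rnm(y ~ factor(parity) + age, rnm_sim$ph, rnm_sim$gr,
                random = c("a", "ce"), residual = "heteroscedastic",
                pedigree = rnm_sim$sim$pedigree,
                genotypes = rnm_sim$sim$genotypes)

test_that("optimized restricted likelihood matches the dense-V oracle", {
  cfg <- sim_config(n_founders = 8, n_generations = 2, n_cg = 4,
                    cg_size_range = c(1, 2), records_per_animal = 1,
                    n_auto_snps = 10, n_x_snps = 0, seed = 5)
  sim <- simulate_dataset(cfg, true_params())
  ph <- sim$phenotypes[seq_len(min(28, nrow(sim$phenotypes))), ]
  gr <- env_gradient(ph)
  fit <- rnm(y ~ age, ph, gr, random = "a", residual = "homogeneous",
             pedigree = sim$pedigree)
  expect_lte(nrow(ph), 30)

  ped <- sim$pedigree
  A <- build_A(ped)
  th <- gradient_for(gr, ph$cg)
  X <- cbind(model.matrix(~ age, ph), b.theta = th)
  eff <- list(list(K = unclass(A), j = match(ph$animal, ped$animal),
                   B = fit$varcomp$blocks$a))
  m2o <- oracle_m2logL(ph$y, X, th, eff,
                       fit$varcomp$residual[["sigma2"]])
  expect_lt(abs(-2 * as.numeric(logLik(fit)) - m2o), 1e-6)
})

test_that("heteroscedastic likelihood also matches a dense oracle", {
  cfg <- sim_config(n_founders = 8, n_generations = 2, n_cg = 4,
                    cg_size_range = c(1, 2), records_per_animal = 1,
                    n_auto_snps = 10, n_x_snps = 0, seed = 6)
  sim <- simulate_dataset(cfg, true_params(residual = c(d0 = 0, d1 = 0.3)))
  ph <- sim$phenotypes[seq_len(min(28, nrow(sim$phenotypes))), ]
  gr <- env_gradient(ph)
  fit <- rnm(y ~ age, ph, gr, random = "a", residual = "heteroscedastic",
             pedigree = sim$pedigree)
  ped <- sim$pedigree
  A <- build_A(ped)
  th <- gradient_for(gr, ph$cg)
  X <- cbind(model.matrix(~ age, ph), b.theta = th)
  eff <- list(list(K = unclass(A), j = match(ph$animal, ped$animal),
                   B = fit$varcomp$blocks$a))
  rv <- exp(fit$varcomp$residual[["d0"]] +
              fit$varcomp$residual[["d1"]] * th)
  m2o <- oracle_m2logL(ph$y, X, th, eff, rv)
  expect_lt(abs(-2 * as.numeric(logLik(fit)) - m2o), 1e-6)
})

test_that("RNM2 never has lower maximized logL than RNM1 (nesting)", {
  expect_gte(as.numeric(logLik(rnm_fit2)), as.numeric(logLik(rnm_fit1)) - 1e-6)
})

test_that("AIC counts covariance parameters only", {
  # a + ce blocks: 3 each; residual: 1 (RNM1) or 2 (RNM2)
  expect_equal(AIC(rnm_fit1), -2 * as.numeric(logLik(rnm_fit1)) + 2 * 7)
  expect_equal(AIC(rnm_fit2), -2 * as.numeric(logLik(rnm_fit2)) + 2 * 8)
})

test_that("choose_model picks the lower AIC and ties go to RNM1", {
  best <- choose_model(rnm_fit1, rnm_fit2)
  want <- if (AIC(rnm_fit1) <= AIC(rnm_fit2)) "homogeneous" else
    "heteroscedastic"
  expect_equal(best$residual_kind, want)
})

test_that("choose_model refuses fits on different data", {
  cfg <- sim_config(n_founders = 12, n_generations = 2, n_cg = 4, seed = 77)
  sim <- simulate_dataset(cfg)
  gr <- env_gradient(sim$phenotypes)
  other <- rnm(y ~ 1, sim$phenotypes, gr, random = "a",
               residual = "homogeneous", pedigree = sim$pedigree)
  expect_error(choose_model(rnm_fit1, other), "same data")
})

test_that("fit object carries coherent solutions and methods", {
  fit <- rnm_fit1
  s <- solutions(fit, "a")
  expect_setequal(s$level, rnm_sim$sim$pedigree$animal)
  expect_true(all(c("intercept", "slope", "se_intercept", "se_slope")
                  %in% names(s)))
  expect_length(fitted(fit), nrow(rnm_sim$ph))
  expect_equal(fitted(fit) + residuals(fit), rnm_sim$ph$y, tolerance = 1e-10)
  expect_s3_class(summary(fit), "summary.rnm")
  expect_output(print(fit), "reaction norm")
  expect_output(print(summary(fit)), "Variance components")
})

test_that("predict evaluates the reaction norms linearly", {
  fit <- rnm_fit1
  s <- solutions(fit, "a")
  p0 <- predict(fit, theta = 0)
  p1 <- predict(fit, theta = 1.3)
  expect_equal(unname(p0), s$intercept, tolerance = 1e-10)
  expect_equal(unname(p1), s$intercept + 1.3 * s$slope, tolerance = 1e-10)
})

test_that("assemble_mme exposes equations whose solution matches the fit", {
  fit <- rnm_fit1
  mm <- assemble_mme(y ~ factor(parity) + age, rnm_sim$ph, rnm_sim$gr,
                     varcomp = fit$varcomp,
                     pedigree = rnm_sim$sim$pedigree,
                     genotypes = rnm_sim$sim$genotypes)
  expect_equal(length(mm$rhs), nrow(mm$C))
  expect_equal(unname(mm$solution[seq_along(fit$beta)]), unname(fit$beta),
               tolerance = 1e-6)
})

test_that("varcomp standard errors from the AI matrix are present and sane", {
  se <- rnm_fit2$varcomp$se$se
  expect_true(all(is.finite(se)))
  expect_true(all(se > 0))
  expect_true(all(c("a.v0", "a.cov", "a.v1") %in% names(se)))
})

test_that("the pe effect and cg_as_class variants run end to end", {
  cfg <- sim_config(n_founders = 16, n_generations = 2, n_cg = 6,
                    records_per_animal = 3, seed = 78)
  tp <- true_params(pe = block2(0.2, 0, 0.05))
  sim <- simulate_dataset(cfg, tp)
  ph <- sim$phenotypes
  gr <- env_gradient(ph)
  fit_pe <- rnm(y ~ 1, ph, gr, random = c("a", "pe"),
                residual = "homogeneous", pedigree = sim$pedigree)
  expect_true("pe" %in% names(fit_pe$varcomp$blocks))
  fit_cg <- rnm(y ~ 1, ph, gr, random = "a", residual = "homogeneous",
                pedigree = sim$pedigree, cg_as_class = TRUE)
  expect_true(fit_cg$converged)
})

test_that("kernel falls back to pedigree-only A when genotypes are absent", {
  k <- additive_kernel(rnm_sim$sim$pedigree)
  expect_equal(k$kind, "A")
  k2 <- additive_kernel(rnm_sim$sim$pedigree, rnm_sim$sim$genotypes)
  expect_equal(k2$kind, "H")
  expect_gt(length(k2$genotyped_ids), 0)
})

test_that("rnm validates its inputs", {
  expect_error(rnm(y ~ 1, rnm_sim$ph, rnm_sim$gr, random = "pe",
                   residual = "homogeneous",
                   pedigree = rnm_sim$sim$pedigree),
               "'a'")
  bad <- rnm_sim$ph
  bad$animal[1] <- "ghost"
  expect_error(rnm(y ~ 1, bad, rnm_sim$gr, random = "a",
                   residual = "homogeneous",
                   pedigree = rnm_sim$sim$pedigree),
               "ghost")
})
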