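# GEBV evaluation, accuracies and stability summaries.

gebv_fit <- local({
  cfg <- sim_config(n_founders = 24, n_generations = 3, n_cg = 8,
                    records_per_animal = 3, seed = 91)
  sim <- simulate_dataset(cfg)
  ph <- apply_record_filters(sim$phenotypes, min_cg = 5)
  gr <- env_gradient(ph)
  fit <- rnm(y ~ 1, ph, gr, random = "a", residual = "homogeneous",
             pedigree = sim$pedigree, genotypes = sim$genotypes, se = TRUE)
  list(fit = fit, sim = sim)
})

test_that("gebv_at evaluates the linear reaction norm", {
  tab <- data.frame(level = c("x", "y"), intercept = c(1, 2),
                    slope = c(0.5, -1))
  expect_equal(unname(gebv_at(tab, 2)), c(2, 0))
  m <- gebv_at(tab, c(-1, 0, 1))
  expect_equal(dim(m), c(2, 3))
  expect_equal(unname(m["y", 3]), 1)
})

test_that("gebv_accuracy implements sqrt(1 - PEV/((1+F) var))", {
  expect_equal(gebv_accuracy(se = 0.5, f = 0, var_coeff = 1),
               sqrt(1 - 0.25))
  expect_equal(gebv_accuracy(se = 0.5, f = 0.25, var_coeff = 1),
               sqrt(1 - 0.25 / 1.25))
  # clamped at zero when PEV exceeds the variance
  expect_equal(gebv_accuracy(se = 2, f = 0, var_coeff = 1), 0)
  expect_error(gebv_accuracy(0.1, 0, -1), "positive")
})

test_that("accuracy_table covers all animals with accuracies in [0,1]", {
  acc <- accuracy_table(gebv_fit$fit)
  expect_setequal(acc$level, gebv_fit$sim$pedigree$animal)
  expect_true(all(acc$acc_intercept >= 0 & acc$acc_intercept <= 1))
  expect_true(all(acc$acc_slope >= 0 & acc$acc_slope <= 1))
  # animals with records should generally beat parentless, recordless ones
  expect_gt(mean(acc$acc_intercept), 0)
})

test_that("weighted correlation uses accuracy-product weights and strict cut", {
  set.seed(4)
  n <- 50
  x <- rnorm(n); y <- x + rnorm(n)
  acc <- runif(n, 0.2, 0.9)
  r <- weighted_gebv_correlation(x, y, acc, acc, min_acc = 0.35)
  sel <- acc > 0.35
  w <- acc[sel]^2
  xs <- x[sel]; ys <- y[sel]
  mx <- weighted.mean(xs, w); my <- weighted.mean(ys, w)
  rw <- sum(w * (xs - mx) * (ys - my)) /
    sqrt(sum(w * (xs - mx)^2) * sum(w * (ys - my)^2))
  expect_equal(r$r, rw, tolerance = 1e-12)
  expect_equal(r$n, sum(sel))
  expect_equal(r$se, sqrt((1 - rw^2) / (sum(sel) - 2)), tolerance = 1e-12)
  expect_output(print(r), "weighted GEBV correlation")
})

test_that("weighted correlation needs at least 3 qualifying animals", {
  expect_error(
    weighted_gebv_correlation(1:5, 1:5, rep(0.1, 5), rep(0.1, 5)),
    "fewer than 3")
})

test_that("offspring_counts counts sire and dam appearances", {
  ped <- gebv_fit$sim$pedigree
  off <- offspring_counts(ped)
  expect_equal(sum(off), sum(!is.na(ped$sire)) + sum(!is.na(ped$dam)))
  one <- names(off)[off > 0][1]
  expect_equal(unname(off[one]),
               sum(ped$sire %in% one) + sum(ped$dam %in% one))
})

test_that("rank_stability reports Spearman correlations at the quantiles", {
  rs <- rank_stability(gebv_fit$fit, gebv_fit$sim$pedigree,
                       min_offspring = 3, min_acc = 0.1)
  expect_equal(dim(rs$spearman), c(3, 3))
  expect_equal(unname(diag(rs$spearman)), rep(1, 3))
  expect_true(all(abs(rs$spearman) <= 1 + 1e-12))
  expect_length(rs$theta, 3)
  expect_gt(rs$n, 0)
})

test_that("sire_trajectories returns linear paths for extreme-slope sires", {
  tr <- sire_trajectories(gebv_fit$fit, gebv_fit$sim$pedigree,
                          min_offspring = 3, top_k = 3)
  expect_true(all(tr$group %in% c("high", "low")))
  s <- solutions(gebv_fit$fit, "a")
  for (lv in unique(tr$level)) {
    d <- tr[tr$level == lv, ]
    row <- s[s$level == lv, ]
    expect_equal(d$gebv, row$intercept + row$slope * d$theta,
                 tolerance = 1e-10)
  }
  # high-group slopes all at least as large as low-group slopes
  hs <- s$slope[match(unique(tr$level[tr$group == "high"]), s$level)]
  ls <- s$slope[match(unique(tr$level[tr$group == "low"]), s$level)]
  expect_gte(min(hs), max(ls) - 1e-12)
})

test_that("sire_trajectories warns when too few sires qualify", {
  expect_warning(
    sire_trajectories(gebv_fit$fit, gebv_fit$sim$pedigree,
                      min_offspring = 3, top_k = 500),
    "qualifying sires")
})
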