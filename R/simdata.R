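#' Simulation configuration
#'
#' Population and genotyping settings for the gene-dropping simulator.  The
#' defaults emulate a maternal-line nucleus population: a closed herd bred
#' for several generations, contemporary groups (CG) of heterogeneous size,
#' and a genotyped subset skewed toward recent generations, with SNPs on 18
#' autosomes and the X chromosome (about 4\% of markers on X).
#'
#' @param n_founders number of founder animals (generation 0).
#' @param n_generations number of bred generations (>= 1 unless only founders
#'   are wanted).
#' @param litter_size_mean mean litter size (Poisson, truncated at 1).
#' @param n_matings_per_gen litters produced per generation; defaults to
#'   `floor(n_founders / 2)`, which keeps the population size roughly stable
#'   per generation times the litter size.
#' @param n_cg number of contemporary groups.
#' @param cg_size_range relative CG weight range `(min, max)`; records are
#'   allocated to CGs with probabilities drawn uniformly from this range, so
#'   group sizes are heterogeneous.
#' @param records_per_animal mean number of phenotypic records per animal
#'   (Poisson, truncated at 1); repeated records land in different CGs.
#' @param n_auto_snps,n_x_snps SNP counts on the autosomes and on X.
#' @param founder_maf_range founder minor-allele-frequency range in (0, 0.5].
#' @param genotyping_fraction proportion of animals marked genotyped, biased
#'   toward later generations.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 80, n_generations = 8,
                       litter_size_mean = 6,
                       n_matings_per_gen = NULL,
                       n_cg = 30, cg_size_range = c(1, 4),
                       records_per_animal = 2,
                       n_auto_snps = 960, n_x_snps = 40,
                       founder_maf_range = c(0.05, 0.5),
                       genotyping_fraction = 0.3,
                       seed = 20210617) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              litter_size_mean = litter_size_mean,
              n_matings_per_gen = if (is.null(n_matings_per_gen))
                max(1L, n_founders %/% 2L) else as.integer(n_matings_per_gen),
              n_cg = as.integer(n_cg),
              cg_size_range = cg_size_range,
              records_per_animal = records_per_animal,
              n_auto_snps = as.integer(n_auto_snps),
              n_x_snps = as.integer(n_x_snps),
              founder_maf_range = founder_maf_range,
              genotyping_fraction = genotyping_fraction,
              seed = as.integer(seed))
  if (cfg$n_founders < 2) stop("need at least two founders")
  if (cfg$n_generations < 0) stop("n_generations must be >= 0")
  if (cfg$genotyping_fraction <= 0 || cfg$genotyping_fraction > 1)
    stop("genotyping_fraction must lie in (0, 1]")
  if (cfg$founder_maf_range[1] <= 0 || cfg$founder_maf_range[2] > 0.5 ||
      diff(cfg$founder_maf_range) < 0)
    stop("founder_maf_range must lie within (0, 0.5]")
  if (cfg$n_cg < 1) stop("need at least one contemporary group")
  class(cfg) <- "sim_config"
  cfg
}

#' True simulation parameters
#'
#' Covariance blocks and fixed effects of the generative reaction-norm model.
#' Each block is the 2x2 intercept/slope covariance of one random effect:
#' `a` (additive genetic, pedigree-correlated), `pe` (animal permanent
#' environment, i.i.d.), `ce` (litter, shared by full sibs).  The residual is
#' either homogeneous (`sigma2`) or exponentially heteroscedastic
#' (`d0`, `d1`), giving `var(e) = exp(d0 + d1 * theta)` along the gradient.
#'
#' @param a,pe,ce 2x2 symmetric PSD matrices (or `NULL` to omit pe/ce).
#' @param residual either `c(sigma2 = ...)` or `c(d0 = ..., d1 = ...)`.
#' @param mu overall mean.
#' @param parity additive effects of parity classes (recycled over parities).
#' @param age regression coefficient on the standardized age covariate.
#' @param b overall fixed regression on the environmental gradient.
#' @return Object of class `true_params`.
#' @export
true_params <- function(a = block2(1, 0.25, 0.18),
                        pe = NULL, ce = NULL,
                        residual = c(sigma2 = 1),
                        mu = 10, parity = c(0, 0.4, 0.6), age = 0.2,
                        b = 1) {
  blocks <- list(a = a, pe = pe, ce = ce)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  for (nm in names(blocks)) check_block(blocks[[nm]], nm)
  if (!"a" %in% names(blocks)) stop("the additive block 'a' is required")
  kind <- if (all(c("d0", "d1") %in% names(residual))) "heteroscedastic"
          else if ("sigma2" %in% names(residual)) "homogeneous"
          else stop("residual must be c(sigma2=) or c(d0=, d1=)")
  if (kind == "homogeneous" && residual[["sigma2"]] < 0)
    stop("residual variance must be non-negative")
  structure(list(blocks = blocks, residual_kind = kind, residual = residual,
                 fixed = list(mu = mu, parity = parity, age = age, b = b)),
            class = "true_params")
}

seed_offset <- function(cfg, k) (cfg$seed + k) %% .Machine$integer.max

#' Simulate a multi-generation pedigree
#'
#' Founders have unknown parents; every later generation is produced by
#' mating randomly sampled dams of the previous generation to a limited pool
#' of sires, one litter per dam per generation.  The returned pedigree is in
#' topological order with `generation` and `litter` columns.
#'
#' @param config a [sim_config()].
#' @return A [as_pedigree()] object.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed_offset(config, 0L))
  nf <- config$n_founders
  sex <- sample(rep(c("M", "F"), length.out = nf))
  ped <- data.frame(animal = sprintf("G0_%04d", seq_len(nf)),
                    sire = NA_character_, dam = NA_character_,
                    sex = sex, generation = 0L,
                    litter = sprintf("L0_%04d", seq_len(nf)),
                    stringsAsFactors = FALSE)
  gens <- list(ped)
  prev <- ped
  for (g in seq_len(config$n_generations)) {
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (!length(males) || !length(females))
      stop(sprintf("impossible mating structure: generation %d has %d males and %d females",
                   g - 1L, length(males), length(females)))
    nm <- min(config$n_matings_per_gen, length(females))
    dams <- sample(females, nm)
    pool <- sample(males, min(length(males), max(1L, ceiling(nm / 4))))
    sires <- sample(pool, nm, replace = TRUE)
    ls <- pmax(1L, rpois(nm, config$litter_size_mean))
    no <- sum(ls)
    lit <- rep(seq_len(nm), ls)
    cur <- data.frame(
      animal = sprintf("G%d_%04d", g, seq_len(no)),
      sire = sires[lit], dam = dams[lit],
      sex = sample(c("M", "F"), no, replace = TRUE),
      generation = g, litter = sprintf("L%d_%04d", g, lit),
      stringsAsFactors = FALSE)
    gens[[g + 1L]] <- cur
    prev <- cur
  }
  as_pedigree(do.call(rbind, gens))
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder alleles are drawn at per-SNP frequencies; each autosomal offspring
#' allele is a random one of the corresponding parent's two.  On the X
#' chromosome females receive the sire's single X plus a random maternal X,
#' while males receive one maternal allele and are dosage-coded on the
#' \{0, 2\} hemizygote scale.  A fraction of animals, biased toward recent
#' generations, is marked genotyped.
#'
#' @param ped pedigree from [simulate_pedigree()] (needs `generation`).
#' @param config a [sim_config()].
#' @return A [genotypes()] object covering every animal, with the genotyped
#'   subset flagged.
#' @export
drop_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  set.seed(seed_offset(config, 1L))
  na <- config$n_auto_snps; nx <- config$n_x_snps
  m <- na + nx
  chr <- c(as.character(sort(rep_len(1:18, na))), rep("X", nx))
  ## positions: uniform over a 150 Mb pseudo-chromosome, sorted within chr
  bp <- unlist(lapply(split(seq_len(m), factor(chr, levels = unique(chr))),
                      function(ix) sort(sample.int(1.5e8, length(ix)))),
               use.names = FALSE)
  map <- data.frame(snp = sprintf("snp%05d", seq_len(m)),
                    chr = chr, bp = bp, stringsAsFactors = FALSE)

  maf <- runif(m, config$founder_maf_range[1], config$founder_maf_range[2])
  isx <- map$chr == "X"
  n <- nrow(ped)
  pi <- ped_indices(ped)
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  male <- ped$sex == "M"
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    if (s == 0L && d == 0L) {
      h1 <- rbinom(m, 1L, maf); h2 <- rbinom(m, 1L, maf)
      if (male[i]) h2[isx] <- h1[isx]      # single X copied to both slots
    } else {
      pick_from <- function(j) {
        if (j == 0L) return(rbinom(m, 1L, maf))  # unknown parent: population allele
        u <- rbinom(m, 1L, 0.5)
        ifelse(u == 1L, H1[j, ], H2[j, ])
      }
      h1 <- pick_from(s)                    # paternal gamete
      h2 <- pick_from(d)                    # maternal gamete
      if (s > 0L) h1[isx] <- H1[s, isx]     # sire transmits his single X
      if (male[i]) h1[isx] <- h2[isx]       # males carry the maternal X only
    }
    H1[i, ] <- h1; H2[i, ] <- h2
  }
  dosage <- H1 + H2
  rownames(dosage) <- ped$animal

  ng <- max(2L, round(config$genotyping_fraction * n))
  w <- (ped$generation + 1)^2
  gen_ids <- sample(ped$animal, ng, prob = w)
  genotypes(dosage, map,
            genotyped = ped$animal %in% gen_ids,
            sex = setNames(ped$sex, ped$animal))
}

#' Simulate phenotypes under the reaction-norm covariance structure
#'
#' A true environmental gradient `theta_i` is drawn per CG (standard normal,
#' then standardized to mean 0, SD 1).  Per animal, additive intercept and
#' slope `(a0, a1)` are generated by a bivariate gene-flow recursion so that
#' their covariance over the pedigree is `A` kron `block_a`; `pe` values are
#' i.i.d. per animal and `ce` values are shared by full-sib litters.  Each
#' record is `y = mu + parity + age * beta_age + b*theta + (a0 + a1*theta) +
#' (pe0 + pe1*theta) + (ce0 + ce1*theta) + e`, with residual variance
#' `sigma2` or `exp(d0 + d1*theta)`.
#'
#' @param ped pedigree (needs `litter` column for the `ce` effect).
#' @param params a [true_params()] object.
#' @param config a [sim_config()].
#' @return Data frame of records (`animal`, `y`, `cg`, `parity`, `age`,
#'   `litter`, `sex`) with attribute `"truth"`: the true gradient, breeding
#'   values, pe/ce values and the generating parameters.
#' @export
simulate_phenotypes <- function(ped, params, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(params, "true_params"),
            inherits(config, "sim_config"))
  set.seed(seed_offset(config, 2L))
  n <- nrow(ped)
  theta <- rnorm(config$n_cg)
  theta <- as.numeric(scale(theta))
  names(theta) <- sprintf("cg%03d", seq_len(config$n_cg))

  blocks <- params$blocks
  ## additive values by gene flow; Mendelian variance scaled by parental F
  f <- inbreeding(ped)
  pi <- ped_indices(ped)
  cb <- chol(blocks$a + diag(1e-12, 2))
  a <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    s <- pi$sire[i]; d <- pi$dam[i]
    mu <- numeric(2); k <- 1
    if (s > 0 && d > 0) {
      mu <- 0.5 * (a[s, ] + a[d, ]); k <- 0.5 - 0.25 * (f[s] + f[d])
    } else if (s > 0) {
      mu <- 0.5 * a[s, ]; k <- 0.75 - 0.25 * f[s]
    } else if (d > 0) {
      mu <- 0.5 * a[d, ]; k <- 0.75 - 0.25 * f[d]
    }
    a[i, ] <- mu + sqrt(k) * drop(rnorm(2) %*% cb)
  }
  rownames(a) <- ped$animal

  pe <- NULL
  if (!is.null(blocks$pe)) {
    pe <- matrix(rnorm(2 * n), n, 2) %*% chol(blocks$pe + diag(1e-12, 2))
    rownames(pe) <- ped$animal
  }
  ce <- NULL
  litters <- NULL
  if (!is.null(blocks$ce)) {
    if (is.null(ped$litter)) stop("pedigree lacks a litter column for 'ce'")
    litters <- unique(ped$litter)
    ce <- matrix(rnorm(2 * length(litters)), ncol = 2) %*%
      chol(blocks$ce + diag(1e-12, 2))
    rownames(ce) <- litters
  }

  nrec <- pmax(1L, rpois(n, config$records_per_animal))
  rec_animal <- rep(seq_len(n), nrec)
  N <- length(rec_animal)
  wcg <- runif(config$n_cg, config$cg_size_range[1], config$cg_size_range[2])
  rec_cg <- sample(names(theta), N, replace = TRUE, prob = wcg)
  rec_par <- unlist(lapply(nrec, seq_len), use.names = FALSE)
  rec_age <- rnorm(N)
  th <- theta[rec_cg]

  fx <- params$fixed
  parity_eff <- fx$parity[pmin(rec_par, length(fx$parity))]
  fixed_part <- fx$mu + parity_eff + fx$age * rec_age + fx$b * th

  gp <- a[rec_animal, 1] + a[rec_animal, 2] * th
  if (!is.null(pe)) gp <- gp + pe[rec_animal, 1] + pe[rec_animal, 2] * th
  if (!is.null(ce)) {
    lid <- ped$litter[rec_animal]
    gp <- gp + ce[lid, 1] + ce[lid, 2] * th
  }
  ve <- if (params$residual_kind == "homogeneous")
    rep(params$residual[["sigma2"]], N)
  else exp(params$residual[["d0"]] + params$residual[["d1"]] * th)
  y <- fixed_part + gp + rnorm(N, sd = sqrt(ve))

  out <- data.frame(animal = ped$animal[rec_animal], y = y,
                    cg = rec_cg, parity = rec_par, age = rec_age,
                    litter = ped$litter[rec_animal],
                    sex = ped$sex[rec_animal],
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(theta = theta, a = a, pe = pe, ce = ce,
                             params = params)
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()], [drop_genotypes()] and
#' [simulate_phenotypes()]; fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param params a [true_params()].
#' @param genotypes generate genotypes (`TRUE`) or skip them.
#' @return List with `pedigree`, `genotypes` (or `NULL`), `phenotypes`,
#'   `truth` and the inputs.
#' @export
simulate_dataset <- function(config = sim_config(), params = true_params(),
                             genotypes = TRUE) {
  ped <- simulate_pedigree(config)
  gen <- if (genotypes) drop_genotypes(ped, config) else NULL
  phe <- simulate_phenotypes(ped, params, config)
  list(pedigree = ped, genotypes = gen, phenotypes = phe,
       truth = attr(phe, "truth"), config = config, params = params)
}
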