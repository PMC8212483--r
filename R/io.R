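#' Write and read the dataset's plain-text files
#'
#' Pedigree and phenotypes travel as CSV, genotypes as a dosage TSV (animals
#' x SNPs, first column the animal id) plus a map TSV (`snp`, `chr`, `bp`,
#' 1-based positions), the gradient as TSV.  Unknown parents are written as
#' `0`.
#'
#' @param ped,pheno,geno,gradient the objects to write.
#' @param path output file path.
#' @name dataset_io
NULL

#' @rdname dataset_io
#' @export
write_pedigree <- function(ped, path) {
  d <- as.data.frame(ped)
  d$sire[is.na(d$sire)] <- "0"
  d$dam[is.na(d$dam)] <- "0"
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_pedigree <- function(path) {
  as_pedigree(read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character"))
}

#' @rdname dataset_io
#' @export
write_phenotypes <- function(pheno, path) {
  write.csv(as.data.frame(pheno), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_phenotypes <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$animal <- as.character(d$animal)
  if (!is.null(d$litter)) d$litter <- as.character(d$litter)
  d$cg <- as.character(d$cg)
  if (anyNA(d$y) || !is.numeric(d$y)) stop("malformed phenotype file: ", path)
  d
}

#' @rdname dataset_io
#' @param map_path path of the SNP map TSV.
#' @export
write_genotypes <- function(geno, path, map_path) {
  d <- data.frame(animal = rownames(geno$dosage),
                  genotyped = as.integer(geno$genotyped),
                  geno$dosage, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(geno$map, map_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @param sex optional named sex vector to attach on read.
#' @export
read_genotypes <- function(path, map_path, sex = NULL) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  map <- read.table(map_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  ids <- as.character(d$animal)
  gn <- as.logical(d$genotyped)
  M <- as.matrix(d[, -(1:2), drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(!apply(d[, -(1:2), drop = FALSE], 1,
                        function(r) all(grepl("^[012]$", r))))[1]
    stop(sprintf("malformed genotype file %s at line %d", path, bad + 1L))
  }
  rownames(M) <- ids
  genotypes(M, map, genotyped = gn, sex = sex)
}

#' @rdname dataset_io
#' @export
write_gradient <- function(gradient, path) {
  write.table(as.data.frame(gradient), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' All thresholds and model switches of the pipeline in one validated list.
#' Defaults follow routine practice for this kind of analysis: genotype QC
#' at call rate 0.90 / MAF 0.01 / heterozygote difference 0.15, CG minimum
#' 10 records, 3.5-SD outlier and gradient cuts, 0.5 % window relevance,
#' accuracy cutoffs 0.35 (trait correlations) and 0.30 (re-ranking), and
#' offspring cutoffs 10 (re-ranking) / 30 (trajectories).
#'
#' @param ... overrides of the defaults listed above; see the source for
#'   the full key set.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pedigree_file = NULL, phenotype_file = NULL,
    genotype_file = NULL, map_file = NULL,
    call_rate_min = 0.90, maf_min = 0.01, het_diff_max = 0.15,
    min_cg = 10, sd_cut = 3.5,
    relevance_percent = 0.5, acc_corr = 0.35, acc_rank = 0.30,
    offspring_rank = 10, offspring_traj = 30,
    model = "auto",            # "RNM1", "RNM2" or "auto" (AIC choice)
    include_x = TRUE, cg_as_class = FALSE, blend = 0.05,
    random = c("a", "ce"),
    fixed = y ~ factor(parity) + age,
    gwas = TRUE, seed = 1L, outdir = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$model %in% c("RNM1", "RNM2", "auto"),
            cfg$relevance_percent >= 0, cfg$min_cg >= 1, cfg$sd_cut > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a DCF text file
#'
#' Flat `key: value` text (Debian-control format, diff-friendly, no code
#' execution).  Numeric and logical values are coerced; `random` may be a
#' comma-separated list; `fixed` is parsed as a formula.
#'
#' @param path file path.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  d <- as.list(read.dcf(path)[1, ])
  for (k in names(d)) {
    v <- trimws(d[[k]])
    if (k == "fixed") v <- as.formula(v)
    else if (k == "random") v <- trimws(strsplit(v, ",")[[1]])
    else if (grepl("^(TRUE|FALSE)$", v)) v <- as.logical(v)
    else if (grepl("^-?[0-9.]+$", v)) v <- as.numeric(v)
    d[[k]] <- v
  }
  do.call(run_config, d)
}

#' Load and cross-validate a dataset from files
#'
#' Reads pedigree, phenotypes and (optionally) genotypes, normalizes parent
#' codes, reorders the pedigree topologically, and verifies that every
#' record and genotyped animal exists in the pedigree.
#'
#' @param config a [run_config()] with file paths.
#' @return List: `pedigree`, `phenotypes`, `genotypes` (or `NULL`).
#' @export
load_dataset <- function(config) {
  ped <- read_pedigree(config$pedigree_file)
  pheno <- read_phenotypes(config$phenotype_file)
  bad <- setdiff(unique(pheno$animal), ped$animal)
  if (length(bad))
    stop("phenotyped animals absent from pedigree: ",
         paste(bad, collapse = ", "))
  geno <- NULL
  if (!is.null(config$genotype_file)) {
    geno <- read_genotypes(config$genotype_file, config$map_file,
                           sex = setNames(ped$sex, ped$animal))
    bad <- setdiff(rownames(geno$dosage), ped$animal)
    if (length(bad))
      stop("genotyped animals absent from pedigree: ",
           paste(bad, collapse = ", "))
  }
  list(pedigree = ped, phenotypes = pheno, genotypes = geno)
}

#' Run the full reaction-norm analysis pipeline
#'
#' Chains record filters, genotype QC, gradient estimation, REML fits of the
#' homogeneous and heteroscedastic models with AIC choice, gradient-dependent
#' genetic parameters, and (optionally) the windowed association scan.
#' Deterministic given `config$seed`.
#'
#' @param config a [run_config()].
#' @param data optional pre-loaded dataset (as from [simulate_dataset()] or
#'   [load_dataset()]); read from the configured files when `NULL`.
#' @return List of class `rnm_pipeline`: the chosen `fit`, both fits, the
#'   gradient, QC report, parameter curve, correlation summary, windows and
#'   regions, plus a machine-readable `summary` list.
#' @export
run_pipeline <- function(config = run_config(), data = NULL) {
  set.seed(config$seed)
  if (is.null(data)) data <- load_dataset(config)
  ped <- data$pedigree
  pheno <- apply_record_filters(data$phenotypes, min_cg = config$min_cg,
                                sd_cut = config$sd_cut)
  flog <- attr(pheno, "filter_log")
  qc <- NULL
  geno <- data$genotypes
  if (!is.null(geno)) {
    qc <- qc_genotypes(geno, call_rate_min = config$call_rate_min,
                       maf_min = config$maf_min,
                       het_diff_max = config$het_diff_max)
    geno <- qc$genotypes
  }
  fixed_terms <- attr(terms(config$fixed), "term.labels")
  grad <- env_gradient(pheno, fixed = fixed_terms, sd_cut = config$sd_cut)
  pheno <- pheno[pheno$cg %in% grad$cg[grad$kept], , drop = FALSE]

  kernel <- additive_kernel(ped, geno, blend = config$blend,
                            include_x = config$include_x)
  fit_one <- function(res) rnm(config$fixed, pheno, grad,
                               random = config$random, residual = res,
                               kernel = kernel,
                               cg_as_class = config$cg_as_class)
  fits <- list()
  if (config$model %in% c("RNM1", "auto"))
    fits$RNM1 <- fit_one("homogeneous")
  if (config$model %in% c("RNM2", "auto"))
    fits$RNM2 <- fit_one("heteroscedastic")
  fit <- if (length(fits) == 2L) choose_model(fits$RNM1, fits$RNM2)
         else fits[[1]]

  curve <- parameter_curve(fit)
  corsum <- env_correlation_summary(fit)
  vc <- fit$varcomp
  slope_se <- if (!is.null(vc$se)) unname(vc$se$se["a.v1"]) else NA_real_

  windows <- regions <- eff <- NULL
  if (isTRUE(config$gwas) && !is.null(geno) && sum(geno$genotyped) >= 2) {
    eff <- snp_effects(fit, geno)
    windows <- window_variance_proportions(
      eff, var_a0 = vc$blocks$a[1, 1], var_a1 = vc$blocks$a[2, 2])
    regions <- rbind(
      find_relevant_regions(windows, "intercept", config$relevance_percent),
      find_relevant_regions(windows, "slope", config$relevance_percent))
  }

  summary <- list(
    model = fit$model,
    aic = vapply(fits, AIC, numeric(1)),
    blocks = vc$blocks, residual = vc$residual,
    slope_variance = vc$blocks$a[2, 2], slope_variance_se = slope_se,
    intercept_slope_correlation =
      intercept_slope_correlation(vc$blocks$a),
    min_env_correlation = corsum$min,
    extreme_env_correlation = corsum$extreme,
    mean_env_correlation = corsum$mean,
    n_records = nrow(pheno), n_cg = sum(grad$kept),
    n_relevant_regions = if (is.null(regions)) NA_integer_ else nrow(regions))

  out <- list(fit = fit, fits = fits, gradient = grad, qc = qc,
              filter_log = flog, curve = curve,
              env_correlations = corsum, snp_effects = eff,
              windows = windows, regions = regions, summary = summary,
              config = config)
  class(out) <- "rnm_pipeline"
  if (!is.null(config$outdir)) write_pipeline_outputs(out, config$outdir)
  out
}

#' @export
print.rnm_pipeline <- function(x, ...) {
  s <- x$summary
  cat("reaction-norm pipeline\n")
  cat(sprintf("  chosen model: %s (AIC %s)\n", s$model,
              paste(sprintf("%s=%.2f", names(s$aic), s$aic), collapse = ", ")))
  cat(sprintf("  slope variance: %.4f (SE %.4f)\n", s$slope_variance,
              s$slope_variance_se))
  cat(sprintf("  intercept-slope correlation: %.3f\n",
              s$intercept_slope_correlation))
  cat(sprintf("  min / extreme cross-environment correlation: %.3f / %.3f\n",
              s$min_env_correlation, s$extreme_env_correlation))
  if (!is.na(s$n_relevant_regions))
    cat(sprintf("  relevant genomic regions: %d\n", s$n_relevant_regions))
  invisible(x)
}

## write all tabular outputs of a pipeline run; coordinates are 1-based
## inclusive, gradient on the standardized (mean 0, SD 1) scale
write_pipeline_outputs <- function(x, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                   row.names = FALSE, quote = FALSE)
  wt(as.data.frame(x$gradient), "gradient.tsv")
  wt(x$curve, "parameter_curve.tsv")
  s <- solutions(x$fit, "a")
  wt(s, "solutions_a.tsv")
  if (!is.null(x$qc)) wt(x$qc$report, "qc_report.tsv")
  if (!is.null(x$windows)) wt(x$windows, "windows.tsv")
  if (!is.null(x$regions)) wt(x$regions, "regions.tsv")
  if (!is.null(x$snp_effects)) wt(as.data.frame(x$snp_effects),
                                  "snp_effects.tsv")
  vt <- summary(x$fit)$varcomp_table
  wt(vt, "varcomp.tsv")
  invisible(outdir)
}
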