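#' Replicate-aware simulator of exome-style cohorts with known causal
#' architecture.
#'
#' The generator emulates a workshop-style design: a fixed mini-exome of
#' mostly-rare variants with synonymous/nonsynonymous annotation, a fixed
#' genotype matrix, and many phenotype replicates that re-draw environmental
#' exposures, trait noise and the latent liability while the genotypes stay
#' fixed.  Quantitative traits are driven by environmental covariates and by
#' the standardized nonsynonymous weighted-sum burden of their causal genes;
#' the binary disease arises from a liability-threshold model whose liability
#' combines the traits, direct environmental effects and an unobserved latent
#' Gaussian component.
#'
#' @name synthetic-data
NULL

#' Build and validate a generator configuration
#'
#' Defaults describe the package's reference scenario: a 500-individual
#' cohort, 30 genes of 3-10 mostly-rare variants, 70% nonsynonymous
#' annotation, two pleiotropically overlapping causal gene sets for Q1 and Q2
#' (Q4 carries environment only), 0.5 trait-SD per-gene effects, a
#' unit-variance latent liability and 30% disease prevalence over 20
#' replicates.
#'
#' @param n_individuals cohort size (shared by every replicate).
#' @param n_genes number of genes.
#' @param variants_per_gene integer range c(min, max) of variants per gene.
#' @param fraction_nonsynonymous probability a variant is nonsynonymous.
#' @param maf_bounds lower/upper truncation bounds for MAF, in (0, 0.5].
#' @param maf_shape Beta(shape1, shape2) density truncated to `maf_bounds`;
#'   the default (0.3, 8) is heavily rare-skewed.
#' @param causal_genes named list mapping trait name ("Q1", "Q2", "Q4") to a
#'   character vector of causal gene ids; NULL gives the default pleiotropic
#'   scenario (Q1: genes 1-5, Q2: genes 4-8, Q4: none).
#' @param effect_size per-causal-gene coefficient on the standardized
#'   nonsynonymous burden score, in trait SD units.
#' @param env_effects named list of coefficient vectors
#'   c(smoking, sex, age) for each of Q1, Q2, Q4 and "liability"; age enters
#'   standardized.
#' @param trait_liability coefficients of the standardized traits in the
#'   liability.
#' @param latent_liability_sd SD of the unobserved liability component.
#' @param prevalence target affected fraction, in (0, 1).
#' @param n_replicates number of phenotype replicates.
#' @param age_range uniform age range in years.
#' @param p_sex,p_smoking Bernoulli rates for sex and smoking.
#' @param per_variant_effects if TRUE, causal genes act through raw
#'   (unweighted) nonsynonymous allele counts instead of the weighted burden
#'   score; a stress-test mode.
#' @param calibration_n Monte Carlo cohort size used once to locate the
#'   liability threshold matching `prevalence`.
#' @param seed master seed; everything downstream is deterministic given it.
#' @return a validated list of class "sim_config".
#' @export
sim_config <- function(n_individuals = 500L,
                       n_genes = 30L,
                       variants_per_gene = c(3L, 10L),
                       fraction_nonsynonymous = 0.7,
                       maf_bounds = c(5e-4, 0.05),
                       maf_shape = c(0.3, 8),
                       causal_genes = NULL,
                       effect_size = 0.5,
                       env_effects = NULL,
                       trait_liability = c(Q1 = 0.7, Q2 = 0.7, Q4 = 0.3),
                       latent_liability_sd = 1,
                       prevalence = 0.3,
                       n_replicates = 20L,
                       age_range = c(20, 80),
                       p_sex = 0.5,
                       p_smoking = 0.3,
                       per_variant_effects = FALSE,
                       calibration_n = 20000L,
                       seed = 1L) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(causal_genes)) {
    causal_genes <- list(
      Q1 = genes[seq_len(min(5L, n_genes))],
      Q2 = genes[seq(min(4L, n_genes), min(8L, n_genes))],
      Q4 = character(0))
  }
  for (tr in c("Q1", "Q2", "Q4")) {
    if (is.null(causal_genes[[tr]])) causal_genes[[tr]] <- character(0)
  }
  if (is.null(env_effects)) {
    env_effects <- list(
      Q1 = c(smoking = 0.5, sex = 0, age = 0),
      Q2 = c(smoking = 0, sex = 0, age = 0.3),
      Q4 = c(smoking = 0.5, sex = 0.3, age = 0),
      liability = c(smoking = 0.6, sex = 0.3, age = 0.4))
  }
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_genes = as.integer(n_genes),
              variants_per_gene = as.integer(variants_per_gene),
              fraction_nonsynonymous = fraction_nonsynonymous,
              maf_bounds = maf_bounds, maf_shape = maf_shape,
              genes = genes, causal_genes = causal_genes,
              effect_size = effect_size, env_effects = env_effects,
              trait_liability = trait_liability,
              latent_liability_sd = latent_liability_sd,
              prevalence = prevalence,
              n_replicates = as.integer(n_replicates),
              age_range = age_range, p_sex = p_sex, p_smoking = p_smoking,
              per_variant_effects = per_variant_effects,
              calibration_n = as.integer(calibration_n),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals >= 1, cfg$n_genes >= 1, cfg$n_replicates >= 1,
            length(cfg$variants_per_gene) == 2,
            all(cfg$variants_per_gene >= 1),
            cfg$variants_per_gene[1] <= cfg$variants_per_gene[2])
  if (cfg$fraction_nonsynonymous < 0 || cfg$fraction_nonsynonymous > 1) {
    stop("fraction_nonsynonymous must lie in [0, 1]")
  }
  if (!(cfg$maf_bounds[1] > 0 && cfg$maf_bounds[2] <= 0.5 &&
        cfg$maf_bounds[1] < cfg$maf_bounds[2])) {
    stop("maf_bounds must satisfy 0 < lower < upper <= 0.5")
  }
  if (!(cfg$prevalence > 0 && cfg$prevalence < 1)) {
    stop("prevalence must lie in (0, 1)")
  }
  bad <- setdiff(unique(unlist(cfg$causal_genes)), cfg$genes)
  if (length(bad)) {
    stop("causal gene(s) not among generated genes: ",
         paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Generate the variant table
#'
#' Assigns each gene a uniform random number of variants in the configured
#' range, draws MAFs from the truncated-Beta rare-skewed spectrum (inverse
#' CDF on the truncated interval) and annotates each variant independently
#' as nonsynonymous with probability `fraction_nonsynonymous`.  Every causal
#' gene is guaranteed at least one nonsynonymous variant (its first variant
#' is promoted if needed) so its configured effect cannot silently vanish.
#'
#' @param config a [sim_config()] object.
#' @return data.frame(variant_id, gene_id, maf, annotation).
#' @export
sim_variants <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "variants"), {
    sizes <- seq.int(config$variants_per_gene[1], config$variants_per_gene[2])
    nv <- sizes[sample.int(length(sizes), config$n_genes, replace = TRUE)]
    gene_id <- rep(config$genes, nv)
    p <- sum(nv)
    lo <- pbeta(config$maf_bounds[1], config$maf_shape[1], config$maf_shape[2])
    hi <- pbeta(config$maf_bounds[2], config$maf_shape[1], config$maf_shape[2])
    maf <- qbeta(runif(p, lo, hi), config$maf_shape[1], config$maf_shape[2])
    ann <- ifelse(runif(p) < config$fraction_nonsynonymous,
                  "nonsynonymous", "synonymous")
    vt <- data.frame(variant_id = sprintf("V%05d", seq_len(p)),
                     gene_id = gene_id, maf = maf, annotation = ann,
                     stringsAsFactors = FALSE)
    causal <- unique(unlist(config$causal_genes))
    for (g in causal) {
      rows <- which(vt$gene_id == g)
      if (!any(vt$annotation[rows] == "nonsynonymous")) {
        vt$annotation[rows[1]] <- "nonsynonymous"
      }
    }
    vt
  })
}

#' Generate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each minor-allele count is drawn independently as Binomial(2, maf).
#'
#' @param variants a variant table from [sim_variants()].
#' @param n_individuals number of rows.
#' @param seed integer seed.
#' @return integer matrix individuals x variants with dimnames.
#' @export
sim_genotypes <- function(variants, n_individuals, seed = 1L) {
  stopifnot(n_individuals >= 1)
  with_seed(seed, {
    p <- nrow(variants)
    g <- vapply(seq_len(p),
                function(j) rbinom(n_individuals, 2L, variants$maf[j]),
                integer(n_individuals))
    g <- matrix(as.integer(g), nrow = n_individuals, ncol = p,
                dimnames = list(sprintf("I%05d", seq_len(n_individuals)),
                                variants$variant_id))
    g
  })
}

# standardized per-gene causal input: nonsynonymous weighted burden (default)
# or raw nonsynonymous allele count (per-variant stress mode)
causal_gene_inputs <- function(genotypes, variants, config) {
  genes <- unique(unlist(config$causal_genes))
  out <- matrix(0, nrow(genotypes), length(genes),
                dimnames = list(rownames(genotypes), genes))
  for (g in genes) {
    s <- if (config$per_variant_effects) {
      j <- variants$variant_id[variants$gene_id == g &
                                 variants$annotation == "nonsynonymous"]
      rowSums(genotypes[, j, drop = FALSE])
    } else {
      burden_score(genotypes, variants, g, annotation = "nonsynonymous",
                   maf_source = "table")
    }
    sdv <- sd(s)
    out[, g] <- if (is.finite(sdv) && sdv > 0) (s - mean(s)) / sdv else 0
  }
  out
}

# env design helpers: age standardized to mean 0, unit SD of its uniform law
standardize_age <- function(age, range) {
  (age - mean(range)) / (diff(range) / sqrt(12))
}

# one draw of phenotypes (and the underlying liability) for a cohort
draw_phenotypes <- function(genotypes, variants, config, seed) {
  with_seed(seed, {
    n <- nrow(genotypes)
    age <- runif(n, config$age_range[1], config$age_range[2])
    sex <- rbinom(n, 1L, config$p_sex)
    smoking <- rbinom(n, 1L, config$p_smoking)
    zage <- standardize_age(age, config$age_range)
    env <- cbind(smoking = smoking, sex = sex, age = zage)
    gin <- causal_gene_inputs(genotypes, variants, config)
    traits <- matrix(0, n, 3, dimnames = list(NULL, c("Q1", "Q2", "Q4")))
    for (tr in c("Q1", "Q2", "Q4")) {
      ee <- config$env_effects[[tr]]
      mu <- drop(env %*% ee[c("smoking", "sex", "age")])
      cg <- config$causal_genes[[tr]]
      if (length(cg)) {
        mu <- mu + config$effect_size * rowSums(gin[, cg, drop = FALSE])
      }
      traits[, tr] <- mu + rnorm(n)
    }
    zt <- scale(traits)
    el <- config$env_effects$liability
    liability <- drop(zt %*% config$trait_liability[colnames(traits)]) +
      drop(env %*% el[c("smoking", "sex", "age")]) +
      rnorm(n, 0, config$latent_liability_sd)
    list(age = age, sex = sex, smoking = smoking, traits = traits,
         liability = liability)
  })
}

#' Simulate one phenotype replicate
#'
#' Draws environmental covariates, the three quantitative traits and the
#' liability, then thresholds the liability into the binary affected status.
#' The threshold is either supplied (shared across replicates, as
#' [sim_replicates()] does after Monte Carlo calibration) or taken as the
#' (1 - prevalence) quantile of this replicate's own liability sample.
#' `replicate_index` perturbs only the stochastic draws; genotypes are
#' untouched.
#'
#' @param genotypes genotype matrix from [sim_genotypes()].
#' @param variants matching variant table.
#' @param config a [sim_config()] object.
#' @param replicate_index which replicate (changes only noise seeds).
#' @param threshold optional fixed liability threshold.
#' @return data.frame(id, age, sex, smoking, Q1, Q2, Q4, affected) with the
#'   latent liability attached as attribute "liability".
#' @export
sim_phenotypes <- function(genotypes, variants, config, replicate_index = 1L,
                           threshold = NULL) {
  validate_sim_config(config)
  d <- draw_phenotypes(genotypes, variants, config,
                       derive_seed(config$seed, "phenotypes",
                                   replicate_index))
  if (is.null(threshold)) {
    threshold <- quantile(d$liability, 1 - config$prevalence, names = FALSE)
  }
  out <- data.frame(id = rownames(genotypes), age = d$age, sex = d$sex,
                    smoking = d$smoking, Q1 = d$traits[, "Q1"],
                    Q2 = d$traits[, "Q2"], Q4 = d$traits[, "Q4"],
                    affected = as.integer(d$liability > threshold),
                    stringsAsFactors = FALSE)
  attr(out, "liability") <- d$liability
  attr(out, "threshold") <- threshold
  out
}

# locate the liability threshold by Monte Carlo on a fresh calibration cohort
calibrate_threshold <- function(variants, config) {
  gcal <- sim_genotypes(variants, config$calibration_n,
                        derive_seed(config$seed, "calibration", 1L))
  d <- draw_phenotypes(gcal, variants, config,
                       derive_seed(config$seed, "calibration", 2L))
  quantile(d$liability, 1 - config$prevalence, names = FALSE)
}

#' Generate a full replicate set with ground truth
#'
#' Composes [sim_variants()], [sim_genotypes()] and [sim_phenotypes()]:
#' one shared variant table and genotype matrix, `n_replicates` phenotype
#' tables drawn with a liability threshold calibrated once by Monte Carlo,
#' and a ground-truth record (causal gene sets and the true edge list:
#' gene -> trait for causal genes, environment -> trait/disease for nonzero
#' environmental coefficients, trait -> disease for nonzero liability
#' weights).
#'
#' @param config a [sim_config()] object.
#' @return object of class "replicate_set": list(variants, genotypes,
#'   phenotypes, truth, threshold, config).
#' @examples
#' rs <- sim_replicates(sim_config(n_individuals = 50, n_genes = 5,
#'                                 n_replicates = 2, calibration_n = 1000))
#' length(rs$phenotypes)
#' @export
sim_replicates <- function(config) {
  validate_sim_config(config)
  variants <- sim_variants(config)
  genotypes <- sim_genotypes(variants, config$n_individuals,
                             derive_seed(config$seed, "genotypes"))
  threshold <- calibrate_threshold(variants, config)
  phenotypes <- lapply(seq_len(config$n_replicates), function(r) {
    sim_phenotypes(genotypes, variants, config, r, threshold)
  })
  truth <- list(causal_genes = config$causal_genes,
                edges = true_edges(config))
  structure(list(variants = variants, genotypes = genotypes,
                 phenotypes = phenotypes, truth = truth,
                 threshold = threshold, config = config),
            class = "replicate_set")
}

# ground-truth edge list implied by the generating equations
true_edges <- function(config) {
  ed <- list()
  add <- function(from, to) ed[[length(ed) + 1L]] <<- c(from, to)
  for (tr in c("Q1", "Q2", "Q4")) {
    for (g in config$causal_genes[[tr]]) add(g, tr)
    ee <- config$env_effects[[tr]]
    for (e in names(ee)) if (ee[[e]] != 0) add(e, tr)
  }
  for (tr in names(config$trait_liability)) {
    if (config$trait_liability[[tr]] != 0) add(tr, "affected")
  }
  el <- config$env_effects$liability
  for (e in names(el)) if (el[[e]] != 0) add(e, "affected")
  m <- do.call(rbind, ed)
  data.frame(from = m[, 1], to = m[, 2], stringsAsFactors = FALSE)
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("Simulated replicate set\n")
  cat(sprintf("  %d individuals, %d genes, %d variants, %d replicates\n",
              nrow(x$genotypes), x$config$n_genes, nrow(x$variants),
              length(x$phenotypes)))
  cat(sprintf("  causal genes: %s\n",
              paste(sprintf("%s:%d", names(x$truth$causal_genes),
                            lengths(x$truth$causal_genes)), collapse = " ")))
  cat(sprintf("  liability threshold %.3f (target prevalence %.2f)\n",
              x$threshold, x$config$prevalence))
  invisible(x)
}
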