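test_that("variant table respects counts, annotation fractions and MAF bounds", {
  cfg <- sim_config(n_genes = 10L, variants_per_gene = c(5L, 5L),
                    fraction_nonsynonymous = 1.0, seed = 3L)
  vt <- sim_variants(cfg)
  expect_equal(nrow(vt), 50L)
  expect_equal(length(unique(vt$gene_id)), 10L)
  expect_true(all(vt$annotation == "nonsynonymous"))
  expect_false(any(duplicated(vt$variant_id)))

  cfg2 <- sim_config(n_genes = 500L, variants_per_gene = c(20L, 20L),
                     maf_bounds = c(0.001, 0.05), seed = 4L)
  vt2 <- sim_variants(cfg2) # 10,000 MAF draws
  expect_gte(nrow(vt2), 10000L)
  expect_lte(max(vt2$maf), 0.05)
  expect_gte(min(vt2$maf), 0.001)
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(maf_bounds = c(0, 0.05)), "maf_bounds")
  expect_error(sim_config(maf_bounds = c(0.01, 0.6)), "maf_bounds")
  expect_error(sim_config(prevalence = 1.2), "prevalence")
  expect_error(sim_config(fraction_nonsynonymous = 1.5),
               "fraction_nonsynonymous")
  expect_error(sim_config(causal_genes = list(Q1 = "NOPE")), "causal")
})

test_that("genotypes follow Binomial(2, maf) and are seed-deterministic", {
  v <- data.frame(variant_id = c("V1", "V2"), gene_id = "G1",
                  maf = c(0.5, 1e-6), annotation = "nonsynonymous")
  g <- sim_genotypes(v, 100000L, seed = 5L)
  expect_true(all(g %in% 0:2))
  # mean allele count for maf = 0.5 is 1; CLT band at n = 100,000
  expect_gt(mean(g[, "V1"]), 0.99)
  expect_lt(mean(g[, "V1"]), 1.01)
  # near-zero MAF: essentially monomorphic
  expect_lte(sum(g[1:100, "V2"]), 2L)
  g2 <- sim_genotypes(v, 100000L, seed = 5L)
  expect_identical(g, g2)
})

test_that("empirical allele frequencies converge to the configured MAF", {
  cfg <- sim_config(n_genes = 4L, variants_per_gene = c(4L, 4L),
                    maf_bounds = c(0.01, 0.2), seed = 6L)
  vt <- sim_variants(cfg)
  g <- sim_genotypes(vt, 10000L, seed = 7L)
  emp <- colMeans(g) / 2
  se <- sqrt(vt$maf * (1 - vt$maf) / (2 * 10000))
  expect_true(all(abs(emp - vt$maf) <= 3 * se + 1e-12))
})

test_that("null generator decouples traits from gene scores", {
  cfg <- sim_config(n_individuals = 10000L, n_genes = 4L,
                    effect_size = 0,
                    env_effects = list(
                      Q1 = c(smoking = 0, sex = 0, age = 0),
                      Q2 = c(smoking = 0, sex = 0, age = 0),
                      Q4 = c(smoking = 0, sex = 0, age = 0),
                      liability = c(smoking = 0, sex = 0, age = 0)),
                    maf_bounds = c(0.01, 0.2), seed = 8L)
  vt <- sim_variants(cfg)
  g <- sim_genotypes(vt, cfg$n_individuals, seed = 9L)
  ph <- sim_phenotypes(g, vt, cfg)
  for (gene in cfg$causal_genes$Q1) {
    s <- burden_score(g, vt, gene, "nonsynonymous", maf_source = "table")
    expect_lt(abs(cor(ph$Q1, s)), 0.05)
  }
})

test_that("liability threshold calibration hits the target prevalence", {
  cfg <- sim_config(n_individuals = 10000L, n_genes = 5L,
                    prevalence = 0.3, n_replicates = 2L, seed = 10L)
  rs <- sim_replicates(cfg)
  frac <- mean(rs$phenotypes[[1]]$affected)
  expect_gte(frac, 0.28)
  expect_lte(frac, 0.32)
})

test_that("replicates share genotypes but re-draw phenotypes", {
  ph1 <- tiny_rs$phenotypes[[1]]
  ph2 <- tiny_rs$phenotypes[[2]]
  expect_false(identical(ph1$Q1, ph2$Q1))
  expect_identical(ph1$id, ph2$id)
  # the genotype matrix is literally shared, one copy for all replicates
  expect_equal(length(tiny_rs$phenotypes), tiny_rs$config$n_replicates)
})

test_that("replicate sets are bit-identical given the same config", {
  rs2 <- sim_replicates(tiny_config())
  expect_identical(tiny_rs$genotypes, rs2$genotypes)
  expect_identical(tiny_rs$variants, rs2$variants)
  expect_identical(tiny_rs$phenotypes, rs2$phenotypes)
})

test_that("ground truth records the configured causal architecture", {
  expect_identical(tiny_rs$truth$causal_genes, tiny_rs$config$causal_genes)
  ed <- tiny_rs$truth$edges
  for (g in tiny_rs$config$causal_genes$Q1) {
    expect_true(any(ed$from == g & ed$to == "Q1"))
  }
  expect_true(all(c("Q1", "Q2") %in% ed$from[ed$to == "affected"]))
})

test_that("trait variance grows monotonically with the effect size", {
  vars <- sapply(c(0, 0.5, 1, 2), function(es) {
    cfg <- sim_config(n_individuals = 2000L, n_genes = 5L,
                      effect_size = es, seed = 11L)
    vt <- sim_variants(cfg)
    g <- sim_genotypes(vt, cfg$n_individuals, seed = 12L)
    var(sim_phenotypes(g, vt, cfg)$Q1)
  })
  expect_true(all(diff(vars) > 0))
})

test_that("causal genes always carry a nonsynonymous variant", {
  cfg <- sim_config(n_genes = 10L, fraction_nonsynonymous = 0.05,
                    seed = 13L)
  vt <- sim_variants(cfg)
  for (g in unique(unlist(cfg$causal_genes))) {
    expect_true(any(vt$annotation[vt$gene_id == g] == "nonsynonymous"))
  }
})
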