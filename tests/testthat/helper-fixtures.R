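# Shared small fixtures, built once per test run.

fx <- rarebn::make_fixtures(seed = 7L)

# a small replicate set with strong Q1 signal, reused across modules
tiny_config <- function(...) {
  sim_config(n_individuals = 200L, n_genes = 8L,
             variants_per_gene = c(3L, 6L), n_replicates = 4L,
             calibration_n = 3000L, seed = 42L, ...)
}

tiny_rs <- sim_replicates(tiny_config())
tiny_scores <- burden_matrix(tiny_rs$genotypes, tiny_rs$variants, "all")

# default typed roles for a 7-node network fixture
roles7 <- c(age = "environment", sex = "environment",
            smoking = "environment", G1 = "gene", G2 = "gene",
            Q1 = "trait", affected = "disease")

# data for the 7-node typed fixture: G1 drives Q1 drives affected
make_data7 <- function(n = 300L, seed = 1L) {
  set.seed(seed)
  d <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5),
                  smoking = rbinom(n, 1, 0.3),
                  G1 = rnorm(n), G2 = rnorm(n))
  d$Q1 <- 0.8 * d$G1 + 0.4 * d$smoking + rnorm(n)
  d$affected <- as.integer(d$Q1 + rnorm(n) > 0.5)
  d[, names(roles7)]
}
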