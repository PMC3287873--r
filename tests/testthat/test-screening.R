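test_that("the vectorized OLS screen reproduces lm() exactly", {
  set.seed(31)
  n <- 80
  smoke <- rbinom(n, 1, 0.3)
  scores <- matrix(rnorm(n * 5), n, 5,
                   dimnames = list(NULL, paste0("G", 1:5)))
  y <- 0.4 * scores[, 2] + 0.3 * smoke + rnorm(n)
  p_fast <- marginal_scan(scores, smoke, y, "continuous")
  for (j in 1:5) {
    p_lm <- summary(lm(y ~ scores[, j] + smoke))$coefficients[2, 4]
    expect_equal(unname(p_fast[j]), p_lm, tolerance = 1e-10)
  }
})

test_that("the binary screen reproduces glm() and falls back on separation", {
  set.seed(32)
  n <- 150
  smoke <- rbinom(n, 1, 0.3)
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * s))
  res <- marginal_regression(s, smoke, y, "binary")
  p_glm <- summary(glm(y ~ s + smoke,
                       family = binomial()))$coefficients["s", 4]
  expect_equal(res$p, p_glm, tolerance = 1e-10)
  expect_false(res$fallback)
  # perfectly separating score triggers the linear-probability fallback
  y_sep <- as.integer(s > 0)
  res_sep <- marginal_regression(s, smoke, y_sep, "binary")
  expect_true(res_sep$fallback)
  expect_lt(res_sep$p, 1e-10)
})

test_that("degenerate and perfect-signal cases behave as contracted", {
  n <- 50
  smoke <- rbinom(n, 1, 0.3)
  res <- marginal_regression(rep(0, n), smoke, rnorm(n), "continuous")
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
  s <- rnorm(n)
  expect_lt(marginal_regression(s, smoke, 2 * s, "continuous")$p, 1e-10)
})

test_that("type-I error of the screen is calibrated at the 0.1 cutoff", {
  set.seed(33)
  n <- 100
  m <- 2000
  smoke <- rbinom(n, 1, 0.3)
  scores <- matrix(rnorm(n * m), n, m)
  p <- marginal_scan(scores, smoke, rnorm(n), "continuous")
  frac <- mean(p < 0.1)
  expect_gte(frac, 0.08)  # 3 binomial SEs around 0.10 at m = 2,000
  expect_lte(frac, 0.12)
})

test_that("retention rule is strict and its bookkeeping consistent", {
  # 4 replicates; response equals the score in replicates 1-2 (p ~ 0),
  # and is constant in replicates 3-4 (p = 1 by the degenerate guard)
  n <- 60
  set.seed(34)
  scores <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("Ga", "Gb")))
  phen <- lapply(1:4, function(r) {
    data.frame(smoking = rbinom(n, 1, 0.3),
               Q1 = if (r <= 2) scores[, "Ga"] else rep(0, n))
  })
  sr2 <- screen_replicates(scores, phen, "Q1", retention_threshold = 2L)
  expect_equal(unname(sr2$counts["Ga"]), 2)
  expect_false(sr2$retained[["Ga"]])   # count == threshold -> NOT retained
  sr1 <- screen_replicates(scores, phen, "Q1", retention_threshold = 1L)
  expect_true(sr1$retained[["Ga"]])    # strictly greater passes
  expect_identical(sr1$retained_genes, "Ga")
  expect_true(all(sr1$retained == (sr1$counts > sr1$retention_threshold)))
})

test_that("screen on the simulated replicate set finds the causal genes", {
  sr <- screen_replicates(tiny_scores, tiny_rs, "Q1")
  causal <- tiny_rs$truth$causal_genes$Q1
  expect_gte(length(intersect(sr$retained_genes, causal)), 3L)
})

test_that("retained sets shrink when the rule tightens", {
  sr <- screen_replicates(tiny_scores, tiny_rs, "Q1")
  tighter_p <- screen_replicates(tiny_scores, tiny_rs, "Q1",
                                 p_cutoff = 0.01)
  expect_true(all(tighter_p$retained_genes %in% sr$retained_genes))
  tighter_t <- screen_replicates(tiny_scores, tiny_rs, "Q1",
                                 retention_threshold = 3L)
  expect_true(all(tighter_t$retained_genes %in% sr$retained_genes))
})

test_that("bootstrap screen is seed-deterministic and finds strong genes", {
  sb <- screen_bootstrap(tiny_scores, tiny_rs, "Q1", n_bootstrap = 60L,
                         seed = 35L)
  sb2 <- screen_bootstrap(tiny_scores, tiny_rs, "Q1", n_bootstrap = 60L,
                          seed = 35L)
  expect_identical(sb$retained_genes, sb2$retained_genes)
  expect_identical(sb$p, sb2$p)
  sr <- screen_replicates(tiny_scores, tiny_rs, "Q1")
  causal <- tiny_rs$truth$causal_genes$Q1
  expect_gte(length(intersect(sb$retained_genes, causal)), 3L)
  # overlap statistic between the two modes is a valid Jaccard index
  ov <- set_overlap(sb$retained_genes, sr$retained_genes)
  expect_gte(ov, 0)
  expect_lte(ov, 1)
})

test_that("union over responses is a plain set union", {
  expect_identical(union_retained(list(c("a"), c("b"), c("c"), c("d"))),
                   c("a", "b", "c", "d"))
  expect_identical(union_retained(list(c("a", "b"), c("a", "b"))),
                   c("a", "b"))
  # commutative and associative
  x <- list(c("a", "b"), c("b", "c"), c("d"))
  expect_identical(union_retained(x), union_retained(rev(x)))
  expect_identical(union_retained(list(union_retained(x[1:2]), x[[3]])),
                   union_retained(x))
})

test_that("expected null retention count matches n_replicates * cutoff", {
  # many null genes, few replicates: mean count ~ R * 0.1
  set.seed(36)
  n <- 100; m <- 300; R <- 10
  scores <- matrix(rnorm(n * m), n, m,
                   dimnames = list(NULL, sprintf("g%03d", 1:m)))
  phen <- lapply(1:R, function(r) {
    data.frame(smoking = rbinom(n, 1, 0.3), Q1 = rnorm(n))
  })
  sr <- screen_replicates(scores, phen, "Q1", retention_threshold = 5L)
  expected <- R * 0.1
  se <- sqrt(R * 0.1 * 0.9 / m)
  expect_lt(abs(mean(sr$counts) - expected), 3 * se)
  expect_equal(length(sr$retained_genes), 0L)
})
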