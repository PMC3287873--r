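test_that("rank-statistic AUC matches pROC and is transform-invariant", {
  skip_if_not_installed("pROC")
  set.seed(71)
  score <- c(rnorm(60), rnorm(40, 1))
  label <- c(rep(0, 60), rep(1, 40))
  expect_equal(auc_mw(score, label),
               as.numeric(pROC::auc(label, score, quiet = TRUE)),
               tolerance = 1e-12)
  # ties handled by midranks
  tied <- round(score)
  expect_equal(auc_mw(tied, label),
               as.numeric(pROC::auc(label, tied, quiet = TRUE)),
               tolerance = 1e-12)
  # invariant under strictly increasing transforms
  expect_equal(auc_mw(exp(score), label), auc_mw(score, label))
  expect_equal(auc_mw(rank(score), label), auc_mw(score, label))
  # constant score is uninformative
  expect_equal(auc_mw(rep(1, 100), label), 0.5)
  expect_true(is.na(auc_mw(score, rep(1, 100))))
})

test_that("feature selection keeps genes wired into quantitative traits only", {
  nodes <- c("smoking", "sex", "age", "Q1", "Q2", "Q4", "affected",
             "geneA", "geneB", "geneC")
  dag <- make_amat(nodes, data.frame(
    from = c("geneA", "geneB", "geneC", "Q1"),
    to = c("Q1", "Q2", "affected", "affected")))
  fs <- select_features(dag)
  expect_setequal(fs$genes, c("geneA", "geneB"))  # geneC -> disease excluded
  expect_setequal(fs$env, c("smoking", "sex", "age"))
  expect_length(fs$traits, 0)
  fs2 <- select_features(dag, include_env = FALSE, include_traits = FALSE)
  expect_setequal(unlist(fs2), c("geneA", "geneB"))
  fs3 <- select_features(dag, include_traits = TRUE)
  expect_setequal(fs3$traits, c("Q1", "Q2", "Q4"))
  # no QTL genes and no other class -> empty feature set error
  dag0 <- make_amat(nodes)
  expect_error(select_features(dag0, include_env = FALSE), "empty")
  # but environment alone is a valid set
  fs4 <- select_features(dag0, include_env = TRUE)
  expect_setequal(unlist(fs4), c("smoking", "sex", "age"))
})

test_that("a separable problem trains to AUC 1 and training is deterministic", {
  set.seed(72)
  x <- cbind(s = c(rnorm(50, -2), rnorm(50, 2)))
  y <- rep(c(0L, 1L), each = 50)
  fit <- train_predictor(x, y, "svm", seed = 73L)
  expect_equal(auc_mw(predict(fit, x), y), 1)
  fit2 <- train_predictor(x, y, "svm", seed = 73L)
  expect_identical(predict(fit, x), predict(fit2, x))
  expect_error(train_predictor(x, rep(1L, 100)), "single class")
  # lasso route works too
  fitl <- train_predictor(x, y, "lasso_logistic", seed = 74L)
  expect_gt(auc_mw(predict(fitl, x), y), 0.99)
})

test_that("permuted labels give chance-level held-out AUC", {
  set.seed(75)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(n, 1, 0.4)
  tr <- 1:200; te <- 201:400
  aucs <- sapply(1:20, function(i) {
    yp <- sample(y)
    fit <- train_predictor(x[tr, ], yp[tr], "svm", seed = i)
    auc_mw(predict(fit, x[te, ]), yp[te])
  })
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
})

test_that("evaluation reports per-replicate AUCs with exact summaries", {
  ph <- tiny_rs$phenotypes
  fs <- structure(list(genes = character(0),
                       env = c("smoking", "sex", "age"),
                       traits = c("Q1", "Q2", "Q4")),
                  class = "feature_set")
  xm <- feature_mat <- rarebn:::feature_matrix(fs, ph[[1]], tiny_scores)
  fit <- train_predictor(xm, ph[[1]]$affected, "svm", seed = 76L)
  rep_ <- evaluate_predictor(fit, fs, ph[2:4], tiny_scores)
  expect_equal(nrow(rep_$auc), 3L)
  ok <- rep_$auc$auc[!is.na(rep_$auc$auc)]
  expect_equal(rep_$mean, mean(ok))
  # SD matches an independent two-pass computation
  two_pass <- sqrt(sum((ok - mean(ok))^2) / (length(ok) - 1))
  expect_equal(rep_$sd, two_pass, tolerance = 1e-12)
  # the latent liability is an oracle upper bound on the same replicates
  for (r in 2:4) {
    oracle <- auc_mw(attr(ph[[r]], "liability"), ph[[r]]$affected)
    expect_gte(oracle + 0.02, rep_$auc$auc[r - 1])
    expect_gt(oracle, 0.8)
  }
})

test_that("single-class replicates are skipped with a warning", {
  ph <- tiny_rs$phenotypes
  fs <- structure(list(genes = character(0), env = "smoking",
                       traits = "Q1"), class = "feature_set")
  xm <- rarebn:::feature_matrix(fs, ph[[1]], tiny_scores)
  fit <- train_predictor(xm, ph[[1]]$affected, "svm", seed = 77L)
  bad <- ph[[2]]
  bad$affected <- 1L
  expect_warning(rep_ <- evaluate_predictor(fit, fs, list(bad, ph[[3]]),
                                            tiny_scores), "skipped")
  expect_equal(rep_$skipped, 1L)
  expect_equal(rep_$n_evaluated, 1L)
})

test_that("rankings separate causal from null genes on a strong-signal set", {
  cfg <- sim_config(n_individuals = 500L, n_genes = 10L,
                    causal_genes = list(Q1 = c("G001", "G002"),
                                        Q2 = character(), Q4 = character()),
                    effect_size = 1, n_replicates = 4L,
                    calibration_n = 3000L, seed = 78L)
  rs <- sim_replicates(cfg)
  sc <- burden_matrix(rs$genotypes, rs$variants, "all")
  pooled_ph <- do.call(rbind, rs$phenotypes)
  pooled_sc <- do.call(rbind, rep(list(sc), 4))
  rk <- lasso_gene_ranking(pooled_sc, pooled_ph, seed = 79L)
  expect_equal(gene_ranking_auc(rk, c("G001", "G002")), 1)
  # and the confidence-based ranking on the same data
  cons <- consensus_network(rs, sc, iterations = 4000L, master_seed = 80L)
  rn <- rank_genes_by_confidence(cons, colnames(sc))
  expect_gte(gene_ranking_auc(rn, c("G001", "G002")), 0.9)
})
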