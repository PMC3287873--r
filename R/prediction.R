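#' Network-guided disease risk prediction and the annotation-stratified
#' experiment grid.
#'
#' Predictors are selected from the consensus network: the QTL genes (gene
#' nodes with a retained edge into a quantitative trait), optionally the
#' environmental variables (smoking, sex, age) and optionally the observed
#' quantitative traits.  A support vector machine (or an L1-penalized
#' logistic comparator) is trained on the training replicates and scored by
#' AUC on each held-out replicate.
#'
#' @name prediction
NULL

#' Rank-statistic AUC (Mann-Whitney form, ties averaged)
#'
#' @param score numeric decision scores.
#' @param label 0/1 outcome.
#' @return AUC in [0, 1]; NA when only one class is present.
#' @export
auc_mw <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1L)
  n0 <- sum(label == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select predictor features from a consensus network
#'
#' QTL genes are the gene-role nodes with at least one retained directed
#' edge into a quantitative trait node (the disease node does not count).
#' Environment (smoking, sex, age) and observed-trait (Q1, Q2, Q4) classes
#' are toggled by flags.
#'
#' @param dag consensus adjacency matrix (or a "consensus_network").
#' @param roles named role vector for the DAG's nodes; inferred from node
#'   names when NULL (Q1/Q2/Q4 traits, affected disease, age/sex/smoking
#'   environment, the rest genes).
#' @param include_env include smoking, sex, age.
#' @param include_traits include Q1, Q2, Q4.
#' @return object of class "feature_set": list(genes, env, traits); errors
#'   when every class is empty.
#' @export
select_features <- function(dag, roles = NULL, include_env = TRUE,
                            include_traits = FALSE) {
  if (inherits(dag, "consensus_network")) dag <- dag$dag
  nodes <- rownames(dag)
  if (is.null(roles)) {
    roles <- setNames(rep("gene", length(nodes)), nodes)
    roles[nodes %in% c("Q1", "Q2", "Q4")] <- "trait"
    roles[nodes == "affected"] <- "disease"
    roles[nodes %in% c("age", "sex", "smoking")] <- "environment"
  }
  traits <- nodes[roles[nodes] == "trait"]
  genes <- nodes[roles[nodes] == "gene"]
  qtl <- genes[vapply(genes, function(g) any(dag[g, traits]), logical(1))]
  fs <- list(genes = qtl,
             env = if (include_env) intersect(c("smoking", "sex", "age"),
                                              nodes) else character(0),
             traits = if (include_traits) traits else character(0))
  if (!length(unlist(fs))) stop("empty feature set")
  structure(fs, class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set: %d QTL gene(s)%s%s\n", length(x$genes),
              if (length(x$env)) " + environment" else "",
              if (length(x$traits)) " + traits" else ""))
  if (length(x$genes)) cat("  genes:", paste(x$genes, collapse = " "), "\n")
  invisible(x)
}

# feature matrix for a phenotype table + score matrix
feature_matrix <- function(features, phenotype, scores) {
  cols <- list()
  if (length(features$genes)) {
    cols$genes <- as.matrix(scores[, features$genes, drop = FALSE])
  }
  if (length(features$env)) {
    cols$env <- as.matrix(phenotype[, features$env, drop = FALSE])
  }
  if (length(features$traits)) {
    cols$traits <- as.matrix(phenotype[, features$traits, drop = FALSE])
  }
  do.call(cbind, cols)
}

#' Train the disease risk predictor
#'
#' Features are standardized (train-set mean/SD); the SVM is a radial-basis
#' C-classification machine returning decision values (optionally grid-tuned
#' by cross-validation), the comparator an L1-penalized logistic regression
#' with the penalty chosen by internal cross-validation.
#'
#' @param x feature matrix (rows = individuals).
#' @param y 0/1 disease outcome; needs both classes.
#' @param model "svm" or "lasso_logistic".
#' @param tune if TRUE, small grid cross-validation of the SVM cost/gamma.
#' @param kernel SVM kernel (default "radial").
#' @param seed integer seed; training is deterministic given it.
#' @return object of class "risk_model".
#' @export
train_predictor <- function(x, y, model = c("svm", "lasso_logistic"),
                            tune = FALSE, kernel = "radial", seed = 1L) {
  model <- match.arg(model)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- with_seed(seed, {
    if (model == "svm") {
      if (tune) {
        tuned <- e1071::tune.svm(xs, factor(y), kernel = kernel,
                                 cost = c(0.1, 1, 10),
                                 gamma = c(0.5, 1, 2) / ncol(xs))
        tuned$best.model
      } else {
        e1071::svm(xs, factor(y), kernel = kernel)
      }
    } else {
      # glmnet requires >= 2 columns; pad single-feature designs with zeros
      if (ncol(xs) < 2) xs <- cbind(xs, `..pad` = 0)
      glmnet::cv.glmnet(xs, y, family = "binomial", nfolds = 5)
    }
  })
  structure(list(model = model, fit = fit, center = ctr, scale = scl,
                 feature_names = colnames(x)),
            class = "risk_model")
}

#' Decision scores from a fitted risk model
#'
#' @param object a "risk_model".
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return numeric decision-score vector (higher = more at risk).
#' @export
predict.risk_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  if (object$model == "svm") {
    dv <- attr(predict(object$fit, xs, decision.values = TRUE),
               "decision.values")
    s <- drop(dv)
    # orient decision values so larger means class "1"
    if (grepl("^0/1$", colnames(dv)[1])) s <- -s
    s
  } else {
    if (ncol(xs) < 2) xs <- cbind(xs, `..pad` = 0)
    drop(predict(object$fit, xs, s = "lambda.min", type = "link"))
  }
}

#' Evaluate a predictor over held-out replicates
#'
#' @param model a "risk_model".
#' @param features a "feature_set".
#' @param phenotypes list of held-out phenotype tables.
#' @param scores score matrix on the shared individuals.
#' @return object of class "prediction_report": per-replicate AUC table,
#'   mean and SD; single-class replicates are skipped with a warning and
#'   noted.
#' @export
evaluate_predictor <- function(model, features, phenotypes, scores) {
  aucs <- rep(NA_real_, length(phenotypes))
  for (r in seq_along(phenotypes)) {
    ph <- phenotypes[[r]]
    if (length(unique(ph$affected)) < 2L) next
    x <- feature_matrix(features, ph, scores)
    aucs[r] <- auc_mw(predict(model, x), ph$affected)
  }
  skipped <- which(is.na(aucs))
  if (length(skipped)) {
    warning(sprintf("skipped %d single-class replicate(s)", length(skipped)))
  }
  ok <- aucs[!is.na(aucs)]
  structure(list(auc = data.frame(replicate = seq_along(phenotypes),
                                  auc = aucs),
                 mean = mean(ok), sd = sd(ok), n_evaluated = length(ok),
                 skipped = skipped, model = model$model,
                 features = features),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Risk prediction (%s): mean AUC %.3f +/- %.3f over %d replicate(s)\n",
              x$model, x$mean, x$sd, x$n_evaluated))
  invisible(x)
}

#' LASSO marginal gene ranking (comparator)
#'
#' Per quantitative trait, an L1-penalized linear model of the trait on all
#' gene scores plus smoking (penalty by 5-fold cross-validation); a gene's
#' rank score is its largest absolute standardized coefficient across
#' traits.
#'
#' @param scores score matrix.
#' @param phenotype one phenotype table (or pooled rows).
#' @param traits trait columns to scan.
#' @param seed integer seed for the CV folds.
#' @return named numeric rank-score vector over genes.
#' @export
lasso_gene_ranking <- function(scores, phenotype,
                               traits = c("Q1", "Q2", "Q4"), seed = 1L) {
  x <- cbind(as.matrix(scores), smoking = phenotype$smoking)
  genes <- colnames(scores)
  with_seed(seed, {
    out <- setNames(rep(0, length(genes)), genes)
    for (tr in traits) {
      cv <- glmnet::cv.glmnet(x, phenotype[[tr]], nfolds = 5)
      b <- coef(cv, s = "lambda.min")[genes, 1]
      b <- abs(b) * apply(scores, 2, sd)
      out <- pmax(out, b)
    }
    out
  })
}

#' AUC of a gene ranking against the true causal genes
#'
#' @param rank_scores named numeric vector over genes (higher = more
#'   causal-looking).
#' @param causal_genes character vector of true causal genes.
#' @return Mann-Whitney AUC of the ranking.
#' @export
gene_ranking_auc <- function(rank_scores, causal_genes) {
  auc_mw(rank_scores, as.integer(names(rank_scores) %in% causal_genes))
}

#' Annotation- and feature-stratified prediction experiment
#'
#' The full experiment grid: replicates are split (seeded) into training and
#' held-out halves; for each annotation class the burden scores are rebuilt,
#' the screen and the replicate-consensus network are rerun on the training
#' half only, features are selected from that network, a predictor is
#' trained on the pooled training rows (subsampled to `max_train_rows`) and
#' evaluated per held-out replicate for each feature combination (genes;
#' genes + environment; genes + environment + traits).  When a network
#' yields no QTL genes, gene-only prediction degenerates to a constant
#' score, reported as AUC 0.5.
#'
#' @param replicates a "replicate_set".
#' @param annotations annotation classes to compare.
#' @param model "svm" or "lasso_logistic".
#' @param p_cutoff,retention_threshold screening rule (threshold defaults to
#'   half the training replicates).
#' @param responses screening responses whose retained sets are unioned.
#' @param cutoff consensus cutoff (NULL = scaled default).
#' @param iterations MCMC iterations per replicate network.
#' @param split_seed seed of the train/test partition (and downstream
#'   stages).
#' @param train_fraction fraction of replicates used for training.
#' @param max_train_rows cap on pooled training rows fed to the predictor.
#' @param tune passed to [train_predictor()].
#' @return object of class "annotation_experiment": AUC mean/SD matrix
#'   (annotation x feature set), the per-cell "prediction_report"s, the
#'   consensus networks and the train/test split.
#' @export
run_annotation_experiment <- function(replicates,
                                      annotations = c("nonsynonymous",
                                                      "synonymous"),
                                      model = "svm", p_cutoff = 0.1,
                                      retention_threshold = NULL,
                                      responses = c("Q1", "Q2", "Q4",
                                                    "affected"),
                                      cutoff = NULL, iterations = 6000L,
                                      split_seed = 1L, train_fraction = 0.5,
                                      max_train_rows = 1000L, tune = FALSE) {
  stopifnot(inherits(replicates, "replicate_set"))
  R <- length(replicates$phenotypes)
  train_idx <- with_seed(derive_seed(split_seed, "split"),
                         sort(sample.int(R, round(train_fraction * R))))
  test_idx <- setdiff(seq_len(R), train_idx)
  feature_grid <- list(
    "genes" = c(env = FALSE, traits = FALSE),
    "genes+env" = c(env = TRUE, traits = FALSE),
    "genes+env+traits" = c(env = TRUE, traits = TRUE))
  reports <- list()
  networks <- list()
  for (ann in annotations) {
    scores <- burden_matrix(replicates$genotypes, replicates$variants,
                            annotation = ann)
    screens <- lapply(responses, function(rv) {
      screen_replicates(scores, replicates$phenotypes[train_idx], rv,
                        p_cutoff = p_cutoff,
                        retention_threshold = retention_threshold)
    })
    selected <- union_retained(screens)
    cons <- NULL
    if (length(selected)) {
      cons <- consensus_network(replicates, scores, selected,
                                cutoff = cutoff, iterations = iterations,
                                master_seed = derive_seed(split_seed, "mcmc",
                                                          match(ann, annotations)),
                                replicate_idx = train_idx)
    }
    networks[[ann]] <- cons
    train_ph <- do.call(rbind, replicates$phenotypes[train_idx])
    train_scores <- do.call(rbind, rep(list(scores), length(train_idx)))
    keep <- with_seed(derive_seed(split_seed, "train"),
                      sample.int(nrow(train_ph),
                                 min(max_train_rows, nrow(train_ph))))
    for (fs_name in names(feature_grid)) {
      fg <- feature_grid[[fs_name]]
      key <- paste(ann, fs_name, sep = ".")
      feats <- tryCatch(
        select_features(if (is.null(cons)) {
          make_amat(c("smoking", "sex", "age", "Q1", "Q2", "Q4", "affected"))
        } else {
          cons$dag
        }, include_env = fg[["env"]], include_traits = fg[["traits"]]),
        error = function(e) NULL)
      if (is.null(feats)) {
        # no features at all (no QTL genes, env/traits excluded):
        # constant predictor, AUC 1/2 by construction
        reports[[key]] <- structure(
          list(auc = data.frame(replicate = test_idx,
                                auc = rep(0.5, length(test_idx))),
               mean = 0.5, sd = 0, n_evaluated = length(test_idx),
               skipped = integer(0), model = "constant",
               features = NULL), class = "prediction_report")
        next
      }
      xm <- feature_matrix(feats, train_ph, train_scores)
      fit <- train_predictor(xm[keep, , drop = FALSE],
                             train_ph$affected[keep], model = model,
                             tune = tune,
                             seed = derive_seed(split_seed, "train",
                                                match(ann, annotations)))
      reports[[key]] <- suppressWarnings(
        evaluate_predictor(fit, feats, replicates$phenotypes[test_idx],
                           scores))
    }
  }
  auc_mean <- matrix(NA_real_, length(annotations), length(feature_grid),
                     dimnames = list(annotations, names(feature_grid)))
  auc_sd <- auc_mean
  for (ann in annotations) for (fs_name in names(feature_grid)) {
    rep_ <- reports[[paste(ann, fs_name, sep = ".")]]
    auc_mean[ann, fs_name] <- rep_$mean
    auc_sd[ann, fs_name] <- rep_$sd
  }
  structure(list(auc_mean = auc_mean, auc_sd = auc_sd, reports = reports,
                 networks = networks, train_idx = train_idx,
                 test_idx = test_idx, model = model),
            class = "annotation_experiment")
}

#' @export
print.annotation_experiment <- function(x, ...) {
  cat("Annotation-stratified risk prediction (mean held-out AUC)\n")
  print(round(x$auc_mean, 3))
  invisible(x)
}

#' Network-vs-LASSO gene ranking comparison
#'
#' Ranks genes two ways on the same replicate set - by maximum gene-to-trait
#' consensus confidence and by the LASSO marginal comparator on the pooled
#' sample - and scores both against the true causal genes.
#'
#' @param replicates a "replicate_set" (must carry ground truth).
#' @param annotation score annotation (default combined is approximated by
#'   "all").
#' @param cutoff,iterations,master_seed consensus parameters.
#' @return list(auc_network, auc_lasso, ranks_network, ranks_lasso).
#' @export
compare_gene_rankings <- function(replicates, annotation = "all",
                                  cutoff = NULL, iterations = 6000L,
                                  master_seed = 1L) {
  stopifnot(inherits(replicates, "replicate_set"))
  scores <- burden_matrix(replicates$genotypes, replicates$variants,
                          annotation = annotation)
  causal <- unique(unlist(replicates$truth$causal_genes))
  cons <- consensus_network(replicates, scores, cutoff = cutoff,
                            iterations = iterations,
                            master_seed = master_seed)
  rn <- rank_genes_by_confidence(cons, colnames(scores))
  pooled_ph <- do.call(rbind, replicates$phenotypes)
  pooled_sc <- do.call(rbind, rep(list(scores),
                                  length(replicates$phenotypes)))
  rl <- lasso_gene_ranking(pooled_sc, pooled_ph,
                           seed = derive_seed(master_seed, "lasso"))
  list(auc_network = gene_ranking_auc(rn, causal),
       auc_lasso = gene_ranking_auc(rl, causal),
       ranks_network = rn, ranks_lasso = rl)
}
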