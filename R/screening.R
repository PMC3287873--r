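#' Gene screening: per-replicate marginal regressions, cross-replicate
#' retention, the bootstrap alternative and the union over responses.
#'
#' Each gene is tested, replicate by replicate, in a two-regressor model
#' (gene burden score + smoking status): ordinary least squares for the
#' quantitative traits, logistic regression for the binary disease outcome.
#' A gene is retained for a response when its p-value beats the cutoff
#' (default 0.1) in strictly more than `retention_threshold` replicates
#' (the "greater than 100 of 200" rule, read strictly).  No multiple-testing
#' correction is applied inside the screen: the raw cutoff plus
#' cross-replicate stability is the error control.
#'
#' @name screening
NULL

#' Marginal regression of a response on one gene score plus smoking
#'
#' Continuous responses use OLS; binary responses use logistic regression
#' with a Wald test, falling back to a linear-probability OLS fit (flagged)
#' when the logistic fit separates.  A constant gene score yields p = 1 with
#' the degenerate flag set.
#'
#' @param gene_score per-individual burden score.
#' @param smoking 0/1 covariate.
#' @param response response vector.
#' @param kind "continuous" or "binary".
#' @return list(p, degenerate, fallback).
#' @export
marginal_regression <- function(gene_score, smoking, response,
                                kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  stopifnot(length(gene_score) == length(response),
            length(smoking) == length(response))
  if (sd(gene_score) < 1e-12) {
    return(list(p = 1, degenerate = TRUE, fallback = FALSE))
  }
  if (kind == "continuous") {
    p <- ols_gene_p(cbind(gene_score), smoking, response)
    return(list(p = unname(p), degenerate = is.na(p) && FALSE,
                fallback = FALSE))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(response ~ gene_score + smoking, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (separated) {
    p <- ols_gene_p(cbind(gene_score), smoking, response)
    return(list(p = unname(p), degenerate = FALSE, fallback = TRUE))
  }
  ct <- summary(fit)$coefficients
  if (!"gene_score" %in% rownames(ct)) {
    return(list(p = 1, degenerate = TRUE, fallback = FALSE))
  }
  list(p = unname(ct["gene_score", 4]), degenerate = FALSE, fallback = FALSE)
}

# OLS p-values of the score coefficient for many genes at once, via the
# partial-correlation identity: residualize response and each score column on
# (1, smoking), then t = r * sqrt(df / (1 - r^2)) with df = n - 3.  Identical
# to the per-gene lm() Wald p-value.
ols_gene_p <- function(scores, smoking, y) {
  n <- length(y)
  Z <- cbind(1, smoking)
  qz <- qr(Z)
  ey <- qr.resid(qz, y)
  es <- qr.resid(qz, scores)
  ssy <- sum(ey^2)
  sss <- colSums(es^2)
  df <- n - qz$rank - 1  # intercept + smoking (when not constant) + gene
  r <- colSums(es * ey) / sqrt(sss * ssy)
  p <- 2 * pt(-abs(r * sqrt(df / (1 - r^2))), df)
  p[!is.finite(p)] <- 1
  p[sss < 1e-12 * n] <- 1  # constant (or smoking-collinear) score
  p
}

#' Marginal p-values for every gene of a score matrix
#'
#' Vectorized screen of all gene columns against one response: the OLS path
#' residualizes once and tests every gene in a single pass; the logistic
#' path loops [marginal_regression()] over genes.
#'
#' @param scores individuals x genes score matrix.
#' @param smoking 0/1 covariate.
#' @param response response vector.
#' @param kind "continuous" or "binary".
#' @return named p-value vector (degenerate genes get p = 1).
#' @export
marginal_scan <- function(scores, smoking, response,
                          kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  scores <- as.matrix(scores)
  if (kind == "continuous") {
    p <- ols_gene_p(scores, smoking, response)
  } else {
    p <- vapply(seq_len(ncol(scores)), function(j) {
      marginal_regression(scores[, j], smoking, response, "binary")$p
    }, numeric(1))
  }
  setNames(p, colnames(scores))
}

response_kind <- function(response) {
  if (response == "affected") "binary" else "continuous"
}

new_screen_result <- function(pmat, response, p_cutoff, retention_threshold,
                              mode) {
  counts <- rowSums(pmat < p_cutoff)
  retained <- counts > retention_threshold
  structure(list(response = response, p = pmat, counts = counts,
                 retained = retained,
                 retained_genes = names(retained)[retained],
                 p_cutoff = p_cutoff,
                 retention_threshold = retention_threshold,
                 n_replicates = ncol(pmat), mode = mode),
            class = "screen_result")
}

#' Screen genes across phenotype replicates
#'
#' Applies [marginal_scan()] replicate by replicate and retains the genes
#' whose p-value beats `p_cutoff` in strictly more than
#' `retention_threshold` replicates.
#'
#' @param scores score matrix shared by all replicates (genotypes are fixed
#'   across replicates), or a list of per-replicate matrices.
#' @param phenotypes list of phenotype tables (one per replicate), or a
#'   "replicate_set".
#' @param response response column name ("Q1", "Q2", "Q4" or "affected").
#' @param p_cutoff per-replicate p-value cutoff (default 0.1).
#' @param retention_threshold strict lower bound on the retention count;
#'   default half the replicates (the 100-of-200 rule scaled).
#' @return object of class "screen_result": p-value matrix (genes x
#'   replicates), retention counts, retained gene set and the rule
#'   parameters.
#' @export
screen_replicates <- function(scores, phenotypes, response,
                              p_cutoff = 0.1, retention_threshold = NULL) {
  if (inherits(phenotypes, "replicate_set")) {
    phenotypes <- phenotypes$phenotypes
  }
  R <- length(phenotypes)
  if (is.null(retention_threshold)) retention_threshold <- floor(R / 2)
  stopifnot(retention_threshold < R)
  kind <- response_kind(response)
  score_r <- function(r) if (is.list(scores)) scores[[r]] else scores
  pmat <- vapply(seq_len(R), function(r) {
    ph <- phenotypes[[r]]
    marginal_scan(score_r(r), ph$smoking, ph[[response]], kind)
  }, numeric(ncol(score_r(1))))
  rownames(pmat) <- colnames(score_r(1))
  new_screen_result(pmat, response, p_cutoff, retention_threshold,
                    "replicates")
}

#' Bootstrap variant of the replicate screen
#'
#' For real data without replicates: the replicate tables are pooled into
#' one combined sample, `n_bootstrap` resamples of the pooled rows (with
#' replacement, same size) are drawn, and each resample is screened as if it
#' were a replicate; the same strict retention rule is then applied.
#'
#' @param scores score matrix on the shared individuals.
#' @param phenotypes list of phenotype tables or a "replicate_set"; rows are
#'   pooled across replicates.
#' @param response response column name.
#' @param n_bootstrap number of bootstrap pseudo-replicates (default 200).
#' @param p_cutoff,retention_threshold as in [screen_replicates()]
#'   (threshold defaults to half of `n_bootstrap`).
#' @param seed integer seed; results are deterministic given it.
#' @return "screen_result" with mode "bootstrap".
#' @export
screen_bootstrap <- function(scores, phenotypes, response,
                             n_bootstrap = 200L, p_cutoff = 0.1,
                             retention_threshold = NULL, seed = 1L) {
  if (inherits(phenotypes, "replicate_set")) {
    phenotypes <- phenotypes$phenotypes
  }
  if (is.null(retention_threshold)) {
    retention_threshold <- floor(n_bootstrap / 2)
  }
  stopifnot(retention_threshold < n_bootstrap)
  kind <- response_kind(response)
  n <- nrow(scores)
  pooled_scores <- do.call(rbind, rep(list(as.matrix(scores)),
                                      length(phenotypes)))
  pooled_y <- unlist(lapply(phenotypes, `[[`, response), use.names = FALSE)
  pooled_smoke <- unlist(lapply(phenotypes, `[[`, "smoking"),
                         use.names = FALSE)
  N <- length(pooled_y)
  pmat <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(N, N, replace = TRUE)
      marginal_scan(pooled_scores[idx, , drop = FALSE], pooled_smoke[idx],
                    pooled_y[idx], kind)
    }, numeric(ncol(scores)))
  })
  rownames(pmat) <- colnames(scores)
  new_screen_result(pmat, response, p_cutoff, retention_threshold,
                    "bootstrap")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "Gene screen (%s) on '%s': %d genes x %d %s\n", x$mode, x$response,
    nrow(x$p), x$n_replicates,
    if (x$mode == "bootstrap") "bootstraps" else "replicates"))
  cat(sprintf("  rule: p < %g in more than %d; retained %d gene(s)\n",
              x$p_cutoff, x$retention_threshold, sum(x$retained)))
  if (sum(x$retained)) {
    cat("  ", paste(x$retained_genes, collapse = " "), "\n")
  }
  invisible(x)
}

#' Union of retained genes over response variables
#'
#' @param results list of "screen_result" objects (e.g. over Q1, Q2, Q4 and
#'   the disease outcome).
#' @return sorted character vector of gene ids.
#' @export
union_retained <- function(results) {
  stopifnot(length(results) >= 1)
  sets <- lapply(results, function(r) {
    if (inherits(r, "screen_result")) r$retained_genes else r
  })
  sort(unique(unlist(sets)))
}

#' Jaccard overlap of two gene sets
#'
#' |A intersect B| / |A union B|; reported when comparing the bootstrap and
#' replicate screens.
#'
#' @param a,b character vectors.
#' @return scalar in [0, 1] (1 when both sets are empty).
#' @export
set_overlap <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0L) return(1)
  length(intersect(a, b)) / length(u)
}
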