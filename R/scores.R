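#' Annotation-stratified weighted-sum burden scores and the data-estimated
#' nonsynonymous weight.
#'
#' The gene-level genetic variable is the weighted sum of minor-allele counts
#' over a gene's variants, each variant down-weighted by a function of its
#' minor allele frequency so rare variants contribute more.  Synonymous-only
#' (S) and nonsynonymous-only (NS) scores are combined as
#' `w * NS + (1 - w) * S`, with w estimated from the proportions of true
#' positive genes found with each annotation class.
#'
#' @name gene-scores
NULL

# per-variant weight; q is the MAF, n the sample size
maf_weight <- function(q, n, method = c("madsen_browning", "inverse_maf",
                                        "beta_sd")) {
  method <- match.arg(method)
  switch(method,
         madsen_browning = 1 / sqrt(n * q * (1 - q)),
         inverse_maf = 1 / q,
         beta_sd = 1 / sqrt(q * (1 - q)))
}

# MAF per variant column: estimated from the sample with a pseudo-count, or
# taken from the variant table
variant_maf <- function(genotypes, variants, maf_source) {
  if (maf_source == "table") {
    setNames(variants$maf, variants$variant_id)
  } else {
    n <- nrow(genotypes)
    q <- (colSums(genotypes) + 1) / (2 * n + 2)
    setNames(pmin(q, 1 - q), colnames(genotypes))
  }
}

#' Weighted-sum burden score for one gene
#'
#' score_i = sum_j weight(q_j) * g_ij over the gene's variants j passing the
#' annotation filter, with g_ij the minor-allele count.  The default weight
#' is the Madsen-Browning form 1 / sqrt(n * q_j * (1 - q_j)); alternatives
#' 1/q and 1/sqrt(q(1-q)) are available.  By default q_j is estimated from
#' the analysis sample with a 1/(2n + 2) pseudo-count; `maf_source = "table"`
#' uses the variant table's MAF column instead.
#'
#' @param genotypes individuals x variants matrix of minor-allele counts.
#' @param variants variant table (variant_id, gene_id, maf, annotation).
#' @param gene gene id to score.
#' @param annotation "all", "synonymous" or "nonsynonymous".
#' @param weight weighting scheme (see above).
#' @param maf_source "sample" (default) or "table".
#' @return numeric per-individual score vector; attribute "degenerate" is
#'   TRUE when no variant passes the filter (all-zero score), and attribute
#'   "n_variants" records how many did.
#' @examples
#' v <- data.frame(variant_id = "V1", gene_id = "G1", maf = 0.1,
#'                 annotation = "nonsynonymous")
#' g <- matrix(c(2L, rep(0L, 99)), 100, 1,
#'             dimnames = list(NULL, "V1"))
#' burden_score(g, v, "G1", maf_source = "table")[1]  # 2/sqrt(100*0.1*0.9)
#' @export
burden_score <- function(genotypes, variants, gene,
                         annotation = c("all", "synonymous", "nonsynonymous"),
                         weight = "madsen_browning",
                         maf_source = c("sample", "table")) {
  annotation <- match.arg(annotation)
  maf_source <- match.arg(maf_source)
  if (!gene %in% variants$gene_id) stop("unknown gene: ", gene)
  sel <- variants$gene_id == gene
  if (annotation != "all") sel <- sel & variants$annotation == annotation
  ids <- variants$variant_id[sel]
  n <- nrow(genotypes)
  if (length(ids) == 0L) {
    out <- rep(0, n)
    attr(out, "degenerate") <- TRUE
    attr(out, "n_variants") <- 0L
    return(out)
  }
  q <- variant_maf(genotypes, variants, maf_source)[ids]
  w <- maf_weight(q, n, weight)
  out <- drop(genotypes[, ids, drop = FALSE] %*% w)
  attr(out, "degenerate") <- FALSE
  attr(out, "n_variants") <- length(ids)
  out
}

#' Burden scores for every gene
#'
#' Column g equals [burden_score()] for gene g; columns follow sorted gene
#' ids.
#'
#' @inheritParams burden_score
#' @return numeric matrix individuals x genes with attributes "score_kind"
#'   (the annotation filter), "n_variants" (per gene) and "degenerate"
#'   (logical per gene).
#' @export
burden_matrix <- function(genotypes, variants,
                          annotation = c("all", "synonymous",
                                         "nonsynonymous"),
                          weight = "madsen_browning",
                          maf_source = c("sample", "table")) {
  annotation <- match.arg(annotation)
  maf_source <- match.arg(maf_source)
  genes <- sort(unique(variants$gene_id))
  cols <- lapply(genes, function(g) {
    burden_score(genotypes, variants, g, annotation, weight, maf_source)
  })
  m <- do.call(cbind, lapply(cols, as.numeric))
  dimnames(m) <- list(rownames(genotypes), genes)
  attr(m, "score_kind") <- annotation
  attr(m, "n_variants") <- vapply(cols, attr, integer(1), "n_variants")
  attr(m, "degenerate") <- vapply(cols, attr, logical(1), "degenerate")
  m
}

#' Estimate the proportion of true-positive genes from p-values
#'
#' Two-group mixture view of per-gene association p-values: the folded
#' z-score |z| = qnorm(1 - p/2) follows a half-standard-normal for null
#' genes and is inflated for true positives.  The default "central"
#' estimator matches the local-FDR recipe with a theoretical N(0,1) null:
#' the null proportion pi0 is the fraction of |z| inside the central window
#' [0, z0] divided by the null mass 2*Phi(z0) - 1 of that window; "storey"
#' uses pi0 = mean(p > lambda) / (1 - lambda).  Both are clipped to [0, 1]
#' and pi1 = 1 - pi0 returned.  The folded form keeps conservative tests
#' (common for sparse rare-variant scores) inside the null window instead
#' of misreading them as signal.
#'
#' @param p per-gene two-sided p-values in (0, 1]; at least 50 (a mixture
#'   fit on fewer is unreliable and refused).
#' @param method "central" (default) or "storey".
#' @param z0 central-window half-width (default 1).
#' @param lambda Storey tuning parameter (default 0.5).
#' @return list(pi1, pi0, method) of class "pi1_estimate".
#' @export
estimate_pi1 <- function(p, method = c("central", "storey"), z0 = 1,
                         lambda = 0.5) {
  method <- match.arg(method)
  if (length(p) < 50) {
    stop("need at least 50 p-values for a stable mixture fit")
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (diff(range(p)) < .Machine$double.eps) {
    stop("degenerate input: all p-values identical")
  }
  pi0 <- switch(method,
    central = {
      z <- qnorm(1 - p / 2)  # folded two-sided z, half-normal under null
      mean(z <= z0) / (2 * pnorm(z0) - 1)
    },
    storey = mean(p > lambda) / (1 - lambda))
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi1 = 1 - pi0, pi0 = pi0, method = method),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("pi1 = %.4f (pi0 = %.4f, %s estimator)\n",
              x$pi1, x$pi0, x$method))
  invisible(x)
}

#' Estimate the nonsynonymous weight from the two true-positive proportions
#'
#' With P_s and P_ns the proportions of true positive genes found with
#' synonymous-only and nonsynonymous-only scores, two estimators are
#' offered: `"as_printed"` returns P_s / (P_s + P_ns) and `"nonsyn_share"`
#' (the default) returns P_ns / (P_s + P_ns).  The nonsyn-share form makes
#' w large when the nonsynonymous class carries the signal, matching w's
#' role as the weight of nonsynonymous variants in the combined score; the
#' other form is retained verbatim.  The formula used is recorded in the
#' result.
#'
#' @param pi1_syn proportion of true positives from synonymous scores (P_s).
#' @param pi1_nonsyn same for nonsynonymous scores (P_ns).
#' @param formula "nonsyn_share" (default) or "as_printed".
#' @return list(w, P_s, P_ns, formula) of class "weight_estimate".
#' @export
estimate_weight <- function(pi1_syn, pi1_nonsyn,
                            formula = c("nonsyn_share", "as_printed")) {
  formula <- match.arg(formula)
  stopifnot(pi1_syn >= 0, pi1_syn <= 1, pi1_nonsyn >= 0, pi1_nonsyn <= 1)
  if (pi1_syn == 0 && pi1_nonsyn == 0) {
    stop("undefined weight: both true-positive proportions are zero ",
         "(a caller may fall back to w = 0.5)")
  }
  w <- switch(formula,
              as_printed = pi1_syn / (pi1_syn + pi1_nonsyn),
              nonsyn_share = pi1_nonsyn / (pi1_syn + pi1_nonsyn))
  structure(list(w = w, P_s = pi1_syn, P_ns = pi1_nonsyn, formula = formula),
            class = "weight_estimate")
}

#' @export
print.weight_estimate <- function(x, ...) {
  cat(sprintf("w = %.4f (%s; P_s = %.4f, P_ns = %.4f)\n",
              x$w, x$formula, x$P_s, x$P_ns))
  invisible(x)
}

#' Combine annotation-stratified score matrices
#'
#' Elementwise convex combination `w * NS + (1 - w) * S`.
#'
#' @param syn synonymous-only score matrix.
#' @param nonsyn nonsynonymous-only score matrix (same shape).
#' @param w weight of the nonsynonymous scores, in [0, 1]; a
#'   "weight_estimate" is also accepted.
#' @return combined matrix with attributes "score_kind" = "combined" and
#'   "w".
#' @export
combine_scores <- function(syn, nonsyn, w) {
  if (inherits(w, "weight_estimate")) w <- w$w
  stopifnot(is.numeric(w), length(w) == 1, w >= 0, w <= 1)
  if (!identical(dim(syn), dim(nonsyn))) {
    stop("synonymous and nonsynonymous matrices must have the same shape")
  }
  m <- w * unclass(nonsyn) + (1 - w) * unclass(syn)
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(syn))
  attr(m, "score_kind") <- "combined"
  attr(m, "w") <- w
  m
}

#' Estimate the annotation weight from data
#'
#' Convenience wrapper for the full weight pipeline on a replicate: computes
#' synonymous-only and nonsynonymous-only burden matrices, obtains per-gene
#' association p-values from the marginal screen against a response
#' (the disease phenotype by default), estimates P_s and P_ns via
#' [estimate_pi1()], and returns the [estimate_weight()] result with both
#' pi1 fits attached.
#'
#' @param genotypes,variants as in [burden_matrix()].
#' @param phenotypes one phenotype table.
#' @param response response column (default "affected").
#' @param pi1_method passed to [estimate_pi1()].
#' @param formula passed to [estimate_weight()].
#' @param ... further arguments for [burden_matrix()].
#' @return a "weight_estimate" with attribute "pi1" (list syn/nonsyn).
#' @export
estimate_weight_from_data <- function(genotypes, variants, phenotypes,
                                      response = "affected",
                                      pi1_method = "central",
                                      formula = "nonsyn_share", ...) {
  kind <- if (response == "affected") "binary" else "continuous"
  p_for <- function(ann) {
    m <- burden_matrix(genotypes, variants, annotation = ann, ...)
    marginal_scan(m, phenotypes$smoking, phenotypes[[response]], kind)
  }
  p_s <- p_for("synonymous")
  p_ns <- p_for("nonsynonymous")
  pi_s <- estimate_pi1(p_s, method = pi1_method)
  pi_ns <- estimate_pi1(p_ns, method = pi1_method)
  out <- estimate_weight(pi_s$pi1, pi_ns$pi1, formula = formula)
  attr(out, "pi1") <- list(synonymous = pi_s, nonsynonymous = pi_ns)
  out
}
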