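#' Replicate-consensus edge confidence and the thresholded final network.
#'
#' The confidence score of a directed edge is the number of replicate- (or
#' bootstrap-) learned networks containing it, count(e) = sum_i 1[e in G_i];
#' the final network keeps the edges whose count reaches an inclusive cutoff
#' ("at least five replicates" in the reference design).
#'
#' @name consensus
NULL

#' Count directed-edge occurrences across learned networks
#'
#' @param networks list of adjacency matrices or "bnet" fits over a shared
#'   node set.
#' @return object of class "edge_confidence": data.frame(from, to, count)
#'   over edges seen at least once, sorted by decreasing count; attributes
#'   "total" (number of networks) and "count_matrix".
#' @export
edge_confidence <- function(networks) {
  stopifnot(length(networks) >= 1)
  amats <- lapply(networks, function(x) if (inherits(x, "bnet")) x$dag else x)
  nodes <- rownames(amats[[1]])
  for (a in amats) {
    if (!identical(rownames(a), nodes) || !identical(colnames(a), nodes)) {
      stop("networks must share one node universe")
    }
  }
  cm <- Reduce(`+`, lapply(amats, function(a) a * 1L))
  idx <- which(cm > 0, arr.ind = TRUE)
  tab <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                    count = cm[idx], stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$from, tab$to), ]
  rownames(tab) <- NULL
  structure(tab, class = c("edge_confidence", "data.frame"),
            total = length(amats), count_matrix = cm)
}

#' Threshold an edge-confidence table into the final network
#'
#' Keeps every edge whose count is at least `cutoff` (inclusive).  If the
#' kept edges contain a directed cycle - possible after thresholding, and
#' also when an edge is retained in both orientations - the lowest-count
#' edge in each offending cycle is dropped (ties broken by lexicographic
#' (from, to) order, deterministically) and the conflict is flagged via the
#' "dropped_edges" attribute and a warning.
#'
#' @param confidence an "edge_confidence" table.
#' @param cutoff minimum count (default 5).
#' @return logical adjacency matrix of the final network, with attributes
#'   "counts" (the kept edges with counts) and "dropped_edges".
#' @export
threshold_network <- function(confidence, cutoff = 5L) {
  stopifnot(cutoff >= 1)
  cm <- attr(confidence, "count_matrix")
  nodes <- rownames(cm)
  amat <- cm >= cutoff
  diag(amat) <- FALSE
  dropped <- data.frame(from = character(0), to = character(0),
                        count = integer(0))
  while (!is_acyclic(amat)) {
    cyc <- find_cycle(amat)
    ed <- data.frame(from = cyc, to = c(cyc[-1], cyc[1]))
    ed$count <- cm[cbind(ed$from, ed$to)]
    ed <- ed[order(ed$count, ed$from, ed$to), ]
    amat[ed$from[1], ed$to[1]] <- FALSE
    dropped <- rbind(dropped, ed[1, ])
  }
  if (nrow(dropped)) {
    warning(sprintf("dropped %d low-count edge(s) to break cycles",
                    nrow(dropped)))
  }
  idx <- which(amat, arr.ind = TRUE)
  counts <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                       count = cm[idx], stringsAsFactors = FALSE)
  attr(amat, "counts") <- counts[order(-counts$count, counts$from), ]
  attr(amat, "dropped_edges") <- dropped
  attr(amat, "cutoff") <- cutoff
  amat
}

# one directed cycle of a cyclic graph, as an ordered node vector
find_cycle <- function(amat) {
  nodes <- rownames(amat)
  color <- setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  parent <- setNames(rep(NA_character_, length(nodes)), nodes)
  cycle <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    for (w in nodes[amat[v, ]]) {
      if (!is.null(cycle)) return()
      if (color[w] == 0L) {
        parent[w] <<- v
        visit(w)
      } else if (color[w] == 1L) {
        path <- v
        while (path[1] != w) path <- c(parent[path[1]], path)
        cycle <<- path
        return()
      }
    }
    color[v] <<- 2L
  }
  for (v in nodes) {
    if (color[v] == 0L && is.null(cycle)) visit(v)
  }
  cycle
}

#' Learn one network per replicate and aggregate into a consensus
#'
#' Builds the node data for each replicate (environment + traits + disease
#' phenotype columns joined with the selected genes' score columns; the
#' scores are shared since genotypes are fixed across replicates), learns a
#' constrained network per replicate with a per-replicate seed derived from
#' `master_seed`, counts edges and thresholds.
#'
#' @param replicates a "replicate_set".
#' @param scores score matrix (individuals x genes).
#' @param selected_genes genes to include as nodes (e.g. the screening
#'   union).
#' @param cutoff confidence cutoff; NULL uses ceiling(0.25 * n_replicates)
#'   with a floor of 2.  A null edge enters one replicate's sampled network
#'   with probability roughly exp(likelihood gain - BIC penalty), a few
#'   percent, so demanding support from a quarter of the replicates drives
#'   the expected false-edge count to near zero (binomial tail) while true
#'   moderate-effect edges appear in essentially every replicate; pass
#'   `cutoff = 5` for the literal at-least-five rule.
#' @param iterations,max_parents,score,... passed to [bn_learn()].
#' @param master_seed per-replicate seeds derive from it.
#' @param replicate_idx optional subset of replicates to use.
#' @return object of class "consensus_network": list(confidence, dag,
#'   networks, cutoff, truth_counts) where `truth_counts` gives the
#'   confidence count of each ground-truth edge when the replicate set
#'   carries truth.
#' @export
consensus_network <- function(replicates, scores, selected_genes = NULL,
                              cutoff = NULL, iterations = 8000L,
                              max_parents = 5L, score = "bic",
                              master_seed = 1L, replicate_idx = NULL, ...) {
  stopifnot(inherits(replicates, "replicate_set"))
  if (is.null(selected_genes)) selected_genes <- colnames(scores)
  if (is.null(replicate_idx)) {
    replicate_idx <- seq_along(replicates$phenotypes)
  }
  R <- length(replicate_idx)
  if (is.null(cutoff)) cutoff <- max(2L, ceiling(0.25 * R))
  nets <- lapply(seq_len(R), function(k) {
    r <- replicate_idx[k]
    d <- node_data(replicates$phenotypes[[r]], scores, selected_genes)
    bn_learn(d$data, roles = d$roles, iterations = iterations,
             max_parents = max_parents, score = score,
             seed = derive_seed(master_seed, "mcmc", r), ...)
  })
  conf <- edge_confidence(nets)
  dag <- threshold_network(conf, cutoff)
  truth_counts <- NULL
  if (!is.null(replicates$truth)) {
    te <- replicates$truth$edges
    te <- te[te$from %in% rownames(dag) & te$to %in% rownames(dag), ]
    if (nrow(te)) {
      cm <- attr(conf, "count_matrix")
      truth_counts <- te
      truth_counts$count <- cm[cbind(te$from, te$to)]
    }
  }
  structure(list(confidence = conf, dag = dag, networks = nets,
                 cutoff = cutoff, truth_counts = truth_counts,
                 selected_genes = selected_genes),
            class = "consensus_network")
}

# assemble the typed node data for one replicate
node_data <- function(phenotype, scores, selected_genes) {
  stopifnot(all(selected_genes %in% colnames(scores)))
  env <- c("age", "sex", "smoking")
  traits <- c("Q1", "Q2", "Q4")
  d <- cbind(phenotype[, c(env, traits, "affected")],
             as.data.frame(scores[, selected_genes, drop = FALSE]))
  roles <- setNames(c(rep("environment", 3), rep("trait", 3), "disease",
                      rep("gene", length(selected_genes))),
                    colnames(d))
  list(data = d, roles = roles)
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("Consensus network over %d replicate networks (cutoff %d)\n",
              attr(x$confidence, "total"), x$cutoff))
  cat(sprintf("  %d edge(s) above cutoff, %d distinct edge(s) observed\n",
              sum(x$dag), nrow(x$confidence)))
  invisible(x)
}

#' Rank genes by their maximum gene-to-trait confidence count
#'
#' The network-based gene ranking: a gene's rank score is the largest
#' confidence count among its outgoing edges into quantitative trait nodes.
#'
#' @param consensus a "consensus_network" (or "edge_confidence").
#' @param genes gene node names to rank.
#' @param traits trait node names (default Q1, Q2, Q4).
#' @return named numeric vector of rank scores (0 for genes never linked).
#' @export
rank_genes_by_confidence <- function(consensus, genes,
                                     traits = c("Q1", "Q2", "Q4")) {
  conf <- if (inherits(consensus, "consensus_network")) {
    consensus$confidence
  } else {
    consensus
  }
  cm <- attr(conf, "count_matrix")
  traits <- intersect(traits, colnames(cm))
  out <- setNames(rep(0, length(genes)), genes)
  for (g in intersect(genes, rownames(cm))) {
    out[g] <- max(cm[g, traits])
  }
  out
}
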