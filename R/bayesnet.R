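#' Linear-Gaussian node and network scores, and constrained DAG structure
#' learning by Metropolis-Hastings MCMC.
#'
#' Each node X with parents U1..UK carries a linear Gaussian conditional
#' density X | u ~ Normal(a0 + sum_k a_k u_k, sigma^2).  The node score is the
#' maximized Gaussian log-likelihood (sigma^2 estimated by ML, i.e. RSS/n),
#' optionally BIC-penalized by (K + 2)/2 * log(n) for the K coefficients,
#' intercept and residual SD.  The network score is the sum of node scores
#' (decomposable), so a single-edge move re-scores at most two nodes.
#'
#' @name bayesnet
NULL

SIGMA_FLOOR <- 1e-8

#' Score one node given a parent set (pure-R reference)
#'
#' Least-squares fit of the child on its parents plus intercept; residual
#' variance uses the ML normalization (divide by n), floored at 1e-16 for
#' degenerate exact fits.  Collinear parents fall back to a tiny-ridge solve
#' and flag the result.
#'
#' @param child numeric response vector.
#' @param parents numeric matrix of parent columns (NULL or 0-column for a
#'   root node).
#' @param score "bic" (default) or "loglik".
#' @return scalar score; attribute "ridged" is TRUE after a collinearity
#'   fallback.
#' @examples
#' x <- rnorm(50)
#' node_score(x, NULL, "loglik")  # closed form -n/2*(log(2*pi*s2)+1)
#' @export
node_score <- function(child, parents = NULL, score = c("bic", "loglik")) {
  score <- match.arg(score)
  n <- length(child)
  K <- if (is.null(parents)) 0L else ncol(as.matrix(parents))
  if (n < K + 2) stop("need at least K + 2 observations to score a node")
  ridged <- FALSE
  if (K == 0L) {
    rss <- sum((child - mean(child))^2)
  } else {
    X <- cbind(1, as.matrix(parents))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      ridged <- TRUE
      XtX <- crossprod(X) + diag(1e-8, ncol(X))
      beta <- solve(XtX, crossprod(X, child))
      rss <- sum((child - X %*% beta)^2)
    } else {
      rss <- sum(qr.resid(qx, child)^2)
    }
  }
  s2 <- max(rss / n, SIGMA_FLOOR^2)
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  out <- if (score == "bic") ll - (K + 2) / 2 * log(n) else ll
  attr(out, "ridged") <- ridged
  out
}

#' Score a whole network (pure-R reference)
#'
#' Sum of [node_score()] over nodes given their parent sets in `amat`.
#'
#' @param amat logical adjacency matrix over the columns of `data`.
#' @param data numeric matrix/data.frame; columns named as in `amat`.
#' @param score "bic" or "loglik".
#' @return scalar network score.
#' @export
network_score <- function(amat, data, score = c("bic", "loglik")) {
  score <- match.arg(score)
  data <- as.matrix(data)
  stopifnot(identical(colnames(data), rownames(amat)))
  tot <- 0
  for (v in colnames(data)) {
    pa <- rownames(amat)[amat[, v]]
    tot <- tot + as.numeric(node_score(
      data[, v], if (length(pa)) data[, pa, drop = FALSE] else NULL, score))
  }
  tot
}

# random constraint-satisfying initial DAG: visit every ordered pair in
# random order and include it with probability `density` when still legal
random_init_dag <- function(nodes, banned, max_parents, density = 0.1) {
  V <- length(nodes)
  amat <- make_amat(nodes)
  pairs <- expand.grid(u = seq_len(V), v = seq_len(V))
  pairs <- pairs[pairs$u != pairs$v, ]
  pairs <- pairs[sample.int(nrow(pairs)), ]
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$u[i]; v <- pairs$v[i]
    if (banned[u, v] || amat[u, v] || amat[v, u]) next
    if (sum(amat[, v]) >= max_parents) next
    if (runif(1) >= density) next
    if (u %in% reachable_from(amat, v)) next
    amat[u, v] <- TRUE
  }
  amat
}

# z-score columns; constant columns are centered only
standardize_columns <- function(data) {
  X <- as.matrix(data)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

#' Learn a constrained Bayesian network by Metropolis-Hastings MCMC
#'
#' Runs an add/delete/reverse Metropolis-Hastings chain over DAGs from a
#' random constraint-satisfying start, tracking the best-scoring structure
#' visited.  A proposal is drawn uniformly from the legal neighborhood and
#' accepted with probability min(1, exp(delta) * H), where delta is the
#' decomposable score change and H = |N(current)| / |N(proposed)| corrects
#' the neighborhood-size asymmetry so the chain's stationary distribution is
#' proportional to exp(score); `hastings = FALSE` gives the uncorrected
#' plain-Metropolis rule.  Columns are z-scored before scoring so BIC
#' comparisons are scale-free; reported parameters are refit on the original
#' scale.
#'
#' @param data data.frame or matrix of numeric columns (binary variables as
#'   0/1), one column per node.
#' @param roles named character vector over the columns of `data` with values
#'   "environment", "gene", "trait" or "disease"; used for the banned-edge
#'   classes.  Defaults to all "trait" (no typed bans).
#' @param constraints banned-edge matrix overriding
#'   [default_constraints()]; NULL uses the role-derived default.
#' @param iterations maximum chain length.
#' @param score "bic" (default) or "loglik" (the raw likelihood; with it every
#'   addition is improving, so the chain saturates at the parent cap).
#' @param max_parents in-degree cap (default 5).
#' @param hastings include the neighborhood-size correction (default TRUE).
#' @param exogenous_env forbid edges into environment nodes (default TRUE).
#' @param init_density edge-inclusion probability of the random start.
#' @param window,tol convergence rule: stop when the best score changes by a
#'   relative amount < `tol` over a window of `window` iterations.
#' @param thin record every `thin`-th network score in the trace.
#' @param record_states keep the full visited-DAG state sequence (<= 7 nodes).
#' @param audit recompute the full network score from scratch at every step
#'   and report the largest discrepancy with the incrementally tracked score.
#' @param seed optional integer; the run is deterministic given it.
#' @return an object of class "bnet": the best DAG (`$dag`), its score, the
#'   per-node linear Gaussian parameters refit on the input scale
#'   (`$params`), the score trace, acceptance rate and run metadata.
#' @examples
#' d <- data.frame(X = rnorm(200))
#' d$Y <- 2 * d$X + rnorm(200)
#' fit <- bn_learn(d, iterations = 2000, seed = 1)
#' fit$dag["X", "Y"]
#' @export
bn_learn <- function(data, roles = NULL, constraints = NULL,
                     iterations = 10000L, score = c("bic", "loglik"),
                     max_parents = 5L, hastings = TRUE, exogenous_env = TRUE,
                     init_density = 0.1, window = 1000L, tol = 1e-6,
                     thin = 1L, record_states = FALSE, audit = FALSE,
                     seed = NULL) {
  score <- match.arg(score)
  data <- as.data.frame(data)
  nodes <- colnames(data)
  if (is.null(roles)) roles <- setNames(rep("trait", length(nodes)), nodes)
  stopifnot(setequal(names(roles), nodes))
  roles <- roles[nodes]
  banned <- if (is.null(constraints)) {
    default_constraints(roles, exogenous_env)
  } else {
    constraints
  }
  stopifnot(identical(dim(banned), c(length(nodes), length(nodes))))

  run <- function() {
    X <- standardize_columns(data)
    S <- crossprod(X) / nrow(X)
    init <- random_init_dag(nodes, banned, max_parents, init_density)
    res <- .mcmc_core(S, nrow(X), banned, init * 1L, as.integer(iterations),
                      as.integer(max_parents), score == "bic", hastings,
                      as.integer(window), tol, as.integer(thin),
                      record_states, audit)
    res$init <- init
    res
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())

  dag <- matrix(as.logical(res$best_amat), length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  structure(list(
    dag = dag,
    score_value = res$best_score,
    score = score,
    params = fit_parameters(dag, data),
    roles = roles,
    banned = banned,
    trace = res$trace,
    states = if (record_states) res$states else NULL,
    accept_rate = res$accept_rate,
    steps = res$steps,
    audit_max_dev = if (audit) res$audit_max_dev else NA_real_,
    init_dag = res$init,
    call_info = list(iterations = iterations, max_parents = max_parents,
                     hastings = hastings, exogenous_env = exogenous_env,
                     window = window, tol = tol, seed = seed),
    data = data
  ), class = "bnet")
}

#' Fit linear Gaussian parameters for a fixed DAG
#'
#' Per-node least squares of the child on its parents; the residual SD uses
#' the ML normalization (divide by n).  A parentless node gets its sample
#' mean and ML sample SD.
#'
#' @param dag logical adjacency matrix.
#' @param data data with columns matching the DAG's nodes.
#' @return named list; per node a list with `parents`, `coef` (intercept
#'   first) and `sigma`.  Class "bn_params".
#' @export
fit_parameters <- function(dag, data) {
  data <- as.matrix(as.data.frame(data))
  nodes <- rownames(dag)
  stopifnot(identical(sort(colnames(data)), sort(nodes)))
  n <- nrow(data)
  out <- lapply(nodes, function(v) {
    pa <- nodes[dag[, v]]
    y <- data[, v]
    if (length(pa) == 0L) {
      list(parents = character(0),
           coef = c(`(Intercept)` = mean(y)),
           sigma = max(sqrt(mean((y - mean(y))^2)), SIGMA_FLOOR))
    } else {
      X <- cbind(`(Intercept)` = 1, data[, pa, drop = FALSE])
      qx <- qr(X)
      beta <- if (qx$rank < ncol(X)) {
        drop(solve(crossprod(X) + diag(1e-8, ncol(X)), crossprod(X, y)))
      } else {
        drop(qr.coef(qx, y))
      }
      names(beta) <- colnames(X)
      r <- y - drop(X %*% beta)
      list(parents = pa, coef = beta,
           sigma = max(sqrt(mean(r^2)), SIGMA_FLOOR))
    }
  })
  names(out) <- nodes
  class(out) <- "bn_params"
  out
}

#' @export
print.bnet <- function(x, ...) {
  cat("Linear-Gaussian Bayesian network (MCMC structure search)\n")
  cat(sprintf("  nodes: %d (%s)\n", nrow(x$dag),
              paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                    collapse = ", ")))
  cat(sprintf("  edges: %d   %s score: %.3f\n", sum(x$dag), x$score,
              x$score_value))
  cat(sprintf("  chain: %d steps, acceptance rate %.3f\n",
              x$steps, x$accept_rate))
  invisible(x)
}

#' @export
summary.bnet <- function(object, ...) {
  ed <- amat_edges(object$dag)
  if (nrow(ed)) {
    ed$coefficient <- mapply(function(f, t) {
      unname(object$params[[t]]$coef[f])
    }, ed$from, ed$to)
  }
  structure(list(edges = ed, score = object$score_value,
                 score_kind = object$score, roles = object$roles,
                 accept_rate = object$accept_rate, steps = object$steps),
            class = "summary.bnet")
}

#' @export
print.summary.bnet <- function(x, ...) {
  cat(sprintf("Best DAG: %d edges, %s score %.3f (%d MCMC steps)\n",
              nrow(x$edges), x$score_kind, x$score, x$steps))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bnet <- function(object, ...) {
  lapply(object$params, `[[`, "coef")
}

#' @export
logLik.bnet <- function(object, ...) {
  data <- as.matrix(object$data)
  ll <- 0
  df <- 0
  for (v in names(object$params)) {
    p <- object$params[[v]]
    mu <- p$coef[1]
    if (length(p$parents)) {
      mu <- mu + drop(data[, p$parents, drop = FALSE] %*% p$coef[-1])
    }
    ll <- ll + sum(dnorm(data[, v], mu, p$sigma, log = TRUE))
    df <- df + length(p$coef) + 1L
  }
  structure(ll, df = df, nobs = nrow(data), class = "logLik")
}

#' @export
residuals.bnet <- function(object, ...) {
  data <- as.matrix(object$data)
  res <- sapply(names(object$params), function(v) {
    p <- object$params[[v]]
    mu <- p$coef[1]
    if (length(p$parents)) {
      mu <- mu + drop(data[, p$parents, drop = FALSE] %*% p$coef[-1])
    }
    data[, v] - mu
  })
  colnames(res) <- names(object$params)
  res
}

#' Predict conditional node means from a fitted network
#'
#' @param object a "bnet" fit.
#' @param newdata data containing the parent columns of `node`.
#' @param node node name to predict.
#' @param ... unused.
#' @return numeric vector of conditional means.
#' @export
predict.bnet <- function(object, newdata, node, ...) {
  p <- object$params[[node]]
  if (is.null(p)) stop("unknown node: ", node)
  newdata <- as.data.frame(newdata)
  mu <- rep(p$coef[1], nrow(newdata))
  if (length(p$parents)) {
    mu <- mu + drop(as.matrix(newdata[, p$parents, drop = FALSE]) %*%
                      p$coef[-1])
  }
  unname(mu)
}

#' Simulate data from a fitted network
#'
#' Ancestral sampling: nodes drawn in topological order from their linear
#' Gaussian conditionals.
#'
#' @param object a "bnet" fit.
#' @param nsim number of rows to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with one column per node.
#' @export
simulate.bnet <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    ord <- topological_order(object$dag)
    nodes <- rownames(object$dag)
    out <- matrix(NA_real_, nsim, length(nodes),
                  dimnames = list(NULL, nodes))
    for (i in ord) {
      v <- nodes[i]
      p <- object$params[[v]]
      mu <- rep(p$coef[1], nsim)
      if (length(p$parents)) {
        mu <- mu + drop(out[, p$parents, drop = FALSE] %*% p$coef[-1])
      }
      out[, v] <- rnorm(nsim, mu, p$sigma)
    }
    as.data.frame(out)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' @export
plot.bnet <- function(x, ...) {
  g <- igraph::graph_from_adjacency_matrix(x$dag * 1, mode = "directed")
  palette <- c(environment = "lightblue", gene = "palegreen",
               trait = "gold", disease = "salmon")
  igraph::V(g)$color <- palette[x$roles[igraph::V(g)$name]]
  igraph::plot.igraph(g, ...)
  invisible(x)
}

#' Exact Boltzmann distribution over all DAGs of a small problem
#'
#' Enumerates every DAG over the data's columns (<= 4 nodes), scores each one
#' and normalizes exp(score).  Serves as the exhaustive oracle for the MCMC
#' sampler's stationary distribution.
#'
#' @param data small data set (<= 4 columns).
#' @param banned optional banned-edge matrix.
#' @param score "bic" or "loglik".
#' @return data.frame with state `code`, `score` and probability `prob`,
#'   plus the list of DAGs as attribute "dags".
#' @export
dag_posterior <- function(data, banned = NULL, score = c("bic", "loglik")) {
  score <- match.arg(score)
  data <- as.matrix(data)
  dags <- enumerate_dags(colnames(data), banned)
  sc <- vapply(dags, network_score, numeric(1), data = data, score = score)
  pr <- exp(sc - max(sc))
  pr <- pr / sum(pr)
  out <- data.frame(code = vapply(dags, encode_state, numeric(1)),
                    score = sc, prob = pr)
  attr(out, "dags") <- dags
  out
}
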