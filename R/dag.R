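#' DAG utilities: adjacency matrices, acyclicity, typed-node edge constraints
#' and the add/delete/reverse move neighborhood.
#'
#' A DAG over V named nodes is held as a V x V logical adjacency matrix
#' `amat` with `amat[u, v] == TRUE` meaning a directed edge u -> v.  Node
#' roles ("environment", "gene", "trait", "disease") drive the banned-edge
#' classes used throughout the network stage.
#'
#' @param nodes character vector of node names.
#' @param edges optional two-column character matrix / data.frame (from, to).
#' @return logical adjacency matrix with dimnames `nodes`.
#' @examples
#' a <- make_amat(c("X", "Y"), data.frame(from = "X", to = "Y"))
#' is_acyclic(a)
#' @export
make_amat <- function(nodes, edges = NULL) {
  V <- length(nodes)
  a <- matrix(FALSE, V, V, dimnames = list(nodes, nodes))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    if (!all(edges %in% nodes)) stop("edge endpoint not among nodes")
    a[edges] <- TRUE
  }
  if (any(diag(a))) stop("self-loops are not allowed")
  a
}

#' Test a directed adjacency matrix for acyclicity (Kahn's algorithm)
#'
#' @param amat logical adjacency matrix, `amat[u, v]` = edge u -> v.
#' @return TRUE if the graph has no directed cycle.
#' @export
is_acyclic <- function(amat) {
  a <- amat
  repeat {
    if (nrow(a) == 0L) return(TRUE)
    roots <- colSums(a) == 0
    if (!any(roots)) return(FALSE)
    a <- a[!roots, !roots, drop = FALSE]
  }
}

# all nodes reachable from `from` (excluding `from` unless on a cycle)
reachable_from <- function(amat, from) {
  seen <- amat[from, ]
  frontier <- which(seen)
  while (length(frontier)) {
    nxt <- which(colSums(amat[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Topological order of a DAG
#' @param amat logical adjacency matrix.
#' @return integer vector of node indices, parents before children.
#' @export
topological_order <- function(amat) {
  V <- nrow(amat)
  indeg <- colSums(amat)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    for (w in which(amat[v, ])) {
      indeg[w] <- indeg[w] - 1L
      if (!is.na(indeg[w]) && indeg[w] == 0L) {
        avail <- c(avail, w)
        indeg[w] <- NA
      }
    }
  }
  if (length(order) < V) stop("graph is cyclic")
  order
}

#' Banned-edge matrix for the typed-node network
#'
#' Encodes the biologically motivated edge bans: (1) no edge from a trait or
#' the disease node into a gene, (2) no edge between genes and environmental
#' variables in either direction, (3) no edge among genes.  Optionally
#' environment nodes are treated as exogenous (no incoming edges at all).
#'
#' @param roles named character vector mapping node name to one of
#'   "environment", "gene", "trait", "disease".
#' @param exogenous_env if TRUE (default), ban every edge into an
#'   environment node; set FALSE for the literal three-class ban only.
#' @return logical matrix `banned` with `banned[u, v]` = TRUE when u -> v is
#'   forbidden (diagonal always TRUE).
#' @export
default_constraints <- function(roles, exogenous_env = TRUE) {
  stopifnot(all(roles %in% c("environment", "gene", "trait", "disease")))
  nodes <- names(roles)
  V <- length(nodes)
  b <- matrix(FALSE, V, V, dimnames = list(nodes, nodes))
  for (u in seq_len(V)) for (v in seq_len(V)) {
    ru <- roles[u]; rv <- roles[v]
    if (u == v) b[u, v] <- TRUE
    # (1) traits (incl. disease outcome) may not point at genes
    if (ru %in% c("trait", "disease") && rv == "gene") b[u, v] <- TRUE
    # (2) no gene <-> environment edges
    if ((ru == "gene" && rv == "environment") ||
        (ru == "environment" && rv == "gene")) b[u, v] <- TRUE
    # (3) no edges among genes
    if (ru == "gene" && rv == "gene") b[u, v] <- TRUE
    if (exogenous_env && rv == "environment") b[u, v] <- TRUE
  }
  b
}

#' Enumerate the legal add/delete/reverse neighborhood of a DAG
#'
#' Pure-R enumeration used for small-instance oracles and for auditing the
#' compiled sampler: candidate additions exclude self-loops, existing or
#' anti-parallel edges, banned edges, cycle-creating edges and parent-cap
#' violations; deletions range over existing edges; reversals are kept only
#' when the flipped edge is itself legal and acyclic.
#'
#' @param amat logical adjacency matrix.
#' @param banned banned-edge matrix (see [default_constraints()]); NULL for
#'   no constraints beyond acyclicity.
#' @param max_parents maximum in-degree.
#' @return data.frame with columns type ("add", "delete", "reverse"),
#'   from, to.
#' @export
legal_moves <- function(amat, banned = NULL, max_parents = 5L) {
  V <- nrow(amat)
  nodes <- rownames(amat)
  if (is.null(banned)) {
    banned <- matrix(FALSE, V, V)
    diag(banned) <- TRUE
  }
  indeg <- colSums(amat)
  out <- list()
  k <- 0L
  for (v in seq_len(V)) for (u in seq_len(V)) {
    if (u == v) next
    if (amat[u, v]) {
      k <- k + 1L
      out[[k]] <- c("delete", u, v)
      # reverse legal iff v->u allowed and removing u->v leaves no u ~> v path
      if (!banned[v, u] && indeg[u] < max_parents) {
        a2 <- amat
        a2[u, v] <- FALSE
        if (!(v %in% reachable_from(a2, u))) {
          k <- k + 1L
          out[[k]] <- c("reverse", u, v)
        }
      }
    } else {
      if (banned[u, v] || amat[v, u] || indeg[v] >= max_parents) next
      if (u %in% reachable_from(amat, v)) next # would create a cycle
      k <- k + 1L
      out[[k]] <- c("add", u, v)
    }
  }
  if (k == 0L) {
    return(data.frame(type = character(0), from = character(0),
                      to = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(type = m[, 1], from = nodes[as.integer(m[, 2])],
             to = nodes[as.integer(m[, 3])])
}

#' Sample one legal move uniformly from the neighborhood
#'
#' @inheritParams legal_moves
#' @return a list with `move` (one-row data.frame, or NULL when the
#'   neighborhood is empty) and `n_moves`.
#' @export
propose_move <- function(amat, banned = NULL, max_parents = 5L) {
  mv <- legal_moves(amat, banned, max_parents)
  if (nrow(mv) == 0L) return(list(move = NULL, n_moves = 0L))
  list(move = mv[sample.int(nrow(mv), 1L), , drop = FALSE],
       n_moves = nrow(mv))
}

# apply a move (list/row with type, from, to) to an adjacency matrix
apply_move <- function(amat, move) {
  u <- move$from; v <- move$to
  switch(as.character(move$type),
         add = { amat[u, v] <- TRUE },
         delete = { amat[u, v] <- FALSE },
         reverse = { amat[u, v] <- FALSE; amat[v, u] <- TRUE },
         stop("unknown move type"))
  amat
}

#' Enumerate every DAG over a small node set
#'
#' Exhaustive enumeration by assigning each unordered node pair one of
#' {no edge, u -> v, v -> u} and keeping the acyclic, constraint-satisfying
#' assignments.  Intended for <= 4 nodes (25 DAGs at 3 nodes, 543 at 4).
#'
#' @param nodes character vector of node names (length <= 4).
#' @param banned optional banned-edge matrix.
#' @return list of adjacency matrices.
#' @export
enumerate_dags <- function(nodes, banned = NULL) {
  V <- length(nodes)
  if (V > 4) stop("exhaustive enumeration supported for at most 4 nodes")
  pairs <- which(upper.tri(matrix(0, V, V)), arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  for (assign_id in seq_len(3^np) - 1L) {
    a <- matrix(FALSE, V, V, dimnames = list(nodes, nodes))
    rest <- assign_id
    ok <- TRUE
    for (j in seq_len(np)) {
      code <- rest %% 3L
      rest <- rest %/% 3L
      u <- pairs[j, 1]; v <- pairs[j, 2]
      if (code == 1L) a[u, v] <- TRUE
      if (code == 2L) a[v, u] <- TRUE
      if (!is.null(banned)) {
        if ((code == 1L && banned[u, v]) || (code == 2L && banned[v, u])) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok && is_acyclic(a)) out[[length(out) + 1L]] <- a
  }
  out
}

# decode a compact state code emitted by the compiled sampler back into an
# adjacency matrix (V <= 7); bit (v-1)*V + (u-1) set <=> edge u -> v
decode_state <- function(code, nodes) {
  V <- length(nodes)
  a <- matrix(FALSE, V, V, dimnames = list(nodes, nodes))
  rest <- code
  for (v in seq_len(V)) for (u in seq_len(V)) {
    bit <- (v - 1L) * V + (u - 1L)
    if (floor(rest / 2^bit) %% 2 == 1) a[u, v] <- TRUE
  }
  a
}

# matching encoder, for oracle-side state bookkeeping
encode_state <- function(amat) {
  V <- nrow(amat)
  code <- 0
  for (v in seq_len(V)) for (u in seq_len(V)) {
    if (amat[u, v]) code <- code + 2^((v - 1L) * V + (u - 1L))
  }
  code
}

# edge data.frame from adjacency matrix
amat_edges <- function(amat) {
  idx <- which(amat, arr.ind = TRUE)
  data.frame(from = rownames(amat)[idx[, 1]],
             to = colnames(amat)[idx[, 2]],
             stringsAsFactors = FALSE)
}
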