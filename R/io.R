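#' Plain-text readers and writers for every pipeline artifact: tab-separated
#' variant/genotype/phenotype/score/screen/confidence tables, JSON ground
#' truth and parameters, GraphML/DOT networks.
#'
#' @name io
NULL

#' @rdname io
#' @param variants variant table.
#' @param file output path.
#' @export
write_variant_table <- function(variants, file) {
  write.table(variants[, c("variant_id", "gene_id", "maf", "annotation")],
              file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_variant_table <- function(file) {
  read.table(file, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname io
#' @param genotypes genotype matrix.
#' @export
write_genotype_matrix <- function(genotypes, file) {
  df <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @export
read_genotype_matrix <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' @rdname io
#' @param phenotypes list of phenotype tables (written with a `replicate`
#'   column).
#' @export
write_phenotype_tables <- function(phenotypes, file) {
  tabs <- lapply(seq_along(phenotypes), function(r) {
    cbind(replicate = r, phenotypes[[r]])
  })
  write.table(do.call(rbind, tabs), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' @rdname io
#' @export
read_phenotype_tables <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  lapply(split(df, df$replicate),
         function(x) x[, setdiff(colnames(x), "replicate")])
}

#' @rdname io
#' @param truth ground-truth list (causal_genes, edges).
#' @export
write_ground_truth <- function(truth, file) {
  jsonlite::write_json(list(causal_genes = truth$causal_genes,
                            edges = truth$edges),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname io
#' @export
read_ground_truth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  x$causal_genes <- lapply(x$causal_genes, as.character)
  x
}

#' @rdname io
#' @param scores burden score matrix (attributes recorded in a header
#'   comment).
#' @param w optional combined-score weight to record.
#' @export
write_gene_scores <- function(scores, file, w = NULL) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# score_kind=%s weight=madsen_browning w=%s",
                     attr(scores, "score_kind") %||% "unknown",
                     if (is.null(w)) attr(scores, "w") %||% "NA" else w),
             con)
  df <- data.frame(id = rownames(scores), unclass(scores),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname io
#' @param screen a "screen_result".
#' @export
write_screen_result <- function(screen, file) {
  df <- data.frame(gene = names(screen$counts), response = screen$response,
                   retention_count = screen$counts,
                   retained = screen$retained)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname io
#' @param confidence an "edge_confidence" table.
#' @param cutoff inclusive retention cutoff recorded in the table.
#' @export
write_edge_confidence <- function(confidence, file, cutoff = 5L) {
  df <- as.data.frame(confidence)
  df$retained <- df$count >= cutoff
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a network as GraphML or DOT with role and confidence attributes
#'
#' @param dag adjacency matrix (a thresholded consensus network or a
#'   "bnet"'s `$dag`).
#' @param file output path.
#' @param roles optional named role vector stored as a node attribute.
#' @param format "graphml" or "dot".
#' @export
write_network <- function(dag, file, roles = NULL,
                          format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- igraph::graph_from_adjacency_matrix(dag * 1, mode = "directed")
  if (!is.null(roles)) {
    igraph::V(g)$role <- unname(roles[igraph::V(g)$name])
  }
  counts <- attr(dag, "counts")
  if (!is.null(counts) && nrow(counts)) {
    el <- igraph::as_edgelist(g)
    key <- paste(counts$from, counts$to)
    igraph::E(g)$confidence <- counts$count[match(paste(el[, 1], el[, 2]),
                                                  key)]
  }
  igraph::write_graph(g, file, format = format)
}

#' @rdname io
#' @param params a "bn_params" list.
#' @export
write_bn_params <- function(params, file) {
  out <- lapply(params, function(p) {
    list(parents = p$parents, coefficients = as.list(p$coef),
         sigma = p$sigma)
  })
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}
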