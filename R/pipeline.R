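#' End-to-end pipeline orchestration and canonical test fixtures.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Nested per-stage settings with a single master seed; every stochastic
#' stage derives its own stream seed from the master so stages can be rerun
#' in isolation.
#'
#' @param generator a [sim_config()]; its `seed` is overridden by
#'   `master_seed`.
#' @param annotation score annotation fed to the screen ("combined" uses the
#'   data-estimated weight; "all", "synonymous", "nonsynonymous" bypass it).
#' @param weight_formula [estimate_weight()] formula for the combined score.
#' @param p_cutoff,retention_threshold screening rule (threshold NULL =
#'   half the replicates).
#' @param responses screening responses.
#' @param consensus_cutoff confidence cutoff (NULL = scaled default).
#' @param iterations MCMC iterations per replicate network.
#' @param max_parents in-degree cap.
#' @param model prediction model.
#' @param train_fraction fraction of replicates used for training.
#' @param master_seed master seed.
#' @return list of class "pipeline_config".
#' @export
pipeline_config <- function(generator = sim_config(),
                            annotation = "combined",
                            weight_formula = "nonsyn_share",
                            p_cutoff = 0.1, retention_threshold = NULL,
                            responses = c("Q1", "Q2", "Q4", "affected"),
                            consensus_cutoff = NULL, iterations = 6000L,
                            max_parents = 5L, model = "svm",
                            train_fraction = 0.5, master_seed = 1L) {
  generator$seed <- as.integer(master_seed)
  validate_sim_config(generator)
  structure(list(generator = generator, annotation = annotation,
                 weight_formula = weight_formula, p_cutoff = p_cutoff,
                 retention_threshold = retention_threshold,
                 responses = responses,
                 consensus_cutoff = consensus_cutoff,
                 iterations = as.integer(iterations),
                 max_parents = as.integer(max_parents), model = model,
                 train_fraction = train_fraction,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, score, screen, learn, aggregate, predict
#'
#' Executes every stage in order, writes each intermediate artifact as plain
#' text under `out_dir` (when given) and returns a manifest recording
#' configuration, seeds, stage summaries and file checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if missing).
#' @return list of class "pipeline_result": replicates, scores, weight,
#'   screens, selected genes, consensus, prediction experiment and the
#'   manifest.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(sim_config(n_individuals = 100, n_genes = 8,
#'                                   n_replicates = 6,
#'                                   calibration_n = 2000),
#'                        iterations = 1500L)
#' res <- run_pipeline(cfg)
#' res$manifest$stages$screening
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  emit <- function(fn, name) {
    if (!is.null(out_dir)) fn(file.path(out_dir, name))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  rs <- sim_replicates(config$generator)
  emit(function(f) write_variant_table(rs$variants, f), "variants.tsv")
  emit(function(f) write_genotype_matrix(rs$genotypes, f), "genotypes.tsv")
  emit(function(f) write_phenotype_tables(rs$phenotypes, f),
       "phenotypes.tsv")
  emit(function(f) write_ground_truth(rs$truth, f), "truth.json")

  weight <- NULL
  if (config$annotation == "combined") {
    syn <- burden_matrix(rs$genotypes, rs$variants, "synonymous")
    ns <- burden_matrix(rs$genotypes, rs$variants, "nonsynonymous")
    weight <- tryCatch(
      estimate_weight_from_data(rs$genotypes, rs$variants,
                                rs$phenotypes[[1]],
                                formula = config$weight_formula),
      error = function(e) NULL)
    w <- if (is.null(weight)) 0.5 else weight$w
    scores <- combine_scores(syn, ns, w)
  } else {
    scores <- burden_matrix(rs$genotypes, rs$variants, config$annotation)
  }
  emit(function(f) write_gene_scores(scores, f), "gene_scores.tsv")

  screens <- lapply(config$responses, function(rv) {
    screen_replicates(scores, rs$phenotypes, rv, p_cutoff = config$p_cutoff,
                      retention_threshold = config$retention_threshold)
  })
  names(screens) <- config$responses
  selected <- union_retained(screens)
  for (rv in config$responses) {
    emit(function(f) write_screen_result(screens[[rv]], f),
         sprintf("screen_%s.tsv", rv))
  }

  consensus <- NULL
  if (length(selected)) {
    consensus <- consensus_network(rs, scores, selected,
                                   cutoff = config$consensus_cutoff,
                                   iterations = config$iterations,
                                   max_parents = config$max_parents,
                                   master_seed = config$master_seed)
    emit(function(f) write_edge_confidence(consensus$confidence, f,
                                           consensus$cutoff),
         "edge_confidence.tsv")
    emit(function(f) {
      roles <- node_data(rs$phenotypes[[1]], scores, selected)$roles
      write_network(consensus$dag, f, roles, "graphml")
    }, "consensus_network.graphml")
  }

  experiment <- run_annotation_experiment(
    rs, model = config$model, p_cutoff = config$p_cutoff,
    retention_threshold = config$retention_threshold,
    cutoff = config$consensus_cutoff, iterations = config$iterations,
    split_seed = config$master_seed,
    train_fraction = config$train_fraction)

  manifest <- list(
    master_seed = config$master_seed,
    config = list(annotation = config$annotation,
                  p_cutoff = config$p_cutoff,
                  responses = config$responses,
                  iterations = config$iterations,
                  model = config$model),
    stages = list(
      simulate = list(n_individuals = nrow(rs$genotypes),
                      n_variants = nrow(rs$variants),
                      n_replicates = length(rs$phenotypes)),
      scores = list(kind = attr(scores, "score_kind") %||% "combined",
                    w = if (is.null(weight)) NA else weight$w),
      screening = list(selected = selected,
                       per_response = lapply(screens, `[[`,
                                             "retained_genes")),
      consensus = if (is.null(consensus)) NULL else
        list(cutoff = consensus$cutoff, n_edges = sum(consensus$dag)),
      prediction = list(auc_mean = experiment$auc_mean)))
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest[names(manifest) != "checksums"],
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  structure(list(replicates = rs, scores = scores, weight = weight,
                 screens = screens, selected_genes = selected,
                 consensus = consensus, experiment = experiment,
                 manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (master seed", x$manifest$master_seed, ")\n")
  cat(sprintf("  %d selected gene(s); consensus edges: %s\n",
              length(x$selected_genes),
              if (is.null(x$consensus)) "none" else sum(x$consensus$dag)))
  print(round(x$experiment$auc_mean, 3))
  invisible(x)
}

#' Canonical small fixtures shared across the test suite
#'
#' Three deterministic instances: `three_node` - a 200-row X -> Y -> Z
#' linear-Gaussian dataset for exhaustive-enumeration oracles; `burden_toy` -
#' the one-gene, one-variant design where one carrier of two minor alleles
#' at MAF 0.1 in a sample of 100 scores 2/sqrt(100 * 0.1 * 0.9) = 2/3;
#' `dag7` - seven small DAGs over five nodes with hand-countable edge
#' overlaps for the confidence tally.
#'
#' @param seed integer seed for the three-node draw.
#' @return named list of fixtures.
#' @export
make_fixtures <- function(seed = 1L) {
  three_node <- with_seed(seed, {
    x <- rnorm(200)
    y <- 1.2 * x + rnorm(200)
    z <- 0.8 * y + rnorm(200)
    data.frame(X = x, Y = y, Z = z)
  })
  burden_toy <- list(
    variants = data.frame(variant_id = "V1", gene_id = "G1", maf = 0.1,
                          annotation = "nonsynonymous",
                          stringsAsFactors = FALSE),
    genotypes = matrix(c(2L, rep(0L, 99)), nrow = 100, ncol = 1,
                       dimnames = list(sprintf("I%03d", 1:100), "V1")),
    expected_score = 2 / sqrt(100 * 0.1 * 0.9))
  nodes <- c("A", "B", "C", "D", "E")
  e <- function(...) make_amat(nodes, matrix(c(...), ncol = 2, byrow = TRUE))
  dag7 <- list(
    e("A", "B", "B", "C"),
    e("A", "B", "B", "C"),
    e("A", "B", "C", "D"),
    e("A", "B", "D", "E"),
    e("B", "C", "D", "E"),
    e("A", "B"),
    e("E", "A", "A", "B"))
  # manual tally: A->B 6, B->C 3, C->D 1, D->E 2, E->A 1
  dag7_counts <- data.frame(
    from = c("A", "B", "C", "D", "E"),
    to = c("B", "C", "D", "E", "A"),
    count = c(6L, 3L, 1L, 2L, 1L), stringsAsFactors = FALSE)
  list(three_node = three_node, burden_toy = burden_toy, dag7 = dag7,
       dag7_counts = dag7_counts)
}
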