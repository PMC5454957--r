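#' Pipeline configuration
#'
#' All tunables of the four-stage prioritization procedure in one place.
#' The defaults reproduce the published full-scale settings: restart 0.8,
#' L1 tolerance 1e-6, probability threshold 1e-5, 1000 permutations,
#' alpha 0.05, MIS threshold 900 (inclusive), MFS threshold 0.8 (strict),
#' seed genes excluded from the ranked output.
#'
#' @param restart restart probability of the walk.
#' @param tol L1 convergence tolerance.
#' @param prob_threshold stationary-probability cutoff for RWR genes.
#' @param n_permutations permutation count of the significance test.
#' @param alpha p-value cutoff (strict `<`).
#' @param mis_threshold minimum interaction score (inclusive `>=`).
#' @param mfs_threshold functional-similarity cutoff (strict `>`).
#' @param rng_seed integer seed driving the permutation draws.
#' @param exclude_seeds drop seed genes from the ranked list.
#' @param max_iter RWR iteration cap.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(restart = 0.8, tol = 1e-6, prob_threshold = 1e-5,
                            n_permutations = 1000L, alpha = 0.05,
                            mis_threshold = 900, mfs_threshold = 0.8,
                            rng_seed = 1L, exclude_seeds = TRUE,
                            max_iter = 10000L) {
  stopifnot(alpha > 0, alpha <= 1, n_permutations >= 1)
  structure(list(restart = restart, tol = tol,
                 prob_threshold = prob_threshold,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 mis_threshold = mis_threshold, mfs_threshold = mfs_threshold,
                 rng_seed = as.integer(rng_seed),
                 exclude_seeds = isTRUE(exclude_seeds),
                 max_iter = as.integer(max_iter)),
            class = "pipeline_config")
}

#' Run the full prioritization pipeline
#'
#' Executes the four stages in order on one network + seed set + annotation
#' map: (1) RWR from the seeds and selection of genes above the probability
#' threshold ("RWR genes"); (2) permutation test and filtering at `alpha`
#' ("candidate genes"); (3) MIS and MFS computation against the seeds and
#' thresholding ("core genes"); (4) assembly of a result table in which every
#' RWR gene carries its probability, p-value, MIS, MFS and the furthest stage
#' it reached. Stage counts are logged via `message()` so the shape of a run
#' is visible without parsing outputs. Deterministic given `rng_seed`.
#'
#' @param net a [weighted_network()].
#' @param seeds a [seed_set()].
#' @param ann an [annotation_map()].
#' @param config a [pipeline_config()].
#' @param verbose emit stage-count messages (default `TRUE`).
#' @return An object of class `rwr_result`: list with `table` (data frame
#'   `gene`, `probability`, `p_value`, `mis`, `mfs`, `stage` where stage is
#'   the ordered factor `rwr_gene < candidate < core`), `probabilities` (the
#'   full stationary vector), `pvalues` (the [permutation_pvalues()] object),
#'   `seed_es`/`candidate_es` enrichment matrices, `config`, `seeds`, and
#'   `counts` (named vector of stage sizes).
#' @export
run_prioritization <- function(net, seeds, ann, config = pipeline_config(),
                               verbose = TRUE) {
  stopifnot(inherits(net, "weighted_network"), inherits(seeds, "seed_set"),
            inherits(ann, "annotation_map"),
            inherits(config, "pipeline_config"))
  if (length(seeds$ids) == 0) stop("seed set is empty")
  say <- function(...) if (verbose) message(sprintf(...))

  cfg <- rwr_config(config$restart, config$tol, config$prob_threshold,
                    config$max_iter)
  tm <- column_normalize(net)
  p0 <- build_initial_vector(net, seeds)
  p <- random_walk_with_restart(tm, p0, cfg)
  rwr_genes <- select_rwr_genes(p, seeds, config$prob_threshold,
                                config$exclude_seeds)
  say("stage 1 (RWR): %d genes above threshold %g", nrow(rwr_genes),
      config$prob_threshold)

  pvals <- permutation_pvalues(net, tm, seeds, rwr_genes, cfg,
                               n_perm = config$n_permutations,
                               rng_seed = config$rng_seed)
  candidates <- filter_candidates(pvals, config$alpha)
  say("stage 2 (permutation test): %d candidates at alpha %g",
      nrow(candidates), config$alpha)

  universe <- annotated_universe(net, ann)
  es_genes <- unique(c(candidates$gene, seeds$ids))
  es <- if (length(universe) > 0 && length(es_genes) > 0) {
    enrichment_vectors(es_genes, net, ann, universe)
  } else {
    matrix(0, nrow = length(es_genes), ncol = length(ann$genes),
           dimnames = list(es_genes, names(ann$genes)))
  }
  candidates$mis <- vapply(candidates$gene, max_interaction_score,
                           integer(1), seeds = seeds, net = net)
  candidates$mfs <- if (nrow(candidates) > 0) {
    vapply(candidates$gene, max_function_score, numeric(1),
           seeds = seeds, es = es)
  } else numeric(0)
  core <- select_core_genes(candidates, config$mis_threshold,
                            config$mfs_threshold)
  say("stage 3 (MIS >= %g, MFS > %g): %d core genes", config$mis_threshold,
      config$mfs_threshold, nrow(core))

  tab <- rwr_genes
  m <- match(tab$gene, pvals$table$gene)
  tab$p_value <- pvals$table$p_value[m]
  cm <- match(tab$gene, candidates$gene)
  tab$mis <- candidates$mis[cm]
  tab$mfs <- candidates$mfs[cm]
  stage <- rep("rwr_gene", nrow(tab))
  stage[tab$gene %in% candidates$gene] <- "candidate"
  stage[tab$gene %in% core$gene] <- "core"
  tab$stage <- factor(stage, levels = c("rwr_gene", "candidate", "core"),
                      ordered = TRUE)
  o <- order(tab$p_value, -tab$probability, tab$gene, method = "radix")
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL

  structure(list(table = tab, probabilities = p, pvalues = pvals,
                 enrichment = es, config = config, seeds = seeds,
                 counts = c(rwr_gene = nrow(rwr_genes),
                            candidate = nrow(candidates),
                            core = nrow(core))),
            class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf(
    "rwr_result: %d RWR genes -> %d candidates -> %d core genes (%d seeds)\n",
    x$counts["rwr_gene"], x$counts["candidate"], x$counts["core"],
    length(x$seeds$ids)))
  invisible(x)
}

#' Core genes of a pipeline result
#'
#' @param result an [run_prioritization()] result.
#' @return character vector of core gene identifiers.
#' @export
core_genes <- function(result) {
  stopifnot(inherits(result, "rwr_result"))
  as.character(result$table$gene[result$table$stage == "core"])
}

#' Write a pipeline result table as TSV
#'
#' Columns `gene`, `probability`, `p_value`, `mis`, `mfs`, `stage`.
#' Probabilities are printed in scientific notation with 3 significant
#' digits (e.g. `2.71e-04`); a p-value of 0 is rendered below the test's
#' resolution (`<0.001` at 1000 permutations); MIS/MFS are empty for genes
#' that never reached the candidate stage; `stage` is the furthest stage
#' attained.
#'
#' @param result an `rwr_result`.
#' @param path output file path.
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "rwr_result"))
  tab <- result$table
  if (nrow(tab) == 0) stop("result table is empty")
  out <- data.frame(
    gene = tab$gene,
    probability = formatC(tab$probability, format = "e", digits = 2),
    p_value = format_pvalue(tab$p_value, result$pvalues$n_perm),
    mis = ifelse(is.na(tab$mis), "", as.character(tab$mis)),
    mfs = ifelse(is.na(tab$mfs), "", formatC(tab$mfs, format = "f", digits = 3)),
    stage = as.character(tab$stage),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-read a TSV written by [write_results()]
#'
#' Numeric fields are recovered at printed precision; a `<...` p-value reads
#' back as 0 (below resolution).
#'
#' @param path file path.
#' @return data frame with the table's columns, numerics parsed.
#' @export
read_results <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  data.frame(
    gene = tab$gene,
    probability = as.numeric(tab$probability),
    p_value = ifelse(startsWith(tab$p_value, "<"), 0,
                     suppressWarnings(as.numeric(tab$p_value))),
    mis = suppressWarnings(as.integer(tab$mis)),
    mfs = suppressWarnings(as.numeric(tab$mfs)),
    stage = factor(tab$stage, levels = c("rwr_gene", "candidate", "core"),
                   ordered = TRUE),
    stringsAsFactors = FALSE)
}

#' Export the seed-plus-core sub-network as an edge list
#'
#' Plain-text substitute for a network figure: all edges of the network whose
#' both endpoints are seed or core genes, written in the three-column STRING
#' format.
#'
#' @param net a [weighted_network()].
#' @param result an `rwr_result`.
#' @param path output file path.
#' @export
write_subnetwork <- function(net, result, path) {
  stopifnot(inherits(net, "weighted_network"), inherits(result, "rwr_result"))
  keep_nodes <- union(result$seeds$ids, core_genes(result))
  e <- net$edges
  e <- e[e$from %in% keep_nodes & e$to %in% keep_nodes, , drop = FALSE]
  writeLines(c("protein1 protein2 combined_score",
               paste(e$from, e$to, e$score)), path)
  invisible(path)
}
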