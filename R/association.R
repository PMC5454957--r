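#' Maximum interaction score to the seed set
#'
#' `MIS(g)` is the largest STRING combined score on an edge between gene `g`
#' and any seed gene, or 0 when `g` has no seed neighbor. A high MIS means
#' the candidate interacts with at least one validated disease gene at high
#' confidence (STRING calls 900 the highest-confidence cutoff).
#'
#' @param gene node identifier (must be in the network).
#' @param seeds a [seed_set()] or character vector of seed IDs.
#' @param net a [weighted_network()].
#' @return integer: 0 or a value in `[150, 999]`.
#' @export
max_interaction_score <- function(gene, seeds, net) {
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else as.character(seeds)
  nb <- network_neighbors(net, gene)
  hit <- nb[names(nb) %in% ids]
  if (length(hit) == 0) 0L else as.integer(max(hit))
}

# Per-term white-ball counts over the universe, shared by all genes.
term_universe_counts <- function(ann, universe) {
  vapply(ann$genes, function(g) length(intersect(g, universe)), integer(1))
}

#' Hypergeometric enrichment-score vector of a gene's neighborhood
#'
#' Encodes what a gene's direct network neighbors do, term by term. For each
#' annotation term, an upper-tail hypergeometric probability asks whether the
#' gene's neighbors are over-represented among the term's genes: with
#' `numW` in-universe genes annotated to the term, `numB` in-universe genes
#' not annotated, and `numDrawn` in-universe neighbors of the gene of which
#' `numWdrawn` are annotated, the score is
#' `-log10 P(X >= numWdrawn)` for `X` hypergeometric — computed via
#' `phyper(numWdrawn - 1, numW, numB, numDrawn, lower.tail = FALSE)`.
#' Terms with `numWdrawn = 0` (including terms annotating no in-universe
#' gene) score 0; tail probabilities are floored at 1e-300 before the log so
#' scores stay finite. The universe is by default all network nodes carrying
#' at least one annotation ([annotated_universe()]).
#'
#' @param gene node identifier.
#' @param net a [weighted_network()].
#' @param ann an [annotation_map()]. GO terms and KEGG pathways (or any term
#'   collections) share one concatenated term axis.
#' @param universe character vector of gene IDs defining the sampling frame.
#' @return named numeric vector of nonnegative scores, one per term, in the
#'   term order of `ann`.
#' @export
enrichment_vector <- function(gene, net, ann,
                              universe = annotated_universe(net, ann)) {
  stopifnot(inherits(ann, "annotation_map"))
  if (length(universe) == 0) stop("enrichment universe is empty")
  nb <- intersect(names(network_neighbors(net, gene)), universe)
  num_w <- term_universe_counts(ann, universe)
  enrichment_scores(nb, ann, universe, num_w)
}

# Core score computation, factored out so pipeline code can reuse the
# per-term numW counts across many genes.
enrichment_scores <- function(neighbors, ann, universe, num_w) {
  n_universe <- length(universe)
  num_drawn <- length(neighbors)
  scores <- stats::setNames(numeric(length(ann$genes)), names(ann$genes))
  if (num_drawn == 0) return(scores)
  num_wdrawn <- vapply(ann$genes, function(g)
    length(intersect(g, neighbors)), integer(1))
  active <- num_wdrawn > 0 & num_w > 0
  if (any(active)) {
    tail_p <- stats::phyper(num_wdrawn[active] - 1, num_w[active],
                            n_universe - num_w[active], num_drawn,
                            lower.tail = FALSE)
    scores[active] <- -log10(pmax(tail_p, 1e-300))
  }
  scores
}

#' Enrichment vectors for a batch of genes
#'
#' Computes [enrichment_vector()] for each gene, sharing the per-term
#' universe counts; this is the cache the functional-similarity filter
#' operates on.
#'
#' @inheritParams enrichment_vector
#' @param genes character vector of node identifiers.
#' @return numeric matrix, one row per gene, one column per term.
#' @export
enrichment_vectors <- function(genes, net, ann,
                               universe = annotated_universe(net, ann)) {
  stopifnot(inherits(ann, "annotation_map"))
  if (length(universe) == 0) stop("enrichment universe is empty")
  num_w <- term_universe_counts(ann, universe)
  rows <- lapply(genes, function(g) {
    nb <- intersect(names(network_neighbors(net, g)), universe)
    enrichment_scores(nb, ann, universe, num_w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- genes
  out
}

#' Cosine relatedness of two enrichment vectors
#'
#' `Gamma(g, g') = ES(g) . ES(g') / (||ES(g)|| ||ES(g')||)`, which lies in
#' `[0, 1]` because enrichment scores are nonnegative. If either vector is
#' all zero (a gene whose neighborhood shows no over-representation) the
#' relatedness is defined as 0, so such genes simply fail the functional
#' filter rather than erroring.
#'
#' @param a,b numeric enrichment vectors over the same term ordering.
#' @return numeric scalar in `[0, 1]`.
#' @export
cosine_relatedness <- function(a, b) {
  if (length(a) != length(b) ||
      (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))) {
    stop("enrichment vectors must share one term ordering")
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, sum(a * b) / (na * nb))
}

#' Maximum function score against the seed set
#'
#' `MFS(g)` is the largest cosine relatedness between `g`'s enrichment
#' vector and any seed gene's enrichment vector: how closely the candidate's
#' neighborhood function profile matches that of the best-matching validated
#' gene.
#'
#' @param gene node identifier.
#' @param seeds a [seed_set()] or character vector of seed IDs.
#' @param es matrix from [enrichment_vectors()] covering `gene` and all
#'   seeds (rows named by gene ID).
#' @return numeric scalar in `[0, 1]`.
#' @export
max_function_score <- function(gene, seeds, es) {
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else as.character(seeds)
  missing <- setdiff(c(gene, ids), rownames(es))
  if (length(missing) > 0) {
    stop("enrichment cache lacks entries for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  g <- es[gene, ]
  max(vapply(ids, function(s) cosine_relatedness(g, es[s, ]), numeric(1)))
}

#' Select core genes on the MIS and MFS thresholds
#'
#' Keeps candidates with `MIS >= mis_threshold` (inclusive; 900 is STRING's
#' highest-confidence cutoff) and `MFS > mfs_threshold` (strict), ordered by
#' p-value ascending, then probability descending, then identifier. The
#' survivors are the core putative disease genes.
#'
#' @param candidates data frame with columns `gene`, `probability`,
#'   `p_value`, `mis`, `mfs`.
#' @param mis_threshold minimum interaction score (default 900, inclusive).
#' @param mfs_threshold functional-similarity cutoff (default 0.8, strict).
#' @return the surviving rows, with a logical `is_core` column set.
#' @export
select_core_genes <- function(candidates, mis_threshold = 900,
                              mfs_threshold = 0.8) {
  stopifnot(all(c("gene", "probability", "p_value", "mis", "mfs") %in%
                  names(candidates)))
  keep <- candidates$mis >= mis_threshold & candidates$mfs > mfs_threshold
  out <- candidates[keep, , drop = FALSE]
  o <- order(out$p_value, -out$probability, out$gene, method = "radix")
  out <- out[o, , drop = FALSE]
  out$is_core <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
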