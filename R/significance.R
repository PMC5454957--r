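#' Permutation-test p-values for RWR genes
#'
#' Controls for genes that rank highly under *any* seed set because of
#' network topology (hubs) rather than proximity to the disease seeds. For
#' each of `n_perm` permutations a node set of the same size as the true seed
#' set is drawn uniformly without replacement from all network nodes and a
#' full RWR run is executed on the same transition model. For each RWR gene
#' `g`, `theta` counts the permutations whose probability for `g` is strictly
#' larger than its probability under the true seeds, and
#' `p = theta / n_perm`. Ties do not increment `theta` (the strict comparison
#' is anti-conservative; documented limitation). No multiple-testing
#' correction is applied: filtering is on raw permutation p-values.
#'
#' @param net a [weighted_network()] (source of the node pool).
#' @param tm the [column_normalize()] transition model (shared across all
#'   permutations; only the initial vector changes).
#' @param seeds a [seed_set()] of true seeds.
#' @param rwr_genes data frame from [select_rwr_genes()] (columns `gene`,
#'   `probability`).
#' @param cfg an [rwr_config()].
#' @param n_perm number of permutations (default 1000, giving p-value
#'   resolution 0.001).
#' @param rng_seed integer seed for the single RNG stream that draws all
#'   permutation sets.
#' @param perm_sets optional list of pre-drawn permutation node sets
#'   (character vectors of the seed-set size); overrides the RNG draw and is
#'   intended for audit and testing.
#' @return An object of class `permutation_result`: list with `table`
#'   (data frame `gene`, `probability`, `theta`, `p_value`), `n_perm`,
#'   `rng_seed`, and `perm_sets` (the node sets actually used, for audit).
#' @export
permutation_pvalues <- function(net, tm, seeds, rwr_genes, cfg = rwr_config(),
                                n_perm = 1000L, rng_seed = 1L,
                                perm_sets = NULL) {
  stopifnot(inherits(net, "weighted_network"),
            inherits(tm, "transition_model"),
            inherits(seeds, "seed_set"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1) stop("n_perm must be at least 1")
  n_seeds <- length(seeds$ids)
  if (n_seeds > length(net$nodes)) {
    stop("seed set larger than the network node set")
  }
  if (is.null(perm_sets)) {
    perm_sets <- withr::with_seed(rng_seed, {
      lapply(seq_len(n_perm), function(i) sample(net$nodes, n_seeds))
    })
  } else {
    stopifnot(length(perm_sets) == n_perm)
  }
  true_p <- stats::setNames(rwr_genes$probability, rwr_genes$gene)
  theta <- stats::setNames(integer(nrow(rwr_genes)), rwr_genes$gene)
  for (s in perm_sets) {
    p0 <- build_initial_vector(net, s)
    p_perm <- random_walk_with_restart(tm, p0, cfg)
    theta <- theta + (p_perm[names(theta)] > true_p)
  }
  structure(list(
    table = data.frame(gene = rwr_genes$gene,
                       probability = rwr_genes$probability,
                       theta = as.integer(theta),
                       p_value = as.numeric(theta) / n_perm,
                       stringsAsFactors = FALSE),
    n_perm = n_perm, rng_seed = rng_seed, perm_sets = perm_sets),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d genes, %d permutations (p resolution %g)\n",
              nrow(x$table), x$n_perm, 1 / x$n_perm))
  invisible(x)
}

#' Filter RWR genes on the permutation p-value
#'
#' Keeps genes with `p` strictly below `alpha`, ordered by p-value ascending,
#' then probability descending, then identifier.
#'
#' @param pvals a [permutation_pvalues()] result.
#' @param alpha significance level in `(0, 1]` (default 0.05).
#' @return data frame with columns `gene`, `probability`, `p_value`.
#' @export
filter_candidates <- function(pvals, alpha = 0.05) {
  stopifnot(inherits(pvals, "permutation_result"), alpha > 0, alpha <= 1)
  tab <- pvals$table
  tab <- tab[tab$p_value < alpha, c("gene", "probability", "p_value")]
  o <- order(tab$p_value, -tab$probability, tab$gene, method = "radix")
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Render a permutation p-value the way reports print it
#'
#' A p-value of exactly 0 means the true probability exceeded every
#' permutation, which is reported as below the test's resolution, e.g.
#' `"<0.001"` at 1000 permutations.
#'
#' @param p numeric p-values on the grid `{0, 1/n_perm, ..., 1}`.
#' @param n_perm number of permutations behind the p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p, n_perm) {
  ifelse(p == 0,
         paste0("<", format(1 / n_perm, scientific = FALSE, trim = TRUE)),
         format(p, scientific = FALSE, trim = TRUE))
}
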