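#' Random-walk-with-restart configuration
#'
#' Bundles the tunable parameters of the walk. The defaults are the standard
#' settings for disease-gene prioritization on a STRING-scale interactome:
#' restart probability 0.8, L1 convergence tolerance 1e-6, stationary
#' probability threshold 1e-5 for calling a gene an "RWR gene", and an
#' iteration cap of 10000 (a safety net; convergence is geometric at rate
#' `1 - restart`).
#'
#' @param restart restart probability `r` in `(0, 1]`: the fraction of walk
#'   mass teleported back to the seed distribution at every step.
#' @param tol L1 convergence tolerance between successive iterates.
#' @param prob_threshold stationary probability above which a gene is
#'   selected.
#' @param max_iter maximum number of update steps before giving up.
#' @return list of class `rwr_config`.
#' @export
rwr_config <- function(restart = 0.8, tol = 1e-6, prob_threshold = 1e-5,
                       max_iter = 10000L) {
  stopifnot(restart > 0, restart <= 1, tol > 0, prob_threshold > 0,
            max_iter >= 1)
  structure(list(restart = restart, tol = tol,
                 prob_threshold = prob_threshold,
                 max_iter = as.integer(max_iter)),
            class = "rwr_config")
}

#' Initial probability vector over seeds
#'
#' Places mass `1/|seeds|` on each seed node and 0 elsewhere, in the node
#' ordering of the network.
#'
#' @param net a [weighted_network()].
#' @param seeds a [seed_set()] (or character vector of in-network IDs).
#' @return named numeric vector summing to 1, one entry per network node.
#' @export
build_initial_vector <- function(net, seeds) {
  stopifnot(inherits(net, "weighted_network"))
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else as.character(seeds)
  if (length(ids) == 0) stop("seed set is empty")
  if (!all(ids %in% net$nodes)) {
    stop("seed identifier(s) absent from the network: ",
         paste(setdiff(ids, net$nodes), collapse = ", "))
  }
  p0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  p0[ids] <- 1 / length(ids)
  p0
}

#' Random walk with restart
#'
#' Iterates `P_{i+1} = (1 - r) A P_i + r P_0` until the L1 distance between
#' successive iterates drops below `cfg$tol`, and returns the first iterate
#' past that point. The column-stochastic matrix `A` pushes the walker's
#' distribution forward one step (entry `(i, j)` is the probability of
#' stepping from `j` to `i`, proportional to the edge score); equivalently
#' this is the transpose of the row-normalized transition matrix applied to
#' the probability column vector, the form in which the update is usually
#' written. Because `A`'s columns sum to 1 and `P_0` sums to 1, every
#' iterate is a probability vector; the fixed point scores each node's
#' network proximity to the seed distribution.
#'
#' @param tm a [column_normalize()] transition model.
#' @param p0 initial probability vector sharing `tm`'s node ordering.
#' @param cfg an [rwr_config()].
#' @return named numeric probability vector with attribute `iterations`.
#' @export
random_walk_with_restart <- function(tm, p0, cfg = rwr_config()) {
  stopifnot(inherits(tm, "transition_model"), inherits(cfg, "rwr_config"))
  if (length(p0) != length(tm$nodes) || !identical(names(p0), tm$nodes)) {
    stop("p0 must share the transition model's node ordering")
  }
  r <- cfg$restart
  A <- tm$A
  p <- p0
  for (it in seq_len(cfg$max_iter)) {
    p_new <- as.numeric((1 - r) * (A %*% p)) + r * p0
    delta <- sum(abs(p_new - p))
    if (delta < cfg$tol) {
      names(p_new) <- tm$nodes
      attr(p_new, "iterations") <- it
      return(p_new)
    }
    p <- p_new
  }
  stop(sprintf("RWR did not converge in %d iterations (last L1 residual %.3e)",
               cfg$max_iter, delta))
}

#' Select RWR genes above the probability threshold
#'
#' Genes whose stationary probability is strictly greater than `threshold`
#' are selected, sorted by probability descending with ties broken by
#' identifier; seed genes are excluded by default, since the goal is novel
#' candidates.
#'
#' @param p probability vector from [random_walk_with_restart()].
#' @param seeds a [seed_set()] or character vector.
#' @param threshold stationary probability cutoff (strict `>`).
#' @param exclude_seeds drop the seed genes from the list (default `TRUE`).
#' @return data frame with columns `gene`, `probability`, ordered as above.
#' @export
select_rwr_genes <- function(p, seeds, threshold = 1e-5,
                             exclude_seeds = TRUE) {
  stopifnot(threshold > 0)
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else as.character(seeds)
  keep <- p > threshold
  if (exclude_seeds) keep <- keep & !(names(p) %in% ids)
  genes <- names(p)[keep]
  prob <- unname(p[keep])
  o <- order(-prob, genes, method = "radix")
  data.frame(gene = genes[o], probability = prob[o],
             stringsAsFactors = FALSE)
}
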