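# Shared fixtures and independent oracles. Oracles deliberately avoid the
# code paths they check: dense base-R linear algebra for the walk,
# combinatorial enumeration for the hypergeometric tail.

toy_edges <- function(...) {
  d <- data.frame(...)
  names(d) <- c("from", "to", "score")
  d$score <- as.integer(d$score)
  d
}

# path a - b - c with scores 2s, s
path_network <- function(scale = 150L) {
  weighted_network(toy_edges(
    from = c("9606.a", "9606.b"),
    to = c("9606.b", "9606.c"),
    score = c(2L * scale, scale)))
}

# random connected-enough test network via the generator (validated type)
random_test_network <- function(n, seed) {
  spec <- synthetic_spec(n_nodes = n, module_size = max(2L, n %/% 5L),
                         rng_seed = seed)
  generate_network(spec)$network
}

# dense linear-solve fixed point: (I - (1 - r) A) P = r P0
dense_rwr_oracle <- function(tm, p0, r) {
  A <- as.matrix(tm$A)
  sol <- solve(diag(nrow(A)) - (1 - r) * A, r * p0)
  stats::setNames(as.numeric(sol), tm$nodes)
}

# exact hypergeometric upper tail P(X >= q) by enumeration over the support
enum_hyper_tail <- function(q, num_w, num_b, num_drawn) {
  ks <- max(q, 0):min(num_w, num_drawn)
  if (length(ks) == 0 || max(q, 0) > min(num_w, num_drawn)) return(0)
  sum(choose(num_w, ks) * choose(num_b, num_drawn - ks)) /
    choose(num_w + num_b, num_drawn)
}

# standard desk-scale fixture: network + annotations + seed split
planted_fixture <- function(rng_seed, n_nodes = 200L, seed_fraction = 0.5) {
  spec <- synthetic_spec(n_nodes = n_nodes,
                         module_size = min(10L, n_nodes %/% 2L),
                         rng_seed = rng_seed)
  gen <- generate_network(spec)
  ann <- generate_annotations(gen$network, gen$truth, spec)
  split <- split_module_seeds(ann$truth, seed_fraction, rng_seed + 1000L)
  list(spec = spec, network = gen$network, annotations = ann$annotations,
       truth = ann$truth, split = split)
}

# pipeline configuration at fixture scale: fewer permutations, looser
# probability threshold than the full-interactome defaults
fixture_config <- function(rng_seed = 1L, n_permutations = 200L) {
  pipeline_config(prob_threshold = 1e-4, n_permutations = n_permutations,
                  rng_seed = rng_seed)
}
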