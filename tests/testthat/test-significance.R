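test_that("permutation p-values equal an explicit re-run-per-permutation loop", {
  fix <- planted_fixture(3L, n_nodes = 10L)
  net <- fix$network
  tm <- column_normalize(net)
  seeds <- seed_set(net$nodes[1:3])
  cfg <- rwr_config(prob_threshold = 1e-4)
  p_true <- random_walk_with_restart(tm, build_initial_vector(net, seeds), cfg)
  rwr_genes <- select_rwr_genes(p_true, seeds, 1e-4)

  n_perm <- 10L
  perm_sets <- withr::with_seed(99L, lapply(seq_len(n_perm), function(i)
    sample(net$nodes, length(seeds$ids))))

  # oracle: brute-force loop re-running the walk per permutation and counting
  # strict exceedances gene by gene with explicit nested loops
  theta_oracle <- stats::setNames(integer(nrow(rwr_genes)), rwr_genes$gene)
  for (s in perm_sets) {
    pp <- random_walk_with_restart(tm, build_initial_vector(net, s), cfg)
    for (g in rwr_genes$gene) {
      if (pp[g] > p_true[g]) theta_oracle[g] <- theta_oracle[g] + 1L
    }
  }

  res <- permutation_pvalues(net, tm, seeds, rwr_genes, cfg,
                             n_perm = n_perm, perm_sets = perm_sets)
  expect_equal(stats::setNames(res$table$theta, res$table$gene), theta_oracle)
  expect_equal(res$table$p_value, unname(theta_oracle) / n_perm)
})

test_that("p-values are reproducible from the rng seed and lie on the grid", {
  fix <- planted_fixture(5L, n_nodes = 30L)
  tm <- column_normalize(fix$network)
  seeds <- seed_set(fix$split$seeds)
  cfg <- rwr_config(prob_threshold = 1e-4)
  p <- random_walk_with_restart(tm, build_initial_vector(fix$network, seeds),
                                cfg)
  rwr_genes <- select_rwr_genes(p, seeds, 1e-4)
  a <- permutation_pvalues(fix$network, tm, seeds, rwr_genes, cfg,
                           n_perm = 25L, rng_seed = 7L)
  b <- permutation_pvalues(fix$network, tm, seeds, rwr_genes, cfg,
                           n_perm = 25L, rng_seed = 7L)
  expect_identical(a$table, b$table)
  expect_identical(a$perm_sets, b$perm_sets)
  expect_true(all(abs(a$table$p_value * 25 -
                        round(a$table$p_value * 25)) < 1e-9))
  expect_true(all(a$table$p_value >= 0 & a$table$p_value <= 1))
  expect_error(permutation_pvalues(fix$network, tm, seeds, rwr_genes, cfg,
                                   n_perm = 0L), "at least 1")
})

test_that("theta counting is strict and anti-monotone in the true probability", {
  # fixed permutation probabilities; only the true probability varies
  perm_p <- c(0.5, 0.3, 0.3, 0.1)
  count_theta <- function(true_p) sum(perm_p > true_p)
  expect_equal(count_theta(0.3), 1L)   # ties do not count
  expect_equal(count_theta(0.05), 4L)
  expect_equal(count_theta(0.9), 0L)
  grid <- seq(0, 1, by = 0.01)
  thetas <- vapply(grid, count_theta, numeric(1))
  expect_true(all(diff(thetas) <= 0))

  # the same strictness inside the implementation: a gene whose probability
  # dominates every permutation gets p = 0, a dominated gene gets p = 1
  net <- path_network()
  tm <- column_normalize(net)
  seeds <- seed_set("9606.a")
  cfg <- rwr_config(prob_threshold = 1e-6)
  p <- random_walk_with_restart(tm, build_initial_vector(net, seeds), cfg)
  rwr <- select_rwr_genes(p, seeds, 1e-6)
  res <- permutation_pvalues(net, tm, seeds, rwr, cfg, n_perm = 4L,
                             perm_sets = rep(list("9606.a"), 4))
  # permutations re-seed the true seed: identical probabilities, no strict
  # exceedance anywhere
  expect_true(all(res$table$p_value == 0))
})

test_that("under a null seed set the p-value distribution is not anti-conservative", {
  fix <- planted_fixture(11L, n_nodes = 100L)
  net <- fix$network
  tm <- column_normalize(net)
  null_seeds <- seed_set(withr::with_seed(2L, sample(net$nodes, 5L)))
  cfg <- rwr_config(prob_threshold = 1e-12)
  p <- random_walk_with_restart(tm, build_initial_vector(net, null_seeds), cfg)
  # score every non-seed gene: thresholding on the walk probability selects
  # for small p-values by construction, so calibration is assessed unselected
  rwr_genes <- select_rwr_genes(p, null_seeds, 1e-12)
  res <- permutation_pvalues(net, tm, null_seeds, rwr_genes, cfg,
                             n_perm = 200L, rng_seed = 31L)
  pv <- res$table$p_value
  # stochastically no smaller than uniform: the empirical CDF should not
  # exceed the uniform CDF by more than sampling noise at any cut
  for (q in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(pv <= q), q + 0.12)
  }
})

test_that("filter_candidates applies a strict alpha and stable ordering", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    probability = c(0.4, 0.3, 0.2, 0.5),
                    theta = c(0L, 5L, 1L, 10L),
                    p_value = c(0, 0.05, 0.01, 0.1))
  res <- structure(list(table = tab, n_perm = 100L, rng_seed = 1L,
                        perm_sets = list()), class = "permutation_result")
  out <- filter_candidates(res, alpha = 0.05)
  # p exactly at alpha is excluded; order by p then probability
  expect_equal(out$gene, c("g1", "g3"))
  empty <- res; empty$table <- tab[0, ]
  expect_equal(nrow(filter_candidates(empty, 0.05)), 0L)
})

test_that("p-values below resolution render as a bound", {
  expect_equal(format_pvalue(c(0, 0.002, 0.05), 1000L),
               c("<0.001", "0.002", "0.050"))
  expect_equal(format_pvalue(0, 200L), "<0.005")
})
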