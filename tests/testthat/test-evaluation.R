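test_that("kfold_partition deals near-equal disjoint parts deterministically", {
  ids <- sprintf("id%03d", 1:146)
  parts <- kfold_partition(ids, 5L, rng_seed = 3L)
  expect_equal(sort(lengths(parts)), c(29L, 29L, 29L, 29L, 30L))
  expect_setequal(unlist(parts), ids)
  expect_equal(sum(lengths(parts)), 146L)
  expect_identical(parts, kfold_partition(ids, 5L, rng_seed = 3L))
  expect_false(identical(parts, kfold_partition(ids, 5L, rng_seed = 4L)))

  small <- kfold_partition(sprintf("g%02d", 1:10), 5L, 1L)
  expect_equal(lengths(small), rep(2L, 5))
  expect_equal(anyDuplicated(unlist(small)), 0L)
  expect_error(kfold_partition(sprintf("g%02d", 1:4), 5L, 1L), "exceeds")
  expect_error(kfold_partition(letters, 1L, 1L), "at least 2")
})

test_that("prf1 reproduces the reported fold arithmetic and set conventions", {
  # counts chosen to give recall 0.400, precision 0.211 (a reported fold)
  held_out <- sprintf("h%02d", 1:30)
  predicted <- c(held_out[1:12], sprintf("fp%02d", 1:45))
  m <- prf1(predicted, held_out)
  expect_equal(m$recall, 12 / 30)
  expect_equal(round(m$precision, 3), 0.211)
  expect_equal(round(m$f1, 3), 0.276)

  perfect <- prf1(c("a", "b"), c("b", "a"))
  expect_equal(c(perfect$recall, perfect$precision, perfect$f1), c(1, 1, 1))
  none <- prf1(c("x", "y"), c("a", "b"))
  expect_equal(c(none$recall, none$precision, none$f1), c(0, 0, 0))
  # set semantics: duplicates and order are irrelevant
  expect_equal(prf1(c("b", "a", "a"), c("a", "b")), perfect)
  # empty prediction
  empty <- prf1(character(0), c("a"))
  expect_equal(c(empty$recall, empty$precision, empty$f1), c(0, 0, 0))
})

test_that("f1 is the harmonic mean, bounded by the arithmetic mean", {
  expect_equal(f1_measure(0.5, 0.5), 0.5)
  expect_equal(f1_measure(0, 0), 0)
  for (i in 1:50) {
    rp <- withr::with_seed(i, stats::runif(2))
    f1 <- f1_measure(rp[1], rp[2])
    expect_lte(f1, mean(rp) + 1e-12)
    expect_gte(f1, 0)
  }
  expect_equal(f1_measure(0.3, 0.3), 0.3)
})

test_that("gba_predict ranks neighbors by weight, truncates, and unions", {
  net <- weighted_network(toy_edges(
    c("s", "s", "s", "t", "t"),
    c("a", "b", "c", "a", "d"),
    c(900L, 800L, 700L, 950L, 300L)))
  expect_equal(gba_predict(net, "s", 2L), c("a", "b"))
  # k at or above the max degree returns all non-seed neighbors
  expect_setequal(gba_predict(net, "s", 10L), c("a", "b", "c"))
  expect_setequal(gba_predict(net, c("s", "t"), 10L), c("a", "b", "c", "d"))
  # shared top neighbors appear once; seeds are excluded from predictions
  both <- gba_predict(net, c("s", "t"), 1L)
  expect_equal(both, "a")
  # ties at the k-th rank break by identifier
  tie_net <- weighted_network(toy_edges(
    c("s", "s", "s"), c("z", "m", "q"), c(500L, 500L, 500L)))
  expect_equal(gba_predict(tie_net, "s", 2L), c("m", "q"))
})

test_that("gba predictions grow with k and stay within k * |seeds|", {
  fix <- planted_fixture(31L, n_nodes = 60L)
  seeds <- fix$split$seeds
  sizes <- vapply(c(1L, 2L, 4L, 8L, 16L), function(k) {
    pred <- gba_predict(fix$network, seeds, k)
    expect_lte(length(pred), k * length(seeds))
    length(pred)
  }, integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("cross_validate isolates folds and averages fold metrics", {
  ids <- sprintf("id%02d", 1:30)
  # leakage canary: a memorizing predictor that returns everything except
  # its training seeds scores perfect recall on every fold
  memorizer <- function(training) setdiff(ids, training)
  cv <- cross_validate(memorizer, ids, 5L, rng_seed = 2L)
  expect_equal(cv$folds$recall, rep(1, 5))
  expect_equal(cv$folds$precision, rep(1, 5))
  expect_equal(unname(cv$means["f1"]), 1)

  # empty predictor scores zero everywhere
  cv0 <- cross_validate(function(training) character(0), ids, 5L, 2L)
  expect_true(all(cv0$folds[, c("recall", "precision", "f1")] == 0))

  # predict-everything: recall 1, precision = |fold| / |non-training nodes|
  universe <- c(ids, sprintf("bg%02d", 1:30))
  everything <- function(training) setdiff(universe, training)
  cve <- cross_validate(everything, ids, 5L, 2L)
  expect_equal(cve$folds$recall, rep(1, 5))
  expect_equal(cve$folds$precision, rep(6 / 36, 5))
})

test_that("the pipeline predictor recovers held-out seeds under cross-validation", {
  fix <- planted_fixture(33L)
  predictor <- rwr_predictor(fix$network, fix$annotations, fixture_config(4L))
  cv <- cross_validate(predictor, fix$truth$module, k_folds = 2L,
                       rng_seed = 6L)
  expect_equal(nrow(cv$folds), 2L)
  expect_gte(unname(cv$means["recall"]), 0.2)
  expect_true(all(cv$folds$f1 >= 0 & cv$folds$f1 <= 1))
})

test_that("gba_grid_search reports per-fold metrics and the smallest best k", {
  fix <- planted_fixture(34L, n_nodes = 60L)
  gs <- gba_grid_search(fix$network, fix$truth$module,
                        k_grid = c(1L, 3L, 5L), k_folds = 2L, rng_seed = 9L)
  expect_equal(nrow(gs$per_k), 6L)
  expect_equal(nrow(gs$best), 2L)
  expect_true(all(gs$best$k %in% c(1L, 3L, 5L)))
  for (i in 1:2) {
    fold_rows <- gs$per_k[gs$per_k$fold == i, ]
    expect_equal(gs$best$f1[i], max(fold_rows$f1))
    # ties break toward the smallest k
    expect_equal(gs$best$k[i],
                 min(fold_rows$k[fold_rows$f1 == max(fold_rows$f1)]))
  }
  # the default grid is the standard 19-value grid
  expect_equal(length(formals(gba_grid_search)$k_grid |> eval()), 19L)
  # a single-value grid is trivially best everywhere
  g1 <- gba_grid_search(fix$network, fix$truth$module, k_grid = 1L,
                        k_folds = 2L, rng_seed = 9L)
  expect_true(all(g1$best$k == 1L))
})

test_that("a constructed second-neighbor module makes k = 3 beat k = 1", {
  # seed s: nearest neighbor is a decoy hub; the held-out genes sit at
  # ranks 2-3, so F1 must strictly improve from k = 1 to k = 3
  net <- weighted_network(toy_edges(
    c("s", "s", "s", "s"),
    c("decoy", "h1", "h2", "bg"),
    c(999L, 900L, 850L, 200L)))
  m1 <- prf1(gba_predict(net, "s", 1L), c("h1", "h2"))
  m3 <- prf1(gba_predict(net, "s", 3L), c("h1", "h2"))
  expect_gt(m3$f1, m1$f1)
})

test_that("reference cross-validation table is internally consistent", {
  ref <- uveitis_cv_reference
  expect_equal(dim(ref), c(10L, 6L))
  rwr <- ref[ref$method == "rwr", ]
  # reported means of the full-scale analysis
  expect_equal(round(mean(rwr$recall), 3), 0.287)
  expect_equal(round(mean(rwr$precision), 3), 0.141)
  expect_equal(round(mean(rwr$f1), 3), 0.189)
  # the RWR pipeline dominates the baseline on F1 in every fold
  gba <- ref[ref$method == "gba", ]
  expect_true(all(rwr$f1 > gba$f1))
})
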