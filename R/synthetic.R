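#' Specification of a synthetic benchmark network
#'
#' Describes a desk-scale network with a planted disease module: an
#' Erdos-Renyi background at low edge probability and low STRING-style
#' scores, plus a densely connected module whose internal edges carry
#' high-confidence scores, and an annotation layer in which "module terms"
#' annotate most module genes. This emulates the structure the
#' prioritization method assumes — disease genes form a high-confidence,
#' functionally coherent neighborhood — at a size where everything runs in
#' seconds. It makes no attempt to mimic the degree distribution or size of
#' a real interactome.
#'
#' @param n_nodes total node count.
#' @param module_size planted module size (< n_nodes).
#' @param p_intra edge probability within the module.
#' @param intra_scores integer range (length 2) of module edge scores.
#' @param p_background background edge probability.
#' @param background_scores integer range of background edge scores.
#' @param n_terms number of background annotation terms.
#' @param n_module_terms number of module-specific terms.
#' @param module_term_fraction fraction of module genes each module term
#'   annotates.
#' @param rng_seed integer seed; the whole fixture is a deterministic
#'   function of the spec.
#' @param organism organism code used to prefix node identifiers so
#'   generated files exercise the real parsers.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 60L, module_size = 10L, p_intra = 0.8,
                           intra_scores = c(850L, 999L), p_background = 0.05,
                           background_scores = c(150L, 500L), n_terms = 20L,
                           n_module_terms = 3L, module_term_fraction = 0.8,
                           rng_seed = 1L, organism = "9606") {
  stopifnot(module_size < n_nodes, module_size >= 2,
            p_intra > 0, p_intra <= 1, p_background > 0, p_background <= 1,
            all(intra_scores >= 150), all(intra_scores <= 999),
            all(background_scores >= 150), all(background_scores <= 999),
            module_term_fraction > 0, module_term_fraction <= 1)
  structure(list(n_nodes = as.integer(n_nodes),
                 module_size = as.integer(module_size),
                 p_intra = p_intra, intra_scores = as.integer(intra_scores),
                 p_background = p_background,
                 background_scores = as.integer(background_scores),
                 n_terms = as.integer(n_terms),
                 n_module_terms = as.integer(n_module_terms),
                 module_term_fraction = module_term_fraction,
                 rng_seed = as.integer(rng_seed), organism = organism),
            class = "synthetic_spec")
}

#' Generate a synthetic network with a planted module
#'
#' Draws the Erdos-Renyi background and the dense planted module described
#' by the spec. A spanning cycle over the module guarantees its
#' connectivity, and any isolated node receives one background edge, so the
#' result always satisfies the network invariants (all scores in
#' `[150, 999]`, no self-loops, no isolated nodes). Node identifiers are
#' synthetic (`<organism>.SYNP####`).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (a [weighted_network()]) and `truth` (list
#'   with `module` gene IDs and, after [generate_annotations()], the
#'   `module_terms`).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$rng_seed, {
    nodes <- sprintf("%s.SYNP%04d", spec$organism, seq_len(spec$n_nodes))
    module <- sort(sample(nodes, spec$module_size), method = "radix")
    pairs <- utils::combn(nodes, 2)
    from <- pairs[1, ]; to <- pairs[2, ]
    in_module <- from %in% module & to %in% module
    p_edge <- ifelse(in_module, spec$p_intra, spec$p_background)
    present <- stats::runif(length(from)) < p_edge
    score <- integer(length(from))
    score[in_module] <- sample(spec$intra_scores[1]:spec$intra_scores[2],
                               sum(in_module), replace = TRUE)
    score[!in_module] <- sample(
      spec$background_scores[1]:spec$background_scores[2],
      sum(!in_module), replace = TRUE)
    edges <- data.frame(from = from[present], to = to[present],
                        score = score[present], stringsAsFactors = FALSE)
    # spanning cycle keeps the module connected
    ring <- sample(module)
    ring_from <- ring
    ring_to <- c(ring[-1], ring[1])
    ring_edges <- data.frame(
      from = pmin(ring_from, ring_to), to = pmax(ring_from, ring_to),
      score = sample(spec$intra_scores[1]:spec$intra_scores[2],
                     length(ring), replace = TRUE),
      stringsAsFactors = FALSE)
    key <- function(d) paste(d$from, d$to)
    edges <- rbind(edges, ring_edges[!key(ring_edges) %in% key(edges), ])
    # attach isolated nodes with one background edge
    lonely <- setdiff(nodes, unique(c(edges$from, edges$to)))
    for (v in lonely) {
      w <- sample(setdiff(nodes, v), 1)
      edges <- rbind(edges, data.frame(
        from = min(v, w), to = max(v, w),
        score = sample(spec$background_scores[1]:spec$background_scores[2], 1),
        stringsAsFactors = FALSE))
    }
    edges <- edges[!duplicated(key(edges)), ]
    list(network = weighted_network(edges),
         truth = list(module = module, module_terms = character()))
  })
}

#' Generate annotations consistent with the planted module
#'
#' Module terms each annotate a random `module_term_fraction` of the module
#' genes plus a couple of random background genes (annotation is never
#' perfectly clean); background terms annotate random gene sets of size 3 to
#' 10. Every term annotates at least one gene. This layer is what gives
#' module genes mutually similar enrichment profiles, the structure the
#' functional-similarity filter exploits.
#'
#' @param net the generated [weighted_network()].
#' @param truth the truth list from [generate_network()].
#' @param spec the same [synthetic_spec()].
#' @return list with `annotations` (an [annotation_map()], possibly empty
#'   when `n_terms + n_module_terms` is 0) and the updated `truth` carrying
#'   `module_terms`.
#' @export
generate_annotations <- function(net, truth, spec) {
  stopifnot(inherits(net, "weighted_network"), inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$rng_seed + 1L, {
    genes <- list(); desc <- character()
    module_terms <- character()
    if (spec$n_module_terms > 0) {
      n_ann <- max(1L, ceiling(spec$module_term_fraction *
                                 length(truth$module)))
      for (i in seq_len(spec$n_module_terms)) {
        term <- sprintf("MT%03d", i)
        module_terms <- c(module_terms, term)
        extra <- sample(setdiff(net$nodes, truth$module),
                        min(2L, spec$n_nodes - length(truth$module)))
        genes[[term]] <- unique(c(sample(truth$module, n_ann), extra))
        desc[term] <- sprintf("synthetic module term %d", i)
      }
    }
    if (spec$n_terms > 0) {
      for (i in seq_len(spec$n_terms)) {
        term <- sprintf("BT%03d", i)
        genes[[term]] <- sample(net$nodes,
                                sample(3:min(10, length(net$nodes)), 1))
        desc[term] <- sprintf("synthetic background term %d", i)
      }
    }
    truth$module_terms <- module_terms
    if (length(genes) == 0) {
      return(list(annotations = structure(list(genes = list(),
                                               descriptions = character()),
                                          class = "annotation_map"),
                  truth = truth))
    }
    list(annotations = annotation_map(genes, desc), truth = truth)
  })
}

#' Split the planted module into seeded and held-out halves
#'
#' Mirrors the cross-validation design at fixture scale: a random fraction
#' of the module plays the validated seed genes, the rest are the held-out
#' genes the pipeline should recover. The seeded side gets
#' `floor(fraction * module size)` genes, clamped so both sides keep at
#' least one gene; a fraction so extreme that clamping cannot help is an
#' error.
#'
#' @param truth truth list carrying `module`.
#' @param fraction fraction of module genes used as seeds, in `(0, 1)`.
#' @param rng_seed integer seed.
#' @return list with `seeds` and `held_out` character vectors.
#' @export
split_module_seeds <- function(truth, fraction = 0.5, rng_seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  m <- length(truth$module)
  if (m < 2) stop("module too small to split")
  n_seed <- min(max(floor(fraction * m), 1L), m - 1L)
  withr::with_seed(rng_seed, {
    seeded <- sample(truth$module, n_seed)
  })
  list(seeds = sort(seeded, method = "radix"),
       held_out = sort(setdiff(truth$module, seeded), method = "radix"))
}

#' Write a complete synthetic fixture to disk
#'
#' Generates network, annotations and seed split from the spec and writes
#' them in the exact external formats the parsers read — a STRING-style
#' links file (each edge listed in both directions, as STRING does), a
#' one-ID-per-line seed list, a GMT annotation file — plus a JSON truth file
#' recording the planted module. Tests and users can then exercise the real
#' parsers end to end.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param seed_fraction fraction of the module written as seeds.
#' @return named list of the four file paths, invisibly; also returns the
#'   in-memory objects in `$objects`.
#' @export
write_synthetic_fixtures <- function(spec, dir, seed_fraction = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_network(spec)
  ann <- generate_annotations(gen$network, gen$truth, spec)
  split <- split_module_seeds(ann$truth, seed_fraction, spec$rng_seed + 2L)
  links <- file.path(dir, "links.txt")
  e <- gen$network$edges
  writeLines(c("protein1 protein2 combined_score",
               paste(e$from, e$to, e$score),
               paste(e$to, e$from, e$score)), links)
  seeds_path <- file.path(dir, "seeds.txt")
  writeLines(c("# synthetic seed genes (planted module, seeded half)",
               split$seeds), seeds_path)
  gmt <- file.path(dir, "annotations.gmt")
  a <- ann$annotations
  writeLines(vapply(names(a$genes), function(t)
    paste(c(t, a$descriptions[[t]], a$genes[[t]]), collapse = "\t"),
    character(1)), gmt)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(module = ann$truth$module,
                            module_terms = ann$truth$module_terms,
                            seeds = split$seeds,
                            held_out = split$held_out),
                       truth_path, pretty = TRUE)
  invisible(list(links = links, seeds = seeds_path, annotations = gmt,
                 truth = truth_path,
                 objects = list(network = gen$network,
                                annotations = ann$annotations,
                                truth = ann$truth, split = split)))
}
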