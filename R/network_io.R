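#' Weighted protein-interaction network
#'
#' Constructs the in-memory network object used throughout the package: an
#' undirected graph over protein/gene identifiers with one integer STRING-style
#' combined score per edge. Scores must lie in `[150, 999]`, self-loops are
#' forbidden, each unordered pair is stored once, and every node participates
#' in at least one edge (networks are defined by their edge lists).
#'
#' @param edges data frame with character columns `from`, `to` and an integer
#'   column `score`. Pair orientation is normalized internally so that
#'   `from < to`.
#' @param n_directed_records optional count of directed input records the
#'   edges were collapsed from (STRING files list each interaction twice);
#'   defaults to `2 * nrow(edges)`.
#' @return An object of class `weighted_network` with elements `nodes`
#'   (sorted character vector), `edges` (normalized data frame) and
#'   `n_directed_records`.
#' @examples
#' net <- weighted_network(data.frame(
#'   from = c("9606.A", "9606.B"), to = c("9606.B", "9606.C"),
#'   score = c(900L, 400L)))
#' net$nodes
#' @export
weighted_network <- function(edges, n_directed_records = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "score") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (any(edges$from == edges$to)) {
    stop("self-loops are not allowed in a weighted_network")
  }
  score <- edges$score
  if (any(is.na(score)) || any(score != round(score))) {
    stop("edge scores must be integers")
  }
  if (nrow(edges) > 0 && (min(score) < 150 || max(score) > 999)) {
    stop("edge scores must lie in [150, 999]")
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(as.integer(score), key, function(s) length(unique(s)))
    if (any(agg > 1)) {
      bad <- names(agg)[agg > 1][1]
      stop("conflicting scores for edge ", gsub("\r", " -- ", bad))
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }
  o <- order(a, b, method = "radix")
  edges <- data.frame(from = a[o], to = b[o], score = as.integer(score[o]),
                      stringsAsFactors = FALSE)
  structure(
    list(nodes = sort(unique(c(edges$from, edges$to)), method = "radix"),
         edges = edges,
         n_directed_records = if (is.null(n_directed_records))
           2L * nrow(edges) else as.integer(n_directed_records)),
    class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network: %d nodes, %d undirected edges (%d directed records)\n",
              length(x$nodes), nrow(x$edges), x$n_directed_records))
  invisible(x)
}

# Accept a file path, a connection, or already-split lines; a single string
# counts as content when it embeds newlines/tabs or names no existing file.
read_input_lines <- function(path) {
  if (!is.character(path)) return(readLines(path))
  if (length(path) != 1) return(path)
  if (grepl("\n", path)) return(strsplit(path, "\n")[[1]])
  if (file.exists(path)) return(readLines(path))
  path
}

#' Parse a STRING protein.links edge list
#'
#' Reads the whitespace-separated three-column dialect of STRING's
#' `protein.links` files (`protein1 protein2 combined_score`). Only records
#' whose two protein identifiers both start with `organism` followed by a dot
#' (e.g. `9606.` for human) are kept; the organism prefix is retained in node
#' identifiers. STRING lists every interaction in both directions: the two
#' directed records of a pair are collapsed to one undirected edge and their
#' scores must agree. Self-loop records are dropped with a warning. An
#' optional header line beginning with `protein1` is skipped.
#'
#' @param path file path or connection, or a character vector of lines.
#' @param organism organism code prefix used for filtering, default `"9606"`.
#' @return A [weighted_network()]; its `n_directed_records` element counts the
#'   organism-matching non-self-loop records before collapsing.
#' @export
parse_string_links <- function(path, organism = "9606") {
  stopifnot(is.character(organism), nzchar(organism))
  lines <- read_input_lines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) > 0 && startsWith(trimws(lines[1]), "protein1")) {
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  if (length(lines) == 0) {
    return(weighted_network(
      data.frame(from = character(), to = character(), score = integer()),
      n_directed_records = 0L))
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf != 3)) {
    i <- which(nf != 3)[1]
    stop(sprintf("line %d: expected 3 whitespace-separated fields, found %d",
                 lineno[i], nf[i]))
  }
  m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  score <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(score)) {
    i <- which(is.na(score))[1]
    stop(sprintf("line %d: non-numeric score '%s'", lineno[i], m[i, 3]))
  }
  prefix <- paste0(organism, ".")
  org <- startsWith(m[, 1], prefix) & startsWith(m[, 2], prefix)
  m <- m[org, , drop = FALSE]; score <- score[org]; lineno <- lineno[org]
  if (any(score != round(score) | score < 150 | score > 999)) {
    i <- which(score != round(score) | score < 150 | score > 999)[1]
    stop(sprintf("line %d: score %s outside the STRING range [150, 999]",
                 lineno[i], format(score[i])))
  }
  self <- m[, 1] == m[, 2]
  if (any(self)) {
    warning(sprintf("dropped %d self-loop record(s)", sum(self)))
    m <- m[!self, , drop = FALSE]; score <- score[!self]
  }
  weighted_network(
    data.frame(from = m[, 1], to = m[, 2], score = as.integer(score),
               stringsAsFactors = FALSE),
    n_directed_records = nrow(m))
}

#' Write a network back to the three-column STRING format
#'
#' Each undirected edge is written once as `from to score`; re-parsing with
#' [parse_string_links()] and the matching organism code reproduces the
#' network exactly.
#'
#' @param net a [weighted_network()].
#' @param path output file path.
#' @param header write the `protein1 protein2 combined_score` header line.
#' @export
write_string_links <- function(net, path, header = TRUE) {
  stopifnot(inherits(net, "weighted_network"))
  out <- paste(net$edges$from, net$edges$to, net$edges$score)
  if (header) out <- c("protein1 protein2 combined_score", out)
  writeLines(out, path)
  invisible(path)
}

#' Symmetric score matrix of a network
#'
#' @param net a [weighted_network()].
#' @return sparse symmetric numeric matrix (class `dgCMatrix`) with node
#'   identifiers as dimnames and STRING scores as entries.
#' @keywords internal
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- length(net$nodes)
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = as.numeric(c(net$edges$score, net$edges$score)),
                       dims = c(n, n), dimnames = list(net$nodes, net$nodes))
}

#' Direct neighbors of a gene
#'
#' @param net a [weighted_network()].
#' @param gene node identifier.
#' @return named numeric vector of edge scores, names are neighbor IDs.
#' @export
network_neighbors <- function(net, gene) {
  stopifnot(inherits(net, "weighted_network"))
  if (!gene %in% net$nodes) stop("gene '", gene, "' absent from network")
  e <- net$edges
  hit <- e$from == gene | e$to == gene
  other <- ifelse(e$from[hit] == gene, e$to[hit], e$from[hit])
  stats::setNames(as.numeric(e$score[hit]), other)
}

#' Column-normalized transition model
#'
#' Builds the column-stochastic matrix `A` of the walk: entry `(i, j)` is
#' `S(i, j) / sum_k S(k, j)`, the probability that a walker at node `j` steps
#' to neighbor `i`, proportional to the STRING combined score of the edge.
#' Because every node of a [weighted_network()] has at least one edge, no
#' column is dangling and every column sums to exactly 1.
#'
#' @param net a non-empty [weighted_network()].
#' @return An object of class `transition_model`: list with `A` (sparse
#'   column-stochastic matrix) and `nodes` (the node ordering).
#' @export
column_normalize <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  if (length(net$nodes) == 0) stop("cannot normalize an empty network")
  W <- adjacency_matrix(net)
  A <- W %*% Matrix::Diagonal(x = 1 / Matrix::colSums(W))
  dimnames(A) <- dimnames(W)
  structure(list(A = methods::as(A, "CsparseMatrix"), nodes = net$nodes),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("transition_model: %d nodes, column-stochastic\n",
              length(x$nodes)))
  invisible(x)
}

#' Load a seed-gene list
#'
#' One identifier per non-blank line; `#` starts a comment. Identifiers
#' present in the network are retained in file order; absent identifiers are
#' recorded and reported with a warning. Retaining zero identifiers is an
#' error: the walk cannot start.
#'
#' @param path file path, connection or character vector of lines.
#' @param net the [weighted_network()] the seeds must belong to.
#' @return An object of class `seed_set`: list with `ids` (ordered unique
#'   in-network identifiers) and `dropped` (identifiers absent from the
#'   network).
#' @export
load_seeds <- function(path, net) {
  stopifnot(inherits(net, "weighted_network"))
  lines <- read_input_lines(path)
  lines <- sub("#.*$", "", lines)
  ids <- trimws(lines)
  ids <- unique(ids[nzchar(ids)])
  present <- ids %in% net$nodes
  if (!any(present)) {
    stop("none of the ", length(ids), " seed identifiers occur in the network")
  }
  if (any(!present)) {
    warning(sprintf("%d seed identifier(s) absent from the network: %s",
                    sum(!present),
                    paste(utils::head(ids[!present], 5), collapse = ", ")))
  }
  seed_set(ids[present], dropped = ids[!present])
}

#' @rdname load_seeds
#' @param ids character vector of in-network seed identifiers.
#' @param dropped identifiers that were requested but absent.
#' @export
seed_set <- function(ids, dropped = character()) {
  ids <- unique(as.character(ids))
  structure(list(ids = ids, dropped = as.character(dropped)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set: %d seed(s), %d dropped\n",
              length(x$ids), length(x$dropped)))
  invisible(x)
}

#' Load a GMT term-to-gene annotation file
#'
#' Standard GMT dialect: one term per line, tab-separated fields
#' `term <tab> description <tab> gene [<tab> gene ...]`. Duplicate genes
#' within a term are deduplicated; a repeated term identifier is an error;
#' a line with fewer than three fields is a parse error. Genes need not all
#' occur in any particular network.
#'
#' @param path file path, connection or character vector of lines.
#' @return An object of class `annotation_map`: list with `genes` (named list
#'   term -> character vector of gene IDs) and `descriptions` (named character
#'   vector).
#' @export
load_annotations <- function(path) {
  lines <- read_input_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("GMT line %d: expected at least 3 tab-separated fields, found %d",
                 which(nf < 3)[1], nf[which(nf < 3)[1]]))
  }
  terms <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(terms)) {
    stop("duplicate term identifier: ", terms[duplicated(terms)][1])
  }
  genes <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(genes) <- terms
  desc <- stats::setNames(vapply(fields, `[[`, character(1), 2), terms)
  annotation_map(genes, desc)
}

#' @rdname load_annotations
#' @param genes named list mapping term IDs to character vectors of gene IDs.
#' @param descriptions optional named character vector of term descriptions.
#' @export
annotation_map <- function(genes, descriptions = NULL) {
  stopifnot(is.list(genes), !is.null(names(genes)))
  if (any(lengths(genes) == 0)) stop("every term must annotate at least one gene")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(genes)), names(genes))
  }
  structure(list(genes = lapply(genes, function(g) unique(as.character(g))),
                 descriptions = descriptions),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d terms, %d distinct genes\n",
              length(x$genes), length(unique(unlist(x$genes)))))
  invisible(x)
}

#' Annotated universe of a network
#'
#' The enrichment universe used for the hypergeometric scores: all network
#' nodes that carry at least one annotation. This makes the white + black
#' ball total of the hypergeometric model a meaningful whole.
#'
#' @param net a [weighted_network()].
#' @param ann an [annotation_map()].
#' @return character vector of node identifiers.
#' @export
annotated_universe <- function(net, ann) {
  stopifnot(inherits(net, "weighted_network"), inherits(ann, "annotation_map"))
  intersect(net$nodes, unique(unlist(ann$genes, use.names = FALSE)))
}
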