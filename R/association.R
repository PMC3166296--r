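#' Upper-tail hypergeometric overlap probability
#'
#' Probability that two gene sets of sizes `M` and `K`, drawn independently
#' from a universe of `N` genes, share `x` or more genes:
#' `P(X >= x)` for `X ~ Hypergeometric(N, M, K)`. Computed as a survival
#' summation in log space over the log-pmf, which stays numerically stable
#' for universes up to at least 1e5 genes (direct `1 - sum(pmf)` summation
#' suffers catastrophic cancellation for small tails and is only suitable as
#' a small-universe cross-check).
#'
#' @param N universe size (genes eligible to appear in any set)
#' @param M,K sizes of the two sets, each `<= N`
#' @param x observed overlap, `0 <= x <= min(M, K)`
#' @return the tail probability, in `(0, 1]`; `P(X >= 0)` is exactly 1
#' @export
#' @examples
#' hypergeometric_tail_p(10, 5, 5, 5)  # 1/choose(10, 5) = 1/252
hypergeometric_tail_p <- function(N, M, K, x) {
  stopifnot(length(N) == 1, length(M) == 1, length(K) == 1, length(x) == 1)
  N <- as.numeric(N); M <- as.numeric(M); K <- as.numeric(K); x <- as.numeric(x)
  if (anyNA(c(N, M, K, x)) || N < 0 || M < 0 || K < 0)
    stop("N, M, K must be non-negative integers")
  if (M > N || K > N)
    stop(sprintf("set sizes exceed the universe: M=%g, K=%g, N=%g", M, K, N))
  if (x > min(M, K))
    stop(sprintf("overlap x=%g exceeds min(M, K)=%g", x, min(M, K)))
  if (x <= 0) return(1)
  i <- x:min(M, K)
  lp <- stats::dhyper(i, M, N - M, K, log = TRUE)
  min(exp(logsumexp(lp)), 1)
}

#' Test the overlap of two directional gene sets
#'
#' Counts the shared genes of two `PhaseChangeSet`s and evaluates the
#' hypergeometric tail probability of an overlap at least that large within
#' a declared gene universe of size `N`. The relation is `"synchronous"`
#' when both sets have the same direction (up-up or down-down) and
#' `"asynchronous"` otherwise.
#'
#' @param a,b two distinct [phase_change_set()]s drawn from the same universe
#' @param N size of the shared gene universe
#' @return an object of class `OverlapTest` with fields `node_a`, `node_b`,
#'   `relation`, `N`, `M`, `K`, `x`, `p`
#' @export
test_pair <- function(a, b, N) {
  stopifnot(inherits(a, "PhaseChangeSet"), inherits(b, "PhaseChangeSet"))
  if (identical(a$node_name, b$node_name))
    stop("a node is never tested against itself")
  M <- length(a$genes)
  K <- length(b$genes)
  x <- length(intersect(a$genes, b$genes))
  structure(list(node_a = a$node_name, node_b = b$node_name,
                 relation = if (a$direction == b$direction) "synchronous"
                            else "asynchronous",
                 N = N, M = M, K = K, x = x,
                 p = hypergeometric_tail_p(N, M, K, x)),
            class = "OverlapTest")
}

#' @export
print.OverlapTest <- function(x, ...) {
  cat(sprintf("OverlapTest %s ~ %s (%s): x=%d of M=%d,K=%d in N=%d, p=%.3g\n",
              x$node_a, x$node_b, x$relation, x$x, x$M, x$K, x$N, x$p))
  invisible(x)
}

empty_edge_frame <- function(with_class = FALSE) {
  df <- data.frame(node_a = character(), node_b = character(),
                   relation = character(), N = integer(), M = integer(),
                   K = integer(), x = integer(), p = numeric(),
                   stringsAsFactors = FALSE)
  if (with_class) df$edge_class <- character()
  df
}

node_frame <- function(sets) {
  data.frame(node_name = vapply(sets, `[[`, "", "node_name"),
             tissue = vapply(sets, function(s) s$phase$tissue, ""),
             phase = vapply(sets, function(s) s$phase$label, ""),
             direction = vapply(sets, `[[`, "", "direction"),
             size = vapply(sets, function(s) length(s$genes), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

# run overlap tests for a list of index pairs; returns a data.frame
run_pair_tests <- function(sets, pairs, N, edge_class = NULL) {
  if (!length(pairs)) return(empty_edge_frame(!is.null(edge_class)))
  rows <- lapply(seq_along(pairs), function(k) {
    ij <- pairs[[k]]
    tst <- test_pair(sets[[ij[1]]], sets[[ij[2]]], N)
    df <- data.frame(node_a = tst$node_a, node_b = tst$node_b,
                     relation = tst$relation, N = tst$N, M = tst$M,
                     K = tst$K, x = tst$x, p = tst$p,
                     stringsAsFactors = FALSE)
    if (!is.null(edge_class)) df$edge_class <- edge_class[k]
    df
  })
  do.call(rbind, rows)
}

#' Build the tissue-association network of one age phase
#'
#' Tests every cross-tissue pair of directional change sets sharing one age
#' phase: for each tissue pair all four directional combinations (up-up,
#' down-down, up-down, down-up) are tested, and pairs with tail probability
#' strictly below `threshold` become edges — synchronous when directions
#' match, asynchronous otherwise. Pairs involving an empty set are untested;
#' nodes with no edge are the phase's "stochastic" tissues. The up and down
#' sets of the same tissue are never tested against each other (disjoint by
#' construction).
#'
#' @param sets list of [phase_change_set()]s, all with the same phase label
#' @param N gene universe size (genes surviving filtering in the dataset)
#' @param threshold significance level; edges require `p < threshold`
#'   (strict). 0.001 and 0.005 are the usual per-phase choices.
#' @param keep_tests also keep the full table of tested pairs (needed for
#'   calibration studies) as the `tests` element
#' @return an object of class `AssociationNetwork`: list with `nodes`
#'   (data.frame: node_name, tissue, phase, direction, size, connected),
#'   `edges` (data.frame: node_a, node_b, relation, N, M, K, x, p),
#'   `n_tests`, `threshold`, `N`, `phase_scope`, and optionally `tests`
#' @export
build_phase_network <- function(sets, N, threshold = 0.005,
                                keep_tests = FALSE) {
  stopifnot(length(sets) > 0, all(vapply(sets, inherits, TRUE, "PhaseChangeSet")),
            is.numeric(threshold), threshold > 0, threshold < 1)
  nodes <- node_frame(sets)
  scope <- unique(nodes$phase)
  if (length(scope) != 1)
    stop("build_phase_network needs sets from a single phase; got: ",
         paste(scope, collapse = ", "))

  nonempty <- nodes$size > 0
  pairs <- list()
  idx <- seq_along(sets)
  for (i in idx) {
    for (j in idx) {
      if (j <= i) next
      if (nodes$tissue[i] == nodes$tissue[j]) next  # up/down of one tissue
      if (!nonempty[i] || !nonempty[j]) next
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  tests <- run_pair_tests(sets, pairs, N)
  edges <- tests[tests$p < threshold, , drop = FALSE]
  rownames(edges) <- NULL
  nodes$connected <- nodes$node_name %in% c(edges$node_a, edges$node_b)

  out <- list(nodes = nodes, edges = edges, n_tests = nrow(tests),
              threshold = threshold, N = N, phase_scope = scope)
  if (keep_tests) out$tests <- tests
  structure(out, class = "AssociationNetwork")
}

#' @export
print.AssociationNetwork <- function(x, ...) {
  s <- summarize_network(x)
  cat(sprintf(
    "AssociationNetwork [%s] N=%d, threshold=%g: %d nodes, %d edges (%d sync, %d async), %d stochastic\n",
    x$phase_scope, x$N, x$threshold, nrow(x$nodes),
    nrow(x$edges), s$sync_edges, s$async_edges, s$stochastic_nodes))
  invisible(x)
}

#' Summarize an association network
#'
#' @param net an `AssociationNetwork` (per-phase or four-dimensional)
#' @return one-row data.frame with `phase_scope`, `sync_edges`,
#'   `async_edges`, `connected_nodes`, `stochastic_nodes`, `n_tests`,
#'   `threshold`, `N`
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "AssociationNetwork"))
  data.frame(phase_scope = net$phase_scope,
             sync_edges = sum(net$edges$relation == "synchronous"),
             async_edges = sum(net$edges$relation == "asynchronous"),
             connected_nodes = sum(net$nodes$connected),
             stochastic_nodes = sum(!net$nodes$connected),
             n_tests = net$n_tests,
             threshold = net$threshold,
             N = net$N,
             stringsAsFactors = FALSE)
}

#' Write a network's edge list as TSV
#'
#' Columns: node_a, node_b, relation, N, M, K, x, p (plus edge_class for
#' four-dimensional networks) and the threshold used, so no output file
#' leaves its significance settings implicit.
#'
#' @param net an `AssociationNetwork`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "AssociationNetwork"))
  edges <- net$edges
  edges$threshold <- rep(net$threshold, nrow(edges))
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML
#'
#' Produces a GraphML file with node attributes (tissue, phase, direction,
#' size) and edge attributes (relation, p, and edge_class where present) for
#' rendering in external graph viewers.
#'
#' @param net an `AssociationNetwork`
#' @param path output file path
#' @return invisibly, `path`
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "AssociationNetwork"))
  vertices <- net$nodes
  edge_cols <- intersect(c("node_a", "node_b", "relation", "p", "edge_class"),
                         names(net$edges))
  g <- igraph::graph_from_data_frame(net$edges[, edge_cols, drop = FALSE],
                                     directed = FALSE, vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
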