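#' Build the global four-dimensional association network
#'
#' Tests every unordered pair of distinct directional change sets across all
#' tissues AND all age phases against the hypergeometric null. The up and
#' down sets of the same tissue-phase are excluded (their overlap is zero by
#' construction, and a forced p = 1 edge is noise); pairs involving an empty
#' set are untested. Each significant edge carries an `edge_class`:
#' `"same-tissue"` (necessarily cross-phase), `"cross-tissue same-phase"`,
#' or `"cross-tissue cross-phase"`. Restricting the result to cross-tissue
#' same-phase pairs reproduces the per-phase networks of
#' [build_phase_network()] exactly at the same threshold.
#'
#' @param sets list of [phase_change_set()]s from one dataset/universe
#' @param N gene universe size
#' @param threshold significance level (strict `<`); four-dimensional maps
#'   typically use stricter levels such as 1e-4 or 5e-4 than per-phase
#'   networks
#' @param keep_tests keep the full tested-pair table as element `tests`
#' @return an object of classes `FourDNetwork`, `AssociationNetwork` with
#'   `phase_scope = "4D"` and an `edge_class` column on `edges`
#' @export
build_4d_network <- function(sets, N, threshold = 1e-4, keep_tests = FALSE) {
  stopifnot(length(sets) > 0,
            all(vapply(sets, inherits, TRUE, "PhaseChangeSet")),
            is.numeric(threshold), threshold > 0, threshold < 1)
  nodes <- node_frame(sets)
  if (anyDuplicated(nodes$node_name)) stop("duplicate node names in sets")
  nonempty <- nodes$size > 0

  pairs <- list()
  classes <- character()
  n <- length(sets)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      same_tissue <- nodes$tissue[i] == nodes$tissue[j]
      same_phase <- nodes$phase[i] == nodes$phase[j]
      if (same_tissue && same_phase) next  # up/down of one node, disjoint
      if (!nonempty[i] || !nonempty[j]) next
      pairs[[length(pairs) + 1L]] <- c(i, j)
      classes <- c(classes,
                   if (same_tissue) "same-tissue"
                   else if (same_phase) "cross-tissue same-phase"
                   else "cross-tissue cross-phase")
    }
  }
  tests <- run_pair_tests(sets, pairs, N, edge_class = classes)
  edges <- tests[tests$p < threshold, , drop = FALSE]
  rownames(edges) <- NULL
  nodes$connected <- nodes$node_name %in% c(edges$node_a, edges$node_b)

  out <- list(nodes = nodes, edges = edges, n_tests = nrow(tests),
              threshold = threshold, N = N, phase_scope = "4D")
  if (keep_tests) out$tests <- tests
  structure(out, class = c("FourDNetwork", "AssociationNetwork"))
}

#' Classify every node of a four-dimensional network
#'
#' Nodes fall into four mutually exclusive categories derived from the
#' classes of their incident edges:
#' * `"specific"` — no edges: the gene set recurs nowhere else in time or
#'   space at the threshold.
#' * `"tissue-specific-temporal"` — edges only within the node's own tissue
#'   (temporal persistence, no spatial association).
#' * `"temporal-associated"` — same-tissue edges plus cross-tissue edges
#'   confined to the node's own phase: temporally persistent, with only
#'   contemporaneous spatial partners.
#' * `"spatio-temporal-associated"` — at least one cross-tissue cross-phase
#'   edge, or cross-tissue edges without same-tissue persistence: the gene
#'   set spans both dimensions of the map.
#'
#' @param net a `FourDNetwork` from [build_4d_network()]
#' @return data.frame with columns `node_name`, `category`
#' @export
classify_4d_nodes <- function(net) {
  stopifnot(inherits(net, "FourDNetwork"))
  edges <- net$edges
  category <- vapply(net$nodes$node_name, function(name) {
    inc <- edges$node_a == name | edges$node_b == name
    if (!any(inc)) return("specific")
    cls <- edges$edge_class[inc]
    same_t <- any(cls == "same-tissue")
    ct_sp <- any(cls == "cross-tissue same-phase")
    ct_cp <- any(cls == "cross-tissue cross-phase")
    if (!ct_sp && !ct_cp) return("tissue-specific-temporal")
    if (same_t && ct_sp && !ct_cp) return("temporal-associated")
    "spatio-temporal-associated"
  }, character(1))
  data.frame(node_name = net$nodes$node_name, category = unname(category),
             stringsAsFactors = FALSE)
}

#' @rdname classify_4d_nodes
#' @param node_name name of one node present in the network
#' @return `classify_4d_node`: the category of that node as a string
#' @export
classify_4d_node <- function(net, node_name) {
  stopifnot(inherits(net, "FourDNetwork"))
  if (!node_name %in% net$nodes$node_name)
    stop("node not in network: ", node_name)
  cats <- classify_4d_nodes(net)
  cats$category[cats$node_name == node_name]
}
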