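#' Directed clustering coefficient
#'
#' For node i with neighborhood L(i) (union of in- and out-neighbors,
#' excluding i itself, k_i = |L(i)|), the coefficient is n_i / (k_i (k_i -
#' 1)) where n_i counts the directed arcs running between members of L(i).
#' The denominator is the number of ordered neighbor pairs, so the value
#' lies in [0, 1] and reaches 1 on a complete bidirectional digraph. Nodes
#' with fewer than two neighbors have an undefined ratio (0/0); the
#' `singleton` convention decides what they report.
#'
#' @param g A [reaction_graph()].
#' @param nodes Nodes to evaluate; default all.
#' @param singleton Value convention for k_i <= 1 nodes: `"zero"`
#'   (default) or `"one"`.
#' @return Tibble with columns `node`, `clustering`.
#' @examples
#' clustering_coefficient(fig1_toy_graph())
#' @export
clustering_coefficient <- function(g, nodes = NULL,
                                   singleton = c("zero", "one")) {
  stopifnot(is_reaction_graph(g))
  singleton <- match.arg(singleton)
  if (is.null(nodes)) nodes <- g$nodes else purrr::walk(nodes, ~ assert_node(g, .x))
  inn <- in_neighbors(g)
  out <- out_neighbors(g)
  arc_key <- paste(g$arcs$from, g$arcs$to, sep = "\r")
  cc <- vapply(nodes, function(v) {
    nb <- setdiff(unique(c(inn[[v]], out[[v]])), v)
    k <- length(nb)
    if (k <= 1L) return(if (singleton == "zero") 0 else 1)
    pairs <- expand.grid(u = nb, w = nb, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$u != pairs$w, ]
    n_i <- sum(paste(pairs$u, pairs$w, sep = "\r") %in% arc_key)
    n_i / (k * (k - 1))
  }, numeric(1))
  tibble(node = nodes, clustering = unname(cc))
}

#' Directed betweenness centrality
#'
#' Unnormalized Freeman betweenness on directed, unweighted shortest
#' paths: for each ordered pair (j, k) with j != k, both distinct from i
#' and connected (sigma_jk > 0), node i accrues sigma_jk(i) / sigma_jk.
#' Values on small graphs are integer-scale path counts, not ratios.
#' Computation is delegated to igraph (Brandes' algorithm).
#'
#' @inheritParams clustering_coefficient
#' @return Tibble with columns `node`, `betweenness`, in lexicographic
#'   node order.
#' @examples
#' betweenness_centrality(fig1_toy_graph())
#' @export
betweenness_centrality <- function(g, nodes = NULL) {
  stopifnot(is_reaction_graph(g))
  if (is.null(nodes)) nodes <- g$nodes else purrr::walk(nodes, ~ assert_node(g, .x))
  if (n_nodes(g) == 0L) return(tibble(node = character(), betweenness = numeric()))
  b <- igraph::betweenness(as_igraph(g), directed = TRUE, normalized = FALSE)
  tibble(node = nodes, betweenness = unname(b[nodes]))
}

#' Directed bridging coefficient
#'
#' The bridging coefficient of node i is the inverse of its total degree
#' divided by the sum of inverse total degrees over its neighborhood L(i)
#' (a neighbor linked in both directions is counted once). The directed
#' ("gated") form additionally reports 0 whenever the node lacks incoming
#' or outgoing arcs, since a node through which no information can flow
#' cannot bridge; the raw (ungated) form is the classical undirected
#' definition evaluated on total degrees and is kept available because both
#' readings appear in published node tables.
#'
#' @inheritParams clustering_coefficient
#' @param gated Apply the directed in-and-out gate (default `TRUE`).
#' @return Tibble with columns `node`, `bridging_coefficient`.
#' @examples
#' bridging_coefficient(fig1_toy_graph(), gated = FALSE)
#' @export
bridging_coefficient <- function(g, nodes = NULL, gated = TRUE) {
  stopifnot(is_reaction_graph(g))
  if (is.null(nodes)) nodes <- g$nodes else purrr::walk(nodes, ~ assert_node(g, .x))
  deg <- node_degrees(g)
  dtot <- setNames(deg$degree_total, deg$node)
  din <- setNames(deg$degree_in, deg$node)
  dout <- setNames(deg$degree_out, deg$node)
  inn <- in_neighbors(g)
  out <- out_neighbors(g)
  bc <- vapply(nodes, function(v) {
    nb <- setdiff(unique(c(inn[[v]], out[[v]])), v)
    if (length(nb) == 0L) return(0)
    if (gated && (din[[v]] == 0L || dout[[v]] == 0L)) return(0)
    (1 / dtot[[v]]) / sum(1 / dtot[nb])
  }, numeric(1))
  tibble(node = nodes, bridging_coefficient = unname(bc))
}

#' Bridging centrality
#'
#' The elementwise product of betweenness centrality and the gated
#' directed bridging coefficient. High values mark low-degree nodes that
#' sit on many shortest paths between well-connected neighbors — the
#' bridges between modules.
#'
#' @inheritParams clustering_coefficient
#' @return Tibble with columns `node`, `bridging_centrality`.
#' @examples
#' bridging_centrality(fig1_toy_graph())
#' @export
bridging_centrality <- function(g, nodes = NULL) {
  b <- betweenness_centrality(g, nodes)
  bc <- bridging_coefficient(g, nodes, gated = TRUE)
  tibble(node = b$node,
         bridging_centrality = b$betweenness * bc$bridging_coefficient)
}

#' Per-node centrality table
#'
#' Joins degrees, clustering coefficient, betweenness, bridging
#' coefficient and bridging centrality into one tibble in lexicographic
#' node order. `bridging_centrality` always uses the gated coefficient;
#' the `bridging_coefficient` column reports the variant selected by
#' `gated`.
#'
#' @inheritParams bridging_coefficient
#' @param singleton Clustering convention for nodes with fewer than two
#'   neighbors, see [clustering_coefficient()].
#' @return Tibble with columns `node`, `degree_in`, `degree_out`,
#'   `degree_total`, `clustering`, `betweenness`, `bridging_coefficient`,
#'   `bridging_centrality`.
#' @examples
#' centrality_table(fig1_toy_graph(), gated = FALSE)
#' @export
centrality_table <- function(g, gated = TRUE, singleton = c("zero", "one")) {
  stopifnot(is_reaction_graph(g))
  if (n_nodes(g) == 0L) {
    return(tibble(node = character(), degree_in = integer(),
                  degree_out = integer(), degree_total = integer(),
                  clustering = numeric(), betweenness = numeric(),
                  bridging_coefficient = numeric(),
                  bridging_centrality = numeric()))
  }
  node_degrees(g) %>%
    left_join(clustering_coefficient(g, singleton = singleton), by = "node") %>%
    left_join(betweenness_centrality(g), by = "node") %>%
    left_join(bridging_coefficient(g, gated = gated), by = "node") %>%
    left_join(bridging_centrality(g), by = "node") %>%
    arrange(.data$node)
}
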