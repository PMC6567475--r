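#' Cascade set of a node
#'
#' When a node fails, every downstream node that depended on it for *all*
#' of its incoming supply also fails, and the failure propagates to a
#' fixpoint: starting from the seed, a node joins the failed set exactly
#' when it has at least one incoming arc in the original graph and every
#' one of its in-neighbors has already failed. Nodes with no incoming arcs
#' (sources) never starve, and nodes inside a directed cycle survive as
#' long as any arc into the cycle stays live. The cascade set is the
#' failed set minus the seed; its size is the cascade number. The fixpoint
#' is order-independent, so the result is deterministic.
#'
#' The implementation keeps a counter of still-live in-neighbors per node
#' and processes a worklist, giving O(|V| + |A|) per seed.
#'
#' @param g A [reaction_graph()].
#' @param node The seed node whose failure is propagated.
#' @return Character vector (sorted) of nodes starved by the failure,
#'   excluding the seed.
#' @examples
#' cascade_set(fig1_toy_graph(), "A")
#' @export
cascade_set <- function(g, node) {
  stopifnot(is_reaction_graph(g))
  assert_node(g, node)
  sort(cascade_from(g, node, in_neighbors(g), out_neighbors(g)))
}

cascade_from <- function(g, seed, inn, out) {
  live_in <- lengths(inn)
  failed <- character()
  work <- seed
  is_failed <- setNames(rep(FALSE, length(g$nodes)), g$nodes)
  is_failed[seed] <- TRUE
  while (length(work)) {
    v <- work[[1]]
    work <- work[-1]
    for (u in out[[v]]) {
      if (is_failed[[u]]) next
      live_in[[u]] <- live_in[[u]] - 1L
      if (live_in[[u]] == 0L) {  # in-degree > 0 by construction
        is_failed[[u]] <- TRUE
        failed <- c(failed, u)
        work <- c(work, u)
      }
    }
  }
  failed
}

#' Cascade analysis of every node
#'
#' Runs [cascade_set()] from every node and augments the result with the
#' independence flag of [leading_cascade_nodes()] and the subnetwork type
#' of [classify_cascade_subnetwork()].
#'
#' @param g A [reaction_graph()].
#' @return Tibble with one row per node (lexicographic order): `node`,
#'   `cascade_number`, `cascade_set` (list column of sorted character
#'   vectors), `independent` (logical: is this a leading cascade node),
#'   `subnetwork_type` (`"empty"`, `"linear_path"`, `"tree"` or
#'   `"other"`).
#' @examples
#' all_cascades(fig1_toy_graph())
#' @export
all_cascades <- function(g) {
  stopifnot(is_reaction_graph(g))
  inn <- in_neighbors(g)
  out <- out_neighbors(g)
  sets <- lapply(g$nodes, function(v) sort(cascade_from(g, v, inn, out)))
  names(sets) <- g$nodes
  res <- tibble(node = g$nodes,
                cascade_number = unname(lengths(sets)),
                cascade_set = unname(sets))
  res$independent <- res$node %in% leading_cascade_nodes(res)
  res$subnetwork_type <- purrr::map2_chr(
    res$node, res$cascade_set,
    function(v, cs) classify_cascade_subnetwork(g, v, cs))
  res
}

#' Leading cascade nodes
#'
#' A node's cascade set is absorbed when the node itself belongs to some
#' other node's cascade set (by the fixpoint, that larger set then
#' contains this one). A node contained in no other cascade set is a
#' *leading cascade node* and its cascade set is *independent*. Mutual
#' membership (two nodes each inside the other's set, which makes their
#' sets equal) is reported as non-leading for both, with a warning.
#'
#' @param cascades Result of [all_cascades()], or a [reaction_graph()]
#'   (in which case cascades are computed first).
#' @return Character vector of leading cascade node ids.
#' @examples
#' leading_cascade_nodes(fig1_toy_graph())
#' @export
leading_cascade_nodes <- function(cascades) {
  if (is_reaction_graph(cascades)) {
    g <- cascades
    inn <- in_neighbors(g); out <- out_neighbors(g)
    cascades <- tibble(
      node = g$nodes,
      cascade_set = lapply(g$nodes,
                           function(v) sort(cascade_from(g, v, inn, out))))
  }
  absorbed <- unique(unlist(cascades$cascade_set))
  leading <- setdiff(cascades$node, absorbed)
  sets <- setNames(cascades$cascade_set, cascades$node)
  mutual <- purrr::keep(cascades$node, function(v) {
    any(vapply(sets[[v]], function(w) v %in% sets[[w]], logical(1)))
  })
  if (length(mutual)) {
    warn(paste0("mutual cascade membership detected for: ",
                paste(sort(mutual), collapse = ", "),
                "; their sets are reported as non-independent"))
  }
  sort(leading)
}

#' Classify the subnetwork induced by a cascade set
#'
#' The cascade subnetwork H is the subgraph induced on the seed plus its
#' cascade set. Types: `"empty"` for cascade number zero; `"tree"` when H
#' is an arborescence rooted at the seed (every cascade member has exactly
#' one incoming arc within H, the seed none, and H is weakly connected);
#' `"linear_path"` for the special tree in which every node of H also has
#' at most one outgoing arc within H; `"other"` otherwise.
#'
#' @param g A [reaction_graph()].
#' @param node Seed node.
#' @param cascade Its cascade set; computed via [cascade_set()] when
#'   omitted.
#' @return One of `"empty"`, `"linear_path"`, `"tree"`, `"other"`.
#' @examples
#' classify_cascade_subnetwork(fig1_toy_graph(), "D")
#' @export
classify_cascade_subnetwork <- function(g, node, cascade = NULL) {
  stopifnot(is_reaction_graph(g))
  assert_node(g, node)
  if (is.null(cascade)) cascade <- cascade_set(g, node)
  if (length(cascade) == 0L) return("empty")
  members <- c(node, cascade)
  arcs <- filter(g$arcs, .data$from %in% members, .data$to %in% members)
  indeg <- table(factor(arcs$to, levels = members))
  outdeg <- table(factor(arcs$from, levels = members))
  ig <- igraph::graph_from_data_frame(arcs[, c("from", "to")],
                                      directed = TRUE,
                                      vertices = members)
  connected <- igraph::is_connected(ig, mode = "weak")
  is_tree <- connected && indeg[[node]] == 0L &&
    all(indeg[cascade] == 1L)
  if (is_tree && all(outdeg <= 1L)) return("linear_path")
  if (is_tree) return("tree")
  "other"
}
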