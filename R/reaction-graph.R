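#' Directed reaction-centric graph
#'
#' A `reaction_graph` is a simple directed graph whose nodes are reaction
#' identifiers and whose arcs run from a producing reaction to a consuming
#' reaction. Each arc may carry the set of metabolites that mediate it
#' (comma-joined in the `metabolites` column); graphs read from bare edge
#' lists carry `NA` there. Self-arcs and parallel arcs are forbidden.
#'
#' @param nodes Character vector of node identifiers (unique, non-empty).
#' @param arcs A data frame with columns `from`, `to` and optionally
#'   `metabolites` (comma-joined metabolite ids, or `NA`).
#' @return A `reaction_graph` object: a list with elements `nodes`
#'   (character) and `arcs` (tibble with columns `from`, `to`,
#'   `metabolites`), both in lexicographic order.
#' @examples
#' g <- reaction_graph(c("A", "B"), data.frame(from = "A", to = "B"))
#' g
#' @export
reaction_graph <- function(nodes = character(), arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    abort("duplicate node identifiers in `nodes`")
  }
  if (any(!nzchar(nodes)) || anyNA(nodes)) {
    abort("node identifiers must be non-empty and non-missing")
  }
  if (is.null(arcs) || nrow(arcs) == 0L) {
    arcs <- tibble(from = character(), to = character(),
                   metabolites = character())
  } else {
    arcs <- as_tibble(arcs)
    if (!all(c("from", "to") %in% names(arcs))) {
      abort("`arcs` needs columns `from` and `to`")
    }
    if (!"metabolites" %in% names(arcs)) arcs$metabolites <- NA_character_
    arcs <- tibble(from = as.character(arcs$from),
                   to = as.character(arcs$to),
                   metabolites = as.character(arcs$metabolites))
  }
  bad <- setdiff(c(arcs$from, arcs$to), nodes)
  if (length(bad)) {
    abort(paste0("arc endpoint(s) not in node set: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(arcs$from == arcs$to)) {
    abort("self-arcs are not allowed in a reaction graph")
  }
  if (anyDuplicated(paste(arcs$from, arcs$to, sep = "\r"))) {
    abort("parallel arcs are not allowed in a reaction graph")
  }
  empty_annot <- !is.na(arcs$metabolites) & !nzchar(arcs$metabolites)
  if (any(empty_annot)) {
    abort("annotated arcs must carry at least one mediating metabolite")
  }
  structure(
    list(nodes = sort(nodes),
         arcs = arrange(arcs, .data$from, .data$to)),
    class = "reaction_graph"
  )
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("<reaction_graph> %d nodes, %d arcs\n",
              length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs)) print(head(x$arcs, 10))
  invisible(x)
}

#' @rdname reaction_graph
#' @param x Object to test or convert.
#' @export
is_reaction_graph <- function(x) inherits(x, "reaction_graph")

n_nodes <- function(g) length(g$nodes)
n_arcs <- function(g) nrow(g$arcs)

assert_node <- function(g, node) {
  if (!node %in% g$nodes) {
    abort(sprintf("node '%s' is not in the graph", node))
  }
  invisible(TRUE)
}

#' Convert between reaction graphs and igraph objects
#'
#' `as_igraph()` returns a directed [igraph::graph] with vertex names and an
#' edge attribute `metabolites`; `as_reaction_graph()` converts back (vertex
#' names required).
#'
#' @param g A `reaction_graph`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(g) {
  stopifnot(is_reaction_graph(g))
  ig <- igraph::make_empty_graph(n = 0, directed = TRUE)
  ig <- igraph::add_vertices(ig, length(g$nodes), name = g$nodes)
  if (nrow(g$arcs)) {
    ig <- igraph::add_edges(ig, rbind(match(g$arcs$from, g$nodes),
                                      match(g$arcs$to, g$nodes)))
    igraph::E(ig)$metabolites <- g$arcs$metabolites
  }
  ig
}

#' @rdname as_igraph
#' @param ig A directed igraph object with named vertices.
#' @export
as_reaction_graph <- function(ig) {
  stopifnot(igraph::is_igraph(ig), igraph::is_directed(ig))
  nodes <- igraph::V(ig)$name
  if (is.null(nodes)) abort("igraph vertices must be named")
  el <- igraph::as_edgelist(ig, names = TRUE)
  met <- if ("metabolites" %in% igraph::edge_attr_names(ig)) {
    igraph::E(ig)$metabolites
  } else {
    rep(NA_character_, nrow(el))
  }
  met[!is.na(met) & !nzchar(met)] <- NA_character_  # "" encodes no annotation
  reaction_graph(nodes, tibble(from = el[, 1], to = el[, 2],
                               metabolites = met))
}

# Named adjacency lists, used by the metric and cascade code.
out_neighbors <- function(g) {
  nb <- split(g$arcs$to, factor(g$arcs$from, levels = g$nodes))
  lapply(nb, as.character)
}

in_neighbors <- function(g) {
  nb <- split(g$arcs$from, factor(g$arcs$to, levels = g$nodes))
  lapply(nb, as.character)
}

#' Node degrees of a reaction graph
#'
#' In-degree counts distinct producing reactions, out-degree distinct
#' consuming reactions; `degree_total = degree_in + degree_out`, so a
#' mutually linked pair contributes one to each side. The graph is simple,
#' hence degrees equal neighbor counts.
#'
#' @param g A `reaction_graph`.
#' @param nodes Optional character vector restricting the output.
#' @return A tibble with columns `node`, `degree_in`, `degree_out`,
#'   `degree_total`, in lexicographic node order.
#' @examples
#' node_degrees(fig1_toy_graph())
#' @export
node_degrees <- function(g, nodes = NULL) {
  stopifnot(is_reaction_graph(g))
  din <- table(factor(g$arcs$to, levels = g$nodes))
  dout <- table(factor(g$arcs$from, levels = g$nodes))
  out <- tibble(node = g$nodes,
                degree_in = as.integer(din),
                degree_out = as.integer(dout)) %>%
    mutate(degree_total = .data$degree_in + .data$degree_out)
  if (!is.null(nodes)) {
    purrr::walk(nodes, ~ assert_node(g, .x))
    out <- filter(out, .data$node %in% nodes)
  }
  out
}

#' @rdname node_degrees
#' @param node A single node identifier.
#' @return `node_degree()` returns a one-row tibble for `node`.
#' @export
node_degree <- function(g, node) {
  assert_node(g, node)
  node_degrees(g, nodes = node)
}
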