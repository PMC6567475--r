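#' Read and write reaction graphs
#'
#' Two exchange formats are supported. `"edge_tsv"` is a UTF-8 TSV with
#' header `from  to  metabolites`; one line per arc with the mediating
#' metabolites comma-joined, in lexicographic `(from, to)` order so output
#' is byte-stable. Isolated nodes are written as a line with an empty `to`
#' field (a dialect extension so that round-trips preserve the node set).
#' `"graphml"` goes through [igraph::write_graph()] with the metabolite
#' annotation as an edge attribute.
#'
#' @param graph A [reaction_graph()].
#' @param path Output (input) file path.
#' @param format `"edge_tsv"` (default) or `"graphml"`.
#' @return `write_reaction_graph()` returns `path` invisibly;
#'   `read_reaction_graph()` returns a [reaction_graph()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_reaction_graph(fig1_toy_graph(), tf)
#' read_reaction_graph(tf)
#' @export
write_reaction_graph <- function(graph, path,
                                 format = c("edge_tsv", "graphml")) {
  stopifnot(is_reaction_graph(graph))
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- as_igraph(graph)
    if (n_arcs(graph) > 0) {
      igraph::E(ig)$metabolites[is.na(igraph::E(ig)$metabolites)] <- ""
    }
    igraph::write_graph(ig, path, format = "graphml")
    return(invisible(path))
  }
  arcs <- graph$arcs
  iso <- setdiff(graph$nodes, unique(c(arcs$from, arcs$to)))
  met <- ifelse(is.na(arcs$metabolites), "", arcs$metabolites)
  lines <- c("from\tto\tmetabolites",
             sprintf("%s\t%s\t%s", arcs$from, arcs$to, met),
             if (length(iso)) sprintf("%s\t\t", sort(iso)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_reaction_graph
#' @export
read_reaction_graph <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "graphml") {
    ig <- igraph::read_graph(path, format = "graphml")
    return(as_reaction_graph(ig))
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || !startsWith(lines[1], "from\tto")) {
    abort("format error: missing 'from\\tto' header")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0L) return(reaction_graph())
  fields <- strsplit(body, "\t", fixed = TRUE)
  rows <- purrr::imap(fields, function(f, i) {
    length(f) <- 3L
    f[is.na(f)] <- ""
    if (!nzchar(f[1])) {
      abort(sprintf("parse error at line %d: empty source field", i + 1L))
    }
    f
  })
  m <- do.call(rbind, rows)
  is_node_line <- !nzchar(m[, 2])
  arcs <- tibble(from = m[!is_node_line, 1], to = m[!is_node_line, 2],
                 metabolites = ifelse(nzchar(m[!is_node_line, 3]),
                                      m[!is_node_line, 3], NA_character_))
  if (any(arcs$from == arcs$to)) {
    abort("validation error: self-arc line in edge file")
  }
  key <- paste(arcs$from, arcs$to, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("validation error: duplicate arc line %s -> %s",
                  arcs$from[duplicated(key)][1], arcs$to[duplicated(key)][1]))
  }
  nodes <- unique(c(arcs$from, arcs$to, m[is_node_line, 1]))
  reaction_graph(nodes, arcs)
}
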