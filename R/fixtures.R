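#' Seven-node worked-example graph
#'
#' The small directed network used throughout the documentation and tests:
#' nodes A-G with arcs A->B, A->C, A->D, B->D, C->D, D->E, E->F, F->G,
#' G->F. It exercises every metric regime in a hand-checkable way: A is a
#' pure source whose failure starves B, C, D and then E; D is the
#' betweenness bottleneck (9 shortest paths); E is the bridge with the
#' highest bridging centrality; and the F<->G 2-cycle keeps F alive when E
#' fails, so cascade sets respect cycle-internal supply.
#'
#' @return A [reaction_graph()] with 7 nodes and 9 arcs.
#' @examples
#' centrality_table(fig1_toy_graph())
#' @export
fig1_toy_graph <- function() {
  arcs <- tibble(
    from = c("A", "A", "A", "B", "C", "D", "E", "F", "G"),
    to   = c("B", "C", "D", "D", "D", "E", "F", "G", "F"))
  reaction_graph(LETTERS[1:7], arcs)
}

#' Three-reaction aspartate-branch model
#'
#' The minimal worked example of reaction-graph construction: ASAD
#' (4pasp <-> aspsa) and HSDy (aspsa <-> hom__L) are reversible, HSK
#' (hom__L -> phom) is not, so the graph is the 2-cycle ASAD <-> HSDy
#' plus HSDy -> HSK.
#'
#' @return A [metabolic_model()] with 3 reactions (cytosolic).
#' @examples
#' build_reaction_graph(example_asad_model())$arcs
#' @export
example_asad_model <- function() {
  mets <- parse_metabolite_id(c("4pasp_c", "aspsa_c", "hom__L_c", "phom_c"))
  reactions <- tibble(
    id = c("ASAD", "HSDy", "HSK"),
    reversible = c(TRUE, TRUE, FALSE),
    substrates = list(c("4pasp_c" = 1), c("aspsa_c" = 1), c("hom__L_c" = 1)),
    products = list(c("aspsa_c" = 1), c("hom__L_c" = 1), c("phom_c" = 1)))
  metabolic_model(mets, reactions, name = "asad_branch")
}

#' Random synthetic metabolic model
#'
#' Emulates the structure the conversion pipeline must cope with: a
#' bipartite stoichiometry over cytosolic metabolites, currency
#' metabolites (drawn from [default_currency_metabolites()]) attached to
#' about 80% of internal reactions, plus designated transport reactions
#' (the same base species moved between the extracellular and cytosolic
#' compartment) and exchange reactions (an extracellular species with an
#' empty product side and an `EX_` id). Counts of exchange and transport
#' reactions are `round(fraction * n_reactions)`. Deterministic given
#' `seed`.
#'
#' @param n_metabolites Internal (non-currency) metabolite count.
#' @param n_reactions Total reaction count.
#' @param reversible_fraction Fraction of internal reactions that are
#'   reversible.
#' @param n_currency How many currency species to use (<= length of the
#'   default list).
#' @param transport_fraction,exchange_fraction Fractions of
#'   `n_reactions` realised as transport / exchange reactions.
#' @param seed Integer seed.
#' @return A [metabolic_model()].
#' @examples
#' synthetic_model(n_metabolites = 20, n_reactions = 30, seed = 1)
#' @export
synthetic_model <- function(n_metabolites = 40L, n_reactions = 60L,
                            reversible_fraction = 0.3, n_currency = 6L,
                            transport_fraction = 0.1,
                            exchange_fraction = 0.1, seed = 1L) {
  stopifnot(n_metabolites >= 2L, n_reactions >= 1L,
            reversible_fraction >= 0, reversible_fraction <= 1,
            transport_fraction >= 0, transport_fraction <= 1,
            exchange_fraction >= 0, exchange_fraction <= 1)
  n_exchange <- round(exchange_fraction * n_reactions)
  n_transport <- round(transport_fraction * n_reactions)
  n_internal <- n_reactions - n_exchange - n_transport
  if (n_internal < 1L) {
    abort("infeasible spec: transport + exchange leave no internal reactions")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  bases <- sprintf("met%03d", seq_len(n_metabolites))
  cyt <- paste0(bases, "_c")
  currency <- head(default_currency_metabolites(), n_currency)
  currency_c <- paste0(currency, "_c")
  # transported species exist in both compartments
  moved <- sample(bases, min(n_transport, n_metabolites))
  ext <- paste0(moved, "_e")

  internal <- purrr::map(seq_len(n_internal), function(i) {
    ns <- sample(1:3, 1); np <- sample(1:3, 1)
    picks <- sample(cyt, ns + np)
    subs <- setNames(rep(1, ns), picks[seq_len(ns)])
    prods <- setNames(rep(1, np), picks[ns + seq_len(np)])
    if (length(currency_c) && stats::runif(1) < 0.8) {
      cur <- sample(currency_c, min(2L, length(currency_c)))
      subs <- c(subs, setNames(1, cur[1]))
      if (length(cur) > 1L) prods <- c(prods, setNames(1, cur[2]))
    }
    tibble(id = sprintf("RXN%04d", i),
           reversible = stats::runif(1) < reversible_fraction,
           substrates = list(subs), products = list(prods))
  })
  transport <- purrr::map(seq_len(n_transport), function(i) {
    b <- moved[((i - 1L) %% length(moved)) + 1L]
    tibble(id = sprintf("%st", toupper(b)), reversible = FALSE,
           substrates = list(setNames(1, paste0(b, "_e"))),
           products = list(setNames(1, paste0(b, "_c"))))
  })
  exchange <- purrr::map(seq_len(n_exchange), function(i) {
    b <- if (length(moved)) moved[((i - 1L) %% length(moved)) + 1L] else bases[i]
    tibble(id = sprintf("EX_%s_e_%d", b, i), reversible = TRUE,
           substrates = list(setNames(1, paste0(b, "_e"))),
           products = list(setNames(numeric(), character())))
  })
  reactions <- bind_rows(c(internal, transport, exchange))
  if (anyDuplicated(reactions$id)) {
    reactions$id <- make.unique(reactions$id, sep = "_")
  }
  ids <- unique(c(cyt, currency_c, ext,
                  unlist(lapply(c(reactions$substrates, reactions$products),
                                names))))
  metabolic_model(parse_metabolite_id(ids),
                  reactions,
                  name = sprintf("synthetic_seed%d", seed))
}

#' Erdos-Renyi random digraph
#'
#' Each of the n(n-1) ordered pairs receives an arc independently with
#' probability `arc_prob`; no self-arcs. Deterministic given `seed`.
#'
#' @param n Number of nodes (>= 1).
#' @param arc_prob Arc probability in [0, 1].
#' @param seed Integer seed.
#' @return A [reaction_graph()] with nodes `n001`, `n002`, ...
#' @export
random_digraph <- function(n, arc_prob, seed = 1L) {
  stopifnot(n >= 1L, arc_prob >= 0, arc_prob <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < arc_prob
  reaction_graph(nodes, pairs[keep, , drop = FALSE])
}

#' Planted two-clique digraph
#'
#' Two bidirectional cliques of `k` nodes each, joined by a single arc
#' from the first clique to the second — the canonical strongly modular
#' graph used to exercise community detection and the modularity null
#' test.
#'
#' @param k Clique size (>= 2).
#' @return A [reaction_graph()] with 2k nodes.
#' @export
planted_two_clique_graph <- function(k = 5L) {
  stopifnot(k >= 2L)
  clique <- function(nodes) {
    p <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    p[p$from != p$to, ]
  }
  a <- sprintf("a%02d", seq_len(k))
  b <- sprintf("b%02d", seq_len(k))
  arcs <- rbind(clique(a), clique(b),
                data.frame(from = a[1], to = b[1]))
  reaction_graph(c(a, b), arcs)
}
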