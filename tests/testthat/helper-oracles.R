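# Independently coded brute-force oracles. These deliberately share no code
# with the package internals: betweenness enumerates simple paths, the
# cascade oracle re-derives supply by repeated stripping, and modularity
# counts arcs directly.

oracle_betweenness <- function(g) {
  nodes <- g$nodes
  adj <- lapply(setNames(nodes, nodes), function(v) {
    g$arcs$to[g$arcs$from == v]
  })
  b <- setNames(rep(0, length(nodes)), nodes)
  for (j in nodes) {
    for (k in nodes) {
      if (j == k) next
      best <- Inf
      paths <- list()
      rec <- function(path) {
        v <- path[length(path)]
        if (v == k) {
          if (length(path) < best) {
            best <<- length(path)
            paths <<- list(path)
          } else if (length(path) == best) {
            paths[[length(paths) + 1L]] <<- path
          }
          return(invisible())
        }
        if (length(path) >= best) return(invisible())
        for (u in adj[[v]]) if (!u %in% path) rec(c(path, u))
      }
      rec(j)
      if (length(paths)) {
        inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
        if (length(inner)) {
          tt <- table(inner)
          b[names(tt)] <- b[names(tt)] + as.numeric(tt) / length(paths)
        }
      }
    }
  }
  b
}

oracle_clustering <- function(g, v, singleton_value = 0) {
  nb <- unique(c(g$arcs$from[g$arcs$to == v], g$arcs$to[g$arcs$from == v]))
  nb <- setdiff(nb, v)
  k <- length(nb)
  if (k <= 1L) return(singleton_value)
  n_i <- 0L
  for (u in nb) {
    for (w in nb) {
      if (u != w && any(g$arcs$from == u & g$arcs$to == w)) n_i <- n_i + 1L
    }
  }
  n_i / (k * (k - 1))
}

oracle_bridging <- function(g, v, gated = TRUE) {
  din <- sum(g$arcs$to == v)
  dout <- sum(g$arcs$from == v)
  nb <- setdiff(unique(c(g$arcs$from[g$arcs$to == v],
                         g$arcs$to[g$arcs$from == v])), v)
  if (length(nb) == 0L) return(0)
  if (gated && (din == 0L || dout == 0L)) return(0)
  dtot <- function(u) sum(g$arcs$to == u) + sum(g$arcs$from == u)
  (1 / dtot(v)) / sum(vapply(nb, dtot, numeric(1))^-1)
}

# Delete the seed, then repeatedly strip any node whose in-neighbors (in the
# original graph) have all been removed; nodes with no in-arcs never starve.
oracle_cascade <- function(g, v) {
  indeg <- vapply(setNames(g$nodes, g$nodes),
                  function(u) sum(g$arcs$to == u), numeric(1))
  removed <- v
  repeat {
    changed <- FALSE
    for (u in setdiff(g$nodes, removed)) {
      if (indeg[[u]] == 0L) next
      inn <- g$arcs$from[g$arcs$to == u]
      if (all(inn %in% removed)) {
        removed <- c(removed, u)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(setdiff(removed, v))
}

oracle_modularity <- function(g, membership) {
  m <- nrow(g$arcs)
  frac_within <- mean(membership[g$arcs$from] == membership[g$arcs$to])
  expected <- 0
  for (com in unique(membership)) {
    members <- names(membership)[membership == com]
    kout <- sum(g$arcs$from %in% members)
    kin <- sum(g$arcs$to %in% members)
    expected <- expected + (kout / m) * (kin / m)
  }
  frac_within - expected
}

# Upper-tail hypergeometric by direct summation of the pmf.
oracle_hyper_upper <- function(k_obs, n_essential, n_total, n_drawn) {
  xs <- k_obs:min(n_essential, n_drawn)
  sum(choose(n_essential, xs) *
        choose(n_total - n_essential, n_drawn - xs)) /
    choose(n_total, n_drawn)
}
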