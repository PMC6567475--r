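test_that("degree distributions are normalized node-count fractions", {
  d <- degree_distribution(fig1_toy_graph(), "total")
  expect_equal(d$probability[d$degree == 2], 4 / 7)
  expect_equal(d$probability[d$degree == 3], 2 / 7)
  expect_equal(d$probability[d$degree == 4], 1 / 7)
  expect_equal(sum(d$probability), 1)

  single <- degree_distribution(reaction_graph("x"))
  expect_equal(single$degree, 0L)
  expect_equal(single$probability, 1)

  # a bidirectional cycle is 2-in 2-out regular: point mass at 4
  nodes <- letters[1:5]
  ring <- reaction_graph(nodes, data.frame(
    from = c(nodes, nodes[c(2:5, 1)]), to = c(nodes[c(2:5, 1)], nodes)))
  dr <- degree_distribution(ring, "total")
  expect_equal(dr$degree, 4L)
  expect_equal(dr$probability, 1)

  expect_error(degree_distribution(reaction_graph()), "empty")
})

test_that("log-log least squares recovers exact power-law exponents", {
  for (gamma in c(-1.3, -1.5, -2.0)) {
    d <- tibble::tibble(degree = 1:100,
                        probability = (1:100)^gamma)
    fit <- fit_power_law(d)
    expect_equal(fit$gamma, gamma, tolerance = 0.02)
    expect_gt(fit$r_squared, 0.999)
  }

  flat <- tibble::tibble(degree = 1:50, probability = rep(0.02, 50))
  expect_equal(fit_power_law(flat)$gamma, 0, tolerance = 1e-9)

  expect_error(
    fit_power_law(tibble::tibble(degree = 1:2, probability = c(.5, .5))),
    "at least 3")
})

test_that("MLE recovers the exponent of continuous Pareto samples", {
  set.seed(11)
  alpha <- 2.5
  x <- (1 - stats::runif(5000))^(-1 / (alpha - 1))  # Pareto, k_min = 1
  d <- tibble::tibble(degree = x, count = 1L,
                      probability = 1 / length(x))
  fit <- fit_power_law(d, method = "mle")
  expect_equal(fit$gamma, -alpha, tolerance = 0.1)
})

test_that("directed modularity matches hand values and the counting oracle", {
  two_cycles <- reaction_graph(c("a", "b", "c", "d"),
                               data.frame(from = c("a", "b", "c", "d"),
                                          to = c("b", "a", "d", "c")))
  expect_equal(graph_modularity(two_cycles, c(a = 1, b = 1, c = 2, d = 2)),
               0.5)
  # the all-in-one partition can never score above zero
  expect_lte(graph_modularity(two_cycles, c(a = 1, b = 1, c = 1, d = 1)), 0)

  for (i in 1:10) {
    g <- random_digraph(sample(4:10, 1), 0.3, seed = 4000 + i)
    if (nrow(g$arcs) == 0) next
    part <- setNames(sample(1:3, n_nodes(g), replace = TRUE), g$nodes)
    expect_equal(graph_modularity(g, part), oracle_modularity(g, part),
                 tolerance = 1e-12)
  }

  expect_error(graph_modularity(two_cycles, c(a = 1, b = 1, c = 2)),
               "misses node")
})

test_that("greedy detection recovers planted cliques and beats singletons", {
  g <- planted_two_clique_graph(5)
  part <- detect_communities(g)
  expect_equal(length(unique(part$community)), 2L)
  split_by <- split(part$node, part$community)
  expect_setequal(vapply(split_by, function(s) paste(sort(substr(s, 1, 1)),
                                                     collapse = ""),
                         character(1)),
                  c("aaaaa", "bbbbb"))

  toy <- fig1_toy_graph()
  q_found <- attr(detect_communities(toy), "modularity")
  q_singletons <- graph_modularity(toy, setNames(seq_len(7), toy$nodes))
  expect_gte(q_found, q_singletons)

  # no arcs: everyone their own community
  iso <- reaction_graph(c("x", "y"))
  expect_equal(detect_communities(iso)$community, 1:2)

  # the move refinement never scores below plain greedy
  q_move <- attr(detect_communities(toy, method = "move", seed = 2),
                 "modularity")
  expect_gte(q_move, q_found - 1e-12)
})

test_that("rewiring preserves in/out degree sequences exactly", {
  for (i in 1:5) {
    g <- random_digraph(20, 0.12, seed = 5000 + i)
    r <- randomize_degree_preserving(g, seed = i)
    expect_identical(node_degrees(r), node_degrees(g))
    expect_true(all(is.na(r$arcs$metabolites)))
  }
  # a lone 2-cycle admits no legal swap
  cyc <- reaction_graph(c("u", "v"),
                        data.frame(from = c("u", "v"), to = c("v", "u")))
  r <- randomize_degree_preserving(cyc, seed = 1)
  expect_identical(r$arcs[, 1:2], cyc$arcs[, 1:2])
  expect_warning(randomize_degree_preserving(reaction_graph("z")),
                 "fewer than 2 arcs")
})

test_that("rewiring a modular graph destroys modularity on average", {
  g <- planted_two_clique_graph(5)
  obs <- attr(detect_communities(g), "modularity")
  nulls <- vapply(1:30, function(i) {
    attr(detect_communities(randomize_degree_preserving(g, seed = i)),
         "modularity")
  }, numeric(1))
  expect_lt(mean(nulls), obs)
})

test_that("the null test separates planted structure and uses add-one p", {
  g <- planted_two_clique_graph(5)
  nt <- modularity_null_test(g, replicates = 30, seed = 9)
  expect_s3_class(nt, "rg_null_summary")
  expect_equal(nt$empirical_p, 1 / 31)
  expect_gt(nt$observed_modularity, nt$null_mean + 3 * nt$null_sd)
  expect_equal(nrow(tidy(nt)), 30L)
  expect_equal(glance(nt)$replicates, 30L)

  # unstructured graph: observed within 3 null standard deviations
  er <- random_digraph(18, 0.25, seed = 77)
  nt2 <- modularity_null_test(er, replicates = 30, seed = 5)
  expect_lt(abs(nt2$observed_modularity - nt2$null_mean),
            3 * max(nt2$null_sd, 1e-3))
  expect_gt(nt2$empirical_p, 0)
})
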