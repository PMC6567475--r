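synthetic_table <- function(n, metric = "betweenness") {
  tibble::tibble(node = sprintf("r%04d", seq_len(n)),
                 "{metric}" := as.numeric(rev(seq_len(n))))
}

test_that("top-fraction enrichment: proportions and hypergeometric tail", {
  # 100 nodes, 20 essential, the top 5 by metric all essential
  tab <- synthetic_table(100)
  labels <- tibble::tibble(node = tab$node,
                           essential = c(rep(TRUE, 5), rep(FALSE, 80),
                                         rep(TRUE, 15)))
  rep5 <- topk_essential_proportion(tab, labels, "betweenness",
                                    fraction = 0.05)
  expect_equal(rep5$n_top, 5L)
  expect_equal(rep5$proportion_essential, 1)
  expect_equal(rep5$hypergeometric_p,
               choose(20, 5) * choose(80, 0) / choose(100, 5))

  # all labels non-essential: proportion 0, p = 1
  none <- tibble::tibble(node = tab$node, essential = FALSE)
  rep0 <- topk_essential_proportion(tab, none, "betweenness", 0.05)
  expect_equal(rep0$proportion_essential, 0)
  expect_equal(rep0$hypergeometric_p, 1)
})

test_that("hypergeometric p equals exhaustive enumeration on small populations", {
  set.seed(8)
  for (i in 1:20) {
    n_total <- sample(8:30, 1)
    n_ess <- sample(1:(n_total - 1), 1)
    n_top <- sample(1:(n_total - 1), 1)
    tab <- synthetic_table(n_total)
    ess_nodes <- sample(tab$node, n_ess)
    labels <- tibble::tibble(node = tab$node,
                             essential = tab$node %in% ess_nodes)
    rep <- topk_essential_proportion(tab, labels, "betweenness",
                                     n_top = n_top)
    expect_equal(rep$hypergeometric_p,
                 oracle_hyper_upper(rep$n_essential_in_top, n_ess,
                                    n_total, n_top),
                 tolerance = 1e-12)
  }
})

test_that("cutoff ties break lexicographically and order does not matter", {
  tab <- tibble::tibble(node = c("b", "a", "d", "c"),
                        betweenness = c(1, 1, 1, 1))
  labels <- tibble::tibble(node = tab$node,
                           essential = tab$node %in% c("a", "b"))
  rep <- topk_essential_proportion(tab, labels, "betweenness", n_top = 2)
  expect_equal(rep$n_essential_in_top, 2L)  # picks a, b
  shuffled <- topk_essential_proportion(tab[c(3, 1, 4, 2), ], labels,
                                        "betweenness", n_top = 2)
  expect_equal(rep, shuffled)
})

test_that("sparse label coverage triggers a warning", {
  tab <- synthetic_table(100)
  few <- tibble::tibble(node = tab$node[1:10], essential = TRUE)
  expect_warning(topk_essential_proportion(tab, few, "betweenness", 0.05),
                 "cover only")
})

test_that("binned essentiality conserves counts and tracks correlation", {
  tab <- synthetic_table(200, metric = "bridging_centrality")
  # essentiality probability rises with the metric by construction
  set.seed(3)
  labels <- tibble::tibble(
    node = tab$node,
    essential = stats::runif(200) < (tab$bridging_centrality / 200) * 0.9)
  bins <- binned_essentiality(tab, labels, "bridging_centrality", 10)
  expect_equal(sum(bins$n_total), 200L)
  expect_equal(sum(bins$n_essential), sum(labels$essential))
  expect_gt(cor(bins$bin, bins$percent_essential), 0.9)

  uniform <- tibble::tibble(node = tab$node, essential = rep(c(TRUE, FALSE),
                                                             100))
  flat <- binned_essentiality(tab, uniform, "bridging_centrality", 4)
  expect_true(all(abs(flat$percent_essential - 50) < 1e-9))
})

test_that("leading-cascade essentiality reproduces printed percentages", {
  # bins fed with the published E. coli numerators/denominators
  counts <- data.frame(r = 0:7,
                       n = c(697, 127, 26, 21, 13, 4, 2, 4),
                       ess = c(94, 37, 8, 10, 2, 1, 1, 4))
  nodes <- unlist(lapply(0:7, function(r) {
    sprintf("r%d_%04d", r, seq_len(counts$n[r + 1]))
  }))
  cascades <- tibble::tibble(
    node = nodes,
    cascade_number = rep(counts$r, counts$n),
    independent = TRUE)
  labels <- tibble::tibble(
    node = nodes,
    essential = unlist(lapply(0:7, function(r) {
      c(rep(TRUE, counts$ess[r + 1]),
        rep(FALSE, counts$n[r + 1] - counts$ess[r + 1]))
    })))
  summ <- cascade_essentiality_summary(cascades, labels)
  # the published table truncates percentages to one decimal
  trunc1 <- function(x) floor(x * 10) / 10
  expect_equal(trunc1(summ$percent_essential),
               c(13.4, 29.1, 30.7, 47.6, 15.3, 25.0, 50.0, 100.0))
  expect_equal(summ$n_leading, counts$n)
  # printed correlation 0.68 (truncated from the computed value)
  expect_equal(floor(attr(summ, "pearson_r") * 100) / 100, 0.68)
  expect_equal(glance(summ)$pearson_r, attr(summ, "pearson_r"))
})

test_that("constant per-bin percentages give zero correlation", {
  cascades <- tibble::tibble(node = sprintf("n%02d", 1:40),
                             cascade_number = rep(0:3, each = 10),
                             independent = TRUE)
  labels <- tibble::tibble(node = cascades$node,
                           essential = rep(c(TRUE, FALSE), 20))
  summ <- cascade_essentiality_summary(cascades, labels)
  expect_equal(attr(summ, "pearson_r"), 0)
})

test_that("label files parse and validate", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tessential", "ASAD\t1", "HSK\t0"), tf)
  lab <- read_essentiality_labels(tf)
  expect_equal(lab$essential, c(TRUE, FALSE))
  writeLines(c("ASAD\t2"), tf)
  expect_error(read_essentiality_labels(tf), "0 or 1")
  writeLines(c("ASAD\t1", "ASAD\t0"), tf)
  expect_error(read_essentiality_labels(tf), "duplicate")
})
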