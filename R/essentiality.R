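#' Read per-reaction essentiality labels
#'
#' Labels are produced externally (reaction-deletion growth simulation by
#' flux balance analysis: a reaction is essential when its removal drops
#' growth below 5% of wild type); this package only consumes the resulting
#' table. Format: TSV with two columns, `reaction_id` and `essential`
#' (0/1), with or without a header line.
#'
#' @param path TSV file path.
#' @return Tibble with columns `node` and `essential` (logical).
#' @export
read_essentiality_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^reaction_id\t", lines[1])) lines <- lines[-1]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    abort(sprintf("parse error at line %d: expected 2 tab-separated fields",
                  bad[1]))
  }
  m <- do.call(rbind, fields)
  ess <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(ess) || !all(ess %in% c(0L, 1L))) {
    abort("essential column must be 0 or 1")
  }
  if (anyDuplicated(m[, 1])) abort("duplicate reaction id in label file")
  tibble(node = m[, 1], essential = ess == 1L)
}

normalize_labels <- function(labels) {
  labels <- as_tibble(labels)
  if (!all(c("node", "essential") %in% names(labels))) {
    abort("labels need columns `node` and `essential`")
  }
  mutate(labels, essential = as.logical(.data$essential))
}

check_coverage <- function(nodes, labels) {
  covered <- mean(nodes %in% labels$node)
  if (covered < 0.5) {
    warn(sprintf("essentiality labels cover only %.0f%% of graph nodes",
                 100 * covered))
  }
  covered
}

#' Essential-reaction enrichment in the top fraction of a metric
#'
#' Ranks nodes by a centrality (or cascade) metric, takes the top
#' `fraction` (ties at the cutoff broken by lexicographic node id, so the
#' selection is deterministic), and reports the proportion of essential
#' reactions among them together with an upper-tail hypergeometric
#' p-value for that many essentials in a draw of `n_top` from the labeled
#' population.
#'
#' @param table A [centrality_table()] (or [all_cascades()]) tibble.
#' @param labels Tibble with `node` and `essential` columns.
#' @param metric Column of `table` to rank by (e.g.
#'   `"bridging_centrality"`, `"betweenness"`, `"degree_total"`,
#'   `"clustering"`, `"cascade_number"`).
#' @param fraction Top fraction in (0, 1]; `n_top = round(fraction * n)`.
#' @param n_top Optional explicit cutoff count overriding `fraction`
#'   (published tables sometimes floor rather than round).
#' @return One-row tibble: `metric`, `top_fraction`, `n_top`,
#'   `n_essential_in_top`, `proportion_essential`, `hypergeometric_p`.
#' @examples
#' tab <- centrality_table(fig1_toy_graph())
#' lab <- tibble::tibble(node = tab$node, essential = tab$node %in% c("D", "E"))
#' topk_essential_proportion(tab, lab, "betweenness", fraction = 0.3)
#' @export
topk_essential_proportion <- function(table, labels, metric,
                                      fraction = 0.05, n_top = NULL) {
  table <- as_tibble(table)
  labels <- normalize_labels(labels)
  if (!metric %in% names(table)) {
    abort(paste0("no such metric column: ", metric))
  }
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  check_coverage(table$node, labels)
  ranked <- table %>%
    select("node", value = dplyr::all_of(metric)) %>%
    left_join(labels, by = "node") %>%
    arrange(dplyr::desc(.data$value), .data$node)
  if (is.null(n_top)) n_top <- round(fraction * nrow(ranked))
  n_top <- as.integer(n_top)
  if (n_top < 1L) abort("top fraction selects no nodes")
  top <- head(ranked, n_top)
  labeled <- filter(ranked, !is.na(.data$essential))
  n_ess_top <- sum(top$essential, na.rm = TRUE)
  n_ess_all <- sum(labeled$essential)
  p <- phyper(n_ess_top - 1L, m = n_ess_all,
              n = nrow(labeled) - n_ess_all, k = n_top,
              lower.tail = FALSE)
  tibble(metric = metric, top_fraction = n_top / nrow(ranked),
         n_top = n_top, n_essential_in_top = n_ess_top,
         proportion_essential = n_ess_top / n_top,
         hypergeometric_p = p)
}

#' Essentiality by metric bin
#'
#' Splits labeled nodes into `n_bins` bins of the metric — by rank
#' (default, near-equal occupancy) or by equal-width value intervals —
#' and reports per-bin totals, essential counts and percentages. Empty
#' bins report `NA` percentages.
#'
#' @inheritParams topk_essential_proportion
#' @param n_bins Number of bins (>= 2).
#' @param binning `"rank"` (default) or `"value"`.
#' @return Tibble: `bin`, `metric_min`, `metric_max`, `n_total`,
#'   `n_essential`, `percent_essential`.
#' @export
binned_essentiality <- function(table, labels, metric, n_bins = 10L,
                                binning = c("rank", "value")) {
  binning <- match.arg(binning)
  table <- as_tibble(table)
  labels <- normalize_labels(labels)
  if (!metric %in% names(table)) abort(paste0("no such metric column: ", metric))
  if (n_bins < 2L) abort("n_bins must be >= 2")
  d <- table %>%
    select("node", value = dplyr::all_of(metric)) %>%
    dplyr::inner_join(labels, by = "node") %>%
    arrange(.data$value, .data$node)
  if (nrow(d) == 0L) abort("no labeled nodes")
  d$bin <- if (binning == "rank") {
    as.integer(ceiling(seq_len(nrow(d)) / nrow(d) * n_bins))
  } else {
    as.integer(cut(d$value, breaks = n_bins, include.lowest = TRUE))
  }
  out <- d %>%
    group_by(.data$bin) %>%
    summarise(metric_min = min(.data$value), metric_max = max(.data$value),
              n_total = dplyr::n(), n_essential = sum(.data$essential),
              .groups = "drop")
  full <- tibble(bin = seq_len(n_bins)) %>%
    left_join(out, by = "bin") %>%
    mutate(n_total = dplyr::coalesce(.data$n_total, 0L),
           n_essential = dplyr::coalesce(.data$n_essential, 0L),
           percent_essential = ifelse(.data$n_total > 0,
                                      100 * .data$n_essential / .data$n_total,
                                      NA_real_))
  class(full) <- c("rg_binned_essentiality", class(full))
  full
}

#' Essentiality of leading cascade reactions by cascade number
#'
#' Restricts to leading cascade nodes (those whose cascade sets are
#' independent), bins them by cascade number 0, 1, ..., 6 with >= 7
#' pooled, and reports the percentage of essential reactions per bin plus
#' the Pearson correlation between the bin's cascade number (the pooled
#' bin contributes its minimum, 7) and the percentage, over non-empty
#' bins.
#'
#' @param cascades Result of [all_cascades()].
#' @param labels Tibble with `node` and `essential` columns.
#' @param pool_at Cascade numbers >= `pool_at` share one bin (default 7).
#' @return Object of class `rg_cascade_essentiality`: tibble `bin`
#'   (`"0"` ... `"6"`, `">=7"`), `cascade_number` (bin value used for the
#'   correlation), `n_leading`, `n_essential`, `percent_essential`, with
#'   the Pearson r in attribute `"pearson_r"` (also via [glance()]).
#' @export
cascade_essentiality_summary <- function(cascades, labels, pool_at = 7L) {
  cascades <- as_tibble(cascades)
  labels <- normalize_labels(labels)
  if (!all(c("node", "cascade_number", "independent") %in% names(cascades))) {
    abort("`cascades` must come from all_cascades()")
  }
  lead <- cascades %>%
    filter(.data$independent) %>%
    dplyr::inner_join(labels, by = "node") %>%
    mutate(cn = pmin(.data$cascade_number, pool_at))
  if (nrow(lead) == 0L) abort("no labeled leading cascade nodes")
  out <- tibble(cascade_number = seq(0L, pool_at)) %>%
    left_join(lead %>%
                group_by(cn = .data$cn) %>%
                summarise(n_leading = dplyr::n(),
                          n_essential = sum(.data$essential),
                          .groups = "drop"),
              by = c(cascade_number = "cn")) %>%
    mutate(bin = ifelse(.data$cascade_number < pool_at,
                        as.character(.data$cascade_number),
                        paste0(">=", pool_at)),
           n_leading = dplyr::coalesce(.data$n_leading, 0L),
           n_essential = dplyr::coalesce(.data$n_essential, 0L),
           percent_essential = ifelse(.data$n_leading > 0,
                                      100 * .data$n_essential / .data$n_leading,
                                      NA_real_)) %>%
    select("bin", "cascade_number", "n_leading", "n_essential",
           "percent_essential")
  nonempty <- filter(out, .data$n_leading > 0)
  r <- if (nrow(nonempty) >= 2L &&
           stats::sd(nonempty$percent_essential) > 0) {
    cor(nonempty$cascade_number, nonempty$percent_essential)
  } else {
    0
  }
  attr(out, "pearson_r") <- r
  class(out) <- c("rg_cascade_essentiality", class(out))
  out
}

#' @export
glance.rg_cascade_essentiality <- function(x, ...) {
  tibble(pearson_r = attr(x, "pearson_r"),
         n_leading = sum(x$n_leading),
         n_essential = sum(x$n_essential),
         percent_essential = 100 * sum(x$n_essential) / sum(x$n_leading))
}
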