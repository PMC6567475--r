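#' Default currency metabolites
#'
#' Ubiquitous cofactor-like species (compartment-stripped BiGG base ids)
#' removed before graph construction: routing paths through ATP, NAD(P)H,
#' water and the like creates biologically meaningless short paths. The
#' published analyses name ATP, NAD and H2O as examples without listing the
#' full set, so this default is an explicit, versioned choice and every
#' entry point accepts an override.
#'
#' @return Character vector of species_base ids.
#' @export
default_currency_metabolites <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "h2o", "h",
    "pi", "ppi", "co2", "o2", "nh4", "coa", "na1", "q8", "q8h2",
    "fad", "fadh2", "gtp", "gdp", "udp", "ump", "so4")
}

#' Filtering configuration for graph construction
#'
#' @param currency_metabolites Compartment-stripped ids to drop from every
#'   reaction before arcs are formed.
#' @param boundary_prefixes Reaction-id prefixes marking exchange /
#'   boundary pseudo-reactions.
#' @param drop_exchange,drop_transport Remove exchange / transport
#'   reactions before graph construction.
#' @return A `filter_config` list.
#' @export
filter_config <- function(currency_metabolites = default_currency_metabolites(),
                          boundary_prefixes = c("EX_", "DM_", "SK_"),
                          drop_exchange = TRUE, drop_transport = TRUE) {
  if (length(currency_metabolites) == 0L) {
    warn("empty currency metabolite list: no currency filtering applied")
  }
  if (any(grepl("\\[|_[a-z0-9]$", currency_metabolites))) {
    abort("currency metabolites must be compartment-stripped base ids")
  }
  structure(list(currency_metabolites = unique(currency_metabolites),
                 boundary_prefixes = boundary_prefixes,
                 drop_exchange = isTRUE(drop_exchange),
                 drop_transport = isTRUE(drop_transport)),
            class = "filter_config")
}

#' Read a filter configuration from YAML or JSON
#'
#' Recognised keys: `currency_metabolites`, `boundary_prefixes`,
#' `drop_exchange`, `drop_transport`; missing keys take the
#' [filter_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("currency_metabolites", "boundary_prefixes",
             "drop_exchange", "drop_transport")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warn(paste0("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", ")))
  }
  do.call(filter_config, raw[intersect(names(raw), known)])
}

species_base_of <- function(model) {
  setNames(model$metabolites$species_base, model$metabolites$id)
}

compartment_of <- function(model) {
  setNames(model$metabolites$compartment, model$metabolites$id)
}

#' Classify a reaction as exchange, transport or internal
#'
#' Exchange: one side of the reaction is empty (a boundary pseudo-reaction)
#' or the id carries a boundary prefix. Transport: the multiset of
#' compartment-stripped species on the substrate side equals that on the
#' product side while the compartment differs for at least one species —
#' pure cross-membrane shuttling. Everything else is internal.
#'
#' @param model A [metabolic_model()].
#' @param reaction_id Reaction id; omit to classify every reaction.
#' @param config A [filter_config()] (only `boundary_prefixes` is used).
#' @return A tibble with columns `id` and
#'   `class` (`"exchange"`, `"transport"` or `"internal"`).
#' @examples
#' classify_reaction(example_asad_model())
#' @export
classify_reaction <- function(model, reaction_id = NULL,
                              config = filter_config()) {
  stopifnot(is_metabolic_model(model))
  rx <- model$reactions
  if (!is.null(reaction_id)) {
    if (!all(reaction_id %in% rx$id)) {
      abort(paste0("unknown reaction id: ",
                   paste(setdiff(reaction_id, rx$id), collapse = ", ")))
    }
    rx <- filter(rx, .data$id %in% reaction_id)
  }
  base <- species_base_of(model)
  comp <- compartment_of(model)
  classify_one <- function(id, substrates, products) {
    s <- names(substrates); p <- names(products)
    if (length(s) == 0L || length(p) == 0L ||
        any(startsWith(id, config$boundary_prefixes))) {
      return("exchange")
    }
    sb <- sort(base[s]); pb <- sort(base[p])
    if (length(sb) == length(pb) && all(sb == pb) &&
        !identical(sort(paste(base[s], comp[s])),
                   sort(paste(base[p], comp[p])))) {
      return("transport")
    }
    "internal"
  }
  tibble(id = rx$id,
         class = purrr::pmap_chr(
           list(rx$id, rx$substrates, rx$products),
           function(id, substrates, products)
             classify_one(id, substrates, products)))
}

#' Build the directed reaction-centric graph of a metabolic model
#'
#' Reactions become nodes; an arc u -> v exists when some metabolite that u
#' can produce is consumed by v. Reversible reactions act in both
#' directions: their producible set is products plus substrates and
#' likewise for consumables, so two consecutive reversible reactions form a
#' 2-cycle of single nodes. Construction steps: (1) drop exchange and/or
#' transport reactions per `config`; (2) delete currency metabolites from
#' every substrate/product set; (3) drop reactions left without any
#' metabolite; (4) connect producers to consumers, annotating each arc with
#' the mediating metabolite set. Self-arcs are never created; reactions
#' left isolated (but non-empty) stay in the node set, where they carry
#' cascade number zero.
#'
#' @param model A [metabolic_model()].
#' @param config A [filter_config()].
#' @return A [reaction_graph()].
#' @examples
#' build_reaction_graph(example_asad_model())
#' @export
build_reaction_graph <- function(model, config = filter_config()) {
  stopifnot(is_metabolic_model(model))
  cls <- classify_reaction(model, config = config)
  keep <- cls$id
  if (config$drop_exchange) keep <- setdiff(keep, cls$id[cls$class == "exchange"])
  if (config$drop_transport) keep <- setdiff(keep, cls$id[cls$class == "transport"])
  rx <- filter(model$reactions, .data$id %in% keep)

  base <- species_base_of(model)
  currency <- model$metabolites$id[base %in% config$currency_metabolites]
  strip <- function(s) s[!names(s) %in% currency]
  rx <- rx %>%
    mutate(substrates = lapply(.data$substrates, strip),
           products = lapply(.data$products, strip)) %>%
    filter(lengths(.data$substrates) + lengths(.data$products) > 0L)

  if (nrow(rx) == 0L) return(reaction_graph())
  producible <- purrr::pmap(list(rx$products, rx$substrates, rx$reversible),
                            function(p, s, rev)
                              unique(c(names(p), if (rev) names(s))))
  consumable <- purrr::pmap(list(rx$substrates, rx$products, rx$reversible),
                            function(s, p, rev)
                              unique(c(names(s), if (rev) names(p))))
  producers <- tibble(node = rep(rx$id, lengths(producible)),
                      met = unlist(producible))
  consumers <- tibble(node = rep(rx$id, lengths(consumable)),
                      met = unlist(consumable))
  arcs <- if (nrow(producers) && nrow(consumers)) {
    dplyr::inner_join(producers, consumers, by = "met",
                      relationship = "many-to-many",
                      suffix = c("_from", "_to")) %>%
      filter(.data$node_from != .data$node_to) %>%
      group_by(from = .data$node_from, to = .data$node_to) %>%
      summarise(metabolites = paste(sort(unique(.data$met)), collapse = ","),
                .groups = "drop")
  } else {
    NULL
  }
  reaction_graph(rx$id, arcs)
}
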