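#' Metabolic model container
#'
#' A `metabolic_model` holds the stoichiometric content needed to build a
#' reaction-centric graph: a metabolite table and a reaction table.
#' Stoichiometric coefficients are stored for provenance but graph
#' construction only uses presence/absence.
#'
#' @param metabolites Tibble with columns `id`, `species_base`,
#'   `compartment`.
#' @param reactions Tibble with columns `id`, `reversible` (logical),
#'   `substrates`, `products` (list-columns of named numeric vectors:
#'   names are metabolite ids, values strictly positive coefficients).
#' @param name Model name.
#' @return A `metabolic_model` object.
#' @export
metabolic_model <- function(metabolites, reactions, name = "model") {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  if (nrow(metabolites) == 0L) {
    metabolites <- tibble(id = character(), species_base = character(),
                          compartment = character())
  }
  if (nrow(reactions) == 0L) {
    reactions <- tibble(id = character(), reversible = logical(),
                        substrates = list(), products = list())
  }
  if (anyDuplicated(metabolites$id)) abort("duplicate metabolite id")
  if (anyDuplicated(reactions$id)) abort("duplicate reaction id")
  if (any(!nzchar(metabolites$species_base))) {
    abort("metabolite species_base must be non-empty")
  }
  canon_side <- function(s) {
    s <- setNames(as.numeric(s), names(s))
    s[order(names(s))]
  }
  reactions$substrates <- lapply(reactions$substrates, canon_side)
  reactions$products <- lapply(reactions$products, canon_side)
  coefs <- unlist(c(reactions$substrates, reactions$products))
  if (length(coefs) && any(coefs <= 0)) {
    abort("stoichiometric coefficients must be strictly positive")
  }
  used <- unique(unlist(lapply(c(reactions$substrates, reactions$products),
                               names)))
  missing <- setdiff(used, metabolites$id)
  if (length(missing)) {
    abort(paste0("reaction references unknown metabolite(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  structure(list(name = name,
                 metabolites = arrange(metabolites, .data$id),
                 reactions = arrange(reactions, .data$id)),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites, %d reactions\n",
              x$name, nrow(x$metabolites), nrow(x$reactions)))
  invisible(x)
}

#' @rdname metabolic_model
#' @param x Object to test.
#' @export
is_metabolic_model <- function(x) inherits(x, "metabolic_model")

#' Split a metabolite id into base species and compartment
#'
#' BiGG-style ids carry the compartment either as a trailing
#' `"_<compartment>"` suffix (`"glc__D_e"`) or in brackets (`"glc__D[e]"`).
#' Both are recognised; ids without either convention get compartment `""`.
#' A suffix is only treated as a compartment when it is 1-2 alphanumeric
#' characters, so `"4pasp"` keeps its full id as base.
#'
#' @param id Character vector of metabolite ids.
#' @return Tibble with columns `id`, `species_base`, `compartment`.
#' @examples
#' parse_metabolite_id(c("glc__D_e", "aspsa_c", "atp[c]", "4pasp"))
#' @export
parse_metabolite_id <- function(id) {
  id <- as.character(id)
  base <- id
  comp <- rep("", length(id))
  br <- grepl("\\[[A-Za-z0-9]{1,2}\\]$", id)
  base[br] <- sub("\\[[A-Za-z0-9]{1,2}\\]$", "", id[br])
  comp[br] <- sub("^.*\\[([A-Za-z0-9]{1,2})\\]$", "\\1", id[br])
  sf <- !br & grepl(".+_[A-Za-z0-9]{1,2}$", id)
  base[sf] <- sub("_[A-Za-z0-9]{1,2}$", "", id[sf])
  comp[sf] <- sub("^.*_([A-Za-z0-9]{1,2})$", "\\1", id[sf])
  tibble(id = id, species_base = base, compartment = comp)
}

# Build the metabolite table for a set of referenced ids, optionally
# honouring compartments declared elsewhere (e.g. SBML attributes).
infer_metabolites <- function(ids, compartments = NULL) {
  tab <- parse_metabolite_id(unique(ids))
  if (!is.null(compartments)) {
    known <- compartments[tab$id]
    use <- !is.na(known) & nzchar(known)
    tab$compartment[use] <- known[use]
    # when the declared compartment matches the id suffix keep the parsed
    # base; otherwise fall back to the full id as base
    mism <- use & !endsWith(tab$id, paste0("_", known)) &
      !endsWith(tab$id, paste0("[", known, "]"))
    tab$species_base[mism] <- tab$id[mism]
  }
  tab
}
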