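#' Read a genome-scale metabolic model from SBML
#'
#' Supports the SBML Level 2 and Level 3 subset used by BiGG exports:
#' species (with compartment attributes), reactions with reactant/product
#' speciesReferences and stoichiometries, the `reversible` attribute, and
#' lower flux bounds (Level 2 kinetic-law `LOWER_BOUND` parameters or Level
#' 3 `fbc:lowerFluxBound` parameter references). A reaction is treated as
#' reversible when its `reversible` attribute is true *or* its lower flux
#' bound is negative, since BiGG releases encode reversibility both ways.
#' Leading `M_`/`R_` prefixes are stripped so identifiers match BiGG ids.
#'
#' @param path Path to an SBML file.
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort(paste0("not well-formed SBML ('", basename(path), "'): ",
                 conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(model_node)) abort("format error: no <model> element")
  name <- xml2::xml_attr(model_node, "id")
  if (is.na(name)) name <- basename(path)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp) == 0L) abort("format error: no <species> listed")
  sp_id_raw <- xml2::xml_attr(sp, "id")
  if (anyNA(sp_id_raw)) abort("format error: <species> without id")
  sp_id <- sub("^M_", "", sp_id_raw)
  sp_comp <- xml2::xml_attr(sp, "compartment")
  comp_map <- setNames(ifelse(is.na(sp_comp), "", sp_comp), sp_id)
  metabolites <- infer_metabolites(sp_id, comp_map)

  # model-level parameters (SBML L3 / fbc flux bounds live here)
  par <- xml2::xml_find_all(doc, ".//model/listOfParameters/parameter")
  par_val <- setNames(as.numeric(xml2::xml_attr(par, "value")),
                      xml2::xml_attr(par, "id"))

  id_map <- setNames(sp_id, sp_id_raw)
  side <- function(rn, which) {
    refs <- xml2::xml_find_all(rn, paste0("./", which, "/speciesReference"))
    if (length(refs) == 0L) return(stats::setNames(numeric(), character()))
    ids <- xml2::xml_attr(refs, "species")
    st <- xml2::xml_attr(refs, "stoichiometry")
    st <- ifelse(is.na(st), 1, suppressWarnings(as.numeric(st)))
    if (anyNA(st)) {
      abort(paste0("format error: bad stoichiometry in reaction ",
                   xml2::xml_attr(rn, "id")))
    }
    mapped <- unname(id_map[ids])
    mapped[is.na(mapped)] <- ids[is.na(mapped)]  # caught by validator
    c(tapply(abs(st), mapped, sum))  # collapse duplicate references
  }

  rn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rx_id <- sub("^R_", "", xml2::xml_attr(rn, "id"))
  if (anyNA(rx_id)) abort("format error: <reaction> without id")
  rev_attr <- tolower(xml2::xml_attr(rn, "reversible")) %in% "true"
  lb <- vapply(rn, function(r) {
    attrs <- xml2::xml_attrs(r)
    fbc <- attrs[endsWith(names(attrs), "lowerFluxBound")]
    if (length(fbc) == 1L && fbc %in% names(par_val)) {
      return(par_val[[fbc]])
    }
    p <- xml2::xml_find_first(
      r, "./kineticLaw/listOfParameters/parameter[@id='LOWER_BOUND']")
    if (!is.na(p)) {
      v <- suppressWarnings(as.numeric(xml2::xml_attr(p, "value")))
      if (!is.na(v)) return(v)
    }
    NA_real_
  }, numeric(1))
  reversible <- rev_attr | (!is.na(lb) & lb < 0)

  reactions <- tibble(
    id = rx_id,
    reversible = unname(reversible),
    substrates = lapply(rn, side, which = "listOfReactants"),
    products = lapply(rn, side, which = "listOfProducts")
  )
  metabolic_model(metabolites, reactions, name = name)
}

split_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(stats::setNames(numeric(), character()))
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  ids <- sub(":.*$", "", parts)
  co <- ifelse(grepl(":", parts, fixed = TRUE), sub("^[^:]*:", "", parts), "1")
  co_num <- suppressWarnings(as.numeric(co))
  if (anyNA(co_num)) {
    abort(sprintf("parse error at line %d: malformed coefficient '%s'",
                  line_no, co[which(is.na(co_num))[1]]))
  }
  c(tapply(co_num, ids, sum))
}

#' Read or write a plain reaction table
#'
#' The table is a UTF-8 TSV with header
#' `reaction_id  reversible  substrates  products`, where `reversible` is
#' 0/1 and each side lists metabolites as `"id:coeff;id:coeff"` (an empty
#' string is an empty side, as in exchange reactions). Metabolites are
#' inferred from the union of referenced ids via [parse_metabolite_id()].
#'
#' @param path File path.
#' @return `read_reaction_table()` returns a [metabolic_model()].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_reaction_table(example_asad_model(), tf)
#' read_reaction_table(tf)
#' @export
read_reaction_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L ||
      !identical(strsplit(lines[1], "\t")[[1]][1], "reaction_id")) {
    abort("format error: missing 'reaction_id' header")
  }
  body <- lines[-1]
  if (length(body) == 0L) {
    return(metabolic_model(tibble(), tibble(),
                           name = sub("\\.tsv$", "", basename(path))))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  rows <- purrr::imap(fields, function(f, i) {
    ln <- i + 1L
    if (length(f) < 2L) {
      abort(sprintf("parse error at line %d: expected 4 tab-separated fields",
                    ln))
    }
    length(f) <- 4L
    f[is.na(f)] <- ""
    rev_num <- suppressWarnings(as.integer(f[2]))
    if (is.na(rev_num) || !rev_num %in% c(0L, 1L)) {
      abort(sprintf("parse error at line %d: reversible must be 0 or 1", ln))
    }
    tibble(id = f[1], reversible = rev_num == 1L,
           substrates = list(split_side(f[3], ln)),
           products = list(split_side(f[4], ln)))
  })
  reactions <- bind_rows(rows)
  if (anyDuplicated(reactions$id)) {
    abort(paste0("validation error: duplicate reaction id ",
                 reactions$id[duplicated(reactions$id)][1]))
  }
  ids <- unlist(lapply(c(reactions$substrates, reactions$products), names))
  metabolites <- infer_metabolites(unique(ids))
  metabolic_model(metabolites, reactions,
                  name = sub("\\.tsv$", "", basename(path)))
}

#' @rdname read_reaction_table
#' @param model A [metabolic_model()].
#' @export
write_reaction_table <- function(model, path) {
  stopifnot(is_metabolic_model(model))
  fmt_side <- function(s) {
    if (length(s) == 0L) return("")
    s <- s[order(names(s))]
    paste(sprintf("%s:%s", names(s), format(unname(s), trim = TRUE,
                                            scientific = FALSE)),
          collapse = ";")
  }
  lines <- c("reaction_id\treversible\tsubstrates\tproducts",
             purrr::pmap_chr(model$reactions, function(id, reversible,
                                                       substrates, products) {
               paste(id, as.integer(reversible), fmt_side(substrates),
                     fmt_side(products), sep = "\t")
             }))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
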