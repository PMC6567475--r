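# Small SBML documents written in code so no binary fixtures are needed.

write_sbml_l2 <- function(path,
                          species = list(c(id = "M_a_c", comp = "c"),
                                         c(id = "M_b_c", comp = "c")),
                          reactions = list(list(
                            id = "R_R1", reversible = "false",
                            reactants = c("M_a_c"), products = c("M_b_c"),
                            lower = NULL))) {
  sp <- paste(vapply(species, function(s) {
    sprintf('      <species id="%s" name="%s" compartment="%s"/>',
            s[["id"]], s[["id"]], s[["comp"]])
  }, character(1)), collapse = "\n")
  rx <- paste(vapply(reactions, function(r) {
    ref <- function(ids) paste(sprintf(
      '          <speciesReference species="%s" stoichiometry="1"/>', ids),
      collapse = "\n")
    kin <- if (!is.null(r$lower)) sprintf(paste0(
      "        <kineticLaw>\n",
      "          <listOfParameters>\n",
      '            <parameter id="LOWER_BOUND" value="%s"/>\n',
      "          </listOfParameters>\n",
      "        </kineticLaw>\n"), r$lower) else ""
    sprintf(paste0(
      '      <reaction id="%s" reversible="%s">\n',
      "        <listOfReactants>\n%s\n        </listOfReactants>\n",
      "        <listOfProducts>\n%s\n        </listOfProducts>\n%s",
      "      </reaction>"),
      r$id, r$reversible, ref(r$reactants), ref(r$products), kin)
  }, character(1)), collapse = "\n")
  writeLines(sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">\n',
    '  <model id="test_l2">\n',
    '    <listOfCompartments><compartment id="c"/></listOfCompartments>\n',
    "    <listOfSpecies>\n%s\n    </listOfSpecies>\n",
    "    <listOfReactions>\n%s\n    </listOfReactions>\n",
    "  </model>\n</sbml>"), sp, rx), path)
  path
}

write_sbml_l3 <- function(path) {
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
    'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
    'level="3" version="1" fbc:required="false">\n',
    '  <model id="test_l3" fbc:strict="true">\n',
    "    <listOfParameters>\n",
    '      <parameter id="lb_rev" value="-1000" constant="true"/>\n',
    '      <parameter id="lb_irr" value="0" constant="true"/>\n',
    "    </listOfParameters>\n",
    "    <listOfSpecies>\n",
    '      <species id="M_4pasp_c" compartment="c"/>\n',
    '      <species id="M_aspsa_c" compartment="c"/>\n',
    "    </listOfSpecies>\n",
    "    <listOfReactions>\n",
    '      <reaction id="R_ASAD" reversible="false" ',
    'fbc:lowerFluxBound="lb_rev" fbc:upperFluxBound="lb_rev">\n',
    "        <listOfReactants>\n",
    '          <speciesReference species="M_4pasp_c" stoichiometry="1"/>\n',
    "        </listOfReactants>\n",
    "        <listOfProducts>\n",
    '          <speciesReference species="M_aspsa_c" stoichiometry="1"/>\n',
    "        </listOfProducts>\n",
    "      </reaction>\n",
    "    </listOfReactions>\n",
    "  </model>\n</sbml>"), path)
  path
}

# Reaction table for the three-step aspartate branch worked example.
write_asad_table <- function(path) {
  writeLines(c(
    "reaction_id\treversible\tsubstrates\tproducts",
    "ASAD\t1\t4pasp_c:1\taspsa_c:1",
    "HSDy\t1\taspsa_c:1\thom__L_c:1",
    "HSK\t0\thom__L_c:1\tphom_c:1"), path)
  path
}

expect_tbl_equal <- function(x, y) {
  expect_equal(as.data.frame(x), as.data.frame(y))
}
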