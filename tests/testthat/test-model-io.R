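test_that("minimal SBML L2 parses to the smallest valid model", {
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml_l2(tf)
  m <- read_sbml_model(tf)
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$metabolites), 2L)
  expect_equal(nrow(m$reactions), 1L)
  expect_false(m$reactions$reversible[1])
  expect_equal(m$reactions$id, "R1")  # R_ prefix stripped
  expect_equal(m$metabolites$compartment, c("c", "c"))
})

test_that("reversibility combines the reversible flag and lower bounds", {
  tf <- withr::local_tempfile(fileext = ".xml")
  write_sbml_l2(tf, reactions = list(
    list(id = "R_FWD", reversible = "false",
         reactants = "M_a_c", products = "M_b_c", lower = "0"),
    list(id = "R_REV_FLAG", reversible = "true",
         reactants = "M_a_c", products = "M_b_c", lower = "0"),
    list(id = "R_REV_LB", reversible = "false",
         reactants = "M_a_c", products = "M_b_c", lower = "-1000")))
  m <- read_sbml_model(tf)
  rev <- setNames(m$reactions$reversible, m$reactions$id)
  expect_false(rev[["FWD"]])
  expect_true(rev[["REV_FLAG"]])
  expect_true(rev[["REV_LB"]])

  # L3: reversible="false" but fbc lower bound -1000 => reversible
  tf3 <- withr::local_tempfile(fileext = ".xml")
  write_sbml_l3(tf3)
  m3 <- read_sbml_model(tf3)
  expect_true(m3$reactions$reversible[1])
  expect_equal(m3$reactions$id, "ASAD")
})

test_that("malformed SBML and unknown species are rejected with clear errors", {
  tf <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model></sbml>", tf)
  expect_error(read_sbml_model(tf), "well-formed")

  tf2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml_l2(tf2, reactions = list(list(
    id = "R_BAD", reversible = "false",
    reactants = "M_a_c", products = "M_ghost_c", lower = NULL)))
  expect_error(read_sbml_model(tf2), "unknown metabolite")
})

test_that("the aspartate-branch reaction table parses as specified", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_asad_table(tf)
  m <- read_reaction_table(tf)
  expect_equal(nrow(m$reactions), 3L)
  rev <- setNames(m$reactions$reversible, m$reactions$id)
  expect_true(rev[["ASAD"]])
  expect_true(rev[["HSDy"]])
  expect_false(rev[["HSK"]])
  expect_setequal(m$metabolites$id,
                  c("4pasp_c", "aspsa_c", "hom__L_c", "phom_c"))
  expect_equal(m$metabolites$species_base[m$metabolites$id == "4pasp_c"],
               "4pasp")
})

test_that("reaction-table edge cases: empty table, duplicates, bad coefficients", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("reaction_id\treversible\tsubstrates\tproducts", tf)
  m <- read_reaction_table(tf)
  expect_equal(nrow(m$reactions), 0L)
  expect_equal(nrow(m$metabolites), 0L)

  writeLines(c("reaction_id\treversible\tsubstrates\tproducts",
               "R1\t0\ta_c:1\tb_c:1",
               "R1\t0\ta_c:1\tb_c:1"), tf)
  expect_error(read_reaction_table(tf), "duplicate reaction id")

  writeLines(c("reaction_id\treversible\tsubstrates\tproducts",
               "R1\t0\ta_c:one\tb_c:1"), tf)
  expect_error(read_reaction_table(tf), "line 2.*coefficient")
})

test_that("reaction tables round-trip a synthetic model", {
  m <- synthetic_model(n_metabolites = 15, n_reactions = 30, seed = 7)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_table(m, tf)
  m2 <- read_reaction_table(tf)
  expect_equal(m2$reactions, m$reactions)
  # the table format carries only referenced metabolites
  ref <- dplyr::semi_join(m$metabolites, m2$metabolites, by = "id")
  expect_equal(as.data.frame(m2$metabolites), as.data.frame(ref))
})

test_that("metabolite id parsing handles suffixes, brackets and bare ids", {
  p <- parse_metabolite_id(c("glc__D_e", "atp[c]", "4pasp", "aspsa_c"))
  expect_equal(p$species_base, c("glc__D", "atp", "4pasp", "aspsa"))
  expect_equal(p$compartment, c("e", "c", "", "c"))
})

test_that("graph files round-trip in both formats and validate on read", {
  set.seed(42)
  for (i in 1:10) {
    g <- random_digraph(sample(2:12, 1), runif(1, 0, 0.4), seed = i)
    tf <- withr::local_tempfile(fileext = ".tsv")
    write_reaction_graph(g, tf)
    expect_identical(read_reaction_graph(tf), g)
    tg <- withr::local_tempfile(fileext = ".graphml")
    write_reaction_graph(g, tg, format = "graphml")
    expect_identical(read_reaction_graph(tg, format = "graphml"), g)
  }

  # annotated arcs survive the trip
  toy <- build_reaction_graph(example_asad_model())
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_graph(toy, tf)
  expect_identical(read_reaction_graph(tf), toy)

  # empty graph -> header-only file
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_graph(reaction_graph(), tf2)
  expect_equal(readLines(tf2), "from\tto\tmetabolites")
  expect_equal(n_nodes(read_reaction_graph(tf2)), 0L)

  # the worked-example toy graph writes one line per arc
  tf3 <- withr::local_tempfile(fileext = ".tsv")
  write_reaction_graph(fig1_toy_graph(), tf3)
  expect_length(readLines(tf3), 1L + 9L)

  # duplicate and self-arc lines are rejected
  tf4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("from\tto\tmetabolites", "A\tB\t", "A\tB\t"), tf4)
  expect_error(read_reaction_graph(tf4), "duplicate arc")
  writeLines(c("from\tto\tmetabolites", "A\tA\t"), tf4)
  expect_error(read_reaction_graph(tf4), "self-arc")
})
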