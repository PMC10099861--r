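test_that("minimal SBML documents parse to the expected network", {
  path <- withr::local_tempfile(fileext = ".xml")
  net <- metabolic_network("mini", list(
    reaction("R1", c(A = 1), c(B = 1), genes = "g1", pathways = "PWY1")))
  write_sbml(net, path)
  back <- read_sbml(path)
  expect_length(back$reactions, 1L)
  expect_setequal(back$metabolites$id, c("A", "B"))
  expect_false(back$reactions$R1$reversible)

  rev_net <- metabolic_network("mini2", list(
    reaction("R1", c(A = 1), c(B = 1), reversible = TRUE)))
  write_sbml(rev_net, path)
  expect_true(read_sbml(path)$reactions$R1$reversible)
})

test_that("SBML fbc gene associations and stoichiometries are parsed", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1">',
    '<model id="m"><listOfSpecies><species id="A"/><species id="B"/></listOfSpecies>',
    '<listOfReactions><reaction id="R1" reversible="true">',
    '<fbc:geneProductAssociation><fbc:or>',
    '<fbc:geneProductRef fbc:geneProduct="g1"/>',
    '<fbc:geneProductRef fbc:geneProduct="g2"/>',
    '</fbc:or></fbc:geneProductAssociation>',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), path)
  net <- read_sbml(path)
  expect_setequal(net$reactions$R1$genes, c("g1", "g2"))
  expect_equal(net$reactions$R1$products, c(B = 2))
  expect_true(net$reactions$R1$reversible)
})

test_that("SBML parse and reference errors are reported", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><listOfReactions>", path)
  expect_error(read_sbml(path), class = "holoscope_format_error")
  writeLines(c(
    '<sbml level="3" version="1"><model id="m">',
    '<listOfSpecies><species id="A"/></listOfSpecies>',
    '<listOfReactions><reaction id="R1" reversible="false">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '<listOfProducts><speciesReference species="GHOST"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>'), path)
  expect_error(read_sbml(path), "GHOST", class = "holoscope_validation_error")
})

test_that("generator networks round-trip through both dialects", {
  holo <- generate_holobiont(n_bins = 3, reactions_per_bin = 10, seed = 7)
  for (net in c(holo$catalog$networks[1:2], list(holo$host))) {
    sbml <- withr::local_tempfile(fileext = ".xml")
    write_sbml(net, sbml)
    expect_network_equal(net, read_sbml(sbml))
    rx <- withr::local_tempfile(fileext = ".tsv")
    gm <- withr::local_tempfile(fileext = ".tsv")
    write_network_tsv(net, rx, gm)
    expect_network_equal(net, read_network_tsv(rx, gm))
  }
})

test_that("TSV dialect parses rows and gene maps as specified", {
  rx <- withr::local_tempfile(fileext = ".tsv")
  gm <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tsubstrates\tproducts\treversible\tpathways",
               "R1\tA:1\tB:1\t0\tPWY1"), rx)
  writeLines(c("gene_id\treaction_id", "g1\tR1", "g2\tR1"), gm)
  net <- read_network_tsv(rx, gm)
  r1 <- net$reactions$R1
  expect_equal(r1$substrates, c(A = 1))
  expect_false(r1$reversible)
  expect_identical(r1$pathways, "PWY1")
  expect_setequal(r1$genes, c("g1", "g2"))

  writeLines(c("gene_id\treaction_id", "g1\tRZ"), gm)
  expect_error(read_network_tsv(rx, gm), "RZ",
               class = "holoscope_validation_error")
  writeLines(c("reaction_id\tsubstrates\tproducts\treversible\tpathways",
               "R1\tA;1\tB:1\t0\t"), rx)
  expect_error(read_network_tsv(rx), class = "holoscope_format_error")
})

test_that("merge_networks unions by id and rejects stoichiometry conflicts", {
  n1 <- metabolic_network("b1", list(
    reaction("R1", c(A = 1), c(B = 1), genes = "g1"),
    reaction("R2", c(B = 1), c(C = 1))))
  n2 <- metabolic_network("b2", list(
    reaction("R1", c(A = 1), c(B = 1), genes = "g3"),
    reaction("R3", c(C = 1), c(D = 1))))

  solo <- merge_networks(list(n1), "x")
  expect_network_equal(solo, n1)

  m <- merge_networks(list(n1, n2), "meta")
  expect_setequal(m$reactions$R1$genes, c("g1", "g3"))
  expect_length(m$reactions, 3L)

  # |reactions(merged)| <= sum of members, equality iff no shared ids
  shared <- length(intersect(names(n1$reactions), names(n2$reactions)))
  expect_equal(length(m$reactions),
               length(n1$reactions) + length(n2$reactions) - shared)

  # associativity/commutativity up to label on conflict-free inputs
  n3 <- metabolic_network("b3", list(reaction("R4", c(D = 1), c(E = 1))))
  m_abc <- merge_networks(list(merge_networks(list(n1, n2)), n3), "z")
  m_cba <- merge_networks(list(n3, merge_networks(list(n2, n1))), "z")
  expect_network_equal(m_abc, m_cba)

  conflict <- metabolic_network("b4", list(
    reaction("R1", c(A = 2), c(B = 1))))
  expect_error(merge_networks(list(n1, conflict)), "R1",
               class = "holoscope_conflict_error")
})

test_that("validate_network reports exactly the planted corruptions", {
  good <- random_toy_network(10, seed = 3)
  expect_identical(nrow(validate_network(good)), 0L)

  # corrupt by hand: dangling reference + empty side
  bad <- good
  bad$reactions[[1]]$substrates <- c(UNDECLARED_MET = 1)
  bad$reactions[[2]]$products <- numeric(0)
  report <- validate_network(bad)
  expect_setequal(report$type, c("dangling_reference", "empty_reaction"))
  expect_true("UNDECLARED_MET" %in% report$id)
  expect_true(bad$reactions[[2]]$id %in% report$id)

  # every generator-emitted network validates
  holo <- generate_holobiont(n_bins = 4, reactions_per_bin = 8, seed = 11)
  for (net in c(holo$catalog$networks, list(holo$host))) {
    expect_identical(nrow(validate_network(net)), 0L)
  }
})

test_that("seed sets read from TSV and JSON", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite_id", "GLC", "WATER"), tsv)
  s <- read_seeds(tsv)
  expect_setequal(as.character(s), c("GLC", "WATER"))

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "medium", metabolites = c("GLC", "Pi")),
                       js, auto_unbox = TRUE)
  s2 <- read_seeds(js)
  expect_identical(attr(s2, "label"), "medium")
  expect_setequal(as.character(s2), c("GLC", "Pi"))
  expect_error(seed_set(character(0)), class = "holoscope_validation_error")
})
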