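test_that("JSON model round-trip preserves every component", {
  m <- miniYeastFixture()$model
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f)
  m2 <- readModel(f)
  expect_identical(nReactions(m2), nReactions(m))
  expect_identical(nMetabolites(m2), nMetabolites(m))
  expect_equal(lowerBounds(m2), lowerBounds(m))
  expect_equal(upperBounds(m2), upperBounds(m))
  expect_equal(as.matrix(stoichiometry(m2))[metaboliteIds(m),
                                            reactionIds(m)],
               as.matrix(stoichiometry(m)))
  expect_identical(geneRules(m2), geneRules(m))
  expect_identical(isExchange(m2), isExchange(m))
  expect_identical(objectiveReaction(m2), objectiveReaction(m))
  expect_identical(carbonExchange(m2), carbonExchange(m))
  expect_identical(taggedReactions(m2, "respiration"),
                   taggedReactions(m, "respiration"))
})

test_that("SBML model round-trip preserves structure, bounds, rules, tags", {
  m <- miniYeastFixture()$model
  f <- withr::local_tempfile(fileext = ".xml")
  writeModel(m, f)
  m2 <- readModel(f)
  expect_identical(nReactions(m2), nReactions(m))
  expect_equal(lowerBounds(m2), lowerBounds(m))
  expect_equal(upperBounds(m2), upperBounds(m))
  expect_equal(as.matrix(stoichiometry(m2))[metaboliteIds(m),
                                            reactionIds(m)],
               as.matrix(stoichiometry(m)))
  # rules round-trip functionally (parenthesization may differ)
  expect_identical(reactionsDisabledByGenes(m2, c("PYC1", "PYC2")),
                   reactionsDisabledByGenes(m, c("PYC1", "PYC2")))
  expect_identical(sort(geneIds(m2)), sort(geneIds(m)))
  expect_identical(taggedReactions(m2, "g6p_isomerase"),
                   taggedReactions(m, "g6p_isomerase"))
  expect_identical(isExchange(m2), isExchange(m))
  expect_identical(carbonExchange(m2), carbonExchange(m))
  # and the loaded model optimizes identically
  fy <- miniYeastFixture()
  expect_equal(objectiveValue(fba(applyMedium(m2, fy$medium))),
               objectiveValue(fba(applyMedium(m, fy$medium))),
               tolerance = 1e-9)
})

test_that("model loading rejects invariant violations with the culprit named", {
  f <- withr::local_tempfile(fileext = ".json")
  doc <- list(
    compartments = list(c = "cytosol"),
    metabolites = list(list(id = "a_c", compartment = "c")),
    reactions = list(list(id = "BAD", metabolites = list(a_c = -1),
                          lower_bound = 5, upper_bound = 1,
                          objective_coefficient = 1)))
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(readModel(f), "BAD")
  doc$reactions[[1]]$lower_bound <- 0
  doc$reactions[[1]]$objective_coefficient <- 0
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(readModel(f), "objective")
  doc$reactions[[1]]$objective_coefficient <- 1
  doc$reactions[[1]]$metabolites <- list(ghost_c = -1)
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(readModel(f), "BAD.*ghost_c")
})

test_that("equation parsing handles coefficients, reversibility, errors", {
  eq <- parseEquation("2 accoa_c -> phb_c")
  expect_equal(eq$stoich[["accoa_c"]], -2)
  expect_equal(eq$stoich[["phb_c"]], 1)
  expect_false(eq$reversible)
  expect_true(parseEquation("a_c <-> b_c")$reversible)
  expect_error(parseEquation("a_c b_c"), "arrow")
  expect_error(parseEquation("2x a_c -> b_c"), "coefficient|term")
})

test_that("pathway tables parse into grafted-ready definitions", {
  pw <- readPathwayTable(system.file("extdata", "mini_yeast_pathways.tsv",
                                     package = "chassisDesign"))
  expect_length(pw, 3)
  # one core reaction + synthesized transport + synthesized exchange
  expect_length(pw$prdA@reactions, 3)
  expect_identical(productExchange(pw$prdA), "EX_prdA")
  # the synthesized exchange drives screening identically to the built-in
  fy <- miniYeastFixture()
  host <- applyMedium(fy$model, fy$medium)
  host <- applyCuration(host, fy$curation)$model
  host <- removeBlockedReactions(host, fy$medium)$model
  pmFile <- buildProducerModel(host, pw$prdC)
  expect_equal(objectiveValue(fba(pmFile)),
               objectiveValue(fba(miniProducer("prdC"))), tolerance = 1e-9)
})

test_that("pathway tables with distinct products give one definition each", {
  f <- withr::local_tempfile(fileext = ".tsv")
  lines <- c("product\treaction_id\tequation\tlb\tub",
             vapply(1:29, function(i)
               sprintf("p%02d\tRX%02d\tpyr_c -> p%02d_c\t0\t1000",
                       i, i, i), character(1)))
  writeLines(lines, f)
  pw <- readPathwayTable(f)
  expect_length(pw, 29)
})

test_that("unparseable pathway equations report the line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("product\treaction_id\tequation\tlb\tub",
               "p1\tR1\tpyr_c -> p1_c\t0\t1000",
               "p1\tR2\tjunk equation without arrow\t0\t1000"), f)
  expect_error(readPathwayTable(f), "line 3")
})

test_that("design reports are canonical and byte-deterministic", {
  ev <- data.frame(
    knockout_set = c("b+a", "c"), n_ko = c(2L, 1L),
    mu_max = c(1.23456789012, 2), p_min = c(0.1, 0),
    v_glc = c(10, 10), growth_yield = c(123.456789012, 200),
    product_yield = c(0.01, 0), survives = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  ev$knockout_set <- vapply(strsplit(ev$knockout_set, "+", fixed = TRUE),
                            function(x) paste(sort(x), collapse = "+"),
                            character(1))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeDesignReport(ev, f1, product = "p")
  writeDesignReport(ev[2:1, ], f2, product = "p")  # permuted input
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  tab <- read.delim(f1)
  expect_identical(tab$knockout_set[1], "a+b")
  # empty evaluations: header-only file
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeDesignReport(ev[0, ], f3, product = "p")
  expect_length(readLines(f3), 1L)
})

test_that("curation and background configs round-trip through YAML", {
  acts <- list(curationAction("merge_duplicates"),
               curationAction("block_secretion", exchange = "EX_acald"),
               curationAction("set_bounds", reaction = "PGI",
                              lb = 0, ub = 1000))
  f <- withr::local_tempfile(fileext = ".yaml")
  writeCurationConfig(acts, f)
  back <- readCurationConfig(f)
  expect_identical(lapply(back, unclass), lapply(acts, unclass))
  bg <- readBackgroundsConfig(system.file("extdata", "backgrounds.yaml",
                                          package = "chassisDesign"))
  expect_identical(bg$glycine_serine, c("SDH3", "SER3", "SER33"))
  expect_identical(bg$tca_reroute, c("ICL1", "KGD1", "PYC1"))
})

test_that("medium tables parse and apply", {
  md <- readMediumTable(system.file("extdata", "mini_yeast_medium.tsv",
                                    package = "chassisDesign"))
  expect_identical(md@carbonSource, "EX_glc")
  m <- applyMedium(miniYeastFixture()$model, md)
  expect_equal(unname(lowerBounds(m)[["EX_glc"]]), -10)
  expect_equal(unname(lowerBounds(m)[["EX_o2"]]), -2)
  # unlisted exchange uptake closed, secretion untouched
  expect_equal(unname(lowerBounds(m)[["EX_gal"]]), 0)
  expect_equal(unname(upperBounds(m)[["EX_etoh"]]), 1000)
})
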