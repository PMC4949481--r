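test_that("duplicate reactions merge with OR-united gene rules", {
  m <- makeModel(list(
    chassisDesign:::.exch("EX_a", "a_e", lb = -10),
    chassisDesign:::.rxn("T1", c(a_e = -1, a_c = 1), gene = "G1"),
    chassisDesign:::.rxn("T2", c(a_e = -1, a_c = 1), gene = "G2"),
    chassisDesign:::.rxn("BIOMASS", c(a_c = -1), tags = "biomass")
  ), objective = "BIOMASS", carbonExchange = "EX_a")
  out <- applyCuration(m, list(curationAction("merge_duplicates")))
  expect_identical(nReactions(out$model), 3L)
  rule <- geneRules(out$model)[["T1"]]
  expect_true(evalGeneRule(parseGeneRule(rule), "G1"))   # isoenzyme left
  expect_false(evalGeneRule(parseGeneRule(rule), c("G1", "G2")))
  expect_match(out$log, "merge_duplicates", all = FALSE)
  # growth unaffected by the merge
  expect_equal(objectiveValue(fba(out$model)), objectiveValue(fba(m)),
               tolerance = 1e-9)
})

test_that("block_secretion closes only the secretion direction", {
  m <- miniYeastFixture()$model
  m <- setBounds(m, "EX_acald", lb = -10, ub = 1000)
  out <- applyCuration(m, list(curationAction("block_secretion",
                                              exchange = "EX_acald")))
  expect_equal(unname(lowerBounds(out$model)[["EX_acald"]]), -10)
  expect_equal(unname(upperBounds(out$model)[["EX_acald"]]), 0)
})

test_that("curation edge cases: identity, missing target, idempotence", {
  m <- miniYeastFixture()$model
  expect_equal(applyCuration(m, list())$model, m)
  expect_error(
    applyCuration(m, list(curationAction("remove_reaction",
                                         reaction = "NOPE"))),
    "action 1.*NOPE")
  acts <- miniYeastFixture()$curation
  once <- applyCuration(m, acts)$model
  twice <- applyCuration(once, acts)$model
  expect_equal(twice, once)
})

test_that("set_bounds, unconstrain_transport and replace_reaction apply", {
  m <- miniYeastFixture()$model
  out <- applyCuration(m, list(
    curationAction("set_bounds", reaction = "PGI", lb = 0, ub = 500),
    curationAction("unconstrain_transport", reaction = "O2t"),
    curationAction("replace_reaction", reaction = "AGX",
                   stoich = c(glx_c = -1, nh4_c = -1, gly_c = 1),
                   geneRule = "AGX1 or AGX2")))
  expect_equal(unname(lowerBounds(out$model)[["PGI"]]), 0)
  expect_equal(unname(upperBounds(out$model)[["PGI"]]), 500)
  expect_identical(unname(lowerBounds(out$model)[["O2t"]]), -Inf)
  expect_identical(geneRules(out$model)[["AGX"]], "AGX1 or AGX2")
})

test_that("blocked-reaction removal drops dead ends and closed routes only", {
  # chain plus a dead-end branch: B -> D with D unconsumed
  ents <- list(
    chassisDesign:::.exch("EX_sub", "sub_e", lb = -10),
    chassisDesign:::.rxn("R1", c(sub_e = -1, b_c = 1)),
    chassisDesign:::.rxn("RDEAD", c(b_c = -1, d_c = 1)),
    chassisDesign:::.rxn("BIOMASS", c(b_c = -1), tags = "biomass")
  )
  m <- makeModel(ents, objective = "BIOMASS", carbonExchange = "EX_sub")
  md <- methods::new("MediumDefinition",
                     exchanges = data.frame(exchange = "EX_sub",
                                            maxUptake = 10,
                                            maxSecretion = 0,
                                            stringsAsFactors = FALSE),
                     carbonSource = "EX_sub")
  out <- removeBlockedReactions(m, md)
  expect_identical(out$removed, "RDEAD")
  expect_true(all(c("R1", "BIOMASS") %in% reactionIds(out$model)))
  # chain alone: nothing to remove
  m2 <- makeChainModel(2)
  md2 <- methods::new("MediumDefinition",
                      exchanges = data.frame(exchange = "EX_sub",
                                             maxUptake = 10,
                                             maxSecretion = 0,
                                             stringsAsFactors = FALSE),
                      carbonSource = "EX_sub")
  expect_length(removeBlockedReactions(m2, md2)$removed, 0)
  # mini-yeast: the galactose route behind its closed exchange is blocked,
  # confirmed independently by a feasibility FVA giving a (0, 0) interval
  fy <- miniYeastFixture()
  withMedium <- applyMedium(fy$model, fy$medium)
  rng <- fva(withMedium, c("GALt", "GALK"), anchor = NULL)
  expect_equal(rng$min, c(0, 0), tolerance = 1e-9)
  expect_equal(rng$max, c(0, 0), tolerance = 1e-9)
  out3 <- removeBlockedReactions(fy$model, fy$medium)
  expect_true(all(c("GALt", "GALK", "EX_gal") %in% out3$removed))
  # removal never changes an optimum computable in the original model
  expect_equal(objectiveValue(fba(out3$model)),
               objectiveValue(fba(withMedium)), tolerance = 1e-9)
})

test_that("producer models add exactly the pathway and keep host optima", {
  fy <- miniYeastFixture()
  host <- applyMedium(fy$model, fy$medium)
  host <- removeBlockedReactions(host, fy$medium)$model
  before <- nReactions(host)
  pm <- buildProducerModel(host, fy$pathways$prdA)
  expect_identical(nReactions(pm), before + 3L)
  expect_true(all(c("PWY_A", "PRDAt", "EX_prdA") %in% reactionIds(pm)))
  expect_identical(taggedReactions(pm, "product_exchange"), "EX_prdA")
  # pathway is optional: host growth optimum unchanged
  expect_equal(objectiveValue(fba(pm)), objectiveValue(fba(host)),
               tolerance = 1e-9)
  # closing the product exchange reproduces the host optimum too
  closed <- setBounds(pm, "EX_prdA", lb = 0, ub = 0)
  expect_equal(objectiveValue(fba(closed)), objectiveValue(fba(host)),
               tolerance = 1e-9)
})

test_that("endogenous products graft as an exchange-only pathway", {
  fy <- miniYeastFixture()
  host <- applyMedium(fy$model, fy$medium)
  # glycerol is endogenous and already reaches glyc_e: exchange-only graft
  pw <- methods::new("PathwayDefinition", productId = "succ",
                     productName = "endogenous acid",
                     reactions = list(
                       chassisDesign:::.rxn("SUCCt", c(succ_c = -1,
                                                       succ_e = 1)),
                       chassisDesign:::.exch("EX_succ", "succ_e",
                                             lb = 0, ub = 1000,
                                             tags = "product_exchange")),
                     exchangeId = "EX_succ", notes = "")
  pm <- buildProducerModel(host, pw)
  expect_identical(nReactions(pm), nReactions(host) + 2L)
  expect_error(buildProducerModel(pm, pw), "collide")
})

test_that("pathways consuming unknown metabolites are rejected", {
  fy <- miniYeastFixture()
  host <- applyMedium(fy$model, fy$medium)
  pw <- methods::new("PathwayDefinition", productId = "px",
                     productName = "broken",
                     reactions = list(
                       chassisDesign:::.rxn("PX", c(unobtainium_c = -1,
                                                    px_c = 1)),
                       chassisDesign:::.exch("EX_px", "px_c", lb = 0,
                                             tags = "product_exchange")),
                     exchangeId = "EX_px", notes = "")
  expect_error(buildProducerModel(host, pw), "unobtainium_c")
})
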