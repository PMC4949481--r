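# Session-cached fixtures: the mini-yeast fixture and its producer models are
# deterministic, so building them once keeps the suite fast.

.fixtureCache <- new.env(parent = emptyenv())

miniYeastFixture <- function() {
  if (is.null(.fixtureCache$fy)) .fixtureCache$fy <- makeMiniYeast()
  .fixtureCache$fy
}

miniProducer <- function(product) {
  key <- paste0("prod_", product)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- miniYeastProducer(product, miniYeastFixture())
  .fixtureCache[[key]]
}

# hand-built fermentative reference for the redox toy: all NADH drains
# through fermentation, no product flux (steady-state feasible by inspection)
rt1FermentativeReference <- function() {
  methods::new("FluxDistribution",
               fluxes = c(EX_glc = -10, Rgly = 10, Biomass = 10, Ferm = 10,
                          Prod = 0, EX_eth = 10, EX_p = 0),
               provenance = "manual", objectiveValue = 10)
}

# tiny linear producer: substrate -> x1 -> product, with a biomass drain on
# the intermediate; used for essentiality checks on a fully bounded model
makeChainProducer <- function() {
  makeModel(list(
    chassisDesign:::.exch("EX_sub", "sub_e", lb = -10, ub = 0),
    chassisDesign:::.rxn("R1", c(sub_e = -1, x1_c = 1), gene = "G1",
                         ub = 100),
    chassisDesign:::.rxn("R2", c(x1_c = -1, p_c = 1), gene = "G2",
                         ub = 100),
    chassisDesign:::.rxn("PT", c(p_c = -1, p_e = 1), ub = 100),
    chassisDesign:::.exch("EX_p", "p_e", lb = 0, ub = 100,
                          tags = "product_exchange"),
    chassisDesign:::.rxn("BIOMASS", c(x1_c = -1), ub = 100,
                         tags = "biomass")
  ), objective = "BIOMASS", carbonExchange = "EX_sub")
}

# two parallel routes from substrate to an intermediate feeding the product
makeParallelProducer <- function() {
  makeModel(list(
    chassisDesign:::.exch("EX_sub", "sub_e", lb = -10, ub = 0),
    chassisDesign:::.rxn("RA", c(sub_e = -1, x1_c = 1), gene = "GA",
                         ub = 100),
    chassisDesign:::.rxn("RB", c(sub_e = -1, x1_c = 1), gene = "GB",
                         ub = 100),
    chassisDesign:::.rxn("R2", c(x1_c = -1, p_e = 1), gene = "G2",
                         ub = 100),
    chassisDesign:::.exch("EX_p", "p_e", lb = 0, ub = 100,
                          tags = "product_exchange"),
    chassisDesign:::.rxn("BIOMASS", c(x1_c = -1), ub = 100,
                         tags = "biomass")
  ), objective = "BIOMASS", carbonExchange = "EX_sub")
}

# bounded redox toy for vertex-enumeration oracles (finite bounds throughout)
makeBoundedRedoxToy <- function() {
  m <- makeRedoxCouplingModel()
  setBounds(m, reactionIds(m)[upperBounds(m) > 100], ub = 100)
}
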