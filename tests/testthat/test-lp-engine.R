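test_that("FBA solves substrate-limited chains and detects degenerate inputs", {
  m <- makeChainModel(3)
  expect_equal(objectiveValue(fba(m)), 10, tolerance = 1e-9)
  closed <- setBounds(m, "EX_sub", lb = 0)
  expect_equal(objectiveValue(fba(closed)), 0, tolerance = 1e-9)
  rt <- makeRedoxCouplingModel()
  expect_equal(objectiveValue(fba(rt)), 10, tolerance = 1e-9)
})

test_that("FBA optimum matches vertex enumeration on bounded toys", {
  for (m in list(makeBoundedRedoxToy(), makeChainProducer(),
                 makeParallelProducer())) {
    lp <- fba(m)
    vo <- fbaVertexOracle(m)
    expect_equal(lp@objective, vo$objective, tolerance = 1e-7)
  }
})

test_that("infeasible and unbounded problems are reported as statuses", {
  # forced uptake with no outlet: infeasible
  m <- makeChainModel(1)
  m <- setBounds(m, "BIOMASS", lb = 0, ub = 0)
  m <- setBounds(m, "EX_sub", lb = -10, ub = -10)
  out <- fba(m)
  expect_identical(lpStatus(out), "infeasible")
  # open-ended cycle through two opposed unbounded reactions
  m2 <- makeModel(list(
    chassisDesign:::.rxn("F", c(a_c = -1, b_c = 1), lb = -Inf, ub = Inf),
    chassisDesign:::.rxn("G", c(b_c = -1, a_c = 1), lb = -Inf, ub = Inf)
  ), objective = "F")
  expect_identical(lpStatus(fba(m2)), "unbounded")
})

test_that("two-stage optimization pins stage 1 and is self-consistent", {
  rt <- makeRedoxCouplingModel()
  wt <- twoStageOptimum(rt, c("Biomass", "max"), c("EX_p", "min"))
  expect_equal(objectiveValue(wt$first), 10, tolerance = 1e-9)
  expect_equal(objectiveValue(wt$second), 0, tolerance = 1e-6)
  ko <- applyKnockouts(rt, "Ferm")
  cp <- twoStageOptimum(ko, c("Biomass", "max"), c("EX_p", "min"))
  expect_equal(objectiveValue(cp$first), 10, tolerance = 1e-9)
  expect_equal(objectiveValue(cp$second), 10, tolerance = 1e-4)
  # second = first reproduces the stage-1 optimum within delta
  self <- twoStageOptimum(rt, c("Biomass", "max"), c("Biomass", "min"))
  expect_equal(objectiveValue(self$second), objectiveValue(self$first),
               tolerance = 1e-5)
  # stage-1 infeasibility propagates
  dead <- setBounds(rt, "EX_glc", lb = -10, ub = -10)
  dead <- setBounds(dead, "Rgly", lb = 0, ub = 0)
  both <- twoStageOptimum(dead, c("Biomass", "max"), c("EX_p", "min"))
  expect_identical(lpStatus(both$first), "infeasible")
  expect_identical(lpStatus(both$second), "infeasible")
})

test_that("pFBA minimizes total flux and silences futile cycles", {
  m <- makeChainModel(2)
  out <- pfba(m)
  expect_equal(objectiveValue(out), 40, tolerance = 1e-6)
  # add a reversible futile pair off the chain: must stay at zero
  ents <- list(
    chassisDesign:::.exch("EX_sub", "sub_e", lb = -10),
    chassisDesign:::.rxn("R1", c(sub_e = -1, x1_c = 1)),
    chassisDesign:::.rxn("R2", c(x1_c = -1, x2_c = 1)),
    chassisDesign:::.rxn("CYC1", c(x1_c = -1, w_c = 1), lb = -1000),
    chassisDesign:::.rxn("CYC2", c(w_c = -1, x1_c = 1), lb = -1000),
    chassisDesign:::.rxn("BIOMASS", c(x2_c = -1), tags = "biomass")
  )
  mc <- makeModel(ents, objective = "BIOMASS", carbonExchange = "EX_sub")
  outc <- pfba(mc)
  v <- fluxes(outc)
  expect_equal(unname(abs(v[c("CYC1", "CYC2")])), c(0, 0),
               tolerance = 1e-7)
  expect_equal(objectiveValue(outc), 40, tolerance = 1e-6)
  # redox toy: both NADH-sink routings give the same minimal total flux
  rt <- makeRedoxCouplingModel()
  viaFerm <- pfba(setBounds(rt, "Prod", ub = 0))
  viaProd <- pfba(setBounds(rt, "Ferm", ub = 0))
  expect_equal(objectiveValue(viaFerm), objectiveValue(viaProd),
               tolerance = 1e-6)
  expect_equal(objectiveValue(pfba(rt)), objectiveValue(viaFerm),
               tolerance = 1e-6)
  # parsimony: total flux is never above that of a plain FBA solution
  plain <- fba(rt)
  expect_lte(objectiveValue(pfba(rt)),
             sum(abs(fluxes(plain))) + 1e-6)
})

test_that("FVA brackets flux capacity and contains FBA/pFBA solutions", {
  m <- makeChainModel(3)
  rng <- fva(m, anchor = list("BIOMASS", 1))
  expect_equal(rng$min, c(-10, 10, 10, 10, 10), tolerance = 1e-6)
  expect_equal(rng$max, c(-10, 10, 10, 10, 10), tolerance = 1e-6)
  # two substitutable routes: each spans (0, 10)
  pp <- makeParallelProducer()
  rng2 <- fva(pp, c("RA", "RB"), anchor = list("BIOMASS", 1))
  expect_equal(rng2$min, c(0, 0), tolerance = 1e-6)
  expect_equal(rng2$max, c(10, 10), tolerance = 1e-6)
  rt <- makeRedoxCouplingModel()
  rng3 <- fva(rt, c("Prod", "Ferm"), anchor = list("Biomass", 1))
  expect_equal(rng3$min, c(0, 0), tolerance = 1e-5)
  expect_equal(rng3$max, c(10, 10), tolerance = 1e-5)
  # anchored FBA and pFBA fluxes lie inside the intervals
  full <- fva(rt, anchor = list("Biomass", 1))
  vf <- fluxes(fba(rt))[full$id]
  vp <- fluxes(pfba(rt))[full$id]
  expect_true(all(vf >= full$min - 1e-5 & vf <= full$max + 1e-5))
  expect_true(all(vp >= full$min - 1e-5 & vp <= full$max + 1e-5))
})

test_that("the two solver backends agree on small models", {
  set.seed(7)
  models <- list(makeBoundedRedoxToy(), makeChainProducer(),
                 makeParallelProducer())
  for (m in models) {
    a <- fba(m, backend = "tableau")
    b <- fba(m, backend = "reference")
    expect_equal(a@objective, b@objective, tolerance = 1e-6)
  }
  # two-stage stage-2 value is backend-invariant despite degenerate
  # stage-1 alternates (the point of the robust construction)
  rt <- makeBoundedRedoxToy()
  ko <- applyKnockouts(rt, "Ferm")
  t1 <- twoStageOptimum(ko, c("Biomass", "max"), c("EX_p", "min"),
                        backend = "tableau")
  t2 <- twoStageOptimum(ko, c("Biomass", "max"), c("EX_p", "min"),
                        backend = "reference")
  expect_equal(objectiveValue(t1$second), objectiveValue(t2$second),
               tolerance = 1e-6)
})

test_that("returned solutions satisfy mass balance and bounds", {
  for (m in list(makeChainModel(2), makeRedoxCouplingModel(),
                 miniProducer("prdB"))) {
    out <- fba(m)
    expect_true(checkSteadyState(m, out@flux))
    outp <- pfba(m)
    expect_true(checkSteadyState(m, outp@flux))
  }
})
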