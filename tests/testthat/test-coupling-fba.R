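test_that("design enumeration counts follow the binomial expansion", {
  expect_length(enumerateDesigns(paste0("r", 1:10), 2), 10 + 45)
  expect_length(enumerateDesigns(paste0("r", 1:4), 3), 4 + 6 + 4)
  withBg <- enumerateDesigns(paste0("r", 1:3), 1, backgrounds = list("x"))
  expect_length(withBg, 6)
  expect_identical(vapply(withBg[4:6], function(d) d$background,
                          character(1)), rep("x", 3))
  # overlap between background and candidates is removed from the pool
  expect_message(
    ov <- enumerateDesigns(c("a", "b", "c"), 1, backgrounds = list("a")),
    "overlap")
  expect_length(ov, 3 + 2)
})

test_that("candidate policy excludes the genetically unimplementable", {
  pm <- miniProducer("prdA")
  cand <- candidateDeletions(pm)
  expect_length(intersect(cand, exchangeReactions(pm)), 0)
  expect_false(objectiveReaction(pm) %in% cand)
  expect_length(intersect(cand, taggedReactions(pm, "heterologous")), 0)
  expect_length(intersect(cand, taggedReactions(pm, "maintenance")), 0)
  rules <- geneRules(pm)[cand]
  expect_true(all(nzchar(rules)))
  expect_identical(cand, sort(cand))
  # "all internal" policy keeps rule-free internal reactions too
  all_int <- candidateDeletions(pm, policy = list(requireGeneRule = FALSE))
  expect_true(all(cand %in% all_int))
  expect_true("O2t" %in% all_int)
})

test_that("design evaluation reproduces the redox-toy hand values", {
  rt <- makeRedoxCouplingModel()
  coupled <- evaluateDesign(rt, "Ferm")
  expect_equal(coupled$mu_max, 10, tolerance = 1e-6)
  expect_equal(coupled$p_min, 10, tolerance = 1e-4)
  expect_equal(coupled$product_yield, 1.0, tolerance = 1e-5)
  wt <- evaluateDesign(rt, character())
  expect_equal(wt$mu_max, 10, tolerance = 1e-6)
  expect_equal(wt$p_min, 0, tolerance = 1e-6)
  cut <- evaluateDesign(rt, "Rgly")   # sole catabolic route removed
  expect_identical(cut$mu_max, 0)
  expect_identical(cut$product_yield, 0)
})

test_that("yield filters implement the three inclusive thresholds", {
  base <- data.frame(knockout_set = c("a", "b", "c"), n_ko = 1L,
                     mu_max = 1, p_min = 1, v_glc = 10,
                     growth_yield = 100,
                     product_yield = c(1.0, 0.95, 0.5),
                     stringsAsFactors = FALSE)
  out <- filterDesigns(base, filterConfig())
  expect_identical(out$survives, c(TRUE, TRUE, FALSE))
  # growth yield below 1e-2 g/mol is rejected regardless of product yield
  low <- base; low$growth_yield <- 0.005
  expect_false(any(filterDesigns(low, filterConfig())$survives))
  # absolute floor: a lone solution at 5e-4 mol/mol is dropped
  lone <- base[1, ]; lone$product_yield <- 5e-4
  expect_false(filterDesigns(lone, filterConfig())$survives)
  # thresholds are inclusive (>=, not >)
  atFloor <- base[1, ]; atFloor$product_yield <- 1e-3
  expect_true(filterDesigns(atFloor, filterConfig())$survives)
  atGrowth <- base[1, ]; atGrowth$growth_yield <- 1e-2
  expect_true(filterDesigns(atGrowth, filterConfig())$survives)
  justBelow <- base[1, ]; justBelow$growth_yield <- 1e-2 * (1 - 1e-9)
  expect_false(filterDesigns(justBelow, filterConfig())$survives)
  # relative rule: exactly 90% of the maximum survives
  rel <- base; rel$product_yield <- c(1.0, 0.9, 0.9 * (1 - 1e-9))
  expect_identical(filterDesigns(rel, filterConfig())$survives,
                   c(TRUE, TRUE, FALSE))
  # the per-product maximum is computed before filtering
  mixed <- base
  mixed$growth_yield <- c(0.005, 100, 100)   # best yield fails growth
  mixed$product_yield <- c(1.0, 0.95, 0.89)
  out2 <- filterDesigns(mixed, filterConfig())
  expect_identical(out2$survives, c(FALSE, TRUE, FALSE))
})

test_that("screening recovers the planted redox coupling and nothing else", {
  rt <- makeRedoxCouplingModel()
  sc <- screenProduct(rt, maxSize = 2)
  expect_identical(sc$knockout_set[sc$survives], "Ferm")
  expect_identical(attr(sc, "product"), "p")
  summ <- attr(sc, "summary")
  expect_equal(summ$best_product_yield[summ$n_ko == 1], 1.0,
               tolerance = 1e-5)
  # removing the heterologous reaction leaves nothing to couple
  gutted <- applyCuration(rt, list(curationAction("remove_reaction",
                                                  reaction = "Prod")))$model
  sc0 <- screenProduct(gutted, candidateDeletions(gutted), maxSize = 2)
  expect_false(any(sc0$survives))
})

test_that("lethal-subset pruning loses nothing", {
  pm <- miniProducer("prdB")
  cand <- candidateDeletions(pm)
  pruned <- screenProduct(pm, cand, maxSize = 2, prune = TRUE)
  full <- screenProduct(pm, cand, maxSize = 2, prune = FALSE)
  expect_identical(pruned$knockout_set[pruned$survives],
                   full$knockout_set[full$survives])
  # and the full evaluation tables agree wherever both evaluated
  both <- merge(pruned, full, by = "knockout_set")
  expect_equal(both$mu_max.x, both$mu_max.y, tolerance = 1e-6)
})

test_that("backgrounds constrain the free enumeration", {
  pm <- miniProducer("prdC")
  bgGenes <- readBackgroundsConfig(
    system.file("extdata", "backgrounds.yaml", package = "chassisDesign"))
  bg <- mapBackgroundGenes(pm, bgGenes)
  expect_identical(sort(bg$glycine_serine), c("SDH", "SER"))
  cand <- c("ADH", "PDC", "RESP", "GPD")
  sc <- screenProduct(pm, cand, maxSize = 1, backgrounds = bg["tca_reroute"])
  keys <- sc$knockout_set
  expect_true(any(grepl("ICL", keys) & grepl("KGD", keys)))
  expect_length(keys, 4 + 4)  # four bare singles + four on the background
})

test_that("surviving designs are robustly coupled (zero-product infeasible)", {
  # direct certificate: product pinned to zero at near-maximal growth
  checkCertificate <- function(model, ev) {
    pex <- chassisDesign:::.productExchangeOf(model)
    for (i in which(ev$survives)) {
      kos <- strsplit(ev$knockout_set[i], "+", fixed = TRUE)[[1]]
      mut <- applyKnockouts(model, kos)
      mut <- setBounds(mut, pex, lb = 0, ub = 0)
      floor <- ev$mu_max[i] * (1 - 1e-6)
      mut <- setBounds(mut, objectiveReaction(mut), lb = floor)
      expect_identical(lpStatus(fba(mut)), "infeasible",
                       label = paste("certificate for", ev$knockout_set[i]))
      expect_gt(ev$p_min[i], 0)
    }
  }
  rt <- makeRedoxCouplingModel()
  checkCertificate(rt, screenProduct(rt, maxSize = 2))
})
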