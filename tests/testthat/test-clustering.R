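test_that("binary distance counts discordant positions over the union", {
  m <- rbind(x = c(1, 1, 1, 0), y = c(1, 0, 0, 1))
  expect_equal(as.numeric(binaryDistance(m)), 3 / 4)
  same <- rbind(a = c(1, 0, 2), b = c(1, 0, 2))
  expect_equal(as.numeric(binaryDistance(same)), 0)
  zero <- rbind(a = c(0, 0), b = c(0, 0))
  expect_equal(as.numeric(binaryDistance(zero)), 0)  # empty-union rule
  # nonzero magnitude is irrelevant, only the on/off pattern counts
  mag <- rbind(x = c(5, 0.1, 3, 0), y = c(1, 0, 0, 9))
  expect_equal(as.numeric(binaryDistance(mag)), 3 / 4)
})

test_that("euclidean distance is the plain L2 row metric", {
  expect_equal(as.numeric(euclideanDistance(rbind(c(0, 0), c(3, 4)))), 5)
  expect_equal(as.numeric(euclideanDistance(rbind(c(1, 2), c(1, 2)))), 0)
  expect_equal(as.numeric(euclideanDistance(rbind(c(1, -1), c(-1, 1)))),
               sqrt(8))
})

test_that("distance properties hold on random profile matrices", {
  set.seed(42)
  for (rep in 1:5) {
    M <- matrix(rbinom(40, 1, 0.4) * runif(40, 0.5, 2), 8, 5,
                dimnames = list(paste0("p", 1:8), NULL))
    for (d in list(binaryDistance(M), euclideanDistance(M))) {
      D <- as.matrix(d)
      expect_equal(D, t(D))
      expect_equal(unname(diag(D)), rep(0, 8))
    }
    # triangle inequality for the euclidean metric
    D <- as.matrix(euclideanDistance(M))
    for (i in 1:8) for (j in 1:8) for (k in 1:8)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("average linkage reproduces the worked agglomeration", {
  D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- averageLinkage(as.dist(D))
  expect_equal(hc$height, c(0.2, 0.7))   # (0.6 + 0.8) / 2
  expect_identical(sort(cutree(hc, 2)[c("A", "B")]), c(A = 1L, B = 1L))
  # two leaves: a single merge at their distance
  hc2 <- averageLinkage(as.dist(matrix(c(0, .3, .3, 0), 2,
                                       dimnames = list(c("u", "v"),
                                                       c("u", "v")))))
  expect_equal(hc2$height, 0.3)
  # all-equal distances: every merge at the same height
  Dflat <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Dflat) <- 0
  expect_equal(averageLinkage(as.dist(Dflat))$height, rep(0.5, 3))
  expect_error(averageLinkage(as.dist(matrix(0, 1, 1))), "two")
})

test_that("average linkage agrees with the stats reference on random data", {
  set.seed(99)
  for (rep in 1:5) {
    M <- matrix(rnorm(60), 10, 6,
                dimnames = list(paste0("p", 1:10), NULL))
    d <- euclideanDistance(M)   # continuous: ties have probability zero
    mine <- averageLinkage(d)
    ref <- stats::hclust(d, method = "average")
    expect_equal(mine$height, ref$height, tolerance = 1e-12)
    for (k in 2:5) {
      a <- cutree(mine, k); b <- cutree(ref, k)
      # same partition up to label renumbering
      expect_identical(unname(table(a, b) > 0) %*% rep(1, k),
                       matrix(1, k, 1))
    }
  }
})

test_that("the dendrogram is invariant to input row permutation", {
  set.seed(7)
  M <- matrix(rbinom(30, 1, 0.5), 6, 5,
              dimnames = list(paste0("p", 1:6), NULL))
  M[2, ] <- M[1, ]   # force exact ties
  hc1 <- averageLinkage(binaryDistance(M))
  perm <- sample(6)
  hc2 <- averageLinkage(binaryDistance(M[perm, ]))
  expect_equal(sort(hc1$height), sort(hc2$height), tolerance = 1e-12)
  for (k in 2:4) {
    a <- cutree(hc1, k)[paste0("p", 1:6)]
    b <- cutree(hc2, k)[paste0("p", 1:6)]
    expect_identical(unname(table(a, b) > 0) %*% rep(1, k),
                     matrix(1, k, 1))
  }
})

test_that("newick export preserves the tree", {
  D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- averageLinkage(as.dist(D))
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(hc, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  # A and B are sisters in the exported topology
  mrcaAB <- ape::getMRCA(phy, c("A", "B"))
  expect_false(mrcaAB == ape::getMRCA(phy, c("A", "C")))
})

test_that("precursor profiles report net native-metabolite exchange", {
  fy <- miniYeastFixture()
  P <- precursorMatrix(fy$pathways, fy$model)
  expect_equal(P["prdC", "pyr_c"], -1)
  expect_equal(P["prdC", "nadh_c"], -1)
  expect_equal(P["prdA", "accoa_c"], -2)
  expect_equal(P["prdA", "nadph_c"], -1)
  expect_equal(P["prdB", "e4p_c"], -1)
  # a pathway releasing CO2 shows it as production
  pwCO2 <- methods::new("PathwayDefinition", productId = "px",
    productName = "decarboxylating", reactions = list(
      chassisDesign:::.rxn("PX", c(pyr_c = -1, px_c = 1, co2_c = 1)),
      chassisDesign:::.rxn("PXt", c(px_c = -1, px_e = 1)),
      chassisDesign:::.exch("EX_px", "px_e", lb = 0,
                            tags = "product_exchange")),
    exchangeId = "EX_px", notes = "")
  P2 <- precursorMatrix(list(pwCO2), fy$model)
  expect_equal(P2["px", "co2_c"], 1)
  expect_equal(P2["px", "pyr_c"], -1)
})

test_that("branched pathways report the cheapest (minimal-flux) route", {
  fy <- miniYeastFixture()
  # two routes to the product: direct from pyruvate, or a two-step detour
  # burning an extra ATP; the minimal-total-flux solution takes the direct one
  pw <- methods::new("PathwayDefinition", productId = "px",
    productName = "branched", reactions = list(
      chassisDesign:::.rxn("PX1", c(pyr_c = -1, px_c = 1)),
      chassisDesign:::.rxn("PX2a", c(pyr_c = -1, atp_c = -1, mid_c = 1)),
      chassisDesign:::.rxn("PX2b", c(mid_c = -1, px_c = 1)),
      chassisDesign:::.rxn("PXt", c(px_c = -1, px_e = 1)),
      chassisDesign:::.exch("EX_px", "px_e", lb = 0,
                            tags = "product_exchange")),
    exchangeId = "EX_px", notes = "")
  P <- precursorMatrix(list(pw), fy$model)
  expect_equal(P["px", "pyr_c"], -1)
  expect_false("atp_c" %in% colnames(P)[P["px", ] != 0])
  # unreachable products are an error naming the product
  broken <- methods::new("PathwayDefinition", productId = "py",
    productName = "broken", reactions = list(
      chassisDesign:::.rxn("PY1", c(pyr_c = -1, py_c = 1), ub = 0),
      chassisDesign:::.exch("EX_py", "py_c", lb = 0,
                            tags = "product_exchange")),
    exchangeId = "EX_py", notes = "")
  expect_error(precursorMatrix(list(broken), fy$model), "py")
})
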