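#' Linear chain toy model
#'
#' A substrate exchange (uptake capped at 10 mmol/gDW/h), \code{nSteps}
#' sequential 1:1 conversion steps and a biomass sink. The FBA optimum is 10
#' for any chain length; with two conversion steps the parsimonious total flux
#' is 40 (uptake plus three unit-stoichiometry steps, each at 10).
#'
#' @param nSteps number of conversion steps (>= 1)
#' @return a \linkS4class{MetabolicModel} with \code{nSteps + 2} reactions
#' @export
makeChainModel <- function(nSteps) {
  if (!is.numeric(nSteps) || nSteps < 1)
    stop("nSteps must be >= 1")
  nSteps <- as.integer(nSteps)
  mets <- c("sub_e", paste0("x", seq_len(nSteps), "_c"))
  rx <- list(.exch("EX_sub", "sub_e", lb = -10, ub = 1000))
  for (i in seq_len(nSteps)) {
    rx[[length(rx) + 1L]] <- .rxn(
      paste0("R", i),
      stats::setNames(c(-1, 1), c(mets[i], mets[i + 1])),
      gene = paste0("G", i))
  }
  rx[[length(rx) + 1L]] <- .rxn("BIOMASS",
                                stats::setNames(-1, mets[nSteps + 1]),
                                tags = "biomass")
  makeModel(rx, objective = "BIOMASS", carbonExchange = "EX_sub")
}

#' Redox-coupling toy model
#'
#' A minimal network in which a heterologous product pathway can become the
#' growth-optimal sink for reduced cofactors, mirroring designs where a
#' heterologous dehydrogenase provides an NADH outlet. Glucose uptake (10) is
#' catabolized to \code{pyrPerSubstrate} pyruvate plus
#' \code{nadhPerSubstrate} NADH; biomass drains pyruvate; fermentation
#' (\code{Ferm}) and the heterologous product reaction (\code{Prod}) each
#' consume one pyruvate and one NADH. With the defaults (2 pyruvate, 1 NADH)
#' the wild type secretes no product at maximal growth, while knocking out
#' \code{Ferm} makes the product the only NADH sink: growth stays at 10 and
#' the minimal product flux at maximal growth is 10 (1 mol/mol glucose).
#'
#' @param nadhPerSubstrate NADH formed per glucose catabolized (default 1)
#' @param pyrPerSubstrate pyruvate formed per glucose catabolized (default 2)
#' @return a \linkS4class{MetabolicModel}
#' @export
makeRedoxCouplingModel <- function(nadhPerSubstrate = 1,
                                   pyrPerSubstrate = 2) {
  if (pyrPerSubstrate <= 0)
    stop("pyrPerSubstrate must be positive: no carbon reaches biomass")
  if (nadhPerSubstrate < 0)
    stop("nadhPerSubstrate must be non-negative")
  catab <- c(glc_e = -1, pyr_c = pyrPerSubstrate)
  if (nadhPerSubstrate > 0) catab <- c(catab, nadh_c = nadhPerSubstrate)
  rx <- list(
    .exch("EX_glc", "glc_e", lb = -10, ub = 1000),
    .rxn("Rgly", catab, gene = "GLK1"),
    .rxn("Biomass", c(pyr_c = -1), tags = "biomass"),
    .rxn("Ferm", c(pyr_c = -1, nadh_c = -1, eth_e = 1), gene = "ADH1"),
    .rxn("Prod", c(pyr_c = -1, nadh_c = -1, p_e = 1), gene = "ldhA",
         tags = "heterologous"),
    .exch("EX_eth", "eth_e", lb = 0, ub = 1000),
    .exch("EX_p", "p_e", lb = 0, ub = 1000, tags = "product_exchange")
  )
  m <- makeModel(rx, objective = "Biomass", carbonExchange = "EX_glc")
  chk <- fba(m)
  if (chk@status != "optimal" || chk@objective <= 1e-9)
    stop("parameter combination gives no growth (max biomass = ",
         if (chk@status == "optimal") chk@objective else chk@status,
         "); increase pyrPerSubstrate or relax nadhPerSubstrate")
  m
}

# ---- mini-yeast fixture ----------------------------------------------------

# Central-carbon host emulating respiro-fermentative yeast: glycolysis,
# oxidative + non-oxidative PPP, TCA cycle with glyoxylate shunt, ethanol
# fermentation, acetate/acetyl-CoA route, serine/glycine/C1 loop with a
# threonine-aldolase bypass, a lumped respiratory chain (oxygen-capped so
# overflow metabolism is active at optimum), and an ATP maintenance drain.
# Cofactors NADH/NADPH/ATP are tracked as their reduced/charged forms with
# the oxidized partners implicit. Carbon counts are carried in the metabolite
# formulas so mass balance is testable.
.miniYeastReactions <- function() {
  list(
    # exchanges
    .exch("EX_glc", "glc_e", lb = -10, ub = 1000),
    .exch("EX_o2", "o2_e", lb = -2, ub = 0),
    .exch("EX_nh4", "nh4_e", lb = -1000, ub = 0),
    .exch("EX_co2", "co2_e", lb = 0, ub = 1000),
    .exch("EX_etoh", "etoh_e", lb = 0, ub = 1000),
    .exch("EX_acald", "acald_e", lb = 0, ub = 1000),
    .exch("EX_gal", "gal_e", lb = 0, ub = 0),
    # transport
    .rxn("GLCt", c(glc_e = -1, glc_c = 1), gene = "HXT1"),
    .rxn("O2t", c(o2_e = -1, o2_c = 1)),
    .rxn("CO2t", c(co2_c = -1, co2_e = 1)),
    .rxn("ETOHt", c(etoh_c = -1, etoh_e = 1)),
    .rxn("ACALDt", c(acald_c = -1, acald_e = 1)),
    .rxn("NH4t", c(nh4_e = -1, nh4_c = 1), gene = "MEP1"),
    .rxn("GALt", c(gal_e = -1, gal_c = 1), gene = "GAL2"),
    .rxn("GALK", c(gal_c = -1, atp_c = -1, g6p_c = 1), gene = "GAL1"),
    # glycolysis (lumped lower part)
    .rxn("HXK", c(glc_c = -1, atp_c = -1, g6p_c = 1), gene = "HXK2"),
    .rxn("PGI", c(g6p_c = -1, f6p_c = 1), lb = -1000, gene = "PGI1",
         tags = "g6p_isomerase"),
    .rxn("PFK", c(f6p_c = -1, atp_c = -1, t3p_c = 2), gene = "PFK1"),
    .rxn("TDH", c(t3p_c = -1, pg3_c = 1, nadh_c = 1, atp_c = 1),
         gene = "TDH1"),
    .rxn("PYK", c(pg3_c = -1, pyr_c = 1, atp_c = 1), gene = "PYK1"),
    # pentose phosphate pathway
    .rxn("ZWF", c(g6p_c = -1, r5p_c = 1, co2_c = 1, nadph_c = 2),
         gene = "ZWF1"),
    .rxn("TKTA", c(r5p_c = -2, f6p_c = 1, e4p_c = 1), lb = -1000,
         gene = "TKL1"),
    .rxn("TKTB", c(f6p_c = -1, t3p_c = -1, r5p_c = 1, e4p_c = 1),
         lb = -1000, gene = "TKL2"),
    # fermentation and acetate
    # glycerol branch: the NADH valve of fermentative growth
    .rxn("GPD", c(t3p_c = -1, nadh_c = -1, glyc_c = 1), gene = "GPD1"),
    .rxn("GLYCt", c(glyc_c = -1, glyc_e = 1), gene = "FPS1"),
    .exch("EX_glyc", "glyc_e", lb = 0, ub = 1000),
    .rxn("PDC", c(pyr_c = -1, acald_c = 1, co2_c = 1), gene = "PDC1"),
    .rxn("ADH", c(acald_c = -1, nadh_c = -1, etoh_c = 1), gene = "ADH1"),
    .rxn("ALD6", c(acald_c = -1, ac_c = 1, nadph_c = 1), gene = "ALD6"),
    .rxn("ACS", c(ac_c = -1, atp_c = -2, accoa_c = 1), gene = "ACS1"),
    # TCA cycle and glyoxylate shunt (cytosolic lump)
    .rxn("PDA", c(pyr_c = -1, accoa_c = 1, co2_c = 1, nadh_c = 1),
         gene = "PDA1"),
    .rxn("PYC", c(pyr_c = -1, co2_c = -1, atp_c = -1, oaa_c = 1),
         gene = "PYC1 or PYC2"),
    .rxn("CITa", c(accoa_c = -1, oaa_c = -1, cit_c = 1), gene = "CIT1"),
    .rxn("CITb", c(accoa_c = -1, oaa_c = -1, cit_c = 1), gene = "CIT2"),
    .rxn("ACO", c(cit_c = -1, icit_c = 1), lb = -1000, gene = "ACO1"),
    .rxn("IDH", c(icit_c = -1, akg_c = 1, co2_c = 1, nadh_c = 1),
         gene = "IDH1"),
    .rxn("IDP", c(icit_c = -1, akg_c = 1, co2_c = 1, nadph_c = 1),
         gene = "IDP2"),
    .rxn("KGD", c(akg_c = -1, succ_c = 1, co2_c = 1, nadh_c = 1),
         gene = "KGD1"),
    .rxn("SDH", c(succ_c = -1, fum_c = 1, nadh_c = 1), gene = "SDH3"),
    .rxn("FUM", c(fum_c = -1, mal_c = 1), lb = -1000, gene = "FUM1"),
    .rxn("MDH", c(mal_c = -1, oaa_c = 1, nadh_c = 1), lb = -1000,
         gene = "MDH1"),
    .rxn("ICL", c(icit_c = -1, succ_c = 1, glx_c = 1), gene = "ICL1"),
    .rxn("MLS", c(accoa_c = -1, glx_c = -1, mal_c = 1), gene = "MLS1"),
    # serine / glycine / C1
    .rxn("SER", c(pg3_c = -1, nh4_c = -1, ser_c = 1, nadh_c = 1),
         gene = "SER3 or SER33"),
    .rxn("SHMT", c(ser_c = -1, gly_c = 1, c1_c = 1), lb = -1000,
         gene = "SHM2"),
    .rxn("GCV", c(gly_c = -1, c1_c = 1, co2_c = 1, nh4_c = 1, nadh_c = 1),
         gene = "GCV1"),
    .rxn("AGX", c(glx_c = -1, nh4_c = -1, gly_c = 1), gene = "AGX1"),
    .rxn("THR", c(oaa_c = -1, atp_c = -1, nadph_c = -2, nh4_c = -1,
                  thr_c = 1), gene = "HOM3"),
    .rxn("THA", c(thr_c = -1, gly_c = 1, acald_c = 1), gene = "GLY1"),
    # respiration lump and maintenance
    .rxn("RESP", c(nadh_c = -1, o2_c = -0.5, atp_c = 2), gene = "COX1",
         tags = "respiration"),
    .rxn("ATPM", c(atp_c = -1), lb = 1, ub = 1000, tags = "maintenance"),
    # biomass (flux = specific growth rate, 1/h)
    .rxn("BIOMASS",
         c(g6p_c = -0.3, r5p_c = -0.2, e4p_c = -0.1, pyr_c = -0.5,
           accoa_c = -0.2, oaa_c = -0.2, akg_c = -0.2, ser_c = -0.15,
           gly_c = -0.15, c1_c = -0.1, nh4_c = -0.5, atp_c = -2,
           nadph_c = -0.4),
         tags = "biomass")
  )
}

.miniYeastCarbons <- c(
  glc = 6, gal = 6, g6p = 6, f6p = 6, t3p = 3, pg3 = 3, pyr = 3, r5p = 5,
  e4p = 4, accoa = 2, oaa = 4, cit = 6, icit = 6, akg = 5, succ = 4,
  fum = 4, mal = 4, glx = 2, ser = 3, gly = 2, c1 = 1, thr = 4, acald = 2,
  ac = 2, etoh = 2, glyc = 3, co2 = 1, prdA = 4, prdB = 7, prdC = 3,
  nadh = 0, nadph = 0, atp = 0, nh4 = 0, o2 = 0
)

.miniYeastPathways <- function() {
  pw <- function(pid, pname, core, notes) {
    methods::new("PathwayDefinition", productId = pid, productName = pname,
                 reactions = c(core, list(
                   .rxn(paste0(toupper(pid), "t"),
                        stats::setNames(c(-1, 1),
                                        paste0(pid, c("_c", "_e"))),
                        tags = "heterologous"),
                   .exch(paste0("EX_", pid), paste0(pid, "_e"),
                         lb = 0, ub = 1000,
                         tags = c("heterologous", "product_exchange"))
                 )),
                 exchangeId = paste0("EX_", pid), notes = notes)
  }
  list(
    prdA = pw("prdA", "acetyl-CoA-derived polyester precursor",
              list(.rxn("PWY_A", c(accoa_c = -2, nadph_c = -1, prdA_c = 1),
                        gene = "phaB", tags = "heterologous")),
              "condenses two acetyl-CoA with an NADPH-dependent reduction"),
    prdB = pw("prdB", "erythrose-4-phosphate-derived aromatic precursor",
              list(.rxn("PWY_B", c(e4p_c = -1, pyr_c = -1, atp_c = -1,
                                   prdB_c = 1),
                        gene = "aroX", tags = "heterologous")),
              "condenses E4P with pyruvate at the cost of one ATP"),
    prdC = pw("prdC", "NADH-consuming reduced product",
              list(.rxn("PWY_C", c(pyr_c = -1, nadh_c = -1, prdC_c = 1),
                        gene = "ldhA", tags = "heterologous")),
              "pyruvate reduction; a potential redox sink")
  )
}

.miniYeastMedium <- function() {
  methods::new("MediumDefinition",
    exchanges = data.frame(
      exchange = c("EX_glc", "EX_o2", "EX_nh4"),
      maxUptake = c(10, 2, 1000),
      maxSecretion = c(0, 0, 0),
      stringsAsFactors = FALSE),
    carbonSource = "EX_glc")
}

.miniYeastCuration <- function() {
  list(
    curationAction("merge_duplicates"),
    curationAction("block_secretion", exchange = "EX_acald")
  )
}

#' Mini-yeast fixture: host model, pathways and planted-coupling manifest
#'
#' A deterministic ~50-reaction central-carbon host emulating
#' respiro-fermentative yeast (oxygen uptake capped at 2 mmol/gDW/h so ethanol
#' overflow is active at optimum), three heterologous product pathways, a
#' minimal glucose medium, a standard curation action list (merge the
#' duplicated citrate synthase pair, block acetaldehyde secretion) and a
#' manifest of planted growth-product couplings:
#' \describe{
#'   \item{prdC}{an NADH-consuming product that couples when respiration and
#'     the ethanol route are cut together (double knockouts pairing the
#'     respiratory lump with alcohol dehydrogenase or pyruvate
#'     decarboxylase), making the product the growth-optimal NADH sink;}
#'   \item{prdB}{an erythrose-4-phosphate-derived product that couples when
#'     the oxidative pentose phosphate branch and one transketolase lump are
#'     deleted, forcing a 1:1 pentose/E4P stoichiometry with an E4P
#'     overflow;}
#'   \item{prdA}{an acetyl-CoA-derived product that couples under a triple
#'     knockout (serine synthesis, glyoxylate transaminase, alcohol
#'     dehydrogenase) that forces glycine through threonine aldolase, whose
#'     acetaldehyde byproduct must drain through acetate into acetyl-CoA.}
#' }
#' The manifest's surviving design sets are certified against the brute-force
#' oracle by [verifyMiniYeastManifest()]; the fixture also carries one
#' isoenzyme gene-rule pair (\code{PYC1 or PYC2}, \code{SER3 or SER33}), one
#' exact duplicate reaction pair (\code{CITa}/\code{CITb}) and a galactose
#' route that is blocked under the glucose minimal medium, so curation and
#' gene-mapping code paths are exercised end to end.
#'
#' @return a list with elements \code{model}, \code{pathways} (list of three
#'   \linkS4class{PathwayDefinition}), \code{medium}
#'   (\linkS4class{MediumDefinition}), \code{curation} (list of curation
#'   actions) and \code{manifest} (per-product certification spec and
#'   expected surviving designs)
#' @seealso [miniYeastProducer()], [verifyMiniYeastManifest()]
#' @export
makeMiniYeast <- function() {
  model <- makeModel(.miniYeastReactions(), objective = "BIOMASS",
                     carbonExchange = "EX_glc")
  # carbon formulas for the mass-balance bookkeeping
  stems <- sub("_[a-z]$", "", model@metabolites$id)
  model@metabolites$formula <- ifelse(
    stems %in% names(.miniYeastCarbons),
    paste0("C", .miniYeastCarbons[stems]), NA_character_)
  list(
    model = model,
    pathways = .miniYeastPathways(),
    medium = .miniYeastMedium(),
    curation = .miniYeastCuration(),
    manifest = .miniYeastManifest()
  )
}

# Certification spec per product: knockout depth, candidate set used for the
# oracle comparison, the planted mechanism, and the oracle-certified surviving
# designs (frozen from the certification run; re-certified against the
# brute-force oracle by verifyMiniYeastManifest()).
.miniYeastManifest <- function() {
  list(
    prdC = list(
      maxKo = 2L,
      candidates = NULL,  # NULL = full default candidate set
      planted = list(c("PDC", "RESP")),
      survivors = c("ADH+RESP", "PDC+RESP")
    ),
    prdB = list(
      maxKo = 2L,
      candidates = NULL,
      planted = list(c("TKTA", "ZWF")),
      survivors = "TKTA+ZWF"
    ),
    prdA = list(
      maxKo = 3L,
      candidates = c("ACS", "ADH", "AGX", "ALD6", "GCV", "GPD", "MLS",
                     "PDC", "RESP", "SER", "SHMT", "THA", "THR"),
      planted = list(c("ADH", "AGX", "SER")),
      survivors = "ADH+AGX+SER"
    )
  )
}

#' Certify the mini-yeast manifest against the brute-force oracle
#'
#' For each product, re-runs both the pruned screening route and the
#' independent brute-force oracle over the manifest's candidate set and
#' knockout depth, and checks that (i) the two routes return identical
#' surviving design sets, (ii) the surviving set equals the manifest's frozen
#' list, and (iii) every planted design is among the survivors.
#'
#' @param fixture a [makeMiniYeast()] fixture
#' @param products products to certify (default: all three)
#' @return invisibly a named list of per-product results (each with elements
#'   \code{screen}, \code{oracle}, \code{agreement}, \code{asManifested});
#'   stops if any certification fails
#' @export
verifyMiniYeastManifest <- function(fixture = makeMiniYeast(),
                                    products = names(fixture$manifest)) {
  out <- list()
  for (p in products) {
    mf <- fixture$manifest[[p]]
    pm <- miniYeastProducer(p, fixture)
    cand <- mf$candidates %||% candidateDeletions(pm)
    sc <- screenProduct(pm, cand, maxSize = mf$maxKo)
    orc <- bruteForceCouplingOracle(pm, mf$maxKo, cand)
    ss <- sc$knockout_set[sc$survives]
    so <- orc$knockout_set[orc$survives]
    agreement <- identical(ss, so)
    asManifested <- identical(ss, mf$survivors)
    plantedIn <- all(vapply(mf$planted, function(d)
      paste(sort(d), collapse = "+") %in% ss, logical(1)))
    if (!agreement)
      stop("certification failed for ", p,
           ": screening and oracle survivors differ")
    if (!asManifested)
      stop("certification failed for ", p,
           ": survivors differ from the frozen manifest")
    if (!plantedIn)
      stop("certification failed for ", p,
           ": planted design not among survivors")
    out[[p]] <- list(screen = sc, oracle = orc, agreement = agreement,
                     asManifested = asManifested)
  }
  invisible(out)
}

#' Build one curated mini-yeast producer model
#'
#' Applies the minimal glucose medium and the standard curation actions to
#' the mini-yeast host, removes blocked reactions, and grafts the requested
#' product pathway.
#'
#' @param product \code{"prdA"}, \code{"prdB"} or \code{"prdC"}
#' @param fixture optionally a pre-built [makeMiniYeast()] fixture
#' @return a \linkS4class{MetabolicModel} producer model
#' @export
miniYeastProducer <- function(product = c("prdA", "prdB", "prdC"),
                              fixture = makeMiniYeast()) {
  product <- match.arg(product)
  host <- applyMedium(fixture$model, fixture$medium)
  host <- applyCuration(host, fixture$curation)$model
  host <- removeBlockedReactions(host, fixture$medium)$model
  buildProducerModel(host, fixture$pathways[[product]])
}
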