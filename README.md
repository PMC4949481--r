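# chassisDesign

Constraint-based design of microbial production strains, built around the
question a metabolic engineer actually asks: *which deletions force my host
to secrete the product whenever it grows, and which reactions must be
overexpressed to reach maximal yield?* Products whose answers overlap can
share one pre-optimized **chassis** strain; the package groups them
accordingly.

The package targets researchers working with stoichiometric (genome-scale
or reduced) metabolic models who want a tested, self-contained R
implementation of growth-coupled strain design — including the linear
programming, so no external solver is required.

## What it computes

On a model with stoichiometric matrix $S$, flux bounds $l \le v \le u$ and
biomass flux $\mu$ (steady state $S v = 0$):

* **Robust growth-product coupling.** For each knockout set $K$, a
  two-stage LP: maximize $\mu$ to $\mu^\*$, then *minimize* product
  secretion $v_p$ subject to $\mu \ge \mu^\* - \delta$. The reported
  $p_{\min}$ is the product flux guaranteed at maximal growth, immune to
  alternate optima. Exhaustive enumeration of single/double/triple
  deletions (optionally on pre-selected background deletion sets) with
  provably lossless lethal-subset pruning, then yield filters: growth yield
  $Y_x = 1000\,\mu/v_{glc} \ge 10^{-2}$ g/mol glucose, product yield
  $Y_p = p_{\min}/v_{glc} \ge 10^{-3}$ mol/mol, and $Y_p$ within 90% of the
  per-product maximum.
* **Regulatory coupling.** A mutant-phenotype predictor that minimizes the
  L1 distance between metabolite *turnovers*
  $t_i = \frac{1}{2}\sum_j |S_{ij} v_j|$ of the mutant and of a
  glucose-repressed reference state (pFBA with respiration closed and the
  glucose-6-phosphate isomerase held toward fructose-6-phosphate), screened
  over single and double knockouts with a relaxed growth-yield floor
  ($10^{-3}$ g/mol).
* **Overexpression targets.** Flux variability analysis at (near-)maximal
  product yield identifies product-essential reactions — those whose flux
  interval excludes zero — and the minimal flux they must carry per unit
  glucose.
* **Chassis modules.** Average-linkage (UPGMA) clustering of
  products-by-reactions incidence profiles (binary distance) and of
  stoichiometric precursor/cofactor-requirement profiles (euclidean
  distance), with Newick export.

Every screening result is checkable against bundled brute-force oracles
(unpruned re-enumeration with an independently coded two-stage LP; vertex
enumeration of the flux polytope), and the package ships deterministic
synthetic models — including a ~50-reaction respiro-fermentative
"mini-yeast" with three certified planted couplings — so the entire
pipeline is testable without downloading anything.

Models are read and written as COBRA-style JSON or an SBML Level 3 subset
(bounds, objectives, gene-product associations); pathways, media and
curation actions travel as annotated TSV/YAML (see `inst/extdata/`).

## Worked example

The redox toy plants the classic coupling in which a heterologous
NADH-consuming product becomes the growth-optimal redox sink once
fermentation is deleted:

```r
library(chassisDesign)
rt <- makeRedoxCouplingModel()
rt
#> MetabolicModel: 5 metabolites x 7 reactions
#>   compartments: c, e
#>   objective: Biomass | carbon exchange: EX_glc
#>   3 exchange reactions, 3 reactions with gene rules

screenProduct(rt, maxSize = 2)
#>   knockout_set n_ko mu_max p_min v_glc growth_yield product_yield survives
#> 1         Ferm    1     10    10    10         1000             1     TRUE
#> 2         Rgly    1      0     0     0            0             0    FALSE
#> 3    Ferm+Rgly    2      0     0     0            0             0    FALSE
```

Deleting fermentation (`Ferm`) leaves growth untouched (`mu_max` 10 h⁻¹)
while forcing 10 mmol gDW⁻¹ h⁻¹ of product at maximal growth (`p_min`) — a
product yield of 1 mol/mol glucose; deleting the catabolic lump (`Rgly`) is
lethal and fails every filter.

The same screen on the mini-yeast producer of an erythrose-4-phosphate-
derived product finds a pentose-phosphate double deletion that makes an E4P
overflow the only route to balance biomass precursor stoichiometry:

```r
fy <- makeMiniYeast()
pm <- miniYeastProducer("prdB", fy)
scB <- screenProduct(pm, maxSize = 2)
subset(scB, survives)
#>     knockout_set n_ko mu_max  p_min v_glc growth_yield product_yield survives
#> 629     TKTA+ZWF    2  3.743 0.3743    10        374.3       0.03743     TRUE

head(productEssentialReactions(pm), 4)
#>   product reaction direction min_flux fva_min fva_max
#> 1    prdB   EX_glc        -1    1.000  -10.00  -10.00
#> 2    prdB    EX_o2        -1    0.200   -2.00   -2.00
#> 3    prdB   EX_co2         1    0.213    2.13    2.13
#> 4    prdB  EX_etoh         1    0.213    2.13    2.13
```

So at maximal growth this double mutant secretes 0.037 mol of product per
mol glucose while still growing at 3.7 h⁻¹ (toy units), and the
essentiality report lists the fluxes any maximal-yield state must carry.
`verifyMiniYeastManifest(fy)` re-certifies all three planted couplings
against the brute-force oracle, and `averageLinkage(binaryDistance(...))`
on the stacked essentiality reports groups the products into chassis
modules.

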