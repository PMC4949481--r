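---
title: "Growth-coupled strain design with chassisDesign: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled strain design with chassisDesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chassisDesign)
```

# The design problem

A production host earns its keep only if carbon flux actually reaches the
product. Because native metabolism is evolved to make biomass, not
heterologous molecules, naive pathway insertion usually yields little. Two
complementary model-driven strategies address this on a genome-scale
stoichiometric model:

* **Growth-product coupling by deletion.** Find reaction knockouts after
  which any flux state that grows maximally *must* secrete the product —
  production becomes a stoichiometric side effect of growth, so adaptive
  evolution works for the engineer instead of against them.
* **Overexpression targets.** Find the reactions that are essential for
  converting substrate into product at maximal yield, and the minimal flux
  they must carry — candidates for upregulation.

Products that share deletion targets or essential-reaction profiles can be
served by one pre-engineered *chassis* strain; hierarchical clustering of
those profiles exposes the modular structure.

# Constraint-based machinery

## The model and its conventions

A `MetabolicModel` is a sparse stoichiometric matrix $S$ (metabolites by
reactions) with flux bounds $l \le v \le u$, gene-reaction rules, a biomass
objective and a designated carbon-source exchange. Steady state imposes
$S v = 0$. Exchange reactions are written `A <->` with coefficient $-1$, so
uptake is a negative flux and secretion a positive one; media are expressed
as magnitudes and applied by `applyMedium()`. Fluxes are in mmol gDW$^{-1}$
h$^{-1}$; the biomass flux is the specific growth rate $\mu$ (h$^{-1}$),
i.e. the biomass equation is normalized to 1 g of biomass per gDW. That
convention is what makes the two yields dimensionally meaningful:

$$Y_x = 1000\,\frac{\mu}{v_{glc}} \quad \text{(g biomass / mol glucose)},
\qquad
Y_p = \frac{v_p}{v_{glc}} \quad \text{(mol product / mol glucose)}.$$

Gene-reaction rules are boolean expressions (`and` = complex, `or` =
isoenzymes). Deletions are simulated at the reaction level —
`applyKnockouts()` zeroes both bounds — and gene-level deletions map through
`reactionsDisabledByGenes()`: deleting one member of an isoenzyme pair
disables nothing, which is why the shipped background configuration
(`backgrounds.yaml`) can legitimately name a single isoenzyme gene.

## Linear programming

All optimization passes through one contract (`solveLP()`): minimize or
maximize $c^\top x$ subject to $A x = b$, $l \le x \le u$. Two backends
implement it. The default is a compiled bounded-variable two-phase primal
simplex (full tableau, Dantzig pricing with a switch to Bland's rule so
degenerate metabolic LPs cannot cycle); it handles infinite bounds and
reports infeasibility and unboundedness as statuses, never as errors. The
second backend is a pure-R standard-form tableau simplex using Bland's rule
from the first pivot, on shifted non-negative variables with explicit slack
rows. It shares no code, formulation or pivoting rule with the compiled
backend and exists so that every load-bearing optimum in the test suite can
be confirmed by an independent route; it boxes infinite bounds at $10^6$
and is only used on small fixtures. A third, solver-free route —
brute-force vertex enumeration of the flux polytope (`enumerateVertices()`)
— cross-checks FBA optima and essentiality calls on fixtures with at most a
dozen reactions.

On top of the contract sit:

* `fba()` — plain flux balance analysis;
* `twoStageOptimum()` — lexicographic two-stage optimization;
* `pfba()` — parsimonious FBA: among states within $\delta$ of the growth
  optimum, minimize total absolute flux $\sum_j |v_j|$, linearized by
  splitting each flux into non-negative forward/backward parts (the split
  never leaks out; net fluxes are reported);
* `fva()` — per-reaction flux minimization/maximization under an anchored
  optimum, also used with no anchor for blocked-reaction detection.

## Numerical choices

* Stage-1 slack $\delta$ in two-stage optimization defaults to
  $\max(10^{-9}, 10^{-6}|f^\ast|)$. A hard equality pin on the stage-1
  optimum is numerically brittle; a small relative slack keeps stage 2
  well-posed while changing the stage-2 value by at most a few parts in
  $10^{6}$.
* The pFBA anchor uses an absolute $10^{-9}$ slack instead. Its secondary
  objective trades one-for-one against the anchor, so a relative slack
  would visibly leak into the reported minimal total flux (the chain
  fixture's closed-form total of 40 would come back as 39.99996).
* Mass-balance and bound verification of returned solutions uses a
  $10^{-6}$ absolute tolerance (`checkSteadyState()`); blocked-reaction
  detection uses $10^{-9}$; FVA essentiality calls use a $10^{-6}$
  zero-exclusion tolerance; the FVA product anchor defaults to
  $1 - 10^{-6}$ of the optimum.
* "Non-zero growth" in screening means growth yield above the filter
  threshold *and* $\mu > 10^{-9}$ absolute.

# The robust coupling criterion

For a knockout set $K$, `evaluateDesign()` computes

1. $\mu^\ast = \max \mu$ subject to the knocked model's constraints, then
2. $p_{\min} = \min v_p$ subject to $\mu \ge \mu^\ast - \delta$.

$p_{\min}$ is the product flux *guaranteed* at maximal growth: it is immune
to alternate optima, because it is the worst case over the optimal face.
A design is a coupling when $p_{\min} > 0$; the test suite additionally
demands the direct certificate that pinning $v_p = 0$ while requiring
$\mu \ge \mu^\ast(1 - 10^{-6})$ is infeasible.

Screening (`screenProduct()`) enumerates all knockout subsets of a candidate
list up to size 3 (default), optionally on top of pre-selected background
deletion sets, evaluates each design, and filters the evaluations:

* growth yield $Y_x \ge 10^{-2}$ g/mol glucose (FBA screening) or
  $\ge 10^{-3}$ (regulatory screening below);
* product yield $Y_p \ge 10^{-3}$ mol/mol glucose (absolute floor);
* $Y_p \ge 0.9 \times$ the maximum $Y_p$ over *all* evaluated designs of
  that product, the maximum being taken before any filtering.

All three comparisons are inclusive ($\ge$). The candidate policy excludes
exchanges, biomass, maintenance, heterologous reactions and reactions
without a gene association (not implementable genetically); it is explicit
configuration, so "all internal reactions" is one switch away.

**Lethal-subset pruning.** Shrinking bounds shrinks the feasible region, so
growth is monotonically non-increasing in the knockout set; any enumerated
set with zero maximal growth therefore proves all its supersets lifeless.
Pruned supersets are recorded with $\mu = 0$ rather than silently skipped,
and the suite asserts that pruned and unpruned screening return identical
evaluation tables. The same monotonicity is itself a tested property.

**The oracle.** `bruteForceCouplingOracle()` re-evaluates every knockout
set with no pruning, no caching, reversed variable ordering, and a stage-2
growth pin implemented as an explicit constraint row instead of a bound
override. Screening must agree with it design-for-design on every fixture;
on the smallest fixtures the oracle itself is additionally run through the
pure-R backend.

# Regulatory coupling by turnover distance

Deletion strains do not instantly adopt growth-optimal fluxes; short of
adaptive evolution, their regulation holds fluxes near the parental state.
The package therefore also screens with a mutant-phenotype predictor based
on metabolite turnovers. The turnover of metabolite $i$,

$$t_i = \tfrac{1}{2} \sum_j |S_{ij} v_j|,$$

equals its production = consumption rate at steady state (an asserted
invariant). Given a reference ("wild-type") distribution with turnovers
$t^{ref}$, `mimblPredict()` solves

$$\min_v \sum_i |t_i(v) - t_i^{ref}| \quad \text{s.t.} \quad S v = 0,\;
l \le v \le u,\; v_j = 0 \; \forall j \in K,$$

with the substrate uptake fixed to the reference value so distances compare
like with like. The L1 objective is linearized with forward/backward flux
splitting and one deviation variable per metabolite; deviations are
unweighted by default, with per-metabolite weights exposed. For reversible
reactions the directional decomposition could in principle inflate a
turnover through simultaneous forward/backward flux; the bundled fixtures
are effectively irreversible along the affected routes, and the vertex
cross-check in the suite guards the reported distances there. Mutants with
no steady state are reported as infeasible with zero product flux.

The reference state represents carbon-catabolite-repressed (high-glucose)
physiology: `ccrReference()` runs pFBA at maximal growth with (i) all
reactions tagged `respiration` closed and (ii) the reaction tagged
`g6p_isomerase` restricted to the fructose-6-phosphate direction. Tag-based
closure of respiratory lumps (rather than shutting the oxygen exchange)
keeps oxygen-requiring biosyntheses feasible. The tagged isomerase must be
written with fructose-6-phosphate on the product side; the loader
convention is documented with the tag. The reference is computed per
producer model — heterologous reactions carry zero reference flux, so this
matches computing it once on the host while keeping the code path uniform.

`screenProductMimbl()` enumerates single and double knockouts only (the
predictor is not validated for deeper deletions), reads growth and product
yields off the *predicted, suboptimal* distribution, and applies the same
filters with the lower growth-yield floor of $10^{-3}$ g/mol.

# Overexpression targets by flux variability

`maxProductYield()` maximizes product secretion with no growth requirement
(the biomass lower bound is dropped to zero; the ATP maintenance drain is
kept by default, and both choices are exposed as configuration — a growth
floor can be anchored instead). `productEssentialReactions()` then holds
product secretion at $1 - 10^{-6}$ of its optimum, pins glucose uptake at
its limit so fluxes are comparable, and runs FVA over all reactions. A
reaction is *product-essential* when its interval excludes zero; its
minimal required flux is the interval endpoint closer to zero, reported per
unit glucose uptake so the numbers are scale-free (an asserted invariant).
`buildDesignMatrix()` stacks the per-product reports into a products ×
reactions matrix (0/1 incidence or minimal-flux entries), optionally
dropping reactions essential for every product, which carry no grouping
information.

# Chassis grouping

Two product-by-feature matrices feed the clustering: the essential-reaction
design matrix, compared with the **binary** distance (fraction of
discordant nonzero positions among positions where at least one profile is
nonzero; an empty union gives distance 0 by convention), and the
stoichiometric precursor-requirement matrix from `precursorMatrix()`,
compared with the **euclidean** distance. The precursor matrix reports, per
unit product secreted, the net consumption/production of every native
metabolite by the heterologous pathway alone — cofactors and byproducts
included, since redox demand groups products as strongly as carbon origin.
Branched pathways are resolved by the minimal-total-flux routing producing
one unit of product.

`averageLinkage()` implements UPGMA agglomeration: merge the closest pair;
the distance between clusters is the unweighted mean of member pairwise
distances (maintained by the size-weighted update). Ties are broken by the
lexicographically smallest pair of cluster labels, which makes the
dendrogram invariant to row permutation of the input even under exact ties
— reference implementations leave tie order unspecified, and dendrograms
differ under ties, so the rule is pinned and tested. The result is a
standard `hclust` object; on tie-free data it reproduces
`stats::hclust(method = "average")` exactly (a suite assertion), and
`writeNewick()` exports it for any tree viewer.

# Model curation and producer construction

`applyCuration()` applies a declarative, YAML-serializable action list:
exact-stoichiometry duplicate merging with `or`-united gene rules,
secretion blocking (upper bound only), transport unconstraining, reaction
replacement/removal, bound setting. Keeping edits as data rather than code
means the same pipeline runs on any host model; the bundled
`mini_yeast_curation.yaml` merges the fixture's duplicated citrate synthase
pair and blocks acetaldehyde secretion. `removeBlockedReactions()` applies
the medium and removes reactions whose feasibility-anchored FVA interval is
$[0, 0]$ (tolerance $10^{-9}$) — provably unable to carry flux, so no
computable optimum changes (asserted). `buildProducerModel()` grafts a
pathway onto the host, adding the pathway reactions and product exchange
and nothing else: no energetic or precursor burden is imposed for enzyme
expression or product secretion, which makes predicted yields upper bounds
in that respect.

Pathway definitions travel in a small TSV dialect (columns `product`,
`reaction_id`, `equation`, `lb`, `ub`, `gene_rule`, `notes`; text equations
with `_c`/`_e` compartment suffixes). A product exchange — and, when the
pathway stops in the cytosol, a transport step — is synthesized on load.
The dialect is this package's own definition, documented by the annotated
example file in `inst/extdata/`.

# The synthetic study system

No external model downloads are needed: the package generates its study
systems, and their planted behaviors are *certified*, not assumed.

**Chain model** (`makeChainModel`): substrate exchange (uptake 10), $n$
unit-stoichiometry steps, biomass sink. Closed forms: FBA optimum 10 for
any $n$; with two steps the parsimonious total flux is 40; all anchored FVA
intervals are $(10, 10)$.

**Redox toy** (`makeRedoxCouplingModel`): glucose is catabolized to 2
pyruvate + 1 NADH (both parameters exposed); biomass drains pyruvate;
fermentation and a heterologous product reaction each consume one pyruvate
plus one NADH. The wild type secretes nothing at maximal growth; deleting
fermentation makes the product the only NADH sink at *unimpaired* growth
($\mu = 10$, $Y_p = 1$ mol/mol) — the classic redox-sink coupling. With the
NADH coefficient at zero, no coupling exists anywhere, and the screen must
come back empty.

**Mini-yeast** (`makeMiniYeast`): a deterministic ~50-reaction
central-carbon host with glycolysis, both pentose phosphate branches, TCA
cycle with glyoxylate shunt, ethanol fermentation, an acetate/acetyl-CoA
route, a serine/glycine/C1 loop with a threonine-aldolase bypass, a
glycerol branch, a lumped respiratory chain, and ATP maintenance. Oxygen
uptake is capped at 2 mmol gDW$^{-1}$ h$^{-1}$, a value chosen so the
optimum is genuinely respiro-fermentative: at maximal growth the model
respires at capacity and overflows carbon into ethanol/glycerol, the
physiology in which deletion designs are interesting. The glycerol branch
is load-bearing twice over: it is the NADH valve that makes *any*
non-respiratory growth state stoichiometrically possible (without it, net
pyruvate export is redox-blocked), and it is exactly what makes naive
single-knockout "couplings" evaporate, forcing the more realistic designs
below. Cofactors are tracked as NADH/NADPH/ATP with implicit oxidized
partners; carbon counts ride along in metabolite formulas, and every
internal reaction balances carbon (a suite assertion).

Three heterologous products echo the main precursor/cofactor families:

* **prdC** (NADH-consuming, lactate-like): couples when respiration *and*
  the ethanol route are cut (`{ADH, RESP}` or `{PDC, RESP}`) — the product
  becomes the growth-optimal NADH sink.
* **prdB** (erythrose-4-phosphate-derived, aromatic-like): couples under
  `{ZWF, TKTA}`. With the oxidative PPP branch gone, one transketolase lump
  is the sole pentose source at a fixed 1:1 pentose/E4P stoichiometry;
  biomass needs them 2:1, and with the second lump deleted the E4P overflow
  has exactly one outlet — the product.
* **prdA** (acetyl-CoA-derived, polyester-like): couples under the triple
  `{SER, AGX, ADH}`. Blocking glycolytic serine synthesis and the
  glyoxylate transamination forces all glycine through threonine aldolase,
  whose acetaldehyde byproduct — with the ethanol route cut and
  acetaldehyde secretion curation-blocked — must drain through acetate into
  acetyl-CoA, overflowing into the product.

The fixture also carries two isoenzyme gene-rule pairs (`PYC1 or PYC2`,
`SER3 or SER33`), an exact duplicate reaction pair for the curation path, a
galactose route that is blocked under the glucose medium (exercising
blocked-reaction removal), and gene names matching the shipped background
sets. The manifest freezes the oracle-certified surviving design sets;
`verifyMiniYeastManifest()` re-runs both screening and the brute-force
oracle and checks (i) route agreement, (ii) agreement with the frozen
lists, (iii) presence of every planted design. Because every generator is
deterministic, two pipeline runs produce byte-identical report files — also
asserted.

## What the fixtures do and do not show

The synthetic systems exercise every code path against independently
computed ground truth, at a scale where exhaustive enumeration is possible.
They do not emulate genome-scale degeneracy (thousands of reactions,
extensive isoenzyme redundancy, compartmentalized cofactor pools), nor
thermodynamic or enzyme-capacity constraints, nor regulation beyond the
CCR-style reference state. A passing suite therefore demonstrates
correctness of the algorithms, not biological completeness of any
particular host model; on a real genome-scale model the same pipeline
applies unchanged, but runtimes grow combinatorially with the candidate
list and knockout depth, and conclusions inherit the model's curation
quality. Problem sizes used throughout the suite and the acceptance script
— toys of 4–7 reactions, a ~50-reaction host, knockout depths 1–3,
candidate lists of 12–33 reactions — were chosen so that the brute-force
oracles remain exhaustive.

# Known limitations

* Knockouts are purely stoichiometric; regulatory and kinetic effects are
  represented only through the turnover-distance predictor's
  minimal-adjustment assumption.
* The turnover-distance LP can in principle exploit forward/backward
  splitting on reversible reactions to inflate turnovers toward the
  reference; this does not arise on the bundled fixtures (verified), but a
  genome-scale application should audit reversible-loop flux in predicted
  states.
* The pure-R reference backend boxes infinite bounds and is quadratic-ish
  per pivot; it is a verification tool, not a production solver.
* SBML support covers the subset this pipeline needs (species,
  compartments, bounds, objectives, gene-product associations, and the
  package's own tag annotations); models relying on richer SBML semantics
  should enter through the JSON reader.
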