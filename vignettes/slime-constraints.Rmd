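---
title: "Constraining lipid metabolism with SLIME reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraining lipid metabolism with SLIME reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimekit)
```

## The problem

A genome-scale metabolic model (GEM) predicts growth by consuming measured
biomass components through a biomass pseudo-reaction. Lipids are the awkward
component: a cell can make hundreds of specific lipid species, but routine
measurements give only two marginal summaries — a *lipid-class profile*
(g/gDW per head-group family: PI, PC, TAG, ergosterol, ...) and an
*acyl-chain profile* from FAME analysis (g/gDW per chain, e.g. 16:0, 18:1).
The two classical ways of wiring this into a GEM each discard one of the
datasets:

* a **permissive** formulation lets every specific species form its generic
  class and constrains only the class totals. Simulations then always pick
  the species that are cheapest in carbon and energy — usually the shortest
  chains — regardless of what FAME analysis says;
* a **restrictive** formulation forces one global acyl-chain distribution
  onto every class via a generic acyl pool, although real class-specific
  chain distributions differ strongly.

`slimekit` implements the middle road: SLIME reactions ("Split Lipids Into
Measurable Entities") plus lipid pseudo-reactions that constrain *both*
marginals while leaving the species mix free.

## The formalism

For every specific lipid $L_{ij}$ (class $i$, chain configuration $j$) a
SLIME reaction is added:

$$ L_{ij} \rightarrow s_i\, B_i + \sum_{k \in j} s_{jk}\, C_k $$

where $B_i$ is the class backbone pseudo-metabolite and $C_k$ the
pseudo-metabolite of chain $k$. Because abundance data come in mass units,
$s_i$ is the molecular weight of the *full* lipid \[g/mmol\] and $s_{jk}$ the
molecular weight of chain $k$ times its number of repetitions in
configuration $j$. A SLIME reaction therefore converts a molar species flux
\[mmol/gDW/h\] into mass fluxes \[g/gDW/h\] on the backbone and chain sides
simultaneously. SLIME reactions are irreversible: they are accounting
constructs, and reversibility would let mass flow backwards out of the
pools.

Three lipid pseudo-reactions then consume these pools:

1. the **backbone pool** pulls every $B_i$ with the class abundances
   \[g/gDW\] as coefficients into a generic backbone;
2. the **chain pool** does the same for every $C_k$ with the FAME abundances;
3. the **merge** reaction combines 1 generic backbone + 1 generic chain into
   the generic lipid consumed by the biomass pseudo-reaction.

Since the biomass flux equals the growth rate $\mu$, each pool flux is
pinned to $\mu$ \[1/h\] and the SLIME fluxes must deliver exactly
$a_i \mu$ g/gDW/h of every backbone and $b_k \mu$ of every chain — both
marginals are enforced, the joint species distribution is not.

The generic pseudo-metabolites deliberately carry no chemical formula: their
mass bookkeeping lives entirely in the pool coefficients, which keeps the
unit conversion (mass → lipid turnover \[1/h\]) in one place.

### Chain mass convention

FAME quantifies chains as fatty-acid equivalents, so chain pseudo-metabolites
use the free-fatty-acid composition $C_nH_{2n-2d}O_2$ by default
(`chain_formula()`); an acyl-residue convention (minus one water) is a
one-argument switch. Molecular weights use the embedded IUPAC 2021 atomic
masses and are always reported in g/mmol.

### Model variants

* `make_permissive()` removes the chain pool, opens an irreversible
  excretion per chain pseudo-metabolite and lets the merge consume only the
  generic backbone. Every enhanced-feasible flux vector remains feasible
  here, so the permissive maximum ATP turnover can never be lower — the
  nesting that the cost analysis exploits.
* `make_restrictive(enhanced, fractions)` re-creates the classical generic
  acyl pool *inside* the SLIME machinery: each class gets its own copies of
  the chain pseudo-metabolites, pooled per class with the global mass
  fractions as coefficients. Because the pool consumes its inputs in fixed
  proportion, each class's realized chain-mass split equals the fractions
  exactly. The builder takes the enhanced model object (not the raw GEM):
  it rewires machinery that only exists after enhancement, and this keeps
  all three variant builders symmetric.

## The enhancement pipeline

`enhance_model()` runs five steps: map species from metabolite names, add
pseudo-metabolites and SLIME reactions (replacing the class
pseudo-reactions), install the three pools (replacing the old lipid
pseudo-reaction), rescale one side of the data to mass consistency, and
normalize biomass to 1 g/gDW.

**Name mapping is rule-driven** (`naming_rules()`): lipid naming conventions
vary too much across models and databases to hard-code, so per-class regex
patterns extract chain labels from metabolite *names*, and lipid-like
metabolites that no rule matches are reported, never silently dropped.

**Rescaling** (`rescale_abundances()`). SLIME constraints are exact mass
balances, so the class profile and the FAME profile must be mutually
proportional; measured tables never are, exactly. One side is multiplied by
a single scalar $f$ — the minimal reading of "make them proportional", and
deterministic, as opposed to a joint optimization over all coefficients
(which would silently redistribute measurement error across classes). $f$ is
found by bisection on a log bracket $[10^{-3}, 10^3]$ (60 iterations):
temporary excretions are attached to every backbone and chain
pseudo-metabolite, an LP minimizes total excretion at each trial factor, and
the side showing surplus (chains vs backbones) gives the search direction.
The accepted residual is $10^{-9}$ g/gDW/h. Two defaults mirror common
designs: `scale_classes` when FAME totals anchor the measurement (chemostat
reference data) and `scale_chains` when the total lipid fraction is assumed.

**Biomass normalization** (`normalize_biomass()`) scales the carbohydrate
pseudo-reaction — the component that is typically not measured — by one
factor so the composition sums to 1 g/gDW. The lipid contribution is counted
from the backbone pool only: the chain pool constrains a *sub-mass* of the
same lipids, and counting it again would double-book mass.

## Numerical core

No LP solver is assumed from the host system: the package carries a dense
two-phase primal simplex (`lp_solve()`) sized for the LPs this toolkit
builds (hundreds of rows/columns). Design points:

* Dantzig pricing with an automatic Bland's-rule fallback once the objective
  stalls — FBA polytopes are massively degenerate and cycling is a real
  risk; pivot tolerance $10^{-9}$;
* fixed variables (`lb == ub`, e.g. chemostat growth) are substituted out
  before the solve; free and one-sided variables are shifted/mirrored/split;
* statuses are reported faithfully and separately: `optimal`, `infeasible`,
  `unbounded` (FVA relies on telling the last two apart).

**pFBA** maximizes the objective, pins it with a floor constraint at
relative slack $10^{-9}$, and minimizes $\sum_r |v_r|$ exactly: irreversible
fluxes enter the objective directly, reversible ones through an auxiliary
magnitude variable $t_r \ge |v_r|$. The floor (rather than an equality)
avoids empty feasible sets under round-off; the tight default is
deliberate — with an exact tableau method a loose floor just parks the
stage-2 solution measurably below the stage-1 optimum, and the slack is an
exposed argument (`opt_tol`) for users with noisier solvers in mind.

**Grouped FVA** (`lipid_variability()`) minimizes/maximizes the summed
chain-mass rate of one (class, chain) group — weights are the $s_{jk}$
coefficients on the class's SLIME reactions — with the ATP maintenance flux
pinned at its maximum (relative slack $10^{-6}$). Pinning is the default
because the variability question of interest is "in how many ways can the
lipid requirement be met at equal energy expenditure"; unpinned exploration
is a flag away.

**Sampling** (`sample_fluxes()`) is artificial-centering hit-and-run: warm-up
points are the per-reaction FVA optima (which doubles as the boundedness
check — an unbounded exchange raises an error telling the caller to cap it),
chord directions are differences between warm-up points and a running
center, and one sample is emitted every `thin = 100` chord steps. The chain
is re-projected onto the null space of the steady-state system every 200
steps, so $\|S v\|_\infty$ stays at solver tolerance ($\le 10^{-6}$
guaranteed, $\sim 10^{-13}$ in practice). Identical seeds give bitwise
identical samples. Abundance back-calculation divides each SLIME flux by
$\mu$ and multiplies by the species molecular weight, giving mg/gDW.

## Parameters that matter

| parameter | unit | default | note |
|---|---|---|---|
| growth rate $\mu$ | 1/h | 0.1 | chemostat dilution rate; pins biomass flux |
| NGAM | mmol/gDW/h | 0.7 | non-growth maintenance, treated as a model constant |
| exchange tolerance | — | 0.05 | ±5% band on measured exchange magnitudes |
| rescale residual | g/gDW/h | 1e-9 | accepted excretion of unused pools |
| pFBA floor slack | relative | 1e-9 | see above |
| sampler thinning | steps | 100 | chord steps per emitted sample |
| LP pivot tolerance | — | 1e-9 | simplex feasibility/pricing threshold |

GAM is reported as `(total turnover − NGAM)/μ` per gram biomass; known
polymerization costs are not subtracted unless the user supplies them, so
the default output keeps raw turnover and NGAM separate.

## What the synthetic fixtures emulate — and what they do not

`toy_fig1_model()` builds the canonical worked example: three lipid classes
times two chains (16:0, 18:0; six species) on a small carbon/ATP core
(glucose uptake capped at 10 mmol/gDW/h, measured uptake 9.5, respiration,
an ATP maintenance sink), with chemostat growth at 0.1 1/h, protein 0.5 and
RNA 0.06 g/gDW, total lipid 0.08 g/gDW (a typical yeast fraction), and
carbohydrate filling the composition to 1 g/gDW. Chain synthesis is
deliberately asymmetric — elongation past C16 and desaturation cost extra
acetyl units and ATP — so the shorter saturated chain is strictly cheaper
per gram of lipid. The abundance tables are *generated from a known species
distribution* (classes prefer 16:0 at molar shares 0.7/0.3/0.5), hence
exactly mass-consistent, with rescaling factor 1 by construction.
`random_lipid_network()` scales the same construction to arbitrary
class/chain counts with seeded preferences; `stress_series()` morphs the
chain data from the all-short-chain composition (exactly what a permissive
model chooses, so the level-0 cost is zero) toward the heterogeneous truth
while NGAM rises.

One formula convention is load-bearing: every species of class $i$ carries
the formula of $m_i$ copies of its chain ($m_i \in \{2,3,4\}$), i.e. a
constant chain-mass fraction $1/m_i$ within each class. With heterogeneous
chain-mass fractions the set of chain-mass vectors deliverable at fixed
class masses is two-dimensional and the data ray crosses its *interior* — a
whole interval of rescaling factors then yields zero excretion and the
factor is not identifiable. With a constant per-class fraction the total
deliverable chain mass is an invariant of the class masses, the
zero-excretion factor is unique, and rescaling recovery can be tested
exactly. Real lipidomes do not have this property; on real data the
recovered factor should be read as "a" consistent factor, not "the" one.

The fixtures reproduce the mathematical structure the method operates on,
not yeast biochemistry: no compartments beyond a token split, no
gene–protein–reaction rules, no cofactor realism, no regulation, no membrane
physics. Passing tests therefore certify the *formalism* — coefficient
correctness, marginal enforcement, feasible-set nesting, rescaling, cost
accounting — and say nothing about the biological accuracy of any particular
host GEM or dataset.

Problem sizes used by the shipped tests and the acceptance script are
desk-scale choices: toy networks of ~30–60 reactions, 10–20 seeded random
networks, 1000–2000 hit-and-run samples. All scale linearly if users want
more.

## Degenerate inputs and tie-breaks

* Classes or chains present in the model but absent from the data get pool
  coefficient 0: their SLIME fluxes are forced to zero, the species stay.
* A class-mass vector whose non-carbohydrate biomass already exceeds
  1 g/gDW is rejected (negative carbohydrate is impossible).
* A single-point flux polytope is detected (empty null space after pinning)
  and returned directly by the sampler.
* Species whose summed chain formula exceeds the lipid formula are a hard
  consistency error — that is corrupt chemistry, not a mappable species.
* Alternate optima in pFBA stage 2 are possible in principle; the simplex is
  deterministic (fixed pivoting rules), so results are reproducible even
  where not unique.

## Known limitations

* The simplex is dense; it is comfortable to a few thousand reactions but
  not tuned for full-scale GEMs with tens of thousands of columns. The
  module boundary (`lp_solve()`) is the swap point for a sparse backend.
* Rescaling fits one global factor; per-class factors would absorb
  class-specific measurement bias but are not identifiable from marginal
  data alone, so they are intentionally out of scope.
* The carbon cost is defined as the difference in net substrate carbon
  consumption (uptake minus secretion, real exchanges only, divided by μ)
  between the two pFBA solutions; other definitions (e.g. carbon routed
  into lipids only) would give different magnitudes. The definition string
  is embedded in every `cost_delta()` result.
* SBML support covers Level 3 + FBC v2 bounds/objectives/formulas — the
  subset constraint-based tools exchange — not the full SBML feature set.
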