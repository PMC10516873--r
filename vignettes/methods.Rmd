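---
title: "Methods: constraint-based energy and redox analysis in cyanoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based energy and redox analysis in cyanoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model and its assumptions

`cyanoflux` analyzes metabolism at steady state: for a stoichiometric
matrix $S$ (metabolites $\times$ reactions) and flux vector $v$
(mmol/gDW/h), all internal metabolite pools are balanced, $S v = 0$, and
each flux is confined to $v_j^{LB} \le v_j \le v_j^{UB}$. A reaction is
irreversible exactly when its lower bound is non-negative. Exchange
reactions follow the BiGG convention `met_e ->`, so uptake is a *negative*
exchange flux: a printed "uptake rate of $u$" becomes a lower bound of
$-u$ on the exchange, and an uptake cap of 0 still permits secretion.

Flux balance analysis maximizes an objective $Z = c^\top v$ over this
polytope. The framework is purely stoichiometric: no enzyme kinetics, no
regulation, no thermodynamic $\Delta G$ bounds beyond reversibility flags.
Conclusions are therefore about what the network *can* do, not what a
regulated cell *will* do.

## Parsimonious FBA

Degenerate flux LPs have many optima. After fixing the objective at its
optimum, `pfba()` minimizes the summed absolute flux over gene-associated
reactions, splitting each into two non-negative direction components.
Boundary reactions, biomass drains and the ATP-maintenance pseudo-reaction
carry no gene product and are excluded from the penalty; heterologous
pathway reactions are enzyme-catalyzed and are penalized, while product
export pseudo-reactions are not. The objective is held in a *relative*
band of $10^{-9}$ rather than pinned exactly — on near-degenerate polytopes
the minimal L1 norm is steeply sensitive to the objective level, and a hard
equality makes the result depend on the last floating-point ulp of the
stage-one optimum. If the band is numerically infeasible it is widened once
to $10^{-6}$ before erroring. pFBA narrows but does not always uniquify
individual fluxes; reported tables should be compared at about $10^{-4}$.

## Flux variability and loopless correction

`fva()` reports per-reaction flux ranges subject to
$c^\top v \ge f \cdot Z^*$ (default $f = 0.95$, i.e. 5 % slack around the
optimum). Per-reaction subproblem failures are recorded as `NA` rows, never
raised, so one pathological reaction cannot sink a genome-scale scan.

Internal cycles that touch no exchange are thermodynamically infeasible but
linearly feasible, and a bound-level FVA range on a cycle reaction is an
artifact. The default `remove_loops()` is a post-hoc correction: with every
boundary flux fixed at its current value, the total absolute internal flux
is minimized subject to each internal flux keeping its sign and magnitude
cap. This provably preserves the objective and all exchange fluxes, needs
no integer programming, and composes with FVA (each subproblem solution is
corrected before the target flux is read off). A strict mode enumerates
direction patterns over the loopable reactions exhaustively and verifies
loop-freeness by LP; it is exponential and hard-capped (default 10 loopable
reactions), existing as ground truth for small instances rather than as a
production path. When pFBA and loopless correction are combined, the order
is pFBA first, then cycle correction.

## Two-step biomass-coupled production

A strict growth/product trade-off makes "maximize product" alone predict
zero growth. `two_step_optimize()` therefore first maximizes biomass, then
pins biomass at a fraction of that maximum (default 0.10, a carbon
partitioning to biomass regarded as feasible for hydrocarbon
overproduction) and maximizes product export parsimoniously. Production is
non-increasing in the coupling fraction; fraction 0 reduces to plain
product FBA, fraction 1 to production at maximal growth. Both the coupled
and uncoupled variants are first-class so either can be reported; results
carry the fraction in their manifest.

## Flux-sum analysis and yields

The turnover of metabolite $i$ is
$\Phi_i = \tfrac12 \sum_j |S_{ij} v_j|$; producers ($S_{ij} v_j > 0$) and
consumers ($< 0$) each sum to $\Phi_i$ at steady state, which the suite
asserts network-wide. Every reaction with nonzero stoichiometry for the
metabolite counts, including phosphotransfer interconversions such as
adenylate kinase — the definition is taken literally rather than curated.
Headline ATP/NADPH/NADH numbers use the cytoplasmic species
(`atp_c`, `nadph_c`, `nadh_c`); flux-sums are per metabolite per
compartment, and cross-compartment aggregation is left to the caller since
the dominant pools are cytoplasmic. Presentation tables round fluxes to two
decimals and display contributions under 0.01 mmol/gDW/h as zero while
keeping them in the percentage bookkeeping, so percentages always close at
100.

Yields divide product export by substrate uptake: mass yield in g/g using
molar masses computed from elemental formulas, c-mol yield as product
carbon over substrate carbon. The substrate basis is the scenario's carbon
source — bicarbonate under the autotrophic preset, glucose under the
mixotrophic one — and is configurable.

## Trophic presets and curation

The shipped presets encode light-limited growth of *Synechocystis*-type
models: autotrophic (CO2 0, bicarbonate 3.7, glucose 0, photon 45
mmol/gDW/h; autotrophic biomass objective) and mixotrophic (inorganic
carbon 0, glucose 0.38, photon 45; mixotrophic biomass). The photon budget
is applied as a single photon-exchange bound rather than split across the
two photosystem absorption reactions — the simpler reading, and the one a
single-exchange toy can share; models that resolve absorption per
photosystem can override the preset.

Model curation is data, not code: the edit set (TCA shunts,
phosphoketolase, Entner-Doudoroff pathway, light-independent serine
biosynthesis, prephenate/arogenate reactions, alternative electron routes,
transhydrogenase handling, zero-constraints, the three-reaction glycine
cleavage replacement, ATPM) ships as a YAML file of native-dialect reaction
records that users can replace wholesale. The shipped stoichiometries are a
synthetic transcription from literature-standard chemistry, flagged as such
in the file header, because the authoritative per-reaction tables live
outside the main text of the source literature. Every addition is
mass-checked where formulas permit; edits apply in order; any single
failure aborts with the edit named. The ATP-maintenance floor defaults to
0 — no numeric maintenance coefficient is imposed, so maintenance flux
emerges from optimization when the network has surplus ATP.

## Numerical choices

There is no LP package in the supported dependency set that handles these
problems, so the package carries its own solver: a dense two-phase tableau
simplex with Dantzig pricing, a Bland anti-cycling fallback after a fixed
iteration budget, and largest-pivot tie-breaking in the ratio test.
Feasibility is reported at $10^{-6}$ (every returned optimal flux state is
asserted against $\|S v\|_\infty \le 10^{-6}$ and its bounds); the solver
tolerance is $10^{-9}$. Infinite bounds are clamped to $10^5$ internally,
and an optimum that pins an objective-carrying variable at a clamp is
reported as unbounded with the offending support listed. Determinism is a
design requirement: single-threaded, fixed pivot rules, no randomized
perturbation, so identical inputs give byte-identical outputs.

Degenerate inputs are handled explicitly: models with zero reactions are
valid (0-column matrix), empty formulas make mass checks "unverifiable"
rather than wrong, a zero flux-sum yields empty producer/consumer tables,
and a zero NADPH turnover makes the ATP/NADPH ratio undefined (`NA`), not
infinite.

## What the synthetic models do and do not show

The generators exist so every stage is testable without downloads. The
linear chain has a unique optimum equal to its uptake bound. The
internal-cycle model plants a flux-carrying loop detached from exchanges.
The random generator samples a non-negative flux vector first and then
draws a sparse stoichiometric matrix with that vector in its null space, so
feasibility is guaranteed by construction and everything is reproducible
from one integer seed.

The phototroph toy is a frozen ~18-reaction fixture (shipped as data so its
hand-derived constants stay valid) emulating the photon-to-cofactor
economy: linear electron flow produces ATP and NADPH at the 1.28
stoichiometric ratio of cyanobacterial photosynthesis, cyclic electron flow
supplies ATP alone, carbon fixation costs 3 ATP + 2 NADPH per carbon, and
biomass (4.5 ATP, 2.5 NADPH per unit) competes with a two-carbon product
(8 ATP, 6 NADPH per unit) for 45 mmol/gDW/h of photons. Both demand ratios
exceed 1.28, so the photon cost per unit is linear (3.8 for biomass, 6.32
for product), giving closed forms: $\mu_{max} = 45/3.8$,
$P_{max} = 45/6.32$, a linear phase-plane frontier, two-step production of
$(1-f) P_{max}$, and ATP/NADPH flux-sums of $4.5\mu$ and $2.5\mu$ (ratio
1.8) at the growth optimum. An NADH leg (catabolic oxidation plus
transhydrogenase) is present but never optimal, pinning the NADH flux-sum
to zero.

What passing these tests shows: the optimization, loop-correction,
flux-sum and yield machinery is exact on networks whose answers are known
in closed form or by brute-force enumeration (vertex enumeration for FBA
and FVA, an independent split LP for pFBA, exhaustive direction enumeration
for looplessness). What it does not show: behavior on genome-scale
degeneracy, compartmentalized cofactor pools, realistic biomass
compositions, or photoinhibition — the toy's frontier is exactly linear,
whereas real phase planes bend where cofactor supply modes switch.

## Problem sizes

The shipped suites run networks of 5–20 reactions, 20 seeded random
instances per property, FVA over all reactions at fractions 0.95–1.0, and
enumeration oracles up to $2^{|loopable|}$ patterns with the cap above.
These sizes keep every oracle exact; the pipeline itself has no size-coded
assumptions beyond dense-matrix LP solving, which is practical to roughly
10^3 reactions.

## Known limitations

- The built-in simplex is dense; genome-scale FVA (two LPs per reaction) is
  minutes, not seconds, of work there.
- Strict loopless mode is enumeration-bounded by design.
- SBML support covers the constraint-based subset (species, reactions,
  fbc bounds/objectives, gene-association presence); groups, layout and
  full gene-protein-reaction boolean rules are out of scope, and the
  gene-associated flag is the only GPR semantics retained.
- Flux units are fixed at mmol/gDW/h throughout.
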