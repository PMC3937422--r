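---
title: "System-level indices of plankton succession: models, conventions and the synthetic study system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{System-level indices of plankton succession}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planksucc)
```

## The problem

Seasonal plankton succession in a temperate lake passes, within a few
months, through the same stages that terrestrial secondary succession
takes decades to traverse: a spring bloom of small, fast-growing
producers, a clear-water phase (CWP) dominated by a keystone
herbivorous crustacean, and a diverse, even late-summer and autumn
community.  `planksucc` computes the family of system-level indices
used to quantify that progression on *quantitative* (flow-weighted)
food webs: biomass-based indices (Shannon functional diversity,
succession rate, eco-exergy), size- and flow-based trophic structure
(flow-weighted trophic positions, biomass/production pyramids, trophic
transfer efficiency, predator-prey body mass ratios, the normalized
biomass size spectrum, metabolic activity, residence times, diet
composition and stoichiometry), information-theoretic flow indices
(flow diversity, average mutual information, ascendency, weighted
connectance) and weighted small-world metrics.

The package ships the Lake Constance pelagic topology (24 functional
guilds aggregated to 8 groups plus a detritus pool, `lc_guilds()`,
`lc_group_links()`) and a seeded generator of mass-balanced seasonal
flow networks and biomass series, so every stage of the pipeline is
exercisable without the original field data.

## Flow networks and mass balance

A `flow_network` holds one phase's internal flow matrix `T[i, j]`
(flow from node *i* to node *j*, µg element m⁻² d⁻¹) for one element
(C or P), plus per-node boundary flows: imports, exports, respiration
and two nonnegative storage terms.  Mass balance requires, per node,

    (internal inflows + import + storage release) =
    (internal outflows + export + respiration + storage accrual)

`validate_mass_balance()` reports per-node residuals relative to the
larger of the node's total inputs and outputs.  Synthetic networks are
held to `rtol = 1e-9`; imported empirical networks usually only close
to a few percent, so a looser tolerance (e.g. `0.05`) is appropriate
there.  Storage is always represented as the two nonnegative terms,
never a signed number, and phosphorus networks carry no respiratory
loss.

Two flow sets are distinguished throughout (`select_flows()`):

* `trophic_detrital` — internal feeding and detrital links only; used
  for weighted connectance, which by definition counts feeding links.
* `full_throughput` — adds imports, exports, respiration and storage as
  flows from/to virtual boundary nodes; used for TST and the
  ascendency family.

**TST convention.** The total system throughput is the sum of the
selected flow multiset, each boundary term counted once (equivalently,
the summed output throughputs of all real and virtual nodes).  A
convention was unavoidable here: summing only the real nodes' outputs
would silently drop imports.  The flow set is an explicit argument on
every index, so either reading can be obtained.

## Resolution changes

`aggregate_network()` sums flows within supernode pairs (intra-group
feeding becomes a flagged self-loop) and conserves TST and every
boundary total exactly.  `disaggregate_flows()` reverses the 24 → 8
aggregation structurally: each group-level flow is divided equally
among the consumer group's guilds with a compatible diet entry, and
within each consumer equally across its resource guilds in the source
group.  The result conserves all group-pair totals — re-aggregation is
exact — but is *not* claimed to balance per guild: the uniform split is
a structural approximation used only for the small-world indices,
mirroring the fact that guild-level flow magnitudes were never
measurable in the field.

## Biomass-based indices

* `shannon_diversity()` — H = −Σ bᵢ log₂ bᵢ over relative biomasses;
  bits by default (base configurable) so that an even 20-guild
  community scores log₂ 20 ≈ 4.32 bits.
* `succession_rate()` — σ = Σᵢ |b₂ᵢ − b₁ᵢ| / Δt, the summed absolute
  change in relative biomass per day, ranging 0 … 2/Δt.  The summed
  absolute-difference form is used; the function records no other
  variant, but the formula sits in one place should a root-sum-square
  alternative ever be wanted.
* `eco_exergy()` — Ex = Σ βᵢ Bᵢ with the group equivalence factors
  (bacteria 8.5, phytoplankton 20, unicellular zooplankton 39, rotifers
  163, crustaceans 232, fish 499; `lc_exergy_weights()`), and
  Ex_sp = Ex/B_tot.  Adult fish enter as one pooled biomass with
  β = 499.

## Trophic structure

`trophic_positions()` solves TPᵢ = 1 + Σⱼ fᵢⱼ TPⱼ with fᵢⱼ the fraction
of consumer *i*'s ingestion taken from *j*; phytoplankton and bacteria
are fixed at TP 1 and the detritus pool at 0.  Cycles — omnivory loops
and cannibalistic self-loops — are handled by the linear solve, and the
fractional level weights pᵢ(k) are propagated recursively (truncated
when the remaining mass drops below 10⁻¹³), so that Σₖ pᵢ(k) = 1 and
Σₖ k·pᵢ(k) = TPᵢ to 10⁻⁹.

`trophic_pyramid()` spreads any per-node quantity over integer levels
by those weights; totals are conserved exactly.  The `chain` argument
restricts the web: `"grazing"` drops the detritus pool and the
bacteria (diets renormalize over the remaining resources), rooting the
pyramid in primary production; `"detritus"` drops the detritus pool
and the phytoplankton, rooting it in bacterial production.  This
static split is an operationalization — field studies allocate
mixed-diet consumers fractionally between chains.

`transfer_efficiency_production()` averages the production ratios
P₂/P₁ and P₃/P₂ geometrically (efficiencies compose multiplicatively;
an arithmetic option exists).  `transfer_efficiency_from_spectrum()`
uses the steady-state relation B_{k+1}/B_k = TE·PPMRᴬ, giving
TE = PPMR^(SSS + 1 − A) with A = 0.25 by default (the magnitude of the
allometric exponent of mass-specific production).

`size_spectrum_slope()` normalizes the biomass in log₂ size class *m*
by the linear class width 2^m and regresses log₂ of the normalized
biomass on *m* by OLS, dropping (not imputing) empty classes; equal
biomass per class — a Sheldon spectrum — yields a slope of −1.

`system_residence_time()` is implemented as the operational definition
stock / outflow (exports + respiration; export only for P).
Residence-time estimates for real lakes are often adopted from tracer
studies rather than computed from one snapshot, so outputs are
labelled by this operational definition.

`weighted_ppmr()` is the weighted geometric mean of the four
dietary-group body-mass ratios with weights (0.1, 0.1, 0.4, 0.4)
established from ingestion fractions (`lc_ppmr_weights()`).

## Information-theoretic flow indices

Over a selected flow set with total TST and flow probabilities
p = T/TST (zero flows skipped):

* flow diversity H_flow = −Σ p log₂ p,
* average mutual information AMI = Σ p log₂(T·TST / (T_out·T_in)),
* conditional entropy (relative overhead) Φ = H_flow − AMI,
* ascendency Asc = TST·AMI, development capacity K_dev = TST·H_flow,
  overhead L_over = K_dev − Asc, relative ascendency
  Asc_rel = AMI/H_flow,
* fitness F = −Asc_rel·ln(Asc_rel), maximal at Asc_rel = 1/e ≈ 0.36,
  defined as 0 at both boundaries by continuity.

The weighted link density is Conn_w = 2^(Φ/2) and the weighted
connectance C_w = Conn_w/S, with S the number of nodes touching a
selected flow (9 for the 8-group + PDOM web).  **Log-base choice:**
entropies are reported in bits; the exponent base of Conn_w follows
the entropy base.  Writing the exponent in base *e* while measuring Φ
in bits would mix bases and break the exact identity
Conn_w = L/S for uniform flows on k-regular webs, which this package
preserves (and tests).  The natural-log variant is available by
setting `base = exp(1)` everywhere.

Ascendency defaults to the full throughput set (boundary flows
included); C_w defaults to the feeding-link set.  Both are arguments.

## Weighted small-world indices

Both indices work on the symmetrized flow graph (edge weight
T[i,j] + T[j,i]; self-loops excluded from the graph, retained in the
binary link count L).

`weighted_path_length()` returns D, the mean distance over reachable
pairs, with d measured in links.  The path between a pair is selected
by maximizing the summed relative flow strength *among minimum-hop
paths* (relative strength f = edge flow / the larger endpoint's total
flow); the hop count itself is topological.  A rule selecting flow-rich
paths of *unconstrained* length is not usable: with nonnegative
weights the summed strength always grows by appending edges, so the
"best" simple path would be near-Hamiltonian for every pair, the mean
distance would approach S−1, and the computation would be NP-hard at
24 nodes.  The minimum-hop reading is also the one consistent with the
empirically observed behaviour of this index family, whose seasonal
variation is negligible when the binary topology is fixed.
D_norm = D/(ln S / ln Conn_bin) compares D to the expected path length
of a random graph with the same binary link density; when
Conn_bin = L/S ≤ 1 the normalization is undefined and D_norm is
returned as `NA` with a warning.

`weighted_clustering()` is the Barrat-style local coefficient: for
node *i*, the flow weights (fᵢⱼ + fᵢₖ)/2 of ordered neighbour pairs
that close a triangle, normalized by sᵢ(Kᵢ − 1) so that 0 ≤ qᵢ ≤ 1;
nodes of degree < 2 contribute 0.  Q_norm = Q/C_bin with
C_bin = L/S² of the directed binary web.

## The succession pipeline

`phase_statistics()` averages any index series onto the 7-phase axis
(1 Late Winter … 7 Early Winter) and summarizes the year as the mean ±
sd of the phase means.  `composite_index()` min-max-normalizes the
four key indices — transfer efficiency, metabolic activity (inverted as
1 − normalized P/B), functional diversity and weighted connectance —
and averages them per phase; a three-index variant omits C_w for
systems without flow data.  `spearman_correlation()` wraps the
standard rank correlation (mid-ranks, asymptotic two-sided p).

`run_full_analysis()` produces the summary report.  Trend labels over
phases 2–6 are assigned by an explicit, tunable rule: relative range
< 5% → `const`; otherwise 0 sign changes of consecutive phase
differences → `up`/`down`, 1 → `uni`, ≥ 2 → `bi`.  The winter phases
are reported but excluded from trend classification, since they are
dominated by abiotic forcing rather than biotic succession.  The rule
is declared, not claimed identical to any published labelling.

## The synthetic study system

The generator (`scenario_config()`, `generate_seasonal_scenario()`,
`generate_biomass_series()`) emulates the seasonal *structure* the
indices are designed to detect, not the field system's numbers:

* **Topology** — the fixed 8-group + PDOM link set (25 trophic + 7
  detrital links); guild-level webs come from the structural
  disaggregation.
* **Flows** — per phase, each consumer's diet fractions are drawn from
  a symmetric Dirichlet over its topological resources (concentration
  `alpha`); gross primary production (base 10⁶ µgC m⁻² d⁻¹, scaled by
  the phase's throughput multiplier, peaking in spring at 2.5×) is
  propagated up the web with availability-aware harvest: a consumer
  removes at most its harvest share of what each resource has left, so
  budgets always close.  Respiration (30–50%) and egestion to PDOM
  (25%) are fixed intake fractions; bacteria return no detritus; the
  remainder is exported.  The detrital loop (egestion → PDOM →
  bacteria → grazers) is resolved by fixed-point iteration of this
  linear propagation, so every network balances to machine precision.
  Within-group feeding (the group-level self-loops: intraguild
  predation among ciliates, rotifers, and cyclopoid cannibalism) is
  fed from the consumer's own production and capped at half of it.
* **Seasonality** — the flow-evenness trajectory that makes C_w rise
  and Asc_rel fall over phases 2–6 is carried mainly by a
  deterministic exploitation ramp (harvest multipliers 0.34 → 1.0:
  early grazers underexploit the bloom, late-season consumers work
  their full prey spectrum), assisted by a modest Dirichlet
  concentration ramp (α 25 → 90: spring diets are more lopsided than
  autumn diets).  Carrying the whole trend on small α values alone
  would bury it in sampling noise, since a symmetric Dirichlet at low
  concentration is uneven in a random direction.  The CWP multiplies
  the keystone grazer's harvest by 1.25, concentrating ingestion
  through the herbivorous crustaceans (`keystone_factor = 0` or `1`
  disables this, making the CWP an ordinary draw of the law).
* **Phosphorus** — derived from carbon by dividing each flow by the
  C:P of its source material (phytoplankton C:P rising 100 → 280 over
  the season as P depletes; bacteria at 50, consumers 90–130, detritus
  250).  Nodes whose intake is P-poorer than their own stoichiometry
  (bacteria, by design) close their budget with a phosphorus import
  representing dissolved-P uptake.
* **Biomass** — weekly 24-guild snapshots; per phase, relative
  plankton biomasses are Dirichlet draws (total concentration 80)
  around a profile that is mildly algae-dominated in early spring,
  keystone-dominated at the CWP (dominance weight 0.72 on the
  daphnid guild, driving functional diversity to its seasonal minimum
  of ~2 bits), and even otherwise; absolute biomass follows a
  per-phase amplitude (1.5–9 × 10⁶ µgC m⁻²).  Fish are a small (~4%)
  slowly varying add-on used by the eco-exergy and trophic-position
  calculations.

What the generator does *not* emulate: absolute flow magnitudes and
stocks of any real lake, week-scale autocorrelation within phases,
interannual variability, co-variation between the flow networks and
the biomass series (they are independent draws given the phase), or
species-level taxonomy.  Passing tests on this synthetic system
therefore demonstrate that the indices detect the structural patterns
they are defined for — not that any real system shows those patterns.

## Numerical choices and degenerate inputs

* Entropy terms use 0·log 0 = 0; zero flows are skipped everywhere.
* Dirichlet draws are floored at 10⁻¹² before normalization so no
  topological link is lost to gamma underflow.
* The trophic linear system reports singularity (a closed consumer
  loop with no basal path) rather than returning a pseudo-solution;
  consumers with zero ingestion are an error, as are all-zero biomass
  vectors, empty flow selections, degenerate min-max ranges and
  constant series passed to the rank correlation.
* Ties in path selection resolve to fewer links, then the higher flow
  score; remaining ties are broken by node order (deterministic).
* Seeded runs are bit-reproducible; each phase derives its own seed
  from the scenario seed so networks can be regenerated independently.

## Problem sizes

All shipped analyses run on the 9-node group web and its 25-node
disaggregation: a full seasonal analysis (7 phases × 2 elements, all
16 indices, report and correlations) takes well under a second, and
the 100-seed trend-recovery sweep a few seconds.  These sizes were
chosen because the scientific object — the group-resolution flow web —
is small by construction; nothing in the implementation assumes it.

## Known limitations

* The guild-level disaggregation is uniform, not flow-calibrated; D
  and Q on the 24-guild web inherit that approximation.
* The static chain split (grazing vs detritus) ignores fractional
  allocation of mixed feeders.
* Empirical SCOR-style network files are not parsed; networks enter as
  the documented CSV pair.
* The trend classifier is a declared rule over 5 phase means; with
  other phase axes the 5% threshold may need revisiting.
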