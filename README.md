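# planksucc

System-level indices of seasonal plankton succession in quantitative
(flow-weighted) food webs.

Ecosystem theory predicts how a community should reorganize during
succession: functional diversity and body size up, mass-specific
metabolic activity and system exports down, energy-flow complexity and
information content up. Testing those predictions needs indices that
live at the *system* level and work on mass-balanced flow networks —
the currency of quantitative food-web ecology. `planksucc` implements
that index family for the canonical model system, the seasonal
plankton succession of a large temperate lake, and is aimed at
ecosystem ecologists who have (or simulate) per-phase flow matrices
and biomass series and want the whole indicator suite from one tested
code base.

## What it computes

For a mass-balanced flow network (internal flows `T_ij` plus imports,
exports, respiration and storage per node; Σin = Σout per node):

* **Activity**: total system throughput `TST = Σ flows` (boundary terms
  once).
* **Information**: flow diversity `H_flow = −Σ p log2 p` with
  `p = T_ij/TST`; average mutual information
  `AMI = Σ p log2(T_ij·TST / (T_i· T_·j))`; overhead `Φ = H_flow − AMI`;
  ascendency `Asc = TST·AMI`; development capacity
  `K_dev = TST·H_flow`; relative ascendency `Asc_rel = AMI/H_flow`;
  fitness `F = −Asc_rel ln Asc_rel` (max at 1/e ≈ 0.36).
* **Connectance**: weighted link density `Conn_w = 2^(Φ/2)` and
  weighted connectance `C_w = Conn_w/S` on the feeding-link set;
  binary `Conn_bin = L/S`, `C_bin = L/S²`.
* **Small world**: weighted characteristic path length `D` (+ `D_norm`
  vs. a random graph) and Barrat-style weighted clustering `Q`
  (+ `Q_norm`).
* **Trophic structure**: flow-weighted trophic positions
  `TP_i = 1 + Σ_j f_ij TP_j` (producers/bacteria at 1, detritus at 0),
  fractional-level biomass/production pyramids, transfer efficiency
  across levels 1–3 (and the size-spectrum route
  `TE = PPMR^(SSS+1−A)`), weighted predator-prey body mass ratios,
  normalized biomass size-spectrum slope, `P_tot/B_tot`, residence
  times `SRT = stock/outflow`, diet composition and diet C:P.
* **Biomass indices**: Shannon functional diversity `H_bio` (bits),
  succession rate `σ = Σ|Δb_i|/Δt`, eco-exergy `Ex = Σ β_i B_i` and
  `Ex_sp = Ex/B_tot` (β: bacteria 8.5 … fish 499).
* **Pipeline**: 7-phase averaging, min-max normalization, a composite
  succession index from TE, P/B, H_bio and C_w, trend classification
  and Spearman correlations.

The Lake Constance topology ships as code (`lc_guilds()`: 24 guilds
with log2 size classes and diets; `lc_group_links()`: 8 groups + PDOM,
25 trophic + 7 detrital links), together with a seeded generator of
mass-balanced seasonal C and P networks and guild biomass series
(`generate_seasonal_scenario()`, `generate_biomass_series()`), so the
full pipeline runs with no external data.

## Worked example

```r
library(planksucc)

cfg <- scenario_config(seed = 1)
net <- generate_balanced_network(cfg = cfg, phase = "Autumn")
validate_mass_balance(net, rtol = 1e-9)   # PASS, worst residual 0
ascendency_suite(net)
#> TST 2.207e+06 | H_flow 3.375 AMI 1.366 Phi 2.008 bits |
#> Conn_w 2.092 C_w 0.232 | Asc 3.015e+06 K_dev 7.449e+06
#> Asc_rel 0.405 F 0.366
```

An autumn network: flows are even (high `H_flow`), the web is
well-connected (`C_w` 0.23), and the relative ascendency sits near the
theoretical fitness optimum of 1/e.

The numbered drivers under `analysis/` run the whole study on the
synthetic seasonal system and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # 7 phases x {C,P} networks + biomass CSVs
Rscript analysis/02_indices.R    # all 16 indices per phase
Rscript analysis/03_report.R     # summary report, composite, correlations
```

`02_indices.R` prints, per phase (seed 1):

```
        phase H_bio     TE     PB   C_w Asc_rel
  Late Winter  4.29 0.0794 0.0907 0.139   0.470
 Early Spring  4.01 0.0407 0.2370 0.122   0.490
  Late Spring  4.27 0.0829 0.1422 0.142   0.467
          CWP  2.04 0.1233 0.1296 0.157   0.454
       Summer  4.23 0.1848 0.0589 0.189   0.432
       Autumn  4.21 0.2736 0.0696 0.232   0.405
```

Reading the columns: functional diversity is bimodal with its minimum
at the clear-water phase (the keystone crustacean dominates the
biomass); metabolic activity peaks in early spring and falls as larger
consumers take over; weighted connectance rises monotonically from
early spring to autumn while relative ascendency declines — the
structural signature of successional progress these indices are built
to detect. `03_report.R` classifies the trends (`C_w` "up", `Asc_rel`
"down", `H_bio` "bi", …) and reports the perfect rank correlation
between TE and C_w in this scenario (ρ = 1.0 across the 7 phases).

## Layout

* `R/` — the package: network container and I/O, resolution changes,
  all index families, the succession pipeline, the synthetic
  generator.
* `analysis/` — the numbered study drivers (simulate → indices →
  report).
* `tests/testthat/` — unit, property and acceptance tests, including
  brute-force oracles for trophic positions, path selection and
  clustering on small enumerable webs.
* `vignettes/succession-indices.Rmd` — the methods vignette: model,
  conventions, generator design and limitations.
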