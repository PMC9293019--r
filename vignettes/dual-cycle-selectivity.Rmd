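---
title: "Modelling stereoselectivity of dual-site enamine organocatalysts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stereoselectivity of dual-site enamine organocatalysts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enaminekin)
```

## The problem

A γ-dipeptide organocatalyst carries two secondary-amine (pyrrolidine)
units. Either one can condense with the ketone to form the nucleophilic
enamine while the other, protonated by the acid additive, activates the
electrophile. That opens **two independent catalytic cycles** (A and B, one
per site), each of which branches again over the **distal/proximal**
conformation of the enamine (C=C away from or near the carboxamide link)
and over the four stereochemical channels of the C–C bond-forming step —
the combinations of prochiral faces that decide whether the product is the
anti or syn diastereomer and which enantiomer of the pair is formed.

Observable selectivity — the diastereomeric ratio (dr), the enantiomeric
excess (ee) and, conceptually, the share of turnover carried by each cycle
— therefore emerges from a branched kinetic competition, not from a single
barrier difference. `enaminekin` models that competition explicitly: a
user-supplied (or generated) set of relative Gibbs energies becomes a
mass-action network, the network is integrated in time, and selectivity is
read off the product fluxes.

## Model and assumptions

**States.** A free-energy landscape lists stationary points with energies
relative to one zero reference (conventionally the most stable separated
enamine + free electrophile): enamine intermediates per (cycle, conformer),
enamine–electrophile reactive complexes, and one C–C transition state per
stereochannel, labelled with its product configuration ("RS" = (2R,1'S),
etc.). The configuration ↔ diastereomer-class mapping is fixed per reaction
type: the (2R,1'S)/(2S,1'R) pair is *anti* in the aldol and *syn* in the
Michael reaction.

**Steps.** `build_dual_cycle_network()` assembles, per cycle:

1. acid protonation of the site (only when both cycles are present, so the
   acid partitions between them),
2. enamine formation per conformer (reversible),
3. distal ⇌ proximal interconversion when both conformers exist,
4. electrophile binding to the reactive complex (reversible),
5. the irreversible C–C step per stereochannel, with
   `eyring_rate(g_TS − g_RC)` — transition-state theory with transmission
   coefficient 1,
6. hydrolytic product release regenerating the protonated catalyst.

**Key kinetic assumptions.**

* *C–C formation is irreversible and stereochemistry-determining.* All
  selectivity information is encoded in the TS energies; downstream
  hydrolysis is a fast lumped step.
* *Equal basicity of the two sites.* Protonation rate constants are equal
  for cycles A and B by default (`protonation_bias` exposes asymmetry), so
  any A:B preference emerges from the landscape, not from the partition
  step.
* *Detailed balance before the C–C step.* Every reversible step's reverse
  constant is computed from the landscape energies
  (k_rev = k_fwd / K_eq, K_eq = exp(−ΔG/RT)). This is what makes the model
  reduce exactly to the Curtin–Hammett limit when interconversion is fast:
  with all pre-C–C pools equilibrated, channel flux is proportional to
  exp(−G_TS/RT), independent of the intermediate energies. The test suite
  asserts agreement with the analytic ratio to well below 0.5% relative.
* *Pseudo-first-order treatment of the nucleophile.* The ketone is present
  in large excess (60 equivalents for the aldol, 8 for the Michael
  reaction, matching the experimental stoichiometries), and bimolecular
  lumped steps use effective constants referenced to the initial excess.

**Selectivity outputs.** `selectivity()` computes dr from product yields
summed by diastereomer class, ee on the (2R,1'S)/(2S,1'R) pair (positive
when (2R,1'S) is major), and the cycle partition by integrating each
channel's instantaneous C–C rate over the trajectory. Flux integration
rather than terminal pools was chosen deliberately: it remains well-defined
if a user builds a network in which both cycles feed shared product states,
and it is the natural definition of "relevance of a cycle". For the
shipped topologies (one product species per channel) the two attributions
coincide.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `temperature` | K | 298.15 | ambient standard; landscapes may override |
| `k_lump` | s⁻¹ | 10³ | enamine formation / protonation / hydrolysis; fast relative to C–C rates so the landscape controls selectivity |
| `k_conf` | s⁻¹ | 10⁴ | conformer interconversion (downhill direction); lower it to approach the frozen-conformer limit |
| `k_bind` | M⁻¹s⁻¹ | 10⁴ | electrophile binding; reverse from detailed balance |
| `electrophile_conc` | M | 0.1 | typical limiting-reagent concentration |
| `catalyst_equiv`, `acid_equiv` | equiv | 0.3 | the loading used in the kinetic experiments |
| `rtol`, `atol` | – | 10⁻⁸, 10⁻¹² | integration tolerances; conservation is checked post hoc to ≤10⁻⁸ relative |

The defaults place every lumped rate two or more orders of magnitude above
the C–C rates of the shipped landscapes (barriers ≥ 17 kcal/mol from the
reactive complex, i.e. k ≲ 10 s⁻¹), which is what justifies reading the
presets as Curtin–Hammett systems. Because ee and dr are invariant to a
uniform rescaling of all rate constants and to the catalyst loading (all
catalytic steps are first order in catalyst), these choices move the time
axis, not the selectivity — both invariances are asserted in the tests.

The Eyring conversion uses CODATA values k_B = 1.380649 × 10⁻²³ J/K,
h = 6.62607015 × 10⁻³⁴ J·s and R = 1.987204 × 10⁻³ kcal/(mol·K).

## The synthetic generators: what they emulate, and what not

**Kinetic traces.** `generate_trace()` produces integral time courses for
the three fluorine signals of a pentafluorophenyl electrophile (initial
levels 2:2:1, the ortho/meta/para multiplicities) against a constant
internal-reference signal, decaying as a single exponential with
multiplicative lognormal noise — the error model appropriate for NMR
integrals, whose uncertainty scales with the signal. Twelve points over
3000 s match hour-scale runs at k_obs ≈ 10⁻³ s⁻¹. The generator does *not*
emulate baseline drift, peak overlap, field instability or relaxation
effects; a passing recovery test shows the estimator is unbiased under
well-behaved integral noise, not that integration of real spectra is
error-free.

**Landscapes.** `landscape_preset()` ships three synthetic energy sets with
the dual-cycle topology. The `dual-cycle-aldol` preset places its TS
energies so that the fast-pre-equilibrium limit gives anti:syn = 92:8,
ee(anti) = +85% and A:B = 58:42, and the `dual-cycle-michael` preset
syn:anti = 90:10, ee = +87% with a strongly A-dominated partition and the
cycle-B reactive complex 7 kcal/mol above its A analogue — the selectivity
regime characteristic of these catalysts. The intermediate energies encode
the qualitative features of the mechanism (cycle-B enamine slightly more
stable yet less reactive; both conformers thermally accessible). These are
*stand-ins*: no quantum-chemical energies ship with the package, and
conclusions about a real catalyst require the user's own landscape via
`read_landscape()`.

**Conformer ensembles.** `generate_conformer_ensemble()` samples two
clusters of the marker dihedral (near 0° and 180°) with a designed energy
gap and equal within-cluster spreads, emulating the output of a force-field
conformational search. Equal spreads leave the designed two-state Boltzmann
split intact in expectation, which is what makes the recovery test sharp.

## Numerical choices and degenerate inputs

* **Integration.** `deSolve::ode` with lsoda (automatic stiff/non-stiff
  switching) on a geometric output grid of 400 points plus t = 0; the
  early-time density resolves the fast relaxation of the lumped steps and
  keeps the trapezoidal flux integrals accurate. Material-tag conservation
  (catalyst, ketone, electrophile, acid proton) is checked on every
  trajectory.
* **Problem sizes.** The shipped simulations integrate 9–28 species to
  full conversion (t_end 2 × 10⁴ s for the aldol preset, 2 × 10⁶ s for the
  slower Michael preset, 3 × 10⁵ s for the two-channel benchmark); each run
  takes well under a second, and the Monte-Carlo recovery study uses 200
  replicates per rate constant.
* **Dihedral tie-break.** |ω| = 90° is assigned to *distal*; only the ≈0°
  and ≈180° extremes are physically meaningful, so the boundary convention
  is arbitrary but fixed and documented.
* **Regression intercept.** The log-ratio transform anchors y(t₀) = 0
  exactly, but the default fit still estimates a free intercept: an error
  in the t₀ integrals otherwise propagates into every residual. The
  anchored mode is available (`intercept = "anchored"`) and agrees on clean
  data.
* **Uncertainty convention.** The reported ± is the cross-signal standard
  deviation of the per-signal constants, matching how multi-signal NMR
  kinetics are usually tabulated; a single-signal trace falls back to the
  regression slope standard error.
* **Reference floor.** Points whose reference integral drops below 10⁻⁶ of
  its maximum are excluded with a warning before fitting.
* **Degenerate cases.** Zero total product raises an undefined-selectivity
  error; conversion below 99% warns; a TS below its reactive complex is a
  specification error in the generator and a barrierless-rate warning in
  the builder; empty ensembles, non-increasing time grids and non-positive
  integrals are rejected with specific error classes.

## Additive enantiocontrol

For dimers the expected ee is the weighted mean of the unit contributions,
each unit giving its monomer ee after the L/D mirror rule (a D unit negates
the value of its L form). With the two monomer values +89 (exo-L) and −81
(endo-L), the model reproduces every NH/NH homo- and heterodimer ee
exactly: +89, −81, 0, 0, +4, +4, +85, −85 for the eight L/L, L/D
combinations. A dimer is *matched* when both mirrored contributions share a
sign. N-methylated units cannot form the enamine, so their weight
reassigns to the NH unit, reproducing the observation that mono-blocked
dimers behave like the corresponding monomers. The 50:50 default weights
can be refined with a microkinetics-derived partition — with w_A = 0.58 the
exo-L/exo-D dimer is predicted at +14.2% rather than 0, the direction seen
experimentally for that catalyst.

## Known limitations

* Gibbs energies are inputs; the package computes nothing from molecular
  structure, and the shipped landscapes are synthetic.
* Enamine formation and hydrolysis are lumped single steps; explicit
  acid/base speciation, water activity and iminium hydrolysis kinetics are
  outside the model.
* The transmission coefficient is fixed at 1; no tunnelling or variational
  corrections.
* Deterministic mass-action only — no stochastic simulation, and
  sensitivity analysis is limited to what the user scripts via rate-constant
  perturbation.
* The NMR module fits single-exponential pseudo-first-order decays only;
  second-order or reversible kinetics are out of scope.
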