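---
title: "Measuring energetic coupling networks with thermodynamic cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring energetic coupling networks with thermodynamic cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclenet)
```

## The problem

Enzymes that couple catalysis to conformational change — synthetases,
motors, polymerases, signaling NTPases — owe part of their rate
acceleration to interactions that exist only transiently, in the
transition state, between parts of the protein that move relative to one
another. Those interactions are invisible to single-point mutagenesis:
they appear only as *non-additivity* when several perturbations are
combined. `cyclenet` implements the quantitative machinery for measuring
such energetic coupling networks from combinatorial perturbation
experiments on an enzyme such as tryptophanyl-tRNA synthetase (TrpRS):
point mutations of a packing motif, substitution of the catalytic metal
(Mg²⁺ → Mn²⁺), deletion/restoration of whole domains, and removal of the
metal by chelation.

## Thermodynamic cycles and the coupling regression

Rates are the experimental currency; free energies are the analytical
one. Every rate or fold-acceleration `k` is converted to a Gibbs
activation energy

&nbsp;&nbsp;&nbsp;&nbsp;ΔG‡ = −RT ln k,

with RT fixed at 0.592 kcal/mol by convention (`rt_constant()`; a
temperature override recomputes RT = 0.0019872·T). Larger rates map to
more negative ΔG‡, so *stabilizing* interactions carry negative sign
throughout the package.

A thermodynamic cycle is a 2^N factorial experiment: every combination
of N perturbations is constructed and assayed. Because the free-energy
change around any closed circuit of states is zero (`cycle_closure()`
checks this), the non-additivity of the cycle is well defined and
measures the coupling energy between the perturbed elements.
`cycle_coupling()` computes the N-way non-additivity as the alternating
corner sum of ΔG‡ — corners with an even number of perturbed factors
enter positively, odd corners negatively — which for N = 2 reduces to the
textbook double-mutant-cycle formula ΔG₁₁ − ΔG₁₀ − ΔG₀₁ + ΔG₀₀.

For N > 2 the cycle algebra generalizes to the effect-coded linear model
fitted by `fit_coupling()`:

&nbsp;&nbsp;&nbsp;&nbsp;ΔG_obs = C + Σ ΔG_i·[i] + Σ ΔG_ij·[i][j] + … +
ΔG_1…N·[1]…[N],

where each indicator [i] is +1 for the reference level (wild-type
residue, Mg²⁺) and −1 for the perturbed one (mutant, Mn²⁺). On a
balanced full factorial the design columns are mutually orthogonal
(X'X = n·I), so each coefficient is simply the corner-parity average of
the responses; with replication, ordinary least squares additionally
yields standard errors, per-term t tests, R² and an overall F test. Main
effects are intrinsic free-energy contributions; cross terms are the
coupling energies.

### Two reporting scales

The highest-order coefficient of the saturated fit and the cycle's
alternating-sum non-additivity measure the same physics on different
scales: the non-additivity over a full 2^k cube equals 2^k times the
generating k-way coefficient. Published histograms of "contributions" do
not always state which scale they use, so every `EffectEstimate` row
carries both: `coefficient` (the regression scale) and `cycle_energy`
(= 2^order × coefficient). The equality of `cycle_coupling()` and the
order-N `cycle_energy` on noiseless data is enforced by the test suite.

### Sign conventions that matter

* +1 = reference, −1 = perturbed. Flipping the coding of one factor
  flips the sign of every odd-order coefficient involving it; the
  magnitude is invariant (tested).
* Rate-enhancing joint behavior ⇒ negative coupling energy.

### Inference choices

Per-term p values are raw t tests by default, as is standard for
factorial mutagenesis reports; `p_adjust = "holm"` is available. A
saturated model fitted to one replicate per corner has zero residual
degrees of freedom: its standard errors are reported as `NA` rather than
fabricated. Unbalanced (missing-corner) designs are fitted by OLS with a
warning, since the orthogonal-averaging interpretation no longer holds.
Weighted fits are available but the default is homoscedastic OLS, which
matches the error structure of the synthetic generator (constant
Gaussian noise on the ΔG scale).

## The metal-depletion model

Chelation titrations measure how much of catalysis the metal accounts
for. Adding EDTA to an assay with residual Mg²⁺ progressively strips the
metal; activity falls and then — for an enzyme with genuinely
metal-independent catalysis — reaches a plateau. Two coupled 1:1
equilibria (Mg·ATP, Mg·EDTA) set the free metal concentration at every
EDTA total. `solve_speciation()` solves the conservation equation

&nbsp;&nbsp;&nbsp;&nbsp;Mg_total = m·(1 + Σ_j L_j,tot /(K_dj + m))

for free metal m by bracketed root search on log m followed by Newton
polishing; conservation residuals are below 1e−10 relative (tested, and
cross-checked against a grid-refinement oracle).

Activity versus free metal follows a two-parameter saturable model
(`predicted_activity()`):

&nbsp;&nbsp;&nbsp;&nbsp;v = v_max·( f + (1 − f)·m/(m + K_D‡) ),

with `f` the metal-free rate fraction (the floor, dimensionless) and
K_D‡ the dissociation constant of the metal from the transition-state
complex (M). `fit_depletion()` fits the *logarithm* of activity — the
titration spans about five decades, and the log scale keeps the floor
from being swamped — jointly across enzyme concentrations (one shared
activity-per-enzyme parameter scales v_max per series). Parameters are
estimated on the log10 scale to enforce positivity and reported with
delta-method standard errors. The Mg·ATP and Mg·EDTA constants are
required configuration: the defaults (`default_kd()`: 10^−4.5 M and
10^−9.5 M) are conditional constants at a typical assay pH, and
parameter recovery is insensitive to the choice as long as generation
and fitting share it.

Identifiability is flagged, not papered over: a flat series (range
< 1.5-fold) returns `kd_identifiable = FALSE` with `kd_ts = NA`; a
titration whose deepest point still leaves the saturable term dominant
(`plateau_reached = FALSE`) marks K_D‡ as weakly identified.

## Burst kinetics and the chemical step

Active-site titration separates the chemical step from turnover: the
product time course shows an exponential burst (amplitude = active
enzyme) followed by a linear steady state. `fit_burst()` fits the
standard burst equation

&nbsp;&nbsp;&nbsp;&nbsp;P(t) = A·(1 − e^(−k_chem·t)) + v_ss·t + C.

Printed renderings of this equation sometimes drop the amplitude factor
or a sign, yielding a curve that *decreases* with time; the standard
form above is the one whose derived quantities (turnover, the
chemical-step/turnover ratio) are internally consistent, and it is the
form implemented and generated here. Turnover is
k_cat = v_ss/(E_total·active_fraction) — the active fraction is an
explicit input (default 1) because it comes from a separate titration
experiment — and the headline ratio k_chem/k_cat is dimensionless and
invariant to rescaling the product axis (tested). Initialization is
deterministic (tail slope for v_ss, early log-decay for k_chem; no
random restarts), the optimizer is Levenberg–Marquardt with tight
tolerances plus a Gauss–Newton polish, so identical inputs give
identical fits and noiseless round trips recover parameters to ≤ 1e−6
relative (the pure-exponential limit to ≤ 1e−9). A burst amplitude
indistinguishable from zero (below 2 standard errors) flags the ratio as
undefined rather than reporting a meaningless number, and the fit then
degrades gracefully to a straight line. `fit_michaelis_menten()`
provides the steady-state complement, initialized from the Hanes–Woolf
linearization and flagging K_M unidentifiable when the data are all
saturating.

## The dynamic-contact filter

To decide *which* residues to permute, invariant packing is filtered
out geometrically. Each conformation of the protein is reduced to one
point per residue — the side-chain heavy-atom centroid, Cα for glycine
(`residue_centroids()`, via `bio3d`; a pure-Cα representation is
available with `point = "ca"`, since published packing analyses do not
always state their representation) — and Delaunay-tessellated into
simplices of four mutually-nearest residues. Simplices present in every
conformation lie within rigid bodies and are invariant; those that
rearrange are *dynamic*, and their residue union is the candidate set
(`dynamic_simplices()`). Intersecting that set with an externally
computed stabilization-design list (`candidate_intersection()`) gives
the final, experimentally tractable candidates; the design list is
consumed as a two-column file, never computed here.

Numerical choices:

* The tessellation engine is an incremental Bowyer–Watson construction
  written in the package (no 3-D Delaunay library is assumed), validated
  against a brute-force empty-circumsphere oracle on ≤ 12 points and
  post hoc on every retained simplex (1e−9 Å slack).
* Cospherical degeneracies are broken by a deterministic jitter (1e−6 Å)
  keyed to the residue-id string, so results are identical across runs
  and conformations; edge lengths are measured on unjittered
  coordinates.
* Simplices with any edge longer than 8 Å (configurable) are discarded
  to suppress spurious surface tetrahedra; together with the
  log-likelihood bands this approximates a core/surface distinction.
* No superposition is performed: Delaunay adjacency is invariant to
  rigid motion (tested), so conformations may sit in arbitrary frames.
* Residue numbering is preserved verbatim as `chain:resno`.

`score_simplices()` attaches a packing log-likelihood Λ per simplex from
a pluggable composition table, with the conventional bands Λ > 0.6
(high) and Λ < 0 (negative). No published statistical potential is
bundled; a uniform table scores everything zero.

## What the synthetic generators emulate — and what they do not

All inputs the analyses consume can be generated with known truth:

* `gen_factorial_dataset()` — full 2^N designs from the effect-coded
  model with Gaussian noise on the ΔG scale (lognormal on rates, the
  multiplicative error structure of replicate rate assays). Defaults:
  3 replicates and σ = 0.3 kcal/mol, matching roughly three-fold
  replication with coefficient standard errors of ~0.03 kcal/mol on a
  2⁵ design.
* `gen_edta_titration()` — activity via the speciation and depletion
  models. Defaults: 10 µM residual Mg²⁺, 100 µM ATP, two enzyme
  concentrations, a 12-point grid dense around the depletion knee (where
  free Mg²⁺ sweeps through K_D‡) and extending to 10 mM EDTA so the
  metal-free floor is visible, 5% lognormal noise. A titration truncated
  before the knee leaves K_D‡ essentially unconstrained — the flags
  exist precisely because the information content of the grid, not the
  optimizer, is usually the limiting factor.
* `gen_burst_course()` — the burst forward model with Gaussian noise,
  sampled through both the millisecond burst and the linear phase.
  Defaults: k_chem = 3125 s⁻¹, k_cat = 5 s⁻¹ (ratio 625).
* `gen_toy_structures()` — self-avoiding pseudo-protein chains (3.8 Å
  steps, ≥ 3.5 Å separation) with a chosen residue set displaced by a
  stated distance in a second conformation, written as synthetic PDB
  files with a JSON truth sidecar.

Every generator is a bit-reproducible function of its seed. What they do
*not* emulate: correlated replicate errors, day/batch effects,
concentration uncertainty in the titrations, pH-dependent conditional
constants, partially occupied or disordered side chains, and real
protein packing statistics. Passing recovery tests therefore
demonstrates the *estimators* are correct and calibrated under the
assumed error model, not that real assays meet those assumptions.

## Problem sizes and test design

The test suite exercises: exact recovery on noiseless data (2⁵
factorials, 24-point titrations, 30-point time courses); calibration
under noise (100-seed Monte-Carlo runs for the kinetic fits; 200-seed
coverage of nominal 95% confidence intervals, required to land in
92–98%); and oracle equivalence (alternating-sum coupling oracle,
corner-parity averages, grid-refinement speciation, brute-force
Delaunay on ≤ 12 points). These sizes were chosen so the entire suite
runs in well under a minute while keeping Monte-Carlo standard errors
small relative to the tested tolerances.

## Known limitations

* Only rate-derived activation energies are modeled; equilibrium-binding
  (K_D) cycles are out of scope.
* The depletion model assumes a single saturable transition-state metal
  site plus a constant floor; enzyme-bound metal is neglected (valid
  when enzyme ≪ ATP and EDTA totals).
* No mixed-effects or Bayesian variants of the coupling regression; no
  model selection beyond interaction-order truncation.
* The Delaunay filter classifies by simplex membership only; it does not
  compute conformational energetics, and the quality of the candidate
  list inherits the quality of the input conformations.
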