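---
title: "Methods: steady-state 13C flux analysis for cultured tissue slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state 13C flux analysis for cultured tissue slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliceMFA)
```

## The problem

Tissue slices cultured ex vivo exchange metabolites with their medium and
can be labeled with ¹³C tracers. Given (i) an atom-mapped model of central
metabolism, (ii) mass-isotopomer distributions (MIDs) measured by LC–MS in
tissue and spent medium, and (iii) net uptake/release rates inferred from
medium composition changes, metabolic flux analysis (MFA) estimates the
intracellular reaction rates that best explain all measurements
simultaneously. The deep-labeling design — every amino acid plus glucose
fully ¹³C-labeled — makes a single experiment informative about many
pathways at once, at the price that isotope dilution by unlabeled sources
(glycogen, tissue-protein breakdown, serum) must be modeled explicitly.

`sliceMFA` implements this workflow end to end: OpenFLUX-dialect model
input, EMU-based simulation, MID quality filtering and natural-abundance
correction, exchange-rate quantification, weighted least-squares fitting
with a χ² fit test, profile-likelihood confidence intervals,
substrate-to-product carbon flows, and a label-free flux variability
analysis (FVA) for contrast.

## Model representation

Models are sheets with one row per reaction: an equation (`A + B = C`),
carbon transitions (`ab + c = abc`), and a type code (`F` irreversible,
`FR` reversible, `S` substrate uptake, `B` sink/release). Carbon counts are
inferred from transition strings and validated; every internal reaction
must balance its carbon-letter multiset; sink reactions may retire carbon.
Species in different compartments are distinct metabolites, connected only
by transport reactions or declared mixtures. Steady state restricts fluxes
to the null space of the stoichiometric matrix over balanced metabolites;
`free_flux_basis()` selects (by column-pivoted QR) a set of reaction fluxes
that parameterize that space. Which fluxes act as free coordinates is not
scientifically meaningful — any independent set spans the same space — so
the choice is automatic but configurable through pinning.

## EMU simulation

At metabolic and isotopic steady state, the MID of any subset of a
metabolite's carbon atoms (an elementary metabolite unit, EMU) satisfies a
linear balance: inflow-weighted MIDs of its precursor EMUs equal total pool
turnover times its own MID. Condensation reactions couple an EMU to the
convolution of smaller EMUs, so the system solves level by level in
increasing EMU size; each level is a dense linear solve (done in compiled
code, as this sits inside the fitting objective). Reversible reactions are
expanded into forward/backward fluxes `f = max(v,0) + x`,
`b = max(-v,0) + x`, with exchange flux `x ≥ 0` a free parameter in flux
units. Pools whose throughput falls below `1e-12` are pruned (multi-start
optimization legitimately visits boundary flux vectors) unless they feed a
requested target, which is an error.

Simulation operates in *tracer-only space*: measured MIDs are corrected for
natural ¹³C abundance rather than natural abundance being added to
simulations, so unlabeled substrates are `M+0 = 1`. Substrate labeling is a
mixture of positional components (per-atom ¹³C probability vectors), which
covers uniformly labeled tracers at a stated purity (default 0.99),
positional tracers, and unlabeled pools.

The test suite checks the EMU engine against an independent brute-force
oracle that enumerates all 2ⁿ isotopomers and solves the species balances
by fixed-point iteration; agreement is required to 1e-10 elementwise on all
bundled toy networks. Superposition in the substrate labeling holds — and is
tested — only for networks without condensation reactions, since
convolution makes products quadratic in substrate labeling.

## Compartment and spent-medium mixtures

Metabolites present in several compartments (cytosol, mitochondria,
lysosomes, endoplasmic reticulum) are observed as convex mixtures of pool
MIDs. Spent medium is modeled pseudo-steady-state as a mixture of fresh
medium and released intracellular metabolite,
`x_spent = α x_fresh + (1−α) x_intra`. Mixture coefficients are free
parameters fitted jointly with the fluxes; in the fitted parameter vector
each mixture has two components and one coefficient `α ∈ [0,1]` (the
general `mix_mids()` supports any number of components; nothing in the
published analysis requires more than two per observation).

## MID processing

* **Areas to fractions.** MI peak areas are normalized to fractions per
  metabolite and sample; all-zero vectors become missing values, not errors.
* **Collision filter.** An MI peak that already appears in unlabeled tissue
  extracts more than 0.05 above the `Bin(n, 0.0107)` natural expectation is
  a co-eluting contaminant and is removed for all samples of that
  metabolite. The filter exempts M+0: an unlabeled compound's M+0 exceeds
  the binomial expectation trivially (apparent M0 ≈ 1), and flagging it
  would defeat the filter's purpose of removing colliding *heavier* peaks.
  The excess is assessed on the mean of the unlabeled replicates (the
  per-sample alternative is a configuration choice, not a published one).
* **Natural-abundance correction.** The binomial transform maps a
  tracer-only MID to measured space by convolving each unlabeled atom with
  natural abundance; the correction inverts this exactly by
  back-substitution on the lower-triangular system, then clips small
  negatives and renormalizes. The correction is applied unconditionally:
  the published "where non-negligible" wording introduces a threshold that
  the exact inverse makes unnecessary (a no-op flag exists for comparison).
* **Enrichment.** `e = Σ i·xᵢ / n`, the mean fraction of labeled carbon.
* **Aggregation.** Replicate mean and sample sd are computed in corrected
  space (the sd floor applied at fitting time refers to corrected MIDs).

## Uptake/release rates

Three routes, all normalized to µmol per gram of tissue per day with the
22-h collection window (after the 2-h medium change), 1.3 ml medium volume,
and measured tissue mass:

1. **Fold change** against the known fresh concentration:
   `Δc_release = c (f − 1)` with `f` = spent/control peak-area ratio.
   The release-positive sign convention follows the flux figures
   ("uptake (negative) and release (positive)"); note the Methods formula
   `Δc = c(1−f)` has the opposite sign under the same reading of `f` — the
   figure convention governs, and the discrepancy is documented rather than
   silently resolved.
2. **Isotope dilution** for metabolites produced by the tissue: mixing
   spent medium 1:1 with fresh ¹²C medium of known concentration `c₀` gives
   `(c+c₀)x_mix = c·x + c₀·x⁰` with `x⁰ = Bin(n, 0.0107)`; the package
   solves for `c` by least squares over all MI indices (the system is
   overdetermined; the published solve is unspecified) and reports a
   residual diagnostic. Indistinguishable labeling (`x ≈ x⁰`) is an
   identifiability error, not a number.
3. **Direct assays** (e.g. glucose, lactate, triglycerides): rate from the
   fresh/spent concentration difference, same normalization.

## Fitting and fit assessment

The objective is the weighted SSR
`Σ ((sim − meas)/sd)²` over MI-fraction rows (sd floored at 0.03 — replicate
sds underestimate systematic error), exchange-flux rows (replicate sd, no
floor: the published floor is stated for MIDs), and literature-constraint
rows (any linear combination of net fluxes with mean and sd, covering O₂
consumption, redox demand, and protein turnover constraints). Parameters
are the free net fluxes, exchange fluxes, and mixture coefficients; the
count `p` follows the same convention as the published `p = 69`, and
degrees of freedom are `n − p` counting every MI row (no −1 per normalized
MID; the alternative convention would change the threshold and is not
used).

MIDs are simulated inside the objective (nested evaluation) and the
box-constrained problem is solved with `nlminb` from 10 seeded random
starts by default, keeping the best feasible solution. Sign constraints on
dependent irreversible fluxes are enforced by a quadratic penalty; a start
only counts as feasible when the violation is below 1e-9 of the squared
flux scale. The published simultaneous formulation (MI fractions as
explicit variables with algebraic constraints, solved in GAMS/CONOPT) is
*not* provided as an optional mode: it requires a general
equality-constrained NLP solver that is not available in this toolchain,
and on all tested problems the nested mode reaches the same optimum — this
is a deliberate deviation recorded here.

Goodness of fit uses the χ² statistic with the one-sided rejection region
at the 90% quantile of `χ²(n − p)`; with `n = 149` and `p = 69` this
reproduces the published threshold 96.6. Per-measurement residuals are
ranked to assess the influence of individual measurements.

## Profile-likelihood confidence intervals

For each reaction the net flux is pushed away from its optimum while all
other parameters are re-optimized; the 90% CI is where the SSR exceeds its
minimum by `χ²(1 dof, 0.90) = 2.706`. The pinned flux is an exact linear
constraint absorbed into the free-flux basis (no penalty tuning), the
search marches outward with step doubling and finishes by bisection, and an
end that reaches the configured flux bound without crossing the threshold
is flagged open-ended (structural non-identifiability). Default bounds are
10× the largest measured flux magnitude.

## Carbon flow

At the optimal flux vector, each substrate `i` is simulated fully labeled
with all others unlabeled; the enrichment `e_ij` of each released
metabolite `j` times its release rate `r_j` (in carbon units: rate × carbon
count) is the carbon flow from `i` to `j`. Metabolites both taken up and
released get `e_ij = 0`, discounting exchange fluxes; compound identity
between external species uses the id prefix before the first dot
(`GLC.ext` / `GLC.med`). With discounting off and a carbon-balanced model,
total flow equals total substrate carbon uptake — a conservation law the
tests verify both in aggregate and per substrate.

## Label-free FVA

For contrast with the labeling-based CIs, each net flux is minimized and
maximized subject only to steady state, bounds, and exchange measurements
within ±1.645 sd — a linear program solved in the free-flux coordinates
(via `boot::simplex`). Interval ends on the configured box bound are
flagged: those fluxes are unbounded without labeling information. On the
bundled model the glucokinase/glucose-6-phosphatase futile cycle is the
canonical example — FVA cannot bound it, the profile CI can.

## The synthetic-data generator

The bundled toy model is an original liver-like network (glycolysis with a
glucokinase/glucose-6-phosphatase futile cycle, glycogenolysis, a lumped
TCA cycle with pyruvate carboxylase and PEPCK, alanine exchange and
transamination, protein synthesis and degradation, lactate and CO₂
release), deliberately small enough for the brute-force isotopomer oracle.
Its ground-truth fluxes are chosen once to reflect fasted-state liver
slices: glycogenolysis 300 µmol g⁻¹ day⁻¹ (within the published 200–400
range), net glucose release exceeding uptake, active futile cycling, net
lactate release, alanine as the main consumed amino acid, and a substantial
unlabeled influx from protein degradation that keeps tissue amino-acid
enrichment visibly below tracer purity (the ¹²C-dilution phenomenon).

Datasets emulate 3 replicate slices with independent Gaussian noise of sd
0.03 on MI fractions (clipped at 0 and renormalized) — the same magnitude
the analysis floors at — and noisy exchange rates with realistic sds.
Features of real data deliberately *not* emulated: chromatographic
collisions and peak detection artifacts (the labeling module's tests build
those structures directly), batch effects and instrument drift,
non-stationary labeling kinetics, and multi-donor variability. A green
recovery test therefore establishes correctness of the estimator under its
own assumptions, not robustness to misspecification.

## Numerical choices

* Steady-state tolerance 1e-6 relative; MID validity 1e-9; EMU/oracle
  agreement 1e-10; pool-pruning threshold 1e-12.
* Optimizer: relative tolerance 1e-10, up to 500 iterations per start;
  feasibility (sign-constraint) tolerance 1e-9 of the squared flux scale.
* Multi-start initialization draws free fluxes uniformly within bounds
  from one seeded generator per run (rejection toward sign feasibility,
  with the penalty guiding infeasible starts); all package randomness is
  funneled through this generator, so every artifact is bit-reproducible
  under a fixed seed.
* Profile CIs: default initial step 5% of the flux scale, bisection to
  0.5% — coarser settings (25%/2%) are used in the high-volume recovery
  study after verifying they reproduce the same intervals to within the
  bisection tolerance.
* The replicate recovery study uses 2 optimization starts per noisy fit
  (versus the default 10) purely for runtime. Best-of-2 occasionally lands
  in a poor local optimum (we have observed this), which can only make the
  χ²-pass-rate and coverage checks *harder* to satisfy, so the scaled-down
  study is conservative; any single fit whose result is interpreted on its
  own uses the full 10 starts.

## Known limitations

* Isotopic steady state is assumed; batch slice cultures only approximate
  it, so fitted fluxes are approximations by construction.
* The fitted parameter vector supports two-component mixtures; K-way
  compartment mixtures are simulated but not fitted.
* Exchange fluxes of fast reversible reactions are weakly identified (as
  in any steady-state MFA); their CIs are typically open-ended.
* The GSM scoring module consumes precomputed gene-level z-scores; the
  differential-expression step itself is out of scope.
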