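# sliceMFA

Steady-state ¹³C metabolic flux analysis (MFA) for tissue slices cultured
ex vivo — written for researchers who measure mass-isotopomer distributions
(MIDs) by LC–MS in ¹³C-labeled tissue and spent medium and want quantitative
intracellular flux estimates with honest uncertainty.

At its core the package fits an atom-mapped metabolic network to data by
weighted least squares. With measured MI fractions and uptake/release rates
collected in a table with means and standard deviations, the fitted fluxes
minimize

    SSR = Σᵢ ( (simᵢ(v, x, α) − measᵢ) / sdᵢ )²

over free net fluxes `v` (steady state `S v = 0` on balanced metabolites),
exchange fluxes `x ≥ 0` of reversible reactions, and compartment/medium
mixture coefficients `α`. MIDs are simulated with the elementary metabolite
unit (EMU) decomposition — a cascade of linear solves, one per EMU size, with
condensation products formed by convolution — in natural-abundance-corrected
space. Goodness of fit uses the χ² statistic with a one-sided rejection
region at the 90% quantile of χ²(n − p); flux uncertainty comes from profile
likelihood (re-optimize everything else while pushing one flux until the SSR
rises by χ²₁,₀.₉ = 2.706); and carbon flows from substrate *i* to released
product *j* are `e_ij · r_j` with enrichments `e_ij` simulated one substrate
at a time.

The pipeline covers:

* **Model I/O** — OpenFLUX-dialect sheets (`rxnID, rxnEQ, rxnCTrans,
  rxnType`), carbon-balance validation, stoichiometric matrix, free-flux
  parameterization.
* **MID processing** — peak areas → fractions, collision filtering against
  unlabeled controls (excess > 0.05 over Bin(n, 0.0107)), exact inversion of
  the natural-abundance binomial transform, enrichment `e = Σ i·xᵢ/n`.
* **Exchange rates** — fold-change, isotope-dilution (1:1 mixing with ¹²C
  medium), and direct-assay routes, normalized to µmol g⁻¹ day⁻¹
  (release positive).
* **Fitting & inference** — multi-start weighted least squares, χ² test,
  residual influence, profile-likelihood CIs, carbon-flow decomposition,
  label-free FVA for contrast.
* **Synthetic data** — a liver-like toy network (glycogenolysis, a
  glucokinase/G6Pase futile cycle, TCA, alanine exchange, protein turnover)
  with a deep-labeling design and ground truth, for end-to-end testing.
* **GSM scoring** — pooled reaction z-scores from SBML gene associations
  (sum of gene z, strict z > 3, deterministic deduplication).

## Worked example

Generate a synthetic deep-labeling experiment on the bundled liver-like
model, fit it, and ask for the glucokinase confidence interval:

```r
library(sliceMFA)

model <- toy_liver_model()
ds  <- generate_dataset(model, noise_sd = 0.03, n_replicates = 3, seed = 11)
fit <- fit_fluxes(model$net, ds$table, model$labeling, model$quantities,
                  n_starts = 3, seed = 2, bounds = list(flux_ub = 2000))
fit
#> mfa_fit: SSR (chi2) = 8.866 on 48 measurements, 14 parameters
#>   dof = 34, 90% threshold = 44.9 -> ACCEPT (start 1 of 3)

profile_ci(fit, "GK")
#> GK: 134 [56.33, 258.2] (90% profile likelihood)
```

The fit is statistically acceptable (SSR 8.9 is far below the 90% rejection
threshold 44.9 for 48 measurements and 14 parameters), and the 90% profile
CI for glucokinase covers the simulation ground truth (150 µmol g⁻¹ day⁻¹).
The interval is wide — the futile glucose cycle is only resolved by the
labeling data; a label-free FVA on the same exchange measurements
(`label_free_fva(model$net, ds$flux_rows)`) leaves glucokinase unbounded up
to the configured flux bound.

Carbon flow at the ground-truth flux state:

```r
cf <- carbon_flow(model$net, model$truth, discount_exchange = FALSE)
round(colSums(cf$flow))
#> PROT_syn  GLC_rel  LAC_rel  CO2_rel
#>      150     2100      360      540
```

which sums to the total substrate carbon uptake (3150 carbon-µmol g⁻¹
day⁻¹), as conservation requires.

## Command line

An installed script exposes the stages as subcommands:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/slicemfa", package="sliceMFA"))') \
    synth --seed 5 --out bundle/
```

Subcommands: `synth`, `process`, `exchange`, `fit`, `ci`, `carbonflow`,
`fva`, `gsm`. Reruns with the same config and seed are byte-identical; every
output embeds a config digest.

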