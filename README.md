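# phlinkage

Constant-pH Monte Carlo simulation and proton-linkage analysis of ligand
binding, for structural bioinformatics and molecular-modelling work where
**binding is coupled to protonation**. The motivating case is the aspartyl
protease family (BACE-1, pepsin, HIV-1 protease, ...): a catalytic
carboxylate dyad titrates anticooperatively, a flap over the active site
opens and closes with pH, and inhibitor binding shifts the dyad's pKa by
several units — so the apparent binding free energy depends strongly on pH,
and fixed-protonation free energy calculations can be wrong by many
kcal/mol.

`phlinkage` provides the whole desk-scale analysis chain:

* **Discrete multi-site protonation models** (`system_model`): titratable
  sites with model-compound reference pKa values (Asp 4.0, Glu 4.4, His 6.5,
  Tyr 9.6, Lys 10.4), discrete conformers, conformer-dependent intrinsic
  shifts and pairwise both-protonated couplings; YAML/JSON model files.
* **Sampling** — Metropolis constant-pH Monte Carlo with replica exchange in
  the pH dimension (`run_ph_remd`): the energy of protonating site *i* is
  `kT ln10 (pH − pKa_ref,i)` plus the model's electrostatic surrogate terms,
  and adjacent replicas swap pH assignments with probability
  `min{1, exp[ln10 (N_i − N_j)(pH_i − pH_j)]}`.
* **Exact oracles** — the semi-grand partition function of any model with up
  to 2^22 microstates is enumerated exactly (`exact_site_fraction`,
  `exact_mean_protons`, `binding_polynomial_ln`), so every sampled quantity
  can be checked against closed-form statistical mechanics.
* **Titration analysis** — per-pH deprotonated fractions and Hill fits
  `s = 1/(1 + 10^{n(pKa − pH)})` with heteroscedasticity-consistent standard
  errors (`fit_hill`, `pka_table`), plus conformer populations vs pH.
* **Binding thermodynamics** — Wyman linkage:
  `ΔG°(pH) = ΔG°_ref + kT ln10 ∫_{pH_ref}^{pH} ΔZ dpH` with
  `ΔZ = Z_PL − Z_P − Z_L` the binding-induced change in bound protons
  (`charge_curve`, `delta_z`, `integrate_profile`), the single-site closed
  form, exact binding-polynomial profiles, a linkage-slope consistency check
  (`wyman_residuals`), and the fixed-protonation-state error scenario
  (`fixed_state_profile`).

## Worked example

Simulate the ten-site aspartyl-protease-like preset (two-conformer flap
surrogate, coupled Asp32/Asp228 dyad) across the pH 1–12 ladder and fit
microscopic pKa values:

```r
library(phlinkage)

pair <- make_preset_pair("bace_like")   # validated apo + holo models
res  <- run_ph_remd(pair$apo, 1:12,
                    mc_schedule(n_attempts = 5e4, seed = 42, thin = 10))
pka_table(demultiplex(res$ledger))
#> Hill-fit microscopic pKa values
#>   Asp106      3.97 +/- 0.01 (1.00)
#>   Asp138      6.29 +/- 0.01 (1.04)
#>   Asp223      5.19 +/- 0.01 (0.95)
#>   Asp228      4.60 +/- 0.01 (0.66)
#>   Asp32       4.65 +/- 0.01 (0.64)
#>   Glu116      7.18 +/- 0.01 (0.99)
#>   Glu265      4.38 +/- 0.01 (0.98)
#>   Glu339      6.58 +/- 0.01 (1.00)
#>   His45       5.59 +/- 0.01 (0.95)
#>   Tyr71       9.62 +/- 0.01 (1.01)
```

Each row is `pKa ± se (Hill n)`. Uncoupled peripheral sites sit at their
(shifted) reference midpoints with `n ≈ 1`; the dyad titrates
anticooperatively (`n ≈ 0.65`, broadened by the +2 pK-unit double-protonation
penalty). In the holo model the dyad's apparent pKa moves to ≈ 9.2 — a
binding-induced shift of ≈ +4.5 pK units — which makes binding
proton-linked.

Turn titration into a pH-dependent binding free energy profile, anchored at
a reference affinity of −9.1 kcal/mol measured at pH 4.5 (exact enumeration
curves on a 0.1-unit grid):

```r
grid <- seq(1, 12, 0.1)
dz <- delta_z(charge_curve(exact_titration_curves(pair$holo, grid), "holo"),
              charge_curve(exact_titration_curves(pair$apo,  grid), "apo"))
prof <- integrate_profile(dz, dg_ref = -9.1, ph_ref = 4.5)
prof[prof$pH %in% c(4.5, 7, 10), ]
#>    pH    deltaZ       dG
#>   4.5 0.9281241 -9.10000
#>   7.0 1.8617693 -3.70045
#>  10.0 0.7403709  1.50957
```

The complex binds protons more tightly than the free protein (`deltaZ > 0`),
so binding weakens as pH rises: by +5.4 kcal/mol from pH 4.5 to 7 and
+10.6 kcal/mol to pH 10. `wyman_residuals(prof)` confirms the profile obeys
the linkage slope identity to 6e-7 kcal/mol per pH unit.

The fixed-protonation error scenario — dyad forced protonated in both
species, as a conventional fixed-state calculation would assume:

```r
sc <- fixed_state_profile(exact_titration_curves(pair$apo, grid),
                          exact_titration_curves(pair$holo, grid),
                          c(Asp32 = "protonated", Asp228 = "protonated"),
                          dg_ref = -9.1, ph_ref = 4.5)
#> fixed-dyad profile at pH 10: -9.10 ; full: 1.51 ; deviation: -10.61
```

The fixed-state profile stays flat at the reference value while the true
profile rises, i.e. the conventional assumption overestimates binding
affinity by ~10.6 kcal/mol at pH 10.

A command-line wrapper with subcommands `preset`, `simulate`, `demux`,
`fit`, `dg`, `scenario` and `oracle` is installed at
`inst/cli/phlinkage`; every command writes a JSON run log alongside its
output.

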