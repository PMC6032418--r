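# predist

Proton-heme iron distances from NMR paramagnetic relaxation enhancement.

## The problem

Where does a substrate sit in a cytochrome P450 active site? The ferric
heme iron is paramagnetic, and a substrate proton near it relaxes faster
in proportion to r^-6. For a substrate in fast exchange with a dilute
enzyme, the enhancement is measurable on the bulk ligand signal, so
per-proton longitudinal relaxation times (T1) plus a handful of
spectroscopic constants yield per-proton distances to the iron — enough
to orient the substrate and rationalize regioselectivity. `predist`
implements the full workflow for structural biologists and enzymologists
working with P450s (or any heme protein with a diamagnetic reference
state):

1. **T1 estimation** from inversion-recovery series:
   `H(d2) = Hinf (1 - 2B exp(-d2/T1))`, bounded nonlinear least squares.
2. **Spectral binding**: Ks from the type I difference titration,
   `dA = Bmax [S]/(Ks + [S])`, and difference-spectrum classification.
3. **Spin state**: three-Gaussian Soret deconvolution (delta, high-spin,
   low-spin bands) giving f_HS, f_LS and the effective spin factor
   `S(S+1) = 8.75 f_HS + 0.75 f_LS`.
4. **Distance**: with T1P from the ferric/ferrous-CO rate difference
   `1/T1P = 1/T1,Fe3+ - 1/T1,Fe2+-CO`, the bound fraction
   `alpha_m = [P450]/(Ks + [S])` and the correlation time tau_c,

   r = [9.78e16 · T1P · alpha_m · S(S+1) · tau_c]^(1/6)  (Å),

   with first-order error propagation from the T1 fits, plus the
   fast-exchange temperature diagnostic (1/T1P vs 1/T must have positive
   slope, R² ≥ 0.95).

Synthetic-data generators (`sim_*`) produce every input modality with
known ground truth for validation, and a complete measured case study —
phenacetin bound to CYP1A2 wild type and the N312L, L382V and
L382V/N312L mutants — ships with the package.

## Worked example

```r
library(predist)

report <- run_study(cyp1a2_phenacetin_study())
compare_site_of_metabolism(report, "-OCH2-")$ranking
#>               enzyme      r_A    r_se_A
#> 2       CYP1A2 L382V 5.931854 0.1814628
#> 4 CYP1A2 L382V/N312L 5.969007 0.2013348
#> 1          CYP1A2 WT 6.562811 0.8268911
#> 3       CYP1A2 N312L 7.866836 1.0614561
```

The ranked proton is phenacetin's -OCH2- group — the site of metabolism,
whose hydrogen is abstracted during O-deethylation. The L382V mutation
pulls that proton ~0.6 Å closer to the iron than in the wild type, while
N312L pushes it ~1.3 Å further away: the distances order
L382V < L382V/N312L < WT < N312L, matching the mutants' catalytic
behavior. Each distance comes from one ferric/ferrous-CO T1 pair; its
standard error reflects the T1 fit errors propagated through the
sixth-root chain (large where the two T1 values nearly coincide, as for
the N312L column).

Single-stage functions work standalone:

```r
fit_inversion_recovery(d2, heights)      # -> T1 ± SE
fit_binding_isotherm(conc_uM, delta_A)   # -> Ks, Bmax ± SE
fit_soret_bands(wavelength_nm, A)        # -> f_HS / f_LS
fast_exchange_check(temps_K, t1p_s)      # -> slope, R², pass/fail
```

A thin CLI over the same functions lives at `inst/scripts/predist`
(subcommands `pipeline`, `fit-t1`, `fit-ks`, `spin`, `distance`,
`check-exchange`, `simulate`).

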