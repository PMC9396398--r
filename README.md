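# ankgroove

Tools for analysing how ankyrin (ANK) tandem-repeat proteins recognise short
peptides in the concave "inner groove" of their repeat solenoid — the binding
mode that anchors membrane proteins such as neurofascin to the ankyrin-G
scaffold at the axon initial segment — and for quantifying the binding by
isothermal titration calorimetry (ITC).

The package covers three connected analyses:

1. **Interface characterisation** of an ANK-repeat/peptide complex:
   solvent-accessible surface area (SASA) by Shrake–Rupley sphere sampling on
   a deterministic Fibonacci lattice; buried surface area
   `BSA(X) = SASA(X alone) − SASA(X in complex)` per component, with
   `interface area = (BSA_a + BSA_b)/2`; geometric hydrogen-bond detection
   (donor–acceptor ≤ 3.5 Å, angle criterion with or without explicit
   hydrogens); hydrophobic residue–residue contacts (apolar heavy atoms
   within 4.5 Å).
2. **Inner-groove layer statistics.** Each ~33-residue ANK repeat contributes
   four inner-groove positions: two hydrophobic layers (Φ1 at the hairpin
   tip, offset 0 from the frame origin; Φ2 on the αA belly, offset +5) and
   two polar layers (ρ2 at the αA bottom, offset +8; ρ1 on the inter-repeat
   loop, offset +31). The package derives these offsets from observed residue
   series, extracts layer residues from sequences or structures, and compares
   the fraction of hydrophobic residues at Φ1/Φ2 (and polar at ρ1/ρ2) between
   a cohort of target-binding repeats, all ANK repeats, and whole-proteome
   natural abundance, with a one-sided exact binomial enrichment test
   `P(X ≥ k | n, p0)`.
3. **One-site ITC binding.** Forward model (Wiseman isotherm): after each
   injection the cell totals are perfusion-corrected, the 1:1 mass-action
   equilibrium is solved in closed form, and the injection heat is
   `Q_i − Q_{i−1} + (v_i/V0)(Q_i + Q_{i−1})/2 + baseline`. Simulation adds
   iid Gaussian noise; fitting is nonlinear least squares over
   `(n, log Ka, ΔH, baseline)` with curvature-based standard errors, a
   Wiseman `c = n·Ka·[cell]` confidence flag, and `Kd` fold-change helpers
   for variant comparisons.

A `synthetic_data` layer generates every fixture with known ground truth:
repeat sequences with controlled per-layer class probabilities, minimal
two-residue geometry fixtures realising exact H-bond/contact geometries, and
two-sphere SASA fixtures with the analytic spherical-cap reference areas.

## Worked example

```r
library(ankgroove)

# layer offsets recovered from the observed AnkG residue series
derive_layer_offsets(list(
  phi1 = c(277, 310, 343, 376, 409, 442),
  phi2 = c(282, 315, 348, 381, 414, 447),
  rho2 = c(318, 351, 384),
  rho1 = c(308, 341, 374)))
#> period 33, offsets phi1 0, phi2 +5, rho2 +8, rho1 +31

# simulate a wild-type titration and fit it back
proto <- itc_protocol()                     # 20 uM cell, 200 uM syringe, 27 x 10 ul
gen   <- one_site_params(n = 1, Kd = 0.22e-6, dH = -8000)
fit   <- fit_one_site(simulate_titration(gen, proto, noise_sd = 0.2, seed = 3))
fit
#> <one_site_fit> n=1.000  Kd=2.14e-07 M (+/- 1.3e-08)  dH=-7969 cal/mol  c=93.6
fold_change(1.2e-6, 0.29e-6)
#> [1] 4.137931
```

The fitted `Kd` of 0.214 µM recovers the generating 0.22 µM within the noise
of a single titration; `c = 94` sits comfortably in the fittable 1–1000
window. The fold-change of 4.1 is the affinity ratio of two repeat
truncations (1.2 µM vs 0.29 µM): values above 1 mean weakened binding.

A command-line front end is installed as `exec/ankgroove`:

```sh
ankgroove itc simulate --kd-um 0.22 --seed 3 --out sim.csv
ankgroove itc fit sim.csv --cell-um 20 --syringe-um 200 --out fit.json
ankgroove interface --structure complex.pdb --chain-a A --chain-b B --out report.json
ankgroove simulate-data repeats --seed 1 --out fixtures/
```

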