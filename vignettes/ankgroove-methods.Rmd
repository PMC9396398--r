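---
title: "Methods: inner-groove interface analysis, layer statistics and one-site ITC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inner-groove interface analysis, layer statistics and one-site ITC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ankgroove)
```

# Scope and model

Ankyrin (ANK) tandem repeats stack into a solenoid whose concave inner
groove binds short, extended peptides. Three quantitative questions arise
for any such complex: how large and what kind of interface is formed; which
repeat positions carry the recognition chemistry; and how strongly the
peptide binds. This package answers each with a small, testable model, and
pairs every analysis with a synthetic generator whose ground truth is known
exactly.

# Solvent-accessible and buried surface area

SASA is computed in the Shrake–Rupley manner: each atom's accessible sphere
(van der Waals radius + probe radius, default probe 1.4 Å for water) is
sampled at `n_points` quasi-uniform directions and a sample point is buried
when it falls strictly inside a neighbour's accessible sphere. Two choices
matter:

* **Deterministic point set.** A Fibonacci lattice replaces random sphere
  sampling, so results are exactly reproducible and the accuracy knob is a
  single integer. At the default 960 points the total SASA of two-sphere
  fixtures agrees with the closed-form spherical-cap solution to better
  than 1%, and refining to 4000 points moves totals by less than 1%.
* **Radii table.** A single configurable table (C 1.70, N 1.55, O 1.52,
  S 1.80 Å) keeps areas comparable to PISA-style calculations. Unknown
  elements fall back to 1.70 Å with a warning.

Buried surface area of a two-component complex is defined per component as
`SASA(component alone) − SASA(component in complex)`; `bsa_total` sums both
sides and `interface_area = bsa_total / 2` is the interface-area convention
used by PISA. Published "total interface" figures are sometimes one and
sometimes the other, so both are always reported; the ~989 Å² acceptance
check targets `bsa_total` with ±10% tolerance and records `interface_area`
alongside. Crystallographic waters are excluded by default (the original
area computation does not state whether they were included; excluding them
is the reproducible choice). Alternate conformations keep the
highest-occupancy copy; missing terminal repeats are simply absent — nothing
is rebuilt.

# Hydrogen bonds and hydrophobic contacts

No bonding criteria are stated alongside published interface inventories,
so standard geometric criteria are used and are configurable:

* donor–acceptor heavy-atom distance ≤ 3.5 Å;
* without explicit hydrogens (the usual case for crystal structures), the
  antecedent–donor–acceptor angle must be ≥ 90°, where the antecedent is
  the nearest covalently bonded heavy atom of the donor;
* with hydrogens, the D–H···A angle must be ≥ 120°.

Donor/acceptor typing follows protein chemistry (backbone N donates except
proline; backbone O accepts; Arg/Lys/Trp side chains donate; Asp/Glu accept;
His, hydroxyls and thiols appear on both sides). The detector is validated
against an exhaustive, independently coded all-pairs scan on randomized toy
structures.

Hydrophobic contacts are residue pairs whose apolar heavy atoms (carbons;
Met/Cys sulfur optional, off by default) approach within 4.5 Å. This is a
deliberately simple, transparent criterion: it recovers pocket assignments
of the form "an aromatic side chain inserted into a three-residue groove"
without any energy model.

# Repeat frames and the four inner-groove layers

A repeat frame is `(start, period)` with the origin anchored at the Φ1
hairpin position. Anchoring at Φ1 (rather than the TPLH motif) was chosen
because published inner-groove residue series are arithmetic in Φ1 — a
constant shift converts to any other convention. The default period of 33
residues is not an assumption: `derive_layer_offsets()` recovers it as the
GCD of spacings within each layer's observed residue series, and derives
the offsets Φ1 0, Φ2 +5, ρ2 +8, ρ1 +31 from the same input. Note the ρ2
series (offset +8) phases with the *following* frame origin relative to the
ρ1 series (+31) — extraction code treats each frame independently, so a
frame's ρ1 residue has a larger residue number than its ρ2 residue minus
one period. Truncated terminal repeats yield `NA` at missing positions,
never a guess.

`motif_scan` is self-consistent: it chooses the tiling phase maximising
identity between consecutive period-length windows, breaking ties toward
the smallest phase. It is intended for synthetic and near-perfect repeats;
profile-based de novo repeat detection is out of scope.

# Residue-class preference statistic

The class scheme is fixed by the analysis being reproduced: hydrophobic
A/C/F/I/L/M/V/W/Y and polar D/E/H/K/N/Q/R/S/T, leaving G and P in neither
class. Cys and Tyr are hydrophobic *in this scheme* even though other
schemes call them polar; the printed sets are authoritative and are the
defaults verbatim. The statistic is the in-class fraction k/n at a layer
position over a cohort of assignments, compared against (i) all ANK repeats
and (ii) residue-weighted whole-proteome abundance. The package adds a
one-sided exact binomial tail `P(X ≥ k | n, p0)` as an enrichment measure —
the visual comparison in the original analysis carries no test, so this is
package-added inference, clearly separated from reproduction targets.

The target-binding cohort (ankyrins R/B/G, KANK1/2, Espin and Espin-like)
is user-supplied as FASTA plus frame annotations: the original analysis
does not enumerate which repeats of each protein were counted, so shipping
a hard-coded cohort would be silent guessing. The package ships only the
structurally grounded AnkG R8–R13 frames as a built-in.

# One-site ITC model

The forward model follows the standard perfusion-cell treatment. With cell
volume $V_0$ and injection volumes $v_i$, the cell totals after injection
$i$ are diluted by $(1 - v_i/V_0)$ and gain titrant $v_i/V_0 \cdot X_s$.
Bound complex comes from the physically meaningful root of the 1:1
mass-action quadratic with site concentration $n M_t$:
$C = \tfrac{1}{2}\big(S + X + K_d - \sqrt{(S + X + K_d)^2 - 4SX}\big)$,
clamped to $[0, \min(S, X)]$. The heat content is $Q_i = V_0\,\Delta H\,C_i$
and the observed injection heat is
$\Delta Q_i = Q_i - Q_{i-1} + \frac{v_i}{V_0}\frac{Q_i + Q_{i-1}}{2} +
\text{baseline}$, in µcal. The displacement term accounts for heat carried
out by overflowed liquid; because free binder perfused out before it binds
is genuinely lost, the idealised sum rule
$\sum \Delta Q \to n\,\Delta H\,(\text{binder moles})$ holds exactly only
as $v_i/V_0 \to 0$, and the test suite checks it in that limit.

Defaults encode the protocol being emulated: 20 µM binder in the cell,
200 µM titrant, 27 × 10 µl injections (reaching molar ratio ≈ 2.7 at the
10:1 concentration ratio; the injection count is not printed in the source
protocol and 27 is the package's choice), 180 s spacing, 25 °C, and a
1.43 ml working volume typical of the named instrument (also not printed;
configurable). First-injection discard is available but off by default.

Fitting minimises squared residuals over $(n, \log K_a, \Delta H,
\text{baseline})$ — log-affinity for conditioning — using Nelder–Mead
polishing into BFGS with parameter scaling tied to the data scale (this
makes the fit invariant to µcal/cal rescaling). Standard errors come from
the Gauss–Newton covariance $2 s^2 H^{-1}$ with $H$ the numerical Hessian
of the sum of squares. Initialisation: $n = 1$, $\Delta H$ from the
first-injection heat against the late-injection baseline, $K_d$ from a
molar-ratio midpoint heuristic. Fits with Wiseman $c = n K_a M_0$ outside
[1, 1000] are flagged low-confidence rather than rejected.

Simulated titrations add iid Gaussian heat noise (default 0.2 µcal, a
realistic per-injection integration noise for the instrument class) and are
reproducible per seed. Across the grid $K_d \in \{0.1, 0.3, 1, 3\}$ µM
under the default protocol, the median $|\log(\hat{K_d}/K_d)|$ stays below
0.1 — the basis for the 15% recovery acceptance band at the wild-type
affinity.

# What the synthetic generators do and do not establish

* `make_repeat_sequences()` draws layer residues in-class with a specified
  probability, uniformly *within* the class set (no proteome frequency
  weighting), and uniformly over the 20 amino acids elsewhere; with
  probability 0 it draws strictly from the class complement. Expected layer
  fractions are therefore analytic, which is the point: a green
  round-trip/convergence test establishes that extraction and counting are
  correct, not that real ANK repeats behave like the generator.
* `make_geometry_fixture()` builds minimal two-residue structures with
  idealized bond lengths (N–H 1.0 Å, C=O 1.23 Å, C–N 1.47 Å) where only
  the inter-component geometry is controlled. It validates detector
  criteria, not force-field realism.
* `make_two_sphere_fixture()` pairs coordinates with the closed-form
  two-sphere cap areas; at zero centre distance with equal radii the
  documented convention is the limiting split (each sphere exposes half its
  area), which differs from the strict-inequality sampling answer exactly
  at that measure-zero configuration.

# Numerical choices and degenerate inputs

* SASA point-in-sphere tests use a 1e-12 slack so exactly tangent spheres
  do not bury points.
* The mass-action discriminant is clamped at zero with a relative guard;
  a genuinely negative discriminant raises an error rather than returning
  a complex root.
* `fit_one_site()` refuses fewer than 6 injections, and non-convergence
  raises a condition carrying the best iterate and residual sum so callers
  can inspect rather than silently trust.
* `derive_layer_offsets()` rejects residue series that are not
  phase-consistent modulo the derived period, naming the offending layer.

# Known limitations

* The mmCIF reader handles the `atom_site` loop (the coordinate payload)
  only; header categories are ignored.
* No electrostatics, ΔG estimation, two-site or competitive binding
  models, baseline drift, or raw thermogram integration.
* Offline environments cannot run the deposited-structure and proteome
  acceptance checks; those tests state this explicitly when they fail
  rather than skipping.
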