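---
title: "Electrostatic interaction mapping and redox analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrostatic interaction mapping and redox analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Multiheme redox enzymes such as anammox hydroxylamine oxidase (HAO) must
pass electrons to small, diffusible single-heme cytochromes. These
encounters are transient: there is no stable complex to crystallize, and
two candidate partner cytochromes can be nearly identical in fold and in
midpoint potential while differing enormously in their competence as
electron acceptors. The working hypothesis this package operationalizes is
electrostatic pre-orientation: a charged patch around the enzyme's electron
outlet (a surface-exposed heme) selects partners whose own heme-access
surface carries the complementary charge. The package provides the three
quantitative legs of that argument — Boltzmann-weighted rigid-body sampling
of the encounter, spectroelectrochemical midpoint determination, and
steady-state kinetics — together with synthetic-data generators so each leg
is testable with known ground truth.

## The electrostatic model

The native field solver is a uniform-dielectric screened-Coulomb
(linearized Debye–Hückel) sum,

$$\varphi(\mathbf{x}) \;=\; l_B(T,\varepsilon_r)\,\sum_i
  \frac{q_i\,e^{-\kappa r_i}}{r_i} \qquad [k_BT/e],$$

with $l_B$ the Bjerrum length (≈ 7.1 Å in water at 300 K,
$\varepsilon_r = 78.5$) and $\kappa$ from the buffer ionic strength. This
is deliberately simpler than a two-dielectric Poisson–Boltzmann solver: it
is analytically checkable (superposition holds exactly; the κ = 0,
$\varepsilon_r$ = 1 limit is plain Coulomb), dependency-free, and preserves
the sign-and-shape contrasts on which the specificity argument rests.
Where full PB accuracy matters, externally computed grids are imported as
OpenDX files (`read_dx()`) and used interchangeably downstream — the Monte
Carlo engine only ever sees a grid.

Parameters and defaults:

* **Buffer**: 20 mM potassium phosphate, pH 7.0. Speciation uses
  Henderson–Hasselbalch with pK\_a2 = 7.20 (first and third pKa are
  irrelevant near pH 7), and potassium counterions complete the mixture to
  electroneutrality, giving I = 0.0355 M and a Debye length of 16.2 Å at
  300 K. This is the assay buffer, so mapping and kinetics see the same
  screening environment.
* **Temperature**: 300 K for field units and sampling (matching the Monte
  Carlo protocol). The Nernst fits use their own 293 K (the
  spectroelectrochemical cell temperature); the two never mix.
* **Grid**: spacing 1 Å with 20 Å padding by default; the mapping analyses
  use 2 Å spacing on a fixed box enclosing the sampling ball. Grid nodes
  closer to an atom than half a spacing are clamped and counted
  (`n_clamped`), since the point-charge potential diverges there; the
  clamp only affects the immediate interior of atoms, which the hard-core
  term excludes from sampling anyway.
* **Interpolation error**: trilinear interpolation is exact at nodes and
  for linear fields; `grid_error_bound()` gives a conservative per-point
  bound from the second radial derivative of the screened kernel at the
  cell's nearest approach to each atom. The tests require grid/direct-sum
  agreement within this bound, so the documented bound *is* the contract.

## Charge assignment

Instead of per-site pKa prediction, side chains carry pH-7 formal charges
(Asp/Glu −1 split over the carboxylate oxygens, Lys +1 on NZ, Arg +1 split
over NH1/NH2, His 0, free termini ±1). The table is united-atom tolerant:
when the canonical charged atoms are absent (coarse bead models), the
residue's formal charge falls on its first atom. This is deterministic and
idempotent — reassignment always starts from zeroed charges. For full
PDB2PQR/PROPKA fidelity, PQR import carries externally assigned charges
and radii unchanged.

c-type hemes: propionate carboxylate oxygens take −0.5 each; the
redox-dependent elementary charge sits entirely on the iron (+1 ferric, 0
ferrous). Published per-atom heme charge sets exist but the distribution
choice is immaterial beyond a few Å — what the mapping sees is the net
1 e difference between states, which this rule makes exact by
construction. The placement is configurable (`fe_charge`), and
`apply_redox_state()` switches states on generator-built models without
touching their other charges.

## The Monte Carlo engine

A rigid ligand (its own internal energy ignored) moves in the receptor
field; the receptor is fixed. The interaction energy of a pose
$(\mathbf{t}, q)$ is $E = \sum_j q_j\,\varphi(R\,\mathbf{x}_j +
\mathbf{t})$ in $k_BT$, with a hard-core sentinel: any ligand/receptor
heavy-atom pair closer than $0.8\,(r_i + r_j)$ makes $E = +\infty$.
Proposals are Gaussian translations (σ = 2 Å) composed with small-angle
rotations about a uniform random axis (σ = 0.2 rad); proposals whose
centre of mass leaves the `d_max` ball are rejected outright (rejection,
not reflection); otherwise the Metropolis rule applies. Each run starts
from a uniformly random, clash-free pose in the ball with a uniform random
orientation, discards a 20 % burn-in, and records every 50th pose.

Move sizes, burn-in, recording interval and the clash factor are not part
of the reference protocol and are package choices, picked once for 30–60 %
acceptance on the coarse synthetic systems and documented here; all are
configurable through `mc_config()`.

**Reproducibility.** The engine uses its own splitmix64 RNG with one
per-run stream derived from the master seed and the run index, so
ensembles are bit-reproducible across platforms and runs are
order-independent by construction. R's RNG is used only by the
single-step `metropolis_step()`/`metropolis_accept()` helpers and the data
generators.

**Problem sizes.** The reference protocol is 10⁶ runs × 25 000 steps with
d\_max = 500 Å. The package's desk-scale default is 400 runs × 25 000
steps with d\_max = 100 Å for the synthetic system (the toy
receptor–ligand contact distance is ~33 Å, about a fifth of the real
system's, and the box scales with it). The per-run chain length is kept at
the reference 25 000 deliberately: equilibration within the sampling ball
depends on chain length, not on the number of independent runs, and
5 000-step chains measurably under-equilibrate at this d\_max — many
never encounter the receptor, which dilutes the patch-hemisphere
pose-density enrichment from ~45-fold to ~3-fold. Scaling down the *run
count* preserves the physics and only widens the statistical error bars.
The redox-variant screen uses 150 runs per variant, and variant fields are
built by superposition (base field plus unit fields of the heme irons),
which is exact for a linear solver.

## Interface extraction

"Preferred poses" are not quantified in the reference protocol; the
package offers two selection rules — bottom fraction by energy
(`lowest_energy`, default fraction 0.1) and most-occupied voxels
(`densest_voxels`) — and the synthetic tests require both to agree on the
patch. A receptor residue is a contact when any heavy atom lies within
5 Å of any transformed ligand heavy atom; frequencies are fractions of
analysed poses. Cofactors are reported separately with minimum approach
distance, and `cofactor_in_interface()` applies a 0.25 frequency
threshold. Cutoff, fraction and threshold are conventional values,
configurable everywhere. Residue charge classes follow the standard
four-way partition (Asp/Glu negative; Lys/Arg/His positive;
Ser/Thr/Asn/Gln/Tyr neutral; the rest hydrophobic); unknown codes classify
as neutral with a warning.

## Nernst fitting

The titration model is the one-electron Nernstian sigmoid in the direction
where the reduced species absorbs more at the Soret band:

$$A(E) = A_{ox} + \frac{a}{1 + \exp\!\big(nF(E - E_m)/RT\big)},$$

with F = 96 485.34 J V⁻¹ mol⁻¹, R = 8.3145 J mol⁻¹ K⁻¹, T = 293 K, n = 1
fixed. The algebraic form is reconstructed from the symbol definitions of
the source protocol (whose equation is only available as a figure); the
reconstruction is pinned by its stated limits — A → A_ox fully oxidized,
amplitude a, midpoint at E_m — and by the 10–90 % transition width
2 ln(9) RT/nF ≈ 110.9 mV, which the tests assert.

Limbs are normalized individually before joint fitting to remove
hysteresis (each limb rescaled affinely so its plateaus map to [0, 1]).
Two plateau estimators are provided: `fitted` (default; per-limb Nernst
fit, then (A − A_ox)/a) and `observed` (mean of the 3 most
extreme-potential points). Fitted plateaus are the default because a
±300 mV window does not reach the oxidized plateau when E_m ≈ +270 mV —
at +300 mV the sigmoid is still ~20 % from its asymptote — which biases
observed-extremes normalization; the fitted estimator stays unbiased
there. Since the joint fit retains free offset and amplitude, any affine
normalization leaves the fitted E_m invariant (a property the tests
check), so the choice affects robustness, not correctness. The joint fit
shares E_m, offset and amplitude across limbs and experiments and runs on
Levenberg–Marquardt (`minpack.lm::nls.lm`), which converges cleanly even
on zero-residual synthetic data.

## Kinetics

Initial rates come from a linear fit over the early progress curve; the
default window is the first 20 s or the first 10 % of substrate
consumption, whichever ends first. The 550 nm slope divided by Δε₅₅₀
(19.1 mM⁻¹ cm⁻¹ for the competent cytochrome construct, 19.6 for bovine
cytochrome c) gives the cytochrome-reduction rate; division by the
3-electron stoichiometry of NH₂OH → NO converts to substrate units
(configurable — the source protocol does not spell this division out, and
the kcat/Km consistency checks are unit-free either way); volume and
enzyme mass give the specific rate. Michaelis–Menten fits run on
replicate-averaged rates (technical triplicates). Derived constants use
k\_cat = V\_max · 10⁻³ · M / 60 with M the molar mass of the catalytic
unit (the HAO trimer). M is a required user input; the analyses use
1.84 × 10⁵ g/mol, the value implied by the printed (V_max, k_cat) pair,
and the unit algebra is itself asserted by that back-solve in the tests.

## What the synthetic generators emulate — and what they do not

`make_patch_receptor()` builds a 25 Å, ~400-bead Fibonacci sphere with a
30° cap of +0.5 e beads (≈ +13 e total, emulating the pronounced positive
charge of the enzyme's predicted interaction surface), an in-patch
"heme3" site 1 Å below the surface and an antipodal "heme1".
`make_ring_ligand()` builds an 8 Å, ~60-bead sphere with a 12-bead
equatorial ring at ±0.5 e (net ∓6 e) around a central heme — the
negative version emulates the competent partner's ring of acidic residues
around its heme, the positive version its incompetent paralog; the two are
bit-identical in geometry, so any behavioural difference is purely
electrostatic. Scales were chosen once: large enough for distinct
hemispheres and a genuine patch/antipode contrast, small enough for
minutes-scale sampling. All noise in the titration and rate generators is
Gaussian (homoscedastic), with limb hysteresis as an affine distortion of
the oxidative limb.

What passing these tests shows: the sampling machinery is Boltzmann-exact,
the field is right, and sign-complementarity alone reproduces the
partner-specificity phenotype on a system where that is the only
difference. What it does not show: behaviour on real coordinates — the
actual proteins' surfaces mix charge with topology (a concave interface
between protrusions), the coordinates are not bundled here, and shape
complementarity, desolvation and van der Waals terms are outside the
model. Qualitative parity with the real interface maps is therefore the
claim; residue-level parity is not.

## Numerical choices and degenerate inputs

* Zero-residual fits: handled by using `nls.lm` directly (the `nls`-class
  wrappers fail on exact fits).
* Flat titration limbs, windows outside progress curves, negative slopes,
  fewer than 4 substrate levels, unknown cofactors, redox states naming
  absent hemes: all hard errors with specific messages.
* Grid queries outside the box: error by default; the Monte Carlo engine
  treats out-of-box ligand atoms as far field (φ = 0), which is consistent
  because the sampling ball plus ligand radius is always inside the box in
  the shipped analyses.
* Quaternions are renormalized only when they deviate from unit norm by
  more than 1e-12, so recorded poses re-evaluate to bit-identical
  energies.
* Ties in voxel occupancy rankings resolve by array order
  (deterministic).

## Known limitations

Uniform dielectric (no low-dielectric protein interior, so the native
field overestimates potentials near the surface relative to PB); rigid
bodies only; no electron-transfer rate theory (the mapping addresses
*where* partners dock, not *how fast* electrons tunnel); formal charges
only at pH 7 unless a PQR supplies better; single-E_m Nernst fits (no
multi-heme deconvolution); no substrate-inhibition or ping-pong kinetics.
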