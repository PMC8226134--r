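---
title: "Multiscale energy-entropy decomposition of solvated systems with eemcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale energy-entropy decomposition of solvated systems with eemcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eemcc)
```

## The model

`eemcc` computes the Gibbs free energy of every molecule in a solvated
simulation as G = H - TS, with both terms taken directly from trajectory
output rather than from an end-point or alchemical construction. Enthalpy is
trivial bookkeeping: the trajectory producer writes per-atom kinetic and
potential energies (multi-body terms pre-divided over the involved atoms),
and the enthalpy of any unit is the sum over its atoms, so the decomposition
is exactly additive over molecules, residues, species and hydration classes.

Entropy is the substantive part. It is summed over *cells* at nested length
scales - united atoms (a heavy atom with its bonded hydrogens), monomers
(residues, whole excipients) and polymers (whole proteins) - and over two
types per scale:

* **Vibrational entropy** measures the width of the local energy well. For
  each molecule and level, the net forces on its units are rotated into
  unit-local frames, mass-weighted (F/sqrt(m)), and accumulated into a
  3M x 3M covariance matrix; torques about each unit's centre of mass are
  likewise inertia-weighted (tau/sqrt(I)). Covariance eigenvalues map to
  quasi-harmonic frequencies nu = (1/2 pi) sqrt(lambda / kB T), and each
  frequency contributes the quantum harmonic-oscillator entropy
  kB [x/(e^x - 1) - ln(1 - e^-x)], x = h nu / kB T. In the mean-field
  approximation, polymer-level forces and torques at all levels are halved.
  At every level below a molecule's highest, the six lowest-frequency force
  modes are removed: they re-express the rigid-body translation and rotation
  already counted one level up.

* **Topographical entropy** measures the probability distribution over
  discrete wells. For dihedrals it is the Shannon entropy of joint conformer
  states: angles are binned into twelve periodic 30-degree bins, peaks are
  bins strictly taller than both circular neighbours (no two peaks closer
  than 60 degrees; the taller one survives, ties break to the lower bin
  index), every angle joins its nearest surviving peak, and the monomer's
  state in a frame is the vector of its dihedral assignments. For water it
  is orientational: each water's coordination shell is found with the
  relative-angular-distance (RAD) construction, in which a closer neighbour
  blocks a farther one whenever 1/r_j^2 < cos(theta_jik)/r_k^2; hydrogen
  bonds are assigned topologically (each donor hydrogen to the acceptor with
  the most negative q_D q_A / r^2); and per shell type c the donor and
  acceptor event fractions p(D_i), p(A_i) give the bias
  p(HB_i) = p(D_i) p(A_i) / (p(D_i) + p(A_i))^2, the shell average p(HB_av),
  the effective neighbour count N_eff = sum p(HB_i) N_i / 0.25, and
  S = kB sum_c p(c) ln[(N_eff pi)^{3/2} p(HB_av) / sigma] with sigma = 2.
  In the bulk limit (four unbiased water neighbours) this gives
  S/kB = ln[(4 pi)^{3/2}/8], about 1.717.

Hydration-shell waters are classified per frame by the solutes in their
shell (one protein WP, two proteins WPP, with excipient/counterion WEP/WEPP,
excipient-only WE, otherwise bulk), and the binding decomposition prices
each solute species X by transferring it from a dilute reference into the
mixed system: waters the mixed state no longer holds are charged at the
bulk-water free energy. Because H, TS and G flow through identical
bookkeeping, dG = dH - T dS holds row by row in every exported table, and
the bookkeeping is antisymmetric under exchanging the two states.

Trajectories produced under a well-tempered metadynamics bias are reweighted
per frame before any solvent statistic is pooled. The weight is
proportional to exp(V(s,t)/kB T) for a bias V saved as the deposited
(positive) Gaussian hill sum at the frame's collective-variable value: a
frame pushed uphill by the bias is over-represented in the biased ensemble
and must be up-weighted to recover the unbiased one. Biases saved in the
opposite convention (as a running free-energy estimate, i.e. -V) are
handled with `sign = -1` in `frame_weights()`. Weights are invariant to any
constant shift of the bias, and the rolling weighted mean equals the batch
weighted mean at the final frame. Protein statistics are left unweighted by
default: protein conformations are not the biased coordinate, and weighting
them only adds variance. A switch (`weight_protein`) exposes full
weighting.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `T` | 298 | K | temperature for kB T, oscillator entropy and weights |
| `cutoff` | 8 | Angstrom | candidate cutoff for shell construction (the usual non-bonded truncation); the shell itself is parameter-free |
| `d0`, `r0` | - | Angstrom | switching-function contact band for collective-variable style counts (5 to 6.5 in the reference protocol); used only to reproduce CVs, never for thermodynamics |
| `sigma` (water) | 2 | - | rotational symmetry number |
| `gamma`, `W0`, `sigma`, `stride` | 20, 1.5 kJ/mol, 0.2, 500 | - | toy well-tempered sampler: bias factor, initial hill height, hill width, deposition interval, following the reference simulation protocol |
| `weight_protein` | FALSE | - | apply frame weights to protein statistics |

Units are fixed package-wide: Angstrom, kJ/mol, amu, entropies in J/K/mol,
reported T dS in kJ/mol at 298 K. Conversions happen only in the readers
(`scales` argument of `read_frames()`).

## Numerical choices

* **Reference frames.** United-atom and larger units use instantaneous
  principal axes of inertia, each axis sign-fixed so its largest-magnitude
  component is positive. Any consistent body frame preserves the
  eigenvalues of a well-sampled covariance; the sign fix only prevents
  frame-to-frame axis flips from corrupting accumulation. Monatomic units
  use the laboratory frame.
* **Rotational mode counting.** 3 modes for nonlinear units, 2 for linear
  (the zero-moment axis carries no torque), 0 for monatomic. Getting the
  axis/moment pairing right matters: the two retained torque components of
  a linear unit must be the ones with non-zero moments.
* **Negative eigenvalues** within a relative 1e-8 of the spectral radius are
  clamped to zero (finite-sampling noise); anything more negative is a hard
  error. Zero frequencies surviving mode removal contribute zero entropy
  with a warning - they signal either an unsampled direction or a covariance
  estimated from fewer frames than dimensions.
* **Mode removal** applies to the translational (force) spectrum only. The
  torque spectrum is left intact; the six removed force modes are the
  rigid-body content by construction.
* **Flat dihedral histograms** (no bin taller than both neighbours) collapse
  to a single conformer with zero entropy and a warning - the conservative
  reading of the peak rule.
* **Degenerate shell types** with N_eff p(HB_av) = 0 cannot enter the
  logarithm; they are dropped and p(c) renormalised, with the count kept in
  the result's diagnostics.
* **Shell-type key.** Orientational statistics pool waters by the sorted
  multiset of neighbour species labels, neighbour waters being labelled by
  the solute whose shell they occupy (nearest wins) and "bulk" otherwise.
* **Exponent grouping.** The orientational prefactor is (N_eff pi)^{3/2} by
  default; the alternative reading N_eff^{3/2} pi^{1/2} differs by a
  constant per shell type and is selectable (`exponent` argument) - the
  choice must be pinned before comparing absolute entropies.
* **Export rounding.** Tables are printed at whole kJ/mol. The exporter
  checks the exact identity first and then allows the rounded component sum
  to differ from the rounded total by at most half a unit per row - printed
  tables of ten components can legitimately drift by a few units even when
  the underlying sums are exact.

## The synthetic generators

Every statistical structure the analysis assumes has a generator with a
closed-form expectation, so the pipeline validates without simulation data:

* `gen_harmonic_ensemble()` draws positions, forces and energies from the
  exact Boltzmann distribution of an isotropic harmonic well; force variance
  k kB T per axis, analytic frequency (1/2 pi) sqrt(k/m). Defaults (k = 500
  kJ/mol/Angstrom^2, m = 16 amu) put h nu / kB T near 1.4, mid-range for the
  oscillator entropy.
* `gen_dihedral_series()` draws wrapped-normal peaks with prescribed
  populations; the recovered entropy converges to -kB sum p ln p with
  multinomial error.
* `gen_water_shells()` emits event-level shell observations with prescribed
  donor/acceptor categorical probabilities; recovered p(D_i), p(A_i) match
  within binomial error and N_eff follows its closed form on the inputs.
* `toy_wtmtd()` integrates overdamped Langevin dynamics on an analytic 1-D
  potential with well-tempered hill deposition (height decay
  W0 exp(-V/kB DeltaT), DeltaT = (gamma - 1) T), returning the exact
  instantaneous bias per frame. Overdamped dynamics was chosen over a
  velocity integrator because it gives exact stationary-distribution control
  with one parameter; the bias equations constrain the hills, not the
  integrator. The converged bias estimates the free energy as
  -gamma/(gamma-1) V(s), and on a double well with 2 kB T asymmetry both the
  read-back well difference (within 1 kB T) and the reweighted state
  populations (within 3 sigma of long unbiased reference) are validated.
* `gen_solvated_box()` assembles a miniature mixed system - model proteins
  with amide-like donors, carbonyl-like acceptors and one registered
  backbone dihedral per residue, polyanions, buffers, counterions and
  three-site waters - with harmonic jitter, per-frame dihedral resampling
  and per-frame water reorientation, in the package's own file dialects.
  Defaults mirror the study composition (two proteins, five polyanions with
  formal charges -4, -5, -5, -5, -5, three buffers) with solvent scaled to
  desk size (60 waters, 100 frames); the frame count is kept above three
  times the largest per-level unit count so covariances are full rank.

What the generators do **not** emulate: real water geometry and hydrogen-bond
cooperativity, force-field energetics (jitter energies are decoupled from
the dihedral and orientational moves), protein secondary structure, and
sampling correlation structure of real MD. Passing tests therefore
demonstrate that the estimators recover known statistical structure and that
the bookkeeping is exact - not that desk-scale runs reproduce
production-scale thermodynamics, which require hundreds of nanoseconds of
all-atom sampling.

## Design decisions taken where the method description is open

* **Shell-construction variant.** The unnormalised, distance-sorted blocking
  test is pinned (block if 1/r_j^2 < cos(theta)/r_k^2 for any closer
  candidate k), validated against a brute-force oracle; the relation is
  deliberately not symmetrised.
* **Category precedence.** WEP/WEPP take precedence over WP/WPP whenever any
  excipient or counterion is present, and buffer molecules count as
  excipient/counterion. Neighbour waters never trigger a solute category.
  The water-environment export totals the four protein-involving categories;
  a WE column is optional (`include_we`).
* **Reweighting sign.** The deposited-hill convention (weight
  exp(+V/kB T)) is the default because it is the one under which biased
  sampling provably reweights to the unbiased ensemble - the package's own
  double-well recovery test is the evidence; the opposite sign is exposed
  for biases saved as free-energy estimates. No time-dependent offset
  (c(t)) is applied; it cancels in all normalised averages over a common
  frame set.
* **Torque modes are never removed** - the six-lowest rule is applied to the
  force spectrum only, where the rigid-body content lives.
* **Hydration rows** use nearest-solute assignment (a water in several
  solute shells counts toward the nearest), so each water contributes to
  exactly one species row per frame and the rows add up.
* **Per-water entropy resolution.** Within one ensemble, the water rows of
  the binding table share the pooled orientational and vibrational entropy
  per water; only their enthalpy and counts are class-resolved. Entropy
  differences between hydration classes enter through the difference
  between ensembles. Class-resolved orientational pooling is a known
  refinement left out of scope.

## Problem sizes

The shipped tests and the acceptance script use: 5000-frame harmonic
ensembles; 3000-5000-angle dihedral series; 2000-4000 shell-event
observations; 2 x 10^5-step biased and 4 x 10^5-step unbiased toy-sampler
runs (hills every 500 steps); solvated boxes of 14-60 waters over 30-100
frames; and shell-oracle sweeps over several hundred random 4-20-atom
configurations. These sizes keep every statistical check inside its quoted
error bars while the full suite runs in well under a minute per module.

## Worked example

```{r example, eval = FALSE}
cfg <- system.file("extdata", "demo_config.yaml", package = "eemcc")
res <- run_pipeline(cfg, output_dir = "demo_out")
res$binding          # binding decomposition with dG = dH - dTS row-wise
```

## Known limitations

Absolute entropies depend on sampling quality: covariances need several
times more frames than matrix dimensions, and sparse shell statistics bias
orientational entropy downward (many singleton shell types). The energy
decomposition trusts the producer's per-atom attribution, including the
long-range mesh split. Excipient orientational entropy is deliberately not
computed. Triclinic boxes are rejected; dihedral geometry assumes molecules
are kept whole across the boundary.
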