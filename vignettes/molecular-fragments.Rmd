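---
title: "Refining protein models with non-interacting molecular fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining protein models with non-interacting molecular fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragmentMD)
```

## The problem

Many functionally important protein conformations — the resting state of a
voltage-sensing domain (VSD), intermediate states of transporters — resist
direct structure determination.  What experiments often *can* deliver is a
set of sparse residue–residue constraints: an engineered Cys–Cd²⁺–Cys or
His–Zn²⁺–His metal bridge that forms only when two helices approach each
other, a stabilizing salt bridge revealed by a double mutant, or a
DEER/EPR distance distribution between two nitroxide spin-labels.

Imposing several such constraints at once in a restrained molecular
dynamics (MD) refinement runs into a practical contradiction: each
constraint requires its own mutations and chemical labels, and two
constraints may claim the same residue or occupy the same pocket.  Building
them all into one physical model produces steric clashes that have nothing
to do with the underlying biology.

`fragmentMD` implements the *non-interacting molecular fragment* scheme
that resolves this.  Each constraint is represented as a small, atomically
detailed fragment — the mutated side chains plus a bridging ion, or a
spin-label side chain — that is overlaid on the host protein:

* the fragment's backbone atoms (N, C, O, C$_\alpha$ of each patched
  residue) sit on top of the corresponding host backbone atoms, held by
  harmonic *anchor* restraints with equilibrium distance 0 Å;
* the fragment interacts with the host environment through ordinary
  (switched Lennard-Jones + Coulomb) nonbonded forces, so it pulls the
  backbone it is anchored to;
* fragments do **not** see each other, and a fragment does not see its own
  target residue (nor the backbone of the two flanking residues), so
  arbitrarily many constraints coexist without clashes;
* interactions *within* each fragment are evaluated normally.

All restraint information is thereby transmitted to the shared host
backbone, which deforms to satisfy every constraint simultaneously.

## Energy model

The package carries a deliberately minimal internal force field — harmonic
bonds and angles, cosine dihedrals, switched Lennard-Jones and Coulomb
terms — because the scientific content of the method is the
restraint/exclusion layer, not the force field.  Parameters live in a small
internal template table (ideal bond lengths and angles for Cys, Asp, His,
Lys, Glu, Trp, a simplified MTSSL arm, and the dummy label).  Systems are
kept at desk scale (10²–10³ atoms) so every mechanism is testable in
seconds to minutes on one CPU.

### Pairwise exclusion and scaling

`buildExclusionModel()` precomputes a pair scale for every atom pair:

| pair | scale |
|---|---|
| host–host | 1 |
| within one fragment | 1 |
| fragments in different exclusion groups | 0 |
| fragment atom ↔ its target host residue | 0 |
| fragment backbone ↔ host backbone of residues $i\pm1$ | 0 |
| 1–2 / 1–3 bonded pairs | 0 |
| fragment ↔ environment | the fragment's copy scale $1/N$ |

### Soft-core effective distance

Because fragments may overlap atoms they are blind to, a pair that *is*
evaluated can find itself at an unphysically small separation.  Pairs
involving a fragment atom are therefore evaluated at the effective
distance

$$ r' = \sqrt{r^2 + \Delta}, $$

which caps the interaction at overlap and keeps forces finite and smooth
at $r = 0$.  $\Delta$ (Å², default 1) is a user parameter.  Following the
method's own description, the soft core applies to fragment–environment
pairs; intra-fragment interactions are left unaltered.

Both the Lennard-Jones and the Coulomb term are smoothly switched off
between 10 and 12 Å (CHARMM-style switching).  Applying the switch to the
Coulomb term as well — rather than truncating it abruptly — keeps the
total energy once-differentiable at the cutoff, which the integrator and
the finite-difference force audits rely on.  There is no reciprocal-space
electrostatics; if a long-range solver is ever substituted, the contract
is that *only the host protein's charges* are accumulated on the grid
while fragments keep their truncated pairwise interactions.

### Bridge restraints

Metal bridges are enforced with harmonic terms $E = k\,(x - x_0)^2$ (note:
no factor ½ — the tabulated force constants are defined under the
extra-bond convention of the reference MD engine):

* **Cd²⁺**: S$_\gamma$–Cd bonds ($k = 10$ kcal/mol/Å², $b_0 = 2.6$ Å) and
  the S$_\gamma$–Cd–S$_\gamma$ angle ($k = 10$ kcal/mol/rad², 180°);
* **Mg²⁺**: O$_{\delta2}$–Mg bonds ($b_0 = 2.1$ Å) and the
  O$_{\delta2}$–Mg–O$_{\delta2}$ angle (180°);
* **Zn²⁺**: N$_\varepsilon$–Zn bonds ($b_0 = 2.1$ Å), the
  C$_{\varepsilon1}$–N$_\varepsilon$–Zn (127.0°) and
  C$_{\delta2}$–N$_\varepsilon$–Zn (125.5°) angles, one dihedral and two
  improper torsions that keep the ion in the imidazole plane;
* **salt bridge**: one N$_\zeta$–O$_{\varepsilon2}$ distance restraint at
  3.5 Å.

Zn coordination is modelled through N$_\varepsilon$ only: coordinating
through N$_\delta$ satisfies the bond distance easily but cannot hold the
ring orientation, so that mode is not implemented.  The parameter table
lists each Zn orientation term once; `metalBridgeRestraints()` follows it
row for row (7 terms per Zn bridge), letting the second ring's orientation
follow through the fragment's internal geometry.  Bridge residues are
built in the deprotonated, negatively charged state so that every fragment
is electrically neutral — a fragment with a net charge would interact with
the environment through an uncompensated monopole.

The salt-bridge force constant is not specified by the source data; the
package defaults to the same $k = 10$ kcal/mol/Å² as the metal-bridge
terms.  Restraints may reference a `rampSchedule()`: force constants are
turned on linearly over a stage (default 0 → 1) so that the host and the
fragments adjust smoothly; secondary-structure (φ/ψ) restraints at the
canonical α-helical (−57°, −47°) targets are typically ramped *down*.

### Restrained-ensemble histogram energy

A DEER experiment yields a *distribution* of distances, not a single
value, so a single spin-label conformer cannot represent it.  Each label
is expanded into $N$ copies (default 25) that do not see each other; each
copy interacts with the environment scaled by $1/N$.  For a site pair
$(i, j)$ the $N^2$ probe–probe distances (nitroxide oxygens for MTSSL,
the pseudo-atom for dummy labels) are smoothed into a differentiable
histogram on bins $n = 1, \dots, 60$ of width $\Delta r = 1$ Å:

$$ \bar h_{ij}(n) = \frac{1}{N^2} \sum_{s=1}^{N}\sum_{s'=1}^{N}
   \frac{1}{\sqrt{2\pi\sigma^2}}
   e^{-(n\Delta r - |r_{is} - r_{js'}|)^2/2\sigma^2},
   \qquad \sigma = 1.1\ \text{Å}, $$

and compared with the experimental target $H_{ij}$ through

$$ U_{RE} = \frac{K}{2} \sum_{\text{pair } ij}\ \sum_{\text{bin } n}
   \left(\bar h_{ij}(n) - H_{ij}(n)\right)^2,
   \qquad K = 500\ \text{kcal/mol/Å}^2. $$

Both histograms are normalized so that $\sum_n h(n)\,\Delta r = 1$.  The
renormalization of $\bar h$ over the 60-bin window is part of the energy,
and the forces differentiate through it (quotient rule): forces must be
the exact gradient of the evaluated energy for the minimizer, the
integrator and the finite-difference audits to be consistent.  (An implementation that
dropped the renormalization term from the force would differ below
typical tolerances whenever the ensemble's mass lies inside the bin
window; the exact gradient is the defensible choice.)  Histogram forces
act on probe atoms only.

### Exclusion-group packing

An engine with a hard cap on fragment slots (255 in the reference
implementation) cannot give each of $34 \times 25 = 850$ label copies its
own slot.  Copies whose minimum inter-atomic separation exceeds the
nonbonded cutoff can share a slot without ever interacting.
`groupFragments()` packs copies greedily — first fit over copies sorted by
site then copy index, ties to the lowest group index — and *verifies* the
within-group distance property.  On a fixture whose sites are all farther
apart than the cutoff plus twice the label reach this yields exactly
$N$ groups (copy $s$ of every site shares group $s$), comfortably inside
the limit.  The greedy pass is deterministic; if it cannot meet the cap it
reports the achieved group count rather than backtracking.

## Engine

* **Minimizer** — monotone adaptive steepest descent with
  Barzilai–Borwein step lengths: accepted steps never increase the
  energy, termination on max force < tol or the step budget, non-finite
  energies abort naming the offending force provider.
* **Dynamics** — BAOAB-splitting Langevin integration, 1 fs default
  timestep, no constraint solver (the reference protocol's 2 fs + SHAKE
  belongs to its full-scale runs).  Velocities initialize from the
  Maxwell–Boltzmann distribution.  At zero friction and temperature the
  scheme reduces to velocity Verlet; a harmonic oscillator conserves
  energy to < 10⁻⁴ relative over 10⁵ steps, and thermostatted runs
  reproduce equipartition, $\langle x^2\rangle = k_BT/2k$, within
  sampling error.  No barostat (desk-scale systems run at constant
  volume without a box).
* **Protocols** — `runRefinement()` chains minimize/dynamics stages with
  ramped bridge restraints and reports bridge-distance statistics
  (mean ± SD over the recorded tail); `runRestrainedEnsemble()`
  equilibrates without $U_{RE}$, then runs production with it, holding
  the host backbone at $k = 100$ kcal/mol/Å² and anchoring label copies
  at $k = 10$ kcal/mol/Å² (bridge anchors default to 50 — both are
  config values, as the two protocols differ in how hard they pin the
  backbone).

Reference-scale stage lengths (1 ns equilibration, 20 ns ramped
refinement, 80 ns hold) map onto config-declared step counts; the
shipped demonstrations use 10³ minimization + a few 10³–10⁴ dynamics
steps, which suffice for the desk-scale fixtures to reach their
restraint targets.

## Synthetic fixtures and what they do (and do not) show

`makeHelixBundle()` builds four ideal antiparallel α-helices (φ/ψ exactly
−57°/−47°, backbone + C$_\beta$) on a square lattice with a catalog of
seven bridge-style site pairs whose starting C$_\beta$–C$_\beta$
separations fall in the 8–16 Å window typical of bridgeable starting
models.
`makeLabelHost()` provides a single-chain host: a compact serpentine of
helical segments (globular, ~160 residues), or one long ideal helix
(extended) when sites must be far apart for grouping demonstrations.
`makeFreeProbes()` is the minimal two-site free-particle system for
histogram-restraint experiments, and `makeTargetHistogram()` builds
normalized Gaussian-mixture targets with a geometric achievability check
(a mode outside `siteDistance ± reach` errors unless overridden).  All
fixtures are deterministic functions of their recipe and seed.

What passing tests on these fixtures demonstrate: the exclusion algebra,
the exactness of forces, restraint convergence, the grouping bound, and
histogram-restraint convergence on achievable targets.  What they do not
demonstrate: behaviour in explicit solvent/membrane, force-field realism,
or reproduction of any published full-scale simulation statistics — those
require cluster-scale runs outside this package's scope.

## Numerical choices

* Harmonic convention $k(x-x_0)^2$ throughout (no ½), matching the bridge
  parameter table's semantics.
* Angle restraints with $\theta_0 = 180°$ operate at the colinear
  singularity by design; the force coefficient
  $(\theta - \theta_0)/\sin\theta$ has a finite limit there, and
  $\sin\theta$ is floored at $10^{-8}$ to suppress 0/0 noise.
* Dihedral/improper deviations use the minimal periodic difference.
* Bond restraints with $b_0 = 0$ (anchors) use the smooth form
  $E = k\,|r|^2$ at the origin, whose gradient is defined everywhere.
* The convergence experiment for the histogram restraint runs free probes
  at 30 K with a 2 fs step: the bias of the thermal ensemble away from
  the target histogram scales with $k_BT/K$, so a cold, well-damped run
  isolates the restraint's convergence from thermostat noise.  A burn-in
  segment after switching the restraint on is discarded before
  time-averaging.
* Copy spreading perturbs side-chain χ torsions with uniform offsets from
  a seeded private RNG stream, so builds are reproducible and do not
  disturb the caller's RNG state.

## Known limitations

* The internal force field is not CHARMM: absolute energies are not
  comparable to any published force field, only the restraint/exclusion
  behaviour is.
* PDB input carries no topology; bonded terms exist only for systems
  built by the generators or the fragment builders.
* No periodic boundaries, no solvent, no PME: long-range electrostatics
  are truncated at the cutoff by design.
* Residue indices are treated as globally unique across chains (the
  fixtures guarantee this); attaching fragments by (chain, residue) pairs
  with duplicated numbering is not supported.
* Rotamer-library label placement and disulfide chemistry are out of
  scope; the MTSSL template is a simplified arm with ideal geometry.
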