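---
title: "Methods: coarse-grained protein–nanoparticle adsorption energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained protein–nanoparticle adsorption energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanosorb)
```

## The model

`nanosorb` estimates the adsorption energy of a rigid, globular protein on an
inorganic nanoparticle by summing per-residue coarse-grained interaction
potentials. The protein is a fixed collection of beads, one per residue, each
bead at the centroid of its side-chain heavy atoms. The bead placement follows
the side-chain-analogue convention of the underlying force field: the
tabulated short-range potentials were parametrized for amino-acid side chains
with the backbone replaced by a hydrogen, so the backbone contributes no
short-range term. Glycine has no side chain; its bead sits on the C-alpha atom
and borrows the alanine table. Protonation states are taken verbatim from the
prepared input structure (pH 7 naming: `ASPP`, `GLUP`, `HSD`/`HSE`/`HSP`); no
titration model is attempted.

For a bead at surface separation distance (SSD) $h_i = d_i - R_{NP}$ — the
distance from the particle surface to the bead centre — the interaction has
three terms:

1. **Short-range surface term** ($h_i < r_c$): a tabulated free-energy
   profile (PMF) per (bead, facet) pair, interpolated with a
   monotone-shape-preserving cubic (Fritsch–Carlson). The cutoff $r_c$ is
   1.0–1.2 nm, the range over which atomistic simulation resolves the
   hydration structure. Tables are zero-referenced so the mean over the last
   0.1 nm before $r_c$ is zero; a profile that has not decayed to within
   0.25 kT of zero at $r_c$ is rejected.
2. **Core dispersion term**: the van der Waals attraction of the bead to the
   particle body, using Hamaker closed forms (two spheres for a spherical
   particle, sphere–half-space for a slab) with Lifshitz constants $A_{132}$.
   At $h_i \ge r_c$ this is the whole nonbonded term. At $h_i < r_c$ the PMF
   already contains the bead's interaction with the flat parametrization slab
   (thickness 1.0–1.2 nm, default 1.1 nm), so only the *remainder* of the
   particle body is added: for a flat particle this telescopes to the
   sphere–half-space form evaluated at gap $+$ slab thickness; for a sphere it
   is the two-sphere energy minus the finite-slab energy. This correction
   tends to the full core term as the slab thickness goes to zero, and the
   two branches meet at $r_c$ within the 0.25 kT zero-referencing tolerance
   (guarded by a test).
3. **Screened electrostatics**: linearized Poisson–Boltzmann,
   $U = z_i e \varphi_s e^{-\kappa h_i} R_{NP}/(R_{NP}+h_i)$, with the
   measured zeta potential standing in for the surface potential
   $\varphi_s$, the Debye screening constant $\kappa$ and Bjerrum length
   derived from the ionic composition, and curvature factor 1 for slabs.

### Geometry conventions

The SSD $h$ always refers to the bead *centre* (it is the collective variable
of the tabulated profiles). The dispersion closed forms require a
surface-to-surface gap; the bead radius $R_{AA}$ converts between the two
(gap $= h - R_{AA}$), with the gap floored at 0.01 nm — by then the tabulated
term's +50 kT excluded-volume wall dominates the total, so the floor only
prevents numerical blow-up, never changes a physically reachable energy.

### Hamaker constants

The dielectric–dielectric case uses the standard two-term Lifshitz
approximation: an entropic zero-frequency term in the static permittivities
plus a dispersion term in the refractive indices with the familiar
$\sqrt{n_j^2+n_3^2}$ combination. Internally both cases derive from a
single-oscillator response $\Delta_j(i\nu) = a_j \omega_j^2/(\nu^2+\omega_j^2)$,
which integrates to $A_{disp} = (3h/8)\, a_1 a_2\, \omega_1\omega_2 /
(\omega_1+\omega_2)$ and reduces exactly to the textbook formula for two
dielectrics. A conducting particle ($\varepsilon(i\nu) = 1 + \nu_p^2/\nu^2$)
enters with amplitude 1 and relaxation frequency $\nu_p/\sqrt{2}$, and total
zero-frequency reflection. Unlike absorption frequencies mix as
$\nu_e = \sqrt{\nu_1\nu_3}$. Silver is modelled as a conductor with
$\nu_p = 2.18\times10^{15}$ Hz (9.0 eV). These constants ship in an editable
YAML material file; the polystyrene/water/polystyrene triple evaluates to
$1.55\times10^{-20}$ J (entropic $0.27$ + dispersion $1.28$), consistent with
the dispersion-dominated textbook value of $1.3$–$1.4\times10^{-20}$ J.

### Orientation and separation sampling

Orientations $(\theta_k, \phi_l)$ rotate the input frame by
$R_z(\phi) R_y(\theta)$ about the protein centre of mass (COM). The grid is
regular in both angles (5° default) with solid-angle weights
$w \propto \sin\theta$, normalized, so orientations are sampled uniformly
over the sphere; unweighted averaging over the raw grid is exposed as an
option (`average_boltzmann(weighted = FALSE)`).

For each orientation, the total energy $U(z)$ is scanned along the separation
$z$ (COM–COM for spheres, COM height for slabs) from first steric contact
(the closest bead at the first tabulated grid point) out to where the total
interaction has decayed below $10^{-3}$ kT. The per-orientation mean energy is
the Boltzmann-weighted average of $U$ over that interval with the geometric
measure of the configuration volume — $dz$ for a slab, $z^2 dz$ for a sphere —
using adaptive quadrature at relative tolerance $10^{-4}$, overflow-guarded by
shifting by the profile minimum. The interval length $a(\theta_k,\phi_l)$ is
recorded per orientation; the nominal $0 \le z \le a$ range is re-anchored at
first contact because separations below steric contact are unphysical for a
rigid body. A single-bead recovery test guards these choices: for one bead on
a slab the engine must reproduce the direct one-dimensional Boltzmann integral
of the input table to $10^{-3}$ kT.

Averaging over orientations gives the simple mean $E_{ads}^A = \sum w_{kl}
E_{kl}$ and the canonical mean $E_{ads}^B = \sum P_{kl} E_{kl}$ with
$P_{kl} \propto w_{kl} e^{-E_{kl}/kT}$; by the covariance inequality
$E_{ads}^B \le E_{ads}^A$ always (property-tested on random maps). Facets are
combined by a weighted arithmetic mean, equal weights by default on the
assumption that all facets contribute equally to the particle surface. The
lowest-energy pose is the global $(\theta, \phi, z)$ minimum, refined by local
minimization in $z$, with ties broken deterministically in grid order;
contacts are the residues within 0.5 nm of the surface.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `r_c` | 1.0 (range 1.0–1.2) | nm | PMF/core boundary |
| `slab_thickness` | 1.1 | nm | parametrization slab removed by the correction |
| grid spacing | 5 | degrees | orientation resolution |
| wall cap | +50 | kT | sub-grid excluded-volume ceiling |
| decay threshold | 1e-3 | kT | z-scan outer bound |
| contact SSD | first table node (0.05) | nm | z-scan inner bound |
| temperature | 300 | K | kT scale; kJ/mol conversion 2.494 kJ/mol |
| salt | 0.15 M monovalent | mol/L | Debye screening (1/kappa = 0.78 nm) |
| zeta potential | per particle | mV | electrostatic amplitude |

The +50 kT wall cap keeps Boltzmann integrals finite while sitting far above
any physically sampled barrier; the linear sub-grid extrapolation uses the
slope at the first grid node, clamped non-attractive.

## Interfacial descriptors

The immersion enthalpy per interfacial area,
$\Delta H_{imm} = (H_{slab-liquid} - H_{slab} - H_{liquid})/A$, measures how
exothermically a liquid wets the crystal facet. When energy time series are
supplied instead of means, standard errors come from block averaging with
block-doubling until the estimate plateaus (relative change < 5% across two
doublings), validated against the analytic standard error of a seeded AR(1)
series. The nanomaterial hydrophobicity descriptor is

$$\log P^{NM} = \frac{\Delta H_{imm,water} - \Delta H_{imm,octanol}}
{RT \ln 10}$$

per nm² of interface at 298.15 K: positive values mean octanol wets the
surface more exothermically (lipophilic surface). The form above is the
package's reference definition of the descriptor; it reproduces the published
Ag(110) and Ag(111) descriptor values (14.49 and 18.13) from their published
enthalpies within 1%. It does **not** reproduce the published
Ag(100) value (6.04; the enthalpies give 1.80) — that entry is flagged
`reproduces = FALSE` in `ag_validation()` and excluded from the package's
validation claims rather than silently adjusted.

PMF summaries follow a flat-bulk-referenced convention: over the sampled
range $L$, $\Delta F_{ads} = -kT \ln[(1/L)\int e^{-F(h)/kT}\,dh]$, which is 0
for a flat profile and deepens monotonically with well depth; $E_{min}$ is
the global minimum of the interpolant. Several bulk-reference conventions are
in circulation for this quantity; the one above is documented here and used
consistently, and absolute per-facet means from the external parametrization
set are not claimed.

## The synthetic profile generator

The external parametrization dataset (96 metadynamics profiles) is not
bundled. `synth_pmf()` generates profiles with the features those tables
show: a steep repulsive wall at contact (no adsorbate displaces the first
hydration shell), an adsorption minimum between the two structured water
adlayers at ~0.2 nm, a second shallower minimum at the second hydration shell
(~0.47 nm) behind a small barrier, smooth decay to zero at $r_c = 1.0$ nm,
and optional seeded roughness. Default depths (−5 and −2.5 kT) sit in the
range typical of side-chain analogues on noble-metal facets; per-bead
variation in `synth_pmf_library()` scales depths by a seeded factor in
[0.5, 1.5].

What the generator does *not* emulate: bead-specific chemistry (aromatic
epitaxial preference, charge-specific ion-layer structure), facet-specific
systematics (e.g. the weaker binding of the most hydrophilic facet), or
correlated noise between facets. Tests that pass on synthetic tables
therefore demonstrate the correctness of the machinery — interpolation,
branch continuity, averaging, pose extraction — not the accuracy of any
specific material parametrization; absolute adsorption energies for real
proteins require the real tables and structures, which is why the packaged
validation uses the published reference values directly.

## Numerical choices and degenerate inputs

* Monotone cubic interpolation (`stats::splinefun`, `monoH.FC`) avoids
  overshoot between sparse nodes; values at nodes are exact, and the value at
  and beyond $r_c$ is exactly zero by contract (taking precedence at the last
  node).
* Quadratures: `stats::integrate` with relative tolerance $10^{-4}$ for the
  $z$-averages; trapezoid on a fine grid (≤ half the smallest node spacing,
  ≤ 1 pm floor) for $\Delta F_{ads}$.
* Zero ionic strength returns the unscreened limit $\kappa = 0$ with a
  warning, not an error; zero charge or zero zeta potential short-circuits to
  exactly 0.
* Beads pushed past the wall during a scan contribute the capped wall energy
  instead of raising, so orientation maps stay finite everywhere.
* Ties in rankings break lexicographically by id and are flagged; ties in
  pose extraction break by grid order, making reports byte-reproducible.
* Angles wrap into $0 \le \theta \le \pi$, $0 \le \phi < 2\pi$; a full-period
  wrap is the identical rotation, and a reflected $\theta$ preserves the body
  axis direction (the two-angle parametrization does not sample the twist
  about the body axis, consistent with the rigid two-angle scheme).

## Problem sizes used in the packaged checks

The test suite and the worked example run on small fixtures chosen for
resolvable orientation maps: toy proteins of 1–6 beads, orientation grids of
15–90°, and single facets where the check is facet-agnostic. The
grid-convergence guard (halving 30° to 15° changes $E_{ads}^B$ by < 2%) uses
a 0.4 nm dumbbell with 0.12 nm-wide wells, a fixture whose map a 30° grid can
resolve; sharper fixtures (1 nm dumbbell, 0.05 nm wells) have orientation
features a few degrees wide and genuinely require finer grids than the
default.

## Known limitations

* Rigid body: no side-chain rearrangement, unfolding, or backbone term; the
  scheme can overestimate binding because every side chain reaches its
  optimal arrangement independently.
* Implicit solvent and linearized electrostatics at the measured zeta
  potential; no image-charge/polarization correction for metals, no
  pH-dependent surface chemistry.
* Cylindrical particles and multi-protein corona kinetics are out of scope.
* The Ag(100) log P entry in the packaged reference table does not follow
  from its printed enthalpies under the adopted definition (above); it is
  reported but flagged.
* PDB output truncates residue names to 4 characters, so carbohydrate beads
  with longer names round-trip through in-memory objects, not through pose
  PDB files.
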