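---
title: "Measuring antibody domain pose: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring antibody domain pose: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabkit)
```

fabkit quantifies antibody Fab conformation from atomic coordinates: the
six-parameter VH–VL pairing orientation, the elbow angle between the
variable and constant modules, buried surface area and polar-contact
networks at the domain interfaces, and ensemble statistics over trajectory
snapshots. This vignette records the model behind each measure, the
conventions and defaults that a user may need to override, and the design
decisions taken where more than one reasonable choice existed.

## The structural model

A structure is a single atom roster with one coordinate set per model;
trajectory snapshots and multi-model depositions are the same object. A
domain map assigns chains and inclusive Chothia residue ranges to VH, VL,
and optionally CH1 and CL. The package never renumbers: residue numbers are
taken from the file and assumed Chothia. Insertion-coded residues (103a,
107a) order after their parent number and belong to the range containing
that number, so kappa-convention maps like `VL: [1, 107]` capture a 107a
insertion.

Each resolved domain must supply at least 20 Cα atoms — fewer is not a
credible immunoglobulin domain and almost always indicates a wrong chain or
range. Alternate locations are resolved at read time to the
highest-occupancy copy (ties: first in file); this matches common practice
and is the only point where the reader discards coordinates. Hydrogens are
kept when present (MD snapshots) but never required; every criterion that
can use them has a heavy-atom fallback.

## VH–VL orientation

The six parameters are defined through reference frames rigidly attached to
each variable domain. A packaged reference domain — an idealized two-layer
β-sandwich Cα coreset with an embedded orthonormal frame — is superposed
onto the observed domain Cαs (matched by position, missing positions
dropped pairwise, hard floor 80% coverage), and the transformed frame
`(origin, v1, v2)` represents the domain. With `C` the vector from the VH
origin to the VL origin: `dc = |C|`, `HL` is the signed dihedral of the two
`v1` vectors about `C`, and the four tilts are the angles of `v1`/`v2`
against `±C`.

Two properties matter and are enforced by construction and tested:

* all six values are invariant under any global rigid transform of the Fab;
* a rigid rotation of one domain about the inter-origin axis changes `HL`
  by exactly the applied angle and nothing else, and a translation along
  that axis changes only `dc`.

The absolute numbers are convention-bound: a different reference frame
shifts every HL by a constant. The packaged reference is generated
deterministically in code (`make_reference_domain()`, fixed seeds) and
versioned with the package; comparisons between variants measured under the
same convention — the package's intended use — are convention-free. The
reference and coreset can be replaced through the `reference` and `coreset`
arguments when compatibility with an external convention is needed.

## Elbow angle

The elbow angle is the angle between two pseudo-twofold axes: the rotation
axis of the Cα superposition VH→VL and that of CH1→CL. Constant domains are
matched by offset-normalized position (their numbering ranges are
arbitrary), preserving gaps. Each dyad axis carries a sign ambiguity; fabkit
fixes the V-module axis toward the fitted VH frame's first vector and the
C-module axis away from the CH1 frame's first vector, then reports
`θ = acos(v·c)` or its reflex `360° − θ` according to the sign of
`(v × c)·u`, with `u` the unit vector from the V-module Cα centroid to the
C-module centroid. This makes elbow values beyond 180° representable — the
regime relevant for lambda-isotype flexibility — and makes the measure
invariant under global rigid transforms. Under this convention the
generator's parallel-dyad assembly reads exactly 180°, and rotating the
constant module by δ about `u` reads 180° + δ. A dyad rotation magnitude
below 90° flags a probable pairing error rather than failing silently.

One genuine coupling deserves note: a torsion (HL) change moves the
V-module dyad axis, so HL and elbow are not independent coordinates. The
generator's ground truth for the elbow is exact only for programs that do
not twist simultaneously; the package measures both honestly, the
interpretation is the user's.

## Surface area and interfaces

Accessible surface area uses the Shrake–Rupley construction with a
deterministic golden-spiral quadrature (default 960 points per atom, probe
1.4 Å). Results are bit-reproducible at fixed point count. Quadrature
points are placed in a canonical principal-axes frame derived from the
evaluated atom set (deterministic sign fix by third moments; degenerate
spectra fall back to the lab frame), which makes ASA exactly invariant
under global rigid transforms of generic structures instead of merely
invariant to within quadrature error. Buried ASA evaluates
`ASA(A) + ASA(B) − ASA(A∪B)` with one shared frame for all three terms, so
the quadrature error cancels: fully separated sides bury exactly zero. The
total (two-face) burial is reported; the one-face interface area,
`bASA / 2`, is attached for comparability with interface-area conventions
used by complexation software. Van der Waals radii come from a packaged
element table; unknown elements get 1.8 Å with a warning.

Interface residues are those losing more than 0.1 Å² of accessible area on
complexation — a floor just above the quadrature resolution, configurable.

Hydrogen bonds require a typed donor and acceptor (backbone N except
proline, backbone O/OXT, and the standard side-chain N/O/S roles) across
the interface within 3.5 Å heavy-atom distance, plus a D–H···A angle of at
least 120° at some donor hydrogen when the structure carries hydrogens;
structures without hydrogens are evaluated distance-only and the report is
flagged. Salt bridges pair Asp/Glu carboxylate oxygens against Lys/Arg/His
nitrogens within 4.0 Å. These are conventional cutoffs, not a reproduction
of any particular interface server's internal criteria, and all are
arguments. Occupancy over a trajectory is reported at both atom-pair and
residue-pair granularity, since published contact-frequency figures are
ambiguous between the two; contacts never observed are absent from the
report rather than listed at zero. Candidate pairs come from a cell-list
spatial hash whose results are verified identical to exhaustive all-pairs
search in the test suite.

## Ensemble analytics

Snapshots are superposed onto the first snapshot by Kabsch superposition on
selected Cαs (typically VH+VL), giving the RMSD convergence series. The
analysis window for all distribution-level quantities defaults to the
second half of the trajectory, expressed as fractions `(0.5, 1)` — the
standard equilibration discard — and is configurable per call. Convergence
screening is deliberately left to the user: `rmsd_plateau()` reports
sliding-window mean drift, but the package never drops data on its own.

RMSF is the per-residue root-mean-square deviation from the window-mean
position of already-aligned coordinates; under isotropic per-coordinate
jitter σ it converges to σ√3, which the tests verify to 2% at 10⁴ frames.
PCA is an eigendecomposition of the 3N-dimensional Cα coordinate covariance
over the window (coordinate-space essential dynamics, not internal-angle
PCA); eigenvalue sum equals total coordinate variance to 1e-9 by
construction of the decomposition.

## Variant comparison

Per-snapshot feature series of two variants are compared feature-by-feature
with the two-sample Kolmogorov–Smirnov statistic on right-continuous
empirical CDFs. Three p-value routes exist: full enumeration of all
`C(n+m, n)` group assignments (exact and valid under ties; used
automatically up to 10⁵ assignments), a lattice-path counting mode (exact
without ties at any practical size), and the asymptotic Kolmogorov
distribution. The tie convention is pinned by enumeration tests.

Multiple testing is controlled by Bonferroni at family level α = 0.01 by
default: feature *i* is significant when `p < α/m`. Some figure legends in
the antibody literature label this correction "false discovery rate"; it is
not — Bonferroni controls the family-wise error rate — and the package says
so rather than silently renaming it. A Benjamini–Hochberg mode is available
for users who want literal FDR. The correction scope `m` defaults to the
number of features in the call and is an explicit parameter, because
correcting across features, across variant pairs, or across both are all
defensible and published figures rarely say which was done. Star coding
follows the figure-legend convention on the corrected p-value: `**` below
0.01, `*` in [0.01, 0.05), `ns` otherwise.

## Dataset construction

Non-redundancy follows the exact-identity rule: records with identical
concatenated VH+VL sequences (case-normalized) collapse to one
representative, chosen as the first identifier in sort order so the
operation is deterministic, idempotent, and order-insensitive. Exact string
matching reproduces the intent of clustering at 100% identity without an
external tool. Interface residue-position profiles report the fraction of
records in which each Chothia position buries surface at the VH–VL
interface; positions under 1% are omitted from the profile (the
conventional reporting filter) but retained in the raw table. Profiles are
computed on the non-redundant set by default — frequency estimates on the
redundant set would be biased by heavily re-deposited antibodies — with the
full set available by passing the un-deduplicated records. Gene origin and
somatic-hypermutation level are accepted as pass-through metadata only;
assigning them requires germline databases outside this package's scope.

## The synthetic generator

`make_toy_fab()` builds an idealized four-domain assembly from the packaged
reference domains: VH and CH1 placed directly, VL and CL created by exact
180° dyad rotations, modules stacked along the elbow direction. Each frame
of a "trajectory" applies a rigid perturbation program — HL twist about the
inter-origin axis, distance offset along it, elbow rotation of the whole
constant module — followed by optional isotropic Gaussian jitter, and the
applied values are returned as per-frame ground truth. Randomness is split
into per-purpose streams keyed by frame index, so extending a trajectory
never changes earlier frames and identical specs produce byte-identical PDB
output.

The generator emulates exactly the features the in-scope measures respond
to: rigid domain pose, its per-frame distribution, and interface geometry
of backbone-stub atoms. It does not emulate side-chain packing, internal
domain deformation, solvent, correlated dynamics, or realistic sequences.
Passing tests therefore demonstrate that the measurement and statistics
machinery is correct on rigid bodies with known ground truth — not that any
biological conclusion about real antibodies follows; on real data the
measures inherit all the caveats of the underlying structures.

Defaults follow the study conditions the package is built for: 60-residue
domains (matching the packaged coreset), ensembles of 500 frames per
variant when statistical power is exercised, a 5° planted torsion shift
against σ = 2° frame-to-frame variation, and 0.05 Å coordinate jitter so
null features fluctuate instead of being degenerate constants. The test
suite uses 10⁴ frames for the RMSF closed form and 100 seeded replicates
for power and type-I checks; these sizes give standard errors comfortably
inside the asserted tolerances.

## Numerical choices and degenerate inputs

* Kabsch superposition corrects the reflection branch to `det(R) = +1` and
  rejects rank-deficient (collinear or coincident) point sets instead of
  returning an arbitrary rotation.
* Axis extraction from a rotation matrix switches from the skew-part
  formula to the +1 eigenvector near 180°, where the skew part vanishes;
  below 10⁻⁴ degrees the axis is reported as a fixed default since it is
  undefined.
* `acos` conditioning limits angle precision to ~10⁻⁶ degrees near 0° and
  180°; tolerances in the tests reflect that, and the 1e-6 recovery
  guarantee for generator perturbations is met with two orders of margin.
* Frame registration drops missing coreset positions pairwise and errors
  below 80% coverage, listing the missing positions.
* Feature computation over a trajectory fails with the model index attached
  rather than silently skipping snapshots; batch annotation
  (`annotate_structure()`) is the one place where per-field failures become
  `NA`s, so one broken structure cannot abort a dataset build.
* Angles are written to tables at two decimals; JSON output keeps full
  precision.

## Limitations

Chothia numbering must be supplied (by the file or the domain map);
automatic renumbering from raw sequence is out of scope. Binary trajectory
formats are not read — snapshots enter as multi-model PDB. The orientation
convention is the package's own fixed one, not a re-implementation of any
published tool's numeric convention, so absolute angles are comparable only
within fabkit. Contact detection covers hydrogen bonds and salt bridges;
π-stacking and cation-π interactions are not typed. The comparison
machinery assumes exchangeable snapshots within each ensemble; strongly
autocorrelated trajectories make the effective sample size smaller than the
frame count, and the KS p-values correspondingly optimistic — thinning or
block selection is the user's responsibility.
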