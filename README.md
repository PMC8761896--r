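# fabkit

Structural analytics for antibody Fab and Fv fragments: how the heavy- and
light-chain variable domains pair, how the variable module sits on the
constant module, what holds the domain interfaces together, and whether two
antibody variants differ in any of it.

Antibody affinity maturation deposits somatic hypermutations not only in the
CDR loops but also in framework positions at the VH–VL and elbow interfaces,
where single substitutions can re-orient whole domains. Detecting such
conformational modulation requires measuring domain pose — not atom-level
RMSD — consistently across crystal structures and simulation snapshots.
fabkit provides that measurement layer for R, aimed at people who analyse
antibody structure ensembles (MD snapshots stored as multi-model PDB,
NMR-style multi-model depositions, or collections of crystal structures).

## What it computes

* **VH–VL pairing orientation, six parameters.** A reference coordinate
  frame is registered onto each variable domain by least-squares (Kabsch)
  superposition of a coreset of Cα positions. With frame origins
  `O_H`, `O_L`, frame vectors `H1, H2, L1, L2`, and `C = O_L − O_H`:
  the torsion angle `HL` (signed dihedral of `H1` and `L1` about `C`), four
  tilt angles `HC1 = ∠(H1, C)`, `HC2 = ∠(H2, C)`, `LC1 = ∠(L1, −C)`,
  `LC2 = ∠(L2, −C)`, and the inter-domain distance `dc = |C|`. Absolute
  values depend on the packaged frame convention; *differences* between
  variants are the meaningful output.
* **Elbow angle.** The pseudo-twofold axes relating VH↔VL and CH1↔CL are
  extracted as the rotation axes of the paired-Cα superpositions; the elbow
  angle is the angle between the two axes with a reflex-branch convention,
  so values above 180° are representable.
* **Interface burial.** Shrake–Rupley accessible surface area with a
  deterministic golden-spiral quadrature; buried ASA
  `bASA = ASA(A) + ASA(B) − ASA(A∪B)` for the VH–VL and elbow interfaces
  (or any custom two-sided split), plus ΔASA-based interface residue lists.
* **Polar contacts.** Hydrogen bonds (donor–acceptor ≤ 3.5 Å, D–H···A ≥ 120°
  when hydrogens are present) and salt bridges (opposite-charge pairs
  ≤ 4.0 Å) across an interface, with per-snapshot occupancy over a
  trajectory.
* **Ensemble statistics.** Trajectory alignment, RMSD series, per-residue
  RMSF, coordinate-space PCA, and per-snapshot feature series for any of the
  above.
* **Variant comparison.** Two-sample Kolmogorov–Smirnov tests per feature
  (exact by enumeration or lattice-path counting where feasible, asymptotic
  otherwise) with Bonferroni family-wise control and conventional star
  coding.
* **Dataset layer.** Non-redundant set construction by exact VH+VL sequence
  identity, structure annotation records, interface residue-position
  frequency profiles under Chothia numbering (insertion codes included),
  and stratified comparisons (light-chain isotype, presence of a residue
  pair such as Gln39H/Gln38L).
* **Synthetic fixtures.** A deterministic rigid-body Fab generator
  (`make_toy_fab()`) producing idealized four-domain assemblies and
  "trajectories" with exactly known applied torsion, distance, and elbow
  perturbations — the ground truth every geometric operation is validated
  against. The toy domains are geometric idealizations, not physical
  proteins.

## Worked example

Two 200-snapshot ensembles of the synthetic Fab, one with a planted +5°
torsion shift — the situation of a framework mutation that rotates the
light chain against the heavy chain:

```r
library(fabkit)

spec_wt  <- toy_fab_spec(n_frames = 200, seed = 11, jitter_sigma = 0.05,
                         hl = list(mode = "gaussian", mean = 0, sd = 2))
spec_mut <- toy_fab_spec(n_frames = 200, seed = 12, jitter_sigma = 0.05,
                         hl = list(mode = "gaussian", mean = 5, sd = 2))
wt  <- make_toy_fab(spec_wt);  fab_wt  <- apply_domain_map(wt$structure,  wt$map)
mut <- make_toy_fab(spec_mut); fab_mut <- apply_domain_map(mut$structure, mut$map)

vhvl_orientation(fab_wt)
#> VH-VL orientation: HL=0.08 HC1=90.06 HC2=0.06 LC1=89.90 LC2=0.12 deg, dc=14.01 A
round(as.numeric(elbow_angle(fab_wt)), 2)
#> [1] 179.96
round(as.numeric(buried_asa(fab_wt, interface_spec("VH-VL"))), 1)
#> [1] 1035.2

tab_wt  <- feature_table(fab_wt,  c("HL","HC1","HC2","LC1","LC2","dc"), window = c(0.5, 1))
tab_mut <- feature_table(fab_mut, c("HL","HC1","HC2","LC1","LC2","dc"), window = c(0.5, 1))
compare_variants(tab_wt, tab_mut, alpha = 0.01)
#> Variant comparison (bonferroni over m = 6 tests, alpha = 0.01):
#>  feature    D        p    p_adj significant stars median_diff n_a n_b
#>       HL 0.85 8.38e-32 5.03e-31        TRUE    **       4.712 100 100
#>      HC1 0.10 6.99e-01 1.00e+00       FALSE    ns       0.000 100 100
#>      HC2 0.09 8.13e-01 1.00e+00       FALSE    ns      -0.005 100 100
#>      LC1 0.12 4.68e-01 1.00e+00       FALSE    ns       0.012 100 100
#>      LC2 0.08 9.06e-01 1.00e+00       FALSE    ns       0.002 100 100
#>       dc 0.15 2.11e-01 1.00e+00       FALSE    ns      -0.003 100 100
```

Reading the output: the unperturbed assembly sits near its convention values
(`HL ≈ 0°`, `dc ≈ 14 Å`, elbow ≈ 180°; the 0.05 Å coordinate jitter accounts
for the small offsets). The comparison flags exactly the planted torsion
shift (`median_diff ≈ +4.7°`, `**` after Bonferroni over six features) and
leaves the untouched parameters non-significant.

Real structures enter through `read_structure()` (multi-model PDB, mmCIF)
plus a YAML domain map assigning chains and Chothia residue ranges to
VH/VL/CH1/CL; `annotate_structure()`, `dedup_by_sequence()`, and
`position_frequencies()` build annotated non-redundant datasets from
collections of such files. A thin command-line front end with
`simulate` / `features` / `compare` / `annotate` subcommands is installed at
`inst/cli/fabkit`.

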