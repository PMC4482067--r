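# rnapivot

Pivot-point detection in large ribosomal RNAs from pairs of atomic
structures.

## The problem

The ribosome's large RNAs move during translation: the two subunits
ratchet against each other, the small-subunit head swivels, the L1 stalk
and a set of peripheral helices reorient as EF-G binds and hydrolyzes
GTP. Comparing two structures of the same rRNA — one state with EF-G
bound, one without — shows all of these motions superimposed, and a
naive global alignment cannot tell a helix that actively hinges from
one that merely rides along with a domain-scale rotation.

`rnapivot` decouples the two. For each candidate helix a short **rigid
stem** upstream of the suspected hinge is superimposed between the
states by a least-squares rigid-body fit with iterative outlier
rejection. With upstream motion removed, the per-residue deviation
profile along the helix isolates the motion that originates locally: the
first residue whose deviation exceeds the noise floor and keeps growing
is the **pivot point**, and the displacement of a designated final-loop
residue measures the magnitude of the motion. Each pivot site is then
classified by its structural motif — G-U wobble, non-canonical pair,
bulge, or three-way junction — from geometry-derived base pairing, and
cascade analysis quantifies how much of a downstream helix's motion is
inherited from an upstream primary pivot.

## The core computation

Given paired coordinate sets $\{a_i\}, \{b_i\}$, the rigid fit minimizes
$\sum_i w_i \lVert R b_i + t - a_i \rVert^2$ over proper rotations $R$
(Kabsch SVD solution with reflection correction), followed by rejection
cycles that discard pairs with residuals above
$\mathrm{reject\_sigma} \times \mathrm{RMSD}_{kept}$ and refit. After a
stem alignment, a residue whose atoms sit at mean distance $r$ from a
hinge axis rotated by $\theta$ moves by the chord

$$d = 2\,\sin(\theta/2)\,r ,$$

which is the analytic law the bundled synthetic generator uses as ground
truth: it builds idealized A-form hairpins (rise 2.81 Å, twist
32.7°/bp), applies a known hinge rotation at a known residue, adds
Gaussian coordinate noise, and records the expected deviation of every
residue. Every pipeline stage is validated against these expectations.

## Worked example

Simulate a hinge pair — 6-bp stem, 12-bp arm, 12° hinge with a G-U
wobble at the pivot, 0.25 Å coordinate noise — and run detection:

```r
library(rnapivot)

spec <- hinge_spec(n_stem = 6, n_arm = 12, hinge_angle = 12,
                   noise_sigma = 0.25, motif_at_pivot = "GU_wobble",
                   seed = 42)
hp <- make_hinge_pair(spec)
hp$a
#> structure_model 'hinge_state_a': 828 atoms, 40 residues, 1 chain(s) [A]

hp$truth$pivot_residue          # first residue moved by the hinge
#> [1] 7
round(hp$truth$expected_tip_chord, 3)   # analytic tip displacement, A
#> [1] 7.793

calls <- detect_pivots(hp$a, hp$b, list(H1 = hp$truth$stem),
                       comparison_id = "demo")
calls[, c("helix_id", "pivot_location", "pivot_partner", "motif_class",
          "displacement", "stem_residual")]
#>   helix_id pivot_location pivot_partner motif_class displacement stem_residual
#> 1       H1              7            34   GU_wobble         7.84         0.352

round(estimate_hinge_angle(hp$a, hp$b, hp$truth$stem), 2)
#> [1] 11.95
```

The detector recovers the pivot at residue 7 (the planted hinge),
classifies the site as a G-U wobble paired with residue 34, and measures
a 7.84 Å tip displacement against the 7.79 Å analytic chord; the stem
residual 0.35 Å reads out the noise floor of the comparison
(≈ σ√2). Re-estimating the rotation between stem-aligned arm frames
recovers the 12° hinge angle.

Cascade analysis on a two-hinge construct (upstream hinge 10°, no local
hinge) shows inherited motion: the branch tip moves 8.25 Å in the
upstream stem's frame but not at all in its own frame:

```r
th <- make_two_hinge_construct(
  hinge_spec(n_stem = 6, n_arm = 10, hinge_angle = 10, seed = 1),
  hinge_spec(n_stem = 4, n_arm = 8, hinge_angle = 0, seed = 2))
cascade_table(th$a, th$b, th$upstream_stem, list(th$local_stem))
#>   helix_id displacement_upstream_aligned displacement_individual
#> 1   branch                          8.25                9.13e-15
#>                    flags
#> 1 individual_below_floor
```

Real structure pairs run through the same functions:
`read_structure()` (PDB or mmCIF), `select_rrna()`,
`apply_numbering()` (author → E. coli numbering via a TSV map), then
`detect_pivots()` with a stem catalog (`read_stem_catalog()`), or the
command-line front end:

```sh
rnapivot simulate   --seed 5 --out_dir sim/
rnapivot detect     --input_a sim/state_a.pdb --input_b sim/state_b.pdb \
                    --stem_catalog sim/stems.tsv --min_len 10 --out_dir sim/
rnapivot global-rmsd --config run.yaml
```

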