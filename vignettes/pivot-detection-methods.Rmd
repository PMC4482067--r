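---
title: "Detecting pivot points in large ribosomal RNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pivot points in large ribosomal RNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnapivot)
```

## The problem

During translation the ribosome cycles between rotated and unrotated
states, the small-subunit head swivels, and the L1 stalk and several
peripheral helices reorient. Comparing crystal or cryo-EM structures of
the same ribosome with and without EF-G bound shows these motions as
coordinate differences, but a *global* superposition of two states mixes
every motion together: a helix that merely rides along with intersubunit
rotation looks as mobile as one that actively hinges.

`rnapivot` implements the decoupling strategy used to localize hinge
("pivot") points in the large rRNAs. For each candidate helix a short
**rigid stem** proximal to the suspected hinge is superimposed between
the two states. Because the stem itself does not deform, this alignment
removes all upstream motion, and whatever displacement remains along the
helix is the motion that originates at the hinge. Walking from the stem
toward the terminal loop, the residue where the deviation profile first
rises above the noise floor — and keeps rising — is the pivot point, and
the displacement of a designated **final-loop (tip) residue** quantifies
the magnitude of the motion.

## The procedure

Detection is a two-step process per comparison:

1. **Screening** (`screen_mobile_helices`): both states are superimposed
   globally over all paired atoms with iterative outlier rejection, and
   contiguous residue runs whose deviation exceeds a mobility threshold
   are ranked as candidate mobile helices. This is how a stem catalog is
   built when none exists.
2. **Local analysis** (`detect_pivots`): for each cataloged helix the
   stem is aligned (`align_stem`), the per-residue deviation profile is
   computed along the helix path (`deviation_profile`), the pivot is
   localized (`locate_pivot`), the tip displacement is measured
   (`tip_displacement`), and the pivot site is classified by its local
   structural motif (`classify_site`).

### Superposition

The rigid-body fit is a standard weighted Kabsch solution: given paired
coordinate sets the rotation is obtained from the SVD of the weighted
cross-covariance matrix, with the reflection branch corrected by sign so
the returned matrix is always a proper rotation. `refine_superposition`
then mimics the contract of visual-best-fit alignment tools: after the
initial fit, atom pairs whose residual distance exceeds
`reject_sigma` × (current retained RMSD) are discarded and the fit is
repeated, up to `max_cycles` times. Both the RMSD over the full original
pairing (`rmsd_all`) and over the retained set (`rmsd_kept`) are
reported, because published comparisons quote a single RMSD without
saying which convention was used; reporting both lets either be matched.

Defaults are `max_cycles = 5`, `reject_sigma = 2.0` for stem fits. The
global screening fit faces a much larger outlier fraction — entire
moving helices rather than a few stray atoms — so it defaults to
`screen_cycles = 20` rejection cycles, which lets the fit converge onto
the rigid majority before deviations are measured.

### Atom pairing

Stem superposition pairs atoms by name within residues matched by
number (or by global sequence alignment, match +1 / mismatch −1 /
gap −2, when numbering differs). The default atom subset is all heavy
atoms, and fewer than `min_atoms = 30` total pairs is an error: a single
complete Watson–Crick pair already supplies just over 30 heavy atoms,
which is the minimum that gives a superposition reproducible enough to
define a direction. Occupancy-zero atoms are dropped at parse time, and
alternate locations are resolved to the highest-occupancy conformer
(ties go to the lexicographically first identifier).

### Deviation metric and pivot localization

The default per-residue deviation is the mean displacement of the
phosphate/sugar trace atoms P, O5′, C5′, C4′, C3′, O3′
(`per_residue_backbone_mean`). Restricting to the backbone keeps base
flips and glycosidic rearrangements from masquerading as hinge motion;
all-atom and max-atom variants are available as options.

`locate_pivot` returns the first residue, in stem-to-loop order, whose
deviation exceeds a threshold with *persistence*: the next
`persistence − 1` present residues must also exceed it. The default
threshold is `max(1.0 Å, 2 × stem residual)` — "above the noise floor of
this particular alignment, and at least 1 Å" — with `persistence = 2`.
Residues missing from either state are flagged and skipped, not treated
as zeros. Reporting honors a `reporting_floor`: calls whose tip
displacement falls below it (the natural choice is the global control
RMSD of a same-state comparison, which measures coordinate
reproducibility) are flagged `sub_threshold` rather than dropped,
because motion smaller than the coordinate uncertainty cannot be
distinguished from noise, yet the helix should still appear in the
report.

When a deviation first exceeds the threshold on both strands of a paired
segment simultaneously, the 5′-strand residue is reported and the
partner recorded — published pivot tables report sites as single
5′-strand positions with the pairing partner noted.

### Motif classification

Pivot sites are classified from geometry-derived base pairing
(`annotate_pairs`): candidate pairs need a C1′–C1′ distance in
[8.5, 11.5] Å, at least two base N/O contacts under 3.5 Å, and
near-coplanar bases (inter-plane angle < 30°). G–U pairs showing the
characteristic wobble contacts (O6⋯N3, N1⋯O2) are classed `GU_wobble`;
A–U and G–C with canonical contacts are `watson_crick`; everything else
is `other_noncanonical`. `classify_site` then applies the precedence

> G-U wobble > non-canonical pair > bulge > three-way junction > unassigned.

A **bulge** is an unpaired run of 1–4 residues whose flanking paired
residues belong to the same helix — operationally, their partners lie
within 2 positions of each other on the partner strand. This
same-helix condition matters: without it, the short single-stranded
linkers of a multibranch junction would satisfy the naive "short
unpaired run between paired runs" definition and the junction class
could never fire. A **three-way junction** call requires the site within
3 residues of a loop where at least three helices meet in the nested
pairing graph (pseudoknotted pairs are skipped when the nesting tree is
built). Kink-turns are deliberately not a class: pivot sites in the
ribosomal RNAs are not directly associated with them, and a kink-turn
detector would add complexity without discriminating power here.

### Cascade analysis

Coupled motion is quantified by measuring each downstream helix's tip
displacement twice: after aligning the two states on an upstream primary
pivot's stem, and after aligning on the downstream helix's own stem
(`cascade_table`). The ratio of the two is the amplification attributable
to the upstream pivot; when the individual displacement is below the
noise floor the ratio is clamped to the floor and flagged rather than
reported as infinite. `contact_network` assembles the pivot network:
undirected `physical_contact` edges between helix paths that approach
within 5 Å (heavy atoms), and directed `induced_motion` edges from the
upstream helix to every downstream helix whose amplification exceeds
1.5. No temporal or causal ordering is claimed — static end states
cannot prove a mechanism, only suggest couplings.

## The synthetic test bed

Real validation targets live on deposited PDB entries, so the package
carries a generator that emulates the essential geometry at desk scale
and provides exact ground truth for every stage.

`make_aform_duplex` builds a capped hairpin with fixed A-form helical
parameters: rise 2.81 Å and twist 32.7°/base pair, phosphates at 9.4 Å
radius (giving the characteristic ~5.9 Å consecutive P–P distance and
~10.4 Å C1′–C1′ span across a pair). Each residue carries the full
12-atom backbone set plus base ring and Watson–Crick-edge atoms placed
so that paired edges sit ~2.9 Å apart. The geometry is self-consistent
rather than chemically exact — the pipeline's mathematics depends on
rigid-body relations and distances, not on bond chemistry — and three
motif variants are constructed on demand: a G–U wobble built by applying
a 2.2 Å in-plane shear to the U (which reproduces the wobble's
characteristic O6⋯N3 / N1⋯O2 contact pattern), a bulge of 1–4 residues
pushed 3 Å off the helix radius, and a side hairpin spliced into one
strand to create a three-way junction.

`make_hinge_pair` produces the two conformational states. State B equals
state A with every residue distal to the pivot base pair rotated by the
hinge angle θ about an axis **anchored at the backbone centroid of the
5′-strand pivot residue and directed radially**, i.e. perpendicular to
the helix axis through that backbone. Anchoring the hinge at one
nucleotide's backbone is the physical picture of an RNA pivot — the
chain bends at a specific residue, not about the helix center — and it
makes the construction self-consistent: the onset of deviation coincides
with the first moving residue, which is what the truth record reports as
the pivot. (Anchoring at the base-pair centroid instead places the first
two moving residues only ~1.4 and ~5.6 Å from the axis, so the
deviation onset would lag the hinge by two residues and no profile-based
detector could honor the generator's own recovery contract.)

Because every atom at mean distance $r$ from the axis moves by the chord

$$d = 2 \sin(\theta/2)\, r,$$

the truth record carries analytic expectations for the whole profile:
per-path-residue mean axis distances $r_j$, the tip radius, and the
expected tip chord. Noise-free runs must reproduce these to numerical
precision, which the test suite asserts at 10⁻⁶ Å.

**Noise model.** `noise_sigma` is the r.m.s. three-dimensional
displacement per atom (per-coordinate standard deviation σ/√3),
independent and isotropic, added to both states. Under this convention a
noise-only comparison has pairwise stem residual σ√2 ≈ 1.3 σ, so the
stem residual reads out the coordinate uncertainty on the σ scale and
the default detection threshold `max(1, 2 × stem residual)` has a direct
interpretation. Correlated, B-factor-shaped crystallographic noise is
deliberately out of scope: the generator tests the pipeline's
statistics, not crystallography.

`make_two_hinge_construct` attaches a branch hairpin rigidly to a trunk
with its own hinge; in state B the branch first pivots locally, then
rides the trunk's upstream rotation. This gives cascade analysis a case
with known decomposition: the branch's own stem frame sees exactly the
local chord, the upstream frame sees the combination.

### What passing the synthetic suite does and does not show

The generator reproduces the *relations* the method relies on — rigid
stems, localized hinges, chord-law displacement growth, motif-dependent
pairing geometry, i.i.d. coordinate noise. It does not reproduce
crystallographic reality: correlated noise and B-factor gradients,
lattice contacts that move helices for non-biological reasons,
incomplete or mis-modeled residues, modified nucleotides, or the
ambiguity of choosing stem sequences on a real secondary structure (the
choice of aligned stem measurably changes the magnitude of the reported
motion, so displacement magnitudes are relative quantities). Passing the
suite therefore establishes correctness of the computation, not accuracy
of any particular biological conclusion drawn from real structure pairs.

## Problem sizes and numerical choices

The shipped validation uses desk-scale problems chosen to exercise every
code path with comfortable margins: hinge pairs of 6-bp stems with 4- to
22-bp arms (tip radii ~10–60 Å), 200 seeded noise runs for the recovery
and false-positive rates, 50 × 1000 random-transform challenges for
superposition optimality, and 20 seeded two-hinge constructs for the
cascade property. All random draws flow from explicit seeds; identical
seeds give bitwise-identical coordinates.

Numerical details worth knowing:

- The rejection cutoff in `refine_superposition` is floored at 10⁻⁸ Å so
  that exact fits (RMSD at machine epsilon) do not reject perfectly
  matched atoms.
- A rejection cycle that would leave fewer than 3 atom pairs is refused;
  the last valid fit is returned with a warning flag.
- Superposition of fewer than 3 points, or an empty residue pairing, is
  an error, while "no pivot found" is a valid, flagged result.
- Reports print floats with 3 decimals and embed the package version and
  an md5 of the run configuration, so reruns are byte-comparable.

## Limitations

- Correspondence is by residue number or sequence alignment only; no
  structure-based correspondence search is attempted, so catalogs for a
  new species must be supplied explicitly.
- Pseudoknots are skipped when the pairing nesting tree is built, so a
  pivot inside a pseudoknotted junction would classify as `unassigned`.
- Multi-model files and multi-assembly bundles are not split
  automatically; the caller provides one coordinate file per state.
- Displacement magnitudes are stem-choice-sensitive by construction;
  compare magnitudes only across runs using the same catalog.
- Small hinge angles shift the reported pivot distally: the chord
  $2\sin(\theta/2)\,r$ one residue past the hinge must clear the
  detection threshold for the call to land on the hinge itself, so when
  $\theta$ is small relative to the threshold floor the first
  qualifying residue lies one or more positions further along the arm.
  Lowering `threshold` (at the cost of noise sensitivity) or inspecting
  the deviation profile directly recovers the onset in such cases.
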