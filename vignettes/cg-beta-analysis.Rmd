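---
title: "Beta structure, surfaces and self-assembly in coarse-grained peptide models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta structure, surfaces and self-assembly in coarse-grained peptide models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgbeta)
```

## The problem

Short amphipathic peptides with detergent-like behaviour ("peptergents")
self-assemble into beta sheets and can wrap the hydrophobic
transmembrane belt of an integral membrane protein, displacing the
surfactant molecules that would otherwise cover it. Simulations of such
systems are usually run in a coarse-grained (CG) representation with a
single backbone bead per residue. That representation has no hydrogen
bonds and no phi/psi angles, so none of the standard secondary-structure
assignments apply; the quantities of interest — beta content over time,
the buried surface between peptides and protein, detergent aggregation —
have to be computed from bead geometry alone. cgbeta implements that
analysis layer as a tested, reusable package, together with synthetic
geometry generators so every metric can be validated on scenes with
known ground truth rather than on microsecond trajectories.

## The beta criterion

A backbone bead `i` is assigned to beta structure when two conditions
hold:

1. **Extendedness.** The unsigned pseudo-dihedral over four consecutive
   backbone beads of its chain exceeds `angle_min` (default 100°).
   Extended strands have pseudo-dihedrals near 180°; helices and turns
   fall well below 100°.
2. **Inter-strand contact.** There exists a bonded-consecutive backbone
   pair (j, j+1) with both beads within `contact_dist` (default 0.6 nm)
   of bead `i`, where the pair is on another chain or at residue
   separation at least `min_seq_sep` (default 4) on the same chain.

Both thresholds operate on bead positions only, so the same criterion
applies unchanged to C-alpha traces of atomistic trajectories.

Several details of this criterion are genuinely open at the level of a
verbal definition, and the package fixes them explicitly:

* **Window placement.** The dihedral window is centred: bead `i` takes
  the window (i−1, i, i+1, i+2). A centred window treats both strand
  directions symmetrically. The first bead and last two beads of a chain
  have no complete window and are *non-evaluable*: they are excluded
  from the denominator of the beta percentage rather than silently
  counted as non-beta.
* **Sign convention.** The dihedral is unsigned, in [0°, 180°];
  "greater than 100°" means |φ| > 100°. Extendedness is symmetric in the
  sign of the twist.
* **Sequence-separation exclusion.** Without an exclusion, a bead's own
  bonded neighbours (at 0.35 nm) would satisfy the contact condition for
  every bead and the criterion would be vacuous. `min_seq_sep = 4` is
  the smallest separation that excludes the dihedral window itself.
* **Strictness.** Both partner beads j and j+1 must individually lie
  within `contact_dist`; requiring only one would let a single close
  bead qualify, blurring the distinction between packing contact and
  strand pairing.

A consequence worth knowing: a *compact* random coil can legitimately
contain beads that satisfy both conditions (a locally extended stretch
touching another part of the chain). This is detector behaviour, not a
bug — the coil fixtures used for zero-beta ground truth are therefore
generated with a self-avoidance exclusion larger than `contact_dist`,
which makes zero provable by construction.

## Strand segments, pairing and registry

Maximal runs of beta beads of length ≥ `min_strand_len` (default 3)
become strand segments. Two segments pair when their mean nearest-bead
distance is at most `pair_dist` (default 0.6 nm, the contact scale);
orientation comes from the sign of the dot product of their direction
vectors. The registry shift — the integer residue offset between paired
strands — is found by minimising the mean matched-bead distance over
shifts |s| ≤ 3, with ties broken toward smaller |s|. The matching is
computed between the *full backbone bead lists* of the two chains (the
second reversed for antiparallel pairs), not between the trimmed beta
runs: trimming is asymmetric under chain reversal and would otherwise
bias antiparallel registries by one residue. For two segments on the
same chain (a hairpin) the segments themselves are matched; registry
values for hairpins should be read with that caveat.

## Surface measures

SASA uses the Shrake–Rupley construction: test points on a sphere of
radius (bead radius + probe radius) around each bead, counted accessible
when outside every other selected bead's expanded sphere. Points are
placed by a golden-spiral (Fibonacci) construction — deterministic, so
surface numbers are bit-stable and carry no RNG state. The defaults are
a probe of 0.256 nm (a CG water-sized probe) and a bead radius of
0.26 nm; 960 points keep the single-sphere quadrature error under 1%,
verified against the closed form 4π(r+p)² and the analytic
two-intersecting-spheres area in the test suite.

The buried interface between groups A and B is
(SASA_A + SASA_B − SASA_AB)/2, each term computed in its own selection
context (beads outside the selection are ignored entirely). The formula
is symmetric, non-negative, bounded by min(SASA_A, SASA_B), and exactly
zero once the closest inter-group bead pair exceeds
r_A + r_B + 2·probe — all verified as properties.

Periodic images are ignored inside SASA: the selections this measure is
meant for (a protein, its peptide corona, a micelle) are compact
assemblies, and a warning is emitted if a selection spans more than half
the box. Minimum-image distances *are* used everywhere else (contacts,
clustering, beta assignment), for orthorhombic boxes; triclinic input is
rejected explicitly rather than mis-wrapped.

## Aggregates and burial

Molecules are delimited by chain identifier (one chain = one peptide or
one detergent). Single-linkage clustering at a cutoff (default 0.6 nm,
the same contact scale as the beta criterion) joins molecules with any
inter-molecule bead pair within the cutoff; labels are deterministic
(lowest molecule index per cluster) and the implementation is checked
against a brute-force union-find oracle. Hydrophobic burial is
1 − (hydrophobic SASA in context)/(isolated single-bead reference),
clamped at zero: 0 for an isolated bead, ~1 for a fully caged one, and
consistently higher for a closed barrel than for the same strands laid
flat.

## Design rules

The sequence-level module encodes the heuristics for beta-amphipathic
detergent peptides: alternating hydrophobic/hydrophilic classes
(amphipathy in an extended strand, where side chains alternate faces), a
12-residue length matched to bilayer width, positive charge in the
N-terminal half complemented by negative charge in the C-terminal half
(favouring antiparallel pairing), and zero net charge. The N/C halves
are the first ceiling(L/2) and remaining floor(L/2) residues — the
simplest documented reading; the minimum alternation score defaults to
0.8, accepting one break per dozen residues. Beta-propensity scoring
(Chou–Fasman style) is deliberately out of scope: residue preference
enters only through the user's choice of sequence.

## Synthetic geometry: what it does and does not emulate

The generators produce every scene class the analyses assume, with exact
ground truth:

* `make_strand()` — a regular extended chain with constant bond length
  (0.35 nm) and constant interior pseudo-dihedral (170°), built by
  natural-extension (NeRF) placement, so both values hold to machine
  precision.
* `make_sheet()` — strands as windows of one exactly periodic planar
  zigzag lattice stacked at 0.48 nm. Using one shared lattice makes
  matched inter-strand distances exact, so "every interior bead is beta"
  and "the detector recovers the construction registry" are theorems
  about the fixture, not hopes. Hydrophobic residues share one lattice
  parity, giving a truly one-sided hydrophobic face.
* `make_barrel()` — strands on a cylinder with the radial zigzag
  pointing hydrophobic beads literally inward; the default radius puts
  neighbouring strands at the sheet spacing.
* `make_coil()` — a seeded self-avoiding walk with exact bond lengths
  and a minimum non-bonded distance.
* `make_cylinder_protein()` / `bacteriorhodopsin_mimic()` — a helical
  bundle with a hydrophobic mid-belt and polar caps;
  the mimic fixes seven ~25-residue helices at ~1 nm packing with
  backbone plus side beads, the scale of a small seven-helix membrane
  protein. It is a synthetic stand-in, not an experimental structure.
* `make_detergent_shell()` — head-out/tail-in detergent molecules on a
  cylindrical shell, uniform or concentrated in `n_patches` seeded
  patches. Patch members sit on a tight jittered ladder in z so each
  patch is internally connected at the 0.6 nm contact scale for any
  seed — patch-count recovery is then a construction guarantee, which is
  what a clustering ground-truth fixture must provide.
* `make_interpolated_trajectory()` — linear coordinate interpolation
  with integer picosecond time stamps.

Geometry constants (0.35 nm rise, 0.48 nm inter-strand spacing) follow
canonical beta-sheet dimensions; they are fixture conventions, not
force-field claims. All generators are pure functions of their
arguments including the seed (the global RNG stream is saved and
restored), and all fixtures round-trip through GRO within the format's
3-decimal precision.

What the fixtures do **not** emulate: thermal noise, force-field
energetics, sheet twist, kinetics, solvent. A passing suite shows the
*measures* are correct on known geometry; it says nothing about whether
a particular force field will actually form these assemblies. Time
series on interpolated trajectories are shape checks (monotone rise of
beta content as strands condense; monotone fall of the detergent
interface as the shell is displaced), not dynamics. For the monotone
beta-content check the start frame is the sheet uniformly expanded about
its centroid, so every inter-bead distance shrinks linearly and each
bead's contact criterion switches on exactly once — monotonicity is
again a property of the construction, which is what makes it a fair test
of the detector.

## Numerical and interface choices

* Coordinates are stored in nm (GRO convention); PDB input is converted
  on read, output on write. One internal unit avoids Å/nm drift across
  thresholds.
* Backbone identification accepts bead names `BB` (CG dialect) and `CA`
  (C-alpha dialect), configurable per read.
* Unknown residues classify as `other` with the default radius instead
  of failing structure reads (non-natural residues are routine in this
  domain); sequence-level design checks, in contrast, *do* fail on
  unknown tokens, since silently misclassifying a designed residue would
  invalidate the report.
* GRO files carry no chain identifiers; chains are inferred from residue
  numbering (a break whenever the residue number fails to continue by
  0 or +1). Multi-molecule scenes whose grouping matters should use PDB,
  which preserves chains — the pipeline tests do exactly this.
* The orthorhombic-only box restriction, the ≤ |3| registry search, the
  0.6 nm default cutoffs shared across modules, and the CSV formats
  (`.` decimal, fixed column order, fixed precision) are all single
  sources of truth: the pipeline configuration echoes module defaults,
  asserted by a test.

## Problem sizes

The shipped tests and the acceptance script run on fixtures between 1
and 350 beads, 100 randomized detector-oracle scenes of up to ~200
beads, and trajectories of up to 6 frames; the full suite completes in
well under a minute on one CPU. These sizes were chosen because every
check above is exact or property-based, so larger systems add cost
without adding discriminating power.

## Known limitations

* One beta class only: the criterion distinguishes beta from non-beta;
  helix/turn/coil are not assigned (nothing in a one-bead backbone
  distinguishes them reliably).
* Registry shifts for hairpin (same-chain) pairings use trimmed
  segments, see above.
* No analytic (power-diagram) SASA and no per-element atomistic radii;
  the Shrake–Rupley quadrature with a single CG radius table is the
  intended scope.
* Single-linkage clustering chains aggregates through any bead contact;
  at high density it merges everything, as single linkage must. The
  cutoff is a parameter, not a claim.
* No compressed/binary trajectory formats; concatenated GRO and
  multi-model PDB cover the fixture-scale scope behind the same
  trajectory contract.
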