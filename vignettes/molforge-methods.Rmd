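---
title: "molforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molforge)
```

## What this package models

molforge is a headless molecular building and editing engine for small
molecules: the kind of structure manipulation an interactive 3D editor
performs, reduced to a library plus a command-line tool so it can run in
scripts and tests. A molecule is an ordered list of atoms (element symbol
plus Cartesian coordinates in Ångström) and an unordered set of bonds over
atom indices. Bonds carry no order attribute: a double bond and a single
bond are the same edge, which is sufficient for connectivity-driven editing
and display, and is why MOL bond orders are read but discarded.

## Bond perception

XYZ files carry no connectivity, so bonds are inferred from geometry: atoms
$i$ and $j$ are bonded iff

$$ \lVert \mathbf{p}_i - \mathbf{p}_j \rVert \; < \; f \,(r_i + r_j), $$

with $f = 1.2$ by default and $r$ the covalent radius. The inequality is
strict: a pair exactly at the cutoff is not bonded. All pairs are examined;
there is no special case for H–H contacts. The radii are the Cordero 2008
compilation (the same single-bond values shipped with RDKit and Open
Babel), stored in a plain TSV under `inst/extdata/` together with Jmol
display colors, atomic masses and main-group valence electron counts, so
the whole constant table is inspectable and replaceable via
`options(molforge.elements = ...)`. Every bond-length statement in the
package — perception cutoffs, construction distances, optimizer targets —
is relative to this shipped table, not to literature values, so swapping
the table moves everything consistently.

Ring membership is decided per query: a bond lies on a ring iff removing it
leaves its endpoints connected (checked with igraph components). Molecules
here are small, so no smallest-set-of-smallest-rings precomputation is
worthwhile.

## Hydrogen autocompletion

When an atom is added or its element changed, hydrogens are autocompleted
for p-block elements only, assuming the octet rule:

$$ n_\mathrm{H} = \mathrm{clamp}(8 - V - B,\; 0,\; 3) $$

where $V$ is the main-group valence electron count and $B$ the number of
bonds the atom already has. The cap of three and the octet assumption give
3/2/1/0 hydrogens for singly-bonded C/N/O/F. d- and f-block atoms get no
autocompletion. Placement geometry comes from the user-selectable
hybridization (default sp³): hydrogens sit at the ideal angle —
$\arccos(-1/3) \approx 109.471^\circ$ for sp³, $120^\circ$ for sp²,
$180^\circ$ for sp — on directions taken from an ideal direction set
rotated so that its first member aligns with the atom's existing bond. The
orientation about that bond axis is arbitrary in principle; the alignment
rotation used here is deterministic (rotation about the cross product of
the two directions, with a fixed perpendicular chosen for the antiparallel
case), so builds are reproducible.

A single hydrogen added to an arbitrary atom ("minimize interactions with
other bonded atoms") is placed along the direction that maximizes the
minimum angle to the existing bonds: analytically the negative normalized
sum of the bond unit vectors for one to three bonds, and a deterministic
golden-spiral grid search (2000 points) otherwise. No other atom moves, so
the result is often not ideal — that is what the optimizer is for.

## The crude optimizer

The relaxation is deliberately not molecular mechanics. Each iteration runs
three damped correction passes in a fixed order:

1. **Bond lengths** — both atoms of each bond move along the bond axis,
   splitting the correction toward $r_i + r_j$ equally.
2. **Bond angles** — for every angle triple at every center, the two arm
   atoms rotate in the plane of the triple, about the axis normal to it,
   toward the center's hybridization ideal. Only the two arm atoms move,
   not their substituents: crude on purpose.
3. **Torsions** — every non-ring bond with substituents on both sides has
   its reference dihedral (first substituent on each side by atom index)
   driven toward the nearest staggered value ($60^\circ + k\cdot
   120^\circ$); the smaller fragment rotates (ties go to the second atom's
   side). Ring bonds are excluded, consistent with the fragment-rotation
   rule; ring strain is handled only by the angle pass.

Corrections are damped by `step_fraction` (default 0.5). Convergence is
declared when the maximum per-atom displacement within an iteration falls
below `coordinate_tolerance` (default 1e-4 Å); the cap is
`max_iterations = 200`. Non-convergence is reported via a flag, never an
error. A surrogate objective $E = \sum_\mathrm{bonds} (\ell -
\ell_0)^2 + \sum_\mathrm{angles} (\theta - \theta_0)^2$ (lengths in Å,
angles in radians) is recorded each iteration as a diagnostic. On the
simple fixtures (eclipsed ethane, stretched or noise-perturbed methane) it
descends monotonically and the structures converge to radii-sum lengths and
ideal angles. On branched molecules with several coupled rotatable bonds
the independent per-bond torsion targets can disagree, and the sweep may
cycle indefinitely with small non-monotone energy steps; the converged flag
reports this honestly. This matches the routine's station in life as a
clean-up step, not an energy minimizer: there are no nonbonded terms, so it
will happily converge to sterically clashing geometries.

The pass structure, damping, convergence test and iteration cap are this
package's own reconstruction; only the three optimization targets (radii
sums, VSEPR ideal angles, torsional relief) are externally given.

## Editing and history

Edits are pure functions from molecule to molecule; the optional
`edit_history` argument is an environment holding bounded undo/redo stacks
of full snapshots (capacity 10, oldest evicted, redo cleared by any new
edit). Deep copies are cheap at this molecular scale, so there is no
structural sharing to get wrong — undo is exact, field for field. Deleting
an atom cascades to its directly bonded hydrogens and nothing else.
Fragment rotation refuses ring bonds; the moving side is the smaller
component, which matches the intuition of rotating a substituent.
Edits maintain the bond set explicitly; bonds are not re-perceived after
an edit, so hand-drawn bonds (e.g. the cube-edge bonds of a unit-cell
illustration) survive editing.

## Rendering

`render_svg()` reproduces a canvas-style painter's algorithm in a static,
byte-stable SVG: orthographic projection (x right, y up, z toward the
viewer), atoms sorted by ascending z and drawn back to front as circles of
radius `sphere_scale` × covalent radius (default 0.5), filled with the
element's Jmol color under a radial gradient (highlight offset toward the
upper left, darkened rim). Each atom then draws one line per bond to every
neighbor painted after it, starting at the 3D intersection of the bond with
its own sphere and ending at the neighbor's projected center — so every
bond is owned by its back atom and drawn exactly once, including the
equal-z case, where ownership falls to the earlier atom in the stable sort.
Molecules with more than `gradient_cutoff` atoms (default 250) switch to
flat fills, trading depth illusion for speed exactly at the documented
cutoff. Spheres are assumed not to overlap; there is no occlusion clipping
beyond the painter's order. Circles carry `data-atom`/`data-z` attributes
so tests can verify the paint order without rasterizing. The exact gradient
stops are a package choice (60 % white at the center, the pure color at
55 %, 40 % black at the rim) since only the *presence* of gradient shading
is externally specified.

## Fixtures as a stated world

`make_fixture()` builds the test molecules in code, from the shipped radii
table, with exact ideal geometry: tetrahedral methane, staggered/eclipsed
ethane, a planar hexagonal benzene (geometry only — no aromaticity model),
the heavy-atom skeleton of methylcyclohexane for ring queries, S-2-butanol
(the S assignment at C2 was verified once against an independent CIP
implementation during development), eight cube-corner zinc atoms on a
5.41 Å cell with deliberately no perceivable bonds, and seeded uniform
random clouds (12 carbons in a 4 Å box by default — dense enough that a
cloud typically perceives several bonds). Optional Gaussian coordinate
noise (`perturb`, in Å, with a mandatory seed) turns ideal fixtures into
optimizer inputs; 0.1 Å is used as a realistic "hand-drawn" displacement
scale. What a green test establishes is therefore internal consistency of
the rules on ideal and near-ideal geometry; none of the fixtures exercise
crowded, strained or metal-coordination chemistry, and the generator makes
no claim to conformational realism.

## Numerical choices and degenerate inputs

Angles are degrees at every API surface, radians internally. The arc-cosine
argument is clamped to $[-1, 1]$; dihedrals use the atan2 form and live in
$(-180, 180]$, so mirror symmetry tests compare angles modulo 360 at the
branch cut. Zero-length measurement arms and collinear dihedral frames
raise a classed degenerate-geometry error rather than returning NaN. Whole-
molecule axis rotations pivot about the centroid (the pivot is a free
choice; it is exposed via `anchor`). A bond exactly along the view axis
projects its sphere-surface start point onto the atom center — a degenerate
but well-defined line. All errors are classed conditions
(`molforge_unknown_element`, `molforge_ring_bond`, ...) so both the CLI and
callers can dispatch without string matching.

## Command-line interface

`exec/molforge` is a thin Rscript over `molforge_main()`: subcommands
`info`, `convert`, `bonds`, `measure`, `transform`, `edit`, `optimize`,
`render`, `fixture`; exit codes 0 (ok), 2 (usage), 3 (parse/file), 4
(domain error). Atom indices are 1-based on the CLI and in the package —
R's native indexing — and files with extensions other than `.xyz`/`.mol`
are rejected with a warning. Configuration is a plain `key = value` file
overridden by flags; there is no environment-variable magic.

## Known limitations

* No bond orders, aromaticity, formal charges or isotopes.
* The optimizer has no nonbonded terms and can cycle on coupled torsions.
* MOL support is read-only V2000 (counts line, atom block, bond block).
* Hydrogen autocompletion is undefined (a no-op) for d-/f-block atoms.
* Rendering assumes non-overlapping spheres and uses no perspective.
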