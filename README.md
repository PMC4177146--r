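# molforge

Headless building, editing and rendering of small-molecule 3D structures
in R: the core of an interactive molecular editor — file I/O, bond
perception, measurement, structure editing with hydrogen autocompletion,
a crude VSEPR-style relaxation, and ball-and-stick rendering — as a
scriptable library plus a command-line tool. It is aimed at teaching
settings and at anyone who needs light-weight, reproducible manipulation
of small organic and inorganic structures without a GUI or a force field.

## The model

A molecule is an ordered atom list (element symbol + Cartesian coordinates
in Å) and an unordered bond set over atom indices, with no bond orders.
The quantitative rules, all relative to the shipped element table
(Cordero 2008 covalent radii, Jmol colors, main-group valence counts):

* **Bond perception** — atoms *i*, *j* bonded iff
  ‖**p**ᵢ − **p**ⱼ‖ < 1.2 (rᵢ + rⱼ), strict inequality, every pair tested.
* **Hydrogen autocompletion** (p-block only) — n_H = clamp(8 − V − B, 0, 3)
  from the octet rule, placed at the hybridization's ideal angle
  (sp³ arccos(−1/3) ≈ 109.471°, sp² 120°, sp 180°) at radii-sum distances.
* **Crude optimization** — damped iterative passes moving bond lengths to
  radii sums, angles to VSEPR ideals, and non-ring torsions to staggered
  (60° + k·120°); convergence when no atom moves more than 1e-4 Å in an
  iteration.
* **Rendering** — orthographic SVG, atoms depth-sorted and painted back to
  front, bond lines from the back atom's sphere surface to the front
  atom's center, radial-gradient shading dropped above 250 atoms.
* **Editing** — add/change/delete atoms and bonds, ring-aware fragment
  rotation, deletion cascading to attached hydrogens, and a 10-deep
  undo/redo snapshot stack.

## Worked example

```r
library(molforge)

m <- make_fixture("methane")
m
#> <molecule> CH4: 5 atoms, 4 bonds
#>   title: methane
sprintf("C-H length: %.3f A", measure_distance(m, 1, 2))
#> "C-H length: 1.070 A"                     # r_C + r_H = 0.76 + 0.31
sprintf("H-C-H angle: %.3f deg", measure_angle(m, 2, 1, 3))
#> "H-C-H angle: 109.471 deg"                # arccos(-1/3)

# turn one hydrogen into a hydroxyl: the H becomes O at the C-O radii sum,
# and the octet rule grants the new O one hydrogen of its own
mol <- change_element(m, 2, "O")
sprintf("after H->OH: %s, %d atoms", molecular_formula(mol), n_atoms(mol))
#> "after H->OH: CH4O, 6 atoms"              # methanol
sprintf("weight: %.3f u", molecular_weight(mol))
#> "weight: 32.042 u"

# relax an eclipsed ethane: torsion pass finds the staggered conformer
res <- optimize_geometry(make_fixture("ethane_eclipsed"))
sprintf("optimize: %d iterations, converged: %s", res$iterations, res$converged)
#> "optimize: 14 iterations, converged: TRUE"
sprintf("H-C-C-H dihedral now: %.2f deg", measure_dihedral(res$molecule, 3, 1, 2, 6))
#> "H-C-C-H dihedral now: 60.00 deg"

render_svg(res$molecule, scene(), file = "ethane.svg")
```

## Command line

```sh
exec/molforge fixture methane -o methane.xyz
exec/molforge info methane.xyz         # atoms, bonds, formula CH4, weight
exec/molforge measure methane.xyz --atoms 2,1,3
exec/molforge optimize methane.xyz -o opt.xyz
exec/molforge render methane.xyz -o methane.svg --labels
```

Exit codes: 0 ok, 2 usage, 3 parse/file, 4 domain error. Indices are
1-based; files must end in `.xyz` or `.mol` (other extensions are rejected
with a warning).

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline end to end from an installed
copy of the package — seeded random-cloud bond perception checked for
self-consistency, an edit/undo round trip, optimization of seeded perturbed
methane, and SVG rendering of the bundled fixtures — and writes its JSON
result object:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/molforge-methods.Rmd` for the full account of the model,
parameter choices and limitations.
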