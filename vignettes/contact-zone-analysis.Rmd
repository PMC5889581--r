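---
title: "Contact-zone analysis of docking ensembles: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-zone analysis of docking ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockzones)
```

## The model

`dockzones` analyses ensembles of candidate configurations of one
two-protein complex. One protein is designated the *reference*, the other
the *paired* protein; the roles are the user's choice (chain selectors)
and anchor everything downstream: superposition, the left column of list
views, and the residue-match term of the similarity score.

**Contact definition.** The distance between two amino acids is the
minimum Euclidean distance over their heavy-atom pairs. A cross-unit
residue pair is a *contact* when that distance lies in the closed interval
[d_min, d_max] and a *collision* when it is strictly below d_min.
Collisions are reported separately and never counted as contacts — they
indicate physically implausible interpenetration rather than interaction.
The atom-level minimum (rather than centroid separation) is a deliberate
choice: the conventional 3–5 Å interaction range describes interatomic
distances, and centroids of large side chains would sit well outside it.

**Frequency matrix.** Each configuration contributes at most one increment
per (reference residue, paired residue) cell. Rows and columns contain
only residues seen in contact in at least one configuration, ordered by
(chain, number, insertion code); zero cells are never stored or exported.
Filtering by a set of required pairs is conjunctive and may use a
tightened range (the `filter_d_max` knob) without touching the matrix
itself; the lower bound stays at d_min, since tightening an interaction
cutoff conventionally means lowering the upper bound only.

**Similarity score.** Against the primary configuration's zone,
`score = R + 4·P − M` with R the shared reference-side contact residues,
P the shared pairs, M the primary pairs absent from the compared zone.
Two readings were open and are fixed here: (i) only *reference-side*
residues earn the +1 (the paired side contributes through the pair term);
(ii) pairs present only in the compared zone are unpenalized — the score
measures agreement with the primary, and penalizing extras would
double-count the missing-pair rule in reverse. The 1/4/−1 weights are
treated as given constants, not tunables.

## Parameters that matter

| parameter | unit | default | why |
|---|---|---|---|
| `d_min` | Å | 3 | lower edge of the interaction range; collision threshold |
| `d_max` | Å | 5 | upper edge; case studies often tighten to 4 |
| `spacing_margin` | Å | 10 | extra clearance between exploded bounding spheres |
| `focal` | Å | 2 × max paired radius | paraboloid curvature of the exploded grid |
| `gap` | Å | 10 | bounding-box clearance between opened units |
| `sort_key` | – | hydrophobicity | list-view left ordering (Kyte–Doolittle) |

Hydrophobicity uses the Kyte–Doolittle hydropathy index; the property
(not the scale) is what matters for reading an interface, and
Kyte–Doolittle is the field's default. Partial-charge coloring is omitted
entirely: no charge-assignment scheme is defined for bare heavy-atom
models, and guessing one would produce confidently wrong colors.

## Geometry

**Superposition.** Docking ensembles repose *identical* sequences, so the
correspondence between reference proteins is exact by residue key. The
package therefore uses key-matched Cα Kabsch superposition rather than a
structural-alignment search (Combinatorial Extension and kin are needed
only for homologs, which are out of scope). Degenerate inputs (< 3 common
Cα, collinear point sets) are hard errors, not warnings: a rotation fitted
to a line is arbitrary about that line.

**Exploded layout.** Reference proteins stay superposed; each paired
protein is *translated only* to a slot on a parabolic grid whose axis is
the mean reference-side contact-zone normal. Slots are spaced
`2·r_max + margin` apart in the grid plane, with the paraboloid
`w = (u² + v²) / (4f)` only adding axial separation, so bounding spheres
of radius ≤ r_max provably never overlap — the non-collision guarantee is
geometric, not empirical. Keeping the paired units un-rotated preserves
each pose's orientation for visual comparison; pairing is retained as
recorded tube endpoints (the two contact-zone centroids, the paired one
translated). The paraboloid parameters have no canonical values; the
defaults above are derived from bounding-sphere radii precisely so the
guarantee holds.

**Open book.** Each side's contact-zone normal is the smallest principal
direction of its contact residues' Cα scatter, sign-oriented toward the
partner's centroid (with < 3 residues the direction to the partner is
used directly). Each unit rotates about its zone centroid by the minimal
rotation taking that normal onto the view direction (+z by convention,
right-handed frame, viewer at +z); an exactly antiparallel normal is
resolved by a fixed 180° turn about the in-plane separation axis, making
the degenerate case deterministic. Residual in-plane twist is left free —
there is no principled anchoring rule, and the minimal rotation is the
least surprising choice. Units are then shifted apart along the in-plane
axis to at least `gap` between bounding boxes.

## The synthetic generator: what it emulates, what it does not

The generator stands in for docking-program output: chains A
(reference) and B (paired) of 5-heavy-atom residues (N/CA/C/O/CB on a
z-planar template), amino-acid names assigned round-robin over the 20
standard types so hydrophobicity sorting is exercised. Residues sit 12 Å
apart on a gently zig-zagged backbone (non-collinear Cα, so superposition
is well-posed); chain B lies 60 Å away except for *planted* pairs, where
residue B:j becomes a copy of A:i's template shifted exactly t along +z.
Because the template is z-planar, every atom pair of a planted couple is
separated by exactly t in z and the minimum heavy-atom distance equals t
to machine precision; the 12 Å spacing keeps every non-planted cross-unit
pair > d_max + 2 Å. The planted table is therefore *closed* ground truth
under the contact definition — no accidental contacts can exist.

What a green test on this world establishes: exact correctness of contact
enumeration, counting, filtering, scoring, ordering and the rigid-body
algebra. What it does not establish: behaviour on real side-chain
geometry, missing atoms, occupancy pathologies, or chemically sensible
interfaces — real backbones are neither straight nor planar, and real
contact zones are not isolated by construction. PDB files print
coordinates at 3 decimals, so plants survive file round-trips exactly only
when targets lie on the 0.001 Å grid; randomized tests round accordingly.

## Numerical choices

- Contact distances are computed with the same subtract-square-sum
  arithmetic as the brute-force reference, so oracle-equivalence tests
  can demand *identical* contact sets, not approximately equal ones.
- The contact interval is closed at both ends; `d == d_max` is a contact,
  `d == d_min` is a contact, `d < d_min` a collision.
- Ties: the closest pair breaks ties by (reference chain, number, paired
  chain, number) ascending; ranking ties preserve ensemble input order;
  altloc ties (equal occupancy) resolve by altloc character order;
  list-view sort ties fall back to chain/residue number.
- Rigid transforms are validated to orthonormality and det +1 within
  1e-9; Kabsch suppresses reflections by determinant correction.
- SVG/JSON/TSV exports are assembled as text with fixed formatting, so
  identical models yield byte-identical files (tested).

## Design decisions taken where the design was open

- An *external* primary (crystal) configuration is stored alongside the
  ensemble rather than appended to its member list: ensemble statistics
  (matrix counts, n) describe the docked set only, which is what the
  frequency matrix means; a primary that is itself a member is referenced
  by id. `get_primary()` abstracts over both.
- Per-residue aggregation for list-view sorting is not canonically
  defined; this package uses each left residue's *minimum* connection
  distance (distance sort) and *maximum* matrix count over its pairs
  (frequency sort), directions hydrophobic-first / closest-first /
  most-frequent-first.
- Chain-role designation (which chains are reference vs. paired) is the
  caller's contract via `--ref-chains` / `--paired-chains`; docking
  outputs carry no such annotation.
- The heat map's high color is fixed at RGB (178, 24, 43) ("intense red"
  is otherwise unspecified); the ramp is linear in RGB from white over
  [0, max count].

## Known limitations

- No mmCIF, gzip, symmetry expansion, or NMR occupancy semantics; PDB
  fixed-width records only.
- Interaction typing (H-bonds, salt bridges, disulphides) is out of
  scope; contacts are purely geometric.
- The exploded view computes tube *endpoints* only; radius-modulated tube
  rendering, molecular surfaces and animation are rendering concerns this
  package deliberately does not have.
- The published NSE1–NSE3 benchmark (3 of 40 HADDOCK models retained at
  d_max = 4 Å for MET 23 × LEU 97) is implemented as an acceptance test
  but requires the supplementary dataset on disk; offline it fails red by
  design rather than being faked on synthetic data.
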