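# dockzones

Contact-zone analysis of protein–protein docking ensembles in R.

## The problem

Protein–protein docking programs (HADDOCK, PyDock, ...) emit dozens to
hundreds of candidate configurations ("poses") of one two-protein complex.
Their internal scores rarely coincide with proteomic relevance, so experts
triage poses by hand, asking: which poses realize a residue pair known to
interact? how do their interfaces compare with a trusted crystal
structure? `dockzones` implements that triage as a headless library + CLI:

- **Contact zones.** Two residues are in contact when their minimum
  heavy-atom Euclidean distance d satisfies d_min ≤ d ≤ d_max (default
  3–5 Å, user-adjustable). Pairs with d < d_min are flagged as collisions,
  never counted as contacts.
- **Frequency matrix.** Over an ensemble S = {CONF_i, 1 ≤ i ≤ n}, the cell
  (r, p) counts the configurations whose contact zone contains the pair
  (r, p) — a heat map of interface consensus, filterable by a conjunction
  of required pairs.
- **Similarity ranking.** Against a primary configuration (typically a
  crystal structure), each pose scores
  `score = R + 4·P − M`, where R = shared reference-side contact residues,
  P = shared contact pairs and M = primary pairs missing from the pose.
- **Contact-zone list views.** Ordered left (reference) residues with
  their partners repeated underneath — one right entry per contact pair,
  so connector lines never cross — sortable by Kyte–Doolittle
  hydrophobicity, mutual distance, or pair frequency; compare/compact
  panels highlight matches and missing residues against the primary.
- **Exploded and open-book geometry.** Kabsch superposition of the
  reference proteins (exact residue-key correspondence on Cα atoms), a
  parabolic grid of translated paired proteins with provably non-colliding
  bounding spheres and recorded pairing-tube endpoints, and rigid
  open-book transforms that rotate both contact-zone normals toward the
  viewer. Everything is emitted as explicit rigid transforms and
  transformed PDB files — no rendering.
- **Synthetic fixtures.** A generator plants residue contacts at exact
  distances in toy two-protein PDB ensembles, so every stage is testable
  offline against known ground truth.

## Worked example

```r
library(dockzones)

# a 4-pose synthetic ensemble with known planted contacts
sp <- ensemble_spec(n_configs = 4, residues_per_unit = 8, plants = data.frame(
  config        = c(1,   1,   2,   3,   3,   4),
  ref_resnum    = c(2,   5,   2,   2,   5,   7),
  paired_resnum = c(3,   6,   3,   3,   6,   8),
  distance      = c(3.8, 4.6, 3.8, 3.9, 4.6, 2.4)))
gen <- generate_ensemble(sp, out_dir = "demo")

ens <- read_ensemble(gen$files, ref_chains = "A", paired_chains = "B",
                     primary = gen$files[1])
#> docking ensemble: n = 4, primary = conf_001

build_frequency_matrix(ens)$cells
#>   row_key col_key count
#> 1     A:2     B:3     3
#> 2     A:5     B:6     2
```

Cell (A:2, B:3) is realized in 3 of 4 poses (pose 4's plant at 2.4 Å is a
collision, not a contact). Filtering on that pair keeps exactly those
three:

```r
names(filter_configurations(ens, pair_selection("A:2", "B:3"))$configurations)
#> [1] "conf_001" "conf_002" "conf_003"

zones <- compute_zones(ens)
rank_configurations(ens, zones[["conf_001"]], zones)
#>   config_id residue_matches pair_matches missing_pairs score rank is_primary
#> 1  conf_001               2            2             0    10    1       TRUE
#> 2  conf_003               2            2             0    10    2      FALSE
#> 3  conf_002               1            1             1     4    3      FALSE
#> 4  conf_004               0            0             2    -2    4      FALSE
```

conf_003 reproduces both primary pairs (2 + 4·2 − 0 = 10); conf_002 misses
one (1 + 4 − 1 = 4); conf_004 shares nothing (0 + 0 − 2 = −2). The closest
pair of the primary zone and an open-book opening:

```r
closest_pair(zones[["conf_001"]])[, c("ref_key", "paired_key", "distance")]
#>   ref_key paired_key distance
#> 1     A:2        B:3      3.8

ob <- open_book_transforms(ens$configurations[["conf_001"]], zones[["conf_001"]])
round(ob$normal_ref_after, 3)
#> [1] 0 0 1          # the contact zone now faces the viewer (+z)
```

The whole workflow (contacts → matrix → filter → rank → list views →
exploded layout → open book, all artifacts on disk) is one call:

```r
run_pipeline(run_config(gen$files, primary = gen$files[1], out_dir = "out",
                        filter_pairs = "A:2-B:3", filter_d_max = 4))
```

## Command line

```sh
DZ=$(Rscript -e 'cat(system.file("cli/dockzones.R", package="dockzones"))')
Rscript $DZ synth --n-configs 10 --seed 7 --out demo_in
Rscript $DZ matrix demo_in/conf_*.pdb --ref-chains A --paired-chains B --out demo_out
Rscript $DZ filter demo_in/conf_*.pdb --pair A:2-B:3 --filter-dmax 4
Rscript $DZ run demo_in/conf_*.pdb --primary demo_in/conf_001.pdb --out demo_out
```

Subcommands: `synth contacts matrix filter rank listview explode openbook
run`; shared flags `--dmin --dmax --ref-chains --paired-chains --primary
--out --seed -v`.

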