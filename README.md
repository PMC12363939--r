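# structforge

Atom-level structure sanitization, featurization and evaluation for
biomolecular modelling in R.

Machine-learning models of biomolecular structure are only as good as the
data fed into them, and experimental structure files are full of edge cases:
alternate conformations with partial occupancies, leaving groups still
present on polymerized residues, missing or wrong formal charges, covalent
ligand attachments hidden in `struct_conn` records, overlapping ligand
copies at crystallographic symmetry centers, and unresolved regions with no
coordinates at all. `structforge` gives R users a single atom-level
representation for structures, a library of composable sanitization
transforms for these cases, the derived features a chirality-aware
structure predictor needs, and the evaluation metrics used to score
predictions — all runnable on built-in synthetic fixtures with no
downloads.

The toolkit is aimed at structural bioinformaticians preparing training or
evaluation data, and at method developers who need reference
implementations of the metrics below.

## What is inside

* **Core model** — an `AtomTable` (one row per atom, stable integer
  `atom_uid`s, plus a typed bond table) wrapped in a `PipelineState`;
  transforms are registered by name, composed into pipelines, serialized
  to/from YAML, and applied with per-stage validation and logging. One
  integer seed governs every stochastic step.
* **Structure I/O** — mmCIF read/write (`atom_site`, `struct_conn`,
  `entity_poly_seq`), CCD-style component dictionaries (`chem_comp_atom` /
  `chem_comp_bond`, with ideal coordinates and leaving-atom flags), and
  read-only PDB support.
* **Sanitization** — altloc resolution, linkage-conditional leaving-group
  removal, covalent-link detection (records first, optional distance
  inference), bond-order correction after nucleophilic addition,
  formal-charge assignment, symmetry-ligand deduplication and
  ideal-coordinate imputation of missing atoms.
* **Chirality** — each stereocenter is encoded by the signed angle

  `theta = asin( u1 . (u2 x u3) / |u2 x u3| )`

  where `u1, u2, u3` are unit vectors from the center to its three ranked
  heavy neighbors. `|theta| = asin(sqrt(2/3)) ~ 0.9553 rad` at ideal
  tetrahedral geometry; the sign flips under reflection and is invariant
  under rotation. The squared error against the signed ideal angle yields
  an analytic per-atom gradient feature, mirror-inversion augmentation is
  provided at a configurable rate (reference: 2% of examples), and
  chiral-center accuracy is reported as a mean over clusters of
  per-molecule percentages.
* **Distance templating** — all-by-all pairwise-distance conditioning
  features over a selection, one-hot distance binning, and an lDDT-style
  adherence score over the constrained pairs.
* **Reference conformers** — components are rebuilt from their graph,
  embedded by seeded distance geometry, and minimized with MMFF94 (UFF
  fallback) through a bundled RDKit helper; energies in kJ/mol.
* **Disorder extension** — unresolved regions grow ideal-geometry extended
  backbones (phi = psi = omega = 180 by default) from the nearest resolved
  anchor via an internal-coordinate (NeRF) builder, with seeded clash
  avoidance.
* **Metrics** — all-atom lDDT (radius 15 A, thresholds 0.5/1/2/4 A),
  interface lDDT, proper-rotation backbone RMSD, Shrake–Rupley SASA,
  relative accessibility (RASA) over residue regions, greedy 40%-identity
  sequence clustering, exact comp_id clustering, and cluster-mean
  reporting.
* **Fixtures** — a built-in ~10-component dictionary (amino acids, water,
  acetate, ethanol, a covalent binder, a ketone, a three-stereocenter
  ligand) constructed in code with ideal coordinates and leaving flags,
  toy-peptide and pathological-structure generators, and seeded coordinate
  perturbation.

## Worked example

```r
library(structforge)

# a pathological structure: two overlapping half-occupancy ligand copies
fx <- make_pathological_cif("symmetry_ligand", dir = tempdir(), seed = 1)
st <- read_mmcif(fx$structure,
                 components = read_component_dictionary(fx$components))
st$table
#> AtomTable: 24 atoms (24 resolved), 0 bonds, 2 chain(s)

out <- apply_pipeline(sanitize_pipeline(components = fx$components), st)
out$table
#> AtomTable: 20 atoms (20 resolved), 18 bonds, 2 chain(s)
tail(unlist(out$log), 2)
#> [1] "deduplicate_symmetry_ligands: 24 -> 20 atoms"
#> [2] "impute_missing: 20 -> 20 atoms"
```

One acetate copy (4 heavy atoms) is gone; the kept copy is the
higher-occupancy one, and a second sanitization pass changes nothing.

Chirality of a mixed L/D peptide:

```r
tp <- make_toy_peptide("AACS", d_positions = 2)
acc <- chiral_center_accuracy(tp$state, tp$state, dict = tp$dict)
acc$overall
#> [1] 1
chiral_center_accuracy(invert_structure(tp$state), tp$state,
                       dict = tp$dict)$overall
#> [1] 0
```

A perfect prediction scores 1; the mirror image gets every center wrong.

Reference conformer with energies:

```r
dict <- builtin_components()
generate_reference_conformer(dict$ETH, seed = 7)
#> ConformerResult ETH: 9 atoms, MMFF94, E 18.25 -> -5.59 kJ/mol (converged)
```

## Command line

A thin CLI over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/structforge.R",
                                       package = "structforge"))')" \
    sanitize in.cif -o out.cif --components dict.cif --report report.json
```

Subcommands: `ingest`, `sanitize`, `eval lddt|ilddt|rmsd|chiral`,
`template`, `extend-disorder`, `conformer`, `fixtures`, `pipeline`.

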