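---
title: "Models and methods behind structforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind structforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structforge)
```

`structforge` prepares biomolecular structures for modelling workflows:
one shared atom-level table, composable sanitization transforms, chirality
and distance-conditioning features, reference conformers, extended-backbone
completion of unresolved regions, and the metrics used to score predicted
structures. This vignette explains the models behind each piece, the
parameters that matter, the numerical choices, and what the bundled
synthetic fixtures do and do not establish.

## The atom-level representation

Everything operates on an `AtomTable`: a data frame with one row per atom
and a typed bond table. Three design choices shape it:

* **Stable surrogate identity.** Each atom receives an integer `atom_uid`
  at ingestion that is never reused. Transforms may delete or reorder atoms
  freely; bonds and derived features reference atoms by uid, never by row
  position, so no transform can silently invalidate another's output.
* **One internal coordinate system.** `res_index` follows the
  label-sequence numbering (1-based); author numbering is retained as an
  annotation. Unresolved polymer residues — present in the sequence but
  absent from the coordinate records — are materialized as placeholder
  atoms with `is_resolved = FALSE` and missing coordinates, so later
  stages (imputation, disorder extension) have slots to fill.
* **Flat, collision-checked extras.** Derived features live in a
  string-keyed map; each registered transform declares the keys it reads
  and writes, and two steps writing one key is a configuration error, not
  a silent overwrite. Precedence rules hide bugs; an error surfaces them.

Pipelines are ordered lists of named transforms with scalar parameters,
serializable to YAML. A single integer seed governs a run; each stochastic
transform derives its own stream by hashing (seed, transform name), so
runs are bit-reproducible and adding a transform does not shift the
stream of another.

## Sanitization transforms

Each rule is a `PipelineState -> PipelineState` function; every deletion is
attributed to its rule in the per-stage log, and each rule is idempotent.

* **Altlocs.** For each atom modelled in several alternate locations, the
  highest-occupancy copy is kept (tie: lexicographically smallest altloc
  id), its altloc cleared, its occupancy preserved. Keep-highest matches
  single-conformer usage; ensemble splitting is out of scope. The
  tie-break is arbitrary but fixed and documented.
* **Leaving groups.** Removal is *linkage-conditional*, mirroring
  component-dictionary semantics: only atoms flagged as leaving that are
  attached (through the component's own bond graph, expanding through
  connected leaving atoms and their hydrogens) to an atom that actually
  participates in an inter-residue covalent bond are deleted. A terminal
  residue therefore keeps its OXT; a polymerized one loses it.
* **Covalent links.** `struct_conn` records are authoritative: `covale`
  and `disulf` rows become single bonds (provenance `struct_conn`);
  `metalc` rows become annotations, because dative metal contacts are not
  covalent bonds for valence bookkeeping. Distance-based inference
  (ligand/polymer heavy-atom pairs within the covalent-radius sum plus
  0.4 angstrom slack, both with free valence) is available but **off by
  default** — in crowded binding sites it produces false positives, and a
  deposited record beats a guess. Polymer backbone bonds between
  consecutive residues are attached from sequence adjacency and carry
  provenance `inferred`.
* **Bond orders after nucleophilic addition.** A new covalent link can
  push an atom over its allowed valence — the classic case is addition to
  a carbonyl carbon. For each atom whose bond-order sum plus implicit
  hydrogens exceeds its maximum allowed valence, one double bond is
  demoted to single, preferring a C=O partner, then C=N, then any other:
  nucleophilic addition chemistry overwhelmingly targets carbonyls. An
  over-valent atom with no demotable double bond is an error — it signals
  an upstream chemistry problem rather than something to patch silently.
* **Formal charges.** `charge = round(bond-order sum + implicit H) -
  closest allowed valence`, with aromatic bonds counting 1.5 and implicit
  hydrogens taken from the component definition (leaving-flagged hydrogens
  are not counted at atoms that already carry an inter-residue bond).
  Hypervalent elements (S, P, Se) list all allowed valences and the
  nearest is used, so sulfones do not acquire spurious charges. A
  carboxylate oxygen with one single bond gets -1; a tetravalent nitrogen
  +1; atoms matching an allowed valence get 0.
* **Symmetry-center ligands.** Among non-polymer residues with the same
  component code, mean occupancy at most 0.5, and centroids within 1
  angstrom, one copy is kept (highest occupancy, then lowest residue
  index). The 0.5 occupancy threshold and the tolerance are configurable:
  deposited conventions vary and neither value is standardized.
* **Imputation.** A residue with at least three resolved heavy atoms
  shared with its component's ideal coordinates gets its missing heavy
  atoms placed by least-squares rigid superposition (proper rotation only)
  of the ideal fragment onto the resolved atoms. Placed atoms stay
  `is_resolved = FALSE` and are listed in `extras$imputed`: imputed
  coordinates are a modelling convenience, not observations. Fewer than
  three shared atoms leaves the pose underdetermined, so such residues are
  reported and skipped.

## The chirality model

A tetrahedral stereocenter is encoded by one signed scalar. With
$\mathbf{u}_1, \mathbf{u}_2, \mathbf{u}_3$ the unit vectors from the
center to its three ranked heavy neighbors,

$$\theta = \arcsin\!\left(\frac{\mathbf{u}_1 \cdot (\mathbf{u}_2 \times
\mathbf{u}_3)}{\lVert \mathbf{u}_2 \times \mathbf{u}_3 \rVert}\right),$$

the signed angle between the first substituent and the plane of the other
two. $\theta$ is invariant under rotation and translation, antisymmetric
under reflection, and equals $\pm\arcsin\sqrt{2/3} \approx \pm 0.9553$
rad ($54.74^\circ$) at perfect tetrahedral geometry — the unique ideal
magnitude under this definition, which is why the package fixes it rather
than exposing it as a parameter.

**Neighbor ranking.** Any fixed ordering of the three neighbors yields a
consistent sign convention; what matters is that the feature and the
accuracy metric use the same one. The package ranks deterministically by
(atomic number, then the sum of the neighbor's own neighbors' atomic
numbers, then atom name). This reproduces the familiar behaviour of
priority rules — including the cysteine quirk, where the sulfur-bearing
side chain outranks the carbonyl carbon, flipping the CA sign convention
relative to the other amino acids while remaining internally consistent.
Centers whose heavy branches tie under the rule are reported as ambiguous
and excluded rather than ordered arbitrarily. An implicit hydrogen counts
as the fourth branch but is never among the ranked neighbors, since
heavy-atom-only coordinate sets are the common case.

**Gradient feature.** The per-atom feature is the analytic gradient of
$E = (\theta - \theta_0)^2$ with respect to the four atom positions,
where $\theta_0$ carries the reference sign. It vanishes exactly at the
ideal geometry, the four vectors sum to zero (translation invariance),
and the tests verify it against a fourth-order central-difference oracle
at step $10^{-4}$ angstrom to within $10^{-5}$ relative error in the
Frobenius norm — the stencil order is chosen so that finite-difference
truncation, not the analytic expression, never limits the comparison.

**Inversion augmentation.** `sample_inversion_augmentation` mirrors the
whole structure (x to -x) with a seeded Bernoulli draw, default
probability 0.02 — the reference rate of one mirrored example per fifty.
Whole-structure mirroring is the only physically consistent choice:
mirroring individual centers would tear covalent geometry apart.

**Accuracy metric.** A center counts as correct when the sign of its
angle in the prediction matches the sign computed from the *deposited*
reference geometry (so a D-residue must be predicted as D; the
ideal-coordinate sign is only a fallback when the reference lacks
coordinates). Per-molecule percentages are averaged within clusters and
the headline number is the unweighted mean across clusters, so one
heavily-represented ligand cannot dominate.

## Distance templating

`build_distance_template` records the pairwise distances of a selection
(every off-diagonal pair in `all_pairs` mode, or listed pairs in
`explicit` mode) with a boolean mask. Templates are functions of
inter-atomic distances only, hence invariant under rigid motion of the
structure. `template_adherence` scores a prediction over the masked pairs
with the lDDT threshold ladder (0.5/1/2/4 angstrom): reusing the lDDT
convention makes "ligand-only" adherence directly comparable to
lDDT-style reports, and no separate adherence statistic needs defining.
Binning for discrete conditioning uses half-open `[lo, hi)` intervals —
an exact-edge distance goes to the upper bin — with default edges 3.25 to
50.75 angstrom in 1.25 steps, a config default rather than anything
load-bearing.

## Reference conformers

`generate_reference_conformer` rebuilds each component from its graph —
atoms, bonds, formal charges — never from deposited coordinates: the point
of a reference conformer is an independent, physically plausible geometry.
Stereo descriptors are perceived from the component's ideal coordinates,
fresh coordinates are embedded by seeded distance geometry (ETKDG), and
the conformer is relaxed with MMFF94, falling back to UFF when MMFF94
parameters are missing; the backend is a bundled RDKit helper script, the
field-standard toolkit for this step. Energies are converted to kJ/mol.
The minimizer cap (2000 iterations) is exposed. Generated conformers are
checked against the component's ideal-coordinate chirality through the
chirality module and mirrored when the embedding picked the opposite
enantiomer.

The force field sees only the annotated graph, which is precisely why
sanitization quality shows up in conformer energies: the test suite
includes a deliberately mis-annotated acetate (carboxylate oxygen +1
instead of -1) whose minimized energy exceeds the correct twin's. Only
the direction of that gap is asserted — its magnitude depends on force
field details that are not this package's contract.

## Extended backbones for unresolved regions

Experimental structures routinely omit disordered regions entirely, and
models trained only on resolved coordinates learn to pack everything
compactly. The disorder extension builder fills unresolved residue runs
with ideal-geometry backbones so that exposure statistics become
computable: bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329 angstrom,
angles N-CA-C 111.0, CA-C-N 117.2, C-N-CA 121.7 degrees, and torsions
phi = psi = omega = 180 degrees by default — the maximally extended
conformation, configurable to strand values, since "extended" is a
modelling choice rather than a measured quantity.

Placement is sequential NeRF: each atom from a (distance, angle, torsion)
triple in the frame of the previous three. Internal gaps and C-terminal
tails grow forward from the residue before the gap; N-terminal tails grow
backward from the first resolved residue, along the reversed chain with
the two backbone lengths and the two peptide-unit angles swapped (the
geometry of a peptide walked C-to-N). Internal gaps are *not* closed onto
the far anchor: loop closure is a hard constrained-optimization problem,
and the purpose here is exposure statistics, not gap-spanning geometry.
If a placed atom falls within 2 angstrom of a resolved heavy atom
(excluding the covalently bonded anchor residue), phi/psi are perturbed
by a seeded +/-20 degrees and the region rebuilt, up to 10 retries, the
least-clashing attempt winning. Resolved atoms are never moved, and
re-running the builder on an extended structure is the identity.

## Metrics

* **lDDT** is computed superposition-free on heavy atoms, excluding
  intra-residue pairs, with inclusion radius 15 angstrom and thresholds
  0.5/1/2/4 angstrom — the standard published parameterization, exposed
  as arguments. Per-pair score: fraction of thresholds within which the
  predicted distance deviation falls; per-atom: mean over that atom's
  pairs; global: mean over atoms with at least one pair. Zero reference
  pairs raises an error, never NaN. The implementation is verified to
  match a naive double-loop enumeration exactly on randomly generated
  structures of up to 200 atoms.
* **Interface lDDT** is lDDT restricted to pairs spanning two disjoint
  groups, symmetric in the groups; "no cross-group pair within the
  radius" is a distinct `no interface` error rather than a zero, because
  the two mean different things. No symmetry correction over alternative
  chain mappings is applied in this version — a known gap relative to
  benchmark-grade scoring of symmetric complexes.
* **Backbone RMSD** uses least-squares superposition with proper rotations
  only (via bio3d), so a mirrored chiral structure scores strictly
  positive.
* **SASA / RASA** is Shrake–Rupley sphere sampling with 960 deterministic
  golden-spiral points per atom, probe 1.4 angstrom, Bondi radii.
  Per-residue relative accessibility divides by the extended
  Gly-X-Gly tripeptide maxima (Tien et al. 2013 theoretical values) and
  clips to [0, 1], since sampled SASA can marginally exceed the tabulated
  maximum.
* **Clustering.** Non-polymers partition by exact component code. Polymer
  sequences cluster greedily: by descending length (ties by id), each
  member joins the first cluster whose representative reaches 40%
  global-alignment identity, with identity defined as matches divided by
  full alignment length *including gaps* — the stricter and
  order-deterministic denominator. `clustered_mean` averages within
  clusters first, then across clusters, unweighted.

## The synthetic fixture suite

All fixtures are generated by code from (specification, seed) and
regenerate bit-identically. The mini component dictionary (~10 components
with ideal coordinates, kekulized orders, leaving flags) is built from
internal coordinates; amino-acid CB placement uses an improper dihedral of
-122.6 degrees, which yields the standard L configuration under the
package's sign convention, and D-residues are produced by mirroring the
side chain through the local N-CA-C plane — keeping the dictionary small
while exercising the geometry path. Each pathological fixture is minimal:
exactly one sanitization rule must fire, and a machine-readable
expectation file states which atoms change.

What passing on these fixtures shows: the rules fire under the exact
conditions they claim, compose idempotently, and preserve referential
integrity. What it does not show: robustness to the full heterogeneity of
deposited data — multi-block CIFs, exotic components, inconsistent
annotations at scale. The fixtures emulate the *categories* of edge case,
not their long tail.

Problem sizes in the tests and the acceptance script (peptides of 8–14
residues, random structures of 20–200 atoms, 50 oracle comparisons,
10,000 augmentation draws) were chosen so the complete suite exercises
every code path in well under a minute while keeping the statistical
checks sharp — e.g. the augmentation count test uses a 3-sigma band
around the expected 200 inversions.

## Known limitations

* mmCIF coverage is the category subset the transforms need; assemblies
  and crystallographic symmetry expansion are not performed — symmetry
  ligand handling operates on deposited coordinates by design.
* Aromaticity is taken from component declarations; no perception.
* Protonation states and tautomers are out of scope.
* E/Z double-bond stereochemistry and atropisomerism are not modelled;
  the chirality machinery covers tetrahedral centers.
* Sequence clustering is greedy with a single-linkage-to-representative
  rule; it is deterministic and fast, not a replacement for dedicated
  clustering tools at database scale.
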