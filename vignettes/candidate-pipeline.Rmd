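---
title: "Ranking PROTAC ternary-complex candidates: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking PROTAC ternary-complex candidates: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protern)
```

## The problem

A PROTAC is a heterobifunctional degrader: an *anchor* ligand that binds an
E3 ubiquitin ligase, a *warhead* ligand that binds a protein of interest
(POI), and a chemical linker joining them. Degradation requires a productive
*ternary complex* — E3–PROTAC–POI — and predicting its geometry in silico is
the bottleneck of rational PROTAC design. A common strategy is to first
predict the protein–protein complex (PPC) of the E3+anchor and POI+warhead
units by rigid docking, and only then dock the PROTAC into the selected
PPCs. The docking stage produces thousands of candidate poses, nearly all of
them wrong; the scientific content of this package is everything that
happens *between* docking and PROTAC placement: filtering, local grid
refinement, clustering, and consensus ranking of rigid candidate poses.

protern implements that middle layer as pure functions over explicit domain
objects (structures, poses, score tables, contact sets, clusters), with an
external-tool adapter at each point where the published workflow calls a
third-party scorer, and a complete DockQ evaluation layer to measure what
the pipeline achieves.

## Pipeline stages and their parameters

1. **Preparation.** Input PDB structures are stripped of waters and
   hydrogens (`prepare_structure()`); all scoring is heavy-atom only.
   Moieties (anchor/warhead) are tagged as the HETATM atoms of each
   structure by default, since each input carries exactly one bound ligand.
2. **Seed poses.** Rigid candidate placements of the mobile protein come
   from an external docking program (imported as transform tables or pose
   PDBs) or from the synthetic generator. The study workflow uses 5000
   seeds per case; every stage here is agnostic to that count.
3. **Rough ligand-based filtration.** Poses whose anchor–warhead
   mass-centre distance falls outside **3–20 Å** (both boundaries
   inclusive) are discarded. The window deliberately over-covers the
   8–15 Å range observed in earlier work so that borderline linkers are
   not lost; it is the cheapest filter and runs first.
4. **Sequential protein-based filtration.** Four score components run in a
   fixed, fastest-first order — clash *stability*, *SASA*,
   Lennard-Jones *energy*, interaction *z-score* — and each stage retains
   the top fraction (default **0.75**) of survivors by that component.
   The published workflow applies absolute per-stage thresholds that are
   specified only in supplementary material; retention fractions preserve
   the sequential architecture without inventing those constants, and any
   absolute rule can be injected as a custom provider.
5. **Rank aggregation.** Survivors are ranked by SASA and by interface
   quality, and the two rank vectors are combined by their mean
   (two-component Borda with average-rank ties, ties in the final order
   broken by pose id). Larger SASA is *better* here, which is unusual and
   worth explaining: a ternary candidate must leave a gap wide enough for
   the PROTAC linker, and a larger complex surface area is a direct proxy
   for that gap. The quality score guards against the degenerate way to
   maximise SASA (no interface at all). The top **200** poses proceed.
6. **Translational grid.** Each selected pose is translated over the full
   Cartesian lattice **±4.5 Å at 1.5 Å resolution** per axis (7³ = 343
   children per pose), then re-filtered and re-ranked; the top **200**
   translated poses proceed.
7. **Rotational grid.** Each survivor is rotated over **±15° at 5°
   resolution** per Euler axis (again 343 children), about the mass centre
   of the mobile protein *in its current pose*, and re-filtered.
8. **Clustering and cluster filtration.** Interface contact sets (residue
   pairs with any heavy-atom pair within **5 Å**) feed
   fraction-of-common-contacts (FCC) clustering at similarity **0.5** with
   minimum cluster size **2**; unclustered poses are eliminated. The
   lowest-energy **25%** of clustered poses are marked, clusters holding
   none of them are eliminated, survivors are re-clustered, and clusters
   are ranked by aggregating their maximum member SASA and maximum member
   quality.

Stage order, keep-counts, window, grids, FCC parameters and the energy
fraction are all held in `pipeline_config()` with the defaults above.

## Score components: what is built in and what is delegated

The published workflow delegates scoring to external programs (an MD-based
stability score, Open Babel's UFF `obenergy`, PIZSA, VoroMQA). protern keeps
that architecture — each component is a pluggable provider — but ships
self-contained surrogates so the whole pipeline runs and is testable with
no third-party binaries:

* **stability** — minus the count of inter-protein heavy-atom pairs closer
  than 2.5 Å (a pure clash penalty; 0 is best).
* **sasa** — Shrake–Rupley solvent-accessible surface area: 960
  deterministic golden-spiral test points per atom, probe 1.4 Å, Bondi
  van der Waals radii. The golden-spiral lattice makes the score exactly
  reproducible; the point count trades ≈0.5% discretisation error against
  time and is configurable.
* **energy** — inter-protein 12-6 Lennard-Jones sum with per-element UFF
  well depths and minimum-energy distances under geometric-mean
  combination, 8 Å pair cutoff. This is a documented surrogate for an
  `obenergy` UFF total, not a reimplementation of a full force field
  (no electrostatics, bonds or torsions — the inter-protein nonbonded term
  is the part that varies between rigid poses).
* **pizsa (interaction z-score)** — the population z-score of a pose's
  interface contact count within the current pose set. A degenerate set
  (zero variance) yields all zeros with a warning rather than an error.
* **quality** — the interface residue-contact count at 5 Å, a monotone
  stand-in for an external structure-quality assessor. It is documented as
  *not* VoroMQA; swapping in the real tool via `external_provider()`
  changes values but not the score-record contract.

Because aggregation is rank-based, any provider that is strictly monotone
in the quantity it replaces yields the same downstream ordering — this is
the property the test suite leans on, and the reason surrogates are
scientifically safe for exercising the architecture (though obviously not
for ranking real candidates).

## Numerical and algorithmic choices

* **Euler convention.** Grid rotations use intrinsic x→y→z rotations,
  `R = Rz(psi) Ry(theta) Rx(phi)`, degrees. The source workflow does not
  state a convention; one is fixed and documented so grid rotations are
  exactly reproducible.
* **Rotation centre.** Rotational children pivot about the mass centre of
  the mobile protein in its translated pose (not the original seed
  centre), keeping children near the parent placement. This choice is
  configurable in effect by composing transforms directly.
* **FCC symmetrisation.** FCC is asymmetric
  (`|a∩b|/|a|`); the pairwise similarity used against the 0.5 criterion is
  the *minimum* of both directions — the conservative choice, available
  alternatives being `mean` and `max`. An empty contact set has
  similarity 0 (with a warning), never NaN.
* **Clustering.** Greedy leader (Taylor–Butina) clustering on the
  thresholded similarity graph, the standard companion algorithm of the
  FCC criterion. Determinism: the centre is the unassigned pose with the
  most unassigned neighbours, ties resolved to the lowest pose id.
* **Ceilings.** Every "top fraction" select uses `ceiling(fraction * n)`,
  so a non-empty input can never be emptied by a filter stage; an
  empty survivor set is a hard error naming the stage.
* **Ties.** All orderings break ties by pose id; two runs of the same
  configuration are byte-identical, which the test suite asserts on the
  written cluster tables.
* **Superposition.** RMSDs use Kabsch superposition via SVD with the
  determinant correction; backbone = N, CA, C, O. DockQ uses the method's
  constants (fnat contacts 5 Å, interface 10 Å, scaling 1.5 Å / 8.5 Å;
  classes Incorrect < 0.23 ≤ Acceptable < 0.49 ≤ Medium < 0.80 ≤ High).

## The synthetic generator

`make_toy_complex()` builds two pseudo-proteins — poly-alanine-like N/CA/C/O/CB
backbones on an ideal-helix lattice (radius 2.3 Å, rise 1.5 Å per residue,
50° turn, 12 residues by default) — docked face-to-face 10.4 Å apart, which
yields a clash-free native interface with ≥10 residue contacts at 5 Å. Each
protein carries a 3-atom hetero moiety placed so the native anchor–warhead
distance (~4.7 Å) sits inside the rough-filter window. `make_decoys()` draws
poses around the native placement: uniform random rotation axes with angles
up to `max_rotation` (default 10°) about the mobile mass centre, translations
up to `max_translation` (default 3 Å), plus a configurable fraction of
"unpromising" decoys displaced 30–40 Å so they fail the rough filter by
construction. Decoy 1 is always the exact native placement. All randomness
lives in this generator (single RNG stream per seed, caller state restored);
pipeline stages are deterministic functions of their inputs.

What the generator does *not* emulate: real docking-score landscapes,
side-chain chemistry, linker flexibility, or the contact topology of real
PPIs. Passing tests therefore demonstrate that the machinery — filters,
grids, clustering, ranking, evaluation — is correct and deterministic, not
that the surrogate scores would rank real ternary candidates as the
external tools do.

## Problem sizes used by the tests

The bundled benchmark statistics recompute in milliseconds from fixture
tables. Geometry, scoring and clustering tests run on the default 12-residue
toy complex. End-to-end pipeline tests use 30–40 decoys, keep-counts of
6–8, a reduced ±1.5 Å / ±5° grid and 240 SASA points per atom, which runs
the full funnel in a few seconds while exercising every stage; the grid
recovery property scans the full 343 × 343 transform product through a
closed-form RMSD expansion. All defaults in exported functions remain the
study settings described above.

## Known limitations

* Builtin score surrogates are monotone proxies, not the external
  statistical potentials; absolute score values are not comparable to the
  external tools' outputs.
* Rigid-body only: no side-chain repacking, backbone flexibility, or
  PROTAC conformer handling (the external docking adapter passes
  structures through untouched).
* The benchmark tables are bundled as printed; the headline per-case DockQ
  values are fixture data, not desk-recomputable from structures without
  the original inputs and docking program.
* Single-model PDB inputs only; mmCIF and multi-model NMR files are out of
  scope.
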