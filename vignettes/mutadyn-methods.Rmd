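---
title: "Methods: comparing the structural dynamics of wild-type and mutant proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the structural dynamics of wild-type and mutant proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutadyn)
```

## The problem this package addresses

Point mutations often act on a protein's function not by touching a binding
residue but by re-shaping the dynamics of regions far from the mutated site.
Interleukin-18 (IL-18) is the motivating system: substitutions at the
non-binding residue Thr63, coupled with the binding-region mutation E6K,
change the flexibility and conformation of the receptor-binding loops. Given
molecular-dynamics (MD) trajectories of a wild-type protein and a set of
point mutants, `mutadyn` computes the standard post-processing readouts used
to judge such effects and condenses them into a per-mutant, per-region
change/no-change table:

1. **Equilibration QC** — per-frame Cα RMSD after least-squares (Kabsch)
   superposition, on an equilibration window of the run.
2. **Conformational change** — the *distance pattern*: for a focal residue
   (here residue 63), the frame-averaged distance between its backbone
   centre of geometry and every other residue's; mutant minus wild-type
   differences localise conformational change.
3. **Flexibility** — per-residue Cα RMSF about the iteratively refined mean
   structure.
4. **Hydrogen-bond relaxation** — geometric H-bond detection per frame,
   aggregated into occupancies; wild-type bonds above 80% occupancy are
   *conventional* bonds whose relaxation is tracked in the mutants.
5. **Classification** — a region shows a conformation change when any
   residue's distance-pattern difference exceeds 2 Å (strictly), and an
   occupancy change when any conventional bond assigned to it moves by more
   than 20 percentage points (strictly).

Sequence-level helpers (pairwise global-alignment identity, Eisenberg-scale
hydrophobicity sums) support the accompanying sequence analyses.

## Input conventions

Trajectories are multi-model PDB files sharing one topology: MODEL/ENDMDL
blocks delimit frames; a file without MODEL records is a one-frame
trajectory. Binary MD formats (DCD/XTC) are intentionally out of scope: the
multi-model dialect is human-readable, diff-able and sufficient at the scale
this package targets; a binary reader is an extension point, not a feature.
Residue numbers follow the **mature-sequence** convention (1-based after
signal-peptide cleavage), so "E6" and "T63" mean positions 6 and 63 of the
mature chain; `read_trajectory(offset =)` remaps author numbering at load.
H-bond analysis requires protonated input — structures without hydrogens
fail fast with an instruction rather than returning an empty table.
Solute-only trajectories are assumed; water-mediated bridges are not
detected.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| H-bond distance cutoff | 3.0 | Å | donor-heavy to acceptor-heavy atom |
| H-bond angle cutoff | 135 | degrees | donor–H–acceptor, vertex at H |
| conventional-bond threshold | 80 | % occupancy | strict `>`, on the wild type |
| conformation threshold | 2 | Å | strict `>`, region max of the pattern difference |
| occupancy-change threshold | 20 | percentage points | strict `>`, per conventional bond |
| equilibration discard | 0.6 | fraction of frames | head of the run dropped |
| snapshots kept | 1500 | frames | equidistant from the remainder |
| QC acceptance | 4 | Å | bound on the window-mean Cα RMSD |

The equilibration defaults mirror the convention of discarding the first
90 ns of a 150 ns production run and analysing 1500 equidistant snapshots of
the final 60 ns; the windowing is fraction-based so it applies at any frame
count.

### Conventions the source analysis left open

Several numerical conventions are not fully pinned down by the analysis this
package operationalises; the choices here are explicit and tested:

* **H-bond distance is donor-heavy to acceptor-heavy**, not hydrogen to
  acceptor — the default convention of the standard trajectory-analysis
  tools whose "default setting" the 3.0 Å / 135° cutoffs quote.
* **Boundary values count as bonded**: distance equal to the cutoff and
  angle equal to the cutoff are both accepted (`<=` / `>=`). By contrast the
  classification thresholds are **strict** ("more than 2 Å", "more than
  20%"): a 2.0 Å change or a 20.0-point occupancy change is *no* change.
* **Bond identity** is the (donor heavy atom, hydrogen, acceptor heavy atom)
  triplet; one donor may bond several acceptors in a frame (no exclusivity),
  matching naive geometric counting. Bonds are displayed acceptor-first as
  `Ile99@O-Thr63@HG1`.
* **Centre of geometry** is the unweighted mean of the three backbone atoms
  N, CA, C — no mass weighting, carbonyl O excluded.
* **The distance pattern averages per-frame distances** (mean of distances),
  not the distance between mean structures. Frame averaging is robust to
  fluctuation and consistent with occupancy-style aggregation; whether the
  original figures were frame-averaged or single-snapshot is not stated, so
  this choice is flagged prominently for users comparing against plots.
  Distances are internal coordinates, so the pattern needs no superposition
  and is rigid-motion invariant (property-tested).
* **RMSF reference = iterative mean structure** (two superposition passes
  starting from the first frame) rather than the first frame itself:
  standard practice that removes reference-choice bias.
* **Region aggregation uses the maximum** |Δd| over region residues — "any
  change of more than 2 Å" read as an existential quantifier, not a mean.
* **Bond-to-region assignment**: a bond belongs to every scored region that
  contains its donor or acceptor residue; bonds matching none are reported
  under `other` but never classified. With the shipped IL-18 region table
  this reproduces the convention that binding site III carries no scored
  conventional bonds.
* **Alignment scoring** defaults to BLOSUM62 with affine gaps (open 10,
  extend 0.5, a gap of length L costing 10 + 0.5 L), the EMBOSS-needle-like
  convention, since the original aligner is unstated; identity values should
  therefore be compared with a ±0.5 percentage-point tolerance, and the
  denominator (alignment length vs shorter sequence) is selectable.

### The shipped IL-18 metadata

`il18_regions()` encodes binding site I (Glu31–Thr45 and Glu130–Phe134),
site II (Lys53–Met60), site III (Gly108–Lys112 and Asp142–Met150) and the
Glu85–Ile100 loop. The two β-sheets flanking site II (Thr45–Tyr52,
Ala61–Cys68) are a separate `site_II_sheets` entry rather than being folded
into site II, so the classified "site II" is exactly the Lys53–Met60 region
that the summary table scores. The loop is sometimes named Glu85–Ile99 and
sometimes Glu85–Ile100 in the source material; the table adopts 85–100 (the
form used by the summary-table and figure conventions). `il18_cavity63()`
lists Thr63 and its twelve cavity neighbours; Tyr52 is grouped hydrophilic
(the structural-figure grouping) although it is elsewhere listed as
hydrophobic — the hydrophobicity sum is unaffected by the grouping:

```{r cavity}
hydrophobicity_index(il18_cavity63()$residue)
```

The Eisenberg consensus scale is transcribed in `eisenberg_scale()` and
validated on load (20 entries, zero-mean normalisation at 2-decimal
precision).

## The synthetic-trajectory generator

`make_toy_protein()` + `make_trajectory()` stand in for the MD engine so
every pipeline stage is testable. The generator emulates an **equilibrated**
trajectory as statistical structure, not physics:

* per-residue isotropic Gaussian fluctuation (σ per coordinate, i.i.d.
  across atoms and frames) — the simplest model with a closed-form RMSF;
* planted rigid displacements of residue ranges, constant across frames (a
  changed conformation, not a transition — the analysed windows are
  equilibrated, so time-dependent switching is deliberately absent);
* planted donor–H–acceptor triplets set to an exact formation geometry in
  exactly `round(p · n_frames)` seeded frames and an exact broken geometry
  otherwise. The planted atoms override the noise, so boundary geometries
  (3.0 Å, 135°) are exact and never blurred;
* optional rigid-body drift, for superposition tests.

The toy chain is serine-like (N, H, CA, C, O, OG, HG per residue) with
residues spaced so that **no inter-residue pair satisfies the H-bond
criterion in the base conformation**: detected bonds on noise-free synthetic
trajectories are exactly the planted ones. Cα atoms lie on a gentle helix so
superposition is never degenerate.

What passing synthetic tests does *not* show: the generator has no force
field, no solvent, no anharmonicity, no correlated loop motion and no
helix–coil transitions. Recovery of planted effects demonstrates that the
*post-processing* is correct, not that any MD-derived number is reproduced.
The published occupancies and ~5 Å loop displacements each sit behind a
150 ns simulation of a homology-modelled structure and are not recomputable
at desk scale; where such values appear in the bundled study they are
**generator inputs**, not results.

### Closed-form RMSF and the finite-chain correction

With isotropic per-coordinate noise σ and no drift, the RMSF of every
residue converges to σ√3. At finite chain length the mean-structure
superposition absorbs the six rigid-body degrees of freedom of each frame's
noise: to first order the fit projects the 3N-dimensional noise onto the
orthogonal complement of the reference's rigid-motion subspace, giving

E[RMSF²ᵢ] = σ² (3 − tr Pᵢᵢ),  Σᵢ tr Pᵢᵢ = 6,

where P projects onto the span of the three translations and three
infinitesimal rotations of the reference Cα geometry. The test suite checks
every residue against this expectation within three delta-method standard
errors (SE(RMSF) ≈ √(6/n)·σ/(2√3)) — at 16 residues the correction is up to
~10% and entirely explains the deviation from σ√3; at 100 residues it is
below 2%. Chain sizes (16 for the per-residue check, 100 for the
convergence check) and frame counts (2000–5000) were fixed from this
analysis before the tests were first run.

## Numerical choices and degenerate inputs

* Kabsch superposition uses SVD with the determinant guard, always returning
  a proper rotation; fits with fewer than 3 selection atoms or collinear
  selections are refused as degenerate rather than silently returning a
  reflection-contaminated fit.
* Detection tolerances: 10⁻¹² Å² on the squared distance and 10⁻⁹ degrees on
  the angle, so exactly-planted boundary geometry is classified
  deterministically despite round-off; coincident atoms (undefined angle)
  are never reported as bonded.
* Equidistant snapshot selection uses `ceiling(i·m/k)`, which returns
  exactly `k` distinct frames whenever `k ≤ m` and reduces to the identity
  when `k = m`; if fewer frames remain than requested, all are returned with
  a warning.
* Occupancies are reported to one decimal place in outputs (matching the
  precision convention of the quantities they mirror); evidence columns
  round distances to 3 decimals.
* Tie-breaking in alignments follows the deterministic backtrack of the
  underlying dynamic program, so identical inputs always give identical
  alignments (the score, which the oracle tests check exhaustively, is
  unique regardless).

## The bundled synthetic study

The `analysis/` drivers generate a 157-residue toy stand-in for mature
IL-18 (250 frames; the first 60% discarded, 100 snapshots analysed — sizes
chosen so the whole study runs in about a minute) with a wild type whose
planted bond propensities mirror the published wild-type occupancies
(94.3%, 87.8%, 74.2%, 63.6%, 83.1% …), an E6K/T63A-like variant (site-I
loop moved 5 Å, site-III Asp142–Met150 loop 3.5 Å, site-I and lid bonds
broken) and a T63A-like variant (site-III Gly108–Lys112 loop moved only,
partial lid relaxation). Because planted formation frames are spread over
the whole run while occupancy is measured on the window, window occupancies
fluctuate around the planted propensities (hypergeometric sampling); a bond
planted at 83.1% can read 80.0% in a given window and drop out of the
strict conventional cut — an instructive borderline case that the drivers
report rather than hide. The classification verdicts recover the planted
region patterns: √ X √ / √ X √ for the coupled variant and X X √ / √ X √
for the single variant, the canonical coupled-vs-single effect signature.

## Known limitations

* No energetic or electrostatic H-bond scoring; purely geometric detection.
* No water-mediated bridges (solute-only input), no secondary-structure
  assignment, no PCA/clustering of trajectories, no binding-affinity or
  activity prediction.
* Pairwise identity only; multiple sequence alignment is out of scope.
* The cross-species identity check against full-length UniProt sequences
  requires one small download (`fetch_uniprot_fasta()`); the package bundles
  no third-party sequence data, so that comparison cannot run offline.
* Classification is purely mechanical from the thresholds; borderline rows
  that a human analyst might adjudicate with additional structural judgment
  are scored exactly as the thresholds dictate.
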