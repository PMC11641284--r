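# mutadyn

Comparative structural dynamics of a wild-type protein and its point
mutants, from multi-model PDB trajectories to a per-mutant effect table.

`mutadyn` is aimed at protein engineers and structural bioinformaticians who
post-process molecular-dynamics (MD) output to ask: *which binding regions
did this mutation actually change?* The motivating system is interleukin-18
(IL-18), where substitutions at the non-binding residue Thr63 coupled with
the binding-region mutation E6K re-shape the receptor-binding loops from a
distance. The package computes the standard readouts of that style of
analysis and condenses them into a change/no-change summary per mutant and
binding region.

## What it computes

For each variant trajectory (frames sharing one topology):

* **Kabsch superposition / RMSD** — per-frame Cα RMSD after least-squares
  fitting, for equilibration QC (window mean expected < 4 Å). The window
  convention discards the leading fraction of the run (default 0.6) and
  keeps `n` equidistant snapshots (default 1500).
* **RMSF** — per-residue Cα fluctuation about the 2-pass iterative mean
  structure: `RMSF_i = sqrt(mean_t |r_i(t) − ⟨r_i⟩|²)`.
* **Distance pattern** — for a focal residue f (residue 63 in IL-18), the
  frame-averaged distance `d_j = ⟨|g_f(t) − g_j(t)|⟩_t` between backbone
  (N, CA, C) centres of geometry; `Δd_j = d_j(mut) − d_j(WT)` localises
  conformational change.
* **H-bond occupancy** — a donor–H–acceptor triplet is bonded in a frame iff
  the donor–acceptor heavy-atom distance ≤ 3.0 Å and the D–H–A angle
  (vertex at H) ≥ 135°; occupancy is the percentage of frames bonded.
  Wild-type bonds with occupancy > 80% are *conventional* bonds.
* **Classification** — per region: conformation change iff
  `max_j |Δd_j| > 2 Å` (strict); occupancy change iff any conventional bond
  in the region moves by > 20 percentage points (strict; bonds absent from
  the mutant count as 0%).
* **Sequence tools** — Needleman–Wunsch global alignment (BLOSUM62, affine
  gaps 10/0.5) with percent identity, and Eisenberg-scale hydrophobicity
  sums (`hydrophobicity_index`).

A seeded synthetic-trajectory generator (`make_toy_protein`,
`make_trajectory`) plants per-residue fluctuation amplitudes, rigid loop
displacements and H-bond occupancies with exact geometry, so the whole
pipeline is testable without MD output. See the methods vignette
(`vignettes/mutadyn-methods.Rmd`) for every convention and its rationale.

## Worked example

```r
library(mutadyn)

# a 30-residue toy protein; wild type with one strong planted bond,
# "mutant" with a 4 A displaced loop and the bond broken
base <- make_toy_protein(30, seed = 5)
bond <- function(p) planted_hbond(list(6, "OG"), list(6, "HG"), list(7, "O"),
                                  occupancy = p)
wt  <- make_trajectory(base, 100, sigma = 0.15, hbonds = list(bond(0.95)), seed = 1)
mut <- make_trajectory(base, 100, sigma = 0.15, hbonds = list(bond(0.05)),
                       shifts = list(planted_shift(c(5, 9), c(-4, 0, 0))), seed = 2)

occupancy_table(wt)[1, c("label", "occupancy")]
#>            label occupancy
#> 1 Ser7@O-Ser6@HG        95

delta <- pattern_difference(distance_pattern(mut, 29), distance_pattern(wt, 29))
regions <- region_set(A = c(5L, 9L), B = c(13L, 17L))
classify_conformation(delta, regions)
#>   region max_abs_delta changed verdict
#> 1      A    4.01153362    TRUE       √
#> 2      B    0.02370919   FALSE       X
```

The planted 95% bond is read back exactly; the 4 Å planted displacement
registers only in region A. The bundled study under `analysis/` runs the
same machinery at IL-18 scale: numbered drivers generate a 157-residue
synthetic wild type whose planted bond propensities mirror the published
wild-type occupancies, plus an E6K/T63A-like and a T63A-like variant, then
emit QC, distance-pattern, RMSF and occupancy tables and the final summary
under `results/`:

```sh
Rscript analysis/01_simulate.R          # trajectories -> scratch/
Rscript analysis/02_qc_equilibration.R  # windowed RMSD QC
Rscript analysis/03_conformation_flexibility.R
Rscript analysis/04_hbonds.R
Rscript analysis/05_sequence_hydrophobicity.R
Rscript analysis/06_report.R            # per-variant verdict table
```

The final driver prints (√ = change vs wild type, X = no change):

```
 mutant conf_site_I conf_site_II conf_site_III occ_site_I occ_site_II occ_loop_85_100
  MUT_A           √            X             √          √           X               √
  MUT_B           X            X             √          √           X               √
```

— the coupled-variant signature (site I + III conformation change, site I +
lid-loop bond relaxation, site II untouched) and the single-variant
signature (site III only), recovered from the planted ground truth.

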