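# ensembleshift

Quantifies ligand-induced population shifts in protein conformational
ensembles, for structural biologists comparing apo and ligand-bound (or
wild-type and mutant) MD ensembles of the same protein.

## The statistic

Apo and liganded frames are pooled and clustered by fixed-radius RMSD
clustering (default radius 2.4 Å over Cα atoms): every frame lies within
the radius of its cluster centroid. With `a_k` apo and `l_k` liganded
frames in cluster `k`, the cluster is **mixed** when

    min(a_k, l_k) >= 0.05 * max(a_k, l_k)

and the **overlap fraction** is the fraction of apo frames in mixed
clusters:

    phi = sum_{k in mixed} a_k / sum_k a_k   in [0, 1]

`phi = 0` means ligand binding eliminated every apo conformation (a
complete ensemble shift); `phi = 1` means the apo ensemble survives
intact. Supporting tools compute per-atom/per-residue discrimination
indices between two structure subgroups (DI, LODR), per-frame structural
metrics (minimum heavy-atom distances, van der Waals contacts at < 4.5 Å,
Cα distances, π-stacking occupancy, per-cluster RMSF), dual-boost
accelerated-MD parameters, and the standard assay fits (two-state CD
melts, FP saturation/competition binding with Cheng–Prusoff `Ki`, Hill
dose-response, HDX uptake differences at the 0.5 Da threshold).

A synthetic-ensemble generator draws frames from Gaussian-perturbed
conformational substates with controllable shared mass `w`, so the
expected overlap fraction is known by construction and the whole pipeline
is testable without trajectory downloads.

## Worked example

Generate an apo/liganded pair designed to share 60% of its apo ensemble,
cluster the two together, and measure the overlap:

```r
library(ensembleshift)

design <- ensemble_pair_design(shared_weight = 0.6,
                               n_frames_apo = 800, n_frames_liganded = 800,
                               seed = 7)
pair <- make_apo_liganded_pair(design)
cc <- combined_cluster(pair$apo, pair$liganded, radius = 2.4)
cc$table
#>   cluster_id count_a count_b
#> 1          1     232     382
#> 2          2     164       0
#> 3          3     252     418
#> 4          4     152       0
overlap_fraction(cc$table)
#> <overlap_result> phi = 0.6050 (484 of 800 apo frames in 2 mixed of 4 clusters)
```

Clusters 1 and 3 contain both provenances in comparable numbers, so they
are mixed; clusters 2 and 4 are apo-exclusive substates the ligand
eliminated. The 484 apo frames in mixed clusters out of 800 give
`phi = 0.605`, within sampling error of the designed 0.6.

The printed worked examples of the mixing rule behave as documented:

```r
overlap_fraction(data.frame(count_a = 293, count_b = 14287))$phi  # 0
overlap_fraction(data.frame(count_a = 1554, count_b = 3269))$phi  # 1
```

## Analysis workflow

`analysis/` holds the numbered drivers that reproduce the shipped study
end to end on synthetic data; each writes its tables under `results/`:

1. `01_simulate.R` — ensemble pairs for `w = 0, 0.3, 0.6, 1.0` (1,500
   frames/side) plus an activity table tying EC50 to the design.
2. `02_cluster_overlap.R` — combined clustering and `phi` per complex
   (`results/phi.csv`); asserts `|phi - w| < 0.05` for every pair.
3. `03_activity_correlation.R` — Pearson `r` of `phi` against
   `log10(EC50)` and fold fractions.
4. `04_structure_metrics.R` — contact frequencies, distance series,
   per-cluster RMSF, π-stacking occupancy.
5. `05_biophys_fits.R` — melt/binding/competition/dose-response round
   trips and an HDX difference table.
6. `06_ensemble_comparison.R` — DI between dominant apo/liganded cluster
   representatives, DI-colored PDB output.

Run them in order from the repository root: `Rscript analysis/01_simulate.R`
etc. Large intermediates (multi-model PDBs) go under `scratch/`.

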