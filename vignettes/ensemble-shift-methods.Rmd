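---
title: "Quantifying ligand-induced ensemble shifts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligand-induced ensemble shifts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleshift)
```

## The scientific problem

Steroid receptors and other allosteric proteins do not occupy a single
structure: they sample an ensemble of conformational substates, and a
ligand acts by redistributing the population across those substates. When a
hormone binds its receptor's ligand-binding domain, some apo conformations
are eliminated and new holo-specific conformations appear. The degree to
which the apo ensemble survives ligand binding is informative: a ligand
that leaves the apo ensemble largely intact tends to be a weak activator,
while one that collapses it onto a new set of states drives a genuine
conformational switch.

`ensembleshift` turns that idea into a measurable pipeline. Its inputs are
conformational ensembles — frames of a molecular-dynamics trajectory, or
synthetic ensembles generated in-package — carrying per-frame provenance
labels (apo vs liganded, wild-type vs mutant). Its central output is the
**overlap fraction**, a single number per receptor–ligand complex.

## The overlap statistic

Frames from the apo and liganded ensembles are pooled (apo first) and
clustered by fixed-radius RMSD clustering: every frame must lie within a
radius $r$ (default 2.4 Å, Cα atoms, after optimal superposition) of its
cluster centroid. Each cluster $k$ then holds $a_k$ apo frames and $l_k$
liganded frames.

A cluster is **mixed** when its smaller provenance component is a
non-negligible part of its larger one:

$$\min(a_k, l_k) \ge t \cdot \max(a_k, l_k), \qquad t = 0.05 .$$

The inequality is inclusive: a smaller component of exactly 5% of the
larger counts as mixed. A cluster of 293 apo and 14,287 liganded frames is
not mixed ($293 < 0.05 \times 14287$); one of 1,554 apo and 3,269 liganded
frames is.

The **overlap fraction** is the fraction of apo frames in mixed clusters:

$$\varphi = \frac{\sum_{k \,\in\, \text{mixed}} a_k}{\sum_k a_k} \in [0, 1].$$

$\varphi = 0$ means ligand binding eliminated every apo conformation (a
complete ensemble shift); $\varphi = 1$ means every apo conformation
remains populated in the liganded ensemble. The denominator is all apo
frames; clusters without apo frames contribute to neither sum.

## The clustering algorithm

Fixed-radius clustering tools in the MD world are specified by a radius,
not by an algorithm; we pin the algorithm for reproducibility:

1. **Leader pass** in frame order: assign each frame to the first existing
   centroid within $r$, else the frame seeds a new cluster.
2. **Refinement** (at most 10 rounds): recompute each centroid as the
   coordinate average of its members after superposition onto the previous
   centroid; reassign every frame to its nearest centroid, spawning a new
   cluster for any frame farther than $r$ from all of them; stop when
   assignments are stable.
3. **Final assignment-only pass**, which guarantees the invariant that
   every frame is within $r$ of its assigned centroid. The suite asserts
   this exactly.

Choices a user should know: leader clustering is order-dependent, and we
accept that — the order is the concatenation order (group A first), fixed
and documented. Ties (a frame equidistant from two centroids within
$10^{-9}$ Å) go to the lower cluster id. Superposition is the Kabsch/SVD
solution with reflection correction; the per-frame kernels are compiled
(RcppArmadillo) because clustering 10,000 frames touches millions of
3×3 SVDs. Cluster ids are dense `1..K` in order of first appearance; a
non-converged refinement warns but still satisfies the radius invariant.

Against an independent oracle (pairwise RMSD matrices from bio3d,
thresholded into graph components), memberships agree exactly on
well-separated test ensembles.

## The synthetic-ensemble generator

Real MD trajectories for this system are not redistributable, so the
package generates ensembles from a discrete Gaussian mixture over rigid
displacement fields — the minimal structure that makes the expected
overlap fraction known by construction.

A reference helix (Cα on a parametric helix: 2.3 Å radius, 100° per
residue, 1.5 Å rise; five pseudo-atoms N/CA/C/O/CB per residue) is
perturbed by per-substate displacement fields. Fields are constant within
each residue and orthonormal across substates in per-residue space, scaled
so that every pairwise substate separation equals the design value
(default 10 Å RMSD) exactly — on the Cα selection and on all atoms alike.
Frames add isotropic Gaussian noise (default σ = 0.3 Å per coordinate).

An apo/liganded pair design with shared mass $w$ gives the apo ensemble
$w$ of its probability on shared substates (split evenly over 2 shared
substates by default) and $1 - w$ on apo-exclusive substates (2 by
default); the liganded ensemble samples only the shared substates. With
equal frame counts per side, shared clusters satisfy the 5% rule whenever
$w \ge 0.05$, so the expected pipeline $\varphi$ equals $w$; the binomial
sampling error at 5,000 frames per side is below 0.01. The defaults
(σ = 0.3 Å, separation 10 Å, seed 2022) keep the design unambiguous under
the 2.4 Å radius: separation exceeds 30σ and four times the radius.

What the generator does **not** emulate: continuous conformational
landscapes, intra-substate anisotropy, correlated backbone motions,
solvent, or force-field physics. Passing recovery tests therefore shows the
statistic and its implementation are correct for populations drawn from
separated substates — not that 2.4 Å is the right radius for any particular
protein, which remains an analysis choice exposed as a parameter.

## Ensemble comparison (discrimination index)

To localize *where* two ensembles differ, two subgroups (e.g. 100
lowest-RMSD representatives of the dominant wild-type and mutant clusters)
are compared after an iterative global overlay (superpose all structures
onto the running mean until the mean moves < $10^{-6}$ Å). For each atom,

$$\mathrm{DI} = \frac{m_\text{between} - m_\text{within}}
{\max(m_\text{between}, m_\text{within})} \in [0, 1],$$

where $m_\text{between}$ is the mean distance of that atom's positions over
all inter-group structure pairs and $m_\text{within}$ pools the intra-group
pairs of both groups. Two readings of "the group" are possible (pooled, or
averaged per group); we pool, which matches the stated [0, 1] range, and
clamp negative values to 0. Distances whose between- and within-means are
both below $10^{-8}$ Å are numerical round-off from superposition, and the
DI is defined as 0 there rather than amplifying noise.

The local profile replaces Cartesian distances with the local overlaid
dipeptide residual (LODR): superpose the pair on
$\{C_{i-1}, O_{i-1}, N_i, CA_i\}$ and take the RMS deviation over
$\{C_i, O_i, N_{i+1}, CA_{i+1}\}$. Rigid-body differences cancel, so a
single backbone-dihedral change registers only at the residue where it
occurs — the suite constructs a ψ-rotation and verifies the profile peaks
there and vanishes beyond. The exact atom sets are a pinned convention
(published descriptions vary) and are local to one function if a different
convention is needed.

## Structural metrics

* **Minimum heavy-atom distance**: minimum over all non-hydrogen atom
  pairs of two residues, per frame; hydrogens identified from the element
  column, else inferred from atom names.
* **van der Waals contact**: strictly less than 4.5 Å, matching the
  convention the distance threshold comes from.
* **π-stacking occupancy**: fraction of frames with ring-centroid distance
  ≤ 5.0 Å and ring-normal angle ≤ 30° (normals from the smallest principal
  axis, angle folded into [0°, 90°]). The criterion itself is a pinned
  convention — common in stacking analyses but not universal — and both
  cutoffs are parameters.
* **Per-cluster RMSF**: within each cluster, frames are superposed onto
  the iteratively refined cluster mean and
  $\mathrm{RMSF}_i = \sqrt{\langle \|\Delta r_{CA,i}\|^2 \rangle}$.
  Because the superposition itself absorbs a small part of any localized
  displacement, a ±0.3 Å single-residue motion reads back as 0.3 Å only up
  to a few percent; singleton clusters are skipped with a warning.

## Accelerated-MD boost parameters

The dual-boost parameter calculator implements the standard selection
rules from average dihedral and total potential energies:
$E_D = E_{avgD} + 3.5\,N_{sr}$, $\alpha_D = 0.2\,E_D$,
$\alpha_P = 0.16\,N_{atom}$, $E_P = E_{avgP} + 0.16\,N_{atom}$ (kcal/mol).
The identities $\alpha_D / E_D = 0.2$ and $\alpha_P / N_{atom} = 0.16$ hold
for all inputs and are asserted property-style. The package only emits
numbers; it does not configure an MD engine.

## Biophysical curve analyses

All temperatures are stored in °C (what instruments report) and converted
to Kelvin for thermodynamics, with $R = 1.987 \times 10^{-3}$
kcal mol⁻¹ K⁻¹.

**Two-state melt.** Baselines are fit linearly on the leading and trailing
20% of the temperature grid (overridable); the fraction denatured follows
the lever rule $f_D = (y - y_N)/(y_D - y_N)$;
$\Delta G(T) = -RT \ln\!\big(f_D/(1-f_D)\big)$ is linearized over
$|\Delta G| \le 1.3$ kcal/mol around the midpoint, where the two-state
approximation is most reliable; the apparent $T_m$ is the zero crossing,
$\Delta S_m$ the negative slope, and $\Delta H_m = T_m \Delta S_m$. On
noiseless synthetic curves the round-trip recovers $T_m$ to < 0.05 K and
$\Delta H_m$ to < 0.1%; the suite requires 0.2 K / 3%, and a Monte-Carlo
study at 2%-of-amplitude noise keeps the median $T_m$ error under 0.5 K.

**Binding and activation.** Saturation FP data fit the one-site hyperbola
$mP(x) = mP_\text{free} + (mP_\text{bound} - mP_\text{free})\,x/(K_d+x)$;
competition data fit a logistic displacement on $\log_{10}$ concentration
whose midpoint converts by Cheng–Prusoff,
$K_i = IC_{50} / (1 + [\text{probe}]/K_{d,\text{probe}})$ (with a 10 nM
probe of $K_d$ 180 nM, $K_i = 33$ nM implies $IC_{50} = 34.83$ nM).
Dose-response curves fit the four-parameter Hill equation; a curve whose
total range is below three times the residual-noise estimate (from
successive differences) is reported as *no activation* with an absent
EC50, which is how non-activating ligands enter downstream correlations.
Fits use Levenberg–Marquardt (minpack.lm) with profile-likelihood 95%
intervals where the profile exists (it degenerates on noiseless data, and
`NA` is returned).

The simulated assay curves report the mean of technical replicates
(6 for FP saturation, 3 for competition and dose-response), with
`noise_sd` defined per replicate — matching how such assays are actually
plotted. At 5% per-replicate noise, the median relative error of
$K_d$/$K_i$/EC50 recovery over 100 seeds stays below 10%.

**HDX differences.** Exchangeable amides per peptide are
$n = \text{length} - 1 - \text{prolines}$ (N-terminal amide and prolines
after the first residue are excluded; no back-exchange correction).
Relative fractional uptake is centroid uptake divided by $n$; a state
difference is significant when $|\Delta\text{centroid}| \ge 0.5$ Da
(inclusive). Swapping states negates both differences exactly.

## Overlap–activity correlation

Per-complex overlap fractions are correlated (Pearson by default,
Spearman available) against $\log_{10}(EC_{50})$ or against fractional
fold activation (fold change at 10 or 100 nM divided by $E_{max}$). EC50
spans orders of magnitude, hence the log transform; complexes without a
measurable EC50 are excluded from that correlation (and counted) rather
than assigned a censored value, but keep their measured fold changes in
the fold-fraction metrics. Fewer than 3 pairs, or zero variance in either
variable, is an error rather than a silent `NA`.

## Problem sizes and reproducibility

The shipped analyses and tests run at deliberately modest scale: ensemble
recovery uses 5,000 frames per side on a 30-residue helix (Cα selection,
150 atoms), the analysis scripts 1,500 frames per side, clustering oracles
≤ 50 frames, and the fit recovery studies 100 seeds. These sizes were
chosen so the designed effects dominate sampling error by an order of
magnitude; everything scales linearly in frames and atoms. Every
stochastic generator takes an explicit seed, and identical seeds give
bitwise-identical output — the suite asserts this.

## Known limitations

* The substate mixture is a stand-in for real conformational landscapes;
  it validates the statistics, not any claim about a specific receptor.
* Leader clustering's order dependence means φ can change slightly if the
  frame order changes; order is part of the specification.
* The π-stacking and LODR conventions are pinned choices among several in
  the literature; both are parameterized.
* PDB is the only trajectory format; fixed-column parsing is delegated to
  bio3d, and coordinates survive a write/read round-trip to the format's
  10⁻³ Å precision, no better.
* No significance testing is attached to φ itself.
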