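---
title: "Assigning function to HMG-box residues: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning function to HMG-box residues: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmgfunc)
```

## The problem

The HMG box is a ~79-residue, L-shaped three-helix domain that binds the
DNA minor groove. Some family members (the 20 human Sox proteins, including
SRY and SOX9) bind DNA sequence-specifically; many others do not.
Disease-associated missense variants in HMG-box proteins cluster at
particular box positions, and asking *why* a position matters — structural
packing, DNA contact, or interaction with a partner protein such as the
androgen receptor's C-terminal extension (CTE) — requires combining several
kinds of evidence. `hmgfunc` implements that combination as a reusable,
fully testable pipeline:

1. **Variant catalog** — disease substitutions indexed by box-relative
   position (1-based from the first box residue of each protein's own
   domain; cross-protein comparison happens only after alignment mapping).
2. **Conservation tiers** — each variant position is mapped through the
   reference sequence into a family-level (HMG) and a subfamily-level (Sox)
   alignment and classified at a 90% threshold: `HMG_CONSERVED`,
   `SOX_CONSERVED` (conserved only in the subfamily), or `NOT_CONSERVED`.
   Positions without variants are `NO_VARIANT`.
3. **Ensemble superposition** — cleaned Cα-only domains are superposed onto
   a reference (canonically the SRY box bound to DNA) by alignment-guided
   Kabsch fitting.
4. **Per-residue dynamics** — from an MD trajectory, the mean Cα RMSD of
   each residue relative to the initial structure, after rigid fitting of
   every frame.
5. **Docking stability** — peptide movement in a receptor-peptide complex
   trajectory under three regimes: docked, docked with an all-alanine
   peptide, and free.

The interpretive pattern the pipeline exposes: family-conserved positions
are the least mobile (packing/DNA scaffold), subfamily-only conservation
marks specificity features, and unconserved variant positions with high
mobility are candidates for protein-protein interaction surfaces.

## Conservation scoring

For an alignment column, the **identity frequency** is the modal residue
count divided by the non-gap count (0 for an all-gap column). **Class
mode**, the default, scores a column as
`max(identity frequency, best physicochemical-class frequency)` with
overlapping classes hydrophobic {A,V,L,I,M,F,W,Y,C}, aromatic {F,W,Y,H},
polar-basic {K,R,H} and polar-acidic {D,E}. Taking the max with identity
guarantees class-mode conservation never falls below identity-mode even at
columns whose modal residue (e.g. Gly, Ser, Pro) belongs to no named
class — without it, a column perfectly conserved as glycine would
paradoxically score 0 in class mode. Class mode is the default because
family-level conservation of the box core is class-phrased in practice
(hydrophobic packing positions, a basic DNA-contact position); a flag
switches to identity-only.

Two deliberate decisions where the ground truth is genuinely open:

* **Threshold semantics**: "90% or greater" is `>= 0.90` computed over the
  non-gap denominator, so partial columns are not penalized for gaps — but
  a column with a gap **majority** (> 50%) is reported `NOT_CONSERVED`
  regardless, since a high frequency over a handful of non-gap sequences is
  not evidence of family conservation.
* **Tier precedence**: the family test runs first; only positions failing
  it are tested in the subfamily. Tier counts therefore always partition
  the variant positions (n_HMG + n_SOX + n_NOT = n_positions), and raising
  the threshold can only demote, never promote, a position — both are
  enforced as property tests.

## Superposition

`kabsch_fit()` computes the least-squares proper rotation and translation
between paired Cα sets via the SVD of the 3×3 cross-covariance, with the
smallest singular direction sign-flipped when needed so that reflections
are rejected (a mirror-image set keeps a positive residual). Fewer than 3
pairs, collinear or coincident geometry raise an error, as the rotation is
then under-determined. The unit and acceptance suites check it against a
brute-force oracle that minimizes RMSD over an Euler-angle grid (with the
translation eliminated analytically by centroid matching) refined by
Nelder-Mead, and against `bio3d`'s fitted RMSD.

Residue correspondence for ensembles comes from a sequence alignment, never
from raw PDB residue numbers (numbering is inconsistent across entries):
Cα pairs are taken at columns where both the structure's row and the
reference's row are non-gapped, and each structure's sequence is verified
against its row. NMR ensembles default to the first reported member;
`trim_ensemble()` optionally drops residues whose Cα spread across members
exceeds 2.0 Å (flag-tunable) to keep only regions of high agreement. The
fit uses all paired Cα with no outlier rejection, matching whole-domain
superposition practice.

## Per-residue dynamics

For a trajectory with frames at a fixed interval (the canonical analysis
uses snapshots every 25 ps over 1000 ps, i.e. 41 frames including t = 0),

$$\mathrm{RMSD}_i = \sqrt{\tfrac{1}{T}\sum_{t=1}^{T}
  \lVert x_i(t) - x_i(0)\rVert^2}$$

over the `T` post-initial frames. Three conventions worth stating:

* **Reference = initial structure**, not the time average: this is a
  deviation-from-start profile, deliberately distinct from an RMSF.
* **Frame 0 is excluded** from the average; it contributes identically zero
  and would deflate every value.
* **Each frame is rigidly fitted** to frame 0 over all Cα before measuring
  (default `fit = "ca"`); without a fit, center-of-mass drift and tumbling
  dominate and per-residue values are meaningless. `fit = "none"` is kept
  for oracle tests against closed forms.

For independent isotropic Gaussian displacements of standard deviation
σ per coordinate, E‖x(t) − x(0)‖² = 3σ², so the profile recovers σ·√3 — the
synthetic generator's ground truth. One numerical subtlety the tests
surface: the all-Cα fit estimates 6 rigid degrees of freedom from noisy
coordinates, so (a) recovery is biased low by roughly 6/(3n) in variance —
negligible at domain size (n ≈ 79 gives ~1%) but material for very short
chains — and (b) under strongly heteroscedastic σ the fit is dominated by
the mobile residues, and quiet residues far from the centroid inherit the
residual rotation error scaled by their lever arm. On the elongated toy
helix this inflates chain-end residues by up to ~10%; the jitter-recovery
check therefore runs at uniform σ, and the varied-σ check runs without
fitting.

## Docking stability

"Peptide movement" is implemented as the peptide Cα RMSD versus frame 0
*after superposing each frame on receptor Cα only* — displacement is thus
measured in the receptor frame, and motion shared by receptor and peptide
cancels exactly. A center-of-mass metric is available behind a flag.
Summary statistics (mean, max) are over post-initial frames, consistent
with the dynamics convention. Pose generation and binding energetics are
out of scope: the module consumes complex trajectories from any source.

## The synthetic-data generator

Every analysis stage is testable offline against constructed ground truth:

* `synth_msa()` draws each engineered column from a
  conserved-symbol-vs-uniform-background mixture at a target frequency (the
  reference row always carries the conserved symbol); unspecified columns
  are uniform. Empirical frequencies land within the binomial band around
  the target.
* `synth_helix()` is an ideal α-helical Cα trace (1.5 Å rise, 100° twist,
  2.3 Å radius — standard helix geometry, chosen as a deterministic toy
  stand-in for box helices).
* `synth_trajectory()` adds per-residue isotropic Gaussian displacement to
  a reference, frame-independent (the analyzed statistic is
  distribution-level and needs no kinetics), with optional random
  rigid-body jitter that all-Cα fitting must remove.
* `synth_complex_trajectory()` realizes the three docking regimes as rigid
  peptide offsets: i.i.d. Gaussian (harmonic-tether stationary
  distribution) for docked, a weaker tether for the all-alanine peptide,
  and an unbiased random walk for free. E‖offset‖ for the tether is
  2σ√(2/π), the Monte-Carlo anchor used in tests.
* One master seed fans out to per-generator child seeds through a fixed
  counter scheme, so adding a generator never perturbs existing fixtures,
  and every generated file re-reads losslessly (write→read→write is a
  byte-level fixpoint at PDB's 3-decimal precision).

The bundled study (`synth_study()`) mirrors the real analysis' conditions:
a 79-residue box; 69 family and 20 subfamily sequences; 44 variant records
at 33 distinct positions across 5 protein labels (all in Sox members except
two in an HMGB1 stand-in); 8 family-conserved positions with
class-consistent symbols (aromatic-hydrophobic at 9, 12, 40, 51;
hydrophobic at 6, 32, 43; basic at 48), 19 subfamily-only positions
(including DNA-contact positions 4 and 29) and 6 unconserved (including 16
and 45); a 1000 ps / 25 ps trajectory with σ = 0.3 Å at family-conserved
positions and 1.0 Å elsewhere; and 1500 ps docking runs (61 frames) with
tether σ 0.5 Å (docked), 1.5 Å (alanine) and a 0.5 Å/frame walk (free).
Engineered conserved columns use target frequency 1.0 over a uniform
background, so the 8/19/6 tier ground truth is exact for every seed rather
than holding only in expectation — what "known ground truth" should mean
for a generator.

What passing on synthetic data does **not** show: real alignments have
phylogenetic correlation between sequences (the binomial column model has
none), real trajectories are autocorrelated and anharmonic, and the toy
helix is more elongated than a folded box (which *amplifies* the lever-arm
effects discussed above rather than hiding them). The synthetic study
validates the machinery and its statistical contracts, not biological
conclusions about any particular protein.

## Worked example

```{r study, eval = FALSE}
dir <- tempfile("hmg_study")
cfg <- synth_study(dir, seed = 1)
res <- run_pipeline(cfg)
summarize_catalog(load_variants(cfg$catalog))
attr(res$report, "partition")
attr(res$annotated, "tier_summary")
res$docking
```

Problem sizes throughout (500-frame recovery runs, 100 oracle instances,
20-seed ordering checks) were chosen to make sampling error comfortably
smaller than the tested tolerances while keeping the whole suite fast on a
single CPU.

## Known limitations

* Alignment computation, structural-alignment algorithms (MUSTANG-style),
  homology modeling and force-field MD are out of scope; the package
  consumes pre-aligned FASTA and multi-model PDB from any source.
* The catalog schema covers single-position events only (substitutions and
  `-` deletions).
* mmCIF and binary trajectory formats (DCD/XTC) are not read; multi-model
  PDB is the trajectory dialect.
* Conservation scoring weights sequences equally; no phylogenetic
  downweighting of redundant sequences.
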