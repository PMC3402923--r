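# hmgfunc

Integrative amino-acid function analysis for the HMG-box DNA-binding
domain, in R.

The HMG box is a ~79-residue three-helix domain that bends the DNA minor
groove; its Sox subfamily (20 human members, including SRY and SOX9) binds
DNA sequence-specifically, and missense variants in these proteins cause
diseases from 46,XY sex reversal to campomelic dysplasia. Given a catalog
of disease variants, family- and subfamily-level sequence alignments,
domain structures and MD trajectories, `hmgfunc` asks, position by
position: is this residue a family-wide structural constraint, a
subfamily-specific feature, or neither — and does its dynamic behavior
match? The package is aimed at structural bioinformaticians dissecting a
protein family with a shared domain; nothing in the machinery is specific
to the HMG box beyond its defaults.

## What it computes

* **Variant catalog** (`load_variants`, `summarize_catalog`): one record
  per disease substitution at a 1-based, box-relative position; counts of
  variants, distinct positions (pooled across proteins on the shared box
  numbering) and proteins.
* **Conservation tiers** (`classify_position`, `conservation_report`):
  each variant position is mapped through the reference into the HMG and
  Sox alignments and classified at a threshold *f* = 0.90 over the non-gap
  denominator — `HMG_CONSERVED` if the family column is conserved,
  else `SOX_CONSERVED` if the subfamily column is, else `NOT_CONSERVED`.
  Conservation is class-aware by default: a column counts as conserved
  when its identity frequency *or* its best physicochemical-class
  frequency (hydrophobic / aromatic / polar-basic / polar-acidic) reaches
  the threshold.
* **Ensemble superposition** (`kabsch_fit`, `superpose_ensemble`):
  SVD-based least-squares rigid superposition (proper rotations only;
  mirror images keep a positive residual), with Cα pairing taken from
  alignment columns rather than PDB numbering, and NMR ensembles reduced
  to the first member (optionally trimmed to regions of high agreement).
* **Per-residue dynamics** (`per_residue_rmsd`): for each residue,
  RMSD_i = sqrt((1/T) Σ_t ‖x_i(t) − x_i(0)‖²) over post-initial frames,
  after rigidly fitting every frame to the initial structure over all Cα.
  This is deviation from the *initial* structure, not an RMSF.
* **Docking stability** (`peptide_displacement`, `compare_conditions`):
  peptide Cα RMSD vs frame 0 measured in the receptor frame (each frame
  fitted on receptor Cα only), compared across docked, all-alanine-docked
  and free regimes.
* **Synthetic data** (`synth_msa`, `synth_helix`, `synth_trajectory`,
  `synth_complex_trajectory`, `synth_variant_table`, `synth_study`):
  generators with known ground truth for every stage, seeded and
  bit-reproducible.
* **Pipeline** (`run_pipeline`): one config (list or YAML) in, a
  deterministic bundle of TSVs, a merged per-position annotation table, a
  summary and a manifest out.

## Worked example

```r
library(hmgfunc)

catalog <- load_variants(system.file("extdata", "synthetic_nv_catalog.tsv",
                                     package = "hmgfunc"))
summarize_catalog(catalog)
#> 44 variants at 33 distinct positions in 5 proteins

dir <- tempfile("hmg_study")
cfg <- synth_study(dir, seed = 1)   # writes alignments, catalog,
res <- run_pipeline(cfg)            # trajectory, docking runs + run.yaml
```

The run's `summary.txt`:

```
HMG residue-function pipeline summary
variants: 44 at 33 distinct positions in 5 proteins
conservation (threshold 0.90, class mode): 8 HMG / 19 Sox / 6 not conserved of 33 positions
mean C-alpha RMSD by tier:
  HMG_CONSERVED  0.549 A
  NOT_CONSERVED  1.674 A
  NO_VARIANT     1.690 A
  SOX_CONSERVED  1.692 A
docking conditions by mean displacement:
  DOCKED     0.788 A
  DOCKED_ALA 2.198 A
  FREE       3.228 A
```

Reading it: of the 33 variant positions, 8 are conserved across the whole
family (27 across the Sox subfamily, i.e. those 8 plus 19 more) and 6 in
neither set. The family-conserved positions are also the least mobile tier
in the trajectory (mean Cα RMSD 0.55 Å vs ≈1.7 Å elsewhere) — the
packing/DNA-scaffold signature — and the docked peptide moves least,
the untethered one most. Per-position detail is in
`res$report` and the merged `residue_annotation.tsv`:

```r
res$report[res$report$position %in% c(6, 16, 48), 1:4]
#>  position          tier identity_freq_hmg identity_freq_sox
#>         6 HMG_CONSERVED         1.0000000              1.00
#>        16 NOT_CONSERVED         0.1014493              0.15
#>        48 HMG_CONSERVED         1.0000000              1.00
```

The bundled catalog at `inst/extdata/synthetic_nv_catalog.tsv` is a
synthetic stand-in constructed to match the published summary facts of the
HMG disease-variant literature (44 variants at 33 box positions in 5
proteins, all in Sox members except two in HMGB1, including the campomelic
dysplasia A16V and the HMGB1 A45E records); it is not a curated clinical
resource.

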