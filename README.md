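# fgseq — sequence-feature analysis of FG nucleoporins

FG nucleoporins (FG Nups) are the intrinsically disordered,
phenylalanine–glycine-repeat proteins that fill the nuclear pore complex
and form its selective permeability barrier. Because they lack stable
structure, their function is encoded in sequence *composition* and in the
*along-sequence layout* of a few residue classes: FG dimers, charged
residues (R/K positive, D/E negative) and polar residues (S/N/T/Q).
`fgseq` is an R package for analyzing that layout across a cohort of
sequences. It is aimed at anyone studying disordered repeat proteins who
has FASTA sequences plus disordered-region annotations and wants
reproducible, tested cohort statistics.

## What it computes

For each protein (on its disordered regions, coordinates 1-based
inclusive throughout):

* **Cohort filter** — disorder fraction > 0.30 and FG density
  > 0.15 FG/AA (dimer occurrences / sequence length).
* **Composition** — mean absolute net charge
  `|n⁺ − n⁻| / L`, charged-residue number density `(n⁺ + n⁻) / L`,
  normalized Kyte–Doolittle hydrophobicity `mean((h + 4.5)/9)`, cohort
  amino-acid abundance sorted by disorder propensity, and
  charge–hydrophobicity plane coordinates.
* **FG linkers** — segments of 10–30 residues strictly between two motif
  anchors; per-linker net charge and charged/polar/hydrophobic densities;
  the fraction of linkers with |net charge| ≤ 1; mean polar density binned
  by charged density (bins of 0.05, ≥ 50 samples, charge density ≤ 0.7).
* **Like-charge regions (LCRs)** — maximal runs of ≥ 2 same-sign charges
  uninterrupted by the opposite sign; per protein the largest LCR with its
  inclusive span and charge content (count/span), plus a
  central-channel/periphery label from the charge count (< 8 central-like,
  ≥ 7 periphery-like, exactly 7 ambiguous).
* **Density clustering** — DBSCAN-semantics clustering of 1-D feature
  positions (FG/GF anchors, charged, polar) with Dunn-index-tuned defaults
  ε = 35/8/2 and minPts = 2/2/4; asymmetric cluster-type overlap
  (shared footprint residues / summed footprint sizes of the focal type);
  `tune_epsilon()` for re-tuning on new cohorts.
* **Zones and groups** — equal-thirds partition of the whole sequence
  (zone 1 = N-terminus); per-zone cluster-residue proportions (10 of 50
  cluster residues in zone 1 ⇒ 0.2); group A when strictly more than half
  of the polar-cluster residues sit in zone 1, else group B; per-group
  FG–polar overlap summaries.

A synthetic-cohort generator (`synth_fg_cohort()`, `synth_disprot()`)
emulates the FG-segment/stalk architecture with exact planted ground truth
(motif anchors, segment boundaries, optional planted LCR), so every stage
is testable without database access.

## Worked example

```r
library(fgseq)

spec <- synthetic_spec(n_proteins = 20, seed = 7)
co <- synth_fg_cohort(spec)
write_fasta(co$records, "cohort.fa")
reg <- do.call(rbind, lapply(co$records, function(r)
  data.frame(id = r$id, start = r$disordered_regions$start,
             end = r$disordered_regions$end)))
writeLines(c("id\tstart\tend",
             sprintf("%s\t%d\t%d", reg$id, reg$start, reg$end)),
           "cohort.regions.tsv")

cfg <- pipeline_config(fasta = "cohort.fa", regions = "cohort.regions.tsv",
                       out_dir = "fgseq_out", seed = 1,
                       min_bin_samples = 20)
res <- run_pipeline(cfg)
#> read 20 records
#> 17 records pass the FG Nup filter
#> 97 FG linkers extracted

head(res$composition, 3)
#>        id n_residues mean_abs_net_charge charge_density mean_hydrophobicity
#> 1 FGN0001        558             0.00717         0.0789               0.454
#> 2 FGN0002        354             0.02260         0.0734               0.468
#> 3 FGN0003        702             0.01282         0.0755               0.471

linker_net_charge_summary(res$linkers)
#> [1] 0.938

head(res$lcrs, 3)
#>        id     sign charge_count span_length charge_content lcr_location_class
#> 1 FGN0001 positive            6          22          0.273       central-like
#> 2 FGN0002 negative            5          24          0.208       central-like
#> 3 FGN0003 positive            7          25          0.280          ambiguous
```

Reading the output: the synthetic cohort has the low net charge and low
charge density characteristic of FG Nups (charge density here ≈ 0.075,
roughly half of a disordered-protein control generated with
`synth_disprot()`), 93.8% of its FG linkers carry a net charge of 0 or ±1,
and each protein's largest like-charge region is summarized by sign,
inclusive span and charge content. `fgseq_out/` contains one TSV per stage
(composition, abundance, linkers, linker curve, LCRs, clusters, overlaps,
zones, group summaries) plus a YAML manifest with the config hash and
per-stage record counts. A thin command-line wrapper over the same
functions ships in `inst/scripts/fgseq.R`
(`Rscript fgseq.R synth|run ...`).

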