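# tilclone

Clonal architecture of tumor-infiltrating T cells, from bulk TCR
repertoires, single-cell V(D)J + expression, and multiplex-IHC spatial
data.

## The problem

Solid tumors — renal cell carcinoma being the motivating case — are
infiltrated by T cells whose clonal structure carries the biological
signal: which clones are expanded, whether expanded clones are confined
to the tumor or also circulate in blood and normal adjacent tissue
(NAT), whether they look exhausted or effector-like, whether any are
shared across patients ("public"), and how densely T cells pack the
tumor margin. `tilclone` provides the quantitative backbone for that
analysis, for immunologists and computational biologists working with:

* bulk TRB-CDR3 rearrangement tables (ImmunoSEQ-export or AIRR
  Rearrangement TSV),
* per-cell TRA/TRB contig tables plus a genes × cells count matrix,
* mIHC cell tables (µm coordinates, CD3/CD4/CD8/Ki67/CAIX positivity)
  with a tumor-border polyline.

## The statistics at its core

For a productive repertoire with clonotype frequencies *p₁…p_U*:

* **Clonality** = 1 − *H*/ln *U*, where *H* = −Σ *pᵢ* ln *pᵢ* is the
  Shannon entropy. 0 = perfectly even, 1 = monoclonal
  (*U* = 1 defined as clonality 1).
* **Similarity** of two samples = |shared unique sequences| / |union of
  unique sequences|.
* **Expanded clonotype**: frequency > 1% (bulk); a TRA/TRB pair seen in
  ≥ 2 cells (single-cell), with size classes singleton / 2–4 / 5–20 /
  > 20 cells.
* **Tissue patterns**: each clonotype maps to one of
  TUMOR / NAT / PBMC / TN / TP / PN / ALL by the tissues it occupies.
* **Public clonotypes**: ≥ 10 patients and > 10 cells in at least one
  tumor; **convergent nucleotypes**: ≥ 2 nucleotide sequences per
  amino-acid junction, each in > 1 cell.
* **Specificity groups**: connected components over shared interior
  CDR3 motifs (k = 3, 4; support ≥ 3; optional 10-fold background
  enrichment) and Hamming-1 near-identity.
* **Infiltration profile**: cell density vs signed distance to the
  tumor border (negative = inside) over ±500 µm; infiltrated/excluded
  by the inside:outside density ratio.

A fully ground-truthed synthetic cohort generator (`synthConfig()`,
`generateRepertoireSet()`, `generateCells()`, `generateSpatial()`)
emulates all three data layers and backs the validation suite.

## Worked example

```r
library(tilclone)

cfg <- synthConfig(seed = 42, n_patients = 3, clones_per_patient = 800,
                   depths = c(TUMOR = 2e4, NAT = 2e4, PBMC = 2e4),
                   sc_cells = 1000)
cohort <- generateRepertoireSet(cfg)
reps <- lapply(cohort$repertoires, filterProductive)

reps[["P01_TUMOR"]]
#> Repertoire: P01_TUMOR (patient P01, TUMOR)
#>   441 unique rearrangements (441 productive), 20000 productive reads
#>   top clonotypes: CASSTQGQGADYF (0.213), CASSDQGADTTYF (0.133), ...

diversityTable(reps[1:3])
#>  sample_id patient_id tissue unique_count entropy normalized_entropy clonality
#>  P01_TUMOR        P01  TUMOR          441    3.87              0.636     0.364
#>    P01_NAT        P01    NAT          450    3.22              0.528     0.472
#>   P01_PBMC        P01   PBMC          519    3.48              0.557     0.443

similarityScore(reps[["P01_TUMOR"]], reps[["P01_PBMC"]])
#> [1] 0.3713355

patternCounts(trackClonotypes(reps[1:3]))
#>  pattern   n fraction
#>    TUMOR 101    0.128
#>      ...
#>      ALL 148    0.187
```

The tumor repertoire is dominated by a 21% clone (clonality 0.36 vs a
more even NAT/PBMC), about a third of unique sequences are shared
between tumor and blood, and 12.8% of this patient's clonotypes are
tumor-restricted while 18.7% appear in all three tissues — the kinds of
quantities used to separate tumor-restricted from recirculating
expansions.

Continuing to the single-cell layer:

```r
sc <- generateCells(cfg, cohort)
cells <- filterDoublets(pairChains(sc$contigs))$cells
clonotypeDensity(pairedClonotypes(cells))
#>  size_class n_pairs density
#>   singleton     196   0.520
#>       small     109   0.289
#>      medium      56   0.149
#>       large      16   0.042
```

Half of the unique TRA/TRB pairs are singletons; 4% are large
(> 20-cell) clones. `assignLineage()`, `classifyPhenotype()`,
`scoreGeneSet()` and `dpClonotypeAnalysis()` then attach CD4/CD8/DP
lineage, phenotype labels and exhaustion/activation/effector scores to
each clone, and `densityProfile()` / `classifyInfiltration()` handle
the spatial layer. `runPipeline()` executes all stages from a YAML or
list config and writes the stage tables plus a `summary.json`.

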