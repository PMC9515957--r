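---
title: "Methods: quantifying the clonal architecture of tumor-infiltrating T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the clonal architecture of tumor-infiltrating T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilclone)
```

# Scope and model

`tilclone` analyzes the clonal structure of T cells infiltrating solid
tumors — prototypically renal cell carcinoma, where tumor, normal
adjacent tissue (NAT) and peripheral blood (PBMC) from the same
nephrectomy patient can all be profiled. Three data layers are
integrated:

1. **Bulk TRB-CDR3 repertoires** (DNA-template sequencing; one row per
   unique rearrangement with nucleotide and amino-acid junction, V/J
   calls, read count).
2. **Single-cell V(D)J + expression** (per-cell TRA/TRB chains plus a
   genes-by-cells count matrix).
3. **Spatial cell tables from multiplex IHC** (marker-positive cells in
   micrometer coordinates with a tumor border delineated by a tumor
   marker such as CAIX).

Each layer has an S4 or Bioconductor-native container: bulk samples are
`Repertoire` objects, cells live in a `SingleCellExperiment` (built by
`buildCellExperiment()`), spatial data are plain coordinate tables plus
a border polyline.

# Diversity and clonality

For a productive-filtered repertoire with clonotype frequencies
$p_1, \dots, p_U$, Shannon entropy is $H = -\sum_i p_i \ln p_i$,
normalized entropy $H/\ln U$, and **clonality** $1 - H/\ln U$. Clonality
is 0 for a perfectly even repertoire, 1 for a monoclonal one, and is
invariant to the logarithm base since numerator and denominator share
it. Two conventions are fixed here:

* **Natural logarithms** internally (base-invariant after
  normalization).
* **$U = 1$:** $H/\ln U$ is $0/0$; we define clonality = 1, the limit
  of a vanishing second clone.

Frequencies are always recomputed from read counts after productive
filtering; frequencies present in input files are retained only for QC
(`file_frequency`).

The **similarity score** between two samples is the number of shared
unique sequences divided by the total number of unique sequences in the
two samples. "Total" is read as the deduplicated union
(Jaccard-style); because the phrase is also readable as the sum of the
two unique counts, `similarityScore(..., denominator = "sum")` exposes
that variant. The union default was chosen because a "total number of
unique sequences in the two samples" most naturally counts each
distinct sequence once.

# Cross-tissue tracking

Clonotypes are matched across a patient's samples by CDR3 amino-acid
sequence (nucleotide-level tracking is available for convergence-aware
work). A clonotype's **tissue pattern** is one of seven labels that
partition the nonempty subsets of {TUMOR, NAT, PBMC}: the three
tissue-specific labels, TN, TP, PN, and ALL. A clonotype is **expanded**
when its frequency strictly exceeds 1% (`expanded_threshold`,
configurable). "Detected in a tissue" defaults to at least one read
(`min_count`); the threshold is exposed because index hopping can
warrant 2-3 reads on some platforms. When a patient lacks a tissue,
patterns are computed over the assayed tissues and `tissues_assayed`
records how many, so ALL is never claimed from two samples.

# Annotation, public clones, convergence

Database annotation is an exact match on the CDR3 amino-acid sequence
(optionally also requiring the V gene): specificity databases annotate
at sequence level and fuzzy matching is out of scope. Control-library
screening keeps the library donor-wise so that **prevalence** (fraction
of control donors carrying a sequence) is computable; a clonotype with
zero prevalence is **patient-unique**. **Public clonotypes** require
detection in at least 10 patients with more than 10 cells (i.e. at
least 11) in at least one tumor. **Convergent recombination** is called
when at least two distinct nucleotide sequences encoding the same
amino-acid junction are each supported by at least 2 cells or reads;
sequences containing ambiguous bases are excluded from nucleotype
analyses.

# Specificity groups (simplified motif clustering)

The grouping deliberately simplifies full GLIPH-style analysis: the
readout used downstream is group-size structure per tissue, not the
enrichment machinery. Sequences are grouped as connected components of
a graph with two edge types:

* shared **interior motif**: k-mers (k = 3, 4) from the CDR3 interior
  (first and last 3 residues trimmed, as largely germline-templated),
  kept when carried by ≥ 3 distinct CDR3s and, if a background set is
  supplied, enriched ≥ 10-fold over the background carrier frequency
  (pseudocount 1 on the background count);
* **near-identity**: equal length and Hamming distance ≤ 1.

Ungrouped sequences form singletons, so groups partition the input;
group ids are canonicalized by the lexicographically smallest member,
making output order-invariant. Fisher-exact enrichment against a
reference repertoire, V-gene bias correction and length modeling are
intentionally omitted; all thresholds are arguments.

# Single-cell integration

* **Pairing:** cells with exactly one TRA and one TRB CDR3 receive the
  pair key; the pair (not TRB alone) defines a clonotype, so identical
  TRB with different TRA are distinct clonotypes.
* **Doublets:** cells with ≥ 2 TRA or ≥ 2 TRB CDR3s are removed.
* **Size classes:** singleton (1 cell), small (2-4), medium (5-20),
  large (> 20); a multiplet is any pair seen ≥ 2 times.
* **Lineage:** CD4 vs CD8 (CD8A + CD8B) at ≥ 1 raw count each;
  both → DP; neither → unassigned. The count threshold is exposed
  because no positivity criterion is canonical.
* **Normalization:** counts per cell scaled to 10,000 and
  log1p-transformed — the conventional default, chosen here explicitly.
* **Phenotype:** the marker-score classifier scores each phenotype as
  the mean, over its markers, of normalized expression minus the
  gene's baseline, estimated as the lower quartile across cells. The
  lower-quartile baseline (rather than a mean/SD or median/MAD z-score)
  is deliberate: when a marker is elevated in an abundant cell state —
  large effector clones can exceed half of all cells — mean- and even
  median-centered scores collapse for exactly the most abundant
  phenotype. The quartile baseline stays anchored to the unshifted
  population for prevalences up to ~75%, above which labels degrade
  (a documented limitation). The default `min_score_margin` is 0
  (argmax), since margins trade recall for precision and no margin is
  canonical; all-zero cells are always unassigned.
* **Markers:** the packaged marker table (phenotype → genes) is a
  compact, documented default covering T_eff, T_em, T_cm, T_scm, naive,
  Th1, Th2, Th17, T_reg; users supply their own for real analyses.
  Protein aliases common in figure legends (TIM3, PD1, CD25, TNFSR9)
  map to gene symbols (HAVCR2, PDCD1, IL2RA, TNFRSF9) automatically.
* **Cluster markers:** genes expressed in ≥ 25% of a cluster's cells
  with |log fold-change| ≥ 0.25, ranked by Wilcoxon rank-sum and
  BH-adjusted — the standard single-cell marker-finding recipe with its
  published thresholds.
* **Bulk concordance:** Pearson correlation of bulk and single-cell
  clonal frequencies matched by TRB-CDR3; both raw and log10
  correlations are reported since either convention is defensible.

# Spatial profiling

Signed distance to the tumor border is Euclidean distance to the
nearest border segment, negative inside the tumor; the tumor side is
declared relative to the vertex order (`tumor_side = "left"`).
Density profiles bin cells over ±500 µm at 50 µm (the range follows the
figure convention for border profiles; bin width is not canonical and
is an argument). Per-bin tissue areas come from deterministic grid
sampling of the mask at 5 µm pitch — each grid point contributes
pitch²; for bins above ~0.01 mm² the relative error is well under 1% —
avoiding a polygon-clipping dependency. A profile is **infiltrated**
when mean inside density exceeds mean outside density by more than 10%
(`epsilon`), **excluded** in the opposite case, else indeterminate.
Ki67 fractions are simple proportions with exact binomial intervals.
All analyses are 2-D; no section-thickness correction is attempted.
Cells positive for both CD4 and CD8 by IHC thresholding are counted in
both lineage classes.

# The synthetic cohort generator

`synthConfig()` + `generateRepertoireSet()` / `generateCells()` /
`generateSpatial()` emulate the statistical structure the analyses
target, with every planted quantity returned as ground truth:

* **Clone abundances** follow a normalized Zipf law over ranks
  (exponent 1.2 by default), reproducing a dominant clone in the
  ~5-25% range at 2,500 clones per patient; depths default to 10⁵
  reads per tissue (survey-level), 14 patients.
* **Tissue occupancy** is drawn per clone from a 7-way pattern
  distribution; per-tissue reads are multinomial over the occupying
  clones. Default pattern weights favor blood-resident and
  three-tissue clones with a substantial tumor-restricted component.
* **Sequences** are templated (`CASS` + i.i.d. interior + `YF`) and
  back-translated with a fixed two-codon table; 5% of clones carry two
  nucleotypes (convergent recombination); 15% of emitted rows are
  non-productive (stop-codon junctions). Motif families (5 + 4 + 3
  members) are planted in the first patient's tumor-occupying clones.
* **Control library:** 55 donors; 63.9% of clones are absent from the
  library (patient-unique), the remainder get a random prevalence.
* **Cells** are sampled per tissue from the clone abundances (4,000
  per sample), each clone carrying one TRA partner, a lineage and a
  pattern-dependent phenotype; 3% doublets; 2.2% DP cells concentrated
  ~5:1 in tumor. Expression is Poisson around a log-normal 300-gene
  baseline; classifier markers are high-expressed genes (rate 15)
  elevated 2-fold on their own phenotype; exhaustion genes get a
  +1 log-unit shift in tumor-restricted clones.
* **Spatial:** homogeneous Poisson points per side of a straight (or
  sinusoidal) border; defaults CD8 500/100 and CD4 300/150 cells/mm²
  inside/outside, Ki67 positivity 0.15.

What the generator does **not** emulate: V(D)J recombination biology
and germline gene usage, sequencing error beyond multinomial sampling,
ambient RNA and batch effects, cell-type-correlated library sizes, and
spatial clustering beyond piecewise-constant intensity. Passing
recovery tests therefore demonstrates the correctness of the
implementations under the stated sampling models, not robustness to
every artifact of real data.

# Numerical choices and problem sizes

* Determinism: every generator seeds the base RNG once from
  `config$seed` (offsets +1 and +2 for the cell and spatial layers);
  identical seeds give byte-identical outputs.
* Ties in `topClonotypes()` break lexicographically (aa, then nt);
  group ids order by smallest member — both make outputs
  order-invariant.
* Degenerate inputs error early and namedly: empty repertoires,
  all-non-productive samples, unknown tissue labels, undefined
  similarity on two empty samples, zero-area profile bins (flagged,
  density NA).
* The test suite validates at reduced but representative sizes chosen
  for fast feedback: repertoires of 150-1,000 clones at depths
  3×10³-10⁵ (with single 10⁵-depth and 10⁶-depth spot checks),
  single-cell runs of 120-4,000 cells per sample, spatial patterns of
  ~10⁴ points, and 20-replicate property checks; the acceptance script
  runs the full default configuration (14 patients, 2,500 clones,
  depth 10⁵, 3 × 4,000 cells).

# Known limitations

* The phenotype classifier is a transparent marker-score argmax, not a
  trained classifier; it assumes markers are reasonably expressed and
  phenotype prevalence below ~75%.
* Specificity groups are a defined simplification; group membership is
  not comparable to full GLIPH2 output.
* Public-clone and prevalence analyses assume exact amino-acid
  matching; no biochemical similarity.
* Spatial area estimation is grid-based; extremely thin mask slivers
  (< ~0.01 mm² per bin) lose accuracy and are flagged rather than
  corrected.
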