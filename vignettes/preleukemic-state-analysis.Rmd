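---
title: "Methods: detecting a preleukemic B-cell-precursor state"
author: "preleuk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting a preleukemic B-cell-precursor state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preleuk)
```

# The biological question

Activating lesions in the IL-7/TSLP receptor axis (IL7RA, CRLF2) can
hold human B-cell precursors in an early developmental stage and let
cells with aberrant immunoglobulin heavy-chain (IgH) rearrangements
survive selection they would normally fail. In xenograft models this
clinically silent state — a preleukemia — is read out through four data
modalities: mass-cytometry immunophenotypes, IgH repertoire sequencing,
matched bulk RNA-seq, and droplet scRNA-seq. `preleuk` implements the
analysis procedures for each modality and seeded generators that
emulate their inputs, so the whole pipeline is exercised end to end by
the test suite with no external data.

# The developmental classifier

## Model

Healthy bone marrow, manually gated into an ordered series of
B-lymphopoiesis stages, defines the reference. For each stage the mean
vector and covariance of arsinh-transformed expression over a ten-marker
panel are estimated (`buildReference()`), and an event is assigned to
the stage of shortest Mahalanobis distance (`classifyEvents()`). The
model treats each stage as a single multivariate Gaussian on the arsinh
scale: adequate for assignment (only the distance ranking matters), not
a claim that marker expression is Gaussian.

## Parameters

* **arsinh cofactor** (default 5, dimensionless divisor of raw ion
  counts). The transform is `asinh(x / cofactor)`; 5 is the mass
  cytometry community convention. It is configuration on
  `MarkerPanel()` because acquisitions differ.
* **covariance shrinkage** (default 0.05, unitless weight in [0, 1]).
  Gated stages can be small or near-collinear, making the sample
  covariance singular; shrinking toward the diagonal,
  `(1 - s) * S + s * diag(S)`, keeps the metric defined without an
  external prior. `s = 1` reduces to a variance-scaled Euclidean
  distance.
* **stage labels** are configuration, deliberately not hard-coded: the
  gating scheme names its own stages, and only some (pro-BII, pre-BI)
  have canonical names. The default panel ships 11 placeholders.
* **covariance scope.** Per-stage covariances are used (each stage its
  own Σ); a pooled-covariance variant was considered and rejected as the
  default because stage geometries differ strongly across
  B-lymphopoiesis (e.g. TdT is tight in late stages, broad in early
  ones). Per-stage estimation is why shrinkage matters.

## Numerical conventions

Ties in the distance argmin go to the earliest stage in developmental
order, making assignments deterministic. Distances are invariant to any
common permutation of marker columns, enforced by name-based
reordering. An event matrix missing a panel marker is an error, never a
silent subset. Group-level composition (`stageComposition()`) reports a
row of `NaN` with a warning for an empty group rather than silent
zeros.

# IgH repertoire statistics

## Definitions

A record with a J call but no V call and a D call is a **DJ-only**
rearrangement; any V-containing record is **VDJ**; records with neither
V nor D are excluded as unresolved, with a logged count. Productivity
is called from the junction alone: in frame iff the junction length is
divisible by 3, and stop-free iff no in-frame TAA/TAG/TGA occurs within
it; DJ-only records are always nonproductive. This junction-only call
is an approximation of the full AIRR `productive` flag (which would
also scan the V region); it is exact for the bundled synthetic locus
and is the only call available when the junction is the sole sequence
field.

## Weighting

Immunosequencing assays report template counts per rearrangement, so
template weighting (`duplicate_count`) is the default for fractions and
clone frequencies. Because figure-level conventions vary, every
fraction is also computable per unique record (`weighting =
"records"`), and the two can disagree when clone sizes correlate with
rearrangement class — both are surfaced rather than choosing silently.

## Clonality and the oligoclonality comparison

Clonality is `1 - H / ln K` over template-weighted clone frequencies
(0 = perfectly polyclonal, 1 = monoclonal); a single-clone repertoire
is defined as 1 by continuity, with a warning. The two-repertoire
comparison (`compareOligoclonality()`) is this package's own
subsampling construction, not a reconstruction of any vendor pipeline:
both repertoires are subsampled to the common template depth, the
clonality difference is averaged over draws, and the null is generated
by exchanging template labels between the pooled repertoires. It
requires at least 100 templates of common depth and warns below 100
iterations.

# Paired differential expression

The procedure follows the matched-batch design in its canonical order:
(1) remove genes whose summed counts across all paired samples are
below 30; (2) per pair, `d_i = log2(case + 1) - log2(control + 1)` with
no further normalization (the pairing within a batch is the
normalization); (3) the paired statistic `t = dbar / (s_d / sqrt(n))`;
(4) tiers from the t quantiles with n − 1 degrees of freedom —
`P<0.05` when `|t| > qt(0.975, n-1)` (2.571 for the canonical n = 6),
else `P<0.1` when `|t| > qt(0.95, n-1)` (2.015). Inequalities are
strict: a statistic exactly at a cutoff takes the weaker tier. For
n ≠ 6 the cutoffs generalize through the same quantile function.

Genes whose pair fold changes are all identical have `s_d = 0`; they
are flagged degenerate, given t = 0 (when `dbar = 0`) or signed
infinity, and always tiered `none`. Ranked lists order by t or mean
fold change descending with a lexicographic gene-id tie-break, so the
ranking is a reproducible total order. BH-adjusted two-sided p-values
are attached as a clearly separate column; the tier rule itself applies
no multiplicity correction.

Under the generator's null (no planted effects, 6 pairs, 2000 genes)
the `P<0.05` tier flags about 5% of genes — the test suite checks this
fraction against the 99% binomial band, tying the fixed cutoff to its
operating characteristic.

# Gene-set scoring

## Enrichment score

The pre-ranked running sum uses hit increments `|s|^p` normalized by
the set's total and miss decrements `1/(N - N_hit)`; the enrichment
score is the signed extremum. The weight defaults to `p = 1` (the
classic weighted statistic); `p = 0` gives the unweighted
Kolmogorov–Smirnov form. When the positive and negative peaks tie in
magnitude (possible on small lists; a measure-zero event on real
scores), the positive extremum is taken, with a 1e-9 guard band so the
choice is stable under floating-point summation order. The permutation
null redraws the set's positions uniformly (gene-label permutation —
the only null available on a pre-ranked list) and reports
`(1 + #{|ES*| >= |ES|}) / (1 + n_perm)`.

## AUC recovery score

Per cell, genes are ranked by expression (ties broken by seeded uniform
jitter, the seed recorded in the output) and the score is the area
under the set-recovery curve within the top `top_fraction` of the
ranking (default 0.05, the cited method's convention), normalized by
the best achievable area. The score is monotone in set-gene rank
improvements and bounded in [0, 1]. Diagnostic panels (e.g. the
15-gene Ph-like panel) are configuration loaded from GMT, not
hard-coded, since panel membership is an external clinical artifact.

# scRNA-seq QC

Cells are discarded when they fail any of three rules: mitochondrial
fraction above 0.10 (strict), detected genes below `median - 2 MAD`, or
log10 total counts below `median - 2 MAD` (both strict "less than", so
a cell exactly at a realized threshold is kept). The MAD is
consistency-scaled by 1.4826 by default, matching the convention of the
QC library family this pipeline style derives from; a raw-MAD flag
exists because the convention is not universal. The realized absolute
cutoffs are always reported beside the rules, reproducing the dual
reporting style ("2 MADs of detected genes (less than N genes)") on any
dataset — the published absolute numbers (455 genes, 728 counts) are
data-derived and only reproduce on the original libraries.

The phrase "% of the cells' detected genes were mitochondrial" is
ambiguous between a counts fraction and a detected-genes fraction; both
variants are implemented (`variant = "counts"` is the default,
community convention) and the variant used is recorded in the metrics.
Gene filtering keeps genes expressed in ≥ 10 cells; HVG selection takes
the top 99 genes by variance of log1p-normalized expression (the
selection method behind the published subset is unspecified;
variance-of-log is this package's documented choice, with a
lexicographic tie-break), and records perplexity 20 as run metadata for
the downstream embedding, which is itself out of scope. The DE filter
is strict on both arms: |FC| > 2 and FDR < 0.1.

# The synthetic generators

Every generator is a pure function of its config (seed included);
repeated calls are byte-identical, and the caller's RNG state is
restored.

* **Cytometry** (`simulateCytof()`): per-stage multivariate normals on
  the arsinh scale, mapped back to raw intensity through the inverse
  transform so classification exercises its own preprocessing. The
  default geometry places stages at a configurable pairwise Mahalanobis
  separation (6 units by default — cleanly separable, as manually gated
  populations are). Not emulated: heavy-tailed ion-count noise,
  spillover, barcoding artifacts, bead normalization drift. Passing
  tests show the classifier recovers planted structure, not that real
  marrow is Gaussian.
* **Repertoire** (`simulateRepertoire()`): junction assembly over a
  synthetic segment library (V ≈ 300 nt contributing a conserved Cys
  codon, D 15–35 nt, J with a Trp anchor), geometric end trimming,
  Poisson N-insertions per junction, junction-based productivity,
  survival selection against nonproductive VDJ clones, and
  Dirichlet-multinomial clone sizes. The library is synthetic — not
  germline IGH alleles — so frame arithmetic is fully controlled and
  enumerable; no somatic hypermutation, class switching or light
  chains. The clone-size law is a modeling convenience whose single
  concentration knob spans polyclonal to oligoclonal regimes; it is not
  a claim about real clone-size distributions.
* **Paired counts** (`simulatePairedCounts()`): log-normal gene
  baselines (log2 mean 5, sd 2 — spanning the realistic dynamic range
  of bulk libraries), shared per-pair offsets (sd 0.25 log2 units,
  a moderate batch effect), negative-binomial sampling (dispersion
  0.1, typical for bulk RNA-seq), and planted shifts of 2 log2 units in
  case columns. Six pairs by default, matching the canonical design.
* **Single cell** (`simulateScCounts()`): multinomial sampling per cell
  from cluster-specific expression profiles with 8-fold elevated
  signature genes, log-normal library sizes (median ≈ 2000 counts), and
  mitochondrial genes pinned to a configurable expected count fraction.
  Not emulated: dropout beyond multinomial sparsity, doublets, ambient
  RNA.

# Problem sizes

The test and acceptance runs use sizes chosen to make their
statistical bounds sharp while keeping a full suite run under a minute:
11,000 events for mixture recovery, 5,500 events (500 per stage) for
classifier accuracy, 5,000 clones for DJ-fraction recovery, 20,000
clones for the enumeration-oracle comparison, 2,000 genes for null
calibration, and exhaustive subset enumeration on 8-gene lists for the
enrichment-score oracle. Stochastic assertions use 99% binomial or
normal tail bounds at fixed seeds.

# Known limitations

* Productivity from the junction alone can miss V-region defects a full
  repertoire annotator would catch.
* The oligoclonality comparison is a generic exchangeability test; it
  does not model template-count overdispersion within clones.
* The paired t tiers are uncorrected by design (the BH column is an
  extension); at 20,000 genes the `P<0.1` tier is expected to flag
  thousands of nulls.
* The classifier assumes inputs already normalized (bead
  standardization, debarcoding, viability gating are upstream).
* FCS binary parsing is delegated: the contract requires only an
  event × marker table (CSV/TSV), which any FCS reader can produce.
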