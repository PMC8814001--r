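# preleuk

Analysis toolkit for detecting and characterizing **preleukemic
B-cell-precursor states** in humanized xenograft models of
IL7RA/CRLF2-driven leukemogenesis. Constitutive IL-7/TSLP receptor
signaling arrests human B-lymphopoiesis at an early progenitor stage and
lets cells with aberrant immunoglobulin heavy-chain (IgH) rearrangements
escape programmed cell death; this package implements the computational
procedures that detect that state across four data modalities, together
with seeded synthetic generators so every stage is testable without any
data download.

## What it computes

**Developmental classification of mass cytometry events.** Healthy bone
marrow, manually gated into an ordered series of B-lymphopoiesis stages
(11 by default), defines a reference: per stage the mean
arsinh-transformed expression vector μ and covariance Σ over a ten-marker
panel (CD45, CD20, CD24, CD34, CD38, IgMi, TdT, CD19, IgMs, CD10). Each
event *x* is assigned to the stage minimizing the Mahalanobis distance

d(x, stage) = √((x − μ)ᵀ Σ⁻¹ (x − μ)),

with diagonal covariance shrinkage to keep the metric defined on small
gates. A blocked differentiation shows up as a shifted stage composition.

**IgH repertoire statistics** from AIRR rearrangement TSVs: the DJ-only
fraction of rearranged loci (early-precursor hallmark), the
nonproductive-to-total ratio (survival of cells that should have died),
N-insertion length profiles (TdT activity), template-weighted clone
frequencies and clone tracking across samples, and a normalized
clonality index 1 − H/ln K with a subsampling/relabeling comparison of
oligoclonality between repertoires.

**Paired differential expression** for matched case/control bulk RNA-seq:
per-pair fold changes dᵢ = log₂(caseᵢ+1) − log₂(controlᵢ+1), a count-sum
< 30 background filter, the paired statistic

t = d̄ / (S_d / √n),  S_d = √((Σdᵢ² − n·d̄²)/(n−1)),

and two significance tiers from the Student-t quantiles — for the
canonical n = 6 design, P < 0.1 when |t| > t(5, 0.95) = 2.015 and
P < 0.05 when |t| > t(5, 0.975) = 2.571 — plus deterministic gene
ranking for downstream enrichment.

**Gene-set scoring**: the classic weighted running-sum enrichment score
(GSEA statistic) with a gene-label permutation p-value on pre-ranked
lists, and a per-cell AUC recovery score (AUCell statistic) for
evaluating signatures such as the 15-gene Ph-like diagnostic panel on
single cells.

**scRNA-seq QC**: median-absolute-deviation outlier rules (discard cells
beyond 2 MADs below the median of detected genes or log10 total counts,
or above 10% mitochondrial fraction), with the realized absolute
cutoffs always reported beside the rules; gene filtering at 10
expressing cells; highly-variable-gene selection; BH-FDR; and the strict
|FC| > 2, FDR < 0.1 differential-expression filter.

## Worked example

Simulate a preleukemic-like repertoire (expanded DJ-only fraction,
elevated TdT activity, high survival of nonproductive clones) against a
control, and summarize:

```r
library(preleuk)

pre  <- simulateRepertoire(repertoireSimConfig(seed = 42, n_clones = 2000,
          n_cells = 20000, p_dj = 0.25, tdt_lambda = 5,
          nonproductive_survival = 0.8))
ctrl <- simulateRepertoire(repertoireSimConfig(seed = 43, n_clones = 2000,
          n_cells = 20000, p_dj = 0.08, tdt_lambda = 2,
          nonproductive_survival = 0.2))

djFraction(pre, "records")             # 0.300
djFraction(ctrl, "records")            # 0.198
nonproductiveFraction(pre, "records")  # 0.872
nonproductiveFraction(ctrl, "records") # 0.586
nInsertionSummary(pre)$mean            # 8.52
nInsertionSummary(ctrl)$mean           # 3.53
```

The IL7RA-activated condition shows the expected triad: more DJ-only
loci (differentiation arrest), a higher nonproductive ratio (apoptosis
escape) and longer N-insertions (TdT). Paired differential expression on
a 6-pair design with 2% planted effects:

```r
sim <- simulatePairedCounts(pairedCountsSimConfig(seed = 7, n_genes = 5000,
         de_fraction = 0.02, log2_effect = 2))
de <- pairedDE(sim$design)
table(de$table$tier)
#>   none  P<0.1 P<0.05
#>   4270    235    321
head(de$ranked, 3)
#>        gene    score
#> 1 gene04278 41.76329
#> 2 gene04828 22.58721
#> 3 gene03958 17.51094
```

The `P<0.05` tier catches the planted genes (about 100 of the 321 calls
above the 2.571 cutoff are the strong planted effects; the remainder
reflect the tier's uncorrected 5% operating level — see
`significanceCall()` for the BH-adjusted column).

## Documentation

The methods vignette (`vignettes/preleukemic-state-analysis.Rmd`)
describes each model, its assumptions, the tunable parameters and
defaults, what the synthetic generators do and do not emulate, and the
numerical conventions (tie-breaks, degenerate cases, boundary rules).
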