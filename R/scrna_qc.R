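# scRNA-seq quality control: per-cell metrics, MAD-based outlier
# thresholds with realized-cutoff reporting, gene filtering, HVG
# selection, BH-FDR, and the fold-change/FDR DE filter.

#' Per-cell QC metrics
#'
#' Totals, detected genes (nonzero entries) and mitochondrial fraction
#' per cell. The mito fraction is either the fraction of the cell's total
#' counts from mitochondrial genes (\code{variant = "counts"}, the
#' community convention) or the fraction of its detected genes that are
#' mitochondrial (\code{variant = "detected"}); the variant used is
#' recorded in the output.
#'
#' @param counts gene x cell matrix.
#' @param mito_genes mitochondrial gene ids; ids absent from the matrix
#'   draw a warning.
#' @param variant \code{"counts"} or \code{"detected"}.
#' @return data.frame per cell: \code{total_counts, detected_genes,
#'   mito_fraction, all_zero}, with the variant in
#'   \code{attr(, "mito_variant")}. All-zero cells get mito fraction 0
#'   and \code{all_zero = TRUE}.
#' @export
computeQCMetrics <- function(counts, mito_genes = character(),
                             variant = c("counts", "detected")) {
  variant <- match.arg(variant)
  miss <- setdiff(mito_genes, rownames(counts))
  if (length(miss))
    warnf("%d mitochondrial gene id(s) not in the matrix", length(miss))
  mito <- intersect(mito_genes, rownames(counts))
  total <- colSums(counts)
  detected <- colSums(counts > 0)
  if (variant == "counts") {
    mito_val <- colSums(counts[mito, , drop = FALSE])
    mf <- ifelse(total > 0, mito_val / total, 0)
  } else {
    mito_det <- colSums(counts[mito, , drop = FALSE] > 0)
    mf <- ifelse(detected > 0, mito_det / detected, 0)
  }
  out <- data.frame(total_counts = total, detected_genes = detected,
                    mito_fraction = mf, all_zero = total == 0,
                    row.names = colnames(counts))
  attr(out, "mito_variant") <- variant
  out
}

#' MAD-based outlier threshold
#'
#' \code{median(x) -/+ nmads * MAD(x)} with
#' \code{MAD = median(|x - median(x)|)}, multiplied by the 1.4826
#' normal-consistency factor when \code{scaled} (the default, matching
#' the usual QC library convention; raw MAD is available since
#' conventions differ).
#'
#' @param values numeric vector, at least 3 finite values.
#' @param nmads number of MADs (default 2).
#' @param side \code{"lower"} or \code{"upper"}.
#' @param scaled apply the 1.4826 consistency factor.
#' @return The threshold; a zero-spread vector yields the median with a
#'   warning.
#' @examples
#' madThreshold(1:9, nmads = 2, side = "lower", scaled = FALSE)  # 1
#' @export
madThreshold <- function(values, nmads = 2, side = c("lower", "upper"),
                         scaled = TRUE) {
  side <- match.arg(side)
  values <- values[is.finite(values)]
  if (length(values) < 3L) stopf("need at least 3 finite values")
  med <- median(values)
  m <- median(abs(values - med)) * if (scaled) 1.4826 else 1
  if (m == 0) warnf("zero MAD: threshold equals the median")
  if (side == "lower") med - nmads * m else med + nmads * m
}

#' Filter low-quality cells
#'
#' A cell is discarded iff it fails any one of three rules: (1) its
#' mitochondrial fraction exceeds \code{mito_max} (default 10\%); (2) its
#' detected-gene count is below \code{nmads} MADs under the population
#' median; (3) its log10 total counts is below \code{nmads} MADs under
#' the population median. The MAD thresholds are derived from the data at
#' hand, and the realized absolute cutoffs (minimum genes, minimum
#' counts) are reported alongside the rules so a run can be quoted as
#' e.g. "2 MADs of detected genes (less than N genes)". Discards at the
#' lower thresholds are strict: a cell exactly at a realized threshold is
#' kept.
#'
#' @param metrics output of [computeQCMetrics()].
#' @param mito_max maximum mitochondrial fraction (default 0.10; discard
#'   is strict greater-than).
#' @param nmads MADs below the median for the two lower rules (default 2).
#' @param scaled consistency-scale the MAD (default TRUE).
#' @return List with \code{keep} (named logical), \code{thresholds}
#'   (realized cutoffs: \code{genes_min}, \code{log10_counts_min},
#'   \code{counts_min}, \code{mito_max}), and per-rule failure counts.
#' @export
filterCells <- function(metrics, mito_max = 0.10, nmads = 2,
                        scaled = TRUE) {
  if (nrow(metrics) == 0L) stopf("empty metrics")
  genes_min <- madThreshold(metrics$detected_genes, nmads, "lower",
                            scaled)
  log10_counts_min <- madThreshold(log10(metrics$total_counts + 1),
                                   nmads, "lower", scaled)
  fail_mito <- metrics$mito_fraction > mito_max
  fail_genes <- metrics$detected_genes < genes_min
  fail_counts <- log10(metrics$total_counts + 1) < log10_counts_min
  keep <- !(fail_mito | fail_genes | fail_counts)
  names(keep) <- rownames(metrics)
  list(keep = keep,
       thresholds = list(genes_min = genes_min,
                         log10_counts_min = log10_counts_min,
                         counts_min = 10 ^ log10_counts_min - 1,
                         mito_max = mito_max, nmads = nmads,
                         mad_scaled = scaled,
                         mito_variant = attr(metrics, "mito_variant")),
       n_fail = c(mito = sum(fail_mito), genes = sum(fail_genes),
                  counts = sum(fail_counts)))
}

#' Filter rarely expressed genes
#'
#' A gene is kept iff it is nonzero in at least \code{min_cells} cells
#' (default 10: expressed in 9 cells is discarded, in 10 kept).
#'
#' @param counts gene x cell matrix.
#' @param min_cells minimum expressing cells.
#' @return Named logical vector, TRUE = kept.
#' @export
filterGenes <- function(counts, min_cells = 10) {
  stopifnot(min_cells >= 0)
  keep <- rowSums(counts > 0) >= min_cells
  names(keep) <- rownames(counts)
  keep
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p-normalized expression
#' (counts scaled per cell to the median library size before log1p) and
#' returns the top \code{n_top} (default 99, the embedding-input subset
#' size), ties broken lexicographically by gene id. Run metadata records
#' the downstream embedding perplexity (20) for provenance; no embedding
#' is computed here.
#'
#' @param counts gene x cell matrix.
#' @param n_top number of genes to select.
#' @return Character vector of gene ids, with the per-gene variances and
#'   the recorded perplexity as attributes.
#' @export
selectHVG <- function(counts, n_top = 99) {
  if (n_top > nrow(counts))
    stopf("n_top (%d) exceeds gene count (%d)", n_top, nrow(counts))
  libsize <- colSums(counts)
  scale_to <- median(libsize[libsize > 0])
  norm <- sweep(counts, 2L, ifelse(libsize > 0, libsize, 1), "/") *
    scale_to
  v <- apply(log1p(norm), 1L, var)
  ord <- order(-v, rownames(counts))
  sel <- rownames(counts)[ord[seq_len(n_top)]]
  structure(sel, variance = v[ord[seq_len(n_top)]],
            tsne_perplexity = 20)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; values are validated to lie
#' in [0, 1].
#'
#' @param pvalues numeric vector of p-values.
#' @return Adjusted values, same length and order.
#' @export
bhFDR <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Differential-expression gene filter
#'
#' Flags a gene iff its absolute (linear-scale) fold change strictly
#' exceeds \code{fc_min} and its FDR is strictly below \code{fdr_max}
#' (defaults 2 and 0.1; FC exactly 2 or FDR exactly 0.1 is not flagged).
#'
#' @param fold_changes per-gene linear fold changes (values in (0, 1)
#'   denote downregulation and are compared as 1/FC; alternatively pass
#'   signed log2 fold changes with \code{log2_scale = TRUE}).
#' @param fdr_values per-gene FDR, aligned with \code{fold_changes}.
#' @param fc_min minimum absolute fold change (exclusive).
#' @param fdr_max maximum FDR (exclusive).
#' @param log2_scale interpret \code{fold_changes} as log2 values.
#' @return Logical mask of differentially expressed genes.
#' @export
deGeneFilter <- function(fold_changes, fdr_values, fc_min = 2,
                         fdr_max = 0.1, log2_scale = FALSE) {
  if (length(fold_changes) != length(fdr_values))
    stopf("fold-change and FDR vectors differ in length")
  absfc <- if (log2_scale) 2 ^ abs(fold_changes)
           else pmax(fold_changes, 1 / fold_changes)
  absfc > fc_min & fdr_values < fdr_max
}
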