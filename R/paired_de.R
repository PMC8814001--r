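# Paired bulk differential expression: log2(count+1) per-pair fold
# changes, low-count filtering, the paired t statistic, significance
# tiers at fixed t quantile cutoffs, and ranked-list export.

#' Per-pair log2 fold changes
#'
#' For each gene and each matched pair,
#' \eqn{d_i = \log_2(case_i + 1) - \log_2(control_i + 1)}; the +1 offset
#' keeps zero counts well-defined. No other normalization is applied.
#'
#' @param design a [PairedCountsDesign-class].
#' @return List with \code{d} (gene x pair matrix of per-pair fold
#'   changes) and \code{dbar} (per-gene mean fold change).
#' @export
log2FCPaired <- function(design) {
  stopifnot(is(design, "PairedCountsDesign"))
  cts <- designCounts(design)
  prs <- designPairs(design)
  d <- log2(cts[, prs$case, drop = FALSE] + 1) -
       log2(cts[, prs$control, drop = FALSE] + 1)
  colnames(d) <- sprintf("d_%d", seq_len(nrow(prs)))
  list(d = d, dbar = rowMeans(d))
}

#' Low-count gene filter
#'
#' Removes background-level genes: a gene is retained iff its summed
#' counts across both members of all pairs reach \code{threshold}
#' (default 30; a total of 29 is removed, 30 retained).
#'
#' @param design a [PairedCountsDesign-class].
#' @param threshold minimum count sum (default 30).
#' @return Named logical vector, TRUE = retained.
#' @export
lowCountFilter <- function(design, threshold = 30) {
  stopifnot(is(design, "PairedCountsDesign"), threshold >= 0)
  prs <- designPairs(design)
  ids <- c(prs$case, prs$control)
  rowSums(designCounts(design)[, ids, drop = FALSE]) >= threshold
}

#' Paired t statistic on per-pair fold changes
#'
#' For each gene, \eqn{t = (\bar d - 0) / (S_d / \sqrt n)} with
#' \eqn{S_d = \sqrt{(\sum d_i^2 - n \bar d^2) / (n - 1)}} over the n
#' matched pairs. Degenerate genes (all pair fold changes identical,
#' \eqn{S_d = 0}) get t = 0 when \eqn{\bar d = 0} and signed infinity
#' otherwise, flagged in the output.
#'
#' @param fc output of [log2FCPaired()] (or any list with a gene x pair
#'   matrix \code{d}).
#' @return data.frame with \code{dbar}, \code{s_d}, \code{n}, \code{t}
#'   and \code{degenerate} per gene.
#' @export
pairedT <- function(fc) {
  d <- fc$d
  n <- ncol(d)
  if (n < 2L) stopf("need at least 2 pairs, got %d", n)
  dbar <- rowMeans(d)
  ss <- rowSums(d ^ 2)
  s_d <- sqrt(pmax(ss - n * dbar ^ 2, 0) / (n - 1))
  degenerate <- s_d == 0
  t <- ifelse(degenerate, ifelse(dbar == 0, 0, sign(dbar) * Inf),
              dbar / (s_d / sqrt(n)))
  data.frame(dbar = dbar, s_d = s_d, n = n, t = t,
             degenerate = degenerate, row.names = rownames(d))
}

#' Significance tiers from t quantile cutoffs
#'
#' Two-tier calls against the Student-t quantiles with n-1 degrees of
#' freedom: \code{P<0.05} when \eqn{|t| > t_{n-1, 0.975}}, else
#' \code{P<0.1} when \eqn{|t| > t_{n-1, 0.95}}, else \code{none}.
#' Inequalities are strict, so a statistic exactly at a cutoff gets the
#' weaker tier. For the canonical 6-pair design these cutoffs are
#' \eqn{t_{5, 0.95} = 2.015} and \eqn{t_{5, 0.975} = 2.571}. Degenerate
#' genes are tier \code{none}. Benjamini-Hochberg adjusted two-sided
#' p-values are attached as an extra column; they are an extension, not
#' part of the tier rule.
#'
#' @param result output of [pairedT()].
#' @return The input with \code{p_value}, \code{tier} (factor: none,
#'   P<0.1, P<0.05) and \code{fdr} columns.
#' @export
significanceCall <- function(result) {
  n <- result$n[1]
  cut10 <- qt(0.95, df = n - 1)
  cut05 <- qt(0.975, df = n - 1)
  at <- abs(result$t)
  tier <- ifelse(result$degenerate, "none",
          ifelse(at > cut05, "P<0.05",
          ifelse(at > cut10, "P<0.1", "none")))
  result$p_value <- 2 * stats::pt(at, df = n - 1, lower.tail = FALSE)
  result$tier <- factor(tier, levels = c("none", "P<0.1", "P<0.05"))
  result$fdr <- bhFDR(ifelse(is.na(result$p_value), 1, result$p_value))
  result
}

#' Rank genes by t statistic or mean fold change
#'
#' Descending order of the chosen score; ties broken lexicographically by
#' gene id so the ranking is a deterministic total order.
#'
#' @param result output of [pairedT()] / [significanceCall()], with gene
#'   ids as rownames.
#' @param by \code{"t"} or \code{"fc"} (mean log2 fold change).
#' @return data.frame with \code{gene} and \code{score}, ordered; suitable
#'   as a pre-ranked list for [gseaEnrichmentScore()].
#' @export
rankGenes <- function(result, by = c("t", "fc")) {
  by <- match.arg(by)
  if (nrow(result) == 0L) stopf("empty result")
  score <- if (by == "t") result$t else result$dbar
  gene <- rownames(result)
  ord <- order(-score, gene)
  data.frame(gene = gene[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Paired differential-expression pipeline
#'
#' Convenience wrapper running the full procedure in its canonical order:
#' low-count filter, per-pair log2(count+1) fold changes, paired t,
#' tiers, ranking. Filtered genes never enter the t computation or the
#' ranked list.
#'
#' @param design a [PairedCountsDesign-class].
#' @param count_threshold low-count filter threshold (default 30).
#' @param rank_by \code{"t"} or \code{"fc"}.
#' @return List with \code{table} (per-gene results) and \code{ranked}
#'   (ranked list).
#' @export
pairedDE <- function(design, count_threshold = 30, rank_by = "t") {
  keep <- lowCountFilter(design, count_threshold)
  kept <- PairedCountsDesign(designCounts(design)[keep, , drop = FALSE],
                             designPairs(design))
  res <- significanceCall(pairedT(log2FCPaired(kept)))
  list(table = res, ranked = rankGenes(res, rank_by))
}
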