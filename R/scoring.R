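# Gene-set scoring: pre-ranked weighted running-sum enrichment (GSEA
# statistic) and per-cell AUC of gene-set recovery (AUCell statistic).

#' GSEA enrichment score on a pre-ranked list
#'
#' Classic weighted Kolmogorov-Smirnov running sum: walking down the
#' ranked list, a hit (set gene) increments the sum by
#' \eqn{|s|^p / \sum_{hits} |s|^p} and a miss decrements it by
#' \eqn{1/(N - N_{hit})}; the enrichment score is the signed extremum of
#' the running sum. ES near +1 means the set is concentrated at the top
#' of the ranking.
#'
#' @param ranked data.frame with columns \code{gene} and \code{score},
#'   ordered by decreasing score (as produced by [rankGenes()]).
#' @param set a [GeneSet-class].
#' @param weight_p hit-weight exponent p >= 0 (default 1, the classic
#'   weighted statistic; 0 gives the unweighted KS form).
#' @return List with \code{es}, \code{running} (the full running sum),
#'   \code{hits} (positions of set genes) and \code{leading_edge} (set
#'   genes at or before the extremum when ES > 0, after it when ES < 0).
#' @export
gseaEnrichmentScore <- function(ranked, set, weight_p = 1) {
  stopifnot(weight_p >= 0)
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% geneIds(set)
  nh <- sum(hit)
  if (nh == 0L) stopf("no overlap between gene set '%s' and ranked list",
                      geneSetName(set))
  if (nh == N) stopf("gene set covers the entire ranked list")
  w <- abs(ranked$score) ^ weight_p
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - nh)
  running <- cumsum(inc)
  # signed extremum; an (up to numerical noise) exact tie between the
  # positive and negative peaks resolves to the positive one
  pos <- max(running); neg <- min(running)
  take_pos <- pos >= -neg - 1e-9
  i_ext <- if (take_pos) which.max(running) else which.min(running)
  es <- running[i_ext]
  le <- if (es >= 0) genes[hit & seq_len(N) <= i_ext]
        else genes[hit & seq_len(N) > i_ext]
  list(es = es, running = running, hits = which(hit), leading_edge = le)
}

#' Permutation p-value for an enrichment score
#'
#' Gene-label permutation null (the pre-ranked GSEA convention: the set's
#' positions are redrawn uniformly, sample permutation being unavailable
#' for a pre-ranked list):
#' \eqn{p = (1 + \#\{|ES^*| \ge |ES|\}) / (1 + n_{perm})}.
#'
#' @inheritParams gseaEnrichmentScore
#' @param n_perm permutations, >= 100.
#' @param seed RNG seed.
#' @return List with \code{es}, \code{p_value}, \code{n_perm},
#'   \code{seed}.
#' @export
gseaPermutationP <- function(ranked, set, weight_p = 1, n_perm = 999,
                             seed = 1) {
  if (n_perm < 100) stopf("n_perm must be at least 100")
  obs <- gseaEnrichmentScore(ranked, set, weight_p)
  nh <- length(obs$hits)
  N <- nrow(ranked)
  w <- abs(ranked$score) ^ weight_p
  esFromHits <- function(idx) {
    inc <- rep(-1 / (N - nh), N)
    inc[idx] <- w[idx] / sum(w[idx])
    running <- cumsum(inc)
    pos <- max(running); neg <- min(running)
    if (pos >= -neg - 1e-9) pos else neg
  }
  withSeed(seed, {
    null <- replicate(n_perm, esFromHits(sample.int(N, nh)))
  })
  list(es = obs$es,
       p_value = (1 + sum(abs(null) >= abs(obs$es))) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

# Per-cell gene rankings from a counts matrix: rank 1 = highest count.
# Ties are broken by uniform jitter under the given seed so every cell
# has a strict ranking (the droplet-data convention for AUC recovery
# scoring); the seed is recorded by callers.
.cellRankings <- function(counts, seed = 1) {
  withSeed(seed, {
    jitter <- matrix(runif(length(counts)), nrow(counts))
    apply(counts + jitter - 0.5, 2L,
          function(x) rank(-x, ties.method = "first"))
  })
}

#' Per-cell AUC gene-set recovery score
#'
#' For one cell, genes are ranked by expression and the recovery curve
#' \eqn{R(i)} counts set genes found at rank <= i for i = 1..k, with
#' \eqn{k = \lceil top\_fraction \cdot N \rceil}. The score is the area
#' \eqn{\sum_{i=1}^k R(i)} normalized by its maximum (all set genes
#' packed at the very top), so it lies in [0, 1]: 1 when the whole set
#' sits at the top of the cell's ranking, 0 when no set gene enters the
#' top k.
#'
#' @param counts gene x cell expression matrix (any monotone scale), or a
#'   precomputed gene x cell ranking matrix with
#'   \code{is_ranking = TRUE}.
#' @param set a [GeneSet-class]; symbols absent from the matrix are
#'   ignored (at least one must be present).
#' @param top_fraction fraction of the ranking scanned (default 0.05).
#' @param seed jitter seed for expression ties.
#' @param is_ranking set TRUE when \code{counts} already holds per-cell
#'   ranks (1 = highest).
#' @return List with \code{scores} (named per-cell vector in [0, 1]),
#'   \code{k}, \code{n_set_used}, \code{missing_genes}, \code{seed}.
#' @export
aucellScore <- function(counts, set, top_fraction = 0.05, seed = 1,
                        is_ranking = FALSE) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (length(geneIds(set)) == 0L) stopf("empty gene set")
  present <- geneIds(set) %in% rownames(counts)
  if (!any(present))
    stopf("no gene of set '%s' found in the expression matrix",
          geneSetName(set))
  rk <- if (is_ranking) counts else .cellRankings(counts, seed)
  N <- nrow(rk)
  k <- ceiling(top_fraction * N)
  setrk <- rk[geneIds(set)[present], , drop = FALSE]
  nset <- nrow(setrk)
  auc_max <- if (nset >= k) k * (k + 1) / 2
             else nset * (nset + 1) / 2 + (k - nset) * nset
  # sum over i<=k of R(i) equals sum over set genes of (k - rank + 1)+
  raw <- colSums(pmax(k - setrk + 1, 0))
  list(scores = raw / auc_max, k = k, n_set_used = nset,
       missing_genes = geneIds(set)[!present], seed = seed)
}

#' Score a clinical gene panel per cell or sample
#'
#' Evaluates a diagnostic expression panel (e.g. the 15-gene Ph-like
#' panel) on a count matrix, either as a per-cell AUC recovery score
#' (default) or as the mean log1p expression of the panel genes. Panel
#' genes missing from the matrix are reported; an empty overlap is an
#' error naming every missing gene.
#'
#' @param counts gene x cell (or gene x sample) matrix.
#' @param panel a [GeneSet-class].
#' @param method \code{"aucell"} or \code{"mean_log"}.
#' @param top_fraction,seed passed to [aucellScore()].
#' @return List with \code{scores} (named numeric per column),
#'   \code{method} and \code{missing_genes}.
#' @export
scorePanel <- function(counts, panel, method = c("aucell", "mean_log"),
                       top_fraction = 0.05, seed = 1) {
  method <- match.arg(method)
  present <- geneIds(panel) %in% rownames(counts)
  if (!any(present))
    stopf("no panel gene present in the matrix; missing: %s",
          paste(geneIds(panel), collapse = ", "))
  if (method == "aucell") {
    res <- aucellScore(counts, panel, top_fraction, seed)
    list(scores = res$scores, method = method,
         missing_genes = res$missing_genes)
  } else {
    sub <- counts[geneIds(panel)[present], , drop = FALSE]
    list(scores = colMeans(log1p(sub)), method = method,
         missing_genes = geneIds(panel)[!present])
  }
}
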