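# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately use different arithmetic routes
# than the code under test.

# Paired t statistic via R's stock paired t-test.
oracle_paired_t <- function(d) {
  unname(stats::t.test(d, mu = 0)$statistic)
}

# GSEA enrichment score by literal position-by-position enumeration of
# the running sum.
oracle_es <- function(scores, hit, p = 1) {
  N <- length(scores)
  nh <- sum(hit)
  sum_w <- sum(abs(scores[hit])^p)
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + abs(scores[i])^p / sum_w
           else cur - 1 / (N - nh)
    run[i] <- cur
  }
  pos <- max(run)
  neg <- min(run)
  if (pos >= -neg - 1e-9) pos else neg
}

# Benjamini-Hochberg by the step-up definition: sort, take running
# minima of p_(i) * m / i from the largest rank down, map back.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- ps * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Mahalanobis distance via explicit matrix inversion.
oracle_mahal <- function(x, mu, S) {
  d <- x - mu
  sqrt(drop(t(d) %*% solve(S) %*% d))
}

# Stop-codon scan by regex: any whole number of leading codons followed
# by an in-frame stop.
oracle_has_stop <- function(junction) {
  grepl("^([ACGTN]{3})*(TAA|TAG|TGA)", junction)
}

# Small hand-buildable AIRR repertoire.
make_repertoire <- function(v_call, d_call, j_call, junction,
                            duplicate_count = 1L) {
  n <- max(lengths(list(v_call, d_call, j_call, junction)))
  data.frame(sequence_id = sprintf("seq%03d", seq_len(n)),
             v_call = v_call, d_call = d_call, j_call = j_call,
             junction = junction, productive = NA,
             duplicate_count = as.integer(duplicate_count),
             stringsAsFactors = FALSE)
}

# Shared small clustered single-cell simulation (cached per session).
sc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateScCounts(scSimConfig(seed = 101, n_cells = 300,
                                             n_genes = 600))
    cache
  }
})
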