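# Seeded generators producing inputs with the statistical structure the
# analyses assume: stage-structured cytometry events, V(D)J repertoires,
# paired negative-binomial bulk counts, and clustered single-cell counts.
# Every generator is a pure function of its config (seed included).

#' Cytometry simulation configuration
#'
#' Emulates healthy-marrow stage-structured marker expression: events are
#' drawn per developmental stage from a multivariate normal on the arsinh
#' scale. Default geometry places stage k (k >= 2) at
#' \code{separation} along marker axis k-1 with stage 1 at the origin and
#' unit covariances, so the smallest pairwise stage-mean separation is
#' exactly \code{separation} Mahalanobis units.
#'
#' @param seed RNG seed.
#' @param n_events total events to draw.
#' @param panel a [MarkerPanel-class] (default: the ten B-lineage markers).
#' @param stage_labels ordered stage labels (default 11 placeholder
#'   stages; rename to the gating scheme in use).
#' @param stage_proportions simplex over stages (default uniform).
#' @param separation pairwise stage-mean separation, Mahalanobis units,
#'   used when \code{stage_means} is NULL.
#' @param stage_means optional stage x marker matrix (arsinh scale).
#' @param stage_covs optional list of per-stage positive-definite
#'   covariances (default identity).
#' @return A \code{CytofSimConfig} list.
#' @export
cytofSimConfig <- function(seed = 1, n_events = 11000,
                           panel = MarkerPanel(),
                           stage_labels = sprintf("stage%02d", 1:11),
                           stage_proportions = NULL, separation = 6,
                           stage_means = NULL, stage_covs = NULL) {
  k <- length(stage_labels)
  p <- length(markerNames(panel))
  if (k > p + 1L && is.null(stage_means))
    stopf("default geometry supports at most %d stages for %d markers",
          p + 1L, p)
  if (is.null(stage_proportions))
    stage_proportions <- rep(1 / k, k)
  if (abs(sum(stage_proportions) - 1) > 1e-12)
    stopf("stage proportions must sum to 1")
  if (any(stage_proportions < 0))
    stopf("stage proportions must be non-negative")
  if (is.null(stage_means)) {
    stage_means <- matrix(0, k, p,
                          dimnames = list(stage_labels, markerNames(panel)))
    for (i in seq_len(k - 1L)) stage_means[i + 1L, i] <- separation
  }
  if (is.null(stage_covs))
    stage_covs <- rep(list(diag(p)), k)
  for (i in seq_len(k)) {
    S <- stage_covs[[i]]
    if (max(abs(S - t(S))) > 1e-10 ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stopf("stage covariance %d must be symmetric positive-definite", i)
  }
  structure(list(seed = seed, n_events = as.integer(n_events),
                 panel = panel, stage_labels = stage_labels,
                 stage_proportions = stage_proportions,
                 stage_means = stage_means, stage_covs = stage_covs),
            class = "CytofSimConfig")
}

#' Simulate stage-structured cytometry events
#'
#' Draws each event's developmental stage from the configured mixture,
#' samples its arsinh-scale marker vector from the stage's multivariate
#' normal, and maps back to raw intensity via the inverse transform
#' (\code{sinh(z) * cofactor}) so the classifier's own preprocessing is
#' exercised end to end.
#'
#' @param config a [cytofSimConfig()] bundle.
#' @return List with \code{events} (event x marker raw-intensity matrix)
#'   and \code{labels} (factor of true stages, levels in stage order).
#' @export
simulateCytof <- function(config) {
  stopifnot(inherits(config, "CytofSimConfig"))
  withSeed(config$seed, {
    k <- length(config$stage_labels)
    stage <- sample.int(k, config$n_events, replace = TRUE,
                        prob = config$stage_proportions)
    p <- length(markerNames(config$panel))
    z <- matrix(NA_real_, config$n_events, p,
                dimnames = list(sprintf("event%06d",
                                        seq_len(config$n_events)),
                                markerNames(config$panel)))
    for (j in seq_len(k)) {
      idx <- which(stage == j)
      if (length(idx))
        z[idx, ] <- MASS::mvrnorm(length(idx), config$stage_means[j, ],
                                  config$stage_covs[[j]])
    }
    events <- sinh(z) * arsinhCofactor(config$panel)
    list(events = events,
         labels = factor(config$stage_labels[stage],
                         levels = config$stage_labels))
  })
}

#' Synthetic V/D/J segment library
#'
#' Generates a fixed, seed-determined library of synthetic heavy-chain
#' segment junction contributions with realistic lengths and an annotated
#' conserved frame anchor: each V contributes a conserved-Cys codon (TGT)
#' plus 0-6 trailing nucleotides, each D a full 15-35 nt sequence, each J
#' 0-6 leading nucleotides plus the anchor Trp codon (TGG). These are
#' synthetic sequences, not germline IGH alleles; they exist to make the
#' frame arithmetic of junction assembly fully controlled.
#'
#' @param seed library seed (default 42; change to get a different
#'   synthetic locus).
#' @param n_v,n_d,n_j segment counts.
#' @return List with character vectors \code{v} (Cys codon + tail),
#'   \code{d}, \code{j} (head + Trp codon), named IGHVs1..., IGHDs1...,
#'   IGHJs1....
#' @export
segmentLibrary <- function(seed = 42, n_v = 20, n_d = 8, n_j = 4) {
  withSeed(seed, {
    rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
    v <- vapply(seq_len(n_v),
                function(i) paste0("TGT", rseq(sample(0:6, 1))),
                character(1))
    d <- vapply(seq_len(n_d),
                function(i) rseq(sample(15:35, 1)), character(1))
    j <- vapply(seq_len(n_j),
                function(i) paste0(rseq(sample(0:6, 1)), "TGG"),
                character(1))
    list(v = setNames(v, sprintf("IGHVs%d", seq_len(n_v))),
         d = setNames(d, sprintf("IGHDs%d", seq_len(n_d))),
         j = setNames(j, sprintf("IGHJs%d", seq_len(n_j))))
  })
}

#' Repertoire simulation configuration
#'
#' Parameters of the V(D)J junction-assembly simulator. \code{p_dj} is
#' the probability that a clone carries an incomplete DJ-only
#' rearrangement; \code{tdt_lambda} the Poisson mean N-insertion length
#' per junction segment (TdT activity); \code{trim_p} the geometric
#' success parameter for exonucleolytic end trimming (1 = no trimming);
#' \code{nonproductive_survival} the probability that a clone whose VDJ
#' rearrangement is nonproductive escapes programmed cell death — the
#' survival advantage conferred by constitutive IL7RA/TSLP signaling.
#'
#' @param seed RNG seed.
#' @param n_cells total templates (cells) sequenced.
#' @param n_clones clones before selection.
#' @param clone_concentration Dirichlet concentration for clone sizes
#'   (small = oligoclonal, large = polyclonal).
#' @param p_dj probability a clone is DJ-only.
#' @param tdt_lambda mean N-insertion length per junction segment.
#' @param trim_p geometric trimming parameter in (0, 1].
#' @param nonproductive_survival survival probability of nonproductive
#'   VDJ clones in [0, 1].
#' @param segments a [segmentLibrary()].
#' @return A \code{RepertoireSimConfig} list.
#' @export
repertoireSimConfig <- function(seed = 1, n_cells = 10000,
                                n_clones = 1000,
                                clone_concentration = 1,
                                p_dj = 0.1, tdt_lambda = 3,
                                trim_p = 0.5,
                                nonproductive_survival = 0.1,
                                segments = segmentLibrary()) {
  stopifnot(p_dj >= 0, p_dj <= 1, tdt_lambda >= 0,
            trim_p > 0, trim_p <= 1,
            nonproductive_survival >= 0, nonproductive_survival <= 1,
            clone_concentration > 0, n_clones <= n_cells)
  structure(list(seed = seed, n_cells = as.integer(n_cells),
                 n_clones = as.integer(n_clones),
                 clone_concentration = clone_concentration, p_dj = p_dj,
                 tdt_lambda = tdt_lambda, trim_p = trim_p,
                 nonproductive_survival = nonproductive_survival,
                 segments = segments),
            class = "RepertoireSimConfig")
}

# Geometric trim length capped at the trimmable span (rgeom counts
# failures before the first success, support 0, 1, 2, ...).
.trim <- function(p, max_len) min(rgeom(1L, p), max_len)

.nseq <- function(lambda) {
  n <- rpois(1L, lambda)
  if (n == 0L) "" else paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
}

#' Simulate an IgH rearrangement repertoire
#'
#' Per clone: a DJ-only rearrangement with probability \code{p_dj},
#' otherwise a complete VDJ; segments drawn uniformly from the library;
#' segment ends trimmed Geometric(\code{trim_p}) (the V's conserved Cys
#' and the J's Trp anchor are never trimmed); Poisson(\code{tdt_lambda})
#' non-templated nucleotides inserted at each junction (two junctions for
#' VDJ, one for DJ); productivity called from the assembled junction
#' (frame + stop scan, [callFrameProductivity()]). Nonproductive VDJ
#' clones survive selection with probability
#' \code{nonproductive_survival}; DJ-only clones are not selected against
#' (the productive allele is unobserved). Clone template counts follow a
#' Dirichlet-multinomial over surviving clones; clones drawn zero times
#' are unobserved and dropped.
#'
#' @param config a [repertoireSimConfig()] bundle.
#' @return An AIRR-style data.frame (one row per observed clone) with the
#'   standard columns plus \code{np1_length}/\code{np2_length} and the
#'   productivity calls.
#' @export
simulateRepertoire <- function(config) {
  stopifnot(inherits(config, "RepertoireSimConfig"))
  seg <- config$segments
  withSeed(config$seed, {
    k <- config$n_clones
    is_dj <- runif(k) < config$p_dj
    rows <- vector("list", k)
    for (i in seq_len(k)) {
      di <- sample(seq_along(seg$d), 1L)
      ji <- sample(seq_along(seg$j), 1L)
      dseq <- seg$d[[di]]
      jseq <- seg$j[[ji]]
      dlen <- nchar(dseq)
      d_tr <- substr(dseq, 1L + .trim(config$trim_p, dlen - 1L), dlen)
      d_tr <- substr(d_tr, 1L,
                     nchar(d_tr) - .trim(config$trim_p, nchar(d_tr) - 1L))
      j_tr <- substr(jseq, 1L + .trim(config$trim_p, nchar(jseq) - 3L),
                     nchar(jseq))
      if (is_dj[i]) {
        n1 <- .nseq(config$tdt_lambda)
        rows[[i]] <- data.frame(
          v_call = NA_character_, d_call = names(seg$d)[di],
          j_call = names(seg$j)[ji],
          junction = paste0(d_tr, n1, j_tr),
          np1_length = nchar(n1), np2_length = NA_integer_,
          stringsAsFactors = FALSE)
      } else {
        vi <- sample(seq_along(seg$v), 1L)
        vseq <- seg$v[[vi]]
        v_tr <- substr(vseq, 1L,
                       nchar(vseq) - .trim(config$trim_p,
                                           nchar(vseq) - 3L))
        n1 <- .nseq(config$tdt_lambda)
        n2 <- .nseq(config$tdt_lambda)
        rows[[i]] <- data.frame(
          v_call = names(seg$v)[vi], d_call = names(seg$d)[di],
          j_call = names(seg$j)[ji],
          junction = paste0(v_tr, n1, d_tr, n2, j_tr),
          np1_length = nchar(n1), np2_length = nchar(n2),
          stringsAsFactors = FALSE)
      }
    }
    clones <- do.call(rbind, rows)
    clones$sequence_id <- sprintf("clone%05d", seq_len(k))
    clones$productive <- NA
    clones$duplicate_count <- 1L
    clones <- callFrameProductivity(clones)
    survives <- clones$productive | is_dj |
      (runif(k) < config$nonproductive_survival)
    if (!any(survives))
      stopf("empty repertoire: selection removed every clone; increase n_clones or nonproductive_survival")
    clones <- clones[survives, , drop = FALSE]
    w <- rgamma(nrow(clones), shape = config$clone_concentration, rate = 1)
    sizes <- as.integer(rmultinom(1L, config$n_cells, prob = w))
    clones$duplicate_count <- sizes
    clones <- clones[sizes > 0L, , drop = FALSE]
    rownames(clones) <- NULL
    clones[, c("sequence_id", "v_call", "d_call", "j_call", "junction",
               "np1_length", "np2_length", "frame_status", "has_stop",
               "productive", "duplicate_count")]
  })
}

#' Paired bulk-counts simulation configuration
#'
#' Emulates a matched case/control bulk RNA-seq design: \code{n_pairs}
#' cord-blood batches each contributing one receptor-transduced (case)
#' and one backbone-control library, gene baselines log-normal on the
#' log2 scale, a shared per-pair offset (batch effect), and
#' negative-binomial counts. A fraction of genes is planted as
#' differentially expressed by shifting case columns \code{log2_effect}
#' log2 units.
#'
#' @param seed RNG seed.
#' @param n_pairs matched pairs (default 6).
#' @param n_genes genes.
#' @param de_fraction fraction of genes planted DE.
#' @param log2_effect planted shift (log2) in case columns.
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @param pair_effect_sd SD (log2) of the shared per-pair offset.
#' @param baseline_log2_mean,baseline_log2_sd gene baseline distribution
#'   on the log2 scale.
#' @return A \code{PairedCountsSimConfig} list.
#' @export
pairedCountsSimConfig <- function(seed = 1, n_pairs = 6, n_genes = 2000,
                                  de_fraction = 0.05, log2_effect = 2,
                                  nb_dispersion = 0.1,
                                  pair_effect_sd = 0.25,
                                  baseline_log2_mean = 5,
                                  baseline_log2_sd = 2) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, nb_dispersion >= 0,
            n_pairs >= 2)
  structure(list(seed = seed, n_pairs = as.integer(n_pairs),
                 n_genes = as.integer(n_genes),
                 de_fraction = de_fraction, log2_effect = log2_effect,
                 nb_dispersion = nb_dispersion,
                 pair_effect_sd = pair_effect_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd),
            class = "PairedCountsSimConfig")
}

#' Simulate paired case/control count matrices
#'
#' @param config a [pairedCountsSimConfig()] bundle.
#' @return List with \code{design} (a [PairedCountsDesign-class]) and
#'   \code{de_genes} (logical truth vector; all FALSE when
#'   \code{log2_effect} is 0).
#' @export
simulatePairedCounts <- function(config) {
  stopifnot(inherits(config, "PairedCountsSimConfig"))
  withSeed(config$seed, {
    g <- config$n_genes; np <- config$n_pairs
    genes <- sprintf("gene%05d", seq_len(g))
    base <- rnorm(g, config$baseline_log2_mean, config$baseline_log2_sd)
    offs <- rnorm(np, 0, config$pair_effect_sd)
    n_de <- round(config$de_fraction * g)
    de <- logical(g)
    if (n_de > 0) de[sample.int(g, n_de)] <- TRUE
    effect <- ifelse(de, config$log2_effect, 0)
    if (config$log2_effect == 0) de[] <- FALSE
    draw <- function(mu) {
      if (config$nb_dispersion == 0) rpois(length(mu), mu)
      else rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
    cols <- vector("list", 2L * np)
    ids <- character(2L * np)
    for (b in seq_len(np)) {
      cols[[2L * b - 1L]] <- draw(2 ^ (base + offs[b] + effect))
      cols[[2L * b]] <- draw(2 ^ (base + offs[b]))
      ids[2L * b - 1L] <- sprintf("case_%d", b)
      ids[2L * b] <- sprintf("ctrl_%d", b)
    }
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(genes, ids)
    storage.mode(counts) <- "integer"
    design <- PairedCountsDesign(counts,
      data.frame(case = sprintf("case_%d", seq_len(np)),
                 control = sprintf("ctrl_%d", seq_len(np))))
    list(design = design, de_genes = setNames(de, genes))
  })
}

#' Clustered single-cell counts simulation configuration
#'
#' Emulates a clustered droplet scRNA-seq count matrix with planted
#' per-cluster signature genes (elevated \code{signature_fold}-fold in
#' their own cluster) and a controllable mitochondrial count fraction:
#' genes named with the \code{MT-} prefix contribute
#' \code{mito_count_fraction} of every cell's expected counts.
#'
#' @param seed RNG seed.
#' @param n_cells,n_genes matrix dimensions.
#' @param cluster_proportions simplex over clusters (default 4 equal).
#' @param n_signature signature genes per cluster.
#' @param signature_fold fold elevation of a cluster's signature genes.
#' @param mito_gene_fraction fraction of genes flagged mitochondrial.
#' @param mito_count_fraction expected fraction of each cell's counts
#'   from mitochondrial genes.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size
#'   parameters (natural log).
#' @return An \code{ScSimConfig} list.
#' @export
scSimConfig <- function(seed = 1, n_cells = 500, n_genes = 1000,
                        cluster_proportions = rep(0.25, 4),
                        n_signature = 20, signature_fold = 8,
                        mito_gene_fraction = 0.02,
                        mito_count_fraction = 0.05,
                        libsize_meanlog = log(2000),
                        libsize_sdlog = 0.3) {
  stopifnot(abs(sum(cluster_proportions) - 1) < 1e-12,
            all(cluster_proportions > 0),
            mito_count_fraction >= 0, mito_count_fraction < 1,
            mito_gene_fraction >= 0, mito_gene_fraction < 1)
  k <- length(cluster_proportions)
  n_mito <- round(mito_gene_fraction * n_genes)
  if (k * n_signature + n_mito > n_genes)
    stopf("not enough genes for %d disjoint signatures of %d plus %d mito genes",
          k, n_signature, n_mito)
  structure(list(seed = seed, n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 cluster_proportions = cluster_proportions,
                 n_signature = as.integer(n_signature),
                 signature_fold = signature_fold,
                 mito_gene_fraction = mito_gene_fraction,
                 mito_count_fraction = mito_count_fraction,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog),
            class = "ScSimConfig")
}

#' Simulate clustered single-cell counts
#'
#' @param config an [scSimConfig()] bundle.
#' @return List with \code{counts} (gene x cell integer matrix),
#'   \code{labels} (cluster factor per cell), \code{signatures} (list of
#'   [GeneSet-class], one per cluster) and \code{mito_genes}.
#' @export
simulateScCounts <- function(config) {
  stopifnot(inherits(config, "ScSimConfig"))
  withSeed(config$seed, {
    k <- length(config$cluster_proportions)
    g <- config$n_genes
    n_mito <- round(config$mito_gene_fraction * g)
    genes <- sprintf("gene%04d", seq_len(g))
    if (n_mito > 0)
      genes[seq_len(n_mito)] <- sprintf("MT-gene%04d", seq_len(n_mito))
    mito <- seq_len(n_mito)
    nonmito <- setdiff(seq_len(g), mito)
    sigs <- split(nonmito[seq_len(k * config$n_signature)],
                  rep(seq_len(k), each = config$n_signature))
    base <- rgamma(g, shape = 0.7, rate = 1) + 1e-3
    probs <- matrix(NA_real_, g, k)
    for (cl in seq_len(k)) {
      w <- base
      w[sigs[[cl]]] <- w[sigs[[cl]]] * config$signature_fold
      mcf <- config$mito_count_fraction
      if (n_mito > 0) {
        w[mito] <- if (mcf > 0)
          base[mito] / sum(base[mito]) * mcf / (1 - mcf) * sum(w[nonmito])
        else 0
      }
      probs[, cl] <- w / sum(w)
    }
    cl_of <- sample.int(k, config$n_cells, replace = TRUE,
                        prob = config$cluster_proportions)
    libsize <- pmax(1L, round(stats::rlnorm(config$n_cells,
                                            config$libsize_meanlog,
                                            config$libsize_sdlog)))
    counts <- matrix(0L, g, config$n_cells,
                     dimnames = list(genes,
                                     sprintf("cell%04d",
                                             seq_len(config$n_cells))))
    for (i in seq_len(config$n_cells))
      counts[, i] <- rmultinom(1L, libsize[i], probs[, cl_of[i]])
    signatures <- lapply(seq_len(k), function(cl)
      GeneSet(sprintf("cluster%d_signature", cl),
              "planted cluster signature", genes[sigs[[cl]]]))
    names(signatures) <- vapply(signatures, geneSetName, character(1))
    list(counts = counts,
         labels = factor(sprintf("cluster%d", cl_of),
                         levels = sprintf("cluster%d", seq_len(k))),
         signatures = signatures,
         mito_genes = genes[mito])
  })
}
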