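# IgH repertoire statistics from AIRR rearrangement tables: locus status,
# junction productivity, DJ fraction, nonproductive ratio, N-insertion
# profile, clone frequencies/tracking, clonality and an oligoclonality
# comparison.

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locus status of rearrangement records
#'
#' A rearranged IgH locus is \code{DJ} when no V segment was called but a
#' D segment was (an incomplete DJ-only rearrangement, the hallmark of an
#' early B-cell precursor), and \code{VDJ} whenever a V segment is
#' present. Records with neither V nor D call are \code{unresolved} and
#' excluded from fraction denominators, with a logged count.
#'
#' @param repertoire data.frame of AIRR records ([readAIRR()]).
#' @return Factor with levels \code{VDJ, DJ, unresolved}, one per record.
#' @export
classifyLocusStatus <- function(repertoire) {
  if (any(isAbsent(repertoire$j_call)))
    stopf("records without a J call are not rearranged IgH loci")
  hasV <- !isAbsent(repertoire$v_call)
  hasD <- !isAbsent(repertoire$d_call)
  status <- ifelse(hasV, "VDJ", ifelse(hasD, "DJ", "unresolved"))
  n_unres <- sum(status == "unresolved")
  if (n_unres > 0)
    message(sprintf("%d record(s) with neither V nor D call: unresolved, excluded from totals",
                    n_unres))
  factor(status, levels = c("VDJ", "DJ", "unresolved"))
}

#' Junction frame and productivity calls
#'
#' The junction (conserved-Cys codon through the J anchor codon) is in
#' frame iff its length is a multiple of 3; a stop codon is any in-frame
#' TAA/TAG/TGA within the junction. A rearrangement is productive iff it
#' is a complete VDJ, in frame, and stop-free; DJ-only rearrangements are
#' always nonproductive. This junction-only call approximates the full
#' AIRR \code{productive} flag, which would additionally scan the V
#' region.
#'
#' @param repertoire data.frame of AIRR records with a \code{junction}
#'   column over the alphabet ACGTN.
#' @return The repertoire with (re)computed \code{frame_status}
#'   (\code{"in"}/\code{"out"}), \code{has_stop} and \code{productive}
#'   columns.
#' @examples
#' rep <- data.frame(sequence_id = "r1", v_call = "IGHV3-15",
#'                   d_call = "IGHD2-2", j_call = "IGHJ4",
#'                   junction = "TGTGCGAGATGG", productive = NA,
#'                   duplicate_count = 1L)
#' callFrameProductivity(rep)$productive  # in-frame, no stop -> TRUE
#' @export
callFrameProductivity <- function(repertoire) {
  jn <- toupper(repertoire$junction)
  if (any(isAbsent(jn)))
    stopf("every record needs a junction sequence")
  if (any(grepl("[^ACGTN]", jn)))
    stopf("junction contains characters outside ACGTN")
  frame_in <- nchar(jn) %% 3L == 0L
  has_stop <- vapply(jn, function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return(FALSE)
    codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    any(codons %in% .STOP_CODONS)
  }, logical(1), USE.NAMES = FALSE)
  status <- classifyLocusStatus(repertoire)
  repertoire$frame_status <- ifelse(frame_in, "in", "out")
  repertoire$has_stop <- has_stop
  repertoire$productive <- frame_in & !has_stop & status == "VDJ"
  repertoire
}

# Shared weighted-fraction helper over resolvable records.
.weightedFraction <- function(flag, status, counts, weighting) {
  keep <- status != "unresolved"
  if (!any(keep)) stopf("no resolvable records in repertoire")
  w <- if (weighting == "templates") counts[keep] else rep(1, sum(keep))
  sum(w[flag[keep]]) / sum(w)
}

#' Fraction of DJ-only rearranged IgH loci
#'
#' \code{(#DJ) / (#DJ + #VDJ)} over resolvable records, weighted either
#' per unique rearrangement record or per template
#' (\code{duplicate_count}). Template weighting is the default because
#' immunosequencing abundances are template-scale; both modes are exposed
#' because figure-level reporting conventions differ.
#'
#' @param repertoire data.frame of AIRR records.
#' @param weighting \code{"templates"} or \code{"records"}.
#' @return Fraction in [0, 1].
#' @export
djFraction <- function(repertoire, weighting = c("templates", "records")) {
  weighting <- match.arg(weighting)
  if (nrow(repertoire) == 0L) stopf("empty repertoire")
  status <- classifyLocusStatus(repertoire)
  .weightedFraction(status == "DJ", status, repertoire$duplicate_count,
                    weighting)
}

#' Ratio of nonproductive to total rearrangements
#'
#' Uses stored \code{productive} calls when present (unknowns excluded
#' with a logged count), otherwise computes them from the junction via
#' [callFrameProductivity()].
#'
#' @inheritParams djFraction
#' @return Fraction in [0, 1].
#' @export
nonproductiveFraction <- function(repertoire,
                                  weighting = c("templates", "records")) {
  weighting <- match.arg(weighting)
  if (nrow(repertoire) == 0L) stopf("empty repertoire")
  if (is.null(repertoire$productive) || all(is.na(repertoire$productive)))
    repertoire <- callFrameProductivity(repertoire)
  known <- !is.na(repertoire$productive)
  if (!any(known)) stopf("no records with known productivity")
  if (any(!known))
    message(sprintf("%d record(s) with unknown productivity excluded",
                    sum(!known)))
  rep2 <- repertoire[known, , drop = FALSE]
  status <- classifyLocusStatus(rep2)
  .weightedFraction(!rep2$productive, status, rep2$duplicate_count,
                    weighting)
}

#' N-insertion length summary
#'
#' Summarizes total non-templated (N) nucleotide insertion length per
#' record, \code{np1_length + np2_length} (the V-D and D-J junction
#' insertions; DJ-only records have a single junction and contribute
#' \code{np1_length}). Expanded N-insertion lengths reflect elevated TdT
#' activity. Records with unknown insertion lengths are excluded with a
#' logged count.
#'
#' @param repertoire data.frame of AIRR records with
#'   \code{np1_length}/\code{np2_length} columns.
#' @param weighting \code{"records"} (default: per unique rearrangement)
#'   or \code{"templates"}.
#' @return List with \code{n}, \code{mean}, \code{quantiles} (0, 25, 50,
#'   75, 100\%), and \code{histogram} (named counts over total lengths 0,
#'   1, 2, ...).
#' @export
nInsertionSummary <- function(repertoire,
                              weighting = c("records", "templates")) {
  weighting <- match.arg(weighting)
  if (is.null(repertoire$np1_length))
    stopf("repertoire has no N-insertion length columns")
  np1 <- repertoire$np1_length
  np2 <- if (!is.null(repertoire$np2_length)) repertoire$np2_length
         else rep(0L, nrow(repertoire))
  total <- np1 + ifelse(is.na(np2) & !is.na(np1), 0L, np2)
  known <- !is.na(total)
  if (!any(known)) stopf("no records with known insertion lengths")
  if (any(!known))
    message(sprintf("%d record(s) with unknown insertion lengths excluded",
                    sum(!known)))
  total <- total[known]
  w <- if (weighting == "templates") repertoire$duplicate_count[known]
       else rep(1L, length(total))
  hist <- tapply(w, factor(total, levels = 0:max(total)), sum,
                 default = 0L)
  list(n = sum(w),
       mean = sum(w * total) / sum(w),
       quantiles = quantile(rep(total, times = w),
                            probs = c(0, .25, .5, .75, 1), names = TRUE),
       histogram = hist)
}

#' Template-weighted clone frequency table
#'
#' Clones are identified by exact \code{(v_call, j_call, junction)} match
#' (V-J rearrangement granularity); frequencies are template-weighted and
#' sum to 1.
#'
#' @param repertoire data.frame of AIRR records.
#' @return data.frame with \code{clone_id, v_call, j_call, junction,
#'   templates, frequency, percent}, sorted by decreasing frequency.
#' @export
cloneFrequencies <- function(repertoire) {
  if (nrow(repertoire) == 0L) stopf("empty repertoire")
  key <- paste(ifelse(isAbsent(repertoire$v_call), "", repertoire$v_call),
               repertoire$j_call, repertoire$junction, sep = "|")
  agg <- tapply(repertoire$duplicate_count, key, sum)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  out <- data.frame(
    clone_id = names(agg),
    v_call = vapply(parts, function(p) if (nzchar(p[1])) p[1]
                    else NA_character_, character(1)),
    j_call = vapply(parts, `[`, character(1), 2L),
    junction = vapply(parts, `[`, character(1), 3L),
    templates = as.integer(agg),
    stringsAsFactors = FALSE)
  out$frequency <- out$templates / sum(out$templates)
  out$percent <- 100 * out$frequency
  out <- out[order(-out$frequency, out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Track a clone's frequency across samples
#'
#' Reports the template-weighted frequency of one clone (identified by V
#' call, J call and junction sequence) in each of an ordered collection of
#' repertoires, 0 when absent — e.g. following a leukemic clone back into
#' the preleukemic compartment of the primary transplant.
#'
#' @param repertoires named list of AIRR data.frames, in sample order.
#' @param v_call,j_call,junction the clone key; \code{v_call = NA} tracks
#'   a DJ-only clone.
#' @return data.frame with \code{sample, templates, total_templates,
#'   frequency, percent}.
#' @export
trackClone <- function(repertoires, v_call, j_call, junction) {
  if (is.null(names(repertoires)))
    names(repertoires) <- paste0("sample", seq_along(repertoires))
  key <- paste(if (is.na(v_call)) "" else v_call, j_call, junction,
               sep = "|")
  rows <- lapply(names(repertoires), function(nm) {
    cf <- cloneFrequencies(repertoires[[nm]])
    hit <- cf[cf$clone_id == key, , drop = FALSE]
    data.frame(sample = nm,
               templates = if (nrow(hit)) hit$templates else 0L,
               total_templates = sum(cf$templates),
               frequency = if (nrow(hit)) hit$frequency else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percent <- 100 * out$frequency
  out
}

#' Normalized clonality index
#'
#' \eqn{1 - H/\ln K} where H is the Shannon entropy of template-weighted
#' clone frequencies and K the number of distinct clones: 0 for a
#' perfectly even (polyclonal) repertoire, 1 for a monoclonal one. A
#' single-clone repertoire is defined as 1 by continuity, with a warning.
#'
#' @param repertoire data.frame of AIRR records.
#' @return Clonality in [0, 1].
#' @export
clonalityIndex <- function(repertoire) {
  cf <- cloneFrequencies(repertoire)
  if (nrow(cf) < 2L) {
    warnf("single-clone repertoire: clonality defined as 1 by continuity")
    return(1)
  }
  p <- cf$frequency[cf$frequency > 0]
  H <- -sum(p * log(p))
  1 - H / log(nrow(cf))
}

#' Compare oligoclonality of two repertoires
#'
#' A subsampling/relabeling construction (not a reconstruction of any
#' vendor pipeline's test): both repertoires are repeatedly subsampled
#' without replacement to the common template depth and the clonality
#' difference is averaged; the null distribution is generated by
#' exchanging template labels between the pooled repertoires at the same
#' depths. The two-sided p-value is
#' \eqn{(1 + \#\{|\Delta^*| \ge |\Delta|\})/(1 + B)}.
#'
#' @param rep_a,rep_b AIRR data.frames.
#' @param n_boot number of subsample/relabel iterations (default 1000;
#'   fewer than 100 draws a warning).
#' @param seed RNG seed.
#' @return List with \code{delta} (clonality a minus b at equal depth),
#'   \code{ci} (2.5/97.5\% subsampling interval), \code{p_value},
#'   \code{depth}, and \code{n_boot}.
#' @export
compareOligoclonality <- function(rep_a, rep_b, n_boot = 1000, seed = 1) {
  if (nrow(rep_a) == 0L || nrow(rep_b) == 0L)
    stopf("both repertoires must be non-empty")
  if (n_boot < 100) warnf("n_boot < 100: p-value resolution is poor")
  ca <- cloneFrequencies(rep_a)
  cb <- cloneFrequencies(rep_b)
  depth <- min(sum(ca$templates), sum(cb$templates))
  if (depth < 100)
    stopf("common template depth %d < 100: too shallow to compare", depth)
  # expand to per-template clone labels for subsampling
  ta <- rep(ca$clone_id, times = ca$templates)
  tb <- rep(cb$clone_id, times = cb$templates)
  clonFromLabels <- function(lab) {
    p <- tabulate(factor(lab)) / length(lab)
    p <- p[p > 0]
    if (length(p) < 2L) return(1)
    1 - (-sum(p * log(p))) / log(length(p))
  }
  withSeed(seed, {
    deltas <- replicate(n_boot,
      clonFromLabels(sample(ta, depth)) - clonFromLabels(sample(tb, depth)))
    delta <- mean(deltas)
    pooled <- c(ta, tb)
    null <- replicate(n_boot, {
      idx <- sample.int(length(pooled), 2L * depth)
      clonFromLabels(pooled[idx[seq_len(depth)]]) -
        clonFromLabels(pooled[idx[depth + seq_len(depth)]])
    })
    p <- (1 + sum(abs(null) >= abs(delta))) / (1 + n_boot)
  })
  list(delta = delta,
       ci = quantile(deltas, c(.025, .975), names = FALSE),
       p_value = p, depth = depth, n_boot = n_boot)
}

#' Repertoire summary statistics
#'
#' One-call surface over the repertoire statistics: record and template
#' counts, DJ fraction, nonproductive fraction, mean total N-insertion
#' length, clonality and top clone frequency.
#'
#' @inheritParams djFraction
#' @return A one-row data.frame.
#' @export
repertoireSummary <- function(repertoire,
                              weighting = c("templates", "records")) {
  weighting <- match.arg(weighting)
  cf <- cloneFrequencies(repertoire)
  ins <- if (!is.null(repertoire$np1_length))
    nInsertionSummary(repertoire)$mean else NA_real_
  data.frame(
    n_records = nrow(repertoire),
    n_templates = sum(repertoire$duplicate_count),
    dj_fraction = djFraction(repertoire, weighting),
    nonproductive_fraction = nonproductiveFraction(repertoire, weighting),
    mean_total_n_insertions = ins,
    clonality = if (nrow(cf) >= 2L) clonalityIndex(repertoire) else 1,
    top_clone_frequency = cf$frequency[1])
}
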