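# Readers/writers for the standard formats the pipeline touches, plus the
# lentiviral titer calculation.

.AIRR_REQUIRED <- c("sequence_id", "v_call", "d_call", "j_call",
                    "junction", "productive", "duplicate_count")

# Adaptive immunosequencing exports use different column names for some
# AIRR fields; mapped on read.
.AIRR_ALIASES <- c(templates = "duplicate_count",
                   seq_count = "duplicate_count",
                   nucleotide = "junction",
                   cdr3_rearrangement = "junction")

#' Read gene sets from a GMT file
#'
#' Each GMT line is \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' Duplicate symbols within a line are dropped with a warning. Gene symbols
#' are kept verbatim (case-sensitive).
#'
#' @param path path to a GMT file.
#' @return A named list of [GeneSet-class] objects (possibly empty).
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("PH_UP\tdesc\tCRLF2\tIL7R", tf)
#' readGMT(tf)
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stopf("GMT parse error at line %d: %d field(s), need >= 3",
            i, length(fields))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[i]] <- GeneSet(fields[[1]], fields[[2]], genes)
  }
  names(sets) <- vapply(sets, geneSetName, character(1))
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of [GeneSet-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(geneSetName(s), s@description, geneIds(s)), collapse = "\t"),
    character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an AIRR rearrangement table
#'
#' Reads a tab-separated rearrangement file using the AIRR Community schema
#' field names. The mandatory columns are \code{sequence_id, v_call,
#' d_call, j_call, junction, productive, duplicate_count}; Adaptive-export
#' aliases (e.g. \code{templates}) are mapped automatically. Missing
#' segment calls (empty or NA) mark DJ-only candidates; \code{productive}
#' is parsed as tri-state logical (\code{TRUE}/\code{FALSE}/\code{NA}).
#'
#' @param path path to a rearrangement TSV.
#' @return A data.frame with one row per rearrangement record. Optional
#'   integer columns \code{np1_length}/\code{np2_length} (N-insertion
#'   lengths at the V-D and D-J junctions) are carried through when
#'   present.
#' @seealso [writeAIRR()], [classifyLocusStatus()]
#' @export
readAIRR <- function(path) {
  if (!file.exists(path)) stopf("AIRR file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = character(),
                   check.names = FALSE, fileEncoding = "UTF-8")
  hit <- names(df) %in% names(.AIRR_ALIASES)
  names(df)[hit] <- .AIRR_ALIASES[names(df)[hit]]
  missing <- setdiff(.AIRR_REQUIRED, names(df))
  if (length(missing))
    stopf("AIRR schema error: missing column(s) %s",
          paste(missing, collapse = ", "))
  df$v_call[isAbsent(df$v_call)] <- NA_character_
  df$d_call[isAbsent(df$d_call)] <- NA_character_
  df$j_call[isAbsent(df$j_call)] <- NA_character_
  prod <- trimws(df$productive)
  df$productive <- ifelse(prod %in% c("T", "TRUE", "true"), TRUE,
                   ifelse(prod %in% c("F", "FALSE", "false"), FALSE, NA))
  df$duplicate_count <- as.integer(df$duplicate_count)
  for (col in c("np1_length", "np2_length"))
    if (col %in% names(df)) {
      df[[col]][isAbsent(df[[col]])] <- NA_character_
      df[[col]] <- as.integer(df[[col]])
    }
  df
}

#' Write an AIRR rearrangement table
#'
#' Inverse of [readAIRR()]: logical \code{productive} is encoded
#' \code{T}/\code{F}/empty, absent calls as empty strings.
#'
#' @param repertoire data.frame of rearrangement records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAIRR <- function(repertoire, path) {
  out <- repertoire
  if (is.logical(out$productive))
    out$productive <- ifelse(is.na(out$productive), "",
                             ifelse(out$productive, "T", "F"))
  for (col in names(out))
    if (!is.character(out[[col]])) {
      v <- as.character(out[[col]])
      v[is.na(v)] <- ""
      out[[col]] <- v
    } else out[[col]][is.na(out[[col]])] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene x sample count matrix
#'
#' Supports dense CSV/TSV (first column = gene ids, header = sample ids)
#' and MatrixMarket triplet files; for \code{format = "mtx"} the row and
#' column names are read from sidecar files (default
#' \code{<path>.rownames} / \code{<path>.colnames}, one id per line).
#' Entries must be non-negative integers; violations are reported with
#' their gene/sample coordinates.
#'
#' @param path path to the matrix file.
#' @param format one of \code{"csv"}, \code{"tsv"}, \code{"mtx"}.
#' @param rownames_path,colnames_path sidecar id files for MTX input.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
readCounts <- function(path, format = c("csv", "tsv", "mtx"),
                       rownames_path = paste0(path, ".rownames"),
                       colnames_path = paste0(path, ".colnames")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("counts file not found: %s", path)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rownames_path, warn = FALSE)
    cn <- readLines(colnames_path, warn = FALSE)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stopf("MTX sidecar id files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                     check.names = FALSE, fileEncoding = "UTF-8")
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stopf("counts validation error: non-integer or negative entry at gene '%s', sample '%s' (value %s)",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
          format(m[bad[1, , drop = FALSE]]))
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix as delimited text
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(counts, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Lentiviral titer from a transduction assay
#'
#' Computes infectious units per ml as
#' \deqn{titer = f \times N_{cells} / V_{\mu l} \times 1000}
#' where \eqn{f} is the transduced fraction measured by flow cytometry,
#' \eqn{N_{cells}} the number of cells at the day of transduction, and
#' \eqn{V} the virus volume per well in microliters. The transduced
#' fraction is taken on the [0, 1] scale by default; set
#' \code{percent = TRUE} to pass percentage values (10 for 10\%).
#'
#' @param transduced_fraction fraction of transduced cells in [0, 1]
#'   (or percent, see \code{percent}).
#' @param cells_at_transduction cell count at the day of transduction.
#' @param virus_volume_ul virus volume per well, microliters, > 0.
#' @param percent logical; interpret \code{transduced_fraction} as percent.
#' @return Titer in infectious units per ml.
#' @examples
#' virusTiter(0.10, 5e4, 100)  # 50,000 IU/ml
#' @export
virusTiter <- function(transduced_fraction, cells_at_transduction,
                       virus_volume_ul, percent = FALSE) {
  f <- if (percent) transduced_fraction / 100 else transduced_fraction
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stopf("transduced fraction must lie in [0, 1] (got %s on the fraction scale)",
          paste(format(f), collapse = ", "))
  if (any(!is.finite(virus_volume_ul)) || any(virus_volume_ul <= 0))
    stopf("virus volume must be positive")
  if (any(cells_at_transduction < 0))
    stopf("cell count must be non-negative")
  f * cells_at_transduction / virus_volume_ul * 1000
}

#' Serialize a ReferencePanel to JSON
#' @param panel a [ReferencePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReferencePanel <- function(panel, path) {
  obj <- list(
    markers = markerNames(panel),
    cofactor = arsinhCofactor(panel),
    stages = lapply(seq_along(panel@labels), function(i) list(
      label = panel@labels[i],
      mean = unname(panel@means[i, ]),
      covariance = unname(panel@covariances[[i]]),
      n_cells = panel@nCells[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ReferencePanel from JSON
#' @param path path written by [writeReferencePanel()].
#' @return A [ReferencePanel-class].
#' @export
readReferencePanel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mp <- MarkerPanel(obj$markers, obj$cofactor)
  k <- nrow(obj$stages)
  means <- do.call(rbind, obj$stages$mean)
  covs <- lapply(obj$stages$covariance, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(obj$markers, obj$markers)
    m
  })
  colnames(means) <- obj$markers
  new("ReferencePanel", panel = mp, labels = obj$stages$label,
      means = means, covariances = covs,
      nCells = as.integer(obj$stages$n_cells))
}
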