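#' @import methods
#' @importFrom stats median mad qt rnorm rpois rgeom rnbinom rgamma runif
#'   setNames var quantile mahalanobis cov rbinom
#' @importFrom utils read.delim read.csv write.table head
NULL

#' GeneSet: a named, ordered collection of unique gene symbols
#'
#' Lightweight container for one gene set as found in a GMT file, e.g. the
#' 15-gene clinical Ph-like diagnostic panel or an up/down signature from a
#' differential-expression contrast.
#'
#' @slot name single identifier string.
#' @slot description free-text description (may be empty).
#' @slot genes character vector of unique gene symbols, at least one.
#'
#' @examples
#' gs <- GeneSet("PH_UP", "Ph-like up signature", c("CRLF2", "IL7R", "PON2"))
#' geneSetName(gs)
#' geneIds(gs)
#' @export
setClass("GeneSet",
  representation(name = "character", description = "character",
                 genes = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "'name' must be a single non-empty string")
    if (length(object@genes) == 0L)
      msg <- c(msg, "'genes' must be non-empty")
    if (anyDuplicated(object@genes))
      msg <- c(msg, "'genes' must not contain duplicate symbols")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a GeneSet
#'
#' Duplicate symbols are removed (first occurrence kept) with a warning,
#' mirroring GMT-reading behaviour.
#'
#' @param name set identifier.
#' @param description free text; defaults to "".
#' @param genes character vector of gene symbols.
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(name, description = "", genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': %d duplicate symbol(s) removed",
                    name, sum(duplicated(genes))))
    genes <- genes[!duplicated(genes)]
  }
  new("GeneSet", name = as.character(name),
      description = as.character(description), genes = genes)
}

#' @describeIn GeneSet set identifier accessor
#' @param x,object a \code{GeneSet}.
#' @export
geneSetName <- function(x) x@name

#' @describeIn GeneSet gene symbol accessor
#' @export
geneIds <- function(x) x@genes

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d genes)\n", object@name, length(object@genes)))
  shown <- head(object@genes, 6L)
  cat("  ", paste(shown, collapse = ", "),
      if (length(object@genes) > 6L) ", ..." else "", "\n", sep = "")
})

#' @export
setMethod("length", "GeneSet", function(x) length(x@genes))

#' MarkerPanel: ordered cytometry markers plus arsinh cofactor
#'
#' The default panel is the ten-marker B-lymphopoiesis panel used by the
#' developmental classifier (CD45, CD20, CD24, CD34, CD38, IgMi, TdT, CD19,
#' IgMs, CD10). The arsinh cofactor (default 5, the mass-cytometry
#' convention) sets the linear-to-log transition scale of the transform.
#'
#' @slot markers ordered unique marker names.
#' @slot cofactor positive arsinh cofactor.
#' @export
setClass("MarkerPanel",
  representation(markers = "character", cofactor = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@markers) == 0L || anyDuplicated(object@markers))
      msg <- c(msg, "'markers' must be non-empty and unique")
    if (length(object@cofactor) != 1L || !is.finite(object@cofactor) ||
        object@cofactor <= 0)
      msg <- c(msg, "'cofactor' must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Default B-lymphopoiesis marker names
#' @return Character vector of the ten classifier markers.
#' @export
bLineageMarkers <- function() {
  c("CD45", "CD20", "CD24", "CD34", "CD38",
    "IgMi", "TdT", "CD19", "IgMs", "CD10")
}

#' Construct a MarkerPanel
#' @param markers ordered unique marker names.
#' @param cofactor positive arsinh cofactor (default 5).
#' @return A [MarkerPanel-class] object.
#' @export
MarkerPanel <- function(markers = bLineageMarkers(), cofactor = 5) {
  new("MarkerPanel", markers = as.character(markers),
      cofactor = as.numeric(cofactor))
}

#' @describeIn MarkerPanel marker name accessor
#' @param x a \code{MarkerPanel} (or \code{ReferencePanel}).
#' @export
markerNames <- function(x) {
  if (is(x, "ReferencePanel")) x@panel@markers else x@markers
}

#' @describeIn MarkerPanel arsinh cofactor accessor
#' @export
arsinhCofactor <- function(x) {
  if (is(x, "ReferencePanel")) x@panel@cofactor else x@cofactor
}

setMethod("show", "MarkerPanel", function(object) {
  cat(sprintf("MarkerPanel: %d markers, arsinh cofactor %g\n",
              length(object@markers), object@cofactor))
  cat("  ", paste(object@markers, collapse = ", "), "\n", sep = "")
})

#' ReferencePanel: stage-structured healthy-marrow classifier reference
#'
#' Holds, for each of an ordered series of developmental stages of B
#' lymphopoiesis (11 by default), the mean arsinh-transformed expression
#' vector and the marker covariance estimated from manually gated healthy
#' bone marrow. Events are assigned to the stage of shortest Mahalanobis
#' distance.
#'
#' @slot panel a [MarkerPanel-class].
#' @slot labels ordered unique stage labels (developmental order).
#' @slot means stage x marker matrix of arsinh-scale means.
#' @slot covariances list of per-stage symmetric positive-definite
#'   marker covariance matrices.
#' @slot nCells integer events used to estimate each stage.
#' @export
setClass("ReferencePanel",
  representation(panel = "MarkerPanel", labels = "character",
                 means = "matrix", covariances = "list",
                 nCells = "integer"),
  validity = function(object) {
    msg <- NULL
    p <- length(object@panel@markers)
    k <- length(object@labels)
    if (anyDuplicated(object@labels))
      msg <- c(msg, "stage labels must be unique")
    if (!identical(dim(object@means), c(k, p)))
      msg <- c(msg, "'means' must be stages x markers")
    if (length(object@covariances) != k || length(object@nCells) != k)
      msg <- c(msg, "one covariance and one cell count per stage")
    for (i in seq_along(object@covariances)) {
      S <- object@covariances[[i]]
      if (!is.matrix(S) || !identical(dim(S), c(p, p))) {
        msg <- c(msg, sprintf("covariance %d has wrong dimension", i))
        next
      }
      if (max(abs(S - t(S))) > 1e-10)
        msg <- c(msg, sprintf("covariance %d is not symmetric", i))
      ev <- tryCatch(min(eigen(S, symmetric = TRUE,
                               only.values = TRUE)$values),
                     error = function(e) -Inf)
      if (!is.finite(ev) || ev <= 0)
        msg <- c(msg, sprintf("covariance %d is not positive-definite", i))
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn ReferencePanel ordered stage labels
#' @param x,object a \code{ReferencePanel}.
#' @export
stageLabels <- function(x) x@labels

#' @describeIn ReferencePanel stage x marker matrix of arsinh-scale means
#' @export
stageMeans <- function(x) x@means

#' @describeIn ReferencePanel list of per-stage covariance matrices
#' @export
stageCovariances <- function(x) x@covariances

setMethod("show", "ReferencePanel", function(object) {
  cat(sprintf(
    "ReferencePanel: %d stages x %d markers (arsinh cofactor %g)\n",
    length(object@labels), length(object@panel@markers),
    object@panel@cofactor))
  cat("  stages: ", paste(object@labels, collapse = " > "), "\n", sep = "")
  cat("  events per stage: ", paste(object@nCells, collapse = ", "),
      "\n", sep = "")
})

#' StageAssignment: per-event classifier output
#'
#' @slot labels factor of assigned stage labels, levels in developmental
#'   order.
#' @slot distances event x stage matrix of Mahalanobis distances.
#' @slot groups optional per-event sample/group labels (may be length 0).
#' @export
setClass("StageAssignment",
  representation(labels = "factor", distances = "matrix",
                 groups = "character"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@labels)
    if (nrow(object@distances) != n)
      msg <- c(msg, "one distance row per event")
    if (!identical(levels(object@labels), colnames(object@distances)))
      msg <- c(msg, "factor levels must equal distance column names")
    if (any(object@distances < 0))
      msg <- c(msg, "distances must be non-negative")
    if (length(object@groups) && length(object@groups) != n)
      msg <- c(msg, "'groups' must be empty or one per event")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn StageAssignment assigned stage labels (factor in
#'   developmental order)
#' @param x,object a \code{StageAssignment}.
#' @export
assignedStages <- function(x) x@labels

#' @describeIn StageAssignment event x stage Mahalanobis distance matrix
#' @export
stageDistances <- function(x) x@distances

setMethod("show", "StageAssignment", function(object) {
  cat(sprintf("StageAssignment: %d events over %d stages\n",
              length(object@labels), ncol(object@distances)))
  print(table(object@labels))
})

#' @export
setMethod("length", "StageAssignment", function(x) length(x@labels))

#' PairedCountsDesign: gene x sample counts with case/control pairing
#'
#' Couples an integer count matrix with an explicit pairing of case and
#' control columns (e.g. receptor-transduced versus backbone-control
#' libraries from the same cord-blood batch). The pairing drives the
#' paired fold-change/t differential-expression statistic.
#'
#' @slot counts gene x sample matrix of non-negative integers with
#'   rownames (genes) and colnames (samples).
#' @slot pairs data.frame with columns \code{case} and \code{control};
#'   every id must exist among the count columns and no sample may be
#'   reused.
#' @export
setClass("PairedCountsDesign",
  representation(counts = "matrix", pairs = "data.frame"),
  validity = function(object) {
    msg <- NULL
    cts <- object@counts
    if (is.null(rownames(cts)) || is.null(colnames(cts)))
      msg <- c(msg, "'counts' needs gene rownames and sample colnames")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "'counts' must be non-negative integers")
    if (!all(c("case", "control") %in% names(object@pairs)))
      msg <- c(msg, "'pairs' needs 'case' and 'control' columns")
    else {
      ids <- c(object@pairs$case, object@pairs$control)
      if (!all(ids %in% colnames(cts)))
        msg <- c(msg, "pair ids missing from count columns")
      if (anyDuplicated(ids))
        msg <- c(msg, "a sample may appear in at most one pair role")
      if (any(object@pairs$case == object@pairs$control))
        msg <- c(msg, "case and control of a pair must differ")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Construct a PairedCountsDesign
#' @param counts gene x sample integer matrix with dimnames.
#' @param pairs data.frame with \code{case} and \code{control} sample ids.
#' @return A [PairedCountsDesign-class] object.
#' @export
PairedCountsDesign <- function(counts, pairs) {
  pairs <- data.frame(case = as.character(pairs$case),
                      control = as.character(pairs$control),
                      stringsAsFactors = FALSE)
  new("PairedCountsDesign", counts = as.matrix(counts), pairs = pairs)
}

#' @describeIn PairedCountsDesign count matrix accessor
#' @param x,object a \code{PairedCountsDesign}.
#' @export
designCounts <- function(x) x@counts

#' @describeIn PairedCountsDesign pairing table accessor
#' @export
designPairs <- function(x) x@pairs

#' @describeIn PairedCountsDesign number of case/control pairs
#' @export
nPairs <- function(x) nrow(x@pairs)

setMethod("show", "PairedCountsDesign", function(object) {
  cat(sprintf("PairedCountsDesign: %d genes x %d samples, %d pairs\n",
              nrow(object@counts), ncol(object@counts),
              nrow(object@pairs)))
})
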