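# Single-cell B-lymphopoiesis developmental classifier for mass cytometry:
# reference construction from gated healthy marrow and
# shortest-Mahalanobis-distance stage assignment.

#' Arsinh transform of cytometry intensities
#'
#' \code{asinh(x / cofactor)}: approximately linear near zero and
#' logarithmic for large intensities, the standard variance-stabilizing
#' transform for mass cytometry.
#'
#' @param x raw intensities (vector or matrix); must be finite.
#' @param cofactor positive scale (default 5, the mass-cytometry
#'   convention).
#' @return Transformed values, same shape as \code{x}.
#' @examples
#' arsinhTransform(5, cofactor = 5)  # asinh(1) = log(1 + sqrt(2))
#' @export
arsinhTransform <- function(x, cofactor = 5) {
  if (length(cofactor) != 1L || !is.finite(cofactor) || cofactor <= 0)
    stopf("cofactor must be a single positive number")
  if (any(!is.finite(x)))
    stopf("non-finite intensity values")
  asinh(x / cofactor)
}

#' Build a developmental reference panel from gated healthy marrow
#'
#' For each manually gated developmental stage, intensities are
#' arsinh-transformed, marker means and sample covariance are estimated,
#' and the covariance is shrunk toward its diagonal:
#' \eqn{\Sigma \leftarrow (1-s)\Sigma + s\,diag(\Sigma)}. Shrinkage keeps
#' the Mahalanobis metric defined when gated stages are small or
#' near-collinear.
#'
#' @param gated named list mapping stage label to an event x marker matrix
#'   of raw intensities (list order = developmental order).
#' @param panel a [MarkerPanel-class]; matrices must contain its markers
#'   by name (extra columns ignored, order free).
#' @param shrinkage diagonal shrinkage weight in [0, 1] (default 0.05).
#' @return A [ReferencePanel-class].
#' @export
buildReference <- function(gated, panel = MarkerPanel(), shrinkage = 0.05) {
  if (shrinkage < 0 || shrinkage > 1)
    stopf("shrinkage must lie in [0, 1]")
  markers <- markerNames(panel)
  p <- length(markers)
  labels <- names(gated)
  if (is.null(labels) || anyDuplicated(labels))
    stopf("'gated' must be a named list with unique stage labels")
  means <- matrix(NA_real_, length(gated), p,
                  dimnames = list(labels, markers))
  covs <- vector("list", length(gated))
  ncells <- integer(length(gated))
  for (i in seq_along(gated)) {
    m <- as.matrix(gated[[i]])
    missing <- setdiff(markers, colnames(m))
    if (length(missing))
      stopf("stage '%s': missing marker(s) %s", labels[i],
            paste(missing, collapse = ", "))
    m <- m[, markers, drop = FALSE]
    if (nrow(m) < p + 2L)
      stopf("stage '%s': %d events, need at least %d to estimate a %dx%d covariance",
            labels[i], nrow(m), p + 2L, p, p)
    z <- arsinhTransform(m, arsinhCofactor(panel))
    means[i, ] <- colMeans(z)
    S <- cov(z)
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), p)
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-12)
      stopf("stage '%s': covariance singular after shrinkage %g; increase shrinkage",
            labels[i], shrinkage)
    dimnames(S) <- list(markers, markers)
    covs[[i]] <- S
    ncells[i] <- nrow(m)
  }
  new("ReferencePanel", panel = panel, labels = labels, means = means,
      covariances = covs, nCells = ncells)
}

#' Mahalanobis distance of an event to a reference stage
#'
#' \eqn{\sqrt{(x-\mu)^T \Sigma^{-1} (x-\mu)}} on the arsinh scale; zero
#' iff the event sits at the stage mean.
#'
#' @param x transformed marker vector, or an event x marker matrix.
#' @param mean stage mean vector.
#' @param covariance stage covariance matrix (positive-definite).
#' @return Non-negative distance(s).
#' @examples
#' mahalanobisDistance(c(2, 1), c(0, 0), diag(c(4, 1)))  # sqrt(2)
#' @export
mahalanobisDistance <- function(x, mean, covariance) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != length(mean) || !identical(dim(covariance),
                                            c(length(mean), length(mean))))
    stopf("dimension mismatch between event, mean and covariance")
  d2 <- mahalanobis(x, center = mean, cov = covariance)
  sqrt(pmax(d2, 0))
}

#' Assign events to developmental stages
#'
#' Raw intensities are arsinh-transformed with the reference panel's
#' cofactor, Mahalanobis distances to every stage are computed, and each
#' event is assigned to the stage of shortest distance (ties broken by the
#' earliest stage in developmental order).
#'
#' @param events event x marker matrix of raw intensities; must contain
#'   all panel markers by name (extra columns ignored).
#' @param reference a [ReferencePanel-class].
#' @param groups optional per-event sample/group labels for
#'   [stageComposition()].
#' @return A [StageAssignment-class] with the assigned labels and the full
#'   event x stage distance matrix.
#' @export
classifyEvents <- function(events, reference, groups = character()) {
  markers <- markerNames(reference)
  events <- as.matrix(events)
  missing <- setdiff(markers, colnames(events))
  if (length(missing))
    stopf("events are missing panel marker(s): %s",
          paste(missing, collapse = ", "))
  z <- arsinhTransform(events[, markers, drop = FALSE],
                       arsinhCofactor(reference))
  k <- length(reference@labels)
  D <- matrix(NA_real_, nrow(z), k,
              dimnames = list(rownames(events), reference@labels))
  for (j in seq_len(k))
    D[, j] <- mahalanobisDistance(z, reference@means[j, ],
                                  reference@covariances[[j]])
  # max.col on -D with ties.method "first" = earliest stage at equal distance
  idx <- max.col(-D, ties.method = "first")
  labels <- factor(reference@labels[idx], levels = reference@labels)
  new("StageAssignment", labels = labels, distances = D,
      groups = as.character(groups))
}

#' Per-group developmental stage composition
#'
#' Frequencies of assigned stages within each sample/group, rows in the
#' panel's developmental stage order. Each row sums to 1; a group with no
#' events yields a row of \code{NaN} with a warning rather than silent
#' zeros.
#'
#' @param assignment a [StageAssignment-class].
#' @param by per-event grouping vector; defaults to the groups stored in
#'   the assignment, or a single group \code{"all"}.
#' @return A group x stage matrix of frequencies.
#' @export
stageComposition <- function(assignment, by = NULL) {
  if (length(assignment) == 0L) stopf("empty assignment")
  if (is.null(by))
    by <- if (length(assignment@groups)) assignment@groups
          else rep("all", length(assignment))
  if (length(by) != length(assignment))
    stopf("'by' must have one entry per event")
  if (!is.factor(by)) by <- factor(by)
  tab <- table(by, assignment@labels)
  freq <- matrix(NA_real_, nlevels(by), nlevels(assignment@labels),
                 dimnames = list(levels(by), levels(assignment@labels)))
  totals <- rowSums(tab)
  empty <- totals == 0
  if (any(empty))
    warnf("group(s) with no events: %s",
          paste(levels(by)[empty], collapse = ", "))
  freq[!empty, ] <- tab[!empty, , drop = FALSE] / totals[!empty]
  freq[empty, ] <- NaN
  freq
}
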