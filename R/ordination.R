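#' Principal coordinates analysis of a divergence matrix
#'
#' Classical multidimensional scaling: the squared dissimilarities are
#' double-centred (B = -1/2 J (D*D) J with J the centering projector), B is
#' eigendecomposed, and coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues. Negative eigenvalues — possible for
#' non-Euclidean divergence matrices — are dropped with a warning; if fewer
#' positive eigenvalues than `nAxes` exist, the remaining axes are
#' zero-padded (with a warning). Axis signs are fixed by forcing the
#' largest-magnitude loading of each axis positive, so results are
#' reproducible across runs and platforms.
#'
#' @param D a [DivergenceMatrix-class] or a plain symmetric matrix with zero
#'   diagonal.
#' @param nAxes number of coordinate axes to keep (default 2).
#' @return an [OrdinationResult-class].
#' @examples
#' pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' D <- as.matrix(dist(pts))
#' ord <- pcoa(D, nAxes = 2)
#' dist(ordinationCoordinates(ord))  # recovers D
#' @export
pcoa <- function(D, nAxes = 2L) {
  if (is(D, "DivergenceMatrix")) D <- divergenceValues(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (any(abs(D - t(D)) > 1e-8))
    stop("D must be symmetric")
  if (any(diag(D) != 0))
    stop("D must have a zero diagonal")
  stopifnot(nAxes >= 1L)
  n <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  A <- -0.5 * D^2
  B <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- eig$values

  nPos <- sum(vals > max(1e-10, 1e-8 * max(abs(vals), 1)))
  if (nPos < length(vals) && any(vals < -1e-8 * max(abs(vals), 1)))
    warning("dropping ", sum(vals < 0), " negative eigenvalue(s); ",
            "divergence matrix is not Euclidean")
  keep <- min(nAxes, nPos)
  coords <- matrix(0, n, nAxes,
                   dimnames = list(labels, paste0("axis", seq_len(nAxes))))
  for (a in seq_len(keep)) {
    v <- eig$vectors[, a]
    if (v[which.max(abs(v))] < 0) v <- -v  # pinned sign convention
    coords[, a] <- v * sqrt(vals[a])
  }
  if (keep < nAxes)
    warning("only ", keep, " positive eigenvalue(s); zero-padding to ",
            nAxes, " axes")
  new("OrdinationResult", coordinates = coords, eigenvalues = vals,
      axesKept = as.integer(nAxes))
}

#' Write PCoA coordinates and eigenvalues as CSV
#'
#' @param ord an [OrdinationResult-class].
#' @param prefix output prefix; writes `<prefix>_coords.csv`
#'   (`population,axis1..axisK`) and `<prefix>_eigenvalues.csv`.
#' @export
writeOrdination <- function(ord, prefix) {
  stopifnot(is(ord, "OrdinationResult"))
  co <- data.frame(population = rownames(ordinationCoordinates(ord)),
                   ordinationCoordinates(ord), check.names = FALSE)
  utils::write.csv(co, paste0(prefix, "_coords.csv"), row.names = FALSE)
  utils::write.csv(data.frame(axis = seq_along(ordinationEigenvalues(ord)),
                              eigenvalue = ordinationEigenvalues(ord)),
                   paste0(prefix, "_eigenvalues.csv"), row.names = FALSE)
  invisible(prefix)
}
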