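# Rigid-body geometry shared across the sampler and trajectory metrics.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' coordinate sets, mass-unweighted, with the usual determinant correction so
#' reflections are never applied.
#'
#' @param mobile n x 3 matrix to move.
#' @param reference n x 3 matrix to match.
#' @return list with `xyz` (superposed mobile), `rotation` (3 x 3),
#'   `rmsd` (Angstrom).
#' @export
kabsch_fit <- function(mobile, reference) {
  stopifnot(is.matrix(mobile), is.matrix(reference),
            ncol(mobile) == 3L, ncol(reference) == 3L)
  if (nrow(mobile) != nrow(reference))
    stop("coordinate sets differ in atom count (",
         nrow(mobile), " vs ", nrow(reference), ")")
  if (nrow(mobile) < 3L)
    stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm); b <- sweep(reference, 2, cr)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(a %*% rot, 2, cr, "+")
  list(xyz = fitted, rotation = rot,
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))))
}

#' Minimal RMSD between two coordinate sets after optimal superposition
#'
#' @param mobile,reference n x 3 matrices (or structures; heavy and hydrogen
#'   atoms are all used — mass-unweighted, all-atom).
#' @param selection optional logical/integer atom mask applied to both sets.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(mobile, reference, selection = NULL) {
  m <- if (inherits(mobile, "ens_structure")) coords(mobile) else mobile
  r <- if (inherits(reference, "ens_structure")) coords(reference) else reference
  if (!is.null(selection)) {
    m <- m[selection, , drop = FALSE]
    r <- r[selection, , drop = FALSE]
  }
  kabsch_fit(m, r)$rmsd
}

# Plain (unfitted) RMSD.
rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Random proper rotation matrix (QR of a Gaussian matrix, det fixed to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Unit vector helper.
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

# Angle between two vectors in degrees.
vec_angle <- function(a, b) {
  ca <- sum(unit(a) * unit(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}
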