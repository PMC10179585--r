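# Pluggable energy models for the excursion sampler.
#
# A model is a plain list: energy(xyz) -> scalar, gradient(xyz) -> n x 3
# matrix, plus a label. xyz is the n x 3 coordinate matrix in Angstrom;
# energies are in kcal/mol so the Boltzmann constant below makes the
# temperatures in the annealing ladder meaningful.

.kB <- 0.0019872041  # kcal / (mol K)

#' Isotropic harmonic well (test model)
#'
#' E = k/2 * sum |r_i - center|^2. Its unique minimum makes it the standard
#' check that annealing and minimisation land where they should.
#'
#' @param k force constant, kcal/mol/A^2.
#' @param center 3-vector, Angstrom.
#' @return an energy model list (`energy`, `gradient`, `label`).
#' @export
harmonic_well_model <- function(k = 1, center = c(0, 0, 0)) {
  list(
    energy = function(xyz) {
      d <- sweep(xyz, 2, center)
      0.5 * k * sum(d^2)
    },
    gradient = function(xyz) k * sweep(xyz, 2, center),
    label = sprintf("harmonic_well(k=%g)", k)
  )
}

#' Coarse-grained bead-chain potential
#'
#' The default toy peptide potential for excursion sampling: one bead per
#' residue, with (i) harmonic springs between consecutive beads, (ii) a
#' harmonic excluded-volume repulsion between beads at least two apart that
#' come closer than `sigma`, and (iii) a cosine dihedral term over each
#' consecutive quadruple that rewards extended torsions and so gives the chain
#' competing compact/extended states for the annealer to hop between.
#'
#' E = sum_bonds k_bond (r - r0)^2
#'   + sum_{|i-j|>=2, r<sigma} k_rep (sigma - r)^2
#'   + sum_dihedrals k_dih (1 + cos phi)
#'
#' Gradients are analytic (checked against finite differences in the test
#' suite).
#'
#' @param n_beads number of beads (>= 2).
#' @param k_bond bond spring constant, kcal/mol/A^2.
#' @param r0 equilibrium bond length, Angstrom (3.8, a CA-CA virtual bond).
#' @param k_rep excluded-volume constant, kcal/mol/A^2.
#' @param sigma excluded-volume onset distance, Angstrom.
#' @param k_dih dihedral barrier, kcal/mol.
#' @return an energy model list (`energy`, `gradient`, `label`, `n_beads`).
#' @export
bead_chain_model <- function(n_beads, k_bond = 10, r0 = 3.8,
                             k_rep = 4, sigma = 4.5, k_dih = 1) {
  stopifnot(n_beads >= 2L)
  bonds <- cbind(seq_len(n_beads - 1L), seq_len(n_beads - 1L) + 1L)
  nb <- which(outer(seq_len(n_beads), seq_len(n_beads),
                    function(i, j) j - i >= 2L), arr.ind = TRUE)
  dih <- if (n_beads >= 4L)
    cbind(1:(n_beads - 3L), 2:(n_beads - 2L), 3:(n_beads - 1L), 4:n_beads)
  else matrix(integer(0), 0, 4)

  pair_terms <- function(xyz) {
    db <- xyz[bonds[, 2], , drop = FALSE] - xyz[bonds[, 1], , drop = FALSE]
    rb <- sqrt(rowSums(db^2))
    dn <- xyz[nb[, 2], , drop = FALSE] - xyz[nb[, 1], , drop = FALSE]
    rn <- sqrt(rowSums(dn^2))
    list(db = db, rb = rb, dn = dn, rn = rn, close = rn < sigma)
  }

  energy <- function(xyz) {
    p <- pair_terms(xyz)
    e <- k_bond * sum((p$rb - r0)^2) +
      k_rep * sum((sigma - p$rn[p$close])^2)
    if (nrow(dih) > 0L)
      e <- e + k_dih * sum(1 + cos(dihedral_angles(xyz, dih)))
    e
  }

  # signed incidence matrix of the nonbonded pair list: scatter-add by one
  # dense matrix product (pair counts are tiny for toy chains)
  inc_nb <- matrix(0, n_beads, nrow(nb))
  inc_nb[cbind(nb[, 1], seq_len(nrow(nb)))] <- -1
  inc_nb[cbind(nb[, 2], seq_len(nrow(nb)))] <- 1

  gradient <- function(xyz) {
    g <- matrix(0, nrow(xyz), 3L)
    p <- pair_terms(xyz)
    # bonds: endpoints of the bond list are unique per column, index directly
    fb <- 2 * k_bond * (p$rb - r0) / pmax(p$rb, 1e-12)
    gb <- p$db * fb
    g[bonds[, 1], ] <- g[bonds[, 1], ] - gb
    g[bonds[, 2], ] <- g[bonds[, 2], ] + gb
    if (any(p$close)) {
      fr <- ifelse(p$close,
                   -2 * k_rep * (sigma - p$rn) / pmax(p$rn, 1e-12), 0)
      g <- g + inc_nb %*% (p$dn * fr)
    }
    if (nrow(dih) > 0L)
      g <- g + dihedral_gradient(xyz, dih, k_dih)
    g
  }

  list(energy = energy, gradient = gradient,
       label = sprintf("bead_chain(n=%d)", n_beads), n_beads = n_beads)
}

# Torsion angles for quadruple index matrix q (one row per dihedral), radians.
dihedral_angles <- function(xyz, q) {
  b1 <- xyz[q[, 2], , drop = FALSE] - xyz[q[, 1], , drop = FALSE]
  b2 <- xyz[q[, 3], , drop = FALSE] - xyz[q[, 2], , drop = FALSE]
  b3 <- xyz[q[, 4], , drop = FALSE] - xyz[q[, 3], , drop = FALSE]
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m <- row_cross(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m * n2), rowSums(n1 * n2))
}

row_cross <- function(a, b) {
  out <- a
  out[, 1] <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  out[, 2] <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  out[, 3] <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  out
}

# Gradient of sum k (1 + cos phi) over the quadruples in q.
dihedral_gradient <- function(xyz, q, k) {
  n <- nrow(xyz)
  g <- matrix(0, n, 3L)
  b1 <- xyz[q[, 2], , drop = FALSE] - xyz[q[, 1], , drop = FALSE]
  b2 <- xyz[q[, 3], , drop = FALSE] - xyz[q[, 2], , drop = FALSE]
  b3 <- xyz[q[, 4], , drop = FALSE] - xyz[q[, 3], , drop = FALSE]
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  m <- row_cross(n1, b2 / nb2)
  phi <- atan2(rowSums(m * n2), rowSums(n1 * n2))
  dEdphi <- -k * sin(phi)
  # standard torsion-angle derivatives (translation- and torque-consistent),
  # verified against central finite differences
  dphi1 <- n1 * (nb2 / rowSums(n1^2))
  dphi4 <- -n2 * (nb2 / rowSums(n2^2))
  c1 <- rowSums(b1 * b2) / nb2^2
  c2 <- rowSums(b3 * b2) / nb2^2
  dphi2 <- -(1 + c1) * dphi1 + c2 * dphi4
  dphi3 <- c1 * dphi1 - (1 + c2) * dphi4
  # consecutive quadruples: each column of q has unique indices
  g[q[, 1], ] <- g[q[, 1], ] + dEdphi * dphi1
  g[q[, 2], ] <- g[q[, 2], ] + dEdphi * dphi2
  g[q[, 3], ] <- g[q[, 3], ] + dEdphi * dphi3
  g[q[, 4], ] <- g[q[, 4], ] + dEdphi * dphi4
  g
}

#' Check an energy model's gradient against central finite differences
#'
#' @param model energy model list.
#' @param xyz coordinates to test at.
#' @param h step size.
#' @return maximum relative error over components (scaled by gradient norm).
#' @export
check_gradient <- function(model, xyz, h = 1e-5) {
  g <- model$gradient(xyz)
  fd <- matrix(0, nrow(xyz), 3L)
  for (i in seq_len(nrow(xyz))) for (c in 1:3) {
    xp <- xyz; xp[i, c] <- xp[i, c] + h
    xm <- xyz; xm[i, c] <- xm[i, c] - h
    fd[i, c] <- (model$energy(xp) - model$energy(xm)) / (2 * h)
  }
  max(abs(g - fd)) / max(sqrt(mean(g^2)), 1)
}
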