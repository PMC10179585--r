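# Independent oracles used against the package's fast paths. Deliberately
# naive: double loops and grid searches, no shared code with the package
# internals they check.

# O(N*M) double-loop minimum distance between two coordinate sets.
brute_min_dist <- function(a, b) {
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- sqrt(sum((a[i, ] - b[j, ])^2))
    if (d < best) best <- d
  }
  best
}

# Brute-force binding residues: loop over residues and atom pairs.
brute_binding_residues <- function(receptor, ligand_atoms, cutoff) {
  rat <- receptor$atom[receptor$atom$is_heavy, , drop = FALSE]
  lat <- ligand_atoms[ligand_atoms$is_heavy, , drop = FALSE]
  keys <- unique(residue_keys(rat))
  hits <- character(0)
  for (k in keys) {
    sub <- rat[residue_keys(rat) == k, , drop = FALSE]
    if (brute_min_dist(coords(sub), coords(lat)) <= cutoff)
      hits <- c(hits, k)
  }
  hits
}

# Minimal RMSD by dense rotation-grid search over ZYZ Euler angles with a
# Nelder-Mead polish; independent of the SVD route.
grid_rmsd <- function(mobile, reference, n_grid = 16) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  rotmat <- function(ang) {
    cz1 <- cos(ang[1]); sz1 <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz2 <- cos(ang[3]); sz2 <- sin(ang[3])
    rz1 <- matrix(c(cz1, sz1, 0, -sz1, cz1, 0, 0, 0, 1), 3, 3)
    ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    rz2 <- matrix(c(cz2, sz2, 0, -sz2, cz2, 0, 0, 0, 1), 3, 3)
    rz1 %*% ry %*% rz2
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rotmat(ang)) - b)^2)))
  best <- Inf; best_ang <- c(0, 0, 0)
  g1 <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  g2 <- seq(0, pi, length.out = n_grid)
  for (a1 in g1) for (a2 in g2) for (a3 in g1) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  polish <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 2000))
  min(best, polish$value)
}

# Exhaustive ddG pose selection count for one run's affinity vector.
brute_select_count <- function(affinities, cutoff) {
  n <- 1L
  for (k in seq_along(affinities)[-1L])
    if (abs(affinities[k] - affinities[1L]) <= cutoff) n <- n + 1L
  n
}

random_structure <- function(n_atoms, seed, spread = 10) {
  set.seed(seed)
  atoms <- data.frame(
    serial = seq_len(n_atoms), name = "CA", element = "C",
    resid = "ALA", resno = seq_len(n_atoms), ins = " ", chain = "A",
    x = runif(n_atoms, -spread, spread),
    y = runif(n_atoms, -spread, spread),
    z = runif(n_atoms, -spread, spread), stringsAsFactors = FALSE)
  ens_structure(atoms, label = sprintf("random_%d", seed))
}
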