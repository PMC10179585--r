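# Geometric detection and classification of the noncovalent interactions
# that dominate small-molecule binding to aromatic-rich disordered peptides:
# hydrogen bonds, pi-pi stacking (parallel and T-shaped), XH-pi (X = C, N, O)
# and lone-pair-pi contacts. All thresholds live in one criteria block; every
# emitted record stores the geometry it was accepted on, so records can be
# re-audited against the criteria.

#' Geometric acceptance criteria for interaction classification
#'
#' Thresholds follow common structural-biology practice; none are fitted.
#' Interplanar angles are folded to \[0, 90\] degrees so the sign ambiguity of
#' ring normals cannot flip a class.
#'
#' @param hbond_d_max donor-acceptor distance cutoff, Angstrom.
#' @param hbond_theta_min donor-H-acceptor angle minimum, degrees.
#' @param pi_d_parallel,pi_a_parallel centroid distance (A) and maximum
#'   interplanar angle (deg) for parallel stacking.
#' @param pi_d_tshaped,pi_a_tshaped centroid distance (A) and minimum
#'   interplanar angle (deg) for T-shaped contacts.
#' @param xh_d_max H-to-centroid distance cutoff, Angstrom.
#' @param xh_lateral_slack allowed in-plane offset beyond the ring radius, A.
#' @param xh_approach_max maximum angle between X->H and H->centroid, deg.
#' @param lp_d_max acceptor-to-centroid distance cutoff, Angstrom.
#' @param lp_axis_max maximum angle off the ring normal, degrees.
#' @param planarity_tol maximum out-of-plane deviation for a ring, Angstrom.
#' @return named list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hbond_d_max = 3.5, hbond_theta_min = 130,
                                 pi_d_parallel = 5.5, pi_a_parallel = 30,
                                 pi_d_tshaped = 6.0, pi_a_tshaped = 60,
                                 xh_d_max = 3.0, xh_lateral_slack = 0.5,
                                 xh_approach_max = 60,
                                 lp_d_max = 3.5, lp_axis_max = 25,
                                 planarity_tol = 0.3) {
  structure(list(hbond_d_max = hbond_d_max, hbond_theta_min = hbond_theta_min,
                 pi_d_parallel = pi_d_parallel, pi_a_parallel = pi_a_parallel,
                 pi_d_tshaped = pi_d_tshaped, pi_a_tshaped = pi_a_tshaped,
                 xh_d_max = xh_d_max, xh_lateral_slack = xh_lateral_slack,
                 xh_approach_max = xh_approach_max,
                 lp_d_max = lp_d_max, lp_axis_max = lp_axis_max,
                 planarity_tol = planarity_tol),
            class = "interaction_criteria")
}

# Sidechain ring templates for the aromatic residues.
.ring_templates <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

make_ring <- function(member_idx, xyz, source, planarity_tol) {
  centroid <- colMeans(xyz)
  centered <- sweep(xyz, 2, centroid)
  sv <- svd(centered)
  normal <- sv$v[, 3L]
  dev <- max(abs(centered %*% normal))
  if (dev > planarity_tol) return(NULL)
  structure(list(members = member_idx, centroid = as.numeric(centroid),
                 normal = as.numeric(normal / sqrt(sum(normal^2))),
                 radius = max(sqrt(rowSums(centered^2))),
                 planarity = dev, source = source),
            class = "aromatic_ring")
}

# Fundamental-cycle perception on a bond table: spanning forest + one cycle
# per chord, keeping 5- and 6-membered rings.
perceive_cycles <- function(bonds, n_atoms) {
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, n_atoms)
  depth <- rep(NA_integer_, n_atoms)
  visited <- rep(FALSE, n_atoms)
  chords <- list()
  for (root in seq_len(n_atoms)) {
    if (visited[root]) next
    visited[root] <- TRUE; depth[root] <- 0L
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE; parent[w] <- v; depth[w] <- depth[v] + 1L
          queue <- c(queue, w)
        } else if (w != parent[v] && v < w) {
          chords[[length(chords) + 1L]] <- c(v, w)
        }
      }
    }
  }
  path_to_root <- function(v) {
    p <- v
    while (!is.na(parent[v])) { v <- parent[v]; p <- c(p, v) }
    p
  }
  rings <- list()
  for (ch in chords) {
    pa <- path_to_root(ch[1]); pb <- path_to_root(ch[2])
    common <- intersect(pa, pb)
    if (length(common) == 0L) next
    lca <- common[1L]
    cyc <- c(pa[seq_len(match(lca, pa))], rev(pb[seq_len(match(lca, pb) - 1L)]))
    if (length(cyc) %in% c(5L, 6L)) rings[[length(rings) + 1L]] <- sort(cyc)
  }
  unique(rings)
}

#' Detect aromatic rings in a structure
#'
#' Protein rings come from fixed residue-name templates (PHE/TYR six-membered,
#' HIS five-membered, TRP both of its rings). Ligand rings come from an
#' explicit annotation (list of atom-index or atom-name vectors) when given,
#' otherwise from fundamental-cycle perception on a supplied bond table.
#' Every candidate must pass the planarity tolerance, which rejects puckered
#' (e.g. pyran-like) rings.
#'
#' @param structure `ens_structure`.
#' @param ligand_rings optional list of integer index vectors (rows of the
#'   atom table) or character atom-name vectors defining ligand rings.
#' @param connectivity optional two-column matrix/data.frame of bonded atom
#'   index pairs for cycle perception.
#' @param criteria `interaction_criteria` (supplies the planarity tolerance).
#' @return list of `aromatic_ring` (members, centroid, unit normal, radius,
#'   source).
#' @export
detect_rings <- function(structure, ligand_rings = NULL, connectivity = NULL,
                         criteria = interaction_criteria()) {
  at <- structure$atom
  xyz <- coords(structure)
  rings <- list()
  keys <- residue_keys(at)
  for (key in unique(keys)) {
    ridx <- which(keys == key)
    resname <- at$resid[ridx[1L]]
    tpl <- .ring_templates[[resname]]
    if (is.null(tpl)) next
    for (members in tpl) {
      m <- ridx[match(members, at$name[ridx])]
      if (any(is.na(m))) next
      ring <- make_ring(m, xyz[m, , drop = FALSE], key,
                        criteria$planarity_tol)
      if (!is.null(ring)) rings[[length(rings) + 1L]] <- ring
    }
  }
  lig_sets <- NULL
  if (!is.null(ligand_rings)) {
    lig_sets <- lapply(ligand_rings, function(r) {
      if (is.character(r)) {
        m <- match(r, at$name)
        if (any(is.na(m)))
          stop("ring annotation names atoms absent from the structure: ",
               paste(r[is.na(m)], collapse = ", "))
        m
      } else {
        if (any(r < 1L | r > nrow(at)))
          stop("ring annotation references atom indices outside the structure")
        as.integer(r)
      }
    })
  } else if (!is.null(connectivity)) {
    lig_sets <- perceive_cycles(as.matrix(connectivity), nrow(at))
  }
  for (s in lig_sets) {
    ring <- make_ring(s, xyz[s, , drop = FALSE],
                      paste0("ligand:", paste(s, collapse = "-")),
                      criteria$planarity_tol)
    if (!is.null(ring)) rings[[length(rings) + 1L]] <- ring
  }
  rings
}

fold_angle <- function(a) {
  a <- a %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Classify a ring-ring aromatic interaction
#'
#' With centroid distance d and interplanar angle alpha folded to \[0, 90\]
#' degrees: parallel stacking when d and alpha are both small, T-shaped when
#' d is moderate and the planes are near-perpendicular; otherwise nothing.
#'
#' @param r1,r2 `aromatic_ring`.
#' @param criteria `interaction_criteria`.
#' @return an interaction record (list with `kind`, `participants`, `d`,
#'   `alpha`) or NULL.
#' @export
classify_aromatic <- function(r1, r2, criteria = interaction_criteria()) {
  d <- sqrt(sum((r1$centroid - r2$centroid)^2))
  alpha <- fold_angle(vec_angle(r1$normal, r2$normal))
  kind <- if (d <= criteria$pi_d_parallel && alpha <= criteria$pi_a_parallel)
    "pi_pi_parallel"
  else if (d <= criteria$pi_d_tshaped && alpha >= criteria$pi_a_tshaped)
    "pi_pi_tshaped"
  else return(NULL)
  list(kind = kind, participants = list(r1$source, r2$source),
       d = d, alpha = alpha)
}

#' Classify an XH-pi interaction (X = C, N, O)
#'
#' Accepted when the hydrogen sits close over the ring face: H-to-centroid
#' distance within the cutoff, in-plane projection within the ring radius
#' plus a slack, and the X-H bond pointing at the ring (small angle between
#' X->H and H->centroid).
#'
#' @param x_xyz,h_xyz 3-vectors: the heavy donor atom X and its hydrogen.
#' @param x_element element of X; must be "C", "N" or "O".
#' @param ring `aromatic_ring`.
#' @param criteria `interaction_criteria`.
#' @return interaction record (`kind`, `d` = H-centroid distance, `lateral`,
#'   `approach` angle) or NULL.
#' @export
classify_xh_pi <- function(x_xyz, h_xyz, x_element, ring,
                           criteria = interaction_criteria()) {
  if (!x_element %in% c("C", "N", "O"))
    stop("XH-pi donor must be C, N or O (got ", x_element, ")")
  if (is.null(h_xyz)) stop("XH-pi classification needs the hydrogen position")
  v <- ring$centroid - h_xyz
  d <- sqrt(sum(v^2))
  if (d > criteria$xh_d_max) return(NULL)
  axial <- sum(v * ring$normal)
  lateral <- sqrt(max(d^2 - axial^2, 0))
  if (lateral > ring$radius + criteria$xh_lateral_slack) return(NULL)
  approach <- vec_angle(h_xyz - x_xyz, v)
  if (approach > criteria$xh_approach_max) return(NULL)
  list(kind = "xh_pi", participants = list(x_element, ring$source),
       d = d, lateral = lateral, approach = approach)
}

#' Classify a lone-pair-pi interaction
#'
#' An O/N acceptor sitting on the ring axis: atom-to-centroid distance within
#' the cutoff and within a small angle of the ring normal.
#'
#' @param a_xyz 3-vector, the acceptor atom (O or N carrying a lone pair).
#' @param element element of the acceptor; must be "O" or "N".
#' @param ring `aromatic_ring`.
#' @param criteria `interaction_criteria`.
#' @return interaction record (`kind`, `d`, `axis_angle`) or NULL.
#' @export
classify_lonepair_pi <- function(a_xyz, element, ring,
                                 criteria = interaction_criteria()) {
  if (!element %in% c("O", "N"))
    stop("lone-pair-pi acceptor must be O or N (got ", element, ")")
  v <- a_xyz - ring$centroid
  d <- sqrt(sum(v^2))
  if (d > criteria$lp_d_max) return(NULL)
  axis_angle <- fold_angle(vec_angle(v, ring$normal))
  if (axis_angle > criteria$lp_axis_max) return(NULL)
  list(kind = "lonepair_pi", participants = list(element, ring$source),
       d = d, axis_angle = axis_angle)
}

#' Hydrogen-bond site annotation
#'
#' @param donors data.frame with columns `donor` (atom index of the heavy
#'   donor) and `h` (index of the attached hydrogen, NA when hydrogens are
#'   absent).
#' @param acceptors integer vector of acceptor atom indices.
#' @return list of class `hbond_sites`.
#' @export
hbond_sites <- function(donors, acceptors) {
  if (is.null(donors)) donors <- data.frame(donor = integer(0), h = integer(0))
  structure(list(donors = donors, acceptors = as.integer(acceptors)),
            class = "hbond_sites")
}

#' Detect hydrogen bonds between two annotated structures
#'
#' A bond is recorded when the donor-acceptor distance is within the cutoff
#' AND the donor-H-acceptor angle meets the minimum (inclusive both).
#' Detection is symmetric: donors of either molecule are paired with
#' acceptors of the other. With `distance_only = TRUE` the angle test is
#' skipped (for structures without hydrogens); otherwise a donor lacking its
#' hydrogen is an error.
#'
#' @param struct_a,struct_b `ens_structure`.
#' @param sites_a,sites_b `hbond_sites` for each structure.
#' @param criteria `interaction_criteria`.
#' @param distance_only skip the angle criterion.
#' @return data.frame, one row per hydrogen bond: `kind`, `donor_mol`,
#'   `donor_idx`, `h_idx`, `acceptor_mol`, `acceptor_idx`, `distance`,
#'   `angle` (NA in distance-only mode).
#' @export
detect_hbonds <- function(struct_a, struct_b, sites_a, sites_b,
                          criteria = interaction_criteria(),
                          distance_only = FALSE) {
  xa <- coords(struct_a); xb <- coords(struct_b)
  one_direction <- function(donors, dx, acceptors, ax, dmol, amol) {
    out <- list()
    for (r in seq_len(nrow(donors))) {
      di <- donors$donor[r]; hi <- donors$h[r]
      if (!distance_only && (is.null(hi) || is.na(hi)))
        stop("donor atom ", di, " in molecule ", dmol,
             " has no hydrogen; use distance_only = TRUE for ",
             "hydrogen-free structures")
      for (ai in acceptors) {
        dvec <- ax[ai, ] - dx[di, ]
        dist <- sqrt(sum(dvec^2))
        if (dist > criteria$hbond_d_max || dist < 1e-6) next
        ang <- NA_real_
        if (!distance_only) {
          h <- dx[hi, ]
          ang <- vec_angle(dx[di, ] - h, ax[ai, ] - h)
          if (ang < criteria$hbond_theta_min) next
        }
        out[[length(out) + 1L]] <- data.frame(
          kind = "hbond", donor_mol = dmol, donor_idx = di,
          h_idx = if (distance_only) NA_integer_ else hi,
          acceptor_mol = amol, acceptor_idx = ai,
          distance = dist, angle = ang, stringsAsFactors = FALSE)
      }
    }
    out
  }
  rows <- c(one_direction(sites_a$donors, xa, sites_b$acceptors, xb, "a", "b"),
            one_direction(sites_b$donors, xb, sites_a$acceptors, xa, "b", "a"))
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), donor_mol = character(0),
                      donor_idx = integer(0), h_idx = integer(0),
                      acceptor_mol = character(0), acceptor_idx = integer(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Re-audit interaction records against the criteria they were emitted under
#'
#' Every record stores the geometry it was accepted on; this re-applies the
#' thresholds and reports whether each record still satisfies them.
#'
#' @param records list of interaction records (from the classifiers) and/or
#'   rows of [detect_hbonds()] output converted with `split(df, seq_len(nrow(df)))`.
#' @param criteria `interaction_criteria`.
#' @return logical vector, one per record.
#' @export
audit_interactions <- function(records, criteria = interaction_criteria()) {
  vapply(records, function(r) {
    if (is.data.frame(r)) r <- as.list(r)
    switch(r$kind,
      hbond = r$distance <= criteria$hbond_d_max &&
        (is.na(r$angle) || r$angle >= criteria$hbond_theta_min),
      pi_pi_parallel = r$d <= criteria$pi_d_parallel &&
        r$alpha <= criteria$pi_a_parallel,
      pi_pi_tshaped = r$d <= criteria$pi_d_tshaped &&
        r$alpha >= criteria$pi_a_tshaped,
      xh_pi = r$d <= criteria$xh_d_max &&
        r$approach <= criteria$xh_approach_max,
      lonepair_pi = r$d <= criteria$lp_d_max &&
        r$axis_angle <= criteria$lp_axis_max,
      FALSE)
  }, logical(1))
}
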