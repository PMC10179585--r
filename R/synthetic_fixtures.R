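# Synthetic fixtures: every input the pipeline consumes can be generated in
# code -- toy bead peptides, a rigid two/three-ring toy ligand, Vina-format
# pose files with controlled affinity gaps and planted contacts, minimal
# interaction geometries with negative twins, and noisy trajectories with
# scripted events. All generators are deterministic given their seed.

.res_code_cycle <- c("ALA", "GLY", "SER", "THR", "VAL", "LEU", "ILE", "PRO",
                     "MET", "TYR", "PHE", "TRP", "HIS", "LYS", "ARG", "ASP",
                     "GLU", "ASN", "GLN", "CYS")

#' Generate a toy bead peptide
#'
#' One carbon bead ("CA") per residue at 3.8 A virtual-bond spacing, residue
#' names cycling through the 20 standard codes (residue 10 is TYR, 11 PHE --
#' convenient for hot-spot fixtures). `extended` lays the chain along +x with
#' a small fixed zigzag; `collapsed` biases a 3.8 A random walk back towards
#' the origin; `random` is an unbiased 3.8 A random walk.
#'
#' @param n_residues number of residues (>= 2).
#' @param conformation `"extended"`, `"collapsed"` or `"random"`.
#' @param seed integer.
#' @return `ens_structure`.
#' @export
make_toy_peptide <- function(n_residues,
                             conformation = c("extended", "collapsed",
                                              "random"),
                             seed = 1L) {
  conformation <- match.arg(conformation)
  if (n_residues < 2L) stop("a toy peptide needs at least 2 residues")
  set.seed(seed)
  step <- 3.8
  xyz <- matrix(0, n_residues, 3L)
  if (conformation == "extended") {
    xyz[, 1] <- (seq_len(n_residues) - 1L) * step
    xyz[, 2] <- 0.3 * (-1)^(seq_len(n_residues))
  } else {
    for (i in 2:n_residues) {
      dir <- stats::rnorm(3)
      if (conformation == "collapsed" && i > 3L)
        dir <- unit(unit(dir) - 0.8 * unit(xyz[i - 1L, ]))
      xyz[i, ] <- xyz[i - 1L, ] + step * unit(dir)
    }
  }
  n <- n_residues
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C",
    resid = rep_len(.res_code_cycle, n), resno = seq_len(n),
    ins = " ", chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  ens_structure(atoms, label = sprintf("toy_peptide_%d_%s", n, conformation))
}

hexagon <- function(center, radius = 1.39, phase = 0, basis = diag(3)[, 1:2]) {
  ang <- phase + seq(0, by = pi / 3, length.out = 6)
  t(vapply(ang, function(a)
    center + radius * (cos(a) * basis[, 1] + sin(a) * basis[, 2]),
    numeric(3)))
}

#' Generate the rigid toy ligand
#'
#' A catechin-like rigid fragment: two planar six-membered carbon rings (A
#' and B) bridged by a puckered ether-containing ring (rejected by the ring
#' planarity filter, like a pyran), one hydroxyl donor (O-H) on ring B, and
#' ether/hydroxyl oxygen acceptors. With `gallate = TRUE` a third planar ring
#' is attached through an ester oxygen. Returned with its bond table, the
#' aromatic-ring annotation and hydrogen-bond site annotation.
#'
#' @param gallate attach the third (gallate-like) aromatic ring.
#' @return list: `structure`, `connectivity` (2-column bond index matrix),
#'   `rings` (list of index vectors, the aromatic rings), `sites`
#'   ([hbond_sites()]), `anchor` (index of the heavy atom used for pose
#'   placement).
#' @export
make_toy_ligand <- function(gallate = FALSE) {
  ringA <- hexagon(c(0, 0, 0))
  # fused puckered ring sharing the A1-A2 edge: the shared-edge hexagon's
  # centre is a1+a2 (ring A centred at the origin); its vertices 2..5 are the
  # four new ring atoms, one of which is lifted out of plane
  centerC <- ringA[1, ] + ringA[2, ]
  angC <- atan2(ringA[1, 2] - centerC[2], ringA[1, 1] - centerC[1])
  ringC_all <- hexagon(centerC, phase = angC)
  newC <- ringC_all[2:5, ]
  newC[2, 3] <- 1.0  # pucker (fails the 0.3 A ring planarity tolerance)
  ringB_attach <- newC[3, ]
  b1 <- ringB_attach + 1.48 * unit(ringB_attach - centerC)
  centerB <- b1 + 1.39 * unit(b1 - ringB_attach)
  angB <- atan2(b1[2] - centerB[2], b1[1] - centerB[1])
  ringB <- hexagon(centerB, phase = angB)
  oh_b <- centerB + 2.75 * unit(ringB[4, ] - centerB)   # hydroxyl O on B
  h_b <- oh_b + 0.96 * unit(oh_b - centerB)             # its hydrogen
  oh_a <- 2.75 * unit(ringA[4, ])                       # hydroxyl O on A (no H)
  xyz <- rbind(ringA, newC, ringB, oh_b, oh_a)
  element <- c(rep("C", 6), "O", "C", "C", "C", rep("C", 6), "O", "O")
  name <- c(paste0("C", 1:6), "O7", paste0("C", 8:10), paste0("C", 11:16),
            "O17", "O18")
  bonds <- rbind(cbind(1:6, c(2:6, 1)),                    # ring A
                 cbind(c(1, 7, 8, 9, 10), c(7, 8, 9, 10, 2)),  # fused ring C
                 cbind(10 + (1:6), 10 + c(2:6, 1)),        # ring B
                 c(9, 11),                                 # C-B bridge
                 c(14, 17),                                # B-OH
                 c(4, 18))                                 # A-OH
  rings <- list(1:6, 11:16)
  if (gallate) {
    u <- unit(c(newC[2, 1:2] - centerC[1:2], 0))
    o_est <- newC[2, ] + 1.36 * u
    g1 <- o_est + 1.36 * u
    centerG <- g1 + 1.39 * u
    ringG <- hexagon(centerG, phase = atan2(g1[2] - centerG[2],
                                            g1[1] - centerG[1]))
    ringG[, 3] <- g1[3]  # keep the gallate ring planar at the ester height
    xyz <- rbind(xyz, o_est, ringG)
    element <- c(element, "O", rep("C", 6))
    name <- c(name, "O19", paste0("C", 20:25))
    bonds <- rbind(bonds, c(8, 19), c(19, 20),
                   cbind(19 + (1:6), 19 + c(2:6, 1)))
    rings <- c(rings, list(20:25))
  }
  n_heavy <- nrow(xyz)
  xyz <- rbind(xyz, h_b)
  element <- c(element, "H")
  name <- c(name, "HO1")
  atoms <- data.frame(serial = seq_len(nrow(xyz)), name = name,
                      element = element, resid = "LIG", resno = 1L,
                      ins = " ", chain = "L",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  s <- ens_structure(atoms, label = if (gallate) "toy_ligand_gallate"
                     else "toy_ligand")
  list(structure = s, connectivity = bonds, rings = rings,
       sites = hbond_sites(
         donors = data.frame(donor = which(name == "O17"),
                             h = which(name == "HO1")),
         acceptors = which(element == "O" & name != "O17")),
       anchor = 1L, n_heavy = n_heavy)
}

#' Fixture specification for pose-set generation
#'
#' @param seed integer.
#' @param poses_per_run MODEL blocks per file (study convention: 9).
#' @param affinity_top affinity of the top pose, kcal/mol.
#' @param gap_distribution list with `kind` (`"uniform"`, `"exponential"` or
#'   `"constant"`) and its parameters (`min`/`max`, `rate`, or `value`);
#'   rank-to-rank affinity gaps are drawn from it (non-negative).
#' @param planted_contacts list of `list(resno =, band = c(lo, hi))`: pose 1
#'   is placed so its nearest heavy atom to that residue falls inside
#'   `(lo, hi]` Angstrom.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, poses_per_run = 9L, affinity_top = -8.0,
                         gap_distribution = list(kind = "uniform",
                                                 min = 0, max = 0.15),
                         planted_contacts = list()) {
  stopifnot(poses_per_run >= 1L, is.finite(affinity_top))
  structure(list(seed = as.integer(seed),
                 poses_per_run = as.integer(poses_per_run),
                 affinity_top = affinity_top,
                 gap_distribution = gap_distribution,
                 planted_contacts = planted_contacts),
            class = "fixture_spec")
}

draw_gaps <- function(dist, n) {
  g <- switch(dist$kind,
              uniform = stats::runif(n, dist$min, dist$max),
              exponential = stats::rexp(n, dist$rate),
              constant = rep(dist$value, n),
              stop("unknown gap distribution: ", dist$kind))
  if (any(g < 0)) stop("gap distribution produced negative gaps")
  g
}

.element_to_adtype <- c(C = "C", N = "N", O = "OA", S = "SA", H = "HD",
                        P = "P", F = "F")

# Constant head/tail of each PDBQT atom line; only coordinates vary between
# poses, so the templates are built once per ligand.
pdbqt_line_templates <- function(atoms) {
  ad <- .element_to_adtype[atoms$element]
  ad[is.na(ad)] <- atoms$element[is.na(ad)]
  name <- ifelse(nchar(atoms$name) < 4L, sprintf(" %-3s", atoms$name),
                 sprintf("%-4s", atoms$name))
  list(head = sprintf("ATOM  %5d %s %-4s%1s%4d    ", atoms$serial, name,
                      atoms$resid, atoms$chain, atoms$resno),
       tail = sprintf("%6.2f%6.2f    %6.3f %-2s", 1.0, 0.0, 0.0, ad))
}

format_pdbqt_atoms <- function(atoms, templates = pdbqt_line_templates(atoms)) {
  paste0(templates$head,
         sprintf("%8.3f%8.3f%8.3f", atoms$x, atoms$y, atoms$z),
         templates$tail)
}

# Place the rigid ligand so that its *nearest heavy atom* to the bead(s) of
# residue `resno` sits at exactly distance d, approaching along the ray from
# the receptor centroid through the residue, ligand body pointing outward.
# The outward offset solving the nearest-atom condition is found by
# root-bracketing (the minimum distance is monotone in the offset).
place_ligand_at <- function(lig, receptor, resno, d) {
  rat <- receptor$atom
  bead <- which(rat$resno == resno & rat$is_heavy)
  if (length(bead) == 0L) stop("receptor has no residue ", resno)
  res_xyz <- coords(rat[bead, , drop = FALSE])
  target <- colMeans(res_xyz)
  u <- target - colMeans(coords(receptor, heavy_only = TRUE))
  # approach perpendicular to the local chain direction so the planted
  # residue, not its sequence neighbours, is the nearest one
  prev <- which(rat$is_heavy & rat$resno == resno - 1L)
  nxt <- which(rat$is_heavy & rat$resno == resno + 1L)
  tangent <- if (length(prev) > 0L && length(nxt) > 0L) {
    colMeans(coords(rat[nxt, , drop = FALSE])) -
      colMeans(coords(rat[prev, , drop = FALSE]))
  } else if (length(prev) + length(nxt) > 0L) {
    colMeans(coords(rat[c(prev, nxt), , drop = FALSE])) - target
  } else NULL
  if (!is.null(tangent)) {
    tangent <- unit(tangent)
    u <- u - sum(u * tangent) * tangent
  }
  if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 0, 1)
  u <- unit(u)
  lxyz <- coords(lig$structure)
  centered <- sweep(lxyz, 2, lxyz[lig$anchor, ])
  body_dir <- unit(colMeans(centered[seq_len(lig$n_heavy), , drop = FALSE]))
  rotated <- centered %*% t(rotation_between(body_dir, u))
  heavy <- rotated[seq_len(lig$n_heavy), , drop = FALSE]
  min_dist_at <- function(t) {
    placed <- sweep(heavy, 2, target + t * u, "+")
    min(sqrt(pmax(outer(rowSums(placed^2), rowSums(res_xyz^2), "+") -
                    2 * placed %*% t(res_xyz), 0)))
  }
  t_star <- stats::uniroot(function(t) min_dist_at(t) - d,
                           lower = 0.05, upper = d + 4 * max(abs(rotated)),
                           tol = 1e-6)$root
  sweep(rotated, 2, target + t_star * u, "+")
}

# Proper rotation taking unit vector a to unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  a <- unit(a); b <- unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(p - sum(p * a) * a)
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Generate a Vina-dialect multi-pose result file for one receptor
#'
#' Writes `poses_per_run` MODEL blocks with affinities `affinity_top` plus
#' cumulative non-negative gaps (best-first rank order by construction). When
#' the spec plants contacts, pose 1 is placed by direct rigid placement so
#' the nearest ligand heavy atom to the planted residue lies inside the
#' stated distance band; placements that cannot satisfy all bands error out.
#' Remaining poses are placed at random around the receptor.
#'
#' @param receptor `ens_structure`.
#' @param spec [fixture_spec()].
#' @param ligand toy ligand from [make_toy_ligand()].
#' @return character vector of file lines (write with `writeLines()`).
#' @export
make_pose_set <- function(receptor, spec, ligand = make_toy_ligand()) {
  set.seed(spec$seed)
  n <- spec$poses_per_run
  affinities <- spec$affinity_top +
    cumsum(c(0, draw_gaps(spec$gap_distribution, n - 1L)))
  lat <- ligand$structure$atom
  templates <- pdbqt_line_templates(lat)
  lxyz0 <- coords(ligand$structure)
  lcen <- colMeans(lxyz0)
  rc <- colMeans(coords(receptor, heavy_only = TRUE))
  lines <- vector("list", n)
  for (p in seq_len(n)) {
    if (p == 1L && length(spec$planted_contacts) > 0L) {
      pc <- spec$planted_contacts[[1L]]
      d_target <- mean(pc$band)
      xyz <- place_ligand_at(ligand, receptor, pc$resno, d_target)
      for (pc_k in spec$planted_contacts) {
        bead <- receptor$atom$resno == pc_k$resno & receptor$atom$is_heavy
        lig_xyz <- xyz[seq_len(ligand$n_heavy), , drop = FALSE]
        res_xyz <- coords(receptor$atom[bead, , drop = FALSE])
        dmin <- min(sqrt(pmax(outer(rowSums(lig_xyz^2), rowSums(res_xyz^2),
                                    "+") - 2 * lig_xyz %*% t(res_xyz), 0)))
        if (!(dmin > pc_k$band[1] && dmin <= pc_k$band[2]))
          stop(sprintf(
            "cannot satisfy planted contact on residue %d: nearest heavy-atom distance %.2f outside (%.2f, %.2f]",
            pc_k$resno, dmin, pc_k$band[1], pc_k$band[2]))
      }
    } else {
      rot <- random_rotation()
      pos <- rc + stats::runif(1, 8, 15) * unit(stats::rnorm(3))
      xyz <- sweep(sweep(lxyz0, 2, lcen) %*% t(rot), 2, pos, "+")
    }
    at <- list(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    lines[[p]] <- c(sprintf("MODEL %d", p),
                    sprintf("REMARK VINA RESULT: %8.3f %10.3f %10.3f",
                            affinities[p], 0, 0),
                    "ROOT",
                    format_pdbqt_atoms(at, templates),
                    "ENDROOT", "TORSDOF 0", "ENDMDL")
  }
  unlist(lines)
}

#' Write one pose file per receptor into a results directory
#'
#' Files follow the `<receptor_label>__<ligand_label>.pdbqt` convention that
#' [assemble_runs()] reads back. Each receptor gets a seed derived from the
#' spec seed and its index, so the whole directory is deterministic.
#'
#' @param receptors list of `ens_structure`.
#' @param labels receptor labels (filenames derive from them).
#' @param ligand_label ligand code for the filename.
#' @param spec [fixture_spec()].
#' @param dir output directory.
#' @param ligand toy ligand.
#' @return invisible character vector of file paths.
#' @export
write_pose_files <- function(receptors, labels, ligand_label, spec, dir,
                             ligand = make_toy_ligand()) {
  stopifnot(length(receptors) == length(labels))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(receptors))
  for (i in seq_along(receptors)) {
    s <- spec
    s$seed <- derive_seed(spec$seed, i)
    paths[i] <- file.path(dir, paste0(labels[i], "__", ligand_label,
                                      ".pdbqt"))
    writeLines(make_pose_set(receptors[[i]], s, ligand), paths[i])
  }
  invisible(paths)
}

ring_structure_atoms <- function(xyz, names, elements, resid, resno, chain,
                                 serial_from = 1L) {
  data.frame(serial = serial_from + seq_len(nrow(xyz)) - 1L, name = names,
             element = elements, resid = resid, resno = resno, ins = " ",
             chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

phe_ring_fragment <- function(center = c(0, 0, 0), normal = c(0, 0, 1),
                              resno = 1L) {
  n <- unit(normal)
  e1 <- unit(if (abs(n[1]) < 0.9) c(1, 0, 0) - n[1] * n else c(0, 1, 0) - n[2] * n)
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  xyz <- hexagon(center, basis = cbind(e1, e2))
  ring_structure_atoms(xyz, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                       rep("C", 6), "PHE", resno, "A")
}

#' Build a minimal two-fragment fixture for one interaction kind
#'
#' Constructs atoms realising the kind's acceptance geometry exactly (e.g.
#' parallel rings at 3.5 A) plus a "negative twin" with exactly one threshold
#' violated, so its own classifier fires on the positive and nothing fires on
#' the negative.
#'
#' @param kind one of `"pi_pi_parallel"`, `"pi_pi_tshaped"`, `"xh_pi"`,
#'   `"lonepair_pi"`, `"hbond"`.
#' @return list with `kind`, `positive` and `negative`; each case carries the
#'   classifier inputs (`receptor`, `ligand` structures, plus kind-specific
#'   pieces: ring annotations, site annotations or atom coordinates).
#' @export
make_interaction_fixture <- function(kind = c("pi_pi_parallel",
                                              "pi_pi_tshaped", "xh_pi",
                                              "lonepair_pi", "hbond")) {
  kind <- match.arg(kind)
  receptor <- ens_structure(phe_ring_fragment(), "receptor_fragment")
  lig_ring <- function(center, normal) {
    xyz <- {
      n <- unit(normal)
      e1 <- unit(if (abs(n[1]) < 0.9) c(1, 0, 0) - n[1] * n
                 else c(0, 1, 0) - n[2] * n)
      e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
              n[1] * e1[2] - n[2] * e1[1])
      hexagon(center, basis = cbind(e1, e2))
    }
    ens_structure(ring_structure_atoms(xyz, paste0("C", 1:6), rep("C", 6),
                                       "LIG", 1L, "L"), "ligand_fragment")
  }
  case <- function(ligand, ...) c(list(receptor = receptor, ligand = ligand),
                                  list(...))
  out <- switch(kind,
    pi_pi_parallel = list(
      positive = case(lig_ring(c(0, 0, 3.5), c(0, 0, 1)), rings = list(1:6)),
      negative = case(lig_ring(c(0, 0, 6.0), c(0, 0, 1)), rings = list(1:6))),
    pi_pi_tshaped = list(
      positive = case(lig_ring(c(0, 0, 5.0), c(1, 0, 0)), rings = list(1:6)),
      negative = case(lig_ring(c(0, 0, 6.5), c(1, 0, 0)), rings = list(1:6))),
    xh_pi = {
      mk <- function(hz, cz) {
        lig <- ens_structure(ring_structure_atoms(
          rbind(c(0, 0, cz), c(0, 0, hz)), c("C1", "H1"), c("C", "H"),
          "LIG", 1L, "L"), "ligand_fragment")
        case(lig, x_idx = 1L, h_idx = 2L)
      }
      list(positive = mk(2.6, 3.69), negative = mk(3.5, 4.59))
    },
    lonepair_pi = {
      mk <- function(z) {
        lig <- ens_structure(ring_structure_atoms(
          matrix(c(0, 0, z), 1), "O1", "O", "LIG", 1L, "L"),
          "ligand_fragment")
        case(lig, a_idx = 1L)
      }
      list(positive = mk(3.0), negative = mk(4.5))
    },
    hbond = {
      donor <- ens_structure(ring_structure_atoms(
        rbind(c(0, 0, 0), c(0, 0, 1.0)), c("OG", "HG"), c("O", "H"),
        "SER", 1L, "A"), "receptor_fragment")
      mk <- function(z) {
        lig <- ens_structure(ring_structure_atoms(
          matrix(c(0, 0, z), 1), "O1", "O", "LIG", 1L, "L"),
          "ligand_fragment")
        list(receptor = donor, ligand = lig,
             sites_receptor = hbond_sites(data.frame(donor = 1L, h = 2L),
                                          integer(0)),
             sites_ligand = hbond_sites(NULL, 1L))
      }
      list(positive = mk(2.9), negative = mk(3.6))
    })
  c(list(kind = kind), out)
}

#' Generate a noisy trajectory with scripted events
#'
#' Each frame is the base structure plus isotropic Gaussian positional noise;
#' planted events override chosen atoms' positions frame by frame (e.g. an
#' acceptor toggling between hydrogen-bonding and distant positions).
#'
#' @param base `ens_structure`.
#' @param n_frames number of frames (>= 1).
#' @param noise_amplitude per-coordinate Gaussian sigma, Angstrom.
#' @param planted_events list of `list(atom =, frames =, on = c(x,y,z),
#'   off = c(x,y,z))`: the atom sits at `on` in the listed frames and at
#'   `off` otherwise (noise-free).
#' @param seed integer.
#' @return `ens_trajectory`.
#' @export
make_trajectory <- function(base, n_frames, noise_amplitude = 0,
                            planted_events = NULL, seed = 1L) {
  stopifnot(n_frames >= 1L)
  set.seed(seed)
  xyz0 <- coords(base)
  n <- nrow(xyz0)
  frames <- lapply(seq_len(n_frames), function(f) {
    x <- xyz0
    if (noise_amplitude > 0)
      x <- x + noise_amplitude * matrix(stats::rnorm(3 * n), n, 3)
    for (ev in planted_events)
      x[ev$atom, ] <- if (f %in% ev$frames) ev$on else ev$off
    x
  })
  ens_trajectory(base, frames)
}
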