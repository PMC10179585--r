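# Trajectory validation metrics: RMSD after optimal superposition, radius of
# gyration, Shrake-Rupley SASA, minimum-distance series, hydrogen-bond time
# series and end-to-end distance. Internally everything is in Angstrom;
# reported length series are in nm (the convention of MD reports), SASA in
# Angstrom^2.

#' A named metric series with summary statistics
#' @param name text.
#' @param values numeric vector.
#' @param unit text.
#' @return list of class `metric_series` with `mean` and `sd`.
#' @export
metric_series <- function(name, values, unit) {
  structure(list(name = name, values = values, unit = unit,
                 mean = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else 0),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series '%s': %d frames, mean %.4f %s (sd %.4f)>\n",
              x$name, length(x$values), x$mean, x$unit, x$sd))
  invisible(x)
}

#' RMSD time series relative to a reference frame
#'
#' Kabsch-superposed, mass-unweighted RMSD of each frame onto the reference.
#'
#' @param traj `ens_trajectory`.
#' @param reference frame index (default 1) or an n x 3 matrix.
#' @param selection optional atom mask.
#' @return `metric_series` in Angstrom.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL) {
  ref <- if (is.matrix(reference)) reference else traj$xyz[[reference]]
  vals <- vapply(traj$xyz, function(x) kabsch_rmsd(x, ref, selection),
                 numeric(1))
  metric_series("rmsd", vals, "A")
}

#' Radius of gyration
#'
#' sqrt(sum w_i |r_i - rbar|^2 / sum w_i), reported in nm.
#'
#' @param structure `ens_structure` (or n x 3 matrix with `mass_weighted =
#'   FALSE`).
#' @param mass_weighted weight by standard atomic masses.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(structure, mass_weighted = FALSE) {
  if (inherits(structure, "ens_structure")) {
    xyz <- coords(structure)
    w <- if (mass_weighted) element_masses(structure$atom$element)
    else rep(1, nrow(xyz))
  } else {
    xyz <- structure
    w <- rep(1, nrow(xyz))
  }
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w)) / 10
}

#' Radius-of-gyration time series
#' @param traj `ens_trajectory`.
#' @param mass_weighted weight by atomic masses.
#' @return `metric_series` in nm.
#' @export
rg_series <- function(traj, mass_weighted = FALSE) {
  w <- if (mass_weighted) element_masses(traj$template$atom$element)
  else rep(1, nrow(traj$template$atom))
  vals <- vapply(traj$xyz, function(xyz) {
    ctr <- colSums(xyz * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w)) / 10
  }, numeric(1))
  metric_series("rg", vals, "nm")
}

# Bondi-style van der Waals radii (Angstrom) used for SASA.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

# Deterministic near-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Each atom is inflated by the probe radius and sampled with a deterministic
#' golden-spiral point set; the accessible fraction is the share of points not
#' buried inside any neighbouring inflated sphere. Per-residue values sum
#' exactly to the total.
#'
#' @param structure `ens_structure`.
#' @param probe_radius probe radius, Angstrom (water = 1.4).
#' @param n_sphere_points sample points per atom (>= 60).
#' @param radii named per-element radius table, Angstrom.
#' @return list: `total` (A^2), `per_residue` (named numeric), `per_atom`.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960L,
                 radii = .vdw_radii) {
  stopifnot(n_sphere_points >= 60L)
  at <- structure$atom
  r <- radii[at$element]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(at$element[is.na(r)]), collapse = ", "))
  r <- unname(r) + probe_radius
  xyz <- coords(structure)
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  per_atom <- numeric(n)
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    neigh <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(neigh) > 0L) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in neigh) {
        if (!any(acc)) break
        dj <- rowSums(sweep(surf[acc, , drop = FALSE], 2, xyz[j, ])^2)
        acc[acc] <- dj >= r[j]^2
      }
      frac <- mean(acc)
    } else frac <- 1
    per_atom[i] <- frac * 4 * pi * r[i]^2
  }
  keys <- residue_keys(at)
  per_res <- vapply(split(per_atom, factor(keys, levels = unique(keys))),
                    sum, numeric(1))
  list(total = sum(per_atom), per_residue = per_res, per_atom = per_atom)
}

#' SASA time series
#' @param traj `ens_trajectory`.
#' @param ... passed to [sasa()].
#' @return `metric_series` in A^2.
#' @export
sasa_series <- function(traj, ...) {
  vals <- vapply(seq_len(n_frames(traj)),
                 function(i) sasa(frame(traj, i), ...)$total, numeric(1))
  metric_series("sasa", vals, "A^2")
}

#' Minimum-distance time series between two atom groups
#'
#' Per frame, the minimum heavy-atom pair distance between the groups,
#' reported in nm.
#'
#' @param traj `ens_trajectory`.
#' @param group_a,group_b integer or logical atom masks.
#' @return `metric_series` in nm.
#' @export
min_distance_series <- function(traj, group_a, group_b) {
  at <- traj$template$atom
  ia <- seq_len(nrow(at))[group_a]; ib <- seq_len(nrow(at))[group_b]
  ia <- ia[at$is_heavy[ia]]; ib <- ib[at$is_heavy[ib]]
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both groups must contain at least one heavy atom")
  vals <- vapply(traj$xyz, function(xyz) {
    a <- xyz[ia, , drop = FALSE]; b <- xyz[ib, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(max(min(d2), 0)) / 10
  }, numeric(1))
  metric_series("min_distance", vals, "nm")
}

#' Centroid-distance time series between two atom groups
#'
#' Alternative to [min_distance_series()]: distance between unweighted
#' heavy-atom centroids, in nm.
#'
#' @inheritParams min_distance_series
#' @return `metric_series` in nm.
#' @export
centroid_distance_series <- function(traj, group_a, group_b) {
  at <- traj$template$atom
  ia <- seq_len(nrow(at))[group_a]; ib <- seq_len(nrow(at))[group_b]
  ia <- ia[at$is_heavy[ia]]; ib <- ib[at$is_heavy[ib]]
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both groups must contain at least one heavy atom")
  vals <- vapply(traj$xyz, function(xyz) {
    sqrt(sum((colMeans(xyz[ia, , drop = FALSE]) -
                colMeans(xyz[ib, , drop = FALSE]))^2)) / 10
  }, numeric(1))
  metric_series("centroid_distance", vals, "nm")
}

#' Hydrogen-bond count time series between two atom subsets of a trajectory
#'
#' Runs [detect_hbonds()] on every frame between the two index sets and
#' returns the per-frame count plus the per-residue average number of bonds
#' (aggregated over frames by the residue of the peptide-side atom).
#'
#' @param traj `ens_trajectory`.
#' @param mask_a,mask_b integer atom masks for the two molecules (e.g.
#'   peptide and ligand). Solvent modes simply take the solvent atom indices;
#'   a trajectory without solvent atoms cannot produce them.
#' @param sites_a,sites_b `hbond_sites` with indices *local* to each mask.
#' @param criteria `interaction_criteria`.
#' @param distance_only skip the angle criterion.
#' @return list: `series` (`metric_series`, count per frame) and
#'   `per_residue` (named mean bonds per frame, keyed by molecule-a residue).
#' @export
hbond_series <- function(traj, mask_a, mask_b, sites_a, sites_b,
                         criteria = interaction_criteria(),
                         distance_only = FALSE) {
  at <- traj$template$atom
  ia <- seq_len(nrow(at))[mask_a]; ib <- seq_len(nrow(at))[mask_b]
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both molecule masks must be non-empty")
  res_a <- residue_keys(at[ia, , drop = FALSE])
  tally <- stats::setNames(numeric(length(unique(res_a))), unique(res_a))
  counts <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$xyz[[f]]
    sa <- ens_structure(transform(at[ia, , drop = FALSE],
                                  x = xyz[ia, 1], y = xyz[ia, 2],
                                  z = xyz[ia, 3]), "a")
    sb <- ens_structure(transform(at[ib, , drop = FALSE],
                                  x = xyz[ib, 1], y = xyz[ib, 2],
                                  z = xyz[ib, 3]), "b")
    hb <- detect_hbonds(sa, sb, sites_a, sites_b, criteria, distance_only)
    counts[f] <- nrow(hb)
    if (nrow(hb) > 0L) {
      a_side <- ifelse(hb$donor_mol == "a", hb$donor_idx, hb$acceptor_idx)
      for (k in res_a[a_side]) tally[k] <- tally[k] + 1
    }
  }
  list(series = metric_series("hbonds", counts, "count"),
       per_residue = tally / n_frames(traj))
}

#' End-to-end distance time series
#'
#' Per-frame distance between the anchor atoms of the first and last residue
#' (default anchor: the alpha-carbon bead "CA"), in nm.
#'
#' @param traj `ens_trajectory`.
#' @param anchor atom name used at both termini.
#' @return `metric_series` in nm.
#' @export
end_to_end_series <- function(traj, anchor = "CA") {
  at <- traj$template$atom
  first_res <- at$resno == min(at$resno)
  last_res <- at$resno == max(at$resno)
  i1 <- which(first_res & at$name == anchor)[1L]
  i2 <- which(last_res & at$name == anchor)[1L]
  if (is.na(i1) || is.na(i2))
    stop("anchor atom '", anchor, "' missing from a terminal residue")
  vals <- vapply(traj$xyz,
                 function(xyz) sqrt(sum((xyz[i1, ] - xyz[i2, ])^2)) / 10,
                 numeric(1))
  metric_series("end_to_end", vals, "nm")
}
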