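# Per-residue ensemble contact statistics: a residue is a binding residue of
# a complex when at least one of its heavy atoms lies within the distance
# cutoff (inclusive) of any ligand heavy atom. Counts are aggregated over all
# selected complexes at several nested cutoffs.

# Cell-list (uniform-grid) nearest-neighbour search: for each row of `a`,
# the minimum distance to any row of `b`, computed exactly for distances
# <= cutoff; pairs farther than the cutoff are reported as Inf. Linear-time
# alternative to a KD-tree, equivalent for fixed-radius queries.
grid_min_dist <- function(a, b, cutoff) {
  stopifnot(cutoff > 0)
  origin <- pmin(apply(a, 2, min), apply(b, 2, min))
  keyize <- function(m) {
    cells <- floor(sweep(m, 2, origin) / cutoff)
    list(cells = cells,
         key = paste(cells[, 1], cells[, 2], cells[, 3], sep = ","))
  }
  kb <- keyize(b)
  buckets <- split(seq_len(nrow(b)), kb$key)
  ka <- keyize(a)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- rep(Inf, nrow(a))
  for (i in seq_len(nrow(a))) {
    neigh_keys <- paste(ka$cells[i, 1] + offsets[, 1],
                        ka$cells[i, 2] + offsets[, 2],
                        ka$cells[i, 3] + offsets[, 3], sep = ",")
    cand <- unlist(buckets[neigh_keys], use.names = FALSE)
    if (length(cand) == 0L) next
    d2 <- (b[cand, 1] - a[i, 1])^2 + (b[cand, 2] - a[i, 2])^2 +
      (b[cand, 3] - a[i, 3])^2
    m <- sqrt(min(d2))
    if (m <= cutoff) out[i] <- m
  }
  out
}

# Per-residue minimum heavy-atom distance from a receptor to a ligand atom
# set; distances beyond `cutoff` come back as Inf.
residue_min_dist <- function(receptor, ligand_atoms, cutoff) {
  rat <- receptor$atom[receptor$atom$is_heavy, , drop = FALSE]
  lat <- ligand_atoms[ligand_atoms$is_heavy, , drop = FALSE]
  if (nrow(rat) == 0L || nrow(lat) == 0L)
    stop("contact analysis needs heavy atoms on both sides")
  dmin <- grid_min_dist(coords(rat), coords(lat), cutoff)
  keys <- residue_keys(rat)
  vapply(split(dmin, factor(keys, levels = unique(keys))), min, numeric(1))
}

#' Binding residues of one receptor/pose complex
#'
#' A residue qualifies when the minimum heavy-atom pair distance between the
#' residue and the ligand is less than or equal to the cutoff; hydrogens are
#' ignored on both sides.
#'
#' @param receptor `ens_structure`.
#' @param pose a pose block from [read_vina_pdbqt()] (or any object with an
#'   `atoms` data.frame), or an `ens_structure` holding the ligand.
#' @param cutoff distance cutoff, Angstrom (> 0).
#' @return character vector of residue keys (e.g. "TYR10"), in receptor
#'   sequence order.
#' @export
binding_residues <- function(receptor, pose, cutoff) {
  stopifnot(cutoff > 0)
  lat <- if (inherits(pose, "ens_structure")) pose$atom else pose$atoms
  dmin <- residue_min_dist(receptor, lat, cutoff)
  names(dmin)[dmin <= cutoff]
}

#' Per-residue contact table over selected complexes
#'
#' For each residue and each distance cutoff, the number of selected
#' complexes in which the residue is a binding residue (default, one count
#' per complex) or the number of heavy-atom contact pairs summed over
#' complexes (`mode = "atom_pairs"`). Rows cover every residue of the
#' receptor sequence, zero-filled.
#'
#' @param selected data.frame from [select_all_poses()] (columns
#'   `receptor_label`, `pose_rank`).
#' @param structures named list of `ens_structure`, indexed by receptor
#'   label.
#' @param runs `docking_runs` supplying the pose coordinates, indexed by
#'   receptor label.
#' @param cutoffs ascending distance cutoffs, Angstrom (default the five
#'   standard contact cutoffs 3.0-5.0).
#' @param mode `"complexes"` or `"atom_pairs"`.
#' @return integer matrix of class `contact_table` (residues x cutoffs) with
#'   attributes `n_complexes` and `mode`.
#' @export
build_contact_table <- function(selected, structures, runs,
                                cutoffs = c(3.0, 3.5, 4.0, 4.5, 5.0),
                                mode = c("complexes", "atom_pairs")) {
  mode <- match.arg(mode)
  stopifnot(nrow(selected) >= 1L, !is.unsorted(cutoffs))
  run_index <- stats::setNames(seq_along(runs),
                               vapply(runs, `[[`, character(1),
                                      "receptor_label"))
  first <- structures[[selected$receptor_label[1L]]]
  if (is.null(first)) stop("no structure for receptor ",
                           selected$receptor_label[1L])
  res_levels <- unique(residue_keys(first$atom[first$atom$is_heavy, ]))
  tab <- matrix(0L, nrow = length(res_levels), ncol = length(cutoffs),
                dimnames = list(res_levels, format(cutoffs)))
  cmax <- max(cutoffs)
  for (i in seq_len(nrow(selected))) {
    lab <- selected$receptor_label[i]
    receptor <- structures[[lab]]
    if (is.null(receptor))
      stop("no structure for receptor ", lab, " (complex row ", i, ")")
    ri <- run_index[[lab]]
    if (is.null(ri) || is.na(ri))
      stop("no docking run for receptor ", lab, " (complex row ", i, ")")
    pose <- runs[[ri]]$poses[[selected$pose_rank[i]]]
    if (mode == "complexes") {
      dmin <- residue_min_dist(receptor, pose$atoms, cmax)
      hit <- match(names(dmin), res_levels)
      for (k in seq_along(cutoffs))
        tab[hit[dmin <= cutoffs[k]], k] <- tab[hit[dmin <= cutoffs[k]], k] + 1L
    } else {
      rat <- receptor$atom[receptor$atom$is_heavy, , drop = FALSE]
      lat <- pose$atoms[pose$atoms$is_heavy, , drop = FALSE]
      d <- sqrt(pmax(outer(rowSums(coords(rat)^2), rowSums(coords(lat)^2),
                           "+") - 2 * coords(rat) %*% t(coords(lat)), 0))
      keys <- factor(residue_keys(rat), levels = res_levels)
      for (k in seq_along(cutoffs)) {
        counts <- rowsum(rowSums(d <= cutoffs[k]), keys)
        tab[rownames(counts), k] <- tab[rownames(counts), k] +
          as.integer(counts)
      }
    }
  }
  structure(tab, class = c("contact_table", class(tab)),
            n_complexes = nrow(selected), mode = mode, cutoffs = cutoffs)
}

#' Rank binding hot spots at one cutoff
#'
#' Residues sorted by contact count (descending, ties broken by residue
#' number ascending), plus the aggregate share of all contacts falling in a
#' residue-number window (0/0 defined as 0).
#'
#' @param table `contact_table`.
#' @param cutoff one of the table's cutoffs.
#' @param window inclusive residue-number range, e.g. `c(10, 20)`.
#' @param top_k number of top residues to report.
#' @return list of class `hotspot_report`: `ranking` (data.frame residue /
#'   resno / count), `window`, `window_share`, `top` (character).
#' @export
rank_hotspots <- function(table, cutoff, window = c(10, 20), top_k = 10L) {
  col <- match(TRUE, abs(attr(table, "cutoffs") - cutoff) < 1e-9)
  if (is.na(col))
    stop("cutoff ", cutoff, " is not a column of the contact table (",
         paste(colnames(table), collapse = ", "), ")")
  counts <- table[, col]
  resno <- as.integer(gsub("[^0-9-]", "", rownames(table)))
  ord <- order(-counts, resno)
  ranking <- data.frame(residue = rownames(table)[ord], resno = resno[ord],
                        count = as.integer(counts[ord]),
                        stringsAsFactors = FALSE)
  total <- sum(counts)
  in_window <- resno >= window[1] & resno <= window[2]
  share <- if (total == 0) 0 else sum(counts[in_window]) / total
  top <- ranking$residue[ranking$count > 0]
  structure(list(ranking = ranking, window = window, window_share = share,
                 top = utils::head(top, top_k)),
            class = "hotspot_report")
}

#' @export
print.hotspot_report <- function(x, ...) {
  cat(sprintf("<hotspot_report: top %s; residues %d-%d share %.3f>\n",
              paste(utils::head(x$top, 3), collapse = ","),
              x$window[1], x$window[2], x$window_share))
  invisible(x)
}
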