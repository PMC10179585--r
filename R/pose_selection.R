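# Selection of near-optimal docking poses by the binding free-energy
# difference (ddG) rule: within each docking run, keep the top-ranked pose
# plus every lower-ranked pose whose affinity lies within a cutoff of the top
# pose. ddG is stored as the magnitude |dG_top - dG_pose| (>= 0, 0 for the
# top pose); comparisons against the cutoff are inclusive.

#' Select poses of one docking run by the ddG cutoff
#'
#' @param run one docking-run record (`receptor_label`, `ligand_label`,
#'   `poses`).
#' @param cutoff ddG cutoff, kcal/mol (>= 0).
#' @return data.frame of selected complexes, one row per pose, in rank order:
#'   `receptor_label`, `ligand_label`, `pose_rank`, `affinity`,
#'   `delta_delta_g`.
#' @export
select_poses <- function(run, cutoff) {
  if (cutoff < 0) stop("ddG cutoff must be non-negative")
  if (length(run$poses) == 0L) stop("docking run has no poses")
  aff <- vapply(run$poses, `[[`, numeric(1), "affinity")
  rank <- vapply(run$poses, `[[`, integer(1), "pose_rank")
  ddg <- abs(aff - aff[1L])
  keep <- c(TRUE, ddg[-1L] <= cutoff)
  data.frame(receptor_label = run$receptor_label,
             ligand_label = run$ligand_label,
             pose_rank = rank[keep],
             affinity = aff[keep],
             delta_delta_g = ddg[keep],
             stringsAsFactors = FALSE)
}

#' Select poses across all runs at one cutoff
#'
#' @param runs `docking_runs` (or plain list of run records).
#' @param cutoff ddG cutoff, kcal/mol.
#' @return data.frame of all selected complexes (rbind of per-run selections).
#' @export
select_all_poses <- function(runs, cutoff) {
  if (length(runs) == 0L) stop("no docking runs supplied")
  do.call(rbind, lapply(runs, select_poses, cutoff = cutoff))
}

#' Selected-set accounting across ddG cutoffs
#'
#' One row per cutoff, labelled "set-1", "set-2", ... in cutoff order:
#' `n_top` (one per run), `n_lower` (lower-ranked poses within the cutoff),
#' `n_total = n_top + n_lower`, which is non-decreasing in the cutoff.
#'
#' @param runs `docking_runs`.
#' @param cutoffs ascending ddG cutoffs, kcal/mol (default 0.1, 0.2, 0.3).
#' @return data.frame of class `selection_summary`.
#' @export
summarize_selection <- function(runs, cutoffs = c(0.1, 0.2, 0.3)) {
  if (length(runs) == 0L) stop("no docking runs supplied")
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly ascending")
  out <- lapply(seq_along(cutoffs), function(i) {
    sel <- select_all_poses(runs, cutoffs[i])
    n_top <- sum(sel$pose_rank == 1L)
    data.frame(set = sprintf("set-%d", i), cutoff = cutoffs[i],
               n_top = n_top, n_lower = nrow(sel) - n_top,
               n_total = nrow(sel), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("selection_summary", "data.frame")
  res
}
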