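# Trajectory container: a fixed atom template plus per-frame coordinates.
# Storing one template and a list of coordinate matrices keeps multi-thousand
# frame runs cheap while still yielding a full structure for any frame.

#' Construct a trajectory
#'
#' @param template `ens_structure` giving the atom table shared by all frames.
#' @param xyz list of n x 3 coordinate matrices (one per frame), or a single
#'   matrix for a one-frame trajectory.
#' @param frame_interval spacing between frames, arbitrary time unit.
#' @return object of class `ens_trajectory`.
#' @export
ens_trajectory <- function(template, xyz, frame_interval = 1) {
  stopifnot(inherits(template, "ens_structure"))
  if (is.matrix(xyz)) xyz <- list(xyz)
  stopifnot(length(xyz) >= 1L)
  n <- nrow(template$atom)
  ok <- vapply(xyz, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3L,
               logical(1))
  if (!all(ok)) stop("all frames must be ", n, " x 3 coordinate matrices")
  structure(list(template = template, xyz = xyz,
                 frame_interval = frame_interval),
            class = "ens_trajectory")
}

#' Build a trajectory from a list of structures with identical atom tables
#' @param structures list of `ens_structure`.
#' @param frame_interval spacing between frames.
#' @export
as_trajectory <- function(structures, frame_interval = 1) {
  stopifnot(length(structures) >= 1L)
  ens_trajectory(structures[[1L]], lapply(structures, coords),
                 frame_interval = frame_interval)
}

#' Number of frames in a trajectory
#' @param traj `ens_trajectory`.
#' @export
n_frames <- function(traj) length(traj$xyz)

#' Extract one frame as a structure
#' @param traj `ens_trajectory`.
#' @param i frame index.
#' @export
frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  set_coords(traj$template, traj$xyz[[i]])
}

#' @export
print.ens_trajectory <- function(x, ...) {
  cat(sprintf("<ens_trajectory: %d frames x %d atoms>\n",
              n_frames(x), nrow(x$template$atom)))
  invisible(x)
}

#' Read a multi-model PDB file as a trajectory
#' @param path file path.
#' @param frame_interval spacing between frames.
#' @export
read_trajectory <- function(path, frame_interval = 1) {
  as_trajectory(read_pdb(path, model_policy = "all"),
                frame_interval = frame_interval)
}
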