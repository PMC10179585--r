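# Per-conformer docking search boxes and assembly of docking runs from
# Vina-dialect result files. Running a docking engine is out of scope; an
# external command hook with placeholder substitution is provided instead.

#' Build a docking search box around a receptor conformer
#'
#' Axis-aligned rectangular box centred at the receptor centroid, sized so
#' that every extent atom has at least `margin` Angstrom of clearance to every
#' face: per axis, half-edge = max |coord - center| + margin.
#'
#' @param receptor `ens_structure`.
#' @param margin minimum atom-to-face distance, Angstrom (default 12).
#' @param heavy_only use heavy atoms for the centroid and extents (default);
#'   set FALSE to include hydrogens.
#' @param mass_weighted weight the centroid by standard atomic masses instead
#'   of the unweighted centroid.
#' @return list of class `search_box`: `center`, `size` (full edge lengths).
#' @export
build_search_box <- function(receptor, margin = 12, heavy_only = TRUE,
                             mass_weighted = FALSE) {
  stopifnot(margin > 0)
  xyz <- coords(receptor, heavy_only = heavy_only)
  if (nrow(xyz) == 0L) stop("receptor has no heavy atoms")
  if (mass_weighted) {
    w <- element_masses(
      (if (heavy_only) receptor$atom[receptor$atom$is_heavy, ] else
        receptor$atom)$element)
    center <- colSums(xyz * w) / sum(w)
  } else {
    center <- colMeans(xyz)
  }
  half <- apply(abs(sweep(xyz, 2, center)), 2, max) + margin
  structure(list(center = as.numeric(center), size = as.numeric(2 * half)),
            class = "search_box")
}

element_masses <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904)
  out <- m[element]
  out[is.na(out)] <- 12.011  # unknown elements treated as carbon-mass
  unname(out)
}

#' Assemble docking runs from a directory of Vina result files
#'
#' One result file per (receptor, ligand) named
#' `<receptor_label>__<ligand_label>.pdbqt`. Runs whose affinities are out of
#' best-first rank order are flagged (`affinity_ordered = FALSE`), never
#' silently reordered.
#'
#' @param result_dir directory of `.pdbqt` files.
#' @param receptor_labels character vector (e.g. the library manifest's
#'   `receptor_label` column).
#' @param ligand_label single ligand code used in the filenames.
#' @return list of class `docking_runs`; each element has `receptor_label`,
#'   `ligand_label`, `poses`, `affinity_ordered`. Attribute `"n_poses"` holds
#'   the total pose count; [validate_runs()] summarises the flags.
#' @export
assemble_runs <- function(result_dir, receptor_labels, ligand_label) {
  if (anyDuplicated(receptor_labels))
    stop("duplicate receptor labels in manifest: ",
         paste(unique(receptor_labels[duplicated(receptor_labels)]),
               collapse = ", "))
  files <- file.path(result_dir,
                     paste0(receptor_labels, "__", ligand_label, ".pdbqt"))
  missing <- !file.exists(files)
  if (any(missing))
    stop("missing result files for: ",
         paste(utils::head(receptor_labels[missing], 10), collapse = ", "),
         if (sum(missing) > 10) sprintf(" (and %d more)", sum(missing) - 10))
  runs <- vector("list", length(files))
  total <- 0L
  for (i in seq_along(files)) {
    poses <- read_vina_pdbqt(files[i])
    aff <- vapply(poses, `[[`, numeric(1), "affinity")
    runs[[i]] <- list(receptor_label = receptor_labels[i],
                      ligand_label = ligand_label,
                      poses = poses,
                      affinity_ordered = !is.unsorted(aff))
    total <- total + length(poses)
  }
  structure(runs, class = "docking_runs", n_poses = total)
}

#' Total number of poses across runs
#' @param runs `docking_runs`.
#' @export
n_poses <- function(runs) {
  sum(vapply(runs, function(r) length(r$poses), integer(1)))
}

#' Validation report for assembled runs
#' @param runs `docking_runs`.
#' @return data.frame: receptor label, pose count, affinity-ordered flag.
#' @export
validate_runs <- function(runs) {
  data.frame(
    receptor_label = vapply(runs, `[[`, character(1), "receptor_label"),
    n_poses = vapply(runs, function(r) length(r$poses), integer(1)),
    affinity_ordered = vapply(runs, `[[`, logical(1), "affinity_ordered"),
    stringsAsFactors = FALSE)
}

#' Invoke an external docking engine through a command template
#'
#' Substitutes `{receptor}`, `{ligand}`, `{cx}` `{cy}` `{cz}`, `{sx}` `{sy}`
#' `{sz}` and `{out}` into the template, runs it through the shell and returns
#' the output path. The output is only checked for existence; parsing is
#' [read_vina_pdbqt()]'s job.
#'
#' @param receptor `ens_structure` (written to a temporary PDB).
#' @param ligand_path path to the ligand input file handed to the engine.
#' @param box `search_box`.
#' @param command_template shell command with all placeholders present.
#' @param out_path where the engine must write its result.
#' @return `out_path`, invisibly checked to exist.
#' @export
external_dock_hook <- function(receptor, ligand_path, box, command_template,
                               out_path = tempfile(fileext = ".pdbqt")) {
  required <- c("{receptor}", "{ligand}", "{cx}", "{cy}", "{cz}",
                "{sx}", "{sy}", "{sz}", "{out}")
  absent <- required[!vapply(required, grepl, logical(1),
                             x = command_template, fixed = TRUE)]
  if (length(absent) > 0L)
    stop("command template missing placeholders: ",
         paste(absent, collapse = ", "))
  receptor_path <- tempfile(fileext = ".pdb")
  write_pdb(receptor, receptor_path)
  subs <- c("{receptor}" = receptor_path, "{ligand}" = ligand_path,
            "{cx}" = format(box$center[1]), "{cy}" = format(box$center[2]),
            "{cz}" = format(box$center[3]),
            "{sx}" = format(box$size[1]), "{sy}" = format(box$size[2]),
            "{sz}" = format(box$size[3]), "{out}" = out_path)
  cmd <- command_template
  for (k in names(subs)) cmd <- gsub(k, subs[[k]], cmd, fixed = TRUE)
  status <- suppressWarnings(system2("sh", c("-c", shQuote(cmd)),
                                     stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0L)
    stop("docking command failed (exit ", code, "): ",
         paste(status, collapse = "\n"))
  if (!file.exists(out_path))
    stop("docking command exited cleanly but produced no output at ", out_path)
  out_path
}
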