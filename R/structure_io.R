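#' @keywords internal
"_PACKAGE"

# Two-letter element symbols we are willing to infer from atom names.
.two_letter_elements <- c("CL", "BR", "FE", "ZN", "MG", "NA", "MN", "CU", "SE", "CA")

#' Construct a structure object
#'
#' A structure is one conformer or one trajectory frame: an ordered atom table
#' plus a text label. The atom table mirrors the fixed-column fields of a PDB
#' record (serial, name, element, residue name/number, insertion code, chain)
#' plus parsed Cartesian coordinates in Angstrom and a heavy-atom flag.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `resid`,
#'   `resno`, `ins`, `chain`, `x`, `y`, `z`.
#' @param label character scalar identifying the conformer/frame.
#' @return An object of class `ens_structure`.
#' @export
ens_structure <- function(atoms, label = "structure") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  need <- c("serial", "name", "element", "resid", "resno", "ins", "chain",
            "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols in atom table")
  atoms$is_heavy <- atoms$element != "H"
  structure(list(atom = atoms, label = label), class = "ens_structure")
}

#' @export
print.ens_structure <- function(x, ...) {
  cat(sprintf("<ens_structure '%s': %d atoms, %d residues>\n",
              x$label, nrow(x$atom), length(unique(residue_keys(x$atom)))))
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param x `ens_structure` or an atom data.frame.
#' @param heavy_only drop hydrogens first.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(x, heavy_only = FALSE) {
  at <- if (inherits(x, "ens_structure")) x$atom else x
  if (heavy_only) at <- at[at$is_heavy, , drop = FALSE]
  cbind(x = at$x, y = at$y, z = at$z)
}

#' Replace the coordinates of a structure
#' @param s `ens_structure`.
#' @param xyz n x 3 matrix matching the atom count.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "ens_structure"),
            nrow(xyz) == nrow(s$atom), ncol(xyz) == 3L)
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s
}

#' Residue identity keys (NAME+NUMBER, insertion code appended when present)
#' @param atoms atom data.frame.
#' @return character vector, e.g. "TYR10".
#' @export
residue_keys <- function(atoms) {
  paste0(atoms$resid, atoms$resno, ifelse(atoms$ins == " " | atoms$ins == "",
                                          "", atoms$ins))
}

# Infer element symbols from atom-name fields.
# Rule: strip digits and primes, take the leading letters; a two-letter symbol
# is used only when the raw 4-char name field starts in its first column
# (PDB convention for CL, BR, FE, ...) and the two letters are a known symbol;
# otherwise the first letter alone.
infer_element <- function(raw_name) {
  stripped <- gsub("[0-9' ]", "", raw_name)
  first_col_used <- substr(raw_name, 1L, 1L) != " "
  two <- toupper(substr(stripped, 1L, 2L))
  one <- toupper(substr(stripped, 1L, 1L))
  ifelse(first_col_used & two %in% .two_letter_elements & nchar(stripped) >= 2L,
         paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))),
         one)
}

# Shared fixed-column atom-record parser for PDB and PDBQT dialects.
# lines: candidate ATOM/HETATM lines; lineno: their 1-based file line numbers.
# drop_altloc: discard alternate locations other than blank/"A" (PDB policy;
# Vina output never carries altlocs, so the PDBQT path keeps rows 1:1).
parse_atom_records <- function(lines, lineno, dialect = c("pdb", "pdbqt"),
                               drop_altloc = TRUE) {
  dialect <- match.arg(dialect)
  short <- nchar(lines) < 54L
  if (any(short))
    stop(sprintf("malformed ATOM/HETATM record at line %d: line shorter than coordinate columns",
                 lineno[which(short)[1L]]))
  xs <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  bad <- !is.finite(xs) | !is.finite(ys) | !is.finite(zs)
  if (any(bad))
    stop(sprintf("malformed ATOM/HETATM record at line %d: non-numeric coordinates",
                 lineno[which(bad)[1L]]))
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  serial[!is.finite(serial)] <- seq_along(lines)[!is.finite(serial)]
  raw_name <- substr(lines, 13, 16)
  altloc <- substr(lines, 17, 17)
  resid <- trimws(substr(lines, 18, 21))   # col 21 tolerated for 4-char codes
  chain <- substr(lines, 22, 22)
  resno <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  if (any(!is.finite(resno)))
    stop(sprintf("malformed ATOM/HETATM record at line %d: non-numeric residue number",
                 lineno[which(!is.finite(resno))[1L]]))
  ins <- substr(lines, 27, 27)
  element <- trimws(substr(lines, 77, 78))
  if (dialect == "pdbqt") {
    # Vina writes the AutoDock atom type in cols 78-79; map it to an element.
    adtype <- trimws(substr(lines, 78, 79))
    element <- ifelse(nzchar(adtype), .adtype_to_element(adtype), "")
  }
  blank <- !nzchar(element)
  element[blank] <- infer_element(raw_name[blank])
  element <- paste0(toupper(substr(element, 1, 1)),
                    tolower(substr(element, 2, 2)))
  out <- data.frame(serial = serial, name = trimws(raw_name),
                    element = element, resid = resid, resno = resno,
                    ins = ins, chain = chain, x = xs, y = ys, z = zs,
                    stringsAsFactors = FALSE)
  if (drop_altloc) out[altloc %in% c(" ", "A", ""), , drop = FALSE] else out
}

# AutoDock atom types -> element symbols (Vina output dialect subset).
.adtype_to_element <- function(t) {
  map <- c(C = "C", A = "C", N = "N", NS = "N", OA = "O", OS = "O",
           O = "O", SA = "S", S = "S", HD = "H", HS = "H", H = "H", P = "P",
           F = "F", Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I")
  out <- unname(map[t])
  out[t == "NA"] <- "N"
  out[is.na(out)] <- ""
  out
}

#' Read a PDB file (single- or multi-model)
#'
#' Fixed-column PDB v3.3 parsing. Alternate locations other than blank or "A"
#' are dropped so heavy-atom sets are deterministic; insertion codes are kept
#' as part of residue identity. When the element columns are blank the element
#' is inferred from the atom-name leading characters (two-letter symbols only
#' when the name starts in the first name column).
#'
#' @param path file path.
#' @param model_policy `"first"` returns one structure; `"all"` returns a list
#'   of structures, one per MODEL block (a file with no MODEL records counts
#'   as one model).
#' @return `ens_structure` or list of them.
#' @export
read_pdb <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  model_starts <- grep("^MODEL", lines)
  model_ends <- grep("^ENDMDL", lines)
  base_label <- sub("\\.pdb$", "", basename(path))
  if (length(model_starts) == 0L) {
    s <- ens_structure(parse_atom_records(lines[is_atom], which(is_atom)),
                       label = base_label)
    return(if (model_policy == "first") s else list(s))
  }
  if (length(model_ends) < length(model_starts))
    model_ends <- c(model_ends, length(lines) + 1L)
  n_models <- if (model_policy == "first") 1L else length(model_starts)
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    idx <- which(is_atom & seq_along(lines) > model_starts[m] &
                   seq_along(lines) < model_ends[m])
    if (length(idx) == 0L) stop("MODEL block ", m, " has no atom records in ", path)
    out[[m]] <- ens_structure(parse_atom_records(lines[idx], idx),
                              label = sprintf("%s#%d", base_label, m))
  }
  if (model_policy == "first") out[[1L]] else out
}

format_atom_lines <- function(atoms) {
  name <- ifelse(nchar(atoms$name) < 4L & nchar(atoms$element) < 2L,
                 sprintf(" %-3s", atoms$name), sprintf("%-4s", atoms$name))
  sprintf("ATOM  %5d %s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, name, atoms$resid,
          ifelse(nzchar(atoms$chain), atoms$chain, " "),
          atoms$resno, ifelse(nzchar(atoms$ins), atoms$ins, " "),
          atoms$x, atoms$y, atoms$z, 1.0, 0.0,
          formatC(toupper(atoms$element), width = 2))
}

#' Write structures to a PDB file
#'
#' A single structure gives a plain PDB; a list gives a multi-model file with
#' MODEL/ENDMDL wrappers. Round-trips through [read_pdb()] preserve atom
#' counts, names, residue identity and coordinates to 3 decimals.
#'
#' @param x `ens_structure` or list of them.
#' @param path output path.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "ens_structure")) {
    out <- c(format_atom_lines(x$atom), "END")
  } else {
    stopifnot(is.list(x), length(x) >= 1L)
    out <- unlist(lapply(seq_along(x), function(m) {
      c(sprintf("MODEL     %4d", m), format_atom_lines(x[[m]]$atom), "ENDMDL")
    }))
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a Vina-dialect PDBQT multi-pose result file
#'
#' Supports the AutoDock Vina *output* dialect only: MODEL/ENDMDL blocks each
#' carrying a `REMARK VINA RESULT:` line whose first numeric field is the
#' binding affinity (kcal/mol), with ROOT/BRANCH/TORSDOF torsion-tree records
#' interleaved among the atom records. AutoDock grid-map and flexible-residue
#' files are rejected. Poses are returned in file order; rank 1 is the first
#' MODEL. Affinity ordering is not enforced here (validated downstream).
#'
#' @param path file path.
#' @return list of pose blocks, each `list(pose_rank, affinity, atoms)`.
#' @export
read_vina_pdbqt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^(BEGIN_RES|END_RES)", lines)))
    stop("AutoDock flexible-residue PDBQT dialect is not supported: ", path)
  if (any(grepl("^GRID_PARAMETER_FILE", lines)))
    stop("AutoDock grid-map file is not a Vina result file: ", path)
  model_starts <- which(startsWith(lines, "MODEL"))
  n_models <- length(model_starts)
  if (n_models == 0L)
    stop("no MODEL blocks in Vina result file: ", path)
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) < n_models)
    model_ends <- c(model_ends, length(lines) + 1L)
  # one vectorised pass: attribute remark/atom lines to their MODEL block
  vina_idx <- which(startsWith(lines, "REMARK VINA RESULT:"))
  vina_model <- findInterval(vina_idx, model_starts)
  first_remark <- match(seq_len(n_models), vina_model)
  if (anyNA(first_remark))
    stop(sprintf("MODEL %d in %s has no 'REMARK VINA RESULT:' line",
                 which(is.na(first_remark))[1L], path))
  affinities <- suppressWarnings(as.numeric(vapply(
    strsplit(trimws(sub("^REMARK VINA RESULT:", "",
                        lines[vina_idx[first_remark]])), "\\s+"),
    `[[`, character(1), 1L)))
  if (any(!is.finite(affinities)))
    stop(sprintf("non-numeric affinity in MODEL %d of %s",
                 which(!is.finite(affinities))[1L], path))
  atom_idx <- which(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))
  atom_model <- findInterval(atom_idx, model_starts)
  inside <- atom_model >= 1L & atom_idx < model_ends[pmax(atom_model, 1L)]
  atom_idx <- atom_idx[inside]; atom_model <- atom_model[inside]
  if (!all(seq_len(n_models) %in% atom_model))
    stop(sprintf("MODEL %d in %s has no atom records",
                 setdiff(seq_len(n_models), atom_model)[1L], path))
  atoms_all <- parse_atom_records(lines[atom_idx], atom_idx,
                                  dialect = "pdbqt", drop_altloc = FALSE)
  atoms_all$is_heavy <- atoms_all$element != "H"
  lapply(seq_len(n_models), function(m) {
    list(pose_rank = m, affinity = affinities[m],
         atoms = atoms_all[atom_model == m, , drop = FALSE])
  })
}
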