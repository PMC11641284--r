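#' Protein structure with a flat atom table
#'
#' A `structure3d` holds one conformation of a (single-chain) protein as a
#' flat atom table plus an `n_atoms x 3` coordinate matrix in Angstroms.
#' Residue numbering follows the mature-sequence convention (1-based), so a
#' focal residue quoted as "residue 63" is row group `resno == 63`.
#'
#' @param atoms data.frame with columns `serial` (integer), `name` (PDB atom
#'   name, e.g. "CA", "OD2", "HG1"), `elem` (element symbol), `resno`
#'   (1-based residue index), `resname` (3-letter residue code).
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param label free-text label (e.g. "WT", "E6K/T63A").
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, coords, label = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("serial", "name", "elem", "resno", "resname")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L) {
    stop("coords must be an n_atoms x 3 matrix (got ",
         nrow(coords), " x ", ncol(coords), " for ", nrow(atoms), " atoms)")
  }
  if (!all(is.finite(coords))) stop("coords contain non-finite values")
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  if (any(atoms$resno < 1L)) stop("residue indices must be >= 1")
  if (is.unsorted(atoms$resno)) {
    stop("atoms must be grouped by strictly increasing residue index")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  out <- list(atoms = atoms, coords = coords, label = label)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat("<structure3d> ", if (nzchar(x$label)) paste0("'", x$label, "' ") else "",
      n_residues(x), " residues, ", nrow(x$atoms), " atoms",
      if (has_hydrogens(x)) " (protonated)" else " (no hydrogens)", "\n", sep = "")
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `structure3d`.
#' @return integer count of distinct residue indices.
#' @export
n_residues <- function(s) length(unique(s$atoms$resno))

#' Residue indices present in a structure
#' @param s a `structure3d`.
#' @return sorted integer vector of residue indices.
#' @export
residue_indices <- function(s) sort(unique(s$atoms$resno))

#' Does the structure carry hydrogens?
#'
#' Hydrogen-bond analysis needs protonated input; loaders flag structures
#' without any hydrogen so that stage can fail fast.
#'
#' @param s a `structure3d`.
#' @return logical scalar.
#' @export
has_hydrogens <- function(s) any(is_hydrogen(s$atoms$name, s$atoms$elem))

# Hydrogen test from element symbol, falling back to the PDB name convention
# (leading digits allowed, as in "1HH1").
is_hydrogen <- function(name, elem) {
  e <- toupper(trimws(elem))
  known <- nzchar(e)
  out <- e == "H"
  fallback <- grepl("^[0-9]*H", toupper(trimws(name)))
  out[!known] <- fallback[!known]
  out
}

#' Locate atoms by residue and atom name
#'
#' @param s a `structure3d`.
#' @param resno residue index (scalar) or NULL for all residues.
#' @param name atom name (scalar or vector) or NULL for all atoms.
#' @return integer vector of atom row indices.
#' @export
atom_index <- function(s, resno = NULL, name = NULL) {
  keep <- rep(TRUE, nrow(s$atoms))
  if (!is.null(resno)) keep <- keep & s$atoms$resno %in% resno
  if (!is.null(name)) keep <- keep & s$atoms$name %in% name
  which(keep)
}

# Indices of one named atom per residue, erroring on residues that lack it.
one_atom_per_residue <- function(s, name, what = name) {
  res <- residue_indices(s)
  idx <- integer(length(res))
  for (k in seq_along(res)) {
    i <- which(s$atoms$resno == res[k] & s$atoms$name == name)
    if (length(i) == 0L) {
      stop("residue ", res[k], " (", s$atoms$resname[match(res[k], s$atoms$resno)],
           ") lacks a ", what, " atom")
    }
    idx[k] <- i[1L]
  }
  idx
}

#' Trajectory: ordered frames sharing one topology
#'
#' @param topology a `structure3d`; its coordinates are conventionally the
#'   first frame but are not consulted by analyses.
#' @param xyz numeric array `n_atoms x 3 x n_frames`.
#' @param frame_spacing optional time between frames (arbitrary units).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, xyz, frame_spacing = NULL) {
  stopifnot(inherits(topology, "structure3d"))
  xyz <- unclass(xyz)
  if (length(dim(xyz)) != 3L) stop("xyz must be an n_atoms x 3 x n_frames array")
  if (dim(xyz)[1] != nrow(topology$atoms) || dim(xyz)[2] != 3L) {
    stop("xyz dimensions (", paste(dim(xyz), collapse = " x "),
         ") do not match the topology's ", nrow(topology$atoms), " atoms")
  }
  if (dim(xyz)[3] < 1L) stop("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("xyz contains non-finite values")
  out <- list(topology = topology, xyz = xyz, frame_spacing = frame_spacing)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames of ", dim(x$xyz)[1], " atoms (",
      n_residues(x$topology), " residues)",
      if (nzchar(x$topology$label)) paste0(" [", x$topology$label, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' Extract one frame's coordinates
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index ", i, " out of range")
  traj$xyz[, , i, drop = TRUE]
}

#' Keep a subset of frames
#' @param traj a `trajectory`.
#' @param idx frame indices to keep, in order.
#' @return a `trajectory`.
#' @export
subset_frames <- function(traj, idx) {
  if (length(idx) < 1L) stop("cannot build an empty trajectory")
  trajectory(traj$topology, traj$xyz[, , idx, drop = FALSE], traj$frame_spacing)
}
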