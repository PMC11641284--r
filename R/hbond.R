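#' Geometric hydrogen-bond criterion
#'
#' A donor-H-acceptor triplet counts as bonded in a frame iff the donor
#' heavy-atom to acceptor heavy-atom distance is at most `dist_cutoff` AND the
#' donor-H-acceptor angle (vertex at the hydrogen) is at least `angle_cutoff`.
#' Defaults are the conventional trajectory-analysis cutoffs of 3.0 Angstrom
#' and 135 degrees. Boundary values equal to either cutoff are accepted; the
#' distance is heavy-atom to heavy-atom, not hydrogen to acceptor.
#'
#' @param dist_cutoff donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_cutoff donor-H-acceptor angle cutoff, degrees (<= 180).
#' @return object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(dist_cutoff = 3.0, angle_cutoff = 135) {
  if (!is.finite(dist_cutoff) || dist_cutoff <= 0) {
    stop("distance cutoff must be positive")
  }
  if (!is.finite(angle_cutoff) || angle_cutoff <= 0 || angle_cutoff > 180) {
    stop("angle cutoff must lie in (0, 180]")
  }
  out <- list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff)
  class(out) <- "hbond_criterion"
  out
}

#' Assign hydrogen-bond donors and acceptors from the topology
#'
#' Donors are (N or O heavy atom, covalently attached hydrogen) pairs: each
#' hydrogen is attached to the nearest same-residue N/O within 1.2 Angstrom
#' (PDB naming plus distance convention; carbon-bound hydrogens are excluded
#' because carbons never enter the donor list). Acceptors are all N and O
#' atoms.
#'
#' @param s a [structure3d()] with hydrogens.
#' @return list with `donors` (data.frame: `d_idx`, `h_idx`, `resno`) and
#'   `acceptors` (data.frame: `a_idx`, `resno`).
#' @export
assign_donors_acceptors <- function(s) {
  stopifnot(inherits(s, "structure3d"))
  hyd <- which(is_hydrogen(s$atoms$name, s$atoms$elem))
  if (length(hyd) == 0L) {
    stop("structure '", s$label, "' has no hydrogens: hydrogen-bond analysis ",
         "requires protonated input (add hydrogens before loading)")
  }
  heavy_no <- which(toupper(s$atoms$elem) %in% c("N", "O"))
  d_idx <- integer(0); h_idx <- integer(0)
  for (h in hyd) {
    cand <- heavy_no[s$atoms$resno[heavy_no] == s$atoms$resno[h]]
    if (length(cand) == 0L) next
    dd <- sqrt(rowSums(sweep(s$coords[cand, , drop = FALSE], 2L,
                             s$coords[h, ])^2))
    j <- which.min(dd)
    if (dd[j] < 1.2) {
      d_idx <- c(d_idx, cand[j])
      h_idx <- c(h_idx, h)
    }
  }
  list(
    donors = data.frame(d_idx = d_idx, h_idx = h_idx,
                        resno = s$atoms$resno[d_idx]),
    acceptors = data.frame(a_idx = heavy_no, resno = s$atoms$resno[heavy_no])
  )
}

#' Detect hydrogen bonds in one frame
#'
#' Vectorised evaluation of the geometric criterion over all donor x acceptor
#' pairs; intra-residue pairs are excluded, and one donor may bond several
#' acceptors in the same frame (no exclusivity).
#'
#' @param coords `n_atoms x 3` frame coordinates.
#' @param donors,acceptors as returned by [assign_donors_acceptors()].
#' @param criterion an [hbond_criterion()].
#' @return data.frame with columns `d_idx`, `h_idx`, `a_idx`.
#' @export
detect_hbonds_frame <- function(coords, donors, acceptors,
                                criterion = hbond_criterion()) {
  nd <- nrow(donors); na <- nrow(acceptors)
  if (nd == 0L || na == 0L) {
    return(data.frame(d_idx = integer(0), h_idx = integer(0),
                      a_idx = integer(0)))
  }
  D <- coords[donors$d_idx, , drop = FALSE]
  A <- coords[acceptors$a_idx, , drop = FALSE]
  # squared distance matrix donors x acceptors
  d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * tcrossprod(D, A)
  ok <- d2 <= criterion$dist_cutoff^2 + 1e-12
  ok <- ok & outer(donors$resno, acceptors$resno, "!=")
  ok <- ok & outer(donors$d_idx, acceptors$a_idx, "!=")
  hit <- which(ok, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(d_idx = integer(0), h_idx = integer(0),
                      a_idx = integer(0)))
  }
  di <- donors$d_idx[hit[, 1L]]
  hi <- donors$h_idx[hit[, 1L]]
  ai <- acceptors$a_idx[hit[, 2L]]
  v1 <- coords[di, , drop = FALSE] - coords[hi, , drop = FALSE]
  v2 <- coords[ai, , drop = FALSE] - coords[hi, , drop = FALSE]
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- !is.na(ang) & ang >= criterion$angle_cutoff - 1e-9
  data.frame(d_idx = di[keep], h_idx = hi[keep], a_idx = ai[keep])
}

#' Hydrogen-bond occupancy table over a trajectory
#'
#' One row per (donor, hydrogen, acceptor) identity detected in at least one
#' frame; occupancy is the percentage of frames in which the bond is present.
#' Rows are ordered by decreasing occupancy.
#'
#' @param traj a [trajectory()] whose topology carries hydrogens.
#' @param criterion an [hbond_criterion()].
#' @return data.frame with donor/hydrogen/acceptor residue numbers, residue
#'   names and atom names, `n_present`, `occupancy` (percent) and `label`
#'   (see [bond_label()]).
#' @export
occupancy_table <- function(traj, criterion = hbond_criterion()) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  da <- assign_donors_acceptors(topo)
  nf <- n_frames(traj)
  counts <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    hits <- detect_hbonds_frame(frame_coords(traj, f), da$donors, da$acceptors,
                                criterion)
    if (nrow(hits) == 0L) next
    keys <- paste(hits$d_idx, hits$h_idx, hits$a_idx)
    for (k in keys) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    out <- data.frame(
      donor_resno = integer(0), donor_resname = character(0),
      donor_name = character(0), h_name = character(0),
      acceptor_resno = integer(0), acceptor_resname = character(0),
      acceptor_name = character(0), n_present = integer(0),
      occupancy = numeric(0), label = character(0)
    )
    return(out)
  }
  idx <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  at <- topo$atoms
  out <- data.frame(
    donor_resno = at$resno[idx[, 1L]],
    donor_resname = at$resname[idx[, 1L]],
    donor_name = at$name[idx[, 1L]],
    h_name = at$name[idx[, 2L]],
    acceptor_resno = at$resno[idx[, 3L]],
    acceptor_resname = at$resname[idx[, 3L]],
    acceptor_name = at$name[idx[, 3L]],
    n_present = vapply(keys, function(k) counts[[k]], integer(1),
                       USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  out$occupancy <- 100 * out$n_present / nf
  out$label <- bond_label(out)
  out <- out[order(-out$occupancy, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conventional hydrogen bonds of the wild type
#'
#' Bonds whose wild-type occupancy is strictly greater than the threshold
#' (default 80 percent) are designated conventional; the mutants' versions of
#' these bonds are then tracked for relaxation.
#'
#' @param wildtype_records occupancy table from the wild-type trajectory.
#' @param threshold occupancy threshold, percent (strict `>`).
#' @return the qualifying rows, ordered by decreasing occupancy, with the
#'   threshold stored in attribute `threshold`.
#' @export
conventional_set <- function(wildtype_records, threshold = 80) {
  out <- wildtype_records[wildtype_records$occupancy > threshold, ,
                          drop = FALSE]
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

# Backbone atom names (amide and Calpha protons included).
BACKBONE_ATOMS <- c("N", "H", "H1", "H2", "H3", "CA", "HA", "HA2", "HA3",
                    "C", "O", "OXT")

#' Hydrogen bonds involving a focal residue
#'
#' Keeps records in which the donor, hydrogen or acceptor belongs to the
#' focal residue and flags whether the focal residue participates through its
#' backbone or side chain.
#'
#' @param records an occupancy table ([occupancy_table()]).
#' @param focal focal residue index.
#' @return the qualifying rows plus a `focal_backbone` logical column.
#' @export
focal_bonds <- function(records, focal) {
  keep <- records$donor_resno == focal | records$acceptor_resno == focal
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    out$focal_backbone <- logical(0)
    return(out)
  }
  focal_atom <- ifelse(out$donor_resno == focal,
                       ifelse(out$h_name %in% BACKBONE_ATOMS &
                                out$donor_name %in% BACKBONE_ATOMS,
                              "bb", "sc"),
                       ifelse(out$acceptor_name %in% BACKBONE_ATOMS, "bb", "sc"))
  out$focal_backbone <- focal_atom == "bb"
  rownames(out) <- NULL
  out
}

#' Display label for a hydrogen bond
#'
#' The acceptor-first display convention
#' `Xxx<acceptor_resno>@<acceptor_atom>-Yyy<donor_resno>@<hydrogen_atom>`,
#' e.g. `Ile99@O-Thr63@HG1`: an amino acid, a residue number, and the oxygen
#' (acceptor) or hydrogen (donor side) atom name. Parseable back with
#' [parse_bond_label()].
#'
#' @param rec one or more occupancy-table rows.
#' @return character vector of labels.
#' @export
bond_label <- function(rec) {
  paste0(title_case3(rec$acceptor_resname), rec$acceptor_resno, "@",
         rec$acceptor_name, "-",
         title_case3(rec$donor_resname), rec$donor_resno, "@", rec$h_name)
}

#' Parse a hydrogen-bond display label
#'
#' @param label labels as produced by [bond_label()].
#' @return data.frame with `acceptor_resname`, `acceptor_resno`,
#'   `acceptor_name`, `donor_resname`, `donor_resno`, `h_name`.
#' @export
parse_bond_label <- function(label) {
  m <- regmatches(label,
                  regexec("^([A-Za-z]{3})([0-9]+)@([^-]+)-([A-Za-z]{3})([0-9]+)@(.+)$",
                          label))
  bad <- vapply(m, length, integer(1)) != 7L
  if (any(bad)) stop("unparseable bond label: ", label[bad][1L])
  data.frame(
    acceptor_resname = toupper(vapply(m, `[`, "", 2L)),
    acceptor_resno = as.integer(vapply(m, `[`, "", 3L)),
    acceptor_name = vapply(m, `[`, "", 4L),
    donor_resname = toupper(vapply(m, `[`, "", 5L)),
    donor_resno = as.integer(vapply(m, `[`, "", 6L)),
    h_name = vapply(m, `[`, "", 7L),
    stringsAsFactors = FALSE
  )
}

title_case3 <- function(x) {
  x <- tolower(x)
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}
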