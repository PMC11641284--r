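#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' coordinate sets over a selection of atoms, by singular value decomposition
#' of the cross-covariance matrix with the usual reflection guard
#' (determinant +1).
#'
#' @param mobile,reference `n x 3` coordinate matrices with matched rows.
#' @param selection atom indices used for the fit (default: all rows). At
#'   least 3 non-collinear atoms are required.
#' @return list with `rotation` (3x3, proper), `translation` (length 3),
#'   `rmsd` (Angstrom, over the selection) such that the fitted mobile
#'   coordinates are `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) {
    stop("degenerate fit: need at least 3 selection atoms, got ",
         length(selection))
  }
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  cm <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cm); Qc <- sweep(Q, 2L, cq)
  if (coord_rank(Pc) < 2L || coord_rank(Qc) < 2L) {
    stop("degenerate fit: selection atoms are collinear")
  }
  H <- crossprod(Pc, Qc)                  # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.vector(cq - R %*% cm), rmsd = rmsd)
}

coord_rank <- function(X, tol = 1e-7) {
  s <- svd(X, nu = 0, nv = 0)$d
  sum(s > tol * max(s, 1))
}

#' Apply a rigid transform to coordinates
#' @param coords `n x 3` matrix.
#' @param fit result of [kabsch_superpose()] (or any list with `rotation`,
#'   `translation`).
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2L, fit$translation, "+")
}

# Calpha atom indices (one per residue), erroring on residues without one.
ca_indices <- function(topology) one_atom_per_residue(topology, "CA", "Calpha")

#' Per-frame Calpha RMSD against a reference frame
#'
#' Each frame is superposed onto the reference frame on Calpha atoms before
#' the RMSD is taken, so rigid-body motion does not register.
#'
#' @param traj a [trajectory()].
#' @param reference_frame frame index used as reference (default 1).
#' @return data.frame with columns `frame` and `rmsd` (Angstrom);
#'   `rmsd[reference_frame]` is 0 up to round-off.
#' @export
rmsd_series <- function(traj, reference_frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  ca <- ca_indices(traj$topology)
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(frame_coords(traj, f), ref, ca)$rmsd
  }, numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), rmsd = vals)
}

#' Equilibration window: discard early frames, take equidistant snapshots
#'
#' Drops the first `floor(discard_fraction * n_frames)` frames (the
#' unequilibrated head of the run) and returns `n_snapshots` equidistant
#' frames from the remainder. If fewer frames remain than requested, all of
#' them are returned with a warning. Defaults mirror the convention of
#' discarding the first 90 ns of a 150 ns run and keeping 1500 equidistant
#' snapshots of the last 60 ns.
#'
#' @param traj a [trajectory()].
#' @param discard_fraction fraction of leading frames to drop, in [0, 1).
#' @param n_snapshots number of equidistant frames to keep, >= 1.
#' @return a [trajectory()].
#' @export
equilibration_window <- function(traj, discard_fraction = 0.6,
                                 n_snapshots = 1500L) {
  stopifnot(inherits(traj, "trajectory"))
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("discard_fraction must lie in [0, 1)")
  }
  if (n_snapshots < 1L) stop("n_snapshots must be >= 1")
  nf <- n_frames(traj)
  drop <- floor(discard_fraction * nf)
  keep <- seq.int(drop + 1L, nf)
  m <- length(keep)
  if (m == 0L) stop("no frames remain after discarding")
  if (m <= n_snapshots) {
    if (m < n_snapshots) {
      warning("only ", m, " frames remain after discarding; requested ",
              n_snapshots, " snapshots - returning all remaining frames")
    }
    return(subset_frames(traj, keep))
  }
  idx <- keep[ceiling(seq_len(n_snapshots) * m / n_snapshots)]
  subset_frames(traj, idx)
}

#' Per-residue Calpha root-mean-square fluctuation
#'
#' Frames are superposed (Calpha) onto an iteratively refined mean structure
#' (two passes, starting from the first frame), then
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` is taken per Calpha.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @return data.frame with columns `resno`, `resname`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF is undefined for a single frame")
  ca <- ca_indices(traj$topology)
  frames_ca <- lapply(seq_len(nf), function(f) frame_coords(traj, f)[ca, , drop = FALSE])
  ref <- frames_ca[[1L]]
  fitted <- frames_ca
  for (pass in 1:2) {
    fitted <- lapply(frames_ca, function(m) {
      apply_transform(m, kabsch_superpose(m, ref))
    })
    ref <- Reduce(`+`, fitted) / nf
  }
  mean_sq <- Reduce(`+`, lapply(fitted, function(m) rowSums((m - ref)^2))) / nf
  res <- residue_indices(traj$topology)
  data.frame(
    resno = res,
    resname = traj$topology$atoms$resname[match(res, traj$topology$atoms$resno)],
    rmsf = sqrt(mean_sq)
  )
}

#' Focal-residue centre-of-geometry distance pattern
#'
#' For every residue j, the mean over frames of the Euclidean distance
#' between the focal residue's backbone centre of geometry and residue j's,
#' where the centre of geometry is the unweighted mean of the three backbone
#' atoms N, CA and C. Distances are internal coordinates, so no superposition
#' is applied (the pattern is invariant under rigid motion of whole frames).
#'
#' @param traj a [trajectory()]; every residue must have N, CA and C atoms.
#' @param focal focal residue index (mature-sequence numbering).
#' @return object of class `distance_pattern`: data.frame with columns
#'   `resno`, `resname`, `dist` (Angstrom), plus attribute `focal`.
#' @export
distance_pattern <- function(traj, focal) {
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  res <- residue_indices(topo)
  if (!focal %in% res) stop("focal residue ", focal, " is not in the topology")
  bb_idx <- cbind(one_atom_per_residue(topo, "N", "backbone N"),
                  one_atom_per_residue(topo, "CA", "backbone CA"),
                  one_atom_per_residue(topo, "C", "backbone C"))
  nf <- n_frames(traj)
  focal_row <- match(focal, res)
  acc <- numeric(length(res))
  for (f in seq_len(nf)) {
    fc <- frame_coords(traj, f)
    centroids <- (fc[bb_idx[, 1L], , drop = FALSE] +
                  fc[bb_idx[, 2L], , drop = FALSE] +
                  fc[bb_idx[, 3L], , drop = FALSE]) / 3
    d <- sweep(centroids, 2L, centroids[focal_row, ])
    acc <- acc + sqrt(rowSums(d^2))
  }
  out <- data.frame(
    resno = res,
    resname = topo$atoms$resname[match(res, topo$atoms$resno)],
    dist = acc / nf
  )
  attr(out, "focal") <- as.integer(focal)
  class(out) <- c("distance_pattern", "data.frame")
  out
}

#' Signed distance-pattern difference, mutant minus wild type
#'
#' @param mutant,wildtype [distance_pattern()] objects sharing the focal
#'   residue and residue set.
#' @return data.frame with columns `resno`, `resname`, `delta` (Angstrom,
#'   signed).
#' @export
pattern_difference <- function(mutant, wildtype) {
  stopifnot(inherits(mutant, "distance_pattern"),
            inherits(wildtype, "distance_pattern"))
  if (!identical(attr(mutant, "focal"), attr(wildtype, "focal"))) {
    stop("patterns have different focal residues (",
         attr(mutant, "focal"), " vs ", attr(wildtype, "focal"), ")")
  }
  if (!identical(mutant$resno, wildtype$resno)) {
    stop("patterns cover different residue sets")
  }
  data.frame(resno = mutant$resno, resname = mutant$resname,
             delta = mutant$dist - wildtype$dist)
}
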