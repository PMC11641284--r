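#' Planted rigid displacement of a residue range
#'
#' Emulates a conformational change: a constant displacement applied to every
#' atom of the residues in `range`, in every frame (a changed conformation,
#' not a transition).
#'
#' @param range inclusive residue-index range, `c(from, to)`.
#' @param displacement 3-vector, Angstrom.
#' @return object of class `planted_shift`.
#' @export
planted_shift <- function(range, displacement) {
  range <- as.integer(range)
  displacement <- as.numeric(displacement)
  stopifnot(length(range) == 2L, range[1] <= range[2],
            length(displacement) == 3L, all(is.finite(displacement)))
  out <- list(range = range, displacement = displacement)
  class(out) <- "planted_shift"
  out
}

#' Planted hydrogen bond with a target occupancy
#'
#' Describes a donor-H-acceptor triplet whose geometry is forced to
#' `formed` (distance/angle satisfying the detection criterion) in a chosen
#' fraction of frames and to `broken` (violating it) otherwise. Atoms are
#' addressed as (residue index, atom name).
#'
#' @param donor,hydrogen,acceptor `list(resno, name)` or `c(resno, name)`;
#'   donor and hydrogen must share a residue.
#' @param occupancy target occupancy p in [0, 1]; the bond is formed in
#'   exactly `round(p * n_frames)` frames.
#' @param formed named vector `c(dist = , angle = )`: donor-acceptor heavy-atom
#'   distance (Angstrom) and donor-H-acceptor angle (degrees) in formed frames.
#' @param broken same, for broken frames.
#' @param criterion the [hbond_criterion()] the geometries are validated
#'   against: `formed` must satisfy it, `broken` must violate it.
#' @return object of class `planted_hbond`.
#' @export
planted_hbond <- function(donor, hydrogen, acceptor, occupancy,
                          formed = c(dist = 2.8, angle = 165),
                          broken = c(dist = 5.0, angle = 90),
                          criterion = hbond_criterion()) {
  as_atom_ref <- function(x) {
    list(resno = as.integer(x[[1]]), name = as.character(x[[2]]))
  }
  donor <- as_atom_ref(donor); hydrogen <- as_atom_ref(hydrogen)
  acceptor <- as_atom_ref(acceptor)
  if (donor$resno != hydrogen$resno) {
    stop("donor and hydrogen must belong to the same residue")
  }
  if (!is.finite(occupancy) || occupancy < 0 || occupancy > 1) {
    stop("target occupancy must lie in [0, 1], got ", occupancy)
  }
  ok_formed <- formed[["dist"]] <= criterion$dist_cutoff &&
    formed[["angle"]] >= criterion$angle_cutoff
  if (!ok_formed) stop("'formed' geometry does not satisfy the H-bond criterion")
  ok_broken <- broken[["dist"]] > criterion$dist_cutoff ||
    broken[["angle"]] < criterion$angle_cutoff
  if (!ok_broken) stop("'broken' geometry satisfies the H-bond criterion")
  out <- list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
              occupancy = occupancy, formed = formed, broken = broken)
  class(out) <- "planted_hbond"
  out
}

#' Build a toy protein for synthetic trajectories
#'
#' An extended serine-like chain: per residue the backbone atoms N, H, CA, C,
#' O plus a polar side-chain donor pair (OG with attached HG, 0.98 Angstrom).
#' Residues are spaced so that no inter-residue pair satisfies the default
#' hydrogen-bond criterion in the base conformation — detected bonds on
#' noise-free synthetic trajectories are then exactly the planted ones. The
#' seed sets a deterministic side-chain rotation per residue.
#'
#' @param n_residues chain length, >= 2.
#' @param seed integer seed (side-chain orientations).
#' @param label topology label.
#' @return a [structure3d()].
#' @export
make_toy_protein <- function(n_residues, seed = 1L, label = "toy") {
  if (!is.finite(n_residues) || n_residues < 2L) {
    stop("a toy protein needs at least 2 residues")
  }
  n_residues <- as.integer(n_residues)
  rot <- local({
    set.seed(as.integer(seed))
    stats::runif(n_residues, 0, 2 * pi)
  })
  spacing <- 6.5
  per_res <- function(i) {
    x <- (i - 1L) * spacing
    # Calphas sit on a gentle helix so no frame's fit selection is collinear
    phi <- (i - 1L) * 2.4
    ca <- c(x + 1.5, 0.8 * cos(phi), 0.8 * sin(phi))
    # side-chain donor pair rotated about the z axis through CA; the +z lift
    # keeps HG > 1.2 A from every backbone heavy atom at any rotation
    og_off <- c(0, 0.9, 1.3)
    hg_off <- c(0, 1.45, 2.13)
    rz <- matrix(c(cos(rot[i]), -sin(rot[i]), 0,
                   sin(rot[i]),  cos(rot[i]), 0,
                   0, 0, 1), 3L, 3L, byrow = TRUE)
    list(
      names  = c("N", "H", "CA", "C", "O", "OG", "HG"),
      elems  = c("N", "H", "C", "C", "O", "O", "H"),
      coords = rbind(
        c(x, 0, 0),
        c(x, -1.0, 0),
        ca,
        c(x + 3.0, 0, 0),
        c(x + 3.0, -1.2, 0),
        ca + as.vector(rz %*% og_off),
        ca + as.vector(rz %*% hg_off)
      )
    )
  }
  parts <- lapply(seq_len(n_residues), per_res)
  coords <- do.call(rbind, lapply(parts, `[[`, "coords"))
  n_per <- 7L
  atoms <- data.frame(
    serial  = seq_len(n_per * n_residues),
    name    = unlist(lapply(parts, `[[`, "names")),
    elem    = unlist(lapply(parts, `[[`, "elems")),
    resno   = rep(seq_len(n_residues), each = n_per),
    resname = "SER",
    stringsAsFactors = FALSE
  )
  structure3d(atoms, coords, label = label)
}

#' Generate a synthetic trajectory with planted statistical structure
#'
#' Frame coordinates are `base + planted shifts + i.i.d. Gaussian noise`
#' (standard deviation `sigma` per coordinate, per residue). Each
#' [planted_hbond()] then overrides the positions of its three atoms: formed
#' geometry in exactly `round(p * n_frames)` seeded frames, broken geometry in
#' the rest, anchored at the (shifted) base donor position — boundary
#' geometries are exact, never blurred by noise. An optional rigid-body
#' `drift` translates frame `t` by `(t - 1) * drift`.
#'
#' @param base a [structure3d()], e.g. from [make_toy_protein()].
#' @param n_frames number of frames, >= 1.
#' @param sigma per-residue isotropic fluctuation (Angstrom per coordinate);
#'   scalar or one value per residue, all >= 0.
#' @param shifts list of [planted_shift()].
#' @param hbonds list of [planted_hbond()].
#' @param drift optional 3-vector: per-frame rigid translation increment.
#' @param seed integer seed; identical seeds give bit-identical trajectories.
#' @return a [trajectory()].
#' @export
make_trajectory <- function(base, n_frames, sigma = 0, shifts = list(),
                            hbonds = list(), drift = NULL, seed = 1L) {
  stopifnot(inherits(base, "structure3d"))
  if (!is.finite(n_frames) || n_frames < 1L) stop("n_frames must be >= 1")
  n_frames <- as.integer(n_frames)
  res <- residue_indices(base)
  if (length(sigma) == 1L) sigma <- rep(sigma, length(res))
  if (length(sigma) != length(res)) {
    stop("sigma must be scalar or one value per residue")
  }
  if (any(sigma < 0)) stop("fluctuation amplitudes must be >= 0")

  shifted <- base$coords
  for (s in shifts) {
    if (!inherits(s, "planted_shift")) stop("shifts must be planted_shift objects")
    if (s$range[1] < min(res) || s$range[2] > max(res)) {
      stop("planted shift range ", s$range[1], "-", s$range[2],
           " lies outside the topology")
    }
    rows <- base$atoms$resno >= s$range[1] & base$atoms$resno <= s$range[2]
    shifted[rows, ] <- sweep(shifted[rows, , drop = FALSE], 2L, s$displacement, "+")
  }

  sigma_atom <- sigma[match(base$atoms$resno, res)]
  na <- nrow(base$atoms)
  set.seed(as.integer(seed))
  xyz <- array(stats::rnorm(na * 3L * n_frames, mean = 0, sd = sigma_atom),
               dim = c(na, 3L, n_frames))
  xyz <- xyz + as.vector(shifted)          # recycles over frames
  if (!is.null(drift)) {
    stopifnot(length(drift) == 3L)
    for (f in seq_len(n_frames)) {
      xyz[, , f] <- sweep(xyz[, , f], 2L, (f - 1L) * drift, "+")
    }
  }

  for (hb in hbonds) {
    if (!inherits(hb, "planted_hbond")) stop("hbonds must be planted_hbond objects")
    d_i <- resolve_atom(base, hb$donor)
    h_i <- resolve_atom(base, hb$hydrogen)
    a_i <- resolve_atom(base, hb$acceptor)
    n_on <- round(hb$occupancy * n_frames)
    on_frames <- if (n_on > 0L) sample(n_frames, n_on) else integer(0)
    u <- shifted[a_i, ] - shifted[d_i, ]
    for (f in seq_len(n_frames)) {
      geo <- if (f %in% on_frames) hb$formed else hb$broken
      pos <- hbond_geometry(shifted[d_i, ], u, geo[["dist"]], geo[["angle"]])
      if (!is.null(drift)) {
        pos <- lapply(pos, function(p) p + (f - 1L) * drift)
      }
      xyz[d_i, , f] <- pos$donor
      xyz[h_i, , f] <- pos$hydrogen
      xyz[a_i, , f] <- pos$acceptor
    }
  }
  trajectory(base, xyz)
}

resolve_atom <- function(s, ref) {
  i <- which(s$atoms$resno == ref$resno & s$atoms$name == ref$name)
  if (length(i) != 1L) {
    stop("cannot resolve atom ", ref$name, " of residue ", ref$resno,
         " (found ", length(i), " matches)")
  }
  i
}

# Place donor/H/acceptor with exact D-A distance and D-H-A angle (degrees).
# The donor stays at p_d; the acceptor lies along direction u; the hydrogen
# (D-H = 0.98 A) is placed in the D-A plane by the triangle's law of sines.
hbond_geometry <- function(p_d, u, dist, angle, r_dh = 0.98) {
  nu <- sqrt(sum(u^2))
  u <- if (nu < 1e-8) c(1, 0, 0) else u / nu
  # any vector perpendicular to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  theta <- angle * pi / 180
  sin_a <- r_dh * sin(theta) / dist       # angle at the acceptor
  sin_a <- min(1, max(-1, sin_a))
  ang_d <- pi - theta - asin(sin_a)       # angle at the donor
  h <- p_d + r_dh * (cos(ang_d) * u + sin(ang_d) * v)
  list(donor = p_d, hydrogen = h, acceptor = p_d + dist * u)
}
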