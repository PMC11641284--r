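# Independent oracles and fixture builders. Everything here is deliberately
# naive (triple loops, exhaustive recursion, grid search) and stays
# independent of the implementation paths it checks.

# --- brute-force H-bond detection: O(donors x acceptors) triple loop -------
brute_hbonds <- function(coords, donors, acceptors, criterion) {
  hits <- list()
  for (i in seq_len(nrow(donors))) {
    for (j in seq_len(nrow(acceptors))) {
      di <- donors$d_idx[i]; hi <- donors$h_idx[i]; ai <- acceptors$a_idx[j]
      if (donors$resno[i] == acceptors$resno[j]) next
      if (di == ai) next
      d <- sqrt(sum((coords[di, ] - coords[ai, ])^2))
      if (d > criterion$dist_cutoff + 1e-12) next
      v1 <- coords[di, ] - coords[hi, ]
      v2 <- coords[ai, ] - coords[hi, ]
      den <- sqrt(sum(v1^2) * sum(v2^2))
      if (den == 0) next
      ang <- acos(min(1, max(-1, sum(v1 * v2) / den))) * 180 / pi
      if (ang >= criterion$angle_cutoff - 1e-9) {
        hits[[length(hits) + 1L]] <- c(di, hi, ai)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(d_idx = integer(0), h_idx = integer(0),
                      a_idx = integer(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(d_idx = m[, 1], h_idx = m[, 2], a_idx = m[, 3])
}

hbond_key <- function(df) sort(paste(df$d_idx, df$h_idx, df$a_idx))

# --- rotation-grid RMSD oracle for planar point sets -----------------------
# For configurations lying in the z = 0 plane the optimal proper rotation is
# about z (the cross-covariance has a zero z row/column), so a fine 1D grid
# over the rotation angle plus centroid matching is an exhaustive search.
grid_rmsd_planar <- function(mobile, reference, step_deg = 0.25) {
  Pc <- sweep(mobile, 2, colMeans(mobile))
  Qc <- sweep(reference, 2, colMeans(reference))
  best <- Inf
  for (a in seq(0, 360 - step_deg, by = step_deg)) {
    t <- a * pi / 180
    R <- matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
    if (r < best) best <- r
  }
  best
}

# --- exhaustive global-alignment enumeration (affine gaps) -----------------
# Recursion over all alignments; a gap of length L costs open + L * extend,
# terminal gaps included (the global-alignment convention of the scoring the
# implementation uses). No memoisation: this enumerates the alignment space.
enum_align_score <- function(a, b, mat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- ext + if (last != "I") open else 0
      best <- max(best, -cost + rec(i + 1, j, "I"))
    }
    if (j <= m) {
      cost <- ext + if (last != "D") open else 0
      best <- max(best, -cost + rec(i, j + 1, "D"))
    }
    best
  }
  rec(1, 1, "S")
}

# --- rigid-motion helpers ---------------------------------------------------
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

rigid_transform_traj <- function(traj, R, t) {
  xyz <- traj$xyz
  for (f in seq_len(dim(xyz)[3])) {
    xyz[, , f] <- sweep(xyz[, , f] %*% t(R), 2, t, "+")
  }
  trajectory(traj$topology, xyz)
}

# --- expected RMSF under mean-structure superposition ----------------------
# Superposing each frame onto the mean projects the iid noise onto the
# orthogonal complement of the reference's 6-dim rigid-motion subspace
# (first order in sigma): E|dev_i|^2 = sigma^2 * (3 - tr(P_ii)). Returns
# tr(P_ii) per atom for the fitted selection.
rigid_leverage <- function(X) {
  N <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  B <- matrix(0, 3 * N, 6)
  for (k in 1:3) {
    v <- matrix(0, N, 3); v[, k] <- 1
    B[, k] <- as.vector(t(v))
  }
  ax <- diag(3)
  for (k in 1:3) {
    v <- t(apply(Xc, 1, function(r) cross3(ax[k, ], r)))
    B[, 3 + k] <- as.vector(t(v))
  }
  Q <- qr.Q(qr(B))
  rowSums(matrix(rowSums(Q^2), ncol = 3, byrow = TRUE))
}

# --- randomized WT/mutant fixture with planted effects ---------------------
# 30-residue toy chain, three scored regions, focal residue 29. Plants one
# conventional bond (p = 0.95) per region in the WT; the mutant breaks the
# bond (p = 0.05) in `occ_regions` and rigidly shifts `conf_regions` by
# 3-6 A away from the focal residue along the chain axis.
make_classification_case <- function(seed) {
  set.seed(seed)
  regions <- region_set(A = c(5L, 9L), B = c(13L, 17L), C = c(21L, 25L))
  conf_planted <- stats::runif(3) < 0.5
  occ_planted <- stats::runif(3) < 0.5
  sigma <- stats::runif(1, 0.05, 0.3)
  base <- make_toy_protein(30, seed = seed)
  anchor <- c(A = 6L, B = 14L, C = 22L)   # donor residue of the planted bond
  wt_bonds <- lapply(anchor, function(r) {
    planted_hbond(donor = list(r, "OG"), hydrogen = list(r, "HG"),
                  acceptor = list(r + 1L, "O"), occupancy = 0.95)
  })
  mut_bonds <- lapply(seq_along(anchor), function(k) {
    planted_hbond(donor = list(anchor[[k]], "OG"),
                  hydrogen = list(anchor[[k]], "HG"),
                  acceptor = list(anchor[[k]] + 1L, "O"),
                  occupancy = if (occ_planted[k]) 0.05 else 0.95)
  })
  shifts <- lapply(which(conf_planted), function(k) {
    planted_shift(regions[[k]][1L, ],
                  c(-(3 + 3 * stats::runif(1)), 0, 0))
  })
  wt <- make_trajectory(base, 40L, sigma = sigma, hbonds = wt_bonds,
                        seed = seed + 1L)
  mut <- make_trajectory(base, 40L, sigma = sigma, shifts = shifts,
                         hbonds = mut_bonds, seed = seed + 2L)
  list(regions = regions, focal = 29L, wt = wt, mut = mut,
       conf_planted = conf_planted, occ_planted = occ_planted)
}
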