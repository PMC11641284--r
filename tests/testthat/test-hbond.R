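test_that("donor/acceptor assignment follows the N-or-O plus attached-H rule", {
  s <- make_toy_protein(5)
  da <- assign_donors_acceptors(s)
  # every residue donates via its backbone amide (N,H) and hydroxyl (OG,HG)
  expect_setequal(unique(s$atoms$name[da$donors$d_idx]), c("N", "OG"))
  for (k in seq_len(nrow(da$donors))) {
    expect_equal(s$atoms$resno[da$donors$d_idx[k]],
                 s$atoms$resno[da$donors$h_idx[k]])
    expect_lt(sqrt(sum((s$coords[da$donors$d_idx[k], ] -
                          s$coords[da$donors$h_idx[k], ])^2)), 1.2)
  }
  # acceptors are exactly the N and O atoms; carbons never appear
  expect_setequal(unique(s$atoms$name[da$acceptors$a_idx]), c("N", "O", "OG"))
  expect_false(any(grepl("^C", s$atoms$name[da$acceptors$a_idx])))
  # carbon-bound hydrogens are not donors
  expect_false(any(s$atoms$elem[da$donors$d_idx] == "C"))
})

test_that("structures without hydrogens fail fast with advice", {
  s <- make_toy_protein(3)
  heavy <- !is_hydrogen(s$atoms$name, s$atoms$elem)
  bare <- structure3d(s$atoms[heavy, ], s$coords[heavy, ], label = "bare")
  expect_error(assign_donors_acceptors(bare), "protonated")
})

# geometry builder for boundary cases: donor at origin, acceptor along +x,
# hydrogen placed for an exact D-H-A angle
boundary_frame <- function(dist, angle_deg) {
  s <- make_toy_protein(2)
  co <- s$coords
  di <- atom_index(s, 1, "OG"); hi <- atom_index(s, 1, "HG")
  ai <- atom_index(s, 2, "O")
  g <- mutadyn:::hbond_geometry(c(0, 0, 0), c(1, 0, 0), dist, angle_deg)
  co[di, ] <- g$donor; co[hi, ] <- g$hydrogen; co[ai, ] <- g$acceptor
  # park everything else far away
  others <- setdiff(seq_len(nrow(co)), c(di, hi, ai))
  co[others, ] <- co[others, ] + 500
  list(s = s, coords = co, di = di, hi = hi, ai = ai)
}

test_that("detection respects the distance and angle cutoffs at the boundary", {
  crit <- hbond_criterion()
  cases <- list(
    list(dist = 2.8, angle = 170, hit = TRUE),
    list(dist = 3.0, angle = 170, hit = TRUE),    # boundary distance accepted
    list(dist = 3.05, angle = 170, hit = FALSE),
    list(dist = 2.8, angle = 135, hit = TRUE),    # boundary angle accepted
    list(dist = 2.8, angle = 134, hit = FALSE)
  )
  for (cs in cases) {
    bf <- boundary_frame(cs$dist, cs$angle)
    da <- assign_donors_acceptors(bf$s)
    hits <- detect_hbonds_frame(bf$coords, da$donors, da$acceptors, crit)
    found <- any(hits$d_idx == bf$di & hits$a_idx == bf$ai)
    expect_identical(found, cs$hit)
  }
})

test_that("intra-residue donor-acceptor pairs are excluded", {
  s <- make_toy_protein(2)
  co <- s$coords
  # drag residue 1's carbonyl O next to its own hydroxyl donor
  di <- atom_index(s, 1, "OG"); hi <- atom_index(s, 1, "HG")
  oi <- atom_index(s, 1, "O")
  g <- mutadyn:::hbond_geometry(co[di, ], c(0, 0, 1), 2.8, 170)
  co[hi, ] <- g$hydrogen; co[oi, ] <- g$acceptor
  da <- assign_donors_acceptors(s)
  hits <- detect_hbonds_frame(co, da$donors, da$acceptors, hbond_criterion())
  expect_false(any(hits$d_idx == di & hits$a_idx == oi))
})

test_that("detection equals the brute-force all-pairs oracle on random frames", {
  s <- make_toy_protein(7)    # 49 atoms
  da <- assign_donors_acceptors(s)
  crit <- hbond_criterion()
  set.seed(51)
  n_hit <- 0L
  for (k in 1:200) {
    co <- s$coords + matrix(stats::rnorm(length(s$coords), 0, 1.6),
                            ncol = 3)
    fast <- detect_hbonds_frame(co, da$donors, da$acceptors, crit)
    slow <- brute_hbonds(co, da$donors, da$acceptors, crit)
    expect_identical(hbond_key(fast), hbond_key(slow))
    n_hit <- n_hit + nrow(fast)
  }
  expect_gt(n_hit, 0)   # the comparison must have exercised real detections
})

test_that("loosening either cutoff never removes a detected bond", {
  s <- make_toy_protein(6)
  da <- assign_donors_acceptors(s)
  set.seed(52)
  co <- s$coords + matrix(stats::rnorm(length(s$coords), 0, 1.5), ncol = 3)
  tight <- detect_hbonds_frame(co, da$donors, da$acceptors,
                               hbond_criterion(3.0, 135))
  wider_d <- detect_hbonds_frame(co, da$donors, da$acceptors,
                                 hbond_criterion(3.6, 135))
  wider_a <- detect_hbonds_frame(co, da$donors, da$acceptors,
                                 hbond_criterion(3.0, 110))
  expect_true(all(hbond_key(tight) %in% hbond_key(wider_d)))
  expect_true(all(hbond_key(tight) %in% hbond_key(wider_a)))
})

test_that("occupancies recover planted fractions exactly on noise-free runs", {
  s <- make_toy_protein(8)
  n <- 200
  for (p in c(0, 0.25, 0.5, 0.8, 1)) {
    hb <- planted_hbond(list(3, "OG"), list(3, "HG"), list(6, "O"),
                        occupancy = p)
    traj <- make_trajectory(s, n, sigma = 0, hbonds = list(hb), seed = 6)
    tab <- occupancy_table(traj)
    if (p == 0) {
      expect_equal(nrow(tab), 0)
    } else {
      expect_equal(nrow(tab), 1)
      expect_equal(tab$occupancy, 100 * round(p * n) / n)
    }
  }
})

test_that("occupancy tables are invariant under frame permutation", {
  s <- make_toy_protein(6)
  traj <- make_trajectory(s, 30, sigma = 1.0, seed = 61)
  tab <- occupancy_table(traj)
  set.seed(62)
  shuffled <- subset_frames(traj, sample(30))
  expect_identical(occupancy_table(shuffled), tab)
})

test_that("empty trajectories and empty tables are handled", {
  s <- make_toy_protein(4)
  traj <- make_trajectory(s, 3, sigma = 0)
  tab <- occupancy_table(traj)
  expect_equal(nrow(tab), 0)
  expect_equal(nrow(conventional_set(tab)), 0)
  expect_equal(nrow(focal_bonds(tab, 2)), 0)
})

test_that("the conventional-bond cut is strictly greater than the threshold", {
  tab <- data.frame(
    donor_resno = c(1L, 2L, 3L), donor_resname = "SER", donor_name = "OG",
    h_name = "HG", acceptor_resno = c(5L, 6L, 7L), acceptor_resname = "SER",
    acceptor_name = "O", n_present = c(800L, 801L, 1000L),
    occupancy = c(80.0, 80.1, 100.0),
    stringsAsFactors = FALSE
  )
  tab$label <- bond_label(tab)
  conv <- conventional_set(tab, threshold = 80)
  expect_setequal(conv$occupancy, c(80.1, 100.0))
  expect_equal(conv$occupancy, c(100.0, 80.1))   # descending order
})

test_that("focal-residue bonds are selected and backbone-flagged", {
  tab <- data.frame(
    donor_resno = c(63L, 39L, 63L), donor_resname = c("THR", "ARG", "THR"),
    donor_name = c("N", "NH2", "OG1"), h_name = c("H", "HH22", "HG1"),
    acceptor_resno = c(50L, 35L, 99L),
    acceptor_resname = c("SER", "ASP", "ILE"),
    acceptor_name = c("O", "O", "O"), n_present = 1L,
    occupancy = c(74.2, 87.8, 94.3), stringsAsFactors = FALSE
  )
  tab$label <- bond_label(tab)
  fb <- focal_bonds(tab, 63)
  expect_equal(nrow(fb), 2)
  expect_setequal(fb$label, c("Ser50@O-Thr63@H", "Ile99@O-Thr63@HG1"))
  expect_equal(fb$focal_backbone[fb$label == "Ser50@O-Thr63@H"], TRUE)
  expect_equal(fb$focal_backbone[fb$label == "Ile99@O-Thr63@HG1"], FALSE)
  # acceptor-side focal participation also counts
  fb2 <- focal_bonds(tab, 99)
  expect_equal(fb2$label, "Ile99@O-Thr63@HG1")
  expect_true(fb2$focal_backbone)     # carbonyl O is backbone
})

test_that("bond labels follow the acceptor@O-donor@H convention and round-trip", {
  rec <- data.frame(
    donor_resno = c(63L, 75L), donor_resname = c("THR", "SER"),
    donor_name = c("OG1", "OG"), h_name = c("HG1", "HG"),
    acceptor_resno = c(99L, 98L), acceptor_resname = c("ILE", "ASP"),
    acceptor_name = c("O", "OD2"), stringsAsFactors = FALSE
  )
  expect_equal(bond_label(rec), c("Ile99@O-Thr63@HG1", "Asp98@OD2-Ser75@HG"))
  # label -> parse -> label is the identity on randomized records
  set.seed(71)
  aa3 <- c("ALA", "ARG", "ASN", "ASP", "SER", "THR", "TYR", "ILE")
  rnd <- data.frame(
    donor_resno = sample(1:157, 20, replace = TRUE),
    donor_resname = sample(aa3, 20, replace = TRUE),
    donor_name = "X",
    h_name = sample(c("H", "HG1", "HH22", "HE21"), 20, replace = TRUE),
    acceptor_resno = sample(1:157, 20, replace = TRUE),
    acceptor_resname = sample(aa3, 20, replace = TRUE),
    acceptor_name = sample(c("O", "OD2", "OG", "NE2"), 20, replace = TRUE),
    stringsAsFactors = FALSE
  )
  lab <- bond_label(rnd)
  back <- parse_bond_label(lab)
  expect_equal(back$acceptor_resno, rnd$acceptor_resno)
  expect_equal(back$donor_resno, rnd$donor_resno)
  expect_equal(back$acceptor_resname, rnd$acceptor_resname)
  expect_equal(back$donor_resname, rnd$donor_resname)
  expect_equal(back$h_name, rnd$h_name)
  expect_equal(bond_label(cbind(back, donor_name = "X")), lab)
})
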