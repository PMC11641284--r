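# Shared setup for the analysis drivers: the synthetic IL-18-like study
# system. A 157-residue toy chain stands in for mature IL-18; the wild type
# carries a set of planted hydrogen bonds whose occupancies mirror the
# published wild-type values, and two variants plant the canonical effect
# patterns (an E6K/T63A-like coupled mutant and a T63A-like single mutant).
# Every driver writes its tables under results/ and bulky trajectory files
# under scratch/.

library(mutadyn)

N_RES <- 157L          # mature-chain length
N_FRAMES <- 250L       # generated frames; the first 60% are discarded as
                       # unequilibrated, leaving 100 analysis snapshots
FOCAL <- 63L
SEED <- 20260920L

traj_dir <- file.path("scratch", "trajectories")
results_dir <- "results"
dir.create(traj_dir, recursive = TRUE, showWarnings = FALSE)
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

traj_path <- function(variant) file.path(traj_dir, paste0(variant, ".pdb"))

# planted H-bond helper: side-chain donor of residue `d` to carbonyl O of
# residue `a` (backbone amide donor when bb = TRUE)
pb <- function(d, a, p, bb = FALSE) {
  if (bb) {
    planted_hbond(list(d, "N"), list(d, "H"), list(a, "O"), occupancy = p)
  } else {
    planted_hbond(list(d, "OG"), list(d, "HG"), list(a, "O"), occupancy = p)
  }
}

# wild-type bond set: occupancies follow the published wild-type values
# (strongest cavity bond 94.3%, site-I helix bond 87.8%, the Ser50/Thr63
# backbone pair 74.2%/63.6%, the Glu85-Ile100 loop lid bonds, and the
# sheet-connecting bond near site III at 83.1%)
wt_bonds <- function() list(
  pb(63L, 99L, 0.943),          # cavity: residue-63 side chain to 99
  pb(39L, 35L, 0.878),          # site I helix bond
  pb(63L, 50L, 0.742, bb = TRUE),  # backbone pair between the two sheets
  pb(50L, 63L, 0.636, bb = TRUE),
  pb(52L, 89L, 0.86),           # loop lid bonds
  pb(73L, 86L, 0.90),
  pb(75L, 98L, 0.85),
  pb(114L, 149L, 0.831)         # sheet bond next to site III (not scored)
)

study_variants <- function() {
  base <- make_toy_protein(N_RES, seed = SEED, label = "IL18-like toy")
  res <- residue_indices(base)
  sigma_wt <- rep(0.30, N_RES)
  # coupled mutant: extra flexibility in the large site-I loop, rigidified
  # small site-I loop
  sigma_mutA <- sigma_wt
  sigma_mutA[res %in% 31:45] <- 0.45
  sigma_mutA[res %in% 130:134] <- 0.18
  list(
    base = base,
    WT = list(sigma = sigma_wt, shifts = list(), bonds = wt_bonds()),
    # E6K/T63A-like: site I large loop moves ~5 A, the Asp142-Met150 loop of
    # site III ~3.5 A; the site-I and cavity/lid bonds relax. Displacements
    # point along the chain axis away from residue 63 so the planted
    # magnitude registers in the focal distance pattern.
    MUT_A = list(
      sigma = sigma_mutA,
      shifts = list(planted_shift(c(31L, 45L), c(-5, 0, 0)),
                    planted_shift(c(142L, 150L), c(3.5, 0, 0))),
      bonds = list(
        pb(63L, 99L, 0.10), pb(39L, 35L, 0.05),
        pb(63L, 50L, 0.70, bb = TRUE), pb(50L, 63L, 0.60, bb = TRUE),
        pb(52L, 89L, 0.86), pb(73L, 86L, 0.68), pb(75L, 98L, 0.30),
        pb(114L, 149L, 0.168)
      )
    ),
    # T63A-like: site III Gly108-Lys112 loop moves, site I conformation kept;
    # the site-I helix bond and one lid bond still relax
    MUT_B = list(
      sigma = sigma_wt,
      shifts = list(planted_shift(c(108L, 112L), c(3.0, 0, 0))),
      bonds = list(
        pb(63L, 99L, 0.10), pb(39L, 35L, 0.10),
        pb(63L, 50L, 0.742, bb = TRUE), pb(50L, 63L, 0.45, bb = TRUE),
        pb(52L, 89L, 0.86), pb(73L, 86L, 0.90), pb(75L, 98L, 0.539),
        pb(114L, 149L, 0.831)
      )
    )
  )
}

VARIANTS <- c("WT", "MUT_A", "MUT_B")
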