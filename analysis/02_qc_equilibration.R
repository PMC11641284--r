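#!/usr/bin/env Rscript
# Equilibration-window quality control: per-frame Calpha RMSD of the retained
# window for every variant; the acceptance bound for the window mean is 4 A.

source(file.path("analysis", "00_common.R"))

qc <- NULL
for (v in VARIANTS) {
  traj <- read_trajectory(traj_path(v), label = v)
  win <- equilibration_window(traj, discard_fraction = 0.6, n_snapshots = 100)
  series <- rmsd_series(win)
  series$variant <- v
  qc <- rbind(qc, series)
  cat(sprintf("%s: kept %d/%d frames, mean post-window RMSD %.3f A (%s 4 A)\n",
              v, n_frames(win), n_frames(traj), mean(series$rmsd),
              if (mean(series$rmsd) < 4) "OK, <" else "WARNING, >="))
}

write_tsv(qc[, c("variant", "frame", "rmsd")],
          file.path(results_dir, "qc_rmsd.tsv"))
cat("Wrote", file.path(results_dir, "qc_rmsd.tsv"), "\n")
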