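#' Assemble the per-mutant effect summary
#'
#' One row per mutant, in input order: the conformation verdict for each
#' scored conformation region and the hydrogen-bond occupancy verdict for
#' each scored occupancy region, with the supporting evidence (the region
#' maxima of |distance change| and |occupancy change|). Regenerating the
#' summary from identical inputs is deterministic.
#'
#' @param wildtype list with elements `pattern` ([distance_pattern()]) and
#'   `records` ([occupancy_table()]) for the wild type.
#' @param mutants named list; each element a list with `pattern` and
#'   `records` for one mutant.
#' @param regions a [region_set()].
#' @param thresholds a [classification_thresholds()].
#' @param conformation_regions,occupancy_regions region labels scored for
#'   conformational change and occupancy change.
#' @param conventional_threshold wild-type occupancy cut for conventional
#'   bonds, percent.
#' @return data.frame, one row per mutant: `mutant`, `conf_<region>` verdict
#'   columns, `occ_<region>` verdict columns, then `max_dd_<region>` and
#'   `max_docc_<region>` evidence columns.
#' @export
build_summary <- function(wildtype, mutants, regions = il18_regions(),
                          thresholds = classification_thresholds(),
                          conformation_regions = c("site_I", "site_II",
                                                   "site_III"),
                          occupancy_regions = c("site_I", "site_II",
                                                "loop_85_100"),
                          conventional_threshold = 80) {
  stopifnot(length(mutants) > 0L, !is.null(names(mutants)))
  conventional <- conventional_set(wildtype$records, conventional_threshold)
  rows <- lapply(names(mutants), function(mut) {
    m <- mutants[[mut]]
    delta <- pattern_difference(m$pattern, wildtype$pattern)
    conf <- classify_conformation(delta, regions, thresholds,
                                  conformation_regions)
    occ <- classify_occupancy(wildtype$records, m$records, conventional,
                              regions, thresholds, occupancy_regions)$verdicts
    row <- data.frame(mutant = mut, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(conf))) {
      row[[paste0("conf_", conf$region[i])]] <- conf$verdict[i]
    }
    for (i in seq_len(nrow(occ))) {
      row[[paste0("occ_", occ$region[i])]] <- occ$verdict[i]
    }
    for (i in seq_len(nrow(conf))) {
      row[[paste0("max_dd_", conf$region[i])]] <- round(conf$max_abs_delta[i], 3)
    }
    for (i in seq_len(nrow(occ))) {
      row[[paste0("max_docc_", occ$region[i])]] <- round(occ$max_abs_delta_occ[i], 1)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_config <- function() {
  list(
    offset = 0L,
    focal = 63L,
    thresholds = list(conformation = 2, occupancy = 20),
    criterion = list(dist = 3.0, angle = 135),
    equilibration = list(discard_fraction = 0.6, n_snapshots = 1500L),
    conventional_threshold = 80,
    conformation_regions = c("site_I", "site_II", "site_III"),
    occupancy_regions = c("site_I", "site_II", "loop_85_100"),
    qc_rmsd_max = 4
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and checks the required fields before any computation:
#' `wildtype` (trajectory path), `mutants` (named paths), `out_dir`. Regions
#' default to [il18_regions()]; thresholds, cutoffs and the equilibration
#' window default to the conventions documented in the respective functions.
#'
#' @param config list, or path to a YAML file holding one.
#' @return the completed config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$wildtype)) stop("config is missing 'wildtype' (trajectory path)")
  if (is.null(cfg$mutants) || length(cfg$mutants) == 0L) {
    stop("config is missing 'mutants' (named trajectory paths)")
  }
  cfg$mutants <- unlist(cfg$mutants)
  if (is.null(names(cfg$mutants)) || any(!nzchar(names(cfg$mutants)))) {
    stop("every mutant trajectory must be named")
  }
  if (is.null(cfg$out_dir)) stop("config is missing 'out_dir'")
  for (p in c(cfg$wildtype, cfg$mutants)) {
    if (!file.exists(p)) stop("trajectory file not found: ", p)
  }
  cfg$regions <- if (is.null(cfg$regions)) {
    il18_regions()
  } else if (inherits(cfg$regions, "region_set")) {
    cfg$regions
  } else {
    do.call(region_set, lapply(cfg$regions, function(r) {
      matrix(as.integer(unlist(r)), ncol = 2L, byrow = TRUE)
    }))
  }
  cfg
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparative-dynamics pipeline
#'
#' Executes, for the wild type and each mutant: equilibration windowing,
#' per-frame RMSD quality control (warning when the post-window mean exceeds
#' `qc_rmsd_max`, default 4 Angstrom), Calpha RMSF, the focal-residue
#' distance pattern and the hydrogen-bond occupancy table; derives the
#' wild-type conventional-bond set; classifies each mutant's conformation and
#' occupancy changes per region; and writes all tables as TSV plus a QC log
#' under `config$out_dir`.
#'
#' @param config list or YAML path, see [validate_config()].
#' @return invisibly, a list with the config, per-variant metric tables and
#'   the summary data.frame.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  crit <- hbond_criterion(cfg$criterion$dist, cfg$criterion$angle)
  thr <- classification_thresholds(cfg$thresholds$conformation,
                                   cfg$thresholds$occupancy)
  paths <- c(WT = unname(cfg$wildtype), cfg$mutants)
  qc_lines <- character(0)
  variants <- list()
  for (v in names(paths)) {
    traj <- run_stage(paste0("read_trajectory[", v, "]"),
                      read_trajectory(paths[[v]], offset = cfg$offset,
                                      label = v))
    run_stage("validate_regions",
              validate_regions(cfg$regions, residue_indices(traj$topology)))
    win <- run_stage(paste0("equilibration_window[", v, "]"),
                     equilibration_window(traj,
                                          cfg$equilibration$discard_fraction,
                                          cfg$equilibration$n_snapshots))
    qc <- run_stage(paste0("rmsd_series[", v, "]"), rmsd_series(win))
    mean_rmsd <- mean(qc$rmsd)
    qc_lines <- c(qc_lines, sprintf(
      "%s: %d/%d frames kept, mean post-window Calpha RMSD %.3f A%s",
      v, n_frames(win), n_frames(traj), mean_rmsd,
      if (mean_rmsd > cfg$qc_rmsd_max) {
        sprintf(" [WARNING: exceeds the %.1f A acceptance]", cfg$qc_rmsd_max)
      } else ""
    ))
    if (mean_rmsd > cfg$qc_rmsd_max) {
      warning("variant ", v, ": mean post-window RMSD ",
              sprintf("%.2f", mean_rmsd), " A exceeds the ",
              cfg$qc_rmsd_max, " A acceptance")
    }
    flex <- run_stage(paste0("rmsf[", v, "]"), rmsf(win))
    pat <- run_stage(paste0("distance_pattern[", v, "]"),
                     distance_pattern(win, cfg$focal))
    occ <- run_stage(paste0("occupancy_table[", v, "]"),
                     occupancy_table(win, crit))
    occ$occupancy <- round(occ$occupancy, 1)
    write_tsv(qc, file.path(cfg$out_dir, paste0("rmsd_", v, ".tsv")))
    write_tsv(flex, file.path(cfg$out_dir, paste0("rmsf_", v, ".tsv")))
    write_tsv(as.data.frame(pat),
              file.path(cfg$out_dir, paste0("distance_pattern_", v, ".tsv")))
    write_tsv(occ, file.path(cfg$out_dir, paste0("hbond_occupancy_", v, ".tsv")))
    variants[[v]] <- list(pattern = pat, records = occ, rmsf = flex, qc = qc)
  }
  conventional <- run_stage("conventional_set",
                            conventional_set(variants$WT$records,
                                             cfg$conventional_threshold))
  write_tsv(conventional, file.path(cfg$out_dir, "conventional_bonds_WT.tsv"))
  summary <- run_stage("build_summary",
                       build_summary(variants$WT,
                                     variants[names(cfg$mutants)],
                                     cfg$regions, thr,
                                     cfg$conformation_regions,
                                     cfg$occupancy_regions,
                                     cfg$conventional_threshold))
  write_tsv(summary, file.path(cfg$out_dir, "mutation_summary.tsv"))
  writeLines(qc_lines, file.path(cfg$out_dir, "qc_log.txt"))
  invisible(list(config = cfg, variants = variants,
                 conventional = conventional, summary = summary))
}
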