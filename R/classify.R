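#' Mutation-effect classification thresholds
#'
#' A region scores a conformational change when any residue's distance-pattern
#' difference exceeds `conformation` (strictly more than 2 Angstrom by
#' default); a hydrogen-bond occupancy change when any conventional bond in
#' the region changes occupancy by strictly more than `occupancy` percentage
#' points (default 20).
#'
#' @param conformation distance threshold, Angstrom (> 0).
#' @param occupancy occupancy-change threshold, percentage points (> 0).
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(conformation = 2, occupancy = 20) {
  if (!is.finite(conformation) || conformation <= 0) {
    stop("conformation threshold must be > 0")
  }
  if (!is.finite(occupancy) || occupancy <= 0) {
    stop("occupancy threshold must be > 0")
  }
  out <- list(conformation = conformation, occupancy = occupancy)
  class(out) <- "classification_thresholds"
  out
}

verdict_symbol <- function(x) ifelse(x, "√", "X")

#' Classify conformational change per region
#'
#' A region's verdict is positive iff the maximum absolute distance-pattern
#' difference over its residues strictly exceeds the threshold ("any change
#' of more than 2 Angstrom"; the maximum, not the mean, implements the
#' existential reading).
#'
#' @param delta data.frame from [pattern_difference()] (`resno`, `delta`).
#' @param regions a [region_set()]; only `region_labels` entries are scored.
#' @param thresholds a [classification_thresholds()].
#' @param region_labels regions to score (default: all in `regions`).
#' @return data.frame with `region`, `max_abs_delta`, `changed` (logical),
#'   `verdict` ("√"/"X").
#' @export
classify_conformation <- function(delta, regions,
                                  thresholds = classification_thresholds(),
                                  region_labels = names(regions)) {
  rows <- lapply(region_labels, function(lab) {
    res <- region_residues(regions, lab)
    miss <- setdiff(res, delta$resno)
    if (length(miss) > 0L) {
      stop("region '", lab, "' residue ", miss[1L],
           " is missing from the distance-pattern difference")
    }
    mx <- max(abs(delta$delta[delta$resno %in% res]))
    data.frame(region = lab, max_abs_delta = mx,
               changed = mx > thresholds$conformation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$verdict <- verdict_symbol(out$changed)
  out
}

# Occupancy of each conventional bond looked up in another variant's table;
# bonds absent from that table count as occupancy 0.
match_occupancy <- function(conventional, records) {
  key <- function(df) paste(df$donor_resno, df$donor_name, df$h_name,
                            df$acceptor_resno, df$acceptor_name)
  i <- match(key(conventional), key(records))
  ifelse(is.na(i), 0, records$occupancy[i])
}

#' Classify hydrogen-bond occupancy change per region
#'
#' For every conventional wild-type bond, the occupancy change to the mutant
#' (bonds absent from the mutant table count as 0) is attributed to each
#' region containing the donor or acceptor residue; a region's verdict is
#' positive iff any of its bonds changes by strictly more than the threshold.
#' Bonds matching no scored region are reported under region `"other"` but
#' carry no verdict.
#'
#' @param wildtype_records,mutant_records occupancy tables
#'   ([occupancy_table()]).
#' @param conventional result of [conventional_set()] on the wild type.
#' @param regions a [region_set()].
#' @param thresholds a [classification_thresholds()].
#' @param region_labels regions to score (default: all in `regions`).
#' @return list with `verdicts` (data.frame: `region`, `max_abs_delta_occ`,
#'   `changed`, `verdict`) and `bonds` (per-bond table with wild-type and
#'   mutant occupancies, change and region assignment).
#' @export
classify_occupancy <- function(wildtype_records, mutant_records, conventional,
                               regions,
                               thresholds = classification_thresholds(),
                               region_labels = names(regions)) {
  occ_wt <- conventional$occupancy
  occ_mut <- match_occupancy(conventional, mutant_records)
  delta <- occ_mut - occ_wt
  region_of_bond <- lapply(seq_len(nrow(conventional)), function(i) {
    in_reg <- vapply(region_labels, function(lab) {
      res <- region_residues(regions, lab)
      conventional$donor_resno[i] %in% res ||
        conventional$acceptor_resno[i] %in% res
    }, logical(1))
    if (any(in_reg)) region_labels[in_reg] else "other"
  })
  bonds <- data.frame(
    label = if (nrow(conventional)) conventional$label else character(0),
    occupancy_wt = occ_wt,
    occupancy_mut = occ_mut,
    delta_occupancy = delta,
    regions = vapply(region_of_bond, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  rows <- lapply(region_labels, function(lab) {
    in_lab <- vapply(region_of_bond, function(r) lab %in% r, logical(1))
    mx <- if (any(in_lab)) max(abs(delta[in_lab])) else 0
    data.frame(region = lab, max_abs_delta_occ = mx,
               changed = mx > thresholds$occupancy,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  verdicts$verdict <- verdict_symbol(verdicts$changed)
  list(verdicts = verdicts, bonds = bonds)
}
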